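#' Construct a knot vector for a spline basis
#'
#' Knots delimit the polynomial pieces of a cubic regression spline. The
#' default rule places knots at the empirical quantiles of the covariate
#' (including the minimum and maximum), so each segment holds roughly the
#' same number of observations; the `uniform` rule spaces them evenly over
#' the covariate range; `explicit` accepts a user-supplied sequence.
#'
#' @param x numeric covariate values the basis will be built for.
#' @param n_knots number of knots (>= 4 for a cubic basis).
#' @param rule placement rule: `"quantile"`, `"uniform"` or `"explicit"`.
#' @param values explicit knot positions (only with `rule = "explicit"`).
#' @return an object of class `hg_knots`: a strictly increasing numeric
#'   vector with a `rule` attribute.
#' @examples
#' make_knots(seq(0, 1, length.out = 101), 5)          # 0, .25, .5, .75, 1
#' make_knots(runif(50), 4, rule = "uniform")
#' @export
make_knots <- function(x, n_knots, rule = c("quantile", "uniform", "explicit"),
                       values = NULL) {
  rule <- match.arg(rule)
  if (rule == "explicit") {
    k <- as.numeric(values)
    if (is.null(values) || any(diff(k) <= 0))
      stop("explicit knots must be a strictly increasing numeric sequence")
    return(structure(k, rule = rule, class = "hg_knots"))
  }
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L)
    stop("degenerate covariate: fewer than 2 distinct finite values")
  if (n_knots < 4L) stop("n_knots must be at least 4 for a cubic basis")
  k <- switch(rule,
    quantile = as.numeric(stats::quantile(x, probs = seq(0, 1, length.out = n_knots),
                                          names = FALSE, type = 7)),
    uniform  = seq(min(x), max(x), length.out = n_knots))
  if (anyDuplicated(k)) {
    # heavily tied data: collapse duplicated quantiles and shrink the basis
    k <- unique(k)
    warning(sprintf("duplicate knots collapsed: %d requested, %d retained",
                    n_knots, length(k)))
    if (length(k) < 4L)
      stop("fewer than 4 distinct knots after collapsing ties")
  }
  structure(k, rule = rule, class = "hg_knots")
}

.knot_values <- function(knots) {
  k <- as.numeric(knots)
  if (length(k) < 4L) stop("at least 4 knots are required")
  if (any(diff(k) <= 0)) stop("invalid knots: must be strictly increasing")
  k
}
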