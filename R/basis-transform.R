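# Identifiability and adaptive-penalty transforms of a smooth basis.

#' Center a smooth basis (sum-to-zero constraint)
#'
#' Reparameterizes the basis so every represented function sums to zero over
#' the supplied covariate values. With a centered smooth alongside a model
#' intercept the intercept absorbs the mean of the response, which is what
#' makes "alpha is the mean pulse pressure" hold in the pulse-pressure
#' model. The penalty is transformed consistently and the basis dimension
#' drops by one.
#'
#' @param basis an `hg_basis`.
#' @param x_values the covariate values the model will be fitted on (a
#'   two-column object for tensor smooths).
#' @return a centered `hg_basis` wrapping the original.
#' @export
apply_centering <- function(basis, x_values) {
  stopifnot(inherits(basis, "hg_basis"))
  m <- colMeans(basis_matrix(basis, x_values))
  Z <- qr.Q(qr(matrix(m, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  pen <- lapply(basis$penalties, function(S) {
    St <- crossprod(Z, S) %*% Z
    (St + t(St)) / 2
  })
  new_hg_basis(basis$kind, basis$knots, basis$df - 1L, pen, setup = NULL,
               centering = TRUE, adaptive_order = basis$adaptive_order,
               parent = basis, Z = Z, margins = basis$margins)
}

#' Split a curvature penalty for adaptive smoothing
#'
#' Replaces a univariate smooth's single curvature penalty with
#' `n_penalty_bases` partial penalties, each weighting the squared-second-
#' derivative integrand by a piecewise-linear bump over a sub-range of the
#' covariate (a hat-function partition of unity; wrapped around the period
#' for a cyclic basis). REML can then assign each region its own smoothing
#' parameter, letting the fit follow a sharp transition -- such as the switch
#' from inspiration to expiration -- while staying very smooth elsewhere.
#' At equal weights the partial penalties sum to the ordinary penalty.
#'
#' @param basis a univariate, uncentered `hg_basis`.
#' @param n_penalty_bases number of penalty sub-bases (1 returns the basis
#'   unchanged).
#' @return an `hg_basis` with `n_penalty_bases` penalty matrices.
#' @export
adaptive_penalty <- function(basis, n_penalty_bases = 5L) {
  stopifnot(inherits(basis, "hg_basis"))
  m <- as.integer(n_penalty_bases)
  if (m <= 1L) return(basis)
  if (basis$kind == "tensor") stop("adaptive penalties are univariate only")
  if (!is.null(basis$parent))
    stop("apply adaptive_penalty before centering")
  k <- if (is.list(basis$knots)) stop("univariate basis required") else basis$knots
  a <- k[1]; b <- k[length(k)]
  cyc <- basis$kind == "cyclic_cubic"
  if (cyc) {
    period <- b - a
    nodes <- a + (seq_len(m) - 1) * period / m
    width <- period / m
    wfun <- function(x, l) {
      d <- abs(((x - nodes[l] + period / 2) %% period) - period / 2)
      pmax(0, 1 - d / width)
    }
  } else {
    nodes <- seq(a, b, length.out = m)
    width <- (b - a) / (m - 1)
    wfun <- function(x, l) pmax(0, 1 - abs(x - nodes[l]) / width)
  }
  # quadrature nodes: split each knot interval at the hat-function breaks;
  # 3-point Gauss per piece is exact (integrand is cubic in x per piece)
  brk <- sort(unique(c(k, nodes[nodes > a & nodes < b])))
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gw <- c(5, 8, 5) / 9
  pens <- rep(list(matrix(0, basis$df, basis$df)), m)
  for (i in seq_len(length(brk) - 1)) {
    lo <- brk[i]; hi <- brk[i + 1]
    xs <- (lo + hi) / 2 + (hi - lo) / 2 * gp
    G2 <- basis_matrix(basis, xs, deriv = 2)
    for (g in seq_along(xs)) {
      outer_g <- tcrossprod(G2[g, ])
      wq <- gw[g] * (hi - lo) / 2
      for (l in seq_len(m)) {
        wl <- wfun(xs[g], l)
        if (wl > 0) pens[[l]] <- pens[[l]] + wq * wl * outer_g
      }
    }
  }
  pens <- lapply(pens, function(S) (S + t(S)) / 2)
  out <- basis
  out$penalties <- pens
  out$adaptive_order <- m
  out
}
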