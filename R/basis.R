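# Spline bases with exact curvature penalties.
#
# Natural cubic and cyclic cubic smooths use the cardinal (value-at-knot)
# parameterization: the j-th coefficient is the function value at knot j, and
# C2 continuity is implicit in the interpolation formulas. The unconstrained
# cubic spline uses a B-spline parameterization. All penalties are the exact
# integral of the squared second derivative over the knot range (one period
# for the cyclic basis).

new_hg_basis <- function(kind, knots, df, penalties, setup,
                         centering = FALSE, adaptive_order = 1L,
                         parent = NULL, Z = NULL, margins = NULL) {
  structure(list(kind = kind, knots = knots, df = df, penalties = penalties,
                 setup = setup, centering = centering,
                 adaptive_order = adaptive_order, parent = parent, Z = Z,
                 margins = margins),
            class = "hg_basis")
}

#' @export
print.hg_basis <- function(x, ...) {
  cat(sprintf("<hg_basis> kind=%s, df=%d, penalties=%d%s%s\n", x$kind, x$df,
              length(x$penalties),
              if (x$centering) ", centered" else "",
              if (x$adaptive_order > 1L)
                sprintf(", adaptive(%d)", x$adaptive_order) else ""))
  invisible(x)
}

## ---- natural cubic (cardinal form) ----------------------------------------

# Matrices mapping knot values to second derivatives at the knots, and the
# exact curvature penalty S = D' B^-1 D (B is the Gram matrix of the hat
# functions interpolating f'' between knots).
.cr_setup <- function(k) {
  K <- length(k); h <- diff(k)
  B <- matrix(0, K - 2, K - 2); D <- matrix(0, K - 2, K)
  for (i in seq_len(K - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < K - 2) B[i, i + 1] <- B[i + 1, i] <- h[i + 1] / 6
  }
  Fm <- solve(B, D)                      # gamma_interior = Fm %*% beta
  S <- crossprod(D, Fm)
  list(k = k, h = h, G = rbind(0, Fm, 0), S = (S + t(S)) / 2)
}

# Interpolation weights within [k_j, k_j+1]; rows of the model matrix are
# a-weights on knot values plus c-weights on knot second derivatives.
.cardinal_rows <- function(x, j, jv, jp, k, h, G, df, deriv) {
  n <- length(x)
  xl <- k[j]; xr <- k[j + 1]; hj <- h[j]
  X <- matrix(0, n, df)
  idx <- seq_len(n)
  if (deriv == 0) {
    am <- (xr - x) / hj; ap <- (x - xl) / hj
    cm <- ((xr - x)^3 / hj - hj * (xr - x)) / 6
    cp <- ((x - xl)^3 / hj - hj * (x - xl)) / 6
  } else if (deriv == 1) {
    am <- -1 / hj; ap <- 1 / hj
    cm <- -(3 * (xr - x)^2 / hj - hj) / 6
    cp <- (3 * (x - xl)^2 / hj - hj) / 6
  } else {
    am <- cm <- NULL
    a0m <- (xr - x) / hj; a0p <- (x - xl) / hj
  }
  if (deriv < 2) {
    X[cbind(idx, jv)] <- X[cbind(idx, jv)] + am
    X[cbind(idx, jp)] <- X[cbind(idx, jp)] + ap
    X <- X + cm * G[j, , drop = FALSE] + cp * G[j + 1, , drop = FALSE]
  } else {
    X <- a0m * G[j, , drop = FALSE] + a0p * G[j + 1, , drop = FALSE]
  }
  X
}

.cr_eval <- function(setup, x, deriv = 0) {
  k <- setup$k; K <- length(k); df <- K
  n <- length(x); X <- matrix(0, n, df)
  lo <- x < k[1]; hi <- x > k[K]; mid <- !(lo | hi)
  if (any(mid)) {
    xm <- x[mid]
    j <- pmin.int(pmax.int(findInterval(xm, k), 1L), K - 1L)
    X[mid, ] <- .cardinal_rows(xm, j, j, j + 1L, k, setup$h, setup$G, df, deriv)
  }
  # natural spline: linear extrapolation beyond the outer knots
  for (side in c("lo", "hi")) {
    sel <- if (side == "lo") lo else hi
    if (!any(sel)) next
    x0 <- if (side == "lo") k[1] else k[K]
    j <- if (side == "lo") 1L else K - 1L
    v0 <- .cardinal_rows(x0, j, j, j + 1L, k, setup$h, setup$G, df, 0)
    s0 <- .cardinal_rows(x0, j, j, j + 1L, k, setup$h, setup$G, df, 1)
    if (deriv == 0) {
      X[sel, ] <- rep(1, sum(sel)) %o% drop(v0) + (x[sel] - x0) %o% drop(s0)
    } else if (deriv == 1) {
      X[sel, ] <- rep(1, sum(sel)) %o% drop(s0)
    } # deriv 2: zero rows
  }
  X
}

## ---- cyclic cubic ----------------------------------------------------------

.cc_setup <- function(k) {
  K <- length(k); n <- K - 1L; h <- diff(k)
  hm <- c(h[n], h[-n])                   # hm[i] = width of interval ending at knot i
  B <- matrix(0, n, n); D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1L) n else i - 1L
    B[i, i] <- (hm[i] + h[i]) / 3
    B[i, ip] <- B[i, ip] + h[i] / 6
    B[i, im] <- B[i, im] + hm[i] / 6
    D[i, i] <- -1 / hm[i] - 1 / h[i]
    D[i, im] <- D[i, im] + 1 / hm[i]
    D[i, ip] <- D[i, ip] + 1 / h[i]
  }
  G <- solve(B, D)                       # second derivatives at knots 1..n
  S <- crossprod(D, G)
  list(k = k, h = h, G = G, S = (S + t(S)) / 2, period = k[K] - k[1])
}

.cc_eval <- function(setup, x, deriv = 0) {
  k <- setup$k; K <- length(k); n <- K - 1L
  xw <- k[1] + (x - k[1]) %% setup$period
  j <- pmin.int(pmax.int(findInterval(xw, k), 1L), n)
  jp <- ifelse(j == n, 1L, j + 1L)       # coefficient index of right knot
  hj <- setup$h[j]; xl <- k[j]; xr <- k[j + 1]
  X <- matrix(0, length(x), n)
  idx <- seq_along(x)
  if (deriv == 0) {
    am <- (xr - xw) / hj; ap <- (xw - xl) / hj
    cm <- ((xr - xw)^3 / hj - hj * (xr - xw)) / 6
    cp <- ((xw - xl)^3 / hj - hj * (xw - xl)) / 6
  } else if (deriv == 1) {
    am <- rep(-1, length(x)) / hj; ap <- 1 / hj
    cm <- -(3 * (xr - xw)^2 / hj - hj) / 6
    cp <- (3 * (xw - xl)^2 / hj - hj) / 6
  } else {
    am <- ap <- NULL
    a0m <- (xr - xw) / hj; a0p <- (xw - xl) / hj
  }
  if (deriv < 2) {
    X[cbind(idx, j)] <- X[cbind(idx, j)] + am
    X[cbind(idx, jp)] <- X[cbind(idx, jp)] + ap
    X <- X + cm * setup$G[j, , drop = FALSE] + cp * setup$G[jp, , drop = FALSE]
  } else {
    X <- a0m * setup$G[j, , drop = FALSE] + a0p * setup$G[jp, , drop = FALSE]
  }
  X
}

## ---- unconstrained cubic (B-spline form) ----------------------------------

.bs_setup <- function(k) {
  K <- length(k); df <- K + 2L
  aug <- c(rep(k[1], 4), k[-c(1, K)], rep(k[K], 4))
  # exact penalty: 2nd derivative of a cubic is linear per interval, so the
  # integrand of f''^2 is quadratic and 2-point Gauss quadrature is exact
  gp <- c(-1, 1) / sqrt(3)
  S <- matrix(0, df, df)
  for (i in seq_len(K - 1)) {
    a <- k[i]; b <- k[i + 1]
    xs <- (a + b) / 2 + (b - a) / 2 * gp
    G2 <- splines::splineDesign(aug, xs, ord = 4, derivs = rep(2L, 2))
    S <- S + (b - a) / 2 * crossprod(G2)
  }
  list(k = k, aug = aug, df = df, S = (S + t(S)) / 2)
}

.bs_eval <- function(setup, x, deriv = 0) {
  k <- setup$k; K <- length(k)
  out <- x < k[1] | x > k[K]
  if (any(out)) {
    warning(sprintf("%d covariate value(s) outside the knot range clamped to the boundary",
                    sum(out)))
    x <- pmin.int(pmax.int(x, k[1]), k[K])
  }
  splines::splineDesign(setup$aug, x, ord = 4, derivs = rep(deriv, length(x)))
}

## ---- public constructors ---------------------------------------------------

#' Cubic regression spline basis
#'
#' Piecewise third-order polynomials with matching value, first and second
#' derivative at every interior knot. With `natural = TRUE` the second and
#' third derivatives at the outer knots are fixed to zero, making the
#' function linear beyond them (and the basis is evaluated by linear
#' extrapolation there); without the natural constraint evaluation outside
#' the knot range is clamped to the boundary, with a warning.
#'
#' @param knots an [make_knots()] result or a strictly increasing numeric
#'   vector of at least 4 knots.
#' @param natural logical; constrain to a natural cubic spline.
#' @return an object of class `hg_basis` with `df` basis functions
#'   (`length(knots)` when natural, `length(knots) + 2` otherwise) and a
#'   single curvature penalty matrix.
#' @seealso [cyclic_cubic_basis()], [tensor_smooth()], [penalty_matrix()]
#' @export
cubic_basis <- function(knots, natural = TRUE) {
  k <- .knot_values(knots)
  if (natural) {
    s <- .cr_setup(k)
    new_hg_basis("natural_cubic", k, length(k), list(s$S), s)
  } else {
    s <- .bs_setup(k)
    new_hg_basis("cubic", k, s$df, list(s$S), s)
  }
}

#' Cyclic cubic regression spline basis
#'
#' A cubic spline on one period whose first and last knots are identified:
#' value, first and second derivative match at the period boundary, so the
#' fitted function continues smoothly from the end of one cycle into the
#' next. Covariate values are wrapped into the period by the modulo
#' operation, never rejected. With `K` nominal knots the basis has `K - 1`
#' coefficients (the wrapped knot is not a free value).
#'
#' @inheritParams cubic_basis
#' @return an `hg_basis` with `length(knots) - 1` basis functions and one
#'   curvature penalty (integral of squared second derivative over one
#'   period); its null space is the constant function only.
#' @export
cyclic_cubic_basis <- function(knots) {
  k <- .knot_values(knots)
  s <- .cc_setup(k)
  new_hg_basis("cyclic_cubic", k, length(k) - 1L, list(s$S), s)
}

#' Tensor-product interaction smooth
#'
#' Builds a bivariate smooth from two marginal bases: the model matrix row at
#' `(x, y)` is the Kronecker product of the marginal rows, and the smooth
#' carries two penalties -- roughness in the x-direction (`S_x %x% I`) and in
#' the y-direction (`I %x% S_y`) -- each with its own smoothing parameter.
#' Periodicity of a cyclic margin is inherited. Column order: the x-margin
#' index varies slowest.
#'
#' @param margin_x,margin_y univariate `hg_basis` objects (possibly
#'   centered), e.g. a non-cyclic cardiac-cycle margin and a cyclic
#'   respiratory-cycle margin.
#' @return an `hg_basis` of kind `"tensor"` with `df = df_x * df_y` and two
#'   penalty matrices.
#' @export
tensor_smooth <- function(margin_x, margin_y) {
  stopifnot(inherits(margin_x, "hg_basis"), inherits(margin_y, "hg_basis"))
  if (margin_x$kind == "tensor" || margin_y$kind == "tensor")
    stop("tensor margins must be univariate bases")
  dx <- margin_x$df; dy <- margin_y$df
  Sx <- Reduce(`+`, margin_x$penalties)
  Sy <- Reduce(`+`, margin_y$penalties)
  pen <- list(Sx %x% diag(dy), diag(dx) %x% Sy)
  new_hg_basis("tensor", list(x = margin_x$knots, y = margin_y$knots),
               dx * dy, pen, setup = NULL,
               margins = list(x = margin_x, y = margin_y))
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a spline basis (model matrix)
#'
#' @param basis an `hg_basis`.
#' @param x numeric vector of covariate values; for a tensor smooth a
#'   two-column matrix or data frame `(x, y)`.
#' @param deriv derivative order 0, 1 or 2 (univariate bases only).
#' @return matrix with one row per evaluation point and `basis$df` columns.
#' @export
basis_matrix <- function(basis, x, deriv = 0) {
  stopifnot(inherits(basis, "hg_basis"))
  if (!is.null(basis$parent)) {          # centered reparameterization
    return(basis_matrix(basis$parent, x, deriv) %*% basis$Z)
  }
  if (basis$kind == "tensor") {
    if (deriv != 0) stop("derivatives are not available for tensor smooths")
    x <- as.matrix(x)
    if (ncol(x) != 2) stop("a tensor smooth needs two covariate columns")
    Xx <- basis_matrix(basis$margins$x, x[, 1])
    Xy <- basis_matrix(basis$margins$y, x[, 2])
    dx <- ncol(Xx); dy <- ncol(Xy)
    return(Xx[, rep(seq_len(dx), each = dy), drop = FALSE] *
           Xy[, rep(seq_len(dy), dx), drop = FALSE])
  }
  x <- as.numeric(x)
  switch(basis$kind,
    natural_cubic = .cr_eval(basis$setup, x, deriv),
    cyclic_cubic  = .cc_eval(basis$setup, x, deriv),
    cubic         = .bs_eval(basis$setup, x, deriv),
    stop("unknown basis kind"))
}

#' Curvature penalty of a smooth basis
#'
#' Returns the matrix `S` such that `t(beta) %*% S %*% beta` equals the
#' integral of the squared second derivative of the represented function over
#' the knot range (one period for a cyclic basis). Tensor and adaptive
#' smooths carry several penalties and return the full list.
#'
#' @param basis an `hg_basis`.
#' @return a symmetric positive semi-definite matrix, or a list of them when
#'   the basis has more than one penalty.
#' @export
penalty_matrix <- function(basis) {
  stopifnot(inherits(basis, "hg_basis"))
  if (length(basis$penalties) == 1L) basis$penalties[[1]] else basis$penalties
}
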