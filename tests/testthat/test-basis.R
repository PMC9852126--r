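# Span, continuity, periodicity and penalty contracts of the spline bases.

unpen_fit <- function(basis, x, y) {
  X <- basis_matrix(basis, x)
  qr.solve(X, y)
}

test_that("every basis kind reproduces functions inside its span exactly", {
  set.seed(3)
  x <- sort(runif(200))
  knots <- make_knots(x, 8)
  for (b in list(cubic_basis(knots), cubic_basis(knots, natural = FALSE))) {
    beta <- unpen_fit(b, x, 2 * x + 1)         # linear lies in every span
    expect_equal(as.numeric(basis_matrix(b, x) %*% beta), 2 * x + 1,
                 tolerance = 1e-10)
  }
  # a cyclic spline reproduces a constant and any cyclic-spline function
  bc <- cyclic_cubic_basis(seq(0, 1, length.out = 8))
  beta <- unpen_fit(bc, x, rep(3.5, length(x)))
  expect_equal(as.numeric(basis_matrix(bc, x) %*% beta), rep(3.5, length(x)),
               tolerance = 1e-10)
  set.seed(4)
  btrue <- rnorm(bc$df)
  ytrue <- as.numeric(basis_matrix(bc, x) %*% btrue)
  expect_equal(as.numeric(basis_matrix(bc, x) %*% unpen_fit(bc, x, ytrue)),
               ytrue, tolerance = 1e-10)
})

test_that("fitted splines are C2 at interior knots (finite-difference check)", {
  set.seed(5)
  x <- sort(runif(300))
  y <- sin(2 * pi * x) + rnorm(300, 0, 0.1)
  for (b in list(cubic_basis(make_knots(x, 9)),
                 cubic_basis(make_knots(x, 9), natural = FALSE),
                 cyclic_cubic_basis(seq(0, 1, length.out = 9)))) {
    beta <- qr.solve(basis_matrix(b, x), y)
    kv <- if (is.list(b$knots)) b$knots$x else b$knots
    interior <- kv[-c(1, length(kv))]
    curv_scale <- max(abs(basis_matrix(b, interior, deriv = 2) %*% beta), 1)
    h <- 1e-4
    for (kx in interior) {
      for (d in 0:1) {
        fl <- fd_deriv(b, beta, kx - 2 * h, order = max(d, 1))
        fr <- fd_deriv(b, beta, kx + 2 * h, order = max(d, 1))
        if (d == 0) {
          expect_lt(abs(as.numeric(basis_matrix(b, kx - 1e-9) %*% beta) -
                        as.numeric(basis_matrix(b, kx + 1e-9) %*% beta)), 1e-6)
        } else {
          expect_lt(abs(fl - fr) / curv_scale, 1e-2)
        }
      }
      # 2nd derivative continuity, evaluated analytically just off the knot
      d2l <- as.numeric(basis_matrix(b, kx - 1e-8, deriv = 2) %*% beta)
      d2r <- as.numeric(basis_matrix(b, kx + 1e-8, deriv = 2) %*% beta)
      expect_lt(abs(d2l - d2r) / curv_scale, 1e-6)
    }
  }
})

test_that("natural constraint zeroes curvature at the outer knots and extrapolates linearly", {
  set.seed(6)
  x <- sort(runif(150))
  b <- cubic_basis(make_knots(x, 8))
  beta <- qr.solve(basis_matrix(b, x), sin(2 * pi * x))
  kv <- b$knots
  expect_lt(abs(as.numeric(basis_matrix(b, kv[1], deriv = 2) %*% beta)), 1e-8)
  expect_lt(abs(as.numeric(basis_matrix(b, kv[length(kv)], deriv = 2) %*% beta)), 1e-8)
  # beyond the outer knot the function continues on its tangent
  f <- function(z) as.numeric(basis_matrix(b, z) %*% beta)
  sl <- as.numeric(basis_matrix(b, kv[1], deriv = 1) %*% beta)
  expect_equal(f(kv[1] - 0.3), f(kv[1]) - 0.3 * sl, tolerance = 1e-10)
  # the unconstrained cubic clamps outside its range, with a warning
  b2 <- cubic_basis(make_knots(x, 8), natural = FALSE)
  beta2 <- qr.solve(basis_matrix(b2, x), sin(2 * pi * x))
  expect_warning(v <- basis_matrix(b2, max(x) + 1), "clamped")
  expect_equal(as.numeric(v %*% beta2),
               as.numeric(basis_matrix(b2, max(kv)) %*% beta2))
})

test_that("cyclic basis is periodic through the 2nd derivative and wraps inputs", {
  bc <- cyclic_cubic_basis(seq(0, 1, length.out = 8))
  expect_identical(bc$df, 7L)            # 8 nominal knots, 7 effective
  set.seed(7)
  beta <- rnorm(bc$df)
  for (d in 0:2) {
    e0 <- as.numeric(basis_matrix(bc, 0, deriv = d) %*% beta)
    e1 <- as.numeric(basis_matrix(bc, 1, deriv = d) %*% beta)
    expect_equal(e0, e1, tolerance = 1e-9)
  }
  x <- runif(30)
  expect_equal(basis_matrix(bc, x), basis_matrix(bc, x + 3), tolerance = 1e-12)
  expect_equal(basis_matrix(bc, x), basis_matrix(bc, x - 2), tolerance = 1e-12)
  # dense fit to a cyclic target
  xg <- seq(0, 1, length.out = 400)
  b12 <- cyclic_cubic_basis(seq(0, 1, length.out = 12))
  beta <- qr.solve(basis_matrix(b12, xg), cos(2 * pi * xg))
  expect_lt(max(abs(basis_matrix(b12, xg) %*% beta - cos(2 * pi * xg))), 0.01)
})

test_that("penalty equals the integral of squared curvature (quadrature oracle)", {
  set.seed(8)
  kk <- sort(runif(8))
  bases <- list(cubic_basis(kk), cubic_basis(kk, natural = FALSE),
                cyclic_cubic_basis(seq(0, 1, length.out = 8)))
  for (b in bases) {
    S <- penalty_matrix(b)
    expect_equal(S, t(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-8 * max(ev))   # PSD
    lo <- if (b$kind == "cyclic_cubic") 0 else min(kk)
    hi <- if (b$kind == "cyclic_cubic") 1 else max(kk)
    for (r in 1:5) {
      beta <- rnorm(b$df)
      expect_equal(drop(t(beta) %*% S %*% beta),
                   quad_curvature(b, beta, lo, hi), tolerance = 1e-6)
    }
  }
  # null space dimensions: constant+linear for natural cubic, constant for cyclic
  nulldim <- function(S) sum(eigen(S, TRUE, TRUE)$values < 1e-9 * max(eigen(S, TRUE, TRUE)$values))
  expect_identical(nulldim(penalty_matrix(bases[[1]])), 2L)
  expect_identical(nulldim(penalty_matrix(bases[[3]])), 1L)
  # straight line incurs zero penalty
  beta_lin <- 2 * kk + 1
  expect_lt(abs(drop(t(beta_lin) %*% penalty_matrix(bases[[1]]) %*% beta_lin)), 1e-6)
})

test_that("tensor smooth inherits periodicity, fits separable surfaces, and has marginal penalties", {
  bx <- cubic_basis(seq(0, 1, length.out = 7))
  by <- cyclic_cubic_basis(seq(0, 1, length.out = 8))
  tb <- tensor_smooth(bx, by)
  expect_identical(tb$df, bx$df * by$df)
  expect_length(tb$penalties, 2L)
  pts <- cbind(runif(20), runif(20))
  expect_equal(basis_matrix(tb, pts), basis_matrix(tb, cbind(pts[, 1], pts[, 2] + 1)),
               tolerance = 1e-12)
  # surface z = sin(2 pi y) * x on a 40 x 40 grid
  g <- expand.grid(x = seq(0, 1, length.out = 40), y = seq(0, 1, length.out = 40))
  z <- sin(2 * pi * g$y) * g$x
  X <- basis_matrix(tb, as.matrix(g))
  beta <- qr.solve(X, z)
  expect_lt(sqrt(mean((X %*% beta - z)^2)), 0.02)
  # coefficient array constant in one margin has zero roughness that way
  beta_cx <- rep(1, bx$df) %x% rnorm(by$df)    # constant in x
  expect_lt(drop(t(beta_cx) %*% tb$penalties[[1]] %*% beta_cx) /
              max(drop(t(beta_cx) %*% tb$penalties[[2]] %*% beta_cx), 1e-12), 1e-8)
})

test_that("centering makes columns sum to zero and leaves fitted values unchanged", {
  set.seed(9)
  x <- runif(120)
  b <- cubic_basis(make_knots(x, 8))
  bc <- apply_centering(b, x)
  expect_identical(bc$df, b$df - 1L)
  expect_lt(max(abs(colSums(basis_matrix(bc, x)))), 1e-10)
  # constant response: intercept takes it all, smooth stays at zero
  y <- rep(4.2, 120)
  des <- hg_design(smooth_term("fx", "x", bc))
  fit <- fit_penalized(des, data.frame(x = x), y, lambdas = 1)
  expect_equal(unname(coef(fit)[1]), 4.2, tolerance = 1e-8)
  expect_lt(max(abs(fitted(fit) - 4.2)), 1e-8)
  # centered and uncentered parameterizations give the same penalized fit
  # (the constant is in the uncentered span, so that model needs no intercept)
  y2 <- sin(2 * pi * x) + rnorm(120, 0, 0.2)
  X <- basis_matrix(b, x); Xc <- cbind(1, basis_matrix(bc, x))
  lam <- 0.37
  pad <- function(S) rbind(0, cbind(0, S))
  f1 <- X %*% solve(crossprod(X) + lam * penalty_matrix(b), crossprod(X, y2))
  f2 <- Xc %*% solve(crossprod(Xc) + lam * pad(penalty_matrix(bc)), crossprod(Xc, y2))
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-8)
})

test_that("adaptive penalties partition the curvature integral", {
  kk <- seq(0, 1, length.out = 10)
  for (b0 in list(cubic_basis(kk), cyclic_cubic_basis(kk))) {
    ba <- adaptive_penalty(b0, 5)
    expect_length(ba$penalties, 5L)
    total <- Reduce(`+`, ba$penalties)
    expect_equal(total, penalty_matrix(b0), tolerance = 1e-8)
    for (S in ba$penalties) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_true(min(ev) > -1e-8 * max(abs(ev)))
    }
  }
  expect_identical(adaptive_penalty(cubic_basis(kk), 1), cubic_basis(kk))
})

test_that("an adaptive smooth tracks a flat-then-sigmoid signal at least as well as an ordinary one", {
  k <- seq(0, 1, length.out = 16)
  ftrue <- function(x) ifelse(x < 0.5, 0, 1 / (1 + exp(-(x - 0.7) / 0.03)))
  rmse_o <- rmse_a <- numeric(20)
  set.seed(11)
  for (r in 1:20) {
    x <- sort(runif(250))
    y <- ftrue(x) + rnorm(250, 0, 0.08)
    dat <- data.frame(x = x)
    fo <- fit_penalized(hg_design(
      smooth_term("f", "x", apply_centering(cubic_basis(k), x))), dat, y)
    fa <- fit_penalized(hg_design(
      smooth_term("f", "x", apply_centering(adaptive_penalty(cubic_basis(k), 5), x))), dat, y)
    rmse_o[r] <- sqrt(mean((fitted(fo) - ftrue(x))^2))
    rmse_a[r] <- sqrt(mean((fitted(fa) - ftrue(x))^2))
  }
  expect_lte(mean(rmse_a), mean(rmse_o))
})
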