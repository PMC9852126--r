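# Penalized fitting, REML, AR(1), quantile loss, prediction, posterior draws.

test_that("fixed-lambda fits match the closed-form solve and the large-lambda line", {
  set.seed(21)
  n <- 150; x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.3)
  des <- simple_design(x, k = 10)
  dat <- data.frame(x = x)
  mm <- hemogam:::hg_model_matrix(des, dat)
  lam <- 2.5
  fit <- fit_penalized(des, dat, y, lambdas = lam)
  beta_oracle <- oracle_pls(mm$X, y, list(mm$pens[[1]]$S),
                            list(mm$pens[[1]]$idx), lam)
  expect_equal(unname(coef(fit)), unname(beta_oracle), tolerance = 1e-8)
  # the penalty null space of a natural cubic smooth is the straight line
  gap <- function(l) max(abs(fitted(fit_penalized(des, dat, y, lambdas = l)) -
                             fitted(lm(y ~ x))))
  expect_lt(gap(1e9), 1e-3)
  # posterior covariance matches (X'X + lam S)^-1 sigma^2
  A <- crossprod(mm$X)
  A[mm$pens[[1]]$idx, mm$pens[[1]]$idx] <-
    A[mm$pens[[1]]$idx, mm$pens[[1]]$idx] + lam * mm$pens[[1]]$S
  expect_equal(fit$posterior_covariance, solve(A) * fit$sigma2,
               tolerance = 1e-6)
})

test_that("confounded unpenalized terms raise an identifiability error", {
  set.seed(22)
  x <- runif(80)
  b1 <- cubic_basis(make_knots(x, 6))        # uncentered: constant in span
  des <- hg_design(smooth_term("f1", "x", b1),
                   smooth_term("f2", "x", apply_centering(b1, x)))
  expect_error(fit_penalized(des, data.frame(x = x), rnorm(80)),
               "unidentifiable|confounded")
})

test_that("REML smooths pure noise to its null space and recovers a sine", {
  set.seed(23)
  n <- 400; x <- runif(n)
  dat <- data.frame(x = x)
  des <- simple_design(x, k = 12)
  # pure noise: the smooth collapses towards its (linear) null space
  fit0 <- fit_penalized(des, dat, rnorm(n))
  expect_lt(fit0$edf[["fx"]], 1.5)           # null space of centered smooth
  # sine + noise, n = 500
  set.seed(42)
  n <- 500; x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  des <- simple_design(x, k = 12); dat <- data.frame(x = x)
  fit <- fit_penalized(des, dat, y)
  expect_lt(sqrt(mean((fitted(fit) - sin(2 * pi * x))^2)), 0.05)
  # REML lambda within a factor of 10 of the truth-MSE-optimal lambda
  lam_grid <- 10^seq(-6, 4, by = 0.25)
  mses <- vapply(lam_grid, function(l)
    mean((fitted(fit_penalized(des, dat, y, lambdas = l)) - sin(2 * pi * x))^2), 0)
  expect_lt(abs(log10(fit$lambdas[["fx"]] / lam_grid[which.min(mses)])), 1)
})

test_that("an unpenalized 20-knot spline overfits n=70 noisy data (training RSS down, CV error up)", {
  set.seed(24)
  n <- 70; x <- sort(runif(n, 0, 2 * pi))
  y <- sin(x) + rnorm(n, 0, 0.35)
  dat <- data.frame(x = x)
  des20 <- hg_design(smooth_term("fx", "x",
    apply_centering(cubic_basis(make_knots(x, 20)), x)))
  f_unpen <- fit_penalized(des20, dat, y, lambdas = 0)
  f_pen <- fit_penalized(des20, dat, y)
  expect_lt(f_unpen$rss, f_pen$rss)
  # 10-fold cross-validation
  folds <- sample(rep(1:10, length.out = n))
  cv <- function(lam) {
    err <- 0
    for (k in 1:10) {
      tr <- folds != k
      b <- apply_centering(cubic_basis(make_knots(x[tr], 20)), x[tr])
      d <- hg_design(smooth_term("fx", "x", b))
      f <- if (is.null(lam)) fit_penalized(d, dat[tr, , drop = FALSE], y[tr])
           else fit_penalized(d, dat[tr, , drop = FALSE], y[tr], lambdas = lam)
      pr <- predict_terms(f, dat[!tr, , drop = FALSE])$prediction$value
      err <- err + sum((y[!tr] - pr)^2)
    }
    err / n
  }
  expect_gt(cv(0), cv(NULL))
})

test_that("REML matches mgcv's REML fit on the same data", {
  set.seed(25)
  n <- 400; x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.25)
  fit <- fit_penalized(simple_design(x, k = 12), data.frame(x = x), y)
  g <- mgcv::gam(y ~ s(x, bs = "cr", k = 12), method = "REML")
  expect_lt(sqrt(mean((fitted(fit) - fitted(g))^2)), 0.01)
  expect_equal(fit$edf_total, sum(g$edf), tolerance = 0.15)
})

test_that("AR(1) whitening with rho = 0 is the identity path and rho is recovered", {
  set.seed(26)
  n <- 800; x <- (seq_len(n) - 1) / n
  dat <- data.frame(x = x)
  des <- simple_design(x, k = 10, cyclic = TRUE)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.4)
  f0 <- fit_ar1(des, dat, y, rho = 0)
  fp <- fit_penalized(des, dat, y)
  expect_identical(coef(f0), coef(fp))
  expect_identical(f0$posterior_covariance, fp$posterior_covariance)
  expect_error(fit_ar1(des, dat, y, rho = 1.2), "rho")
  # rho recovery at n = 5000
  set.seed(27)
  n <- 5000; x <- seq(0, 5, length.out = n) %% 1
  dat <- data.frame(x = x)
  des <- simple_design(x, k = 10, cyclic = TRUE)
  e <- as.numeric(stats::filter(rnorm(n, 0, 0.5 * sqrt(1 - 0.36)), 0.6,
                                method = "recursive"))
  fa <- fit_ar1(des, dat, 2 * sin(2 * pi * x) + e)
  expect_gt(fa$rho, 0.5); expect_lt(fa$rho, 0.7)
})

test_that("median fit agrees with the Gaussian fit under symmetric noise", {
  set.seed(28)
  n <- 400; x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.3)
  des <- simple_design(x, k = 10); dat <- data.frame(x = x)
  fg <- fit_penalized(des, dat, y)
  fq <- suppressWarnings(fit_quantile(des, dat, y))
  expect_identical(fq$loss, "quantile")
  X <- hemogam:::hg_model_matrix(des, dat)$X
  se <- sqrt(pmax(rowSums((X %*% fg$posterior_covariance) * X), 0))
  expect_lt(max(abs(fitted(fq) - fitted(fg)) / se), 2)
})

test_that("per-term predictions are additive, cyclic and interval-exact", {
  sim <- gen_pp_series(n_beats = 120, trend = list(type = "linear", delta = 1),
                       seed = 31)
  fit <- fit_pp_model(sim$beats)
  nd <- data.frame(resp_position = c(0, 0.25, 1), time = rep(60, 3))
  pt <- predict_terms(fit, nd)
  csum <- Reduce(`+`, lapply(pt$terms, `[[`, "value"))
  expect_equal(csum, pt$prediction$value, tolerance = 1e-10)
  # cyclic covariate: prediction at 0 equals at 1
  expect_equal(pt$prediction$value[1], pt$prediction$value[3], tolerance = 1e-8)
  # interval half-width equals 1.96 sqrt(x' V x) for the full design row
  mm <- hemogam:::hg_model_matrix(fit$design, nd, check_identifiable = FALSE)
  hw <- 1.96 * sqrt(diag(mm$X %*% fit$posterior_covariance %*% t(mm$X)))
  expect_equal(pt$prediction$upper - pt$prediction$value, hw, tolerance = 1e-8)
  expect_error(predict_terms(fit, data.frame(time = 1)), "resp_position")
})

test_that("posterior draws reproduce the mean and covariance and are seed-deterministic", {
  set.seed(32)
  x <- runif(200); y <- sin(2 * pi * x) + rnorm(200, 0, 0.3)
  fit <- fit_penalized(simple_design(x, k = 8), data.frame(x = x), y)
  dr <- posterior_draws(fit, 50000L, seed = 5)
  mc_se <- sqrt(diag(fit$posterior_covariance) / 50000)
  expect_true(all(abs(colMeans(dr) - coef(fit)) < 3 * mc_se + 1e-12))
  Vhat <- stats::cov(dr)
  expect_lt(norm(Vhat - fit$posterior_covariance, "F") /
              norm(fit$posterior_covariance, "F"), 0.05)
  expect_identical(dr, posterior_draws(fit, 50000L, seed = 5))
  expect_false(identical(dr[1, ], posterior_draws(fit, 1, seed = 6)[1, ]))
})

test_that("nested models never increase training RSS and recovery improves with n", {
  sim <- gen_cvp_wave(duration_s = 12, seed = 33, ar1_rho = 0)
  s <- sim$samples
  fa <- fit_cvp_additive(s, k_cardiac = 16, k_resp = 10, k_time = 6, ar1 = 0)
  fi <- fit_cvp_interaction(s, k_cardiac = 16, k_resp = 10, k_time = 6,
                            k_tensor = c(6, 5), ar1 = 0)
  expect_lte(fi$rss, fa$rss)
  # smooth-function RMSE at n = 200 vs n = 2000 on a fixed generator
  rmse_at <- function(n) {
    set.seed(34)
    x <- runif(n); y <- sin(2 * pi * x) + rnorm(n, 0, 0.4)
    f <- fit_penalized(simple_design(x, k = 12), data.frame(x = x), y)
    sqrt(mean((fitted(f) - sin(2 * pi * x))^2))
  }
  expect_lt(rmse_at(2000), 0.5 * rmse_at(200) + 1e-9)
})
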