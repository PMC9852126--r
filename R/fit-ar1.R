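# AR(1) residual model via whitening.
#
# High-resolution waveforms have autocorrelated noise; ignoring it makes
# confidence bands too narrow. The fit applies the exact AR(1) whitening
# transform (first row of each section scaled by sqrt(1 - rho^2), subsequent
# rows r_t - rho r_{t-1}) to both response and model matrix, restarting the
# recursion at section boundaries, and solves the penalized problem on the
# whitened data. The automatic rho is a two-pass scheme: fit with rho = 0,
# estimate the lag-1 autocorrelation of the residuals within sections,
# whiten and refit.

.ar1_whiten <- function(M, rho, first) {
  # M: matrix (or vector) ordered by time; first: logical, TRUE at the first
  # observation of each section
  M <- as.matrix(M)
  W <- rbind(0, M[-nrow(M), , drop = FALSE])
  out <- M - rho * W
  out[first, ] <- M[first, , drop = FALSE] * sqrt(1 - rho^2)
  out
}

.lag1_acf <- function(r, first) {
  ok <- !first                            # pairs within a section
  num <- sum(r[ok] * r[which(ok) - 1L])
  den <- sum(r^2)
  if (den <= 0) 0 else num / den
}

#' Fit an additive model with AR(1) residuals
#'
#' @inheritParams fit_penalized
#' @param rho `"auto"` (two-pass estimate) or a known value in `[0, 1)`.
#' @param section optional vector of section labels (same length as `y`);
#'   the AR(1) recursion restarts at each section boundary. Defaults to
#'   `data$section` when present, otherwise a single section.
#' @return an `hg_fit` whose `rho` element holds the AR(1) coefficient;
#'   `fitted_values`/`residuals` are on the original (unwhitened) scale
#'   while `posterior_covariance` and `sigma2` come from the whitened
#'   problem.
#' @export
fit_ar1 <- function(design, data, y, rho = "auto", section = NULL) {
  if (is.null(section)) section <- data$section
  if (is.null(section)) section <- rep(1L, length(y))
  first <- c(TRUE, section[-1] != section[-length(section)])
  auto <- identical(rho, "auto")
  if (!auto) {
    rho <- as.numeric(rho)
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  }
  mm <- hg_model_matrix(design, data)
  X <- mm$X; n <- length(y); p <- ncol(X)
  clusters <- .pen_clusters(mm$pens)
  fit0 <- NULL
  if (auto) {
    XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
    lam0 <- .reml_optimize(XtX, Xty, yty, n, p, mm$pens, clusters)
    fit0 <- .finalize_fit(design, mm, X, y, XtX, Xty, yty, n, lam0, clusters)
    rho <- min(max(.lag1_acf(fit0$residuals, first), 0), 0.99)
  }
  if (rho == 0) {
    fit <- if (is.null(fit0)) fit_penalized(design, data, y) else fit0
    fit$rho <- 0
    return(fit)
  }
  Xw <- .ar1_whiten(X, rho, first)
  yw <- drop(.ar1_whiten(y, rho, first))
  XtX <- crossprod(Xw); Xty <- crossprod(Xw, yw); yty <- sum(yw^2)
  lam <- .reml_optimize(XtX, Xty, yty, n, p, mm$pens, clusters)
  fit <- .finalize_fit(design, mm, Xw, yw, XtX, Xty, yty, n, lam, clusters)
  # report fit on the original scale; inference stays on the whitened problem
  fit$fitted_values <- drop(X %*% fit$coefficients)
  fit$residuals <- y - fit$fitted_values
  fit$rho <- rho
  fit
}

#' Fit the conditional median (or another quantile) of the signal
#'
#' Minimizes the pinball (check) loss plus the curvature penalties, by
#' iteratively reweighted least squares on a smoothed pinball loss: the
#' weight of residual `u` is `|tau - 1(u < 0)| / sqrt(u^2 + delta^2)` with
#' `delta` tied to a robust residual scale (median absolute deviation).
#' Because large residuals get small weights, transient artifacts barely
#' move the fit -- unlike least squares, which echoes an artifact into every
#' other cycle. Smoothing parameters are re-selected by REML on the final
#' weighted problem.
#'
#' @inheritParams fit_penalized
#' @param tau target quantile in (0, 1); 0.5 fits the median.
#' @param max_iter,tol IRLS iteration cap and relative coefficient-change
#'   tolerance.
#' @return an `hg_fit` with `loss = "quantile"`.
#' @export
fit_quantile <- function(design, data, y, tau = 0.5, max_iter = 40L, tol = 1e-7) {
  stopifnot(tau > 0, tau < 1)
  mm <- hg_model_matrix(design, data)
  X <- mm$X; n <- length(y); p <- ncol(X)
  clusters <- .pen_clusters(mm$pens)
  # initial Gaussian fit supplies starting residual scale and lambdas
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  lam <- .reml_optimize(XtX, Xty, sum(y^2), n, p, mm$pens, clusters)
  beta <- .pls_fit(XtX, Xty, sum(y^2), n, p, mm$pens, lam, clusters)$beta
  irls <- function(beta, lam, iters) {
    for (it in seq_len(iters)) {
      u <- y - drop(X %*% beta)
      # bandwidth of the smoothed pinball loss: a fraction of the robust
      # residual scale, annealed over the first iterations so early steps
      # are stable and late steps approach the exact check loss
      delta <- max(stats::mad(u) * max(0.5^it, 0.05),
                   1e-6 * max(stats::sd(y), 1e-12))
      w <- abs(tau - (u < 0)) / sqrt(u^2 + delta^2)
      w <- w * n / sum(w)
      Xw <- X * sqrt(w); yw <- y * sqrt(w)
      res <- .pls_fit(crossprod(Xw), crossprod(Xw, yw), sum(yw^2), n, p,
                      mm$pens, lam, clusters)
      done <- max(abs(res$beta - beta)) <=
        tol * max(abs(beta), 1e-8)
      beta <- res$beta
      if (done) break
    }
    list(beta = beta, w = w, converged = done)
  }
  st <- irls(beta, lam, max_iter)
  # re-select lambda on the final weighted problem, then polish
  Xw <- X * sqrt(st$w); yw <- y * sqrt(st$w)
  lam <- .reml_optimize(crossprod(Xw), crossprod(Xw, yw), sum(yw^2), n, p,
                        mm$pens, clusters)
  st <- irls(st$beta, lam, max_iter)
  if (!st$converged)
    warning("quantile IRLS did not fully converge; returning last iterate")
  Xw <- X * sqrt(st$w); yw <- y * sqrt(st$w)
  fit <- .finalize_fit(design, mm, Xw, yw, crossprod(Xw), crossprod(Xw, yw),
                       sum(yw^2), n, lam, clusters, loss = "quantile", w = st$w)
  fit$fitted_values <- drop(X %*% fit$coefficients)
  fit$residuals <- y - fit$fitted_values
  fit
}
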