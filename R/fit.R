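# Penalized least squares with REML smoothing-parameter selection.
#
# Gaussian fits minimize ||y - X b||^2 + sum_j lambda_j b' S_j b. For fixed
# lambda the solution is the closed form (X'X + sum lambda_j S_j)^-1 X'y.
# Automatic lambdas maximize the Gaussian restricted marginal likelihood,
# with sigma^2 profiled out:
#   score(log lambda) = (n - Mp) log(RSS_pen / (n - Mp))
#                       + log|X'X + S_lambda| - log|S_lambda|_+
# where Mp is the dimension of the total penalty null space and |.|_+ the
# product of positive eigenvalues. The score is minimized in log-lambda
# space (golden-section for one parameter, Nelder-Mead otherwise).

# group penalties whose column spans overlap (adaptive / tensor terms):
# their generalized determinant must be computed jointly
.pen_clusters <- function(pens) {
  if (!length(pens)) return(list())
  grp <- seq_along(pens)
  for (i in seq_along(pens)) for (j in seq_len(i - 1L)) {
    if (length(intersect(pens[[i]]$idx, pens[[j]]$idx)))
      grp[grp == grp[i]] <- grp[j]
  }
  lapply(unique(grp), function(g) which(grp == g))
}

.assemble_S <- function(p, pens, lambdas) {
  S <- matrix(0, p, p)
  for (j in seq_along(pens)) {
    idx <- pens[[j]]$idx
    S[idx, idx] <- S[idx, idx] + lambdas[j] * pens[[j]]$S
  }
  S
}

# log generalized determinant and rank of the penalty, by cluster
.logdet_Splus <- function(p, pens, lambdas, clusters) {
  ld <- 0; rk <- 0L
  for (cl in clusters) {
    idx <- sort(unique(unlist(lapply(pens[cl], `[[`, "idx"))))
    M <- matrix(0, length(idx), length(idx))
    for (j in cl) {
      loc <- match(pens[[j]]$idx, idx)
      M[loc, loc] <- M[loc, loc] + lambdas[j] * pens[[j]]$S
    }
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    pos <- ev[ev > max(ev) * 1e-10]
    ld <- ld + sum(log(pos)); rk <- rk + length(pos)
  }
  list(logdet = ld, rank = rk)
}

.chol_solve <- function(A, B) {
  R <- tryCatch(chol(A), error = function(e) {
    chol(A + diag(1e-8 * max(diag(A)) + 1e-300, nrow(A)))
  })
  list(R = R, sol = backsolve(R, forwardsolve(t(R), B)),
       logdet = 2 * sum(log(diag(R))))
}

# core penalized solve on sufficient statistics
.pls_fit <- function(XtX, Xty, yty, n, p, pens, lambdas, clusters) {
  S <- .assemble_S(p, pens, lambdas)
  cs <- .chol_solve(XtX + S, Xty)
  beta <- drop(cs$sol)
  rss <- max(yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta)), 0)
  pen <- sum(beta * (S %*% beta))
  gd <- .logdet_Splus(p, pens, lambdas, clusters)
  mp <- p - gd$rank
  rsspen <- max(rss + pen, 1e-10 * max(yty, 1) * .Machine$double.eps * n + 1e-300)
  score <- (n - mp) * log(rsspen / (n - mp)) + cs$logdet - gd$logdet
  list(beta = beta, rss = rss, pen = pen, score = score, R = cs$R, S = S, mp = mp)
}

.reml_optimize <- function(XtX, Xty, yty, n, p, pens, clusters) {
  auto <- which(vapply(pens, function(pn) identical(pn$policy, "auto"), TRUE))
  lambdas <- vapply(pens, function(pn)
    if (identical(pn$policy, "auto")) 1 else as.numeric(pn$policy), 0)
  if (!length(auto)) return(lambdas)
  # scale-matched starting values
  for (j in auto) {
    idx <- pens[[j]]$idx
    trX <- sum(diag(XtX)[idx]); trS <- sum(diag(pens[[j]]$S))
    lambdas[j] <- if (trS > 0) max(trX, 1e-8) / trS else 1
  }
  f <- function(lg) {
    lam <- lambdas; lam[auto] <- exp(lg)
    .pls_fit(XtX, Xty, yty, n, p, pens, lam, clusters)$score
  }
  if (length(auto) == 1L) {
    o <- stats::optimize(f, interval = log(lambdas[auto]) + c(-18, 18), tol = 1e-7)
    lambdas[auto] <- exp(o$minimum)
  } else {
    o <- stats::optim(log(lambdas[auto]), f, method = "Nelder-Mead",
                      control = list(maxit = 500 * length(auto), reltol = 1e-8))
    if (o$convergence != 0)
      warning("REML optimization did not fully converge; using best lambda found")
    lambdas[auto] <- exp(o$par)
  }
  lambdas
}

.finalize_fit <- function(design, mm, X, y, XtX, Xty, yty, n, lambdas,
                          clusters, loss = "gaussian", w = NULL) {
  p <- ncol(X)
  res <- .pls_fit(XtX, Xty, yty, n, p, mm$pens, lambdas, clusters)
  Ainv <- chol2inv(res$R)
  edf_diag <- rowSums(Ainv * XtX)        # diag of (X'X+S)^-1 X'X
  edf <- vapply(mm$cols, function(idx) sum(edf_diag[idx]), 0)
  edf_tot <- sum(edf_diag)
  sigma2 <- res$rss / max(n - edf_tot, 1)
  V <- (Ainv + t(Ainv)) / 2 * sigma2
  fitted <- drop(X %*% res$beta)
  names(lambdas) <- vapply(mm$pens, `[[`, "", "name")
  structure(list(
    design = design, cols = mm$cols, pens = mm$pens, meta = mm$meta,
    coefficients = res$beta, posterior_covariance = V,
    lambdas = lambdas, rho = 0,
    fitted_values = fitted, residuals = y - fitted,
    edf = edf, edf_total = edf_tot, sigma2 = sigma2,
    rss = res$rss, reml_score = res$score, n = n,
    loss = loss, weights = w), class = "hg_fit")
}

#' Fit an additive model by penalized least squares
#'
#' @param design an [hg_design()].
#' @param data data frame holding every covariate the design's terms read.
#' @param y numeric response vector (one value per row of `data`).
#' @param lambdas optional named or positional numeric vector overriding
#'   every penalty's smoothing parameter; by default each penalty follows
#'   its term's policy (`"auto"` REML or a fixed value).
#' @return an object of class `hg_fit` with elements `coefficients`,
#'   `posterior_covariance` (Bayesian covariance of the coefficients given
#'   lambda), `lambdas`, `rho`, `fitted_values`, `residuals`, per-term `edf`
#'   and `sigma2` (residual variance, RSS / (n - total edf)).
#' @seealso [select_lambda_reml()], [fit_ar1()], [fit_quantile()],
#'   [predict_terms()]
#' @export
fit_penalized <- function(design, data, y, lambdas = NULL) {
  mm <- hg_model_matrix(design, data)
  X <- mm$X; n <- length(y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  if (n < p)
    warning("fewer observations than basis functions; the penalties regularize the fit")
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  clusters <- .pen_clusters(mm$pens)
  if (is.null(lambdas)) {
    lambdas <- .reml_optimize(XtX, Xty, yty, n, p, mm$pens, clusters)
  } else {
    lambdas <- rep_len(as.numeric(lambdas), length(mm$pens))
  }
  .finalize_fit(design, mm, X, y, XtX, Xty, yty, n, lambdas, clusters)
}

#' REML selection of smoothing parameters
#'
#' Returns the smoothing parameters maximizing the restricted marginal
#' likelihood of the Gaussian penalized model, without the full fit.
#'
#' @inheritParams fit_penalized
#' @return named numeric vector of lambdas, one per penalty.
#' @export
select_lambda_reml <- function(design, data, y) {
  mm <- hg_model_matrix(design, data)
  X <- mm$X
  lam <- .reml_optimize(crossprod(X), crossprod(X, y), sum(y^2),
                        length(y), ncol(X), mm$pens, .pen_clusters(mm$pens))
  names(lam) <- vapply(mm$pens, `[[`, "", "name")
  lam
}

#' @export
print.hg_fit <- function(x, ...) {
  cat(sprintf("<hg_fit> %s loss, n=%d, total edf=%.2f, sigma=%.4g, rho=%.3f\n",
              x$loss, x$n, x$edf_total, sqrt(x$sigma2), x$rho))
  cat("terms:", paste(sprintf("%s(edf %.2f)", names(x$edf), x$edf),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.hg_fit <- function(object, ...) object$coefficients

#' @export
residuals.hg_fit <- function(object, ...) object$residuals

#' @export
fitted.hg_fit <- function(object, ...) object$fitted_values
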