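# Per-term predictions with pointwise intervals, and posterior simulation.

# rebuild one term's model-matrix block on new data
.term_matrix <- function(term, newdata, n, meta = NULL) {
  if (term$type == "factor") {
    lev <- meta$levels                   # levels frozen at fit time
    f <- as.character(newdata[[term$var]])
    if (!all(f %in% lev)) stop("unknown level in factor term ", term$var)
    Xf <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(n))
    return(matrix(Xf, nrow = n))
  }
  miss <- !(term$vars %in% names(newdata))
  if (any(miss)) stop("missing covariate column: ",
                      paste(term$vars[miss], collapse = ", "))
  xs <- newdata[term$vars]
  xv <- if (length(term$vars) == 2L) as.matrix(xs) else xs[[1]]
  Xt <- basis_matrix(term$basis, xv)
  if (!is.null(term$by)) Xt <- Xt * as.numeric(newdata[[term$by$var]] == term$by$level)
  Xt
}

#' Per-term contributions and overall prediction
#'
#' Evaluates each model term on new data, returning the term's contribution
#' to the linear predictor with a pointwise 95% interval (+-1.96 posterior
#' standard errors), plus the overall prediction (sum of all contributions,
#' intercept included).
#'
#' @param fit an `hg_fit`.
#' @param newdata data frame with every covariate the design needs.
#' @return a list with `terms` (named list of data frames `value`, `se`,
#'   `lower`, `upper`) and `prediction` (data frame `value`, `se`, `lower`,
#'   `upper`).
#' @export
predict_terms <- function(fit, newdata) {
  stopifnot(inherits(fit, "hg_fit"))
  n <- nrow(newdata)
  V <- fit$posterior_covariance
  terms <- list()
  total <- numeric(n); Xall <- matrix(0, n, length(fit$coefficients))
  blocks <- c(list(`(Intercept)` = NULL), stats::setNames(fit$design$terms,
              vapply(fit$design$terms, `[[`, "", "label")))
  for (lab in names(fit$cols)) {
    idx <- fit$cols[[lab]]
    Xt <- if (lab == "(Intercept)") matrix(1, n, 1)
          else .term_matrix(blocks[[lab]], newdata, n, fit$meta[[lab]])
    bt <- fit$coefficients[idx]
    val <- drop(Xt %*% bt)
    se <- sqrt(pmax(rowSums((Xt %*% V[idx, idx, drop = FALSE]) * Xt), 0))
    terms[[lab]] <- data.frame(value = val, se = se,
                               lower = val - 1.96 * se, upper = val + 1.96 * se)
    total <- total + val
    Xall[, idx] <- Xt
  }
  se_tot <- sqrt(pmax(rowSums((Xall %*% V) * Xall), 0))
  list(terms = terms,
       prediction = data.frame(value = total, se = se_tot,
                               lower = total - 1.96 * se_tot,
                               upper = total + 1.96 * se_tot))
}

#' Draw coefficient vectors from the posterior of a fit
#'
#' Samples from the multivariate normal with mean equal to the fitted
#' coefficients and covariance equal to the posterior covariance (given the
#' smoothing parameters). Used to propagate uncertainty into derived
#' statistics such as PPV.
#'
#' @param fit an `hg_fit` with Gaussian loss.
#' @param n_draws number of samples.
#' @param seed integer seed; identical seeds give identical draws.
#' @return `n_draws` x `p` matrix of coefficient samples.
#' @export
posterior_draws <- function(fit, n_draws, seed = 1L) {
  stopifnot(inherits(fit, "hg_fit"))
  if (fit$loss != "gaussian")
    stop("posterior draws are defined for Gaussian-loss fits")
  V <- fit$posterior_covariance
  e <- eigen(V, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values)))) {
    warning("posterior covariance not PSD; negative eigenvalues clipped to 0")
  }
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_draws * ncol(V)), n_draws, ncol(V))
  sweep(Z %*% L, 2, fit$coefficients, `+`)
}
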