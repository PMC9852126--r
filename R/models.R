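# The pulse-pressure model and the PPV statistic.

#' Fit the additive pulse-pressure model
#'
#' Models a per-beat pulse-pressure series as
#' `PP = alpha + f(resp_position) + f(time) + noise`, where the respiratory
#' smooth is a centered cyclic cubic spline on the cycle fraction `[0, 1)`
#' and the trend is a centered natural cubic spline of time with knots at
#' time quantiles. Because the smooths are centered, `alpha` equals the mean
#' pulse pressure of the sample. Smoothing parameters are selected by REML.
#'
#' @param beats data frame with columns `time`, `pulse_pressure` and
#'   `resp_position` (see [detect_beats()], [resp_position()]); rows with a
#'   missing respiratory position are dropped.
#' @param k_resp,k_time basis dimensions of the respiratory and trend
#'   smooths (nominal knots; the cyclic basis has `k_resp - 1` free
#'   coefficients).
#' @param lambda smoothing policy passed to both smooths (`"auto"` or a
#'   fixed value).
#' @return an `hg_fit` with `model = "pp"` and term labels `resp_cycle` and
#'   `time_trend`.
#' @export
fit_pp_model <- function(beats, k_resp = 10, k_time = 10, lambda = "auto") {
  beats <- beats[is.finite(beats$resp_position) & is.finite(beats$pulse_pressure), ]
  if (nrow(beats) < 8L)
    stop("too few observations: need at least 8 beats with a respiratory position")
  b_resp <- apply_centering(
    cyclic_cubic_basis(seq(0, 1, length.out = k_resp)), beats$resp_position)
  kt <- make_knots(beats$time, k_time, "quantile")
  b_time <- apply_centering(cubic_basis(kt, natural = TRUE), beats$time)
  des <- hg_design(
    smooth_term("resp_cycle", "resp_position", b_resp, lambda = lambda),
    smooth_term("time_trend", "time", b_time, lambda = lambda))
  fit <- fit_penalized(des, beats, beats$pulse_pressure)
  fit$model <- "pp"
  fit$data <- beats
  fit
}

#' Pulse pressure variation from a fitted pulse-pressure model
#'
#' PPV is the range of the fitted respiratory smooth divided by the mean
#' pulse pressure: `PPV = (max f - min f) / alpha`, in percent. Because
#' `alpha` is the mean PP, this matches the classic
#' `(PPmax - PPmin) / ((PPmax + PPmin) / 2)` definition. The smooth's
#' extrema are located on a dense grid over one respiratory cycle, and the
#' confidence interval is the 2.5/97.5 percentile of PPV recomputed over
#' posterior draws of the model coefficients.
#'
#' @param fit an `hg_fit` from [fit_pp_model()].
#' @param n_draws posterior draws for the confidence interval.
#' @param seed integer seed for the draws.
#' @param grid_n grid points over one respiratory cycle used to locate the
#'   extrema.
#' @return an object of class `hg_ppv`: list with `ppv`, `ci_low`,
#'   `ci_high` (percent), `alpha` (mmHg), `smooth_range` (mmHg), `n_beats`,
#'   `n_draws`, `seed`.
#' @export
compute_ppv <- function(fit, n_draws = 50000L, seed = 1L, grid_n = 512L) {
  stopifnot(inherits(fit, "hg_fit"))
  if (!identical(fit$model, "pp"))
    stop("compute_ppv expects a fit produced by fit_pp_model")
  grid <- seq(0, 1, length.out = grid_n + 1L)[-(grid_n + 1L)]
  term <- fit$design$terms[[which(vapply(fit$design$terms, `[[`, "", "label")
                                  == "resp_cycle")]]
  G <- basis_matrix(term$basis, grid)            # grid_n x df
  ir <- fit$cols[["resp_cycle"]]; ii <- fit$cols[["(Intercept)"]]
  sm <- drop(G %*% fit$coefficients[ir])
  alpha <- fit$coefficients[ii]
  rng <- max(sm) - min(sm)
  ppv <- 100 * rng / alpha
  dr <- posterior_draws(fit, n_draws, seed)
  B <- dr[, ir, drop = FALSE]
  hi <- rep(-Inf, n_draws); lo <- rep(Inf, n_draws)
  for (j in seq_len(grid_n)) {
    v <- drop(B %*% G[j, ])
    hi <- pmax(hi, v); lo <- pmin(lo, v)
  }
  ppv_d <- 100 * (hi - lo) / dr[, ii]
  ci <- stats::quantile(ppv_d, c(0.025, 0.975), names = FALSE)
  structure(list(ppv = ppv, ci_low = ci[1], ci_high = ci[2], alpha = alpha,
                 smooth_range = rng, n_beats = fit$n,
                 n_draws = n_draws, seed = seed),
            class = "hg_ppv")
}

#' @export
print.hg_ppv <- function(x, ...) {
  cat(sprintf("PPV %.1f%% (95%% CI %.1f-%.1f%%); mean PP %.2f mmHg, respiratory swing %.2f mmHg over %d beats\n",
              x$ppv, x$ci_low, x$ci_high, x$alpha, x$smooth_range, x$n_beats))
  invisible(x)
}
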