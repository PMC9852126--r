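# Independent oracles and small generators used across tests.

# adaptive-quadrature oracle for the curvature integral of a fitted spline
quad_curvature <- function(basis, beta, lo, hi) {
  f2sq <- function(x) as.numeric((basis_matrix(basis, x, deriv = 2) %*% beta)^2)
  # integrate piecewise between knots: f''' jumps there
  kv <- if (is.list(basis$knots)) basis$knots$x else basis$knots
  brk <- sort(unique(c(lo, hi, kv[kv > lo & kv < hi])))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    total <- total + stats::integrate(function(x) vapply(x, f2sq, 0),
                                      brk[i], brk[i + 1],
                                      rel.tol = 1e-10, subdivisions = 200L)$value
  }
  total
}

# central finite difference of a fitted spline curve
fd_deriv <- function(basis, beta, x, order = 1, h = 1e-5) {
  f <- function(z) as.numeric(basis_matrix(basis, z) %*% beta)
  if (order == 1) (f(x + h) - f(x - h)) / (2 * h)
  else (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# closed-form ridge-type solve for a fixed-lambda penalized fit
oracle_pls <- function(X, y, S_list, idx_list, lambdas) {
  p <- ncol(X)
  A <- crossprod(X)
  for (j in seq_along(S_list)) {
    idx <- idx_list[[j]]
    A[idx, idx] <- A[idx, idx] + lambdas[j] * S_list[[j]]
  }
  drop(solve(A, crossprod(X, y)))
}

# clean synthetic arterial-pressure-like waveform: one sharp systolic
# upstroke per beat over a diastolic decay
gen_abp <- function(duration = 60, heart_rate = 60, fs = 125, pp = 20,
                    dia = 80, noise_sd = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phase <- (t * heart_rate / 60) %% 1
  pulse <- exp(-((phase - 0.3) / 0.12)^2)
  v <- dia + pp * pulse / max(pulse)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  data.frame(time = t, value = v)
}

# single-smooth design on x in [0,1]
simple_design <- function(x, k = 12, cyclic = FALSE, center = TRUE) {
  b <- if (cyclic) cyclic_cubic_basis(seq(0, 1, length.out = k))
       else cubic_basis(make_knots(x, k))
  if (center) b <- apply_centering(b, x)
  hg_design(smooth_term("fx", "x", b))
}

expect_no_condition <- function(expr) testthat::expect_silent(expr)
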