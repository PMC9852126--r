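# Waveform preprocessing: beats, cycle positions, respiratory rate.

#' Detect beats in an arterial-pressure-like waveform
#'
#' Finds one systolic peak per cardiac cycle (local maxima subject to a
#' refractory period of `60 / max_heart_rate` seconds and a minimum
#' prominence) and the preceding diastolic minimum. The beat is timed at the
#' diastole, and pulse pressure is systolic minus diastolic pressure.
#'
#' @param time,value waveform samples (seconds, mmHg), uniformly sampled.
#' @param min_heart_rate,max_heart_rate plausible heart-rate band in bpm.
#' @param prominence minimum peak prominence in mmHg; default 25% of the
#'   5-95% amplitude range of the segment (a robust pulse-height scale).
#' @param beat_time `"diastole"` (default) or `"systole"`.
#' @return data frame (a beat series) with columns `time`, `systolic`,
#'   `diastolic`, `pulse_pressure`; zero rows (with a warning) when no beats
#'   are found.
#' @export
detect_beats <- function(time, value, min_heart_rate = 30, max_heart_rate = 180,
                         prominence = NULL, beat_time = c("diastole", "systole")) {
  beat_time <- match.arg(beat_time)
  n <- length(value)
  empty <- data.frame(time = numeric(0), systolic = numeric(0),
                      diastolic = numeric(0), pulse_pressure = numeric(0))
  if (n < 3L || max(value) - min(value) < sqrt(.Machine$double.eps)) {
    warning("no beats found (flat or too-short signal)")
    return(empty)
  }
  if (is.null(prominence)) {
    q <- stats::quantile(value, c(0.05, 0.95), names = FALSE)
    prominence <- 0.25 * (q[2] - q[1])
  }
  # strict local maxima
  cand <- which(value[-c(1, n)] > value[-c(n - 1, n)] &
                value[-c(1, n)] >= value[-c(1, 2)]) + 1L
  if (!length(cand)) {
    warning("no beats found")
    return(empty)
  }
  prom <- vapply(cand, function(i) {
    l <- i; lm <- value[i]
    while (l > 1L && value[l] <= value[i]) { l <- l - 1L; lm <- min(lm, value[l]) }
    r <- i; rm <- value[i]
    while (r < n && value[r] <= value[i]) { r <- r + 1L; rm <- min(rm, value[r]) }
    value[i] - max(lm, rm)
  }, 0)
  keep <- cand[prom >= prominence]
  if (!length(keep)) {
    warning("no beats found above the prominence threshold")
    return(empty)
  }
  # refractory: accept peaks in order of height, rejecting close neighbours
  refract <- 60 / max_heart_rate
  ord <- keep[order(value[keep], decreasing = TRUE)]
  acc <- numeric(0)
  for (i in ord) {
    if (!length(acc) || min(abs(time[i] - time[acc])) >= refract)
      acc <- c(acc, i)
  }
  sys_idx <- sort(acc)
  # diastole: minimum between this peak and the previous one (or up to one
  # slowest-plausible cycle before the first peak)
  dia_idx <- integer(length(sys_idx))
  for (b in seq_along(sys_idx)) {
    lo <- if (b == 1L) {
      max(1L, sys_idx[1] - ceiling((60 / min_heart_rate) /
                                   stats::median(diff(time))))
    } else sys_idx[b - 1L] + 1L
    seg <- lo:(sys_idx[b] - 1L)
    if (!length(seg)) seg <- sys_idx[b]
    dia_idx[b] <- seg[which.min(value[seg])]
  }
  data.frame(
    time = if (beat_time == "diastole") time[dia_idx] else time[sys_idx],
    systolic = value[sys_idx],
    diastolic = value[dia_idx],
    pulse_pressure = value[sys_idx] - value[dia_idx])
}

#' Position in the respiratory cycle
#'
#' For a timestamp `t` inside the cycle `[s_k, s_k+1)` delimited by two
#' inspiration starts, the position is `(t - s_k) / (s_k+1 - s_k)`, a
#' fraction in `[0, 1)`. Timestamps before the first or at/after the last
#' inspiration start are unidentifiable (partial cycles) and come back as
#' `NA`, with a warning reporting the count.
#'
#' @param times numeric timestamps in seconds.
#' @param insp_starts strictly increasing inspiration-start times (>= 2).
#' @return numeric vector of fractions in `[0, 1)` (NA where dropped).
#' @export
resp_position <- function(times, insp_starts) {
  if (length(insp_starts) < 2L || any(diff(insp_starts) <= 0))
    stop("insp_starts must be a strictly increasing sequence of length >= 2")
  k <- findInterval(times, insp_starts)
  out <- rep(NA_real_, length(times))
  ok <- k >= 1L & times < insp_starts[length(insp_starts)]
  if (any(!ok))
    warning(sprintf("%d timestamp(s) outside the annotated inspiration window dropped",
                    sum(!ok)))
  kk <- k[ok]
  out[ok] <- (times[ok] - insp_starts[kk]) /
    (insp_starts[kk + 1L] - insp_starts[kk])
  out
}

#' Respiratory-cycle position from the respiratory period alone
#'
#' Fallback when no inspiration annotations exist but the respiratory period
#' is known (e.g. from [estimate_resp_rate()]): the position is
#' `((t - phase) mod T) / T`; its phase is arbitrary.
#'
#' @param times numeric timestamps in seconds.
#' @param period respiratory period T in seconds.
#' @param phase time origin of the cycle (default 0).
#' @export
resp_position_modulo <- function(times, period, phase = 0) {
  stopifnot(period > 0)
  ((times - phase) %% period) / period
}

#' Position in the cardiac cycle (seconds since the latest P wave)
#'
#' P-wave times are the QRS times minus a constant, user-measured PR
#' interval; the exact value mainly ensures the atrial contraction falls at
#' the start of a cycle rather than the end of the previous one. Samples
#' before the first P wave are returned as `NA` with a warning.
#'
#' @param times numeric timestamps in seconds.
#' @param qrs_times increasing QRS-complex times in seconds.
#' @param pr_interval PR interval in seconds (default 0.15, a conventional
#'   value; measure it for real recordings).
#' @return seconds since the latest P wave.
#' @export
cardiac_position <- function(times, qrs_times, pr_interval = 0.15) {
  if (!length(qrs_times)) stop("qrs_times is empty")
  if (pr_interval < 0) stop("pr_interval must be >= 0")
  p <- sort(qrs_times) - pr_interval
  k <- findInterval(times, p)
  out <- rep(NA_real_, length(times))
  if (any(k == 0L))
    warning(sprintf("%d sample(s) before the first P wave dropped", sum(k == 0L)))
  out[k > 0L] <- times[k > 0L] - p[k[k > 0L]]
  out
}

#' Estimate the respiratory rate by spectral analysis
#'
#' Uses a classical periodogram for uniformly sampled series (e.g. a CVP
#' waveform) and a least-squares (Lomb-Scargle) spectrum for irregular ones
#' (e.g. a per-beat pulse-pressure series). The estimate is the frequency of
#' the largest spectral peak inside the plausible band; if that peak does
#' not exceed `threshold` times the median in-band power the series is
#' judged to carry no confident respiratory tone and an error is raised.
#'
#' @param time sample times in seconds.
#' @param value sampled values.
#' @param band plausible respiratory band in Hz (default 0.1-0.67 Hz,
#'   i.e. 6-40 breaths/min).
#' @param threshold peak-to-median power factor required for confidence
#'   (the default 12 is far above the ~6x ratio white noise produces, and
#'   far below the ratio of any clear respiratory tone).
#' @return respiratory rate in cycles per second (Hz), with the frequency
#'   resolution `1/duration` as attribute `"bin"`.
#' @export
estimate_resp_rate <- function(time, value, band = c(0.1, 0.67), threshold = 12) {
  stopifnot(length(time) == length(value), length(time) > 8)
  dur <- max(time) - min(time)
  if (dur <= 3 / band[1]) stop("need at least ~3 respiratory cycles of data")
  value <- stats::residuals(stats::lm(value ~ time))   # remove mean + drift
  dt <- diff(time)
  uniform <- (max(dt) - min(dt)) < 1e-6
  freqs <- seq(1 / dur, band[2] + 1 / dur, by = 1 / dur)
  if (uniform) {
    n <- length(value)
    sp <- Mod(stats::fft(value))^2 / n
    f_all <- (seq_len(n) - 1) / (n * dt[1])
    sel <- f_all >= band[1] & f_all <= band[2]
    pow <- sp[sel]; freqs <- f_all[sel]
  } else {
    freqs <- freqs[freqs >= band[1] & freqs <= band[2]]
    pow <- vapply(freqs, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * time)), sum(cos(2 * w * time))) / (2 * w)
      ct <- cos(w * (time - tau)); st <- sin(w * (time - tau))
      0.5 * (sum(value * ct)^2 / sum(ct^2) + sum(value * st)^2 / sum(st^2))
    }, 0)
  }
  if (!length(pow)) stop("no spectral support inside the plausible band")
  pk <- which.max(pow)
  if (pow[pk] < threshold * stats::median(pow))
    stop("no confident respiratory-rate estimate: spectral peak too weak")
  structure(freqs[pk], bin = 1 / dur)
}
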