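# Synthetic generators with known ground truth.
#
# Everything the models estimate -- respiratory modulation of pulse
# pressure, CVP cardiac template with a/c/x'/v/y landmarks, a cardiac x
# respiratory interaction, slow trend, AR(1) noise, artifact bursts -- is
# generated from explicit components, and those components are returned
# alongside the data so fits can be scored against truth.

# cyclic respiratory effect shapes, all mean-zero over one cycle
.resp_shape <- function(type, amplitude, phase = 0) {
  f <- switch(type,
    sinusoid = function(pos) sin(2 * pi * (pos - phase)),
    skewed   = function(pos) {
      v <- sin(2 * pi * (pos - phase)) + sin(4 * pi * (pos - phase)) / 3
      v
    },
    plateau  = function(pos) {
      # smooth rise over inspiration, plateau, sharp-ish fall in expiration
      p <- pos %% 1
      ramp <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
      v <- ramp(p / 0.15) - ramp((p - 0.30) / 0.12)
      v
    },
    stop("unknown resp_effect type: ", type))
  grid <- seq(0, 1, length.out = 2048L)[-2048L]
  mu <- mean(f(grid))
  sc <- amplitude / max(abs(f(grid) - mu))
  function(pos) sc * (f(pos) - mu)
}

.trend_fun <- function(trend, t0, t1) {
  if (is.null(trend)) return(function(t) rep(0, length(t)))
  type <- trend$type %||% "linear"
  delta <- trend$delta %||% 0
  switch(type,
    linear  = function(t) delta * (t - t0) / (t1 - t0),
    sigmoid = function(t) delta / (1 + exp(-((t - (t0 + t1) / 2) / ((t1 - t0) / 12)))),
    stop("unknown trend type: ", type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic pulse-pressure beat series
#'
#' Beats occur at a fixed heart rate; each beat's pulse pressure is the mean
#' PP plus a cyclic respiratory modulation evaluated at the beat's position
#' in the respiratory cycle, a slow trend and white noise. Defaults emulate
#' a deeply sedated, mechanically ventilated adult: mean PP 8 mmHg above a
#' 60 mmHg diastole, 24 breaths/min, sinusoidal respiratory effect of
#' amplitude 0.6 mmHg (true PPV 15%).
#'
#' @param n_beats number of beats.
#' @param mean_pp mean pulse pressure (mmHg) -- the alpha truth.
#' @param resp_rate breaths per minute.
#' @param heart_rate beats per minute.
#' @param resp_effect list: `type` (`"sinusoid"` or `"skewed"`), `amplitude`
#'   (mmHg), optional `phase`.
#' @param trend list: `type` (`"linear"` or `"sigmoid"`), `delta` (mmHg over
#'   the record); `NULL` for no trend.
#' @param noise_sd white-noise SD in mmHg.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration and this seed.
#' @return list with `beats` (data frame `time`, `systolic`, `diastolic`,
#'   `pulse_pressure`, `resp_position`), `insp_starts`, and `truth` (`alpha`,
#'   `ppv` in percent, the respiratory-effect function `resp_fun`, the trend
#'   function `trend_fun`).
#' @export
gen_pp_series <- function(n_beats = 300, mean_pp = 8, resp_rate = 24,
                          heart_rate = 75,
                          resp_effect = list(type = "sinusoid", amplitude = 0.6),
                          trend = NULL, noise_sd = 0.3, seed = 1L) {
  stopifnot(mean_pp > resp_effect$amplitude, resp_rate > 0, heart_rate > 0)
  rf <- .resp_shape(resp_effect$type, resp_effect$amplitude,
                    resp_effect$phase %||% 0)
  t <- (seq_len(n_beats) - 1) * 60 / heart_rate
  t_resp <- 60 / resp_rate
  insp <- seq(0, max(t) + 2 * t_resp, by = t_resp)
  pos <- resp_position(t, insp)
  tf <- .trend_fun(trend, min(t), max(t))
  pp <- .with_seed(seed,
    mean_pp + rf(pos) + tf(t) + stats::rnorm(n_beats, 0, noise_sd))
  grid <- seq(0, 1, length.out = 2048L)[-2048L]
  truth_ppv <- 100 * (max(rf(grid)) - min(rf(grid))) / mean_pp
  dia <- 60
  list(beats = data.frame(time = t, systolic = dia + pp, diastolic = dia,
                          pulse_pressure = pp, resp_position = pos),
       insp_starts = insp,
       truth = list(alpha = mean_pp, ppv = truth_ppv, resp_fun = rf,
                    trend_fun = tf))
}

#' Default CVP cardiac-cycle template
#'
#' Gaussian bumps for the a, c and v waves and dips for the x' and y
#' descents; `center` and `width` are fractions of the nominal cardiac
#' cycle, `amplitude` is in mmHg. Edit the returned data frame to change
#' landmark geometry in [gen_cvp_wave()].
#'
#' @return data frame with columns `landmark`, `center`, `width`,
#'   `amplitude`.
#' @export
cvp_default_template <- function() {
  data.frame(
    landmark = c("a", "c", "xprime", "v", "y"),
    center = c(0.08, 0.18, 0.35, 0.62, 0.80),
    width = c(0.05, 0.04, 0.07, 0.08, 0.06),
    amplitude = c(2.2, 1.2, -2.5, 1.8, -1.8))
}

.template_fun <- function(template, cycle_s) {
  centers <- template$center * cycle_s
  widths <- template$width * cycle_s
  amps <- template$amplitude
  function(pos_s, which = seq_len(nrow(template))) {
    v <- 0
    for (i in which)
      v <- v + amps[i] * exp(-(pos_s - centers[i])^2 / (2 * widths[i]^2))
    v
  }
}

#' Generate a synthetic CVP waveform with annotations and ground truth
#'
#' The waveform is the sum of a baseline, a cardiac-cycle template (Gaussian
#' a/c/v bumps and x'/y dips at fixed times after the P wave), a cyclic
#' additive respiratory effect, an interaction that modulates the depth of
#' the x' descent by respiratory phase (gain `g`: the x' amplitude is scaled
#' by `1 + g sin(2 pi resp_pos)`), a slow trend, AR(1) noise and optional
#' artifact bursts. Heart rate can be modulated by respiratory phase to
#' mimic respiratory sinus arrhythmia.
#'
#' @param duration_s record length in seconds.
#' @param sample_rate sampling rate in Hz (default 125).
#' @param heart_rate,resp_rate bpm / breaths per minute.
#' @param hr_rsa relative heart-period modulation by respiratory phase
#'   (0 = none).
#' @param baseline mean CVP in mmHg.
#' @param template cardiac template data frame (see
#'   [cvp_default_template()]).
#' @param resp_effect list `type` (`"plateau"` or `"sinusoid"`), `amplitude`
#'   mmHg.
#' @param interaction_gain x'-depth modulation gain `g` (0 disables the
#'   interaction).
#' @param trend as in [gen_pp_series()].
#' @param ar1_rho,noise_sd AR(1) coefficient and marginal SD of the noise.
#' @param outliers `NULL`, or list `at` (start times, s), `magnitude`
#'   (mmHg), `duration_s` of each artifact burst.
#' @param pr_interval PR interval used to place QRS annotations after the
#'   P waves.
#' @param seed integer seed.
#' @return list with `wave` (data frame `time`, `cvp`), `qrs_times`,
#'   `p_times`, `insp_starts`, `samples` (model-ready table: `time`, `cvp`,
#'   `cardiac_position`, `resp_position`) and `truth` (component functions
#'   and fields: `template_fun`, `resp_fun`, `interaction_fun(pos_s, resp)`,
#'   `trend_fun`, `baseline`, plus the noise-free component values per
#'   sample).
#' @export
gen_cvp_wave <- function(duration_s = 60, sample_rate = 125, heart_rate = 70,
                         resp_rate = 15, hr_rsa = 0, baseline = 8,
                         template = cvp_default_template(),
                         resp_effect = list(type = "plateau", amplitude = 2),
                         interaction_gain = 0.5, trend = NULL,
                         ar1_rho = 0.6, noise_sd = 0.3, outliers = NULL,
                         pr_interval = 0.15, seed = 1L) {
  stopifnot(ar1_rho >= 0, ar1_rho < 1)
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  t_resp <- 60 / resp_rate
  insp <- seq(0, duration_s + t_resp, by = t_resp)
  rpos_of <- function(tt) resp_position_modulo(tt, t_resp)
  # P-wave times, optionally with respiratory sinus arrhythmia
  cycle <- 60 / heart_rate
  p_times <- numeric(0); tp <- 0
  while (tp < duration_s + cycle) {
    p_times <- c(p_times, tp)
    tp <- tp + cycle * (1 + hr_rsa * sin(2 * pi * rpos_of(tp)))
  }
  qrs <- p_times + pr_interval
  cpos <- t - p_times[findInterval(t, p_times)]
  rpos <- rpos_of(t)
  tfun <- .template_fun(template, cycle)
  ix <- which(template$landmark == "xprime")
  rf <- .resp_shape(resp_effect$type, resp_effect$amplitude)
  interaction_fun <- function(pos_s, resp)
    interaction_gain * sin(2 * pi * resp) * tfun(pos_s, which = ix)
  trf <- .trend_fun(trend, 0, duration_s)
  comp <- list(cardiac = tfun(cpos), resp = rf(rpos),
               interaction = interaction_fun(cpos, rpos), trend = trf(t))
  noise <- .with_seed(seed, {
    innov <- stats::rnorm(length(t), 0, noise_sd * sqrt(1 - ar1_rho^2))
    as.numeric(stats::filter(innov, ar1_rho, method = "recursive"))
  })
  cvp <- baseline + comp$cardiac + comp$resp + comp$interaction + comp$trend + noise
  if (!is.null(outliers)) {
    for (i in seq_along(outliers$at)) {
      sel <- t >= outliers$at[i] & t < outliers$at[i] + outliers$duration_s
      cvp[sel] <- cvp[sel] + outliers$magnitude
    }
  }
  samples <- data.frame(time = t, cvp = cvp, cardiac_position = cpos,
                        resp_position = rpos)
  list(wave = data.frame(time = t, cvp = cvp),
       qrs_times = qrs[qrs <= duration_s], p_times = p_times,
       insp_starts = insp[insp <= duration_s],
       samples = samples,
       truth = list(baseline = baseline, template_fun = tfun, resp_fun = rf,
                    interaction_fun = interaction_fun, trend_fun = trf,
                    components = comp, noise = noise, ar1_rho = ar1_rho,
                    cycle_s = cycle))
}
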