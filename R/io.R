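# Delimited text input/output.
#
# Waveforms are 2-column delimited text (time_s, value_mmHg) with a header;
# event files are single-column timestamps in seconds; beat tables carry
# time_s, systolic_mmHg, diastolic_mmHg. The synthetic generators write the
# same formats the loaders read, so the command-line interface round-trips
# on files.

#' Read a waveform file
#'
#' @param path 2-column delimited text file (time_s, value_mmHg) with a
#'   header; the delimiter is sniffed from the header line (comma or tab).
#' @return data frame with columns `time`, `value` and attributes
#'   `sample_rate` (Hz, validated uniform within 1e-6 s).
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 2) stop("waveform file needs 2 columns (time_s, value)")
  names(d)[1:2] <- c("time", "value")
  dt <- diff(d$time)
  if (any(dt <= 0)) stop("waveform time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("waveform is not uniformly sampled (spacing varies by > 1e-6 s)")
  attr(d, "sample_rate") <- 1 / stats::median(dt)
  d
}

#' Read an event-timestamp file (one timestamp in seconds per line)
#' @param path single-column delimited text, with or without a header.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  first <- suppressWarnings(as.numeric(strsplit(readLines(path, n = 1), "[,\t ]")[[1]][1]))
  d <- utils::read.table(path, header = is.na(first))
  ev <- as.numeric(d[[1]])
  if (any(diff(ev) <= 0)) stop("event timestamps must be strictly increasing")
  ev
}

#' Read a beat table (time_s, systolic_mmHg, diastolic_mmHg)
#' @param path delimited text file with a header.
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop("beat table not found: ", path)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time_s", "systolic_mmHg", "diastolic_mmHg")
  if (!all(need %in% names(d)))
    stop("beat table needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(time = d$time_s, systolic = d$systolic_mmHg,
                    diastolic = d$diastolic_mmHg,
                    pulse_pressure = d$systolic_mmHg - d$diastolic_mmHg)
  if (any(out$pulse_pressure <= 0))
    warning("non-positive pulse pressures in beat table")
  out
}

#' @rdname read_waveform
#' @param wave data frame with `time` and a value column.
#' @export
write_waveform <- function(wave, path) {
  d <- data.frame(time_s = wave$time, value_mmHg = wave[[2]])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_events
#' @param events numeric timestamps.
#' @export
write_events <- function(events, path) {
  utils::write.table(data.frame(time_s = events), path, row.names = FALSE,
                     col.names = TRUE, sep = ",")
  invisible(path)
}

#' @rdname read_beats
#' @param beats beat series data frame.
#' @export
write_beats <- function(beats, path) {
  utils::write.csv(data.frame(time_s = beats$time,
                              systolic_mmHg = beats$systolic,
                              diastolic_mmHg = beats$diastolic), path,
                   row.names = FALSE)
  invisible(path)
}

# tidy long-format export of per-term grids: one row per (term, grid point)
.term_grid_table <- function(fit, newdata, terms) {
  pt <- predict_terms(fit, newdata)
  out <- NULL
  for (lab in terms) {
    tt <- pt$terms[[lab]]
    out <- rbind(out, cbind(data.frame(term = lab), newdata,
                            value = tt$value, se = tt$se))
  }
  out
}

.fit_summary_list <- function(fit, extra = list()) {
  c(list(package_version = as.character(utils::packageVersion("hemogam")),
         loss = fit$loss, n = fit$n, rho = fit$rho,
         sigma = sqrt(fit$sigma2),
         lambda = as.list(fit$lambdas), edf = as.list(round(fit$edf, 3))),
    extra)
}
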