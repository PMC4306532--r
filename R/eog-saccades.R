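# Saccade-onset detection from EOG and trial-exclusion rules.
#
# Onset is the time of the maximal absolute first difference of the smoothed
# horizontal EOG within a post-target search window; trials are excluded for
# baseline blinks, under-sized or misdirected first saccades, latencies
# outside 75-500 ms, or an undetermined onset.

#' Detect the saccade onset of one trial
#'
#' @param h_eog,v_eog smoothed horizontal and vertical EOG traces (same
#'   length). Positive horizontal deflection = rightward saccade.
#' @param sfreq sampling rate, Hz.
#' @param t0 time of the first sample, s relative to target onset.
#' @param search_window onset search window, s post-target (default
#'   `c(0.075, 0.7)`; latency validity is enforced separately).
#' @param min_slope noise floor for the per-sample differential; a maximum
#'   below it flags the trial `undetermined`.
#' @param calibration horizontal EOG units corresponding to the full stimulus
#'   eccentricity (saccade amplitude is reported as a fraction of it).
#' @param baseline_window window (s) used for the blink check on the vertical
#'   channel.
#' @param blink_threshold absolute vertical excursion (same units as `v_eog`)
#'   flagged as a blink/fixation violation within the baseline.
#' @return one-row `data.frame`: `onset_ms`, `direction`, `amplitude`,
#'   `undetermined`, `blink`.
#' @export
detect_saccade_onset <- function(h_eog, v_eog, sfreq, t0,
                                 search_window = c(0.075, 0.7),
                                 min_slope = 0.02, calibration = 1,
                                 baseline_window = c(-1, 0),
                                 blink_threshold = 0.5) {
  n <- length(h_eog)
  times <- t0 + (seq_len(n) - 1L) / sfreq
  if (times[n] < search_window[2] * 0.99) {
    stop("trace does not cover the onset search window")
  }
  d <- diff(h_eog)
  dt <- times[-1]
  cand <- which(dt >= search_window[1] & dt <= search_window[2])
  imax <- cand[which.max(abs(d[cand]))]   # which.max: earliest wins on ties
  undet <- abs(d[imax]) < min_slope
  onset_ms <- if (undet) NA_real_ else dt[imax] * 1000
  direction <- if (undet) NA_character_ else if (d[imax] > 0) "right" else "left"
  amplitude <- NA_real_
  if (!undet) {
    pre <- which(times >= dt[imax] - 0.15 & times <= dt[imax] - 0.05)
    post <- which(times >= dt[imax] + 0.05 & times <= dt[imax] + 0.15)
    if (length(pre) && length(post)) {
      amplitude <- abs(mean(h_eog[post]) - mean(h_eog[pre])) / calibration
    }
  }
  bidx <- which(times >= baseline_window[1] & times <= baseline_window[2])
  blink <- max(abs(v_eog[bidx] - stats::median(v_eog[bidx]))) > blink_threshold
  data.frame(onset_ms = onset_ms, direction = direction,
             amplitude = amplitude, undetermined = undet, blink = blink,
             stringsAsFactors = FALSE)
}

#' Detect saccades on all trials of an EOG recording
#'
#' Smooths each trace with the Savitzky-Golay filter ([smooth_eog()], order 3,
#' window 31 samples) and applies [detect_saccade_onset()] per trial.
#'
#' @param eog an `eog_traces` object ([simulate_eog()] or any list with
#'   trials x samples matrices `h`, `v`, plus `times` and `sfreq`).
#' @param sg_order,sg_window Savitzky-Golay parameters.
#' @param ... passed to [detect_saccade_onset()].
#' @return `data.frame` of saccade events, one row per trial, with `trial_id`.
#' @export
detect_saccades <- function(eog, sg_order = 3, sg_window = 31, ...) {
  n <- nrow(eog$h)
  t0 <- eog$times[1]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    h <- smooth_eog(eog$h[i, ], sg_order, sg_window)
    v <- smooth_eog(eog$v[i, ], sg_order, sg_window)
    rows[[i]] <- detect_saccade_onset(h, v, eog$sfreq, t0, ...)
  }
  out <- do.call(rbind, rows)
  out$trial_id <- seq_len(n)
  out[, c("trial_id", setdiff(names(out), "trial_id"))]
}

#' Apply the trial-exclusion rules
#'
#' Excludes trials with a baseline blink/fixation violation, a first-saccade
#' amplitude below half the stimulus eccentricity, a saccade directed away
#' from a single target (directional error), a latency outside
#' `latency_range`, or an undetermined onset. Exclusion is idempotent:
#' re-applying it to an already filtered table removes nothing.
#'
#' @param events saccade events from [detect_saccades()], one row per trial
#'   of `table` (matched by `trial_id`).
#' @param table a `trial_table`.
#' @param latency_range valid saccade latencies, ms (default `c(75, 500)`).
#' @param min_amplitude minimum saccade amplitude, fraction of eccentricity.
#' @return list with `table` (the included trials, `rt` replaced by the
#'   detected latency) and `report` (an `exclusion_report`: per-reason counts,
#'   per-trial reasons, fraction excluded).
#' @export
apply_exclusions <- function(events, table, latency_range = c(75, 500),
                             min_amplitude = 0.5) {
  ev <- events[match(table$trial_id, events$trial_id), , drop = FALSE]
  if (any(is.na(ev$trial_id))) stop("events missing for some trials")
  undet <- ev$undetermined | is.na(ev$onset_ms)
  blink <- ev$blink
  amp <- !undet & !is.na(ev$amplitude) & ev$amplitude < min_amplitude
  direrr <- !undet & table$condition %in% c("left", "right") &
    ev$direction != table$condition
  lat <- !undet &
    (ev$onset_ms < latency_range[1] | ev$onset_ms > latency_range[2])
  reasons <- cbind(`blink/fixation` = blink, amplitude = amp,
                   `direction-error` = direrr, `latency-range` = lat,
                   undetermined = undet)
  excl <- rowSums(reasons) > 0
  reason_str <- apply(reasons, 1, function(z) {
    paste(colnames(reasons)[z], collapse = ";")
  })
  out <- table[!excl, , drop = FALSE]
  out$rt <- ev$onset_ms[!excl]
  report <- structure(list(
    n_trials = nrow(table), n_excluded = sum(excl),
    fraction_excluded = mean(excl),
    reason_counts = colSums(reasons),
    trial_reasons = data.frame(trial_id = table$trial_id,
                               excluded = excl, reason = reason_str,
                               stringsAsFactors = FALSE)),
    class = "exclusion_report")
  list(table = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion_report:", x$n_excluded, "of", x$n_trials, "trials excluded (",
      sprintf("%.1f%%", 100 * x$fraction_excluded), ")\n")
  print(x$reason_counts)
  invisible(x)
}
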