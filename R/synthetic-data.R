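# Synthetic-data generator: trial schedules with a non-aging foreperiod,
# reaction times with controlled deterministic and spontaneous structure,
# sensor-level MEG epochs produced by dipole sources in a spherical head
# model with ground-truth amplitude-RT coupling, and EOG traces.

#' Define a ground-truth oscillatory source
#'
#' A dipolar source emitting band-limited noise whose baseline envelope is
#' coupled, trial by trial, to the reaction time through a shared standardized
#' latent variable.
#'
#' @param position 3-vector, head-frame mm (head sphere centered at origin).
#' @param orientation unit 3-vector dipole orientation; only its tangential
#'   component radiates in a spherical conductor. `NULL` (default) picks a
#'   tangential direction automatically.
#' @param center_freq,bandwidth center frequency and full bandwidth, Hz.
#' @param base_amplitude source RMS in sensor units of its unit-norm field
#'   topography (see [simulate_sensor_epochs()]).
#' @param rt_coupling_r target Pearson correlation between the trial's
#'   baseline envelope and RT, in `[-1, 1]`.
#' @param coupling_window window (s, relative to target onset) over which the
#'   per-trial envelope scaling applies.
#' @param envelope_depth fractional envelope modulation per latent SD
#'   (default 0.4): the per-trial envelope factor is
#'   `max(1 + envelope_depth * z, 0.05)` with `z ~ N(0, 1)`. The default
#'   keeps the across-trial envelope variation well above the narrowband
#'   amplitude-estimation noise (CV ~ 0.1 for a 10 Hz band over 1 s), so the
#'   injected coupling is measurable at the sensors.
#' @return object of class `ground_truth_source`.
#' @export
ground_truth_source <- function(position, orientation = NULL,
                                center_freq = 10, bandwidth = 10,
                                base_amplitude = 2, rt_coupling_r = 0,
                                coupling_window = c(-1, 0),
                                envelope_depth = 0.4) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3)
  if (abs(rt_coupling_r) > 1) stop("|rt_coupling_r| must be <= 1")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(orientation)) {
    orientation <- .tangential_basis(position)[, 1]
  }
  orientation <- as.numeric(orientation)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(position = position, orientation = orientation,
                 center_freq = center_freq, bandwidth = bandwidth,
                 base_amplitude = base_amplitude,
                 rt_coupling_r = rt_coupling_r,
                 coupling_window = as.numeric(coupling_window),
                 envelope_depth = envelope_depth),
            class = "ground_truth_source")
}

# moments of the truncated-exponential foreperiod on [a, b], rate `rate`
.foreperiod_moments <- function(range, rate) {
  w <- range[2] - range[1]
  den <- 1 - exp(-rate * w)
  m1 <- stats::integrate(function(x) x * rate * exp(-rate * x) / den, 0, w)$value
  m2 <- stats::integrate(function(x) x^2 * rate * exp(-rate * x) / den, 0, w)$value
  list(mean = range[1] + m1, var = m2 - m1^2)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic experiment. Defaults reproduce the
#' study conditions the generator emulates: 800 trials in 4 equal blocks,
#' three equiprobable trial types (left/right single target, two-target free
#' choice), a non-aging foreperiod on `[3, 4]` s (constant-hazard truncated
#' exponential), a 262 ms grand-mean RT with 48 ms total SD of which the
#' inter-trial interval accounts for 1.2%, current x previous condition for
#' 7.9% and blockwise linear trends for 8.6% of the variance, 600 Hz sampling
#' and an epoch of `[-2.7, 0.7]` s around target onset.
#'
#' Deterministic RT effect sizes may be given directly (`iti_slope`,
#' `condition_offsets`, `block_trend_slopes`); when `NULL` they are derived
#' from the variance shares. `condition_offsets` is a 3x3 matrix (current x
#' previous condition, order left/right/choice); the derived version keeps the
#' current-condition choice penalty at `choice_penalty` ms and scales a
#' previous-condition repeat/alternate pattern so the total between-cell
#' variance matches `var_share_condition`.
#'
#' @param n_trials,n_blocks trial count and number of contiguous equal blocks.
#' @param condition_probs probabilities of left/right/choice trials (sum 1).
#' @param foreperiod_range,foreperiod_rate truncation interval (s) and hazard
#'   rate (1/s) of the foreperiod.
#' @param rt_mean,rt_total_sd grand mean and total SD of RT, ms.
#' @param var_share_iti,var_share_condition,var_share_block variance fractions
#'   of the deterministic components.
#' @param iti_slope ms of RT per second of ITI (overrides `var_share_iti`).
#' @param condition_offsets 3x3 ms offsets (overrides `var_share_condition`).
#' @param block_trend_slopes ms per trial, one per block (overrides
#'   `var_share_block`).
#' @param choice_penalty ms added to choice trials (kept exact in the derived
#'   offsets).
#' @param choice_bias probability that a choice trial ends leftward.
#' @param rt_sd_spontaneous residual RT SD, ms; derived from `rt_total_sd`
#'   minus all injected components when `NULL`.
#' @param sfreq sampling rate, Hz.
#' @param epoch_window epoch limits (s) relative to target onset.
#' @param n_channels number of MEG channels on the sensor cap.
#' @param head_radius,sensor_radius,sensor_cap_deg head-sphere radius, sensor
#'   shell radius (mm) and angular cap extent (degrees).
#' @param source_specs list of [ground_truth_source()] objects.
#' @param sensor_noise_sd i.i.d. Gaussian sensor noise SD, sensor units.
#' @param eog_amplitude,eog_noise_sd,eog_tau EOG step amplitude (1 = full
#'   stimulus eccentricity), additive noise SD and sigmoid time constant (s).
#' @param seed integer RNG seed; every generator draw derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 800, n_blocks = 4,
                       condition_probs = c(left = 1/3, right = 1/3, choice = 1/3),
                       foreperiod_range = c(3, 4), foreperiod_rate = 1 / 0.35,
                       rt_mean = 262, rt_total_sd = 48,
                       var_share_iti = 0.012, var_share_condition = 0.079,
                       var_share_block = 0.086,
                       iti_slope = NULL, condition_offsets = NULL,
                       block_trend_slopes = NULL,
                       choice_penalty = 14, choice_bias = 0.5,
                       rt_sd_spontaneous = NULL,
                       sfreq = 600, epoch_window = c(-2.7, 0.7),
                       n_channels = 30, head_radius = 90,
                       sensor_radius = 110, sensor_cap_deg = 75,
                       source_specs = list(), sensor_noise_sd = 2,
                       eog_amplitude = 1, eog_noise_sd = 0.02, eog_tau = 0.005,
                       seed = 1L) {
  condition_probs <- as.numeric(condition_probs)
  if (length(condition_probs) != 3 || any(condition_probs < 0) ||
      abs(sum(condition_probs) - 1) > 1e-8) {
    stop("condition_probs must be 3 non-negative probabilities summing to 1")
  }
  names(condition_probs) <- c("left", "right", "choice")
  if (n_trials %% n_blocks != 0) {
    stop("n_trials must divide into n_blocks equal blocks")
  }
  if (diff(foreperiod_range) <= 0) stop("invalid foreperiod_range")
  for (s in source_specs) {
    if (!inherits(s, "ground_truth_source")) {
      stop("source_specs must be a list of ground_truth_source objects")
    }
    if (sqrt(sum(s$position^2)) >= head_radius) {
      stop("source position outside the head sphere")
    }
  }

  v_tot <- rt_total_sd^2
  fp <- .foreperiod_moments(foreperiod_range, foreperiod_rate)

  if (is.null(iti_slope)) {
    iti_slope <- sqrt(var_share_iti * v_tot / fp$var)
  }
  v_iti <- iti_slope^2 * fp$var

  p <- condition_probs
  if (is.null(condition_offsets)) {
    # current-condition part: exact choice penalty, zero offset on single
    # targets so rt_mean is the single-target grand mean (the reporting
    # convention for saccadic RT)
    cur <- c(left = 0, right = 0, choice = choice_penalty)
    cur_c <- cur - sum(p * cur)
    v_cur <- sum(p * cur_c^2)
    target <- var_share_condition * v_tot
    if (target < v_cur - 1e-9) {
      stop("var_share_condition too small for the requested choice_penalty")
    }
    # previous-condition pattern, unit weighted variance, scaled to remainder
    prev <- c(left = -1, right = 1, choice = 0.5)
    prev <- prev - sum(p * prev)
    pv <- sum(p * prev^2)
    prev <- if (pv > 1e-12) {
      prev / sqrt(pv) * sqrt(max(0, target - v_cur))
    } else rep(0, 3)  # degenerate probabilities: no previous-condition cells
    condition_offsets <- outer(cur, rep(1, 3)) + outer(rep(1, 3), prev)
    dimnames(condition_offsets) <- list(current = names(p), previous = names(p))
  } else {
    condition_offsets <- as.matrix(condition_offsets)
    stopifnot(all(dim(condition_offsets) == c(3, 3)))
  }
  cellp <- outer(p, p)
  off_c <- condition_offsets - sum(cellp * condition_offsets)
  v_cond <- sum(cellp * off_c^2)

  m <- n_trials / n_blocks
  v_time <- (m^2 - 1) / 12   # variance of the within-block trial index
  if (is.null(block_trend_slopes)) {
    b <- sqrt(var_share_block * v_tot / v_time)
    block_trend_slopes <- b * rep_len(c(1, -1), n_blocks)
  }
  stopifnot(length(block_trend_slopes) == n_blocks)
  v_block <- mean(block_trend_slopes^2) * v_time

  coupling_r <- vapply(source_specs, function(s) s$rt_coupling_r, numeric(1))
  coupling_beta <- coupling_r * sqrt(v_tot)
  v_coup <- sum(coupling_beta^2)

  if (is.null(rt_sd_spontaneous)) {
    v_res <- v_tot - v_iti - v_cond - v_block - v_coup
    if (v_res <= 0) {
      stop("requested variance shares exceed the total RT variance")
    }
    rt_sd_spontaneous <- sqrt(v_res)
  } else {
    v_tot <- rt_sd_spontaneous^2 + v_iti + v_cond + v_block + v_coup
    coupling_beta <- coupling_r * sqrt(v_tot)  # keep target correlations
  }

  structure(list(
    n_trials = as.integer(n_trials), n_blocks = as.integer(n_blocks),
    condition_probs = condition_probs,
    foreperiod_range = foreperiod_range, foreperiod_rate = foreperiod_rate,
    rt_mean = rt_mean, rt_total_sd = sqrt(v_tot),
    iti_slope = iti_slope, condition_offsets = condition_offsets,
    block_trend_slopes = block_trend_slopes,
    choice_penalty = choice_penalty, choice_bias = choice_bias,
    rt_sd_spontaneous = rt_sd_spontaneous,
    coupling_beta = coupling_beta,
    foreperiod_moments = fp,
    component_variances = c(iti = v_iti, condition = v_cond,
                            block = v_block, coupling = v_coup,
                            residual = rt_sd_spontaneous^2),
    sfreq = sfreq, epoch_window = as.numeric(epoch_window),
    n_channels = as.integer(n_channels), head_radius = head_radius,
    sensor_radius = sensor_radius, sensor_cap_deg = sensor_cap_deg,
    source_specs = source_specs, sensor_noise_sd = sensor_noise_sd,
    eog_amplitude = eog_amplitude, eog_noise_sd = eog_noise_sd,
    eog_tau = eog_tau,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_trials, "trials /", x$n_blocks, "blocks,",
      x$n_channels, "channels @", x$sfreq, "Hz, epoch [",
      x$epoch_window[1], ",", x$epoch_window[2], "] s\n")
  cat("  RT:", x$rt_mean, "ms mean,", round(x$rt_total_sd, 1), "ms SD;",
      length(x$source_specs), "ground-truth source(s)\n")
  invisible(x)
}

# inverse-CDF draw from the constant-hazard (exponential) foreperiod
# truncated to `range`
.draw_foreperiod <- function(n, range, rate) {
  w <- range[2] - range[1]
  u <- stats::runif(n)
  range[1] - log(1 - u * (1 - exp(-rate * w))) / rate
}

#' Generate the trial schedule
#'
#' Draws conditions i.i.d. from `condition_probs`, a constant-hazard
#' foreperiod truncated to `foreperiod_range`, contiguous equal-sized blocks,
#' and the choice outcome of choice trials (Bernoulli with `choice_bias`).
#' The previous-trial condition of the first trial of each block is the
#' dedicated level `"start"`. RT is filled in by [generate_rt()].
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `trial_table` with columns `trial_id`,
#'   `block`, `time_in_block`, `condition`, `prev_condition`, `iti`,
#'   `choice_made`, `rt`, `excluded`, `reason`.
#' @export
generate_trial_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_trials
  m <- n / config$n_blocks
  cond_levels <- c("left", "right", "choice")
  condition <- sample(cond_levels, n, replace = TRUE, prob = config$condition_probs)
  block <- rep(seq_len(config$n_blocks), each = m)
  time_in_block <- rep(seq_len(m), times = config$n_blocks)
  prev <- c("start", condition[-n])
  prev[time_in_block == 1] <- "start"
  iti <- .draw_foreperiod(n, config$foreperiod_range, config$foreperiod_rate)
  choice_made <- rep("none", n)
  is_choice <- condition == "choice"
  choice_made[is_choice] <- ifelse(
    stats::runif(sum(is_choice)) < config$choice_bias, "left", "right")
  out <- data.frame(trial_id = seq_len(n), block = block,
                    time_in_block = time_in_block,
                    condition = condition, prev_condition = prev,
                    iti = iti, choice_made = choice_made,
                    rt = NA_real_, excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Generate reaction times with controlled structure
#'
#' RT is the sum of the grand mean, a linear ITI effect, current x previous
#' condition offsets, a within-block linear trend, the amplitude-coupling term
#' `sum(beta_s * z_s)` over ground-truth sources, and a Gaussian residual.
#' Coupling coefficients are chosen in [sim_config()] so that the population
#' correlation between each source's standardized latent envelope and RT
#' equals its `rt_coupling_r`. Non-positive RTs are redrawn (residual only).
#'
#' @param table a `trial_table` from [generate_trial_schedule()].
#' @param config the matching [sim_config()].
#' @param latent_amplitude trials x sources matrix of standardized latent
#'   envelopes (from [simulate_sensor_epochs()]), or `NULL` when there are no
#'   sources or no coupling is wanted.
#' @return `table` with the `rt` column filled; the deterministic/stochastic
#'   components are attached as attribute `"rt_components"` for bookkeeping.
#' @export
generate_rt <- function(table, config, latent_amplitude = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(table)
  iti_c <- table$iti - mean(table$iti)
  comp_iti <- config$iti_slope * iti_c

  off <- config$condition_offsets   # applied as configured (no re-centering)
  cur_idx <- match(table$condition, c("left", "right", "choice"))
  prev_idx <- match(table$prev_condition, c("left", "right", "choice"))
  comp_cond <- numeric(n)
  in_cell <- !is.na(prev_idx)
  comp_cond[in_cell] <- off[cbind(cur_idx[in_cell], prev_idx[in_cell])]
  # block-start trials: current-condition marginal effect only
  marg <- as.numeric(off %*% config$condition_probs)
  comp_cond[!in_cell] <- marg[cur_idx[!in_cell]]

  m <- n / config$n_blocks
  t_c <- table$time_in_block - (m + 1) / 2
  comp_block <- config$block_trend_slopes[table$block] * t_c

  comp_coup <- numeric(n)
  if (length(config$source_specs) > 0) {
    if (is.null(latent_amplitude)) {
      stop("latent_amplitude required when source_specs are present")
    }
    latent_amplitude <- as.matrix(latent_amplitude)
    stopifnot(nrow(latent_amplitude) == n,
              ncol(latent_amplitude) == length(config$source_specs))
    comp_coup <- as.numeric(latent_amplitude %*% config$coupling_beta)
  }

  resid <- stats::rnorm(n, 0, config$rt_sd_spontaneous)
  rt <- config$rt_mean + comp_iti + comp_cond + comp_block + comp_coup + resid
  bad <- which(rt <= 0)
  while (length(bad) > 0) {
    resid[bad] <- stats::rnorm(length(bad), 0, config$rt_sd_spontaneous)
    rt[bad] <- config$rt_mean + comp_iti[bad] + comp_cond[bad] +
      comp_block[bad] + comp_coup[bad] + resid[bad]
    bad <- which(rt <= 0)
  }
  table$rt <- rt
  attr(table, "rt_components") <- list(iti = comp_iti, condition = comp_cond,
                                       block = comp_block, coupling = comp_coup,
                                       residual = resid)
  table
}

#' Epoch time axis of a configuration
#' @param config a [sim_config()].
#' @return numeric vector of sample times (s) relative to target onset.
#' @export
epoch_times <- function(config) {
  n_samp <- round(diff(config$epoch_window) * config$sfreq) + 1L
  config$epoch_window[1] + (seq_len(n_samp) - 1L) / config$sfreq
}

# smooth 0/1 window over `win` with raised-cosine ramps (`ramp` s)
.smooth_window <- function(times, win, ramp = 0.1) {
  w <- numeric(length(times))
  w[times >= win[1] & times <= win[2]] <- 1
  up <- times >= (win[1] - ramp) & times < win[1]
  w[up] <- 0.5 * (1 + cos(pi * (win[1] - times[up]) / ramp))
  dn <- times > win[2] & times <= (win[2] + ramp)
  w[dn] <- 0.5 * (1 + cos(pi * (times[dn] - win[2]) / ramp))
  w
}

#' Simulate multi-channel MEG epochs from the ground-truth sources
#'
#' Each source emits band-limited Gaussian noise (its `center_freq +/-
#' bandwidth/2`), normalized per trial to RMS `base_amplitude` over the
#' coupling window and then multiplied by a smooth per-trial envelope
#' `max(1 + envelope_depth * z, 0.05)` inside that window (`z` the standardized
#' latent shared with [generate_rt()]). Source signals reach the sensors
#' through the spherical-conductor forward operator with the source's field
#' topography normalized to unit L2 norm, so `base_amplitude` and
#' `sensor_noise_sd` set the sensor-level SNR directly. I.i.d. Gaussian noise
#' is added to every channel.
#'
#' @param table a `trial_table` (row order defines the trial axis).
#' @param config the matching [sim_config()].
#' @return a list with components
#'   `epochs` (a `sensor_epochs` object: `data` trials x channels x samples,
#'   `sfreq`, `t0`, `times`, `channel_positions`, `channel_orientations`,
#'   `model`), `true_amplitude` (trials x sources envelope factors) and
#'   `latents` (the standardized latents to pass to [generate_rt()]).
#' @export
simulate_sensor_epochs <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(table)
  times <- epoch_times(config)
  n_samp <- length(times)
  model <- sphere_head_model(radius = config$head_radius)
  sensors <- fibonacci_cap_sensors(config$n_channels,
                                   radius = config$sensor_radius,
                                   cap_deg = config$sensor_cap_deg)
  n_src <- length(config$source_specs)
  data <- array(stats::rnorm(n * config$n_channels * n_samp,
                             0, config$sensor_noise_sd),
                dim = c(n, config$n_channels, n_samp))
  latents <- matrix(numeric(0), nrow = n, ncol = 0)
  true_amp <- matrix(numeric(0), nrow = n, ncol = 0)
  if (n_src > 0) {
    latents <- matrix(stats::rnorm(n * n_src), n, n_src)
    true_amp <- matrix(1, n, n_src)
    for (k in seq_len(n_src)) {
      s <- config$source_specs[[k]]
      lf <- leadfield(model, s$position, s$orientation, sensors)
      lf <- lf / sqrt(sum(lf^2))
      raw <- matrix(stats::rnorm(n_samp * n), n_samp, n)
      raw <- bp_filter(raw, config$sfreq,
                       s$center_freq - s$bandwidth / 2,
                       s$center_freq + s$bandwidth / 2)
      in_win <- times >= s$coupling_window[1] & times <= s$coupling_window[2]
      rms <- sqrt(colMeans(raw[in_win, , drop = FALSE]^2))
      raw <- sweep(raw, 2, s$base_amplitude / rms, `*`)
      fac <- pmax(1 + s$envelope_depth * latents[, k], 0.05)
      true_amp[, k] <- fac
      w <- .smooth_window(times, s$coupling_window)
      env <- 1 + outer(w, fac - 1)            # samples x trials
      src <- raw * env
      # accumulate lf (x) src into the epoch array
      contrib <- outer(lf, t(src))            # channels x trials x samples
      data <- data + aperm(contrib, c(2, 1, 3))
    }
  }
  epochs <- structure(list(data = data, sfreq = config$sfreq,
                           t0 = config$epoch_window[1], times = times,
                           channel_positions = sensors$positions,
                           channel_orientations = sensors$orientations,
                           model = model),
                      class = "sensor_epochs")
  list(epochs = epochs, true_amplitude = true_amp, latents = latents)
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("sensor_epochs:", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", x$sfreq, "Hz, t0 =", x$t0, "s\n")
  invisible(x)
}

#' Simulate horizontal and vertical EOG traces
#'
#' The horizontal EOG of each trial is a smooth sigmoidal step of amplitude
#' `eog_amplitude` (sign by saccade direction: rightward positive) starting at
#' `target onset + rt`, plus Gaussian noise. Optional blink artifacts (a large
#' Gaussian bump on the vertical channel during the baseline) and reduced
#' saccade amplitudes can be injected per trial for exclusion-rule tests.
#'
#' @param table a `trial_table` with `rt` filled.
#' @param config the matching [sim_config()].
#' @param amplitude_frac optional per-trial saccade amplitude as a fraction of
#'   the stimulus eccentricity (default 1).
#' @param blink optional logical per-trial blink-injection flags.
#' @param direction optional per-trial saccade direction override
#'   (`"left"`/`"right"`); defaults to the target side (single-target trials)
#'   or the recorded choice.
#' @return list of class `eog_traces` with matrices `h`, `v`
#'   (trials x samples), `times` and `sfreq`.
#' @export
simulate_eog <- function(table, config, amplitude_frac = NULL, blink = NULL,
                         direction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(is.na(table$rt))) stop("rt must be generated before EOG")
  set.seed(config$seed + 3L)
  n <- nrow(table)
  times <- epoch_times(config)
  if (is.null(amplitude_frac)) amplitude_frac <- rep(1, n)
  if (is.null(blink)) blink <- rep(FALSE, n)
  if (is.null(direction)) {
    direction <- ifelse(table$condition == "choice",
                        table$choice_made, table$condition)
  }
  sgn <- ifelse(direction == "right", 1, -1)
  h <- matrix(stats::rnorm(n * length(times), 0, config$eog_noise_sd),
              n, length(times))
  v <- matrix(stats::rnorm(n * length(times), 0, config$eog_noise_sd),
              n, length(times))
  for (i in seq_len(n)) {
    t_sac <- table$rt[i] / 1000
    step <- config$eog_amplitude * amplitude_frac[i] *
      stats::plogis((times - t_sac) / config$eog_tau)
    h[i, ] <- h[i, ] + sgn[i] * step
    if (blink[i]) {
      t_b <- -0.5
      v[i, ] <- v[i, ] + 1.5 * config$eog_amplitude *
        exp(-((times - t_b) / 0.05)^2)
    }
  }
  structure(list(h = h, v = v, times = times, sfreq = config$sfreq),
            class = "eog_traces")
}
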