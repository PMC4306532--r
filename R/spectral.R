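# Virtual-electrode reconstruction, Hilbert filter-bank time-frequency
# amplitude/phase, trial-wise TF correlation maps, fast/slow spectra and the
# r-timecourse trend analysis.

#' Define a virtual electrode
#'
#' @param name electrode label (e.g. `"V1-L-01"`, `"SEF"`).
#' @param position head-frame position, mm.
#' @return object of class `virtual_electrode`.
#' @export
virtual_electrode <- function(name, position) {
  structure(list(name = name, position = as.numeric(position)),
            class = "virtual_electrode")
}

#' Map MNI-like coordinates onto the synthetic head sphere
#'
#' The electrode fixtures carry literature MNI coordinates; with no
#' individual anatomy in scope they are mapped to the spherical model by a
#' single documented affine scaling that keeps every site inside the head.
#'
#' @param p coordinate 3-vector or n x 3 matrix, mm.
#' @param scale scaling factor (default 0.75).
#' @return scaled coordinates.
#' @export
mni_to_head <- function(p, scale = 0.75) {
  p * scale
}

#' Load the bundled virtual-electrode fixture
#'
#' Twenty synthetic V1 sites (10 per hemisphere along a calcarine-like axis)
#' plus SEF, left/right FEF and left/right IPS at literature MNI coordinates,
#' mapped to the head sphere with [mni_to_head()].
#'
#' @param file JSON fixture path; defaults to the bundled file.
#' @param scale passed to [mni_to_head()].
#' @return named list of [virtual_electrode()] objects.
#' @export
load_virtual_electrodes <- function(file = system.file("extdata",
                                      "virtual_electrodes_synthetic.json",
                                      package = "prestim"),
                                    scale = 0.75) {
  spec <- as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    virtual_electrode(spec$name[i],
                      mni_to_head(c(spec$x[i], spec$y[i], spec$z[i]), scale))
  })
  stats::setNames(out, spec$name)
}

#' Project epochs through a virtual electrode
#'
#' Beamformer weights at the electrode position are estimated from a
#' broadband (0-100 Hz by default) global covariance and the full-bandwidth
#' signal is projected through them, giving one source time series per trial
#' with unit gain at the electrode.
#'
#' @param epochs a `sensor_epochs` object.
#' @param electrode a [virtual_electrode()].
#' @param cov_obj optional precomputed [global_covariance()]; computed from
#'   `cov_band`/`cov_window` when `NULL`.
#' @param cov_band,cov_window band (Hz) and window (s) of the weight
#'   covariance (defaults 0-100 Hz, whole epoch).
#' @param reg diagonal-loading fraction (see [sam_weights()]).
#' @return trials x samples matrix with attributes `sfreq`, `times`, `name`.
#' @export
project_virtual_electrode <- function(epochs, electrode, cov_obj = NULL,
                                      cov_band = c(0, 100),
                                      cov_window = NULL, reg = 0.05) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  model <- epochs$model
  if (sqrt(sum((electrode$position - model$center)^2)) >= model$radius) {
    stop("electrode position outside the head")
  }
  if (is.null(cov_obj)) {
    if (is.null(cov_window)) cov_window <- range(epochs$times)
    cov_obj <- global_covariance(epochs, cov_band, cov_window)
  }
  sensors <- list(positions = epochs$channel_positions,
                  orientations = epochs$channel_orientations)
  ws <- sam_weights(cov_obj, model,
                    list(positions = matrix(electrode$position, nrow = 1)),
                    sensors, reg = reg)
  w <- ws$weights[1, ]
  d <- dim(epochs$data)
  proj <- matrix(NA_real_, d[1], d[3])
  for (i in seq_len(d[1])) proj[i, ] <- w %*% epochs$data[i, , ]
  attr(proj, "sfreq") <- epochs$sfreq
  attr(proj, "times") <- epochs$times
  attr(proj, "name") <- electrode$name
  proj
}

#' Hilbert filter-bank time-frequency decomposition
#'
#' For each center frequency, band-pass filters `f +/- half_bw` Hz (zero-phase
#' Butterworth, mirror padding) and takes the analytic signal: amplitude is
#' its modulus, phase its argument. Time is then decimated by plain
#' subsampling (the narrow bands guarantee anti-aliasing).
#'
#' @param x trials x samples matrix (e.g. from
#'   [project_virtual_electrode()]); a plain matrix with `sfreq`/`times`
#'   attributes or explicit arguments.
#' @param sfreq sampling rate, Hz (default from attribute).
#' @param times sample times, s (default from attribute).
#' @param freqs center frequencies, Hz (default `5:100`).
#' @param half_bw half bandwidth of each band, Hz (default 4).
#' @param order one-way Butterworth order (default 4).
#' @param decim decimation factor (default 2).
#' @return object of class `tf_tensor`: `amplitude` and `phase`
#'   (trials x freqs x time), `freqs`, `times`, `sfreq`.
#' @export
hilbert_tf <- function(x, sfreq = attr(x, "sfreq"), times = attr(x, "times"),
                       freqs = 5:100, half_bw = 4, order = 4, decim = 2) {
  stopifnot(is.matrix(x), !is.null(sfreq), !is.null(times))
  if (sfreq < 2 * (max(freqs) + half_bw)) {
    stop("sfreq too low for the requested frequency range")
  }
  n_tr <- nrow(x)
  keep <- seq(1, ncol(x), by = decim)
  amp <- array(NA_real_, c(n_tr, length(freqs), length(keep)))
  ph <- array(NA_real_, c(n_tr, length(freqs), length(keep)))
  xt <- t(x)   # time x trials
  for (k in seq_along(freqs)) {
    z <- analytic_bp(xt, sfreq, freqs[k] - half_bw, freqs[k] + half_bw,
                     order = order)
    z <- z[keep, , drop = FALSE]
    amp[, k, ] <- t(Mod(z))
    ph[, k, ] <- t(Arg(z))
  }
  structure(list(amplitude = amp, phase = ph, freqs = freqs,
                 times = times[keep], sfreq = sfreq / decim),
            class = "tf_tensor")
}

#' @export
print.tf_tensor <- function(x, ...) {
  d <- dim(x$amplitude)
  cat("tf_tensor:", d[1], "trials x", d[2], "freqs (",
      min(x$freqs), "-", max(x$freqs), "Hz ) x", d[3], "time points\n")
  invisible(x)
}

# indices of `times` grouped into consecutive `bin_sec` bins over `window`
.time_bins <- function(times, bin_sec, window = range(times)) {
  edges <- seq(window[1], window[2], by = bin_sec)
  if (length(edges) < 2) stop("window shorter than one bin")
  lapply(seq_len(length(edges) - 1), function(b) {
    which(times >= edges[b] & times < edges[b + 1])
  })
}

#' Trial-wise time-frequency correlation map
#'
#' Averages the TF amplitude within consecutive time bins per trial, then
#' computes the Pearson correlation across trials between the regressor and
#' the binned amplitude at each (frequency, bin) cell. Maps from several
#' electrodes are averaged on the r-values with [average_tf_maps()].
#'
#' @param tf a [hilbert_tf()] tensor.
#' @param regressor per-trial values (RT or a corrected variant).
#' @param bin_sec bin width, s (default 0.05).
#' @param window analysis window, s (default the tensor's full extent).
#' @return object of class `tf_map`: `r` (freqs x bins), `freqs`,
#'   `bin_centers`, `n_trials`.
#' @export
tf_correlation <- function(tf, regressor, bin_sec = 0.05,
                           window = range(tf$times)) {
  stopifnot(inherits(tf, "tf_tensor"))
  n <- dim(tf$amplitude)[1]
  if (length(regressor) != n) stop("regressor/tensor misalignment")
  if (stats::sd(regressor) == 0) stop("regressor is constant")
  bins <- .time_bins(tf$times, bin_sec, window)
  bins <- bins[lengths(bins) > 0]
  nf <- length(tf$freqs)
  nb <- length(bins)
  binned <- array(NA_real_, c(n, nf, nb))
  for (b in seq_len(nb)) {
    sl <- tf$amplitude[, , bins[[b]], drop = FALSE]
    binned[, , b] <- rowMeans(sl, dims = 2)
  }
  rmat <- matrix(suppressWarnings(
    stats::cor(matrix(binned, nrow = n), regressor)), nf, nb)
  centers <- vapply(bins, function(i) mean(tf$times[i]), numeric(1))
  structure(list(r = rmat, freqs = tf$freqs, bin_centers = centers,
                 n_trials = n), class = "tf_map")
}

#' Average TF correlation maps across electrodes (on the r-values)
#'
#' @param maps list of [tf_correlation()] maps with identical axes.
#' @return a `tf_map` whose `r` is the element-wise mean.
#' @export
average_tf_maps <- function(maps) {
  out <- maps[[1]]
  out$r <- Reduce(`+`, lapply(maps, `[[`, "r")) / length(maps)
  out
}

#' Per-trial band/window-averaged TF amplitude
#'
#' Mean amplitude over the frequencies inside `band` and the times inside
#' `window`, per trial — the reduction used when a single per-trial amplitude
#' is needed from a TF tensor (V1 regressors, cross-checks against the
#' windowed beamformer amplitude).
#'
#' @param tf a [hilbert_tf()] tensor.
#' @param band `c(low, high)` Hz (inclusive).
#' @param window `c(t1, t2)` s.
#' @return numeric per-trial vector.
#' @export
tf_band_amplitude <- function(tf, band, window) {
  fi <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  ti <- which(tf$times >= window[1] & tf$times <= window[2])
  if (!length(fi) || !length(ti)) stop("empty band or window")
  rowMeans(tf$amplitude[, fi, ti, drop = FALSE], dims = 1)
}

#' Fast/slow median-split spectra and band time courses
#'
#' Splits trials at the RT median (with an odd trial count the median trial
#' joins the fast half), and returns (a) the mean baseline amplitude spectrum
#' of each half, normalized by subtracting the all-trial mean over
#' `norm_band`, and (b) per-band amplitude time courses normalized to zero
#' all-trial mean over `tc_norm_window`.
#'
#' @param tf a [hilbert_tf()] tensor.
#' @param rt per-trial reaction times, ms.
#' @param baseline_window spectrum window, s (default `c(-1, 0)`).
#' @param norm_band spectrum normalization band, Hz (default `c(5, 70)`).
#' @param bands named list of `c(low, high)` bands for the time courses.
#' @param tc_norm_window time-course normalization window, s.
#' @return list: `freqs`, `spectrum_fast`, `spectrum_slow`, `spectrum_all`,
#'   `tc_times`, `tc_fast`, `tc_slow` (bands x time matrices), `split`
#'   (per-trial `"fast"`/`"slow"`).
#' @export
fast_slow_spectrum <- function(tf, rt, baseline_window = c(-1, 0),
                               norm_band = c(5, 70),
                               bands = list(`5-15` = c(5, 15),
                                            `15-25` = c(15, 25),
                                            `25-35` = c(25, 35)),
                               tc_norm_window = c(-2, -1)) {
  stopifnot(inherits(tf, "tf_tensor"))
  n <- dim(tf$amplitude)[1]
  if (n < 4) stop("need at least 2 trials per half")
  ord <- order(rt)
  n_fast <- ceiling(n / 2)
  fast <- ord[seq_len(n_fast)]
  slow <- ord[(n_fast + 1):n]
  ti <- which(tf$times >= baseline_window[1] & tf$times <= baseline_window[2])
  spec_of <- function(idx) {
    colMeans(matrix(rowMeans(tf$amplitude[idx, , ti, drop = FALSE], dims = 2),
                    nrow = length(idx)))
  }
  spec_all <- spec_of(seq_len(n))
  nb <- tf$freqs >= norm_band[1] & tf$freqs <= norm_band[2]
  offset <- mean(spec_all[nb])
  tcn <- which(tf$times >= tc_norm_window[1] & tf$times <= tc_norm_window[2])
  if (!length(tcn)) tcn <- seq_along(tf$times)
  tc_of <- function(idx, fi) {
    colMeans(matrix(rowMeans(aperm(tf$amplitude[idx, fi, , drop = FALSE],
                                   c(1, 3, 2)), dims = 2),
                    nrow = length(idx)))
  }
  tc_fast <- tc_slow <- matrix(NA_real_, length(bands), length(tf$times),
                               dimnames = list(names(bands), NULL))
  for (k in seq_along(bands)) {
    fi <- which(tf$freqs >= bands[[k]][1] & tf$freqs <= bands[[k]][2])
    all_tc <- tc_of(seq_len(n), fi)
    off <- mean(all_tc[tcn])
    tc_fast[k, ] <- tc_of(fast, fi) - off
    tc_slow[k, ] <- tc_of(slow, fi) - off
  }
  split <- rep("slow", n)
  split[fast] <- "fast"
  list(freqs = tf$freqs,
       spectrum_fast = spec_of(fast) - offset,
       spectrum_slow = spec_of(slow) - offset,
       spectrum_all = spec_all - offset,
       tc_times = tf$times, tc_fast = tc_fast, tc_slow = tc_slow,
       split = split)
}

#' Trend of correlation values over the baseline
#'
#' Per-subject least-squares slope of r over time within `window`, plus the
#' group-level one-sample t-test of the slopes against zero.
#'
#' @param r_series subjects x time matrix of r values (a single subject may
#'   pass a vector).
#' @param times time axis, s.
#' @param window analysis window, s (default `c(-2, 0)`).
#' @return list: `slopes` (per subject), `t`, `p`, `df`.
#' @export
r_timecourse_trend <- function(r_series, times, window = c(-2, 0)) {
  if (is.null(dim(r_series))) r_series <- matrix(r_series, nrow = 1)
  ti <- which(times >= window[1] & times <= window[2])
  if (length(ti) < 3) stop("need at least 3 time points in the window")
  t_c <- times[ti] - mean(times[ti])
  slopes <- as.numeric(r_series[, ti, drop = FALSE] %*% t_c / sum(t_c^2))
  gt <- if (length(slopes) >= 2) one_sample_group_test(matrix(slopes)) else
    list(t = NA_real_, p = NA_real_)
  list(slopes = slopes, t = gt$t, p = gt$p, df = length(slopes) - 1)
}

#' Mean V1 amplitude regressor
#'
#' Average, across all 20 V1 virtual electrodes, of each electrode's per-trial
#' mean band amplitude over the analysis window.
#'
#' @param tf_list named list of [hilbert_tf()] tensors, one per V1 electrode.
#' @param band `c(low, high)` Hz.
#' @param window `c(t1, t2)` s (default `c(-1, 0)`).
#' @param expected electrode names that must all be present (default the
#'   names of `tf_list`; pass the canonical 20 V1 names to enforce them).
#' @return per-trial numeric vector.
#' @export
v1_amplitude_regressor <- function(tf_list, band, window = c(-1, 0),
                                   expected = NULL) {
  if (!is.null(expected)) {
    missing <- setdiff(expected, names(tf_list))
    if (length(missing)) {
      stop("missing V1 electrodes: ", paste(missing, collapse = ", "))
    }
    tf_list <- tf_list[expected]
  }
  per <- vapply(tf_list, tf_band_amplitude, numeric(dim(tf_list[[1]]$amplitude)[1]),
                band = band, window = window)
  rowMeans(as.matrix(per))
}
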