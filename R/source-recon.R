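# Spherical-conductor forward model, scalar (SAM-style) beamformer with
# global covariance, per-trial band amplitudes, correlational source volumes
# and the left/right choice contrast.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal tangential basis (2 columns) at a point relative to the origin
.tangential_basis <- function(pos) {
  r <- sqrt(sum(pos^2))
  if (r < 1e-9) {
    return(cbind(c(1, 0, 0), c(0, 1, 0)))
  }
  u <- pos / r
  helper <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- .cross3(helper, u)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- .cross3(u, t1)
  cbind(t1, t2)
}

#' Spherical head model
#'
#' Single homogeneous conducting sphere. The analytic dipole field in this
#' model is self-contained and exact; radially oriented dipoles are
#' magnetically silent. The lead-field interface also accepts externally
#' computed matrices for users with realistic forward models.
#'
#' @param center sphere center, mm (default origin).
#' @param radius sphere radius, mm.
#' @return object of class `sphere_head_model`.
#' @export
sphere_head_model <- function(center = c(0, 0, 0), radius = 90) {
  stopifnot(radius > 0, length(center) == 3)
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_head_model")
}

#' Spherical-cap sensor layout
#'
#' Quasi-uniform (Fibonacci spiral) layout of radially oriented
#' gradiometer-like sensors on a spherical cap above the head.
#'
#' @param n number of sensors.
#' @param radius sensor shell radius, mm.
#' @param cap_deg angular extent of the cap from the vertex, degrees.
#' @param center sphere center, mm.
#' @return list with `positions` and `orientations` (n x 3 matrices).
#' @export
fibonacci_cap_sensors <- function(n, radius = 110, cap_deg = 75,
                                  center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  zmin <- cos(cap_deg * pi / 180)
  z <- 1 - (1 - zmin) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(phi), s * sin(phi), z)
  positions <- sweep(u * radius, 2, center, `+`)
  list(positions = positions, orientations = u)
}

#' Lead field of a current dipole in a conducting sphere
#'
#' Analytic magnetic field of a current dipole inside a homogeneous conducting
#' sphere (volume currents included), projected on each sensor's orientation.
#' The multiplicative constant (mu0/4pi) is dropped: fields are in arbitrary
#' units, which leaves beamformer weights, correlations and localization
#' unchanged. Radial dipoles produce an identically zero field.
#'
#' @param model a [sphere_head_model()].
#' @param position dipole position, mm (inside the sphere).
#' @param orientation dipole moment direction (3-vector, any norm; the field
#'   is linear in the moment).
#' @param sensors sensor layout from [fibonacci_cap_sensors()] (or any list
#'   with `positions`/`orientations`).
#' @return numeric vector of per-channel fields.
#' @export
leadfield <- function(model, position, orientation, sensors) {
  stopifnot(inherits(model, "sphere_head_model"))
  r0 <- as.numeric(position) - model$center
  if (sqrt(sum(r0^2)) >= model$radius) {
    stop("dipole position at or outside the sphere radius")
  }
  q <- as.numeric(orientation)
  qxr0 <- .cross3(q, r0)
  pos <- sweep(sensors$positions, 2, model$center)
  nchan <- nrow(pos)
  out <- numeric(nchan)
  for (i in seq_len(nchan)) {
    r <- pos[i, ]
    a <- r - r0
    an <- sqrt(sum(a^2))
    rn <- sqrt(sum(r^2))
    adotr <- sum(a * r)
    FF <- an * (rn * an + rn^2 - sum(r0 * r))
    gradF <- (an^2 / rn + adotr / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + adotr / an) * r0
    B <- (FF * qxr0 - sum(qxr0 * r) * gradF) / FF^2
    out[i] <- sum(B * sensors$orientations[i, ])
  }
  out
}

#' Regular source grid inside the head sphere
#'
#' @param model a [sphere_head_model()].
#' @param spacing grid spacing, mm.
#' @param margin minimum distance of voxels from the sphere surface, mm.
#' @param zmin optional lower z bound, mm (restricts to the upper head).
#' @return object of class `source_grid`: list with `positions`
#'   (n x 3 matrix), `spacing`, `labels` (character, "" = unlabelled).
#' @export
source_grid <- function(model, spacing = 20, margin = 15, zmin = -Inf) {
  stopifnot(inherits(model, "sphere_head_model"))
  ax <- seq(-model$radius, model$radius, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- sweep(g, 2, model$center, `+`)
  d <- sqrt(rowSums(sweep(g, 2, model$center)^2))
  # the exact center is magnetically silent (any dipole there produces no
  # field in a sphere), so it cannot carry a beamformer voxel
  keep <- d <= (model$radius - margin) & d > 1 & g[, 3] >= zmin
  structure(list(positions = g[keep, , drop = FALSE], spacing = spacing,
                 labels = rep("", sum(keep)), model = model),
            class = "source_grid")
}

#' Label grid voxels from ROI spheres
#'
#' @param grid a [source_grid()].
#' @param rois named list; each element a list with `center` (mm) and
#'   `radius` (mm). Later ROIs do not overwrite earlier labels.
#' @return the grid with `labels` filled.
#' @export
label_grid_rois <- function(grid, rois) {
  for (nm in names(rois)) {
    d <- sqrt(rowSums(sweep(grid$positions, 2, rois[[nm]]$center)^2))
    hit <- d <= rois[[nm]]$radius & grid$labels == ""
    grid$labels[hit] <- nm
  }
  grid
}

#' Pooled ("global") band-limited sensor covariance
#'
#' Zero-phase band-pass filters every trial, crops to the analysis window,
#' pools the samples of all trials and returns the channel covariance.
#'
#' @param epochs a `sensor_epochs` object.
#' @param band numeric `c(low, high)` in Hz (`low <= 0` gives a low-pass).
#' @param window numeric `c(t1, t2)` in seconds relative to target onset.
#' @param order Butterworth order of the one-way filter (default 4).
#' @param filtered optional precomputed [filter_epochs()] array for this
#'   band (avoids filtering twice when amplitudes are computed too).
#' @return list of class `band_covariance`: `cov` (channels x channels),
#'   `band`, `window`, `n_samples`, `rank_deficient` flag.
#' @export
global_covariance <- function(epochs, band, window, order = 4,
                              filtered = NULL) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  filt <- if (is.null(filtered)) filter_epochs(epochs, band, order = order)
          else filtered
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  d <- dim(filt)
  n_pool <- d[1] * length(idx)
  rank_def <- n_pool < d[2] + 1
  if (rank_def) {
    warning("fewer pooled samples than channels + 1; covariance is rank ",
            "deficient and must be regularized")
  }
  # stack trials x window samples as rows
  x <- matrix(aperm(filt[, , idx, drop = FALSE], c(1, 3, 2)), ncol = d[2])
  x <- sweep(x, 2, colMeans(x))
  structure(list(cov = crossprod(x) / (nrow(x) - 1), band = band,
                 window = window, n_samples = n_pool,
                 rank_deficient = rank_def),
            class = "band_covariance")
}

#' Band-pass filter all epochs (zero phase)
#'
#' @inheritParams global_covariance
#' @return trials x channels x samples array.
#' @export
filter_epochs <- function(epochs, band, order = 4) {
  d <- dim(epochs$data)
  # time along rows, (trial, channel) along columns: one FFT pass
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  y <- bp_filter(x, epochs$sfreq, band[1], band[2], order = order)
  aperm(array(y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Scalar beamformer weights (SAM-style)
#'
#' For each voxel the source orientation is restricted to the tangential
#' plane (radial sources are silent in a sphere) and chosen to maximize the
#' unit-gain beamformer output power, i.e. the generalized eigenproblem on the
#' 2x2 matrix `t(L) C^-1 L` (minimum eigenvector). Weights are
#' `C^-1 l / (t(l) C^-1 l)`, giving exact unit gain `t(w) l = 1`. The
#' covariance is diagonally loaded by `reg` times its mean eigenvalue.
#'
#' @param cov_obj a [global_covariance()] result (or any list with `cov`).
#' @param model a [sphere_head_model()].
#' @param grid a [source_grid()] or any list with a `positions` matrix.
#' @param sensors sensor layout matching the covariance channels.
#' @param reg diagonal-loading fraction of the mean eigenvalue (default 0.05).
#' @return object of class `weight_set`: `weights` (voxels x channels),
#'   `orientations` (voxels x 3), `band`, `window`, `reg`.
#' @export
sam_weights <- function(cov_obj, model, grid, sensors, reg = 0.05) {
  C <- cov_obj$cov
  nchan <- ncol(C)
  load <- reg * mean(diag(C))
  Cr <- C + diag(load, nchan)
  Ci <- tryCatch(solve(Cr), error = function(e) {
    stop("covariance is singular; increase the diagonal loading `reg`")
  })
  pos <- grid$positions
  nv <- nrow(pos)
  W <- matrix(NA_real_, nv, nchan)
  ori <- matrix(NA_real_, nv, 3)
  for (v in seq_len(nv)) {
    Tb <- .tangential_basis(pos[v, ] - model$center)
    L <- cbind(leadfield(model, pos[v, ], Tb[, 1], sensors),
               leadfield(model, pos[v, ], Tb[, 2], sensors))
    M <- crossprod(L, Ci %*% L)
    e <- eigen(M, symmetric = TRUE)
    u <- e$vectors[, 2]        # smallest eigenvalue -> max output power
    l <- as.numeric(L %*% u)
    Cil <- Ci %*% l
    W[v, ] <- Cil / as.numeric(crossprod(l, Cil))
    ori[v, ] <- as.numeric(Tb %*% u)
  }
  structure(list(weights = W, orientations = ori,
                 band = cov_obj$band, window = cov_obj$window,
                 reg = reg, grid = grid),
            class = "weight_set")
}

#' Per-trial source band amplitude
#'
#' Band-pass filters the epochs, crops to the window, projects each trial
#' through every voxel's spatial filter, and takes the RMS over the window.
#' (For narrowband signals RMS agrees with the mean Hilbert envelope up to a
#' constant, which Pearson correlations ignore.)
#'
#' @param weights a [sam_weights()] result.
#' @param epochs a `sensor_epochs` object.
#' @param band,window band (Hz) and window (s); default to those the weights
#'   were computed for.
#' @param filtered optional precomputed [filter_epochs()] array.
#' @return trials x voxels matrix of non-negative amplitudes, with `band` and
#'   `window` attributes.
#' @export
trial_band_amplitude <- function(weights, epochs, band = weights$band,
                                 window = weights$window, filtered = NULL) {
  stopifnot(inherits(weights, "weight_set"))
  filt <- if (is.null(filtered)) filter_epochs(epochs, band) else filtered
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  n <- dim(filt)[1]
  W <- weights$weights
  out <- matrix(NA_real_, n, nrow(W))
  for (i in seq_len(n)) {
    proj <- W %*% filt[i, , idx]             # channels x samples -> voxels x samples
    out[i, ] <- sqrt(rowMeans(proj^2))
  }
  attr(out, "band") <- band
  attr(out, "window") <- window
  out
}

#' Correlational source volume
#'
#' Pearson product-moment correlation, across trials, between each voxel's
#' band amplitude and a behavioral regressor (saccadic latency or any of its
#' corrected variants).
#'
#' @param amp trials x voxels amplitude matrix ([trial_band_amplitude()]).
#' @param regressor per-trial numeric values, aligned with the amplitude rows.
#' @param grid optional [source_grid()] carried into the result.
#' @param tag optional regressor label.
#' @return object of class `stat_volume` with `values` (per-voxel r; `NaN`
#'   where the amplitude is constant), `stat = "r"`, `n_trials`, `band`,
#'   `window`, `grid`, `tag`.
#' @export
correlational_sam <- function(amp, regressor, grid = NULL, tag = "rt") {
  amp <- as.matrix(amp)
  if (length(regressor) != nrow(amp)) stop("regressor/amplitude misalignment")
  if (nrow(amp) < 3) stop("need at least 3 trials")
  if (stats::sd(regressor) == 0) stop("regressor is constant")
  r <- suppressWarnings(as.numeric(stats::cor(amp, regressor)))
  structure(list(values = r, stat = "r", n_trials = nrow(amp),
                 band = attr(amp, "band"), window = attr(amp, "window"),
                 grid = grid, tag = tag),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  cat("stat_volume (", x$stat, "): ", length(x$values), " voxels, n = ",
      x$n_trials, ", peak |", x$stat, "| = ",
      round(max(abs(x$values), na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Left/right choice contrast of source amplitudes
#'
#' Per-voxel two-sample comparison (left minus right choices): pooled-variance
#' t statistic and standardized mean difference.
#'
#' @param amp trials x voxels amplitude matrix.
#' @param labels per-trial labels, `"left"`/`"right"`.
#' @param grid optional grid carried into the result.
#' @return `stat_volume` with `values` = t, plus `d` (standardized mean
#'   difference) and `mean_diff`.
#' @export
choice_contrast <- function(amp, labels, grid = NULL) {
  amp <- as.matrix(amp)
  iL <- labels == "left"
  iR <- labels == "right"
  n1 <- sum(iL); n2 <- sum(iR)
  if (n1 < 2 || n2 < 2) stop("need at least 2 trials per choice label")
  m1 <- colMeans(amp[iL, , drop = FALSE])
  m2 <- colMeans(amp[iR, , drop = FALSE])
  v1 <- apply(amp[iL, , drop = FALSE], 2, stats::var)
  v2 <- apply(amp[iR, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  tval <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  structure(list(values = tval, stat = "t", d = (m1 - m2) / sp,
                 mean_diff = m1 - m2, n_trials = n1 + n2,
                 df = n1 + n2 - 2, grid = grid, tag = "choice"),
            class = "stat_volume")
}
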