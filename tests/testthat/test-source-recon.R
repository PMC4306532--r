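# Forward model, covariance, scalar beamformer and correlational volumes.

test_that("sphere leadfield is silent for radial dipoles and linear in moment", {
  model <- sphere_head_model()
  sens <- fibonacci_cap_sensors(20)
  pos <- c(25, -40, 30)
  tangential <- prestim:::.tangential_basis(pos)[, 1]
  lf_t <- leadfield(model, pos, tangential, sens)
  lf_r <- leadfield(model, pos, pos / sqrt(sum(pos^2)), sens)
  expect_lt(max(abs(lf_r)), 1e-12 * max(abs(lf_t)))
  expect_equal(leadfield(model, pos, 2 * tangential, sens), 2 * lf_t)
  expect_error(leadfield(model, c(0, 0, 95), tangential, sens), "outside")
})

test_that("sphere leadfield matches the free-space dipole field radially", {
  # for radial sensors the volume currents of the sphere contribute nothing,
  # so the analytic solution must equal a direct Biot-Savart evaluation of
  # the primary current dipole (same constant convention)
  model <- sphere_head_model()
  sens <- fibonacci_cap_sensors(3)
  pos <- c(20, -50, 30)
  q <- prestim:::.tangential_basis(pos)[, 1]
  lf <- leadfield(model, pos, q, sens)
  for (i in 1:3) {
    r <- sens$positions[i, ]
    a <- r - pos
    b_primary <- c(q[2] * a[3] - q[3] * a[2],
                   q[3] * a[1] - q[1] * a[3],
                   q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
    expect_equal(lf[i], sum(b_primary * sens$orientations[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("global covariance is white for noise and rank-1 for one source", {
  cfg <- quick_config(n_trials = 60, seed = 51, n_blocks = 2,
                      sensor_noise_sd = 1)
  tab <- generate_trial_schedule(cfg)
  sim <- simulate_sensor_epochs(tab, cfg)
  cv <- global_covariance(sim$epochs, c(10, 40), c(-1, 0))
  # white noise: diagonal ~ sigma^2 * band fraction, off-diagonals near zero
  band_frac <- 30 / (cfg$sfreq / 2)
  expect_equal(mean(diag(cv$cov)), band_frac, tolerance = 0.1)
  off <- cv$cov[upper.tri(cv$cov)]
  expect_lt(max(abs(off)) / mean(diag(cv$cov)), 0.1)
  # determinism
  cv2 <- global_covariance(sim$epochs, c(10, 40), c(-1, 0))
  expect_identical(cv$cov, cv2$cov)
  # single noiseless source: rank 1
  src <- ground_truth_source(c(10, -70, 20), center_freq = 10, bandwidth = 6)
  cfg1 <- quick_config(n_trials = 30, seed = 52, n_blocks = 2,
                       sensor_noise_sd = 0, source_specs = list(src))
  sim1 <- simulate_sensor_epochs(generate_trial_schedule(cfg1), cfg1)
  cv1 <- global_covariance(sim1$epochs, c(5, 15), c(-1, 0))
  ev <- eigen(cv1$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-8)
})

test_that("beamformer weights honor unit gain and reconstruct a source", {
  src <- ground_truth_source(c(10, -70, 20), center_freq = 10, bandwidth = 6,
                             coupling_window = c(-1, 0))
  cfg <- sim_config(n_trials = 30, n_blocks = 2, seed = 53,
                    epoch_window = c(-1.1, 0.1), n_channels = 30,
                    sensor_noise_sd = 0, source_specs = list(src))
  tab <- generate_trial_schedule(cfg)
  sim <- simulate_sensor_epochs(tab, cfg)
  sensors <- default_sensors(sim$epochs)
  model <- sim$epochs$model
  grid <- source_grid(model, spacing = 20)
  cv <- global_covariance(sim$epochs, c(5, 15), c(-1, 0))
  ws <- sam_weights(cv, model, grid, sensors, reg = 1e-4)
  # unit gain at every voxel for the chosen orientation
  for (v in sample(nrow(grid$positions), 12)) {
    l <- leadfield(model, grid$positions[v, ], ws$orientations[v, ], sensors)
    expect_equal(sum(ws$weights[v, ] * l), 1, tolerance = 1e-8)
  }
  # reconstructed time course at the nearest voxel matches the true source
  d2 <- rowSums(sweep(grid$positions, 2, src$position)^2)
  vsrc <- which.min(d2)
  filt <- filter_epochs(sim$epochs, c(5, 15))
  rec <- as.numeric(ws$weights[vsrc, ] %*% filt[5, , ])
  lf <- leadfield(model, src$position, src$orientation, sensors)
  lf <- lf / sqrt(sum(lf^2))
  truth <- as.numeric(lf %*% filt[5, , ])   # noiseless: any projection of the
  expect_gt(abs(cor(rec, truth)), 0.999)    # rank-1 data recovers the source
})

test_that("a beamformer filter suppresses a second, distant source", {
  s1 <- ground_truth_source(c(10, -70, 20), center_freq = 10, bandwidth = 6)
  s2 <- ground_truth_source(c(-20, 45, 35), center_freq = 10, bandwidth = 6)
  cfg <- sim_config(n_trials = 40, n_blocks = 2, seed = 54,
                    epoch_window = c(-1.1, 0.1), n_channels = 30,
                    sensor_noise_sd = 0.05, source_specs = list(s1, s2))
  tab <- generate_trial_schedule(cfg)
  sim <- simulate_sensor_epochs(tab, cfg)
  sensors <- default_sensors(sim$epochs)
  model <- sim$epochs$model
  cv <- global_covariance(sim$epochs, c(5, 15), c(-1, 0))
  ws <- sam_weights(cv, model, list(positions = rbind(s1$position)), sensors)
  w <- ws$weights[1, ]
  lf1 <- leadfield(model, s1$position, s1$orientation, sensors)
  lf2 <- leadfield(model, s2$position, s2$orientation, sensors)
  gain1 <- abs(sum(w * lf1 / sqrt(sum(lf1^2))))
  gain2 <- abs(sum(w * lf2 / sqrt(sum(lf2^2))))
  expect_gt(20 * log10(gain1 / gain2), 20)   # > 20 dB suppression
})

test_that("trial band amplitudes scale with the source envelope", {
  src <- ground_truth_source(c(10, -70, 20), center_freq = 10, bandwidth = 6,
                             rt_coupling_r = 0.3)
  cfg <- sim_config(n_trials = 60, n_blocks = 2, seed = 55,
                    epoch_window = c(-1.1, 0.1), n_channels = 30,
                    sensor_noise_sd = 0, source_specs = list(src))
  tab <- generate_trial_schedule(cfg)
  sim <- simulate_sensor_epochs(tab, cfg)
  sensors <- default_sensors(sim$epochs)
  cv <- global_covariance(sim$epochs, c(5, 15), c(-1, 0))
  ws <- sam_weights(cv, sim$epochs$model,
                    list(positions = rbind(src$position)), sensors)
  amp <- trial_band_amplitude(ws, sim$epochs)
  expect_true(all(amp >= 0))
  expect_gt(cor(amp[, 1], sim$true_amplitude[, 1]), 0.999)
  # homogeneity: scaling the data scales amplitudes by |c|
  ep2 <- sim$epochs
  ep2$data <- -3 * ep2$data
  amp2 <- trial_band_amplitude(ws, ep2)
  expect_equal(amp2[, 1], 3 * amp[, 1], tolerance = 1e-10)
  # all-zero epochs give zero amplitude
  ep0 <- sim$epochs
  ep0$data[] <- 0
  expect_equal(max(trial_band_amplitude(ws, ep0)), 0)
})

test_that("correlational volumes behave on worked examples", {
  amp <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  expect_equal(correlational_sam(amp, c(210, 220, 230, 240, 250))$values, 1)
  expect_equal(correlational_sam(amp, c(250, 240, 230, 220, 210))$values, -1)
  # regressor equal to one voxel's amplitude -> r = 1 there
  set.seed(6)
  A <- matrix(rnorm(200), 50, 4)
  sv <- correlational_sam(A, A[, 3])
  expect_equal(sv$values[3], 1, tolerance = 1e-12)
  expect_error(correlational_sam(A, rep(1, 50)), "constant")
  expect_error(correlational_sam(A[1:2, ], 1:2), "3 trials")
  # constant voxel -> NaN there, finite elsewhere
  A[, 2] <- 7
  sv <- correlational_sam(A, rnorm(50))
  expect_true(is.na(sv$values[2]))
  expect_true(all(is.finite(sv$values[-2])))
})

test_that("choice contrast is antisymmetric and calibrated under the null", {
  set.seed(7)
  amp <- matrix(rnorm(400 * 50), 400, 50)
  labels <- rep(c("left", "right"), each = 200)
  cc <- choice_contrast(amp, labels)
  cc_flip <- choice_contrast(amp, rev(labels))
  expect_equal(cc$values, -cc_flip$values, tolerance = 1e-12)
  # identical distributions: ~5% of voxels beyond the two-sided t criterion
  frac <- mean(abs(cc$values) > qt(0.975, df = cc$df))
  expect_lt(frac, 0.15)
  expect_error(choice_contrast(amp, rep("left", 400)), "2 trials")
  # injected offset at one voxel dominates in most replicates
  hits <- 0
  for (k in 1:10) {
    set.seed(700 + k)
    A <- matrix(rnorm(400 * 50), 400, 50)
    A[1:200, 17] <- A[1:200, 17] + 0.5
    if (which.max(abs(choice_contrast(A, labels)$values)) == 17) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("correlation volumes are invariant to affine rescaling", {
  set.seed(8)
  A <- matrix(rnorm(300), 60, 5)
  reg <- rnorm(60)
  r0 <- correlational_sam(A, reg)$values
  r1 <- correlational_sam(A * 3 + 2, 0.5 * reg - 7)$values
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("direction-symmetric coupling shows no lateralization", {
  # the generator couples amplitude to RT identically for left and right
  # targets, so left-trial minus right-trial r-volumes must center on zero
  # and pass a sign-flip permutation test across subjects
  n_sub <- 6
  diffs <- NULL
  for (i in seq_len(n_sub)) {
    cfg <- coupled_config(n_trials = 160, r = 0.2, seed = 600 + i,
                          n_channels = 20)
    sub <- simulate_subject(cfg, eog = FALSE)
    grid <- source_grid(sub$epochs$model, spacing = 30)
    sensors <- default_sensors(sub$epochs)
    filt <- filter_epochs(sub$epochs, c(5, 15))
    cv <- global_covariance(sub$epochs, c(5, 15), c(-1, 0), filtered = filt)
    ws <- sam_weights(cv, sub$epochs$model, grid, sensors)
    amp <- trial_band_amplitude(ws, sub$epochs, filtered = filt)
    tab <- sub$table
    rL <- correlational_sam(amp[tab$condition == "left", ],
                            tab$rt[tab$condition == "left"])$values
    rR <- correlational_sam(amp[tab$condition == "right", ],
                            tab$rt[tab$condition == "right"])$values
    diffs <- rbind(diffs, rL - rR)
  }
  expect_lt(abs(mean(diffs)), 0.05)
  om <- permutation_omnibus(diffs)
  expect_gt(min(om$p_corrected), 0.05)
})

test_that("coupling injected at a source is recovered at and around it", {
  cfg <- coupled_config(n_trials = 300, r = 0.25, seed = 56)
  sub <- simulate_subject(cfg, eog = FALSE)
  grid <- source_grid(sub$epochs$model, spacing = 20)
  sm <- subject_sam_maps(sub, grid = grid)
  v <- sm$maps[[1]][[1]]$raw
  peak <- which.max(v$values)
  d <- sqrt(sum((grid$positions[peak, ] - cfg$source_specs[[1]]$position)^2))
  expect_lte(d, sqrt(3) * grid$spacing)
  se <- (1 - 0.25^2) / sqrt(300)
  expect_lt(abs(v$values[peak] - 0.25), 3 * se + 0.05)
})
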