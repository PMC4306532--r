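# Virtual electrodes, Hilbert filter bank, TF correlation, fast/slow split
# and the r-timecourse trend.

test_that("Hilbert filter bank recovers amplitude and phase of a cosine", {
  sfreq <- 600
  times <- seq(-2.7, 0.7, by = 1 / sfreq)
  A <- 2.4
  x <- matrix(A * cos(2 * pi * 10 * times), nrow = 1)
  tf <- hilbert_tf(x, sfreq = sfreq, times = times, freqs = c(10, 20))
  i0 <- which.min(abs(tf$times))
  interior <- tf$times > -2.2 & tf$times < 0.4
  expect_lt(max(abs(tf$amplitude[1, 1, interior] - A)) / A, 0.02)
  expect_lt(abs(tf$phase[1, 1, i0]), 0.05)
  # out-of-band row sees almost nothing
  expect_lt(max(tf$amplitude[1, 2, interior]) / A, 0.05)
})

test_that("the filter bank tracks an amplitude-modulated envelope", {
  sfreq <- 600
  times <- seq(-2.7, 0.7, by = 1 / sfreq)
  env <- 1 + 0.5 * sin(2 * pi * 0.5 * times)
  x <- matrix(env * cos(2 * pi * 20 * times), nrow = 1)
  tf <- hilbert_tf(x, sfreq = sfreq, times = times, freqs = 20)
  interior <- tf$times > -2.2 & tf$times < 0.4
  env_d <- 1 + 0.5 * sin(2 * pi * 0.5 * tf$times)
  expect_gt(cor(tf$amplitude[1, 1, interior], env_d[interior]), 0.98)
})

test_that("mixed components separate with low cross-talk", {
  sfreq <- 600
  times <- seq(-2.7, 0.7, by = 1 / sfreq)
  x <- matrix(1.0 * cos(2 * pi * 10 * times) + 0.7 * sin(2 * pi * 40 * times),
              nrow = 1)
  tf <- hilbert_tf(x, sfreq = sfreq, times = times, freqs = c(10, 40))
  interior <- tf$times > -2.2 & tf$times < 0.4
  m10 <- mean(tf$amplitude[1, 1, interior])
  m40 <- mean(tf$amplitude[1, 2, interior])
  expect_lt(abs(m10 - 1.0), 0.05)
  expect_lt(abs(m40 - 0.7), 0.05 * 0.7)
  # adding a far out-of-band component changes a row by < 5%
  x2 <- x + matrix(2 * cos(2 * pi * 70 * times), nrow = 1)
  tf2 <- hilbert_tf(x2, sfreq = sfreq, times = times, freqs = c(10, 40))
  expect_lt(max(abs(tf2$amplitude[1, 1, interior] -
                      tf$amplitude[1, 1, interior])) / m10, 0.05)
  expect_error(hilbert_tf(x, sfreq = 150, times = times, freqs = c(10, 90)),
               "too low")
})

test_that("virtual electrode projection recovers a co-located source", {
  src <- ground_truth_source(c(10, -70, 20), center_freq = 10, bandwidth = 6)
  cfg <- sim_config(n_trials = 40, n_blocks = 2, seed = 61,
                    epoch_window = c(-1.1, 0.1), n_channels = 30,
                    sensor_noise_sd = 0.02, source_specs = list(src))
  tab <- generate_trial_schedule(cfg)
  sim <- simulate_sensor_epochs(tab, cfg)
  el <- virtual_electrode("probe", src$position)
  proj <- project_virtual_electrode(sim$epochs, el)
  # reconstruct the true band signal at the electrode
  filt <- filter_epochs(sim$epochs, c(5, 15))
  sensors <- default_sensors(sim$epochs)
  lf <- leadfield(sim$epochs$model, src$position, src$orientation, sensors)
  lf <- lf / sqrt(sum(lf^2))
  truth <- as.numeric(lf %*% filt[7, , ])
  projf <- bp_filter(proj[7, ], cfg$sfreq, 5, 15)
  expect_gt(abs(cor(projf, truth)), 0.999)
  # all-zero epochs project to zero
  ep0 <- sim$epochs
  ep0$data[] <- 0
  proj0 <- project_virtual_electrode(ep0, el, cov_obj =
    global_covariance(sim$epochs, c(0, 100), range(sim$epochs$times)))
  expect_equal(max(abs(proj0)), 0)
  # a distant source is strongly attenuated
  far <- ground_truth_source(c(-20, 45, 35), center_freq = 10, bandwidth = 6)
  cfg2 <- sim_config(n_trials = 40, n_blocks = 2, seed = 62,
                     epoch_window = c(-1.1, 0.1), n_channels = 30,
                     sensor_noise_sd = 0.02,
                     source_specs = list(src, far))
  sim2 <- simulate_sensor_epochs(generate_trial_schedule(cfg2), cfg2)
  proj2 <- project_virtual_electrode(sim2$epochs, el)
  lf_far <- leadfield(sim2$epochs$model, far$position, far$orientation, sensors)
  lf_far <- lf_far / sqrt(sum(lf_far^2))
  w_gain_near <- 1                                  # unit gain by construction
  cv2 <- global_covariance(sim2$epochs, c(0, 100), range(sim2$epochs$times))
  ws2 <- sam_weights(cv2, sim2$epochs$model,
                     list(positions = rbind(src$position)), sensors)
  gain_far <- abs(sum(ws2$weights[1, ] * lf_far))
  lf_near <- leadfield(sim2$epochs$model, src$position, src$orientation, sensors)
  gain_near <- abs(sum(ws2$weights[1, ] * lf_near / sqrt(sum(lf_near^2))))
  expect_lt((gain_far / gain_near)^2, 0.1)
  expect_error(project_virtual_electrode(sim$epochs,
                                         virtual_electrode("out", c(0, 0, 99))),
               "outside")
})

test_that("TF correlation recovers injected coupling and respects the null", {
  # construct a TF tensor whose 10 Hz amplitude carries the coupling directly
  set.seed(63)
  n <- 400
  freqs <- c(6, 10, 14)
  times <- seq(-1.5, 0, by = 0.02)
  z <- rnorm(n)
  rt <- 262 + 48 * (0.3 * z + sqrt(1 - 0.09) * rnorm(n))
  amp <- array(abs(rnorm(n * 3 * length(times), 1, 0.2)),
               c(n, 3, length(times)))
  in_win <- times >= -1
  amp[, 2, in_win] <- 1 + 0.25 * z + 0.05 * amp[, 2, in_win]
  tf <- structure(list(amplitude = amp,
                       phase = array(0, dim(amp)), freqs = freqs,
                       times = times, sfreq = 50), class = "tf_tensor")
  tfm <- tf_correlation(tf, rt)
  cells10 <- tfm$r[2, tfm$bin_centers >= -1]
  se <- (1 - 0.09) / sqrt(n)
  expect_lt(abs(mean(cells10) - 0.3), 3 * se + 0.02)
  # uncoupled rows sit at the null level
  null_cells <- tfm$r[c(1, 3), ]
  expect_lt(max(abs(null_cells)), 4 / sqrt(n))
  # shuffled regressor: everything at the null level
  tfm0 <- tf_correlation(tf, sample(rt))
  expect_gt(mean(abs(tfm0$r) < 3 / sqrt(n)), 0.95)
  # r = 1 when the regressor is the binned amplitude itself
  binned <- rowMeans(amp[, 2, times >= -1 & times < -0.95, drop = FALSE],
                     dims = 1)
  tfm1 <- tf_correlation(tf, as.numeric(binned))
  expect_equal(max(tfm1$r[2, ]), 1, tolerance = 1e-9)
  # invariance to affine regressor rescaling
  tfm2 <- tf_correlation(tf, 2 * rt - 100)
  expect_equal(tfm2$r, tfm$r, tolerance = 1e-12)
  expect_error(tf_correlation(tf, rep(1, n)), "constant")
})

test_that("electrode averaging happens on r-values", {
  set.seed(64)
  mk_map <- function() {
    structure(list(r = matrix(rnorm(6), 2, 3), freqs = 1:2,
                   bin_centers = 1:3, n_trials = 10), class = "tf_map")
  }
  maps <- list(mk_map(), mk_map(), mk_map())
  avg <- average_tf_maps(maps)
  expect_equal(avg$r, (maps[[1]]$r + maps[[2]]$r + maps[[3]]$r) / 3)
})

test_that("fast/slow split normalizes exactly and detects coupling sign", {
  set.seed(65)
  n <- 200
  freqs <- 5:40
  times <- seq(-1.5, 0.2, by = 0.02)
  z <- rnorm(n)
  rt <- 262 + 48 * (0.5 * z + sqrt(0.75) * rnorm(n))
  amp <- array(abs(rnorm(n * length(freqs) * length(times), 1, 0.1)),
               c(n, length(freqs), length(times)))
  alpha <- freqs >= 8 & freqs <= 13
  amp[, alpha, ] <- amp[, alpha, ] + 0.3 * z   # higher amplitude -> longer RT
  tf <- structure(list(amplitude = amp, phase = array(0, dim(amp)),
                       freqs = freqs, times = times, sfreq = 50),
                  class = "tf_tensor")
  fs <- fast_slow_spectrum(tf, rt, norm_band = c(5, 40),
                           tc_norm_window = c(-1.5, -1))
  expect_equal(mean(fs$spectrum_all[freqs >= 5 & freqs <= 40]), 0,
               tolerance = 1e-12)
  expect_gt(mean(fs$spectrum_slow[alpha]), mean(fs$spectrum_fast[alpha]))
  expect_equal(sum(fs$split == "fast"), 100)
  # zero coupling: halves agree within sampling error
  amp0 <- array(abs(rnorm(n * 4 * length(times), 1, 0.1)),
                c(n, 4, length(times)))
  tf0 <- structure(list(amplitude = amp0, phase = array(0, dim(amp0)),
                        freqs = 5:8, times = times, sfreq = 50),
                   class = "tf_tensor")
  fs0 <- fast_slow_spectrum(tf0, rt, norm_band = c(5, 8),
                            tc_norm_window = c(-1.5, -1))
  expect_lt(max(abs(fs0$spectrum_slow - fs0$spectrum_fast)),
            5 * 0.1 / sqrt(n / 2 * length(times)))
  # odd trial count: median trial joins the fast half
  fs_odd <- fast_slow_spectrum(
    structure(list(amplitude = amp0[1:199, , , drop = FALSE],
                   phase = array(0, c(199, 4, length(times))),
                   freqs = 5:8, times = times, sfreq = 50),
              class = "tf_tensor"),
    rt[1:199], norm_band = c(5, 8), tc_norm_window = c(-1.5, -1))
  expect_equal(sum(fs_odd$split == "fast"), 100)
})

test_that("r-timecourse trends are recovered and antisymmetric", {
  times <- seq(-2, 0, by = 0.1)
  r_const <- matrix(0.2, 3, length(times))
  tr <- r_timecourse_trend(r_const, times)
  expect_equal(tr$slopes, rep(0, 3))
  # ramping coupling: positive slopes in replicate groups of 12 subjects
  set.seed(66)
  hits <- 0
  for (k in 1:20) {
    rmat <- matrix(rep(seq(0, 0.3, length.out = length(times)), each = 12),
                   12) + matrix(rnorm(12 * length(times), 0, 0.05), 12)
    tr <- r_timecourse_trend(rmat, times)
    if (all(tr$slopes > 0) && tr$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # reversing time flips the slope sign exactly
  rmat <- matrix(rnorm(5 * length(times)), 5)
  a <- r_timecourse_trend(rmat, times)
  b <- r_timecourse_trend(rmat[, rev(seq_along(times))], times)
  expect_equal(a$slopes, -b$slopes, tolerance = 1e-12)
})

test_that("the V1 regressor is the electrode mean of band amplitudes", {
  set.seed(67)
  n <- 30
  times <- seq(-1.2, 0, by = 0.02)
  mk_tf <- function(amp) {
    structure(list(amplitude = amp, phase = array(0, dim(amp)),
                   freqs = 8:12, times = times, sfreq = 50),
              class = "tf_tensor")
  }
  base <- array(abs(rnorm(n * 5 * length(times), 1, 0.1)),
                c(n, 5, length(times)))
  tfs <- list(a = mk_tf(base), b = mk_tf(base), c = mk_tf(base))
  reg <- v1_amplitude_regressor(tfs, band = c(8, 12), window = c(-1, 0))
  expect_equal(reg, tf_band_amplitude(tfs$a, c(8, 12), c(-1, 0)))
  # scaling one of 20 electrodes by 3 shifts the mean by 2/20 of it
  tfs20 <- rep(list(mk_tf(base)), 20)
  names(tfs20) <- sprintf("V1-%02d", 1:20)
  reg20 <- v1_amplitude_regressor(tfs20, c(8, 12), c(-1, 0))
  tfs20b <- tfs20
  tfs20b[[5]]$amplitude <- 3 * tfs20b[[5]]$amplitude
  reg20b <- v1_amplitude_regressor(tfs20b, c(8, 12), c(-1, 0))
  expect_equal(reg20b - reg20,
               (2 / 20) * tf_band_amplitude(tfs20[[5]], c(8, 12), c(-1, 0)),
               tolerance = 1e-12)
  # missing electrodes are reported by name
  expect_error(v1_amplitude_regressor(tfs20[-3], c(8, 12), c(-1, 0),
                                      expected = names(tfs20)),
               "V1-03")
})
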