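test_that("identical seeds give bit-identical synthetic data", {
  a <- sim_titration("fluorescein", noise = 0.02, seed = 42)
  b <- sim_titration("fluorescein", noise = 0.02, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$signal,
                         sim_titration("fluorescein", noise = 0.02,
                                       seed = 43)$signal))
  expect_identical(sim_melt(noise = 0.02, seed = 1),
                   sim_melt(noise = 0.02, seed = 1))
  expect_identical(sim_nmr_series(noise = 0.05, seed = 1),
                   sim_nmr_series(noise = 0.05, seed = 1))
  expect_identical(sim_mals(noise = 0.01, seed = 1),
                   sim_mals(noise = 0.01, seed = 1))
  expect_identical(sim_image_pair(seed = 1), sim_image_pair(seed = 1))
  expect_identical(sim_spectra(noise = 0.02, seed = 1),
                   sim_spectra(noise = 0.02, seed = 1))
  expect_identical(sim_ca_trace(seed = 1), sim_ca_trace(seed = 1))
})

test_that("generators use independent streams and restore the RNG state", {
  # a generator call must not perturb the ambient RNG sequence
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(sim_titration(seed = 7)); after <- rnorm(3)
  expect_identical(before, after)
  # different generators draw from different streams under one caller seed:
  # the standardized first noise draws differ
  t1 <- sim_titration("fluorescein", noise = 0.02, seed = 5)
  mu_t <- t1$truth$s_free + (t1$truth$s_sat - t1$truth$s_free) *
    fraction_bound(t1$truth$kd_uM, t1$labeled_conc_uM, t1$titrant_uM) /
    t1$labeled_conc_uM
  m1 <- sim_melt(tm_C = 92, noise = 0.02, seed = 5)
  mu_m <- 1 / (1 + exp((92 - m1$temperature_C) / 2))
  eps_t <- t1$signal / mu_t - 1           # multiplicative draw
  eps_m <- m1$signal - mu_m               # additive draw
  expect_false(isTRUE(all.equal(eps_t[1] / 0.02, eps_m[1] / 0.02)))
})

test_that("noiseless titration endpoints and half-saturation behave analytically", {
  cv <- sim_titration("fluorescein", noise = 0)
  expect_equal(cv$signal[1], cv$truth$s_free)
  # endpoint approaches S_sat once the titrant saturates the sites
  sat <- sim_titration("fluorescein", kd_uM = 0.125,
                       titrant_uM = c(0, 0.1, 0.5, 1, 5, 20, 100),
                       noise = 0)
  expect_equal(sat$signal[length(sat$signal)], sat$truth$s_sat,
               tolerance = 0.005)
  # dilute-receptor curve crosses half saturation near L = Kd
  cv2 <- sim_titration("fluorescein", kd_uM = 0.5, labeled_conc_uM = 0.001,
                       titrant_uM = seq(0, 10, 0.01), noise = 0)
  half <- (cv2$truth$s_free + cv2$truth$s_sat) / 2
  l_half <- cv2$titrant_uM[which.min(abs(cv2$signal - half))]
  expect_equal(l_half, 0.5, tolerance = 0.02)
})

test_that("melt and NMR generators satisfy their structural invariants", {
  m <- sim_melt(tm_C = c(55, 80), amplitude = c(0.3, 0.7), noise = 0)
  expect_true(all(diff(m$signal) >= 0))
  expect_equal(range(m$signal), c(0, 1), tolerance = 0.01)
  # inflection of a single transition at the configured Tm
  m1 <- sim_melt(tm_C = 60, slope_C = 2, noise = 0,
                 temperature_C = seq(20, 95, 0.1))
  d <- diff(m1$signal)
  expect_equal(m1$temperature_C[which.max(d)], 60, tolerance = 0.15)
  ser <- sim_nmr_series(noise = 0)
  wide <- split(ser$intensity, ser$state)
  # free + bound normalized intensities sum to 1 when scales are equal
  expect_equal(unique(round(wide$free + wide$bound, 12)), 1)
  expect_equal(ser$intensity[ser$state == "bound" & ser$titrant_uM == 0],
               rep(0, 6))
})

test_that("image generator hits designed overlaps including the degenerate ones", {
  full <- sim_image_pair(overlap = 1, n_red = 50, n_green_only = 0,
                         mode = "binary", seed = 1)
  res <- manders_coefficients(full$red, full$green)
  expect_equal(res$M1, 1); expect_equal(res$M2, 1)
  none <- sim_image_pair(overlap = 0, n_red = 50, mode = "binary", seed = 1)
  expect_equal(manders_coefficients(none$red, none$green)$M1, 0)
})

test_that("spectra and calcium generators expose their design truths", {
  s <- sim_spectra(donor_scale = 0, acceptor_amp = 0, noise = 0)
  # background-only mixture inverts to a zero donor level
  expect_equal(donor_level_from_ratio_curve(s$coexpressing, s$background,
                                            s$donor),
               0, tolerance = 1e-6)
  expect_true(all(diff(s$background$wavelength_nm) > 0))
  tr <- sim_ca_trace(amplitude = 0.4, baseline = 50, noise = 0)
  expect_equal(min(tr$fluorescence[tr$time_s < 60]), 50)
  expect_equal(max(tr$fluorescence) / 50 - 1, 0.4, tolerance = 1e-9)
})
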