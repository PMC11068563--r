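test_that("CSP is the 0.14-weighted Euclidean norm", {
  expect_equal(csp_total(0, 0), 0)
  expect_equal(csp_total(0.05, 0), 0.05)
  expect_equal(csp_total(0.1, 1.0), sqrt(0.1^2 + 0.14^2))
  expect_equal(csp_total(0.1, 1.0), 0.17205, tolerance = 1e-4)
  # sign symmetry and norm oracle on random pairs
  set.seed(3)
  dh <- rnorm(1000, 0, 0.1); dn <- rnorm(1000, 0, 1)
  expect_equal(csp_total(dh, dn), csp_total(-dh, -dn))
  oracle <- vapply(seq_along(dh),
                   function(i) norm(matrix(c(dh[i], 0.14 * dn[i])), "F"),
                   numeric(1))
  expect_equal(csp_total(dh, dn), oracle, tolerance = 1e-12)
})

test_that("mean + 1 SD classification flags the right residues", {
  r <- classify_large_csp(c(1, 1, 1, 1))
  expect_equal(r$threshold, 1)
  expect_false(any(r$flagged))
  r2 <- classify_large_csp(c(0, 0, 0, 1))
  expect_equal(r2$mean, 0.25)
  expect_equal(r2$sd, 0.5)
  expect_equal(r2$threshold, 0.75)
  expect_equal(which(r2$flagged), 4L)
  # translation equivariance: constant offset shifts threshold, not flags
  r3 <- classify_large_csp(c(0, 0, 0, 1) + 0.2)
  expect_equal(r3$threshold, 0.95)
  expect_equal(r3$flagged, r2$flagged)
  expect_error(classify_large_csp(c(1, 2)), "3")
})

test_that("global slow-exchange fit recovers a shared Kd from noiseless series", {
  ser <- sim_nmr_series(kd_uM = 0.18, labeled_conc_uM = 100,
                        titrant_uM = c(0, 25, 50, 100, 150),
                        n_peaks = 6, states = "free", noise = 0)
  fit <- fit_global_slow_exchange(ser, labeled_conc_uM = 100)
  expect_equal(fit$kd, 0.18, tolerance = 1e-6)
  expect_equal(fit$n_series, 6)
  # at L = 0 every free series returns I0 exactly
  at0 <- ser$titrant_uM == 0
  expect_equal(predict(fit)[at0], fit$scales$scale[match(
    paste(ser$peak_id[at0], "free"),
    paste(fit$scales$peak_id, fit$scales$state))])
  # bound-state orientation closes too
  serb <- sim_nmr_series(kd_uM = 0.737, states = "bound", noise = 0,
                         scales = c(1, 2, 0.5, 1.5, 3, 0.8))
  fitb <- fit_global_slow_exchange(serb, 100)
  expect_equal(fitb$kd, 0.737, tolerance = 1e-5)
  expect_equal(sort(fitb$scales$scale), sort(c(1, 2, 0.5, 1.5, 3, 0.8)),
               tolerance = 1e-6)
})

test_that("global fit with a single series equals the per-series fit", {
  ser <- sim_nmr_series(kd_uM = 0.3, n_peaks = 3, states = "free",
                        noise = 0.05, seed = 21)
  one <- ser[ser$peak_id == ser$peak_id[1], ]
  f_single <- fit_global_slow_exchange(one, 100)
  f_global <- fit_global_slow_exchange(ser, 100)
  f_single2 <- fit_global_slow_exchange(one, 100)
  expect_identical(f_single$kd, f_single2$kd)   # deterministic
  # single-series result is a genuine 1-series global fit
  expect_equal(f_single$n_series, 1)
  expect_gt(f_global$n_series, f_single$n_series)
})

test_that("stoichiometric regime reproduces the two-segment titration shape", {
  p <- 100; kd <- p / 1000   # P/Kd = 1000, effectively stoichiometric
  l <- seq(0, 150, by = 5)
  fb <- fraction_bound(kd, p, l) / p
  expect_equal(fb, pmin(l / p, 1), tolerance = 0.02)
})

test_that("noisy global fits keep the median Kd near truth and report profile CIs", {
  kds <- vapply(1:40, function(i) {
    ser <- sim_nmr_series(kd_uM = 0.737, n_peaks = 6, states = "bound",
                          noise = 0.05, seed = i)
    fit_global_slow_exchange(ser, 100)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 0.737) / 0.737, 0.25)
  ser <- sim_nmr_series(kd_uM = 0.18, n_peaks = 6, noise = 0.05, seed = 1)
  fit <- fit_global_slow_exchange(ser, 100)
  expect_true(fit$kd_ci[1] <= fit$kd && fit$kd <= fit$kd_ci[2])
})

test_that("degenerate NMR inputs are rejected or flagged", {
  ser <- sim_nmr_series(noise = 0)
  expect_error(fit_global_slow_exchange(ser[, -4], 100), "intensity")
  z <- ser[ser$titrant_uM == 0, ]
  expect_error(fit_global_slow_exchange(z, 100), "zero-concentration")
  neg <- ser; neg$intensity[2] <- -0.5
  fit <- fit_global_slow_exchange(neg, 100)
  expect_true(fit$clipped_negative)
})
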