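test_that("noiseless generator/fitter round trips recover Kd to 1e-6 relative", {
  for (kd in c(0.05, 0.125, 0.5, 2)) {
    cv <- sim_titration("fluorescein", kd_uM = kd, noise = 0)
    fit <- fit_one_site(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)
    expect_true(fit$converged)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$s_free, 100, tolerance = 1e-6)
    expect_equal(fit$s_sat, 35, tolerance = 1e-6)
  }
  # ANS orientation: protein depleted, increasing signal
  cv <- sim_titration("ans", kd_uM = 1.5, noise = 0)
  fit <- fit_ans_titration(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)
  expect_equal(fit$kd, 1.5, tolerance = 1e-6)
})

test_that("Kd is invariant to affine rescaling of the signal axis", {
  cv <- sim_titration("fluorescein", kd_uM = 0.2, noise = 0.02, seed = 7)
  f1 <- fit_one_site(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)
  f2 <- fit_one_site(cv$titrant_uM, 3.5 * cv$signal + 12, cv$labeled_conc_uM)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f2$s_free, 3.5 * f1$s_free + 12, tolerance = 1e-6)
  expect_equal(f2$s_sat, 3.5 * f1$s_sat + 12, tolerance = 1e-6)
})

test_that("flat titrations are flagged non-identifiable with no Kd", {
  l <- seq(0, 2, length.out = 10)
  fit <- fit_one_site(l, rep(50, 10), 0.1)
  expect_false(fit$identifiable)
  expect_true(is.na(fit$kd))
  fit2 <- fit_ans_titration(l, rep(0, 10), 5.2)
  expect_false(fit2$identifiable)
  expect_error(fit_one_site(l[1:4], rep(1, 4), 0.1), "5")
})

test_that("median Kd over seeded noisy replicates stays near truth", {
  kds <- vapply(1:50, function(i) {
    cv <- sim_titration("fluorescein", kd_uM = 0.133, noise = 0.02, seed = i)
    fit_one_site(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 0.133) / 0.133, 0.10)

  kds_ans <- vapply(1:50, function(i) {
    cv <- sim_titration("ans", kd_uM = 1.5, noise = 0.02, seed = i)
    fit_ans_titration(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds_ans) - 1.5) / 1.5, 0.15)
})

test_that("binding_fit methods are coherent", {
  cv <- sim_titration("fluorescein", kd_uM = 0.25, noise = 0.02, seed = 11)
  fit <- fit_one_site(cv$titrant_uM, cv$signal, cv$labeled_conc_uM)
  expect_s3_class(fit, "binding_fit")
  expect_named(coef(fit), c("kd", "s_free", "s_sat"))
  expect_equal(fitted(fit) + residuals(fit), fit$data$signal)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, 0), fit$s_free, tolerance = 1e-9)
  expect_output(print(fit), "Kd")
  expect_output(print(summary(fit)), "Std. Error")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), fit$n)
})

test_that("dilution-expectation statistic matches the depletion oracle and its bounds", {
  # stoichiometric and weak-binding limits for a 2-fold dilution
  expect_equal(expected_dilution_decrease(10, 5, 0, factor = 2), 0.5)
  expect_equal(expected_dilution_decrease(10, 5, 1e6, factor = 2), 0.75,
               tolerance = 1e-4)
  # oracle via the bisection solver at both states
  p <- 41.63; l <- 50; kd <- 1.5
  d_oracle <- 1 - bisect_bound(kd, p / 2, l / 2) / bisect_bound(kd, p, l)
  expect_equal(expected_dilution_decrease(p, l, kd, 2), d_oracle,
               tolerance = 1e-9)
  expect_equal(d_oracle, 0.533, tolerance = 1e-3)
  # successive steps stay inside the analytic (0.5, 0.75) band when L < P
  d3 <- expected_dilution_decrease(41.63, 30, 1.5, 2, n_steps = 3)
  expect_true(all(d3 > 0.5 & d3 < 0.75))
  expect_error(expected_dilution_decrease(1, 0, 1, 2), "no binding")
  expect_error(expected_dilution_decrease(1, 1, 1, 1), "factor")
})
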