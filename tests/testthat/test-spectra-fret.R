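test_that("trapezoid band areas converge to closed-form Gaussian areas", {
  # second-order convergence under grid refinement
  errs <- vapply(c(2, 1, 0.5), function(h) {
    wl <- seq(488, 750, by = h)
    y <- 40 * exp(-(wl - 609)^2 / (2 * 20^2))
    abs(auc_spectrum(wl, y, 550, 700) - gauss_area(40, 609, 20, 550, 700))
  }, numeric(1))
  expect_lt(errs[3], 1e-3 * gauss_area(40, 609, 20, 550, 700))
  expect_gt(errs[1] / errs[2], 3)   # ~4x per halving
  expect_gt(errs[2] / errs[3], 3)
  # negatives floored at zero
  wl <- seq(550, 700, 1)
  expect_equal(auc_spectrum(wl, rep(-1, length(wl))), 0)
})

test_that("donor level inversion is exact for noiseless mixtures", {
  for (alpha in c(0, 0.37, 1, 2.5)) {
    s <- sim_spectra(donor_scale = alpha, acceptor_amp = 0, noise = 0)
    got <- donor_level_from_ratio_curve(s$coexpressing, s$background, s$donor)
    expect_equal(got, alpha, tolerance = 1e-6)
  }
  # observed ratio outside the standard curve
  s <- sim_spectra(donor_scale = 20, acceptor_amp = 0, noise = 0)
  expect_error(donor_level_from_ratio_curve(s$coexpressing, s$background,
                                            s$donor, alpha_max = 5),
               "outside")
})

test_that("donor subtraction recovers the acceptor band and QC-flags off-peak residuals", {
  s <- sim_spectra(donor_scale = 1, noise = 0)
  # subtract donor and background contributions: acceptor Gaussian remains
  co_minus_bg <- s$coexpressing
  co_minus_bg$intensity <- co_minus_bg$intensity - s$background$intensity
  acc <- acceptor_fret_spectrum(co_minus_bg, s$donor, donor_scale = 1)
  expect_equal(acc$intensity, s$acceptor$intensity, tolerance = 1e-9)
  expect_false(attr(acc, "off_peak"))
  expect_equal(attr(acc, "peak_nm"), 609)
  # zero residual is flagged
  z <- acceptor_fret_spectrum(s$donor, s$donor, donor_scale = 1)
  expect_true(attr(z, "off_peak"))
  # residual peaking away from 609 nm is flagged
  s2 <- sim_spectra(donor_scale = 0, acceptor_center_nm = 590, noise = 0)
  off <- acceptor_fret_spectrum(s2$acceptor, s$donor, donor_scale = 0)
  expect_true(attr(off, "off_peak"))
  expect_equal(attr(off, "peak_nm"), 590)
  neg <- s$donor; neg$intensity <- -neg$intensity - 1
  expect_error(acceptor_fret_spectrum(neg, s$donor, donor_scale = 0),
               "negative")
})

test_that("FRET ratios equal analytic area ratios and scale correctly", {
  # fine grid so trapezoid discretization is negligible against closed form
  s <- sim_spectra(donor_scale = 1, donor_amp = 100, acceptor_amp = 40,
                   wavelength_nm = seq(488, 750, by = 0.01), noise = 0)
  fr <- fret_ratios(s$acceptor, s$donor, s$total_acceptor)
  a_acc <- gauss_area(40, 609, 20, 550, 700)
  a_don <- gauss_area(100, 510, 15, 550, 700)
  a_tot <- gauss_area(64, 609, 20, 550, 700)
  expect_equal(fr$emission_ratio, a_acc / a_don, tolerance = 1e-6)
  expect_equal(fr$excitation_ratio, a_acc / a_tot, tolerance = 1e-6)
  # acceptor identical to total acceptor -> excitation ratio 1
  fr2 <- fret_ratios(s$total_acceptor, s$donor, s$total_acceptor)
  expect_equal(fr2$excitation_ratio, 1)
  # halving the acceptor halves both ratios; common gain cancels
  half <- s$acceptor; half$intensity <- half$intensity / 2
  fr3 <- fret_ratios(half, s$donor, s$total_acceptor)
  expect_equal(fr3$emission_ratio, fr$emission_ratio / 2)
  expect_equal(fr3$excitation_ratio, fr$excitation_ratio / 2)
  gain <- function(sp) { sp$intensity <- 7 * sp$intensity; sp }
  fr4 <- fret_ratios(gain(s$acceptor), gain(s$donor), gain(s$total_acceptor))
  expect_equal(fr4$emission_ratio, fr$emission_ratio, tolerance = 1e-12)
  expect_equal(fr4$excitation_ratio, fr$excitation_ratio, tolerance = 1e-12)
  zero <- s$donor; zero$intensity <- 0 * zero$intensity
  expect_error(fret_ratios(s$acceptor, zero, s$total_acceptor), "zero area")
})
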