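test_that("Manders coefficients hit the binary-mask identities", {
  r <- matrix(0, 10, 10); r[1:5, ] <- 1
  # identical masks
  res <- manders_coefficients(r, r)
  expect_equal(res$M1, 1); expect_equal(res$M2, 1)
  # disjoint masks
  g <- matrix(0, 10, 10); g[6:10, ] <- 1
  res2 <- manders_coefficients(r, g)
  expect_equal(res2$M1, 0); expect_equal(res2$M2, 0)
  # designed 83% overlap equals the counting fraction exactly
  ip <- sim_image_pair(overlap = 0.83, n_red = 100, mode = "binary", seed = 2)
  expect_equal(manders_coefficients(ip$red, ip$green)$M1, 0.83)
  # for binary images M1 is |R intersect G| / |R|
  expect_equal(manders_coefficients(ip$red, ip$green)$M1,
               sum(ip$red > 0 & ip$green > 0) / sum(ip$red > 0))
})

test_that("M1 is invariant to positive rescaling of the red channel", {
  ip <- sim_image_pair(overlap = 0.7, n_red = 300, mode = "continuous",
                       seed = 5)
  a <- manders_coefficients(ip$red, ip$green, thr_red = 0.1, thr_green = 0.1)
  b <- manders_coefficients(3.7 * ip$red, ip$green, thr_red = 3.7 * 0.1,
                            thr_green = 0.1)
  expect_equal(b$M1, a$M1, tolerance = 1e-12)
  expect_equal(b$M2, a$M2, tolerance = 1e-12)
})

test_that("empty above-threshold sets raise errors naming the channel", {
  r <- matrix(1, 4, 4); g <- matrix(1, 4, 4)
  expect_error(manders_coefficients(r, g, thr_red = 2), "red")
  expect_error(manders_coefficients(r, g, thr_green = 2), "green")
  expect_error(manders_coefficients(r, g[1:3, 1:3, drop = FALSE]),
               "dimensions")
})

test_that("Costes threshold equals the exhaustive-scan oracle on small images", {
  for (s in 1:5) {
    ip <- sim_image_pair(overlap = 0.85, n_red = 600, n_green_only = 40,
                         dim = c(48, 48), mode = "continuous", seed = s)
    got <- costes_threshold(ip$red, ip$green)
    expect_equal(got$thr_red, costes_bruteforce(ip$red, ip$green))
    eq <- costes_threshold(ip$red, ip$green, equal = TRUE)
    expect_equal(eq$thr_red, costes_bruteforce(ip$red, ip$green, equal = TRUE))
    expect_identical(eq$thr_red, eq$thr_green)
  }
})

test_that("Costes threshold separates a correlated bright population from dim noise", {
  ip <- sim_image_pair(overlap = 0.9, n_red = 800, n_green_only = 50,
                       mode = "continuous", bg_level = 0.05, seed = 3)
  ct <- costes_threshold(ip$red, ip$green)
  bright_min <- min(ip$red[ip$red > 0.05])
  expect_gt(ct$thr_red, 0)        # above the lowest intensities
  expect_lt(ct$thr_red, bright_min)  # below the bright population
  # Manders restricted by the threshold still sees the designed overlap
  mc <- manders_coefficients(ip$red, ip$green, ct$thr_red, ct$thr_green)
  expect_gt(mc$M1, 0.8)
})

test_that("Costes degenerate contracts: identical channels and independent noise", {
  r <- matrix(stats::runif(400, 0, 1), 20, 20)
  ct <- costes_threshold(r, r)
  expect_equal(ct$thr_red, min(r))   # no pixel excluded
  expect_equal(manders_coefficients(r, r, ct$thr_red, ct$thr_green)$M1, 1)
  # statistically independent channels: correlation <= 0 -> error, or a
  # threshold near the top of the intensity range if the sample r is positive
  set.seed(9)
  a <- matrix(stats::runif(400), 20, 20); b <- matrix(stats::runif(400), 20, 20)
  res <- tryCatch(costes_threshold(a, b), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "correlation")
  } else {
    expect_gt(res$thr_red, stats::quantile(a, 0.5))
  }
  expect_error(costes_threshold(matrix(1, 4, 4), matrix(1:16 / 16, 4, 4)),
               "non-constant")
})

test_that("preprocessing pipeline records its provenance and keeps images valid", {
  ip <- sim_image_pair(overlap = 0.8, n_red = 200, mode = "continuous",
                       seed = 4)
  out <- preprocess_channel(ip$red, background_radius = 3,
                            saturate_pct = 0.35, smooth = TRUE)
  expect_length(attr(out, "preprocessing"), 3)
  expect_true(all(out >= 0) && all(is.finite(out)))
  expect_identical(dim(out), dim(ip$red))
  # identity configuration changes nothing
  noop <- preprocess_channel(ip$red, background_radius = NULL,
                             saturate_pct = NULL, smooth = FALSE)
  expect_equal(as.vector(noop), as.vector(ip$red))
})
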