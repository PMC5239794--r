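fake_contours <- function(steps, spacings = rep(20, length(steps))) {
  out <- data.frame(contour_id = seq_along(steps), step_deg = steps,
                    spacing_px = spacings)
  out$length_bin <- length_bin(spacings)
  out
}

test_that("occurrence counts reflect planted class ratios and conservation", {
  ctr <- fake_contours(c(rep(0, 30), rep(30, 10), rep(20, 5)))
  occ <- occurrence_by_curvature(ctr)
  expect_equal(occ$n[occ$curvature_class_deg == 0], 30)
  expect_equal(occ$n[occ$curvature_class_deg == 30], 10)
  expect_equal(occ$n[occ$curvature_class_deg == 10], 0)
  # conservation against the per-length-bin table
  tab <- bin_contours(ctr)
  for (k in seq(0, 40, 10))
    expect_equal(sum(tab$n[tab$curvature_class_deg == k]),
                 occ$n[occ$curvature_class_deg == k])
  empty <- occurrence_by_curvature(fake_contours(numeric(0)))
  expect_true(all(empty$n == 0))
})

test_that("end distributions are normalized by per-class contour totals", {
  ctr <- fake_contours(rep(20, 10))
  ends <- data.frame(contour_id = rep(1:10, each = 2),
                     end = "tail", orientation_rel_deg = 20,
                     x = 0, y = 0)
  dist <- end_orientation_distribution(ends, ctr)
  expect_equal(sum(dist$count), 20)
  # single-bin distribution at +20
  expect_equal(dist$bin_center_deg[dist$count > 0], 20)
  # normalization is by the number of contours of the class
  expect_equal(sum(dist$normalized_frequency), 20 / 10)
})

test_that("histogram mean matches a planted Gaussian end distribution", {
  set.seed(77)
  n <- 2000
  rel <- rnorm(n, mean = 13, sd = 17)
  ctr <- fake_contours(rep(20, n))
  ends <- data.frame(contour_id = 1:n, end = "tail",
                     orientation_rel_deg = rel, x = 0, y = 0)
  dist <- end_orientation_distribution(ends, ctr)
  mu <- sum(dist$bin_center_deg * dist$count) / sum(dist$count)
  expect_lt(abs(mu - 13), 1.5)
  fit <- fit_distribution_gaussian(stats::aggregate(
    cbind(count, normalized_frequency) ~ bin_center_deg, dist, sum))
  expect_false(fit$degenerate)
  expect_lt(abs(fit$M - 13), 1.5)
  expect_lt(abs(fit$SD - 17) / 17, 0.15)
})

test_that("noise-free distribution parameters are recovered to <2%", {
  x <- seq(-90, 90, 10)
  gen <- list(A = 0.3, M = 24.05, SD = 23.92)
  d <- data.frame(bin_center_deg = x,
                  normalized_frequency = gen$A *
                    exp(-0.5 * (x - gen$M)^2 / gen$SD^2))
  fit <- fit_distribution_gaussian(d)
  expect_lt(abs(fit$A - gen$A) / gen$A, 0.02)
  expect_lt(abs(fit$M - gen$M) / gen$M, 0.02)
  expect_lt(abs(fit$SD - gen$SD) / gen$SD, 0.02)
})

test_that("symmetric and flat distributions behave as expected", {
  x <- seq(-90, 90, 10)
  sym <- data.frame(bin_center_deg = x,
                    normalized_frequency = 0.4 * exp(-0.5 * x^2 / 30^2))
  expect_lt(abs(fit_distribution_gaussian(sym)$M), 1e-6)
  flat <- data.frame(bin_center_deg = x,
                     normalized_frequency = rep(0.05, length(x)))
  ffit <- fit_distribution_gaussian(flat)
  expect_true(ffit$degenerate || is.na(ffit$r_squared) ||
                ffit$r_squared < 0.25)
})

test_that("exponential peak trend recovers generating parameters", {
  x <- c(0, 10, 20, 30)
  gen <- list(S = 3.017, K = 0.074)
  y <- gen$S * exp(gen$K * x)
  fit <- fit_peak_trend(x, y, "exponential")
  expect_lt(abs(fit$parameters["S"] - gen$S) / gen$S, 0.01)
  expect_lt(abs(fit$parameters["K"] - gen$K) / gen$K, 0.01)
  expect_gt(fit$r_squared, 0.999)
  # the implied peak stays below the identity line at 30 degrees
  expect_lt(gen$S * exp(gen$K * 30), 30)
})

test_that("constant peaks give a near-zero growth rate and linear fits work", {
  fit <- fit_peak_trend(c(0, 10, 20, 30), rep(5, 4), "exponential")
  expect_lt(abs(fit$parameters["K"]), 1e-6)
  lf <- fit_peak_trend(c(1, 2, 3, 4), c(2, 4, 6, 8), "linear")
  expect_equal(unname(lf$parameters["slope"]), 2, tolerance = 1e-9)
  expect_error(fit_peak_trend(1:2, 1:2), "3 points")
})
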