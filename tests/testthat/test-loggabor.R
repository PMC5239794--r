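test_that("radial log-Gabor amplitude peaks at fc and vanishes at DC", {
  spec <- radial_log_gabor_spec()
  expect_equal(radial_log_gabor_amplitude(spec, 0.1), 1)
  expect_equal(radial_log_gabor_amplitude(spec, 0), 0)
  expect_lt(radial_log_gabor_amplitude(spec, 0.4), 0.1)
  expect_error(radial_log_gabor_spec(fc = 0.7), "fc")
})

test_that("half-amplitude bandwidth is 1.5 octaves and matches the closed form", {
  spec <- radial_log_gabor_spec(fc = 0.1, B0 = 1.5, decay = 5.77)
  bw <- log_gabor_bandwidth_octaves(spec)
  closed <- 2 * spec$B0 * sqrt(log(2) / spec$decay) / log(2)
  expect_equal(bw, closed, tolerance = 1e-8)
  expect_equal(bw, 1.5, tolerance = 1e-3)
  # scaling check on an independent parameterization
  spec2 <- radial_log_gabor_spec(fc = 0.05, B0 = 1, decay = 4)
  expect_equal(log_gabor_bandwidth_octaves(spec2),
               2 * 1 * sqrt(log(2) / 4) / log(2), tolerance = 1e-8)
})

test_that("radial filtering removes DC and a constant image yields no crossings", {
  img <- matrix(0.7, 128, 128)
  filt <- radial_log_gabor_filter(img)
  expect_lt(max(abs(filt)), 1e-10)
  expect_equal(nrow(zero_crossings(filt, radius = 60)), 0)
})

test_that("a vertical step edge is localized within 1 px after thresholding", {
  img <- matrix(0.3, 128, 128)
  img[, 65:128] <- 0.7
  filt <- radial_log_gabor_filter(img)
  zc <- zero_crossings(filt, radius = 50, center = c(64.5, 64.5))
  expect_gt(nrow(zc), 20)
  expect_true(all((zc$row - 64.5)^2 + (zc$col - 64.5)^2 <= 50^2))
  # the raw crossings include weak ringing lines flanking the step, but
  # the main crossing line sits on the step itself ...
  main <- zc[abs(zc$col - 64.5) <= 1, ]
  expect_gt(nrow(main), 20)
  # ... and after orientation-energy thresholding only edges on the step
  # survive, oriented vertically (90 degrees)
  edges <- orientation_energy(img, zc, threshold_frac = 0.3)
  expect_gt(nrow(edges), 5)
  expect_true(all(abs(edges$x - 64.5) <= 1))
  expect_true(all(abs(wrap90(edges$orientation_deg - 90)) <= 5))
})

test_that("orientation energy recovers a planted grating orientation", {
  n <- 192
  row <- matrix(rep(1:n, n), n)
  col <- matrix(rep(1:n, each = n), n)
  th <- 40 * pi / 180
  perp <- -col * sin(th) + row * cos(th)
  img <- 0.5 + 0.4 * sin(2 * pi * 0.1 * perp)
  filt <- radial_log_gabor_filter(img)
  zc <- zero_crossings(filt, radius = 70, center = c(n / 2, n / 2))
  edges <- orientation_energy(img, zc[seq(1, nrow(zc), by = 7), ],
                              profiles = TRUE)
  expect_gt(nrow(edges), 10)
  expect_true(all(abs(wrap90(edges$orientation_deg - 40)) <= 5))
  prof <- attr(edges, "energy_profiles")
  expect_equal(rowSums(prof), rep(1, nrow(prof)), tolerance = 1e-12)
})

test_that("no candidates gives an empty edge table", {
  img <- matrix(0.5, 64, 64)
  out <- orientation_energy(img, data.frame(row = integer(0),
                                            col = integer(0)))
  expect_equal(nrow(out), 0)
})

test_that("recovered orientations are equivariant under image rotation", {
  set.seed(21)
  specs <- list(planted_contour_spec(0, 24, n_elements = 4,
                                     start_xy = c(190, 240),
                                     heading_deg = 25))
  img <- render_planted_image(specs, seed = 2)$image
  rot <- rotate_image(img, 30)
  e1 <- extract_edges(prepare_image(img))
  e2 <- extract_edges(prepare_image(rot))
  m1 <- sort(e1$orientation_deg[e1$peak_energy >
                                  0.5 * max(e1$peak_energy)])
  m2 <- sort(e2$orientation_deg[e2$peak_energy >
                                  0.5 * max(e2$peak_energy)])
  expect_gt(length(m1), 2)
  expect_gt(length(m2), 2)
  shift <- wrap90(median(m2) - median(m1))
  expect_equal(shift, 30, tolerance = 3)
})
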