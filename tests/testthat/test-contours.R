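test_that("pair geometry handles collinear and cocircular cases", {
  a <- list(x = 0, y = 0, orientation_deg = 0)
  b <- list(x = 10, y = 0, orientation_deg = 0)
  g <- pair_geometry(a, b)
  expect_equal(g$d, 10)
  expect_equal(g$phi, 0)
  expect_equal(g$theta, 0)
  expect_true(is_continuous(g, 5))
  # cocircular: orientation difference is twice the relative direction
  b2 <- list(x = 10 * cos(15 * pi / 180), y = 10 * sin(15 * pi / 180),
             orientation_deg = 30)
  g2 <- pair_geometry(a, b2)
  expect_equal(g2$phi, 15, tolerance = 1e-9)
  expect_equal(g2$theta, 30)
  expect_true(is_continuous(g2, 5))
  expect_false(is_continuous(list(d = 10, phi = 0, theta = 30), 5))
  expect_true(is_continuous(list(d = 10, phi = 10, theta = 20), 5))
  expect_error(pair_geometry(a, a), "coincident")
})

test_that("swapping the pair preserves d, negates theta, and shifts phi by theta", {
  set.seed(14)
  for (i in 1:50) {
    a <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
              orientation_deg = runif(1, 0, 180))
    b <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
              orientation_deg = runif(1, 0, 180))
    g_ab <- pair_geometry(a, b)
    g_ba <- pair_geometry(b, a)
    expect_equal(g_ab$d, g_ba$d)
    expect_equal(g_ab$theta, -g_ba$theta, tolerance = 1e-9)
    # phi is measured from each element's own orientation, so the swapped
    # phi is the original one minus the orientation difference (axially)
    expect_equal(g_ba$phi, wrap90(g_ab$phi - g_ab$theta), tolerance = 1e-9)
    # continuity is symmetric, and for continuous pairs phi negates too
    expect_equal(is_continuous(g_ab, 5), is_continuous(g_ba, 5))
    if (is_continuous(g_ab, 1e-9))
      expect_equal(g_ba$phi, -g_ab$phi, tolerance = 1e-6)
  }
  # brute-force check of phi negation over random cocircular pairs
  for (i in 1:50) {
    a <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
              orientation_deg = runif(1, 0, 180))
    phi <- runif(1, -44, 44)
    d <- runif(1, 5, 40)
    dir <- (a$orientation_deg + phi) * pi / 180
    b <- list(x = a$x + d * cos(dir), y = a$y + d * sin(dir),
              orientation_deg = (a$orientation_deg + 2 * phi) %% 180)
    expect_equal(pair_geometry(b, a)$phi, -pair_geometry(a, b)$phi,
                 tolerance = 1e-9)
  }
})

test_that("a planted chain on an empty field is mapped exactly", {
  chain <- make_chain(20, 20, 4, x0 = 40, y0 = 40, heading = 10)
  ctr <- find_contours(chain)
  expect_equal(nrow(ctr), 1)
  expect_equal(ctr$step_deg, 20, tolerance = 1e-6)
  expect_equal(ctr$spacing_px, 20, tolerance = 1e-6)
  expect_equal(as.character(ctr$length_bin), "18-24")
  mem <- attr(ctr, "members")
  expect_equal(sort(mem$x), sort(chain$x), tolerance = 1e-9)
})

test_that("collinear equally spaced edges map to a zero-step contour", {
  chain <- make_chain(0, 12, 4, x0 = 10, y0 = 50, heading = 30)
  ctr <- find_contours(chain)
  expect_equal(nrow(ctr), 1)
  expect_equal(ctr$step_deg, 0, tolerance = 1e-9)
})

test_that("violating the equal-spacing criterion suppresses the contour", {
  chain <- make_chain(20, 20, 4, x0 = 40, y0 = 40, heading = 10)
  # displace the third element along the chain by more than d/5
  dir <- atan2(chain$y[3] - chain$y[2], chain$x[3] - chain$x[2])
  chain$x[3] <- chain$x[3] + 6 * cos(dir)
  chain$y[3] <- chain$y[3] + 6 * sin(dir)
  expect_equal(nrow(find_contours(chain)), 0)
  expect_length(oracle_find_all(chain), 0)
})

test_that("no edge is a member of two mapped contours", {
  set.seed(33)
  edges <- rbind(make_chain(10, 15, 4, 20, 20, 5),
                 make_chain(-20, 10, 4, 70, 60, 120),
                 data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100),
                            orientation_deg = runif(30, 0, 180)))
  ctr <- find_contours(edges)
  mem <- attr(ctr, "members")
  expect_equal(anyDuplicated(mem[, c("x", "y")]), 0)
})

test_that("horizontal reflection negates every contour's step", {
  for (seed in 1:10) {
    set.seed(seed)
    edges <- rbind(
      make_chain(sample(c(-30, -20, 20, 30), 1), runif(1, 10, 20), 4,
                 runif(1, 20, 40), runif(1, 20, 60), runif(1, 0, 180)),
      make_chain(sample(c(-10, 10), 1), runif(1, 8, 14), 4,
                 runif(1, 60, 80), runif(1, 50, 80), runif(1, 0, 180)))
    ctr <- find_contours(edges)
    refl <- data.frame(x = 100 - edges$x, y = edges$y,
                       orientation_deg = (180 - edges$orientation_deg) %% 180)
    ctr_r <- find_contours(refl)
    expect_equal(nrow(ctr), nrow(ctr_r))
    expect_equal(sort(ctr$step_deg), sort(-ctr_r$step_deg),
                 tolerance = 1e-6)
  }
})

test_that("greedy results always satisfy the independently coded criteria", {
  for (seed in 1:25) {
    f <- random_field(seed, n_distractors = 25, step = (seed %% 5) * 10,
                      spacing = 8 + seed %% 7)
    ctr <- find_contours(f$edges)
    mem <- attr(ctr, "members")
    for (id in ctr$contour_id) {
      m <- mem[mem$contour_id == id, ]
      idx <- match(paste(m$x, m$y), paste(f$edges$x, f$edges$y))
      expect_true(oracle_quad_valid(f$edges, idx))
    }
  }
})

test_that("planted continuations are recorded at their relative orientation", {
  for (step in c(-20, 0, 20)) for (rho in c(-20, 0, 20, 40)) {
    spacing <- 20
    sgn <- if (step != 0) sign(step) else 1
    chain <- make_chain(step, spacing, 4, 40, 60, 15)
    # continuation beyond the tail, cocircular with offset rho; built from
    # the unwrapped terminal orientation so the travel direction continues
    o4 <- 15 + 3 * step
    o_end <- o4 + sgn * rho
    dir <- (o4 + sgn * rho / 2) * pi / 180
    ends_el <- data.frame(x = chain$x[4] + spacing * cos(dir),
                          y = chain$y[4] + spacing * sin(dir),
                          orientation_deg = o_end %% 180)
    edges <- rbind(chain, ends_el)
    ctr <- find_contours(edges)
    match_row <- which(abs(abs(ctr$step_deg) - abs(step)) < 2 &
                         abs(ctr$spacing_px - spacing) < 2)
    expect_gte(length(match_row), 1)
    rec <- extract_end_elements(ctr, edges)
    rec <- rec[rec$contour_id %in% ctr$contour_id[match_row], ]
    hit <- abs(rec$orientation_rel_deg - rho) < 1e-6
    if (rho == step) {
      # continuation indistinguishable from the chain: the mapper may take
      # the 4-element window ending at the continuation itself
      expect_true(nrow(rec) == 0 || any(hit))
    } else {
      expect_true(any(hit))
    }
  }
})

test_that("end candidates behind the contour terminus are excluded", {
  chain <- make_chain(0, 20, 4, 40, 40, 0)
  # candidate at 120 degrees from the travel direction: doubling back
  back <- data.frame(x = chain$x[4] + 20 * cos(120 * pi / 180),
                     y = chain$y[4] + 20 * sin(120 * pi / 180),
                     orientation_deg = 120)
  edges <- rbind(chain, back)
  ctr <- find_contours(edges)
  rec <- extract_end_elements(ctr, edges)
  expect_false(any(abs(rec$x - back$x) < 1e-6 & abs(rec$y - back$y) < 1e-6))
})

test_that("length bins follow the printed bin edges", {
  expect_equal(as.character(length_bin(c(8, 20, 9, 17, 24, 25, 33, 34, 42))),
               c("1-8", "18-24", "9-17", "9-17", "18-24", "25-33", "25-33",
                 "34-42", "34-42"))
  expect_equal(as.character(length_bin(c(0.4, 43))),
               c("unbinned", "unbinned"))
  empty <- bin_contours(data.frame(step_deg = numeric(0),
                                   spacing_px = numeric(0)))
  expect_true(all(empty$n == 0))
  one <- bin_contours(data.frame(step_deg = 20, spacing_px = 20))
  expect_equal(one$n[one$curvature_class_deg == 20 &
                       one$length_bin == "18-24"], 1)
})
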