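test_that("a straight spec gives six collinear, equally oriented elements", {
  path <- build_contour_path(contour_spec(curvature_angle_deg = 0,
                                          end_direction_deg = 0,
                                          end_separation_deg = 0.75))
  expect_equal(nrow(path), 6)
  expect_equal(path$orientation_deg, rep(0, 6))
  expect_equal(path$y_deg, rep(0, 6), tolerance = 1e-12)
  expect_equal(diff(path$x_deg), rep(0.75, 5), tolerance = 1e-12)
})

test_that("core orientations step by the curvature angle; ends follow their direction", {
  path <- build_contour_path(contour_spec(curvature_angle_deg = 30,
                                          end_direction_deg = -10))
  core <- path[path$role == "core", ]
  expect_equal(diff(core$orientation_deg), rep(30, 3))
  # tail end element: oriented along its direction from the last core element
  expect_equal(path$orientation_deg[6], (core$orientation_deg[4] - 10) %% 180)
  expect_equal(path$orientation_deg[1], (core$orientation_deg[1] + 10) %% 180)
})

test_that("consecutive element separations equal the specified distances", {
  for (a in c(0, 10, 20, 30, 40)) for (th in c(-30, 0, 40)) {
    sp <- contour_spec(curvature_angle_deg = a, end_direction_deg = th,
                       end_separation_deg = 1.5)
    path <- build_contour_path(sp)
    d <- sqrt(diff(path$x_deg)^2 + diff(path$y_deg)^2)
    expect_equal(d, c(1.5, rep(sp$core_separation_deg, 3), 1.5),
                 tolerance = 1e-9)
  }
})

test_that("S-shaped contours flip the step sign once and have smaller net turn", {
  cpath <- build_contour_path(contour_spec(curvature_angle_deg = 30,
                                           shape = "C"))
  spath <- build_contour_path(contour_spec(curvature_angle_deg = 30,
                                           shape = "S"))
  step <- function(p) diff(p[p$role == "core", "orientation_deg"])
  sc <- vapply(step(cpath), function(x) (x + 90) %% 180 - 90, numeric(1))
  ss <- vapply(step(spath), function(x) (x + 90) %% 180 - 90, numeric(1))
  expect_equal(sc, c(30, 30, 30))
  expect_equal(ss, c(30, -30, -30))
  expect_lt(abs(sum(ss)), abs(sum(sc)))
})

test_that("malformed contour specs error", {
  expect_error(contour_spec(n_elements = 5), "4 or 6")
  expect_error(build_contour_path(contour_spec(curvature_angle_deg = 0,
                                               shape = "S")), "S shape")
  expect_error(contour_spec(end_separation_deg = 0), "separations")
})

test_that("grid placement puts each element in a distinct cell, deterministically", {
  path <- build_contour_path(contour_spec(curvature_angle_deg = 0,
                                          end_separation_deg = 0.75))
  placed <- place_contour_in_grid(path, rng_seed = 42)
  expect_equal(nrow(unique(placed[, c("cell_row", "cell_col")])), 6)
  expect_true(all(placed$cell_row %in% 1:16 & placed$cell_col %in% 1:16))
  placed2 <- place_contour_in_grid(path, rng_seed = 42)
  expect_identical(placed, placed2)
  expect_false(identical(placed,
                         place_contour_in_grid(path, rng_seed = 43)))
})

test_that("an impossible path is rejected by the placement search", {
  long_path <- data.frame(x_deg = seq(0, 12, length.out = 6), y_deg = 0,
                          orientation_deg = 0, role = "core")
  expect_error(place_contour_in_grid(long_path, 1), "cannot fit")
})

test_that("filled fields hold exactly 256 elements, one per cell", {
  path <- build_contour_path(contour_spec(curvature_angle_deg = 20))
  placed <- place_contour_in_grid(path, rng_seed = 7)
  field <- fill_noise_and_render(placed, rng_seed = 8, render = FALSE)
  el <- field$elements
  expect_equal(nrow(el), 256)
  expect_equal(sum(el$is_contour), 6)
  expect_true(all(table(el$cell_row, el$cell_col) == 1))
  expect_true(all(el$orientation_deg >= 0 & el$orientation_deg < 180))
})

test_that("a noise-only field has 256 elements and no contour flags", {
  field <- fill_noise_and_render(NULL, rng_seed = 3, render = FALSE)
  expect_equal(nrow(field$elements), 256)
  expect_equal(sum(field$elements$is_contour), 0)
})

test_that("identical seeds give bit-identical rendered stimuli", {
  path <- build_contour_path(contour_spec(curvature_angle_deg = 10))
  placed <- place_contour_in_grid(path, rng_seed = 5)
  f1 <- fill_noise_and_render(placed, rng_seed = 6)
  f2 <- fill_noise_and_render(placed, rng_seed = 6)
  expect_identical(f1$image, f2$image)
  expect_equal(dim(f1$image), c(512, 512))
  expect_true(all(f1$image >= 0 & f1$image <= 1))
})

test_that("condition grids have the study's sizes", {
  e1 <- enumerate_conditions(1)
  expect_equal(nrow(e1), 50)
  expect_equal(sum(e1$n_trials_block), 1250)
  expect_setequal(unique(e1$contour_angle_deg), c(0, 10, 20, 30, 40))
  expect_setequal(unique(e1$end_direction_deg), seq(-30, 60, 10))
  e2 <- enumerate_conditions(2)
  expect_equal(sum(!e2$baseline), 20)
  expect_equal(sum(e2$baseline), 2)
  expect_error(enumerate_conditions(3), "1 or 2")
})

test_that("stimuli round-trip to disk as PNG + CSV + JSON", {
  dir <- withr::local_tempdir()
  sp <- contour_spec(curvature_angle_deg = 10)
  placed <- place_contour_in_grid(build_contour_path(sp), rng_seed = 2)
  field <- fill_noise_and_render(placed, rng_seed = 4)
  paths <- write_stimulus(field, file.path(dir, "stim"), spec = sp, seed = 2)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths["csv"])
  expect_equal(nrow(tab), 256)
  img <- png::readPNG(paths["png"])
  expect_equal(dim(img), c(512, 512))
})
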