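#' Specify a contour stimulus
#'
#' Describes one target contour for the detection stimuli: a core of four
#' elements turning by a constant curvature angle per element, flanked
#' (optionally) by two end elements whose direction relative to the last core
#' element is manipulated.
#'
#' Positive `curvature_angle_deg` and positive `end_direction_deg` share the
#' same rotational sense, so a positive end direction continues ("is
#' clockwise to") the curvature. `shape = "S"` flips the sign of the
#' orientation step between the two middle core elements.
#'
#' @param n_elements 6 (core of four plus two end elements) or 4 (core-only
#'   baseline).
#' @param curvature_angle_deg per-element orientation step of the core, in
#'   degrees (0 to 40 in the study).
#' @param end_direction_deg direction of each end element relative to the
#'   orientation of the adjacent core element, degrees (-30 to 60 in the
#'   study); its orientation equals its direction.
#' @param end_separation_deg distance of end elements from the adjacent core
#'   element, degrees of visual angle.
#' @param core_separation_deg distance between adjacent core elements,
#'   degrees of visual angle. Default follows the study: 0.75 for a straight
#'   (0 deg) contour, 0.5 otherwise.
#' @param shape `"C"` (single curvature sign) or `"S"` (sign flip at the
#'   core midpoint).
#' @return an object of class `contour_spec`.
#' @export
contour_spec <- function(n_elements = 6, curvature_angle_deg = 0,
                         end_direction_deg = 0, end_separation_deg = 0.5,
                         core_separation_deg = NULL, shape = c("C", "S")) {
  shape <- match.arg(shape)
  if (!n_elements %in% c(4L, 6L))
    stop("`n_elements` must be 4 or 6", call. = FALSE)
  if (is.null(core_separation_deg))
    core_separation_deg <- if (curvature_angle_deg == 0) 0.75 else 0.5
  if (core_separation_deg <= 0 || end_separation_deg <= 0)
    stop("separations must be > 0", call. = FALSE)
  structure(list(n_elements = as.integer(n_elements),
                 curvature_angle_deg = curvature_angle_deg,
                 end_direction_deg = end_direction_deg,
                 end_separation_deg = end_separation_deg,
                 core_separation_deg = core_separation_deg,
                 shape = shape),
            class = "contour_spec")
}

#' Build the geometry of a contour stimulus
#'
#' Lays out the contour in stimulus coordinates (degrees of visual angle)
#' starting from the origin with the first core element horizontal. Adjacent
#' core elements are separated by `core_separation_deg`, with orientation
#' stepping by the curvature angle; each inter-element displacement bisects
#' the two orientations, so adjacent core elements are cocircular. End
#' elements (when `n_elements = 6`) sit at `end_separation_deg` from the
#' terminal core elements, displaced in direction `end_direction_deg`
#' relative to the terminal element's orientation, and oriented along their
#' own direction.
#'
#' @param spec a [contour_spec()].
#' @return data frame with columns `x_deg`, `y_deg`, `orientation_deg`,
#'   `role` (`"end"` or `"core"`), ordered along the path.
#' @examples
#' build_contour_path(contour_spec(curvature_angle_deg = 30,
#'                                 end_direction_deg = -10))
#' @export
build_contour_path <- function(spec) {
  stopifnot(inherits(spec, "contour_spec"))
  a <- spec$curvature_angle_deg
  if (spec$shape == "C") {
    steps <- c(a, a, a)
  } else {
    if (a == 0)
      stop("S shape requires a non-zero curvature angle", call. = FALSE)
    # sign flips once, between the two middle core elements
    steps <- c(a, -a, -a)
  }
  ori <- cumsum(c(0, steps))          # orientations of the 4 core elements
  x <- y <- numeric(4)
  for (i in 2:4) {
    dir <- (ori[i - 1] + steps[i - 1] / 2) * pi / 180
    x[i] <- x[i - 1] + spec$core_separation_deg * cos(dir)
    y[i] <- y[i - 1] + spec$core_separation_deg * sin(dir)
  }
  path <- data.frame(x_deg = x, y_deg = y, orientation_deg = ori,
                     role = "core", stringsAsFactors = FALSE)
  if (spec$n_elements == 6L) {
    th <- spec$end_direction_deg
    # tail end: continues forward from the last core element
    dir_t <- ori[4] + th
    tail_el <- c(x[4] + spec$end_separation_deg * cos(dir_t * pi / 180),
                 y[4] + spec$end_separation_deg * sin(dir_t * pi / 180),
                 dir_t)
    # head end: mirror-symmetric continuation backwards from the first
    dir_h <- ori[1] + 180 - th
    head_el <- c(x[1] + spec$end_separation_deg * cos(dir_h * pi / 180),
                 y[1] + spec$end_separation_deg * sin(dir_h * pi / 180),
                 dir_h - 180)
    path <- rbind(
      data.frame(x_deg = head_el[1], y_deg = head_el[2],
                 orientation_deg = head_el[3], role = "end",
                 stringsAsFactors = FALSE),
      path,
      data.frame(x_deg = tail_el[1], y_deg = tail_el[2],
                 orientation_deg = tail_el[3], role = "end",
                 stringsAsFactors = FALSE))
  }
  path$orientation_deg <- path$orientation_deg %% 180
  rownames(path) <- NULL
  path
}

#' Place a contour path in the stimulus grid
#'
#' Applies random rigid motions (uniform rotation about the path centroid,
#' uniform translation) until every element centroid falls inside the 8 x 8
#' deg field with each centroid in a distinct 0.5 x 0.5 deg cell of the
#' 16 x 16 grid. Deterministic for a given seed.
#'
#' @param path data frame from [build_contour_path()].
#' @param rng_seed integer seed for the placement search.
#' @param field_deg field side length in degrees (default 8).
#' @param n_cells cells per side (default 16).
#' @param max_attempts attempts before giving up.
#' @return the path with transformed coordinates plus `cell_row`, `cell_col`
#'   columns (1-based).
#' @export
place_contour_in_grid <- function(path, rng_seed, field_deg = 8,
                                  n_cells = 16, max_attempts = 10000) {
  cell <- field_deg / n_cells
  span <- max(dist(path[, c("x_deg", "y_deg")]))
  if (span > field_deg * sqrt(2))
    stop("contour path cannot fit in the field", call. = FALSE)
  cx <- mean(path$x_deg); cy <- mean(path$y_deg)
  with_seed(rng_seed, {
    for (att in seq_len(max_attempts)) {
      rot <- runif(1, 0, 360)
      th <- rot * pi / 180
      xr <- cos(th) * (path$x_deg - cx) - sin(th) * (path$y_deg - cy)
      yr <- sin(th) * (path$x_deg - cx) + cos(th) * (path$y_deg - cy)
      tx <- runif(1, 0, field_deg)
      ty <- runif(1, 0, field_deg)
      xs <- xr + tx; ys <- yr + ty
      if (any(xs <= 0 | xs >= field_deg | ys <= 0 | ys >= field_deg)) next
      col <- floor(xs / cell) + 1L
      row <- floor(ys / cell) + 1L
      if (anyDuplicated(paste(row, col))) next
      out <- path
      out$x_deg <- xs; out$y_deg <- ys
      out$orientation_deg <- (path$orientation_deg + rot) %% 180
      out$cell_row <- row; out$cell_col <- col
      return(out)
    }
    stop("placement search exhausted after ", max_attempts, " attempts",
         call. = FALSE)
  })
}

#' Fill empty grid cells with noise elements and render the stimulus
#'
#' Every grid cell not claimed by a contour element receives one element with
#' orientation uniform on `[0, 180)` and centroid uniform within the cell, so
#' the complete field always holds `n_cells^2` elements (256 by default) with
#' approximately equal local density. When the contour claims fewer distinct
#' cells than it has elements (possible for widely separated end elements),
#' correspondingly fewer noise elements are added so the total count is
#' conserved. Patches are composited additively in contrast space on a
#' mid-gray background and mapped to `[0, 1]`; out-of-range pixels are
#' clipped and counted.
#'
#' @param placed placed contour path from [place_contour_in_grid()], or
#'   `NULL` for a noise-only (target-absent) field.
#' @param rng_seed seed for noise element sampling.
#' @param params a [gabor_params()] describing every element.
#' @param contrast peak Michelson contrast of each element.
#' @param field_deg,n_cells field geometry (8 deg, 16 cells).
#' @param render logical; if `FALSE`, skip rasterization (elements only).
#' @return an object of class `stimulus_field`: list with `elements`
#'   (data frame: `x_deg`, `y_deg`, `orientation_deg`, `is_contour`,
#'   `cell_row`, `cell_col`), `image` (matrix in `[0, 1]`, row 1 = top),
#'   `background_level`, `n_clipped`, `px_per_deg`.
#' @export
fill_noise_and_render <- function(placed = NULL, rng_seed = 1,
                                  params = gabor_params(), contrast = 1,
                                  field_deg = 8, n_cells = 16,
                                  render = TRUE) {
  cell <- field_deg / n_cells
  n_total <- n_cells^2
  if (is.null(placed)) {
    contour <- data.frame(x_deg = numeric(0), y_deg = numeric(0),
                          orientation_deg = numeric(0),
                          cell_row = integer(0), cell_col = integer(0))
  } else {
    contour <- placed[, c("x_deg", "y_deg", "orientation_deg",
                          "cell_row", "cell_col")]
  }
  occupied <- unique(paste(contour$cell_row, contour$cell_col))
  free <- expand.grid(cell_row = seq_len(n_cells), cell_col = seq_len(n_cells))
  free <- free[!paste(free$cell_row, free$cell_col) %in% occupied, ]
  n_noise <- n_total - nrow(contour)
  noise <- with_seed(rng_seed, {
    pick <- free[sample.int(nrow(free), min(n_noise, nrow(free))), ]
    data.frame(
      x_deg = (pick$cell_col - 1 + runif(nrow(pick))) * cell,
      y_deg = (pick$cell_row - 1 + runif(nrow(pick))) * cell,
      orientation_deg = runif(nrow(pick), 0, 180),
      cell_row = pick$cell_row, cell_col = pick$cell_col)
  })
  elements <- rbind(
    cbind(contour, is_contour = rep(TRUE, nrow(contour))),
    cbind(noise, is_contour = rep(FALSE, nrow(noise))))
  elements <- elements[, c("x_deg", "y_deg", "orientation_deg", "is_contour",
                           "cell_row", "cell_col")]
  rownames(elements) <- NULL

  img <- NULL; n_clipped <- 0L
  if (render) {
    ppd <- params$px_per_deg
    side <- round(field_deg * ppd)
    patch_n <- 2L * ceiling(3 * params$sigma_px) + 1L
    half <- (patch_n - 1L) %/% 2L
    canvas <- matrix(0, side, side)
    for (i in seq_len(nrow(elements))) {
      px <- elements$x_deg[i] * ppd
      py <- elements$y_deg[i] * ppd
      c0 <- round(px); r0 <- round(py)
      patch <- contrast * gabor_patch(params, elements$orientation_deg[i],
                                      patch_n, c(px - c0, py - r0))
      rr <- (r0 - half):(r0 + half)
      cc <- (c0 - half):(c0 + half)
      keep_r <- rr >= 1 & rr <= side
      keep_c <- cc >= 1 & cc <= side
      canvas[rr[keep_r], cc[keep_c]] <-
        canvas[rr[keep_r], cc[keep_c]] + patch[keep_r, keep_c]
    }
    n_clipped <- sum(abs(canvas) > 1)
    img <- 0.5 + 0.5 * clamp(canvas, -1, 1)
  }
  structure(list(elements = elements, image = img,
                 background_level = 0.5, n_clipped = n_clipped,
                 px_per_deg = params$px_per_deg, field_deg = field_deg,
                 n_cells = n_cells),
            class = "stimulus_field")
}

#' @export
print.stimulus_field <- function(x, ...) {
  cat("<stimulus_field> ", nrow(x$elements), " elements (",
      sum(x$elements$is_contour), " contour), ",
      x$n_cells, "x", x$n_cells, " grid over ",
      x$field_deg, " deg", sep = "")
  if (!is.null(x$image))
    cat("; image ", nrow(x$image), "x", ncol(x$image), " px", sep = "")
  cat("\n")
  invisible(x)
}

#' Enumerate the stimulus conditions of the two experiments
#'
#' Experiment 1 crosses five contour curvature angles (0-40 deg) with ten end
#' directions (-30 to 60 deg): 50 conditions. Experiment 2 crosses five end
#' separations (0.5-2 deg) with contour shape (C/S) and end-element
#' orientation (collinear 0 deg / cocircular 30 deg) at a 30 deg contour
#' angle: 20 conditions plus two four-element baselines flagged by
#' `baseline = TRUE`.
#'
#' @param experiment 1 or 2.
#' @param reps_per_block repetitions of each condition in one block
#'   (Experiment 1 default 25, i.e. 1250 trials per block).
#' @return data frame of conditions; Experiment 1 rows carry
#'   `contour_angle_deg`, `end_direction_deg`, `n_trials_block`; Experiment 2
#'   rows carry `end_separation_deg`, `shape`, `end_direction_deg`,
#'   `baseline`.
#' @export
enumerate_conditions <- function(experiment, reps_per_block = 25) {
  if (!experiment %in% c(1, 2))
    stop("`experiment` must be 1 or 2", call. = FALSE)
  if (experiment == 1) {
    g <- expand.grid(contour_angle_deg = c(0, 10, 20, 30, 40),
                     end_direction_deg = seq(-30, 60, by = 10))
    g <- g[order(g$contour_angle_deg, g$end_direction_deg), ]
    g$n_trials_block <- reps_per_block
    rownames(g) <- NULL
    g
  } else {
    g <- expand.grid(end_separation_deg = c(0.5, 0.75, 1, 1.5, 2),
                     shape = c("C", "S"),
                     end_direction_deg = c(0, 30),
                     stringsAsFactors = FALSE)
    g$baseline <- FALSE
    base <- data.frame(end_separation_deg = NA_real_, shape = c("C", "S"),
                       end_direction_deg = NA_real_, baseline = TRUE,
                       stringsAsFactors = FALSE)
    g <- rbind(g, base)
    g$contour_angle_deg <- 30
    rownames(g) <- NULL
    g
  }
}

#' Write a rendered stimulus to disk
#'
#' Writes the raster as 8-bit grayscale PNG, the element table as CSV, and a
#' JSON sidecar with the contour specification and seeds.
#'
#' @param field a `stimulus_field`.
#' @param path_prefix file path prefix; `<prefix>.png`, `<prefix>.csv` and
#'   `<prefix>.json` are written.
#' @param spec the generating [contour_spec()] (or `NULL`).
#' @param seed the generating seed (or `NULL`).
#' @return invisibly, the paths written.
#' @export
write_stimulus <- function(field, path_prefix, spec = NULL, seed = NULL) {
  stopifnot(inherits(field, "stimulus_field"))
  paths <- c(png = paste0(path_prefix, ".png"),
             csv = paste0(path_prefix, ".csv"),
             json = paste0(path_prefix, ".json"))
  if (!is.null(field$image))
    png::writePNG(field$image, paths["png"])
  el <- field$elements
  el$element_id <- seq_len(nrow(el))
  utils::write.csv(el[, c("element_id", "x_deg", "y_deg", "orientation_deg",
                          "is_contour", "cell_row", "cell_col")],
                   paths["csv"], row.names = FALSE)
  meta <- list(spec = if (is.null(spec)) NULL else unclass(spec),
               seed = seed, background_level = field$background_level,
               n_clipped = field$n_clipped, px_per_deg = field$px_per_deg)
  jsonlite::write_json(meta, paths["json"], auto_unbox = TRUE, null = "null")
  invisible(paths)
}
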