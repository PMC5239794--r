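#' Specify a planted constant-curvature chain
#'
#' Describes a chain of equally spaced edge elements whose orientation turns
#' by a constant step, to be rendered into a synthetic test image. Adjacent
#' elements are cocircular: each displacement direction bisects the two
#' element orientations. Optional continuation ("end") elements are planted
#' one spacing beyond each chain end at an orientation offset relative to
#' the curvature direction (positive offsets continue the curvature), again
#' placed so the pairing with the terminal element is continuous.
#'
#' @param step_deg signed curvature step per element, degrees.
#' @param spacing_px inter-element distance, 1-42 px.
#' @param n_elements number of core elements (>= 4).
#' @param start_xy (x, y) of the first element, pixels.
#' @param heading_deg orientation of the first element, degrees.
#' @param end_offset_deg orientation of planted continuation elements
#'   relative to the curvature direction, or `NULL` for none.
#' @param contrast peak contrast of the rendered elements.
#' @return an object of class `planted_contour_spec`.
#' @export
planted_contour_spec <- function(step_deg, spacing_px, n_elements = 4,
                                 start_xy = c(240, 240), heading_deg = 0,
                                 end_offset_deg = NULL, contrast = 0.8) {
  if (spacing_px < 1 || spacing_px > 42)
    stop("`spacing_px` must lie in 1-42 px", call. = FALSE)
  if (n_elements < 4) stop("`n_elements` must be >= 4", call. = FALSE)
  structure(list(step_deg = step_deg, spacing_px = spacing_px,
                 n_elements = as.integer(n_elements),
                 start_xy = start_xy, heading_deg = heading_deg,
                 end_offset_deg = end_offset_deg, contrast = contrast),
            class = "planted_contour_spec")
}

# Element table (x, y, orientation_deg, role) for a planted spec.
planted_elements <- function(spec) {
  n <- spec$n_elements
  o <- spec$heading_deg + spec$step_deg * (0:(n - 1))
  x <- y <- numeric(n)
  x[1] <- spec$start_xy[1]; y[1] <- spec$start_xy[2]
  for (i in 2:n) {
    dir <- (o[i - 1] + spec$step_deg / 2) * pi / 180
    x[i] <- x[i - 1] + spec$spacing_px * cos(dir)
    y[i] <- y[i - 1] + spec$spacing_px * sin(dir)
  }
  el <- data.frame(x = x, y = y, orientation_deg = o %% 180,
                   role = "core", stringsAsFactors = FALSE)
  if (!is.null(spec$end_offset_deg)) {
    rho <- spec$end_offset_deg
    sgn <- if (abs(spec$step_deg) > 1e-9) sign(spec$step_deg) else 1
    # tail continuation
    o_t <- o[n] + sgn * rho
    dir_t <- (o[n] + sgn * rho / 2) * pi / 180
    # head continuation (travel direction reversed, so the curvature sign
    # seen from that end flips)
    o_h <- o[1] - sgn * rho
    dir_h <- (o[1] + 180 - sgn * rho / 2) * pi / 180
    el <- rbind(el, data.frame(
      x = c(x[n] + spec$spacing_px * cos(dir_t),
            x[1] + spec$spacing_px * cos(dir_h)),
      y = c(y[n] + spec$spacing_px * sin(dir_t),
            y[1] + spec$spacing_px * sin(dir_h)),
      orientation_deg = c(o_t, o_h) %% 180,
      role = "end", stringsAsFactors = FALSE))
  }
  el
}

# Render one edge element: an odd-symmetric luminance step along the
# element's orientation, windowed by a Gaussian envelope elongated along
# the edge (a short anti-aliased edge segment). The zero-crossing detector
# localizes this structure at the element center, and the elongation keeps
# the element's orientation well defined to the oriented filter bank.
render_edge_element <- function(canvas, x0, y0, orientation_deg, contrast,
                                sigma_along_px = 3.5, sigma_perp_px = 1.4,
                                ramp_px = 1) {
  half <- ceiling(3 * max(sigma_along_px, sigma_perp_px))
  nr <- nrow(canvas); nc <- ncol(canvas)
  rr <- max(1, round(y0) - half):min(nr, round(y0) + half)
  cc <- max(1, round(x0) - half):min(nc, round(x0) + half)
  th <- orientation_deg * pi / 180
  x <- matrix(rep(cc, each = length(rr)), length(rr)) - x0
  y <- matrix(rep(rr, length(cc)), length(rr)) - y0
  along <- x * cos(th) + y * sin(th)
  perp <- -x * sin(th) + y * cos(th)
  env <- exp(-(along^2 / (2 * sigma_along_px^2) +
                 perp^2 / (2 * sigma_perp_px^2)))
  edge <- tanh(perp / ramp_px)
  canvas[rr, cc] <- canvas[rr, cc] + contrast * env * edge
  canvas
}

# 1/f amplitude noise field in [-1, 1]-ish contrast units (RMS = `rms`).
one_over_f_noise <- function(n, rms, seed) {
  with_seed(seed, {
    g <- freq_grid(n, n)
    r <- sqrt(g$fx^2 + g$fy^2)
    amp <- 1 / pmax(r, 1 / n)
    amp[1, 1] <- 0
    ph <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
    f <- amp * exp(1i * ph)
    x <- Re(stats::fft(f, inverse = TRUE)) / (n * n)
    x * rms / stats::sd(x)
  })
}

#' Render a synthetic image with planted contour chains
#'
#' Builds a grayscale raster (default 480 x 480 px) containing the planted
#' chains over a configurable background, together with a ground-truth
#' table of every planted element. Elements are rendered as Gaussian-
#' windowed luminance edges. Background options: `"uniform"` mid-gray,
#' `"onef"` 1/f noise (a crude stand-in for the spectral structure of
#' natural scenes), optionally with scattered distractor edge elements of
#' random position and orientation.
#'
#' @param specs list of [planted_contour_spec()] objects (possibly empty).
#' @param seed RNG seed; identical seeds give identical rasters.
#' @param size_px image side length.
#' @param background `"uniform"` or `"onef"`.
#' @param noise_rms RMS contrast of the 1/f background.
#' @param n_distractors number of random distractor edge elements.
#' @param distractor_contrast contrast of distractor elements.
#' @return list with `image` (matrix in `[0, 1]`), `truth` (data frame:
#'   `chain_id`, `element`, `x`, `y`, `orientation_deg`, `role`,
#'   `step_deg`, `spacing_px`).
#' @export
render_planted_image <- function(specs, seed = 1, size_px = 480,
                                 background = c("uniform", "onef"),
                                 noise_rms = 0.03, n_distractors = 0,
                                 distractor_contrast = 0.5) {
  background <- match.arg(background)
  canvas <- matrix(0, size_px, size_px)
  if (background == "onef")
    canvas <- canvas + one_over_f_noise(size_px, noise_rms, seed + 7L)
  truth <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    el <- planted_elements(sp)
    for (i in seq_len(nrow(el)))
      canvas <- render_edge_element(canvas, el$x[i], el$y[i],
                                    el$orientation_deg[i], sp$contrast)
    truth[[k]] <- data.frame(chain_id = k, element = seq_len(nrow(el)),
                             el, step_deg = sp$step_deg,
                             spacing_px = sp$spacing_px)
  }
  if (n_distractors > 0) {
    dst <- with_seed(seed + 13L, data.frame(
      x = stats::runif(n_distractors, 20, size_px - 20),
      y = stats::runif(n_distractors, 20, size_px - 20),
      orientation_deg = stats::runif(n_distractors, 0, 180)))
    for (i in seq_len(n_distractors))
      canvas <- render_edge_element(canvas, dst$x[i], dst$y[i],
                                    dst$orientation_deg[i],
                                    distractor_contrast)
  }
  img <- clamp(0.5 + 0.5 * canvas, 0, 1)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chain_id = integer(0), element = integer(0), x = numeric(0),
               y = numeric(0), orientation_deg = numeric(0),
               role = character(0), step_deg = numeric(0),
               spacing_px = numeric(0))
  list(image = img, truth = truth)
}

#' Default corpus manifest
#'
#' Describes a synthetic corpus that emulates the qualitative structure
#' reported for natural scenes: planted chain counts decrease monotonically
#' with curvature class, and continuation elements are planted at the
#' curvature step (so end elements follow the curvature direction).
#'
#' @param n_images number of images.
#' @param seed master seed.
#' @param class_weights relative frequency of curvature classes
#'   0, 10, 20, 30, 40 degrees.
#' @param spacing_px inter-element spacings to draw from.
#' @param chains_per_image planted chains per image.
#' @param end_offset_sd_deg spread (SD, degrees) of the planted continuation
#'   offsets around the curvature step.
#' @return an object of class `corpus_manifest`.
#' @export
default_corpus_manifest <- function(n_images = 50, seed = 1,
                                    class_weights = c(5, 4, 3, 2, 1),
                                    spacing_px = c(20, 24, 28),
                                    chains_per_image = 4,
                                    end_offset_sd_deg = 12) {
  structure(list(n_images = as.integer(n_images), seed = as.integer(seed),
                 classes = seq(0, 40, 10), class_weights = class_weights,
                 spacing_px = spacing_px,
                 chains_per_image = as.integer(chains_per_image),
                 end_offset_sd_deg = end_offset_sd_deg),
            class = "corpus_manifest")
}

#' Generate a synthetic image corpus
#'
#' Draws planted chain specifications from the manifest and renders each
#' image. Chains are placed on a coarse within-image grid of start
#' positions so chains do not overlap; curvature signs and headings are
#' randomized. End continuation elements are planted at `end_offset_deg`
#' relative to the curvature direction (defaulting to the chain's own step,
#' i.e. good continuation of the curvature).
#'
#' @param manifest a [default_corpus_manifest()].
#' @param out_dir optional directory; when given, each image is written as
#'   `img_###.png` with a `truth_###.csv` ground-truth table and a
#'   `manifest.json` sidecar.
#' @param end_offset_deg continuation offset, or `NULL` to use each chain's
#'   curvature step, or a function(step) returning the offset.
#' @return list of `render_planted_image()` results (invisibly when
#'   `out_dir` is given).
#' @export
generate_corpus <- function(manifest, out_dir = NULL,
                            end_offset_deg = NULL) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  p <- manifest$class_weights / sum(manifest$class_weights)
  # allocate curvature classes across the whole corpus in exact proportion
  # to the weights (largest-remainder rounding), so the planted class mix
  # is the manifest's mix rather than a multinomial draw around it
  total <- manifest$n_images * manifest$chains_per_image
  n_per_class <- floor(p * total)
  rem <- order(p * total - n_per_class, decreasing = TRUE)
  short <- total - sum(n_per_class)
  if (short > 0) n_per_class[rem[seq_len(short)]] <-
      n_per_class[rem[seq_len(short)]] + 1L
  class_pool <- rep(manifest$classes, n_per_class)
  class_pool <- with_seed(manifest$seed + 17L,
                          sample(class_pool, length(class_pool)))
  # start positions keep chains inside the 216 px analysis radius
  anchors <- expand.grid(x = c(120, 240, 340), y = c(130, 250, 360))
  out <- vector("list", manifest$n_images)
  for (im in seq_len(manifest$n_images)) {
    seed_im <- manifest$seed + im * 101L
    cls_im <- class_pool[(im - 1) * manifest$chains_per_image +
                           seq_len(manifest$chains_per_image)]
    specs <- with_seed(seed_im, {
      cls <- cls_im
      sp <- sample(manifest$spacing_px, manifest$chains_per_image,
                   replace = TRUE)
      sgn <- sample(c(-1, 1), manifest$chains_per_image, replace = TRUE)
      head <- stats::runif(manifest$chains_per_image, 0, 180)
      slots <- anchors[sample.int(nrow(anchors),
                                  manifest$chains_per_image), ]
      jitter_sd <- manifest$end_offset_sd_deg %||% 0
      jit <- stats::rnorm(manifest$chains_per_image, 0, jitter_sd)
      lapply(seq_len(manifest$chains_per_image), function(k) {
        step <- sgn[k] * cls[k]
        off <- if (is.null(end_offset_deg))
          clamp(cls[k] + jit[k], -85, 85)
        else if (is.function(end_offset_deg)) end_offset_deg(cls[k])
        else end_offset_deg
        planted_contour_spec(step_deg = step, spacing_px = sp[k],
                             start_xy = c(slots$x[k], slots$y[k]),
                             heading_deg = head[k],
                             end_offset_deg = off)
      })
    })
    out[[im]] <- render_planted_image(specs, seed = seed_im)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      tag <- sprintf("%03d", im)
      png::writePNG(out[[im]]$image, file.path(out_dir,
                                               paste0("img_", tag, ".png")))
      utils::write.csv(out[[im]]$truth,
                       file.path(out_dir, paste0("truth_", tag, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}

#' Generate simulated 2IFC response tables
#'
#' Wraps [simulate_observer()] over the condition grid of either
#' experiment. The default tuning surface for Experiment 1 follows the
#' study's group-average Gaussian fits per contour angle; Experiment 2
#' conditions are simulated from the 30-degree surface.
#'
#' @param experiment 1 or 2.
#' @param n_trials trials per condition.
#' @param seed RNG seed.
#' @param surface optional tuning surface (see [simulate_observer()]).
#' @return response table (conditions plus `n_trials`, `n_correct`).
#' @export
generate_responses <- function(experiment, n_trials = 200, seed = 1,
                               surface = NULL) {
  if (is.null(surface)) surface <- default_tuning_surface()
  cond <- enumerate_conditions(experiment)
  if (experiment == 2) {
    cond$end_direction_deg[is.na(cond$end_direction_deg)] <- 0
  }
  simulate_observer(surface, cond, n_trials, seed)
}

#' Group-average tuning surface of the detection experiment
#'
#' Amplitude decreases and the preferred end direction shifts clockwise
#' with curvature angle; widths are broad (about 61 degrees, and broader
#' still at 40 degrees where performance approaches chance).
#'
#' @return data frame with `contour_angle_deg`, `A`, `M`, `SD`.
#' @export
default_tuning_surface <- function() {
  data.frame(contour_angle_deg = c(0, 10, 20, 30, 40),
             A = c(0.908, 0.834, 0.773, 0.687, 0.566),
             M = c(0, 8.054, 13.63, 23.618, 2.76),
             SD = c(61, 61, 61, 61, 92))
}
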