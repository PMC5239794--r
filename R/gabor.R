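#' Gabor micro-pattern parameters
#'
#' Parameter bundle for the elementary stimulus unit: a sinusoidal carrier
#' windowed by a circular Gaussian envelope. Defaults reproduce the study
#' stimulus: envelope SD 4 px and carrier period 8 px at a raster scale of
#' 64 px/deg, giving a peak spatial frequency of 8 cycles/deg.
#'
#' @param sigma_px envelope standard deviation in pixels (> 0).
#' @param lambda_px carrier period in pixels (> 0).
#' @param aspect_gamma spatial aspect ratio of the envelope; 1 keeps the
#'   envelope circular.
#' @param phase_psi carrier phase in radians; 0 is even-symmetric and
#'   bright-centered.
#' @param px_per_deg raster scale in pixels per degree of visual angle.
#' @return an object of class `gabor_params`.
#' @examples
#' p <- gabor_params()
#' carrier_frequency_cpd(p)  # 8 cycles/deg
#' @export
gabor_params <- function(sigma_px = 4, lambda_px = 8, aspect_gamma = 1,
                         phase_psi = 0, px_per_deg = 64) {
  if (!is.numeric(sigma_px) || sigma_px <= 0)
    stop("`sigma_px` must be > 0", call. = FALSE)
  if (!is.numeric(lambda_px) || lambda_px <= 0)
    stop("`lambda_px` must be > 0", call. = FALSE)
  if (!is.numeric(px_per_deg) || px_per_deg <= 0)
    stop("`px_per_deg` must be > 0", call. = FALSE)
  structure(list(sigma_px = sigma_px, lambda_px = lambda_px,
                 aspect_gamma = aspect_gamma, phase_psi = phase_psi,
                 px_per_deg = px_per_deg),
            class = "gabor_params")
}

#' Carrier spatial frequency in cycles per degree
#'
#' @param p a [gabor_params()] object.
#' @return carrier frequency in cycles/deg of visual angle.
#' @export
carrier_frequency_cpd <- function(p) {
  stopifnot(inherits(p, "gabor_params"))
  p$px_per_deg / p$lambda_px
}

# Evaluate the Gabor on a pixel grid. `center_offset` shifts the pattern
# center by a subpixel amount (x, y) relative to the patch center, which is
# how field rendering honours non-integer centroids.
gabor_patch <- function(p, orientation_deg, patch_size_px,
                        center_offset = c(0, 0)) {
  half <- (patch_size_px + 1) / 2
  xs <- seq_len(patch_size_px) - half - center_offset[1]
  ys <- seq_len(patch_size_px) - half - center_offset[2]
  th <- orientation_deg * pi / 180
  x <- matrix(rep(xs, each = patch_size_px), patch_size_px, patch_size_px)
  y <- matrix(rep(ys, patch_size_px), patch_size_px, patch_size_px)
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  env <- exp(-(xp^2 + p$aspect_gamma^2 * yp^2) / (2 * p$sigma_px^2))
  env * cos(2 * pi * xp / p$lambda_px + p$phase_psi)
}

#' Render a Gabor micro-pattern
#'
#' Evaluates the product of a circular Gaussian envelope and an oriented
#' sinusoidal carrier on a centered pixel grid rotated by `orientation_deg`:
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`.
#'
#' @param p a [gabor_params()] object.
#' @param orientation_deg carrier orientation in degrees.
#' @param patch_size_px side of the square patch; must be at least
#'   `6 * sigma_px` so the envelope is fully contained.
#' @return numeric `patch_size_px` x `patch_size_px` matrix with values in
#'   `[-1, 1]`.
#' @examples
#' g <- render_gabor(gabor_params(), 0, 33)
#' range(g)
#' @export
render_gabor <- function(p, orientation_deg, patch_size_px) {
  stopifnot(inherits(p, "gabor_params"))
  if (patch_size_px < 6 * p$sigma_px)
    stop("`patch_size_px` must be >= 6 * sigma_px", call. = FALSE)
  gabor_patch(p, orientation_deg, patch_size_px)
}
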