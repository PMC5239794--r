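#' Radial (non-oriented) log-Gabor filter specification
#'
#' The filter amplitude is Gaussian in log frequency,
#' `H(r) = exp(-decay * (log(r / fc) / B0)^2)` (natural logarithms), with
#' zero DC response. With the default decay coefficient 5.77 and bandwidth
#' parameter 1.5, the separation between the two half-amplitude radial
#' frequencies is 1.5 octaves (see [log_gabor_bandwidth_octaves()]).
#'
#' @param fc peak spatial frequency in cycles/pixel (0 < fc <= 0.5).
#' @param B0 bandwidth parameter.
#' @param decay positive decay coefficient of the log-frequency Gaussian.
#' @return an object of class `radial_log_gabor_spec`.
#' @export
radial_log_gabor_spec <- function(fc = 0.1, B0 = 1.5, decay = 5.77) {
  if (fc <= 0 || fc > 0.5) stop("`fc` must be in (0, 0.5]", call. = FALSE)
  if (B0 <= 0 || decay <= 0) stop("`B0` and `decay` must be > 0", call. = FALSE)
  structure(list(fc = fc, B0 = B0, decay = decay),
            class = "radial_log_gabor_spec")
}

#' Radial log-Gabor amplitude at given frequencies
#'
#' @param spec a [radial_log_gabor_spec()].
#' @param r radial frequency in cycles/pixel (vector).
#' @return amplitude values; 0 at `r = 0`, 1 at `r = fc`.
#' @export
radial_log_gabor_amplitude <- function(spec, r) {
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- exp(-spec$decay * (log(r[pos] / spec$fc) / spec$B0)^2)
  out
}

#' Half-amplitude bandwidth of the radial log-Gabor, in octaves
#'
#' Locates, by numeric root finding, the two radial frequencies at which the
#' amplitude falls to one half of its peak, and returns `log2` of their
#' ratio. The closed form is `2 * B0 * sqrt(ln 2 / decay) / ln 2` octaves;
#' the default parameters give 1.5 octaves to within 1e-3.
#'
#' @param spec a [radial_log_gabor_spec()].
#' @return bandwidth in octaves.
#' @examples
#' log_gabor_bandwidth_octaves(radial_log_gabor_spec())
#' @export
log_gabor_bandwidth_octaves <- function(spec) {
  f <- function(r) radial_log_gabor_amplitude(spec, r) - 0.5
  lo <- stats::uniroot(f, c(spec$fc * 1e-4, spec$fc), tol = 1e-14)$root
  hi <- stats::uniroot(f, c(spec$fc, spec$fc * 1e4), tol = 1e-14)$root
  log2(hi / lo)
}

# FFT frequency coordinates (cycles/sample) for an n-point dimension.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# Frequency-domain radial grid for an nr x nc image (cycles/pixel).
freq_grid <- function(nr, nc) {
  fy <- fft_freq(nr)
  fx <- fft_freq(nc)
  list(fx = matrix(rep(fx, each = nr), nr, nc),
       fy = matrix(rep(fy, nc), nr, nc))
}

#' Filter an image with the radial log-Gabor
#'
#' Multiplies the image spectrum by the radial log-Gabor amplitude (zero at
#' DC) and inverts. The result is a band-pass image whose zero crossings
#' mark candidate edge loci.
#'
#' @param image numeric matrix (prepared grayscale image).
#' @param spec a [radial_log_gabor_spec()].
#' @return filtered matrix of the same dimensions (real-valued).
#' @export
radial_log_gabor_filter <- function(image, spec = radial_log_gabor_spec()) {
  stopifnot(is.matrix(image))
  g <- freq_grid(nrow(image), ncol(image))
  r <- sqrt(g$fx^2 + g$fy^2)
  H <- radial_log_gabor_amplitude(spec, r)
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / length(image)
}

#' Oriented log-Gabor filter bank specification
#'
#' Polar-separable log-Gabor: the radial term of
#' [radial_log_gabor_spec()] times an angular Gaussian of full width at half
#' amplitude `orientation_bandwidth_deg`, supported on a single half-plane
#' of the spectrum so that the even (cosine-phase) and odd (sine-phase)
#' responses form a quadrature pair.
#'
#' @param fc peak frequency, cycles/pixel.
#' @param B0,decay radial bandwidth parameters as in
#'   [radial_log_gabor_spec()].
#' @param orientation_bandwidth_deg angular full width at half amplitude
#'   (degrees).
#' @param orientations_deg filter orientations; orientation energy is
#'   180-degree periodic so `0, 10, ..., 170` covers the full circle.
#' @return an object of class `oriented_log_gabor_spec`.
#' @export
oriented_log_gabor_spec <- function(fc = 0.1, B0 = 1.5, decay = 5.77,
                                    orientation_bandwidth_deg = 40,
                                    orientations_deg = seq(0, 170, by = 10)) {
  structure(list(fc = fc, B0 = B0, decay = decay,
                 orientation_bandwidth_deg = orientation_bandwidth_deg,
                 orientations_deg = orientations_deg),
            class = "oriented_log_gabor_spec")
}

# Complex quadrature response of the oriented log-Gabor at one orientation.
# `orientation_deg` is the EDGE orientation the filter is tuned to; its
# spectral energy lies along the perpendicular direction. Returns a complex
# matrix whose real part is the even-phase and imaginary part the odd-phase
# response.
oriented_log_gabor_response <- function(image, spec, orientation_deg,
                                        F_img = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  g <- freq_grid(nr, nc)
  r <- sqrt(g$fx^2 + g$fy^2)
  radial <- radial_log_gabor_amplitude(
    radial_log_gabor_spec(spec$fc, spec$B0, spec$decay), r)
  normal <- (orientation_deg + 90) * pi / 180   # frequency direction
  ang <- atan2(g$fy, g$fx)
  d <- atan2(sin(ang - normal), cos(ang - normal))  # (-pi, pi]
  sigma_th <- (spec$orientation_bandwidth_deg / 2) * pi / 180 / sqrt(2 * log(2))
  angular <- exp(-d^2 / (2 * sigma_th^2))
  # single-sided support makes the inverse transform a quadrature pair
  angular[abs(d) > pi / 2] <- 0
  H <- radial * angular
  if (is.null(F_img)) F_img <- stats::fft(image)
  stats::fft(F_img * H, inverse = TRUE) / length(image)
}

#' Orientation energy profiles at candidate pixels
#'
#' Filters the image with the oriented log-Gabor bank in quadrature (even
#' and odd phase); per orientation, the squared responses are summed into
#' orientation energy. Each candidate pixel keeps its energy profile across
#' orientations, normalized to sum to one. Candidates whose peak energy is
#' below `threshold_frac` of the strongest response among candidates are
#' discarded. The edge orientation is the bank orientation of the profile
#' peak refined by parabolic interpolation of log energy over the peak and
#' its two (circular) neighbours.
#'
#' @param image prepared grayscale matrix.
#' @param candidates data frame with integer `row`, `col` of candidate
#'   pixels (from [zero_crossings()]).
#' @param spec an [oriented_log_gabor_spec()].
#' @param threshold_frac significance threshold as a fraction of the
#'   maximum candidate response (default 0.1).
#' @param profiles logical; attach the normalized energy-profile matrix as
#'   attribute `"energy_profiles"`.
#' @return data frame of edge elements: `x`, `y` (pixel coordinates,
#'   `x` = column, `y` = row), `orientation_deg` in `[0, 180)`,
#'   `peak_energy` (raw), `peak_energy_norm` (peak of the normalized
#'   profile). Empty if all candidates are rejected.
#' @export
orientation_energy <- function(image, candidates,
                               spec = oriented_log_gabor_spec(),
                               threshold_frac = 0.1, profiles = FALSE) {
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      orientation_deg = numeric(0),
                      peak_energy = numeric(0),
                      peak_energy_norm = numeric(0))
  if (nrow(candidates) == 0) return(empty)
  oris <- spec$orientations_deg
  idx <- (candidates$col - 1L) * nrow(image) + candidates$row
  F_img <- stats::fft(image)
  E <- matrix(0, nrow(candidates), length(oris))
  for (k in seq_along(oris)) {
    resp <- oriented_log_gabor_response(image, spec, oris[k], F_img)
    E[, k] <- Mod(resp[idx])^2
  }
  peak <- apply(E, 1, max)
  keep <- peak >= threshold_frac * max(peak)
  if (!any(keep)) return(empty)
  E <- E[keep, , drop = FALSE]
  peak <- peak[keep]
  cand <- candidates[keep, , drop = FALSE]
  tot <- rowSums(E)
  En <- E / tot
  step <- if (length(oris) > 1) diff(oris[1:2]) else 180
  ori_est <- numeric(nrow(En))
  for (i in seq_len(nrow(En))) {
    k <- which.max(En[i, ])
    m <- length(oris)
    l <- if (k == 1) m else k - 1
    r <- if (k == m) 1 else k + 1
    lv <- log(En[i, l] + 1e-300)
    cv <- log(En[i, k] + 1e-300)
    rv <- log(En[i, r] + 1e-300)
    denom <- lv - 2 * cv + rv
    off <- if (denom < 0) 0.5 * (lv - rv) / denom else 0
    off <- clamp(off, -0.5, 0.5)
    ori_est[i] <- (oris[k] + off * step) %% 180
  }
  out <- data.frame(x = cand$col, y = cand$row,
                    orientation_deg = ori_est,
                    peak_energy = peak,
                    peak_energy_norm = apply(En, 1, max))
  if (profiles) attr(out, "energy_profiles") <- En
  out
}
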