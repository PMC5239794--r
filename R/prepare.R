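#' Read a raster image as a grayscale matrix
#'
#' Reads PNG (always) or TIFF (if the `tiff` package is installed) into a
#' numeric matrix in `[0, 1]`, converting RGB(A) to luminance with Rec. 601
#' weights.
#'
#' @param path image file path.
#' @return numeric matrix, rows top to bottom.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  to_grayscale(arr)
}

# RGB(A) array or matrix -> luminance matrix
to_grayscale <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    if (ch >= 3)
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    return(arr[, , 1])
  }
  stop("unsupported image array", call. = FALSE)
}

#' Prepare an image for contour analysis
#'
#' Converts to grayscale, optionally applies a luminance linearization hook,
#' center-crops to the aperture bounding square, and windows the result with
#' a circular aperture (default diameter 480 px). Pixels outside the
#' aperture are set to the mean luminance inside it, so the aperture border
#' itself introduces no spurious contrast edge.
#'
#' @param image numeric matrix or 3-channel array, values in `[0, 1]`.
#' @param aperture_px aperture diameter in pixels.
#' @param analysis_radius_px radius (from the aperture center) within which
#'   downstream stages consider edge elements.
#' @param linearize optional function applied to the grayscale matrix before
#'   windowing (e.g. an exposure-based luminance correction); `NULL` to skip.
#' @return an object of class `prepared_image`: list with `image`
#'   (aperture-sized matrix), `mask` (logical matrix, `TRUE` inside the
#'   aperture), `center` (row, col), `analysis_radius_px`.
#' @export
prepare_image <- function(image, aperture_px = 480,
                          analysis_radius_px = 216, linearize = NULL) {
  img <- to_grayscale(image)
  if (nrow(img) < aperture_px || ncol(img) < aperture_px)
    stop("image must be at least ", aperture_px, " px in both dimensions",
         call. = FALSE)
  if (!is.null(linearize)) img <- linearize(img)
  r0 <- (nrow(img) - aperture_px) %/% 2
  c0 <- (ncol(img) - aperture_px) %/% 2
  img <- img[r0 + seq_len(aperture_px), c0 + seq_len(aperture_px)]
  ctr <- (aperture_px + 1) / 2
  row <- matrix(rep(seq_len(aperture_px), aperture_px), aperture_px)
  col <- matrix(rep(seq_len(aperture_px), each = aperture_px), aperture_px)
  mask <- (row - ctr)^2 + (col - ctr)^2 <= (aperture_px / 2)^2
  bg <- mean(img[mask])
  img[!mask] <- bg
  structure(list(image = img, mask = mask, center = c(ctr, ctr),
                 analysis_radius_px = analysis_radius_px),
            class = "prepared_image")
}

#' @export
print.prepared_image <- function(x, ...) {
  cat("<prepared_image> ", nrow(x$image), "x", ncol(x$image),
      " px, analysis radius ", x$analysis_radius_px, " px\n", sep = "")
  invisible(x)
}

#' Zero crossings of a band-pass filtered image
#'
#' A pixel is a crossing candidate when the filtered value changes sign
#' against a 4-neighbour and the pixel is the one of the pair closer to
#' zero, yielding a one-pixel-wide crossing line. Only pixels within
#' `radius` of the image center are returned. Sign flips whose magnitudes
#' fall below `eps` are ignored, so numerically flat regions (e.g. a
#' constant image, whose band-pass response is pure floating-point
#' residue) produce no candidates.
#'
#' @param filtered real matrix (output of [radial_log_gabor_filter()]).
#' @param radius analysis radius in pixels from the image center.
#' @param center optional (row, col) center; defaults to the matrix center.
#' @param eps magnitude floor for a sign change to count.
#' @return data frame with integer columns `row`, `col`.
#' @export
zero_crossings <- function(filtered, radius = 216, center = NULL,
                           eps = 1e-10) {
  stopifnot(is.matrix(filtered))
  nr <- nrow(filtered); nc <- ncol(filtered)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  cross <- matrix(FALSE, nr, nc)
  a <- filtered[, -nc]; b <- filtered[, -1]
  h <- a * b < 0 & pmax(abs(a), abs(b)) > eps
  left_closer <- abs(a) <= abs(b)
  cross[, -nc] <- cross[, -nc] | (h & left_closer)
  cross[, -1] <- cross[, -1] | (h & !left_closer)
  a <- filtered[-nr, ]; b <- filtered[-1, ]
  v <- a * b < 0 & pmax(abs(a), abs(b)) > eps
  top_closer <- abs(a) <= abs(b)
  cross[-nr, ] <- cross[-nr, ] | (v & top_closer)
  cross[-1, ] <- cross[-1, ] | (v & !top_closer)
  idx <- which(cross, arr.ind = TRUE)
  keep <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 <= radius^2
  data.frame(row = as.integer(idx[keep, 1]), col = as.integer(idx[keep, 2]))
}

#' Extract oriented edge elements from a prepared image
#'
#' Convenience wrapper running the full edge-extraction chain: radial
#' log-Gabor filtering, zero-crossing detection within the analysis radius,
#' orientation-energy analysis with the significance threshold, and a
#' thinning pass that removes a crossing pixel when an 8-neighbour with
#' orientation within `thin_tol_deg` has higher peak energy (suppressing
#' duplicate responses across the crossing line).
#'
#' @param prepared a [prepare_image()] result (or a plain matrix, windowed
#'   as-is).
#' @param radial_spec a [radial_log_gabor_spec()].
#' @param oriented_spec an [oriented_log_gabor_spec()].
#' @param threshold_frac orientation-energy significance threshold.
#' @param thin logical; apply the thinning pass.
#' @param thin_tol_deg orientation agreement for thinning, degrees.
#' @param thin_radius_px suppression radius; defaults to roughly half the
#'   filter's carrier wavelength (`0.6 / fc`), within which same-orientation
#'   crossings are responses to the same underlying edge (the band-pass
#'   response to one edge rings, putting secondary crossing lines about half
#'   a wavelength to either side).
#' @return edge table as from [orientation_energy()].
#' @export
extract_edges <- function(prepared,
                          radial_spec = radial_log_gabor_spec(),
                          oriented_spec = oriented_log_gabor_spec(),
                          threshold_frac = 0.1, thin = TRUE,
                          thin_tol_deg = 5,
                          thin_radius_px = 0.6 / radial_spec$fc) {
  if (inherits(prepared, "prepared_image")) {
    img <- prepared$image
    radius <- prepared$analysis_radius_px
    center <- prepared$center
  } else {
    img <- prepared
    radius <- min(dim(img)) / 2
    center <- NULL
  }
  filt <- radial_log_gabor_filter(img, radial_spec)
  cand <- zero_crossings(filt, radius = radius, center = center)
  edges <- orientation_energy(img, cand, oriented_spec,
                              threshold_frac = threshold_frac)
  if (thin && nrow(edges) > 1)
    edges <- thin_edges(edges, tol_deg = thin_tol_deg,
                        radius_px = thin_radius_px)
  edges
}

# Non-maximum suppression among crossing pixels: greedily keep the
# strongest remaining candidate and drop weaker candidates within
# `radius_px` whose orientation agrees within `tol_deg`. Ties in energy are
# broken by row-major position so the result is deterministic.
thin_edges <- function(edges, tol_deg = 5, radius_px = 6) {
  n <- nrow(edges)
  ord <- order(-edges$peak_energy, edges$y, edges$x)
  e <- edges[ord, ]
  alive <- rep(TRUE, n)
  keep <- logical(n)
  r2 <- radius_px^2
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    d2 <- (e$x - e$x[i])^2 + (e$y - e$y[i])^2
    sup <- alive & d2 <= r2 &
      abs(wrap90(e$orientation_deg - e$orientation_deg[i])) <= tol_deg
    sup[i] <- FALSE
    alive[sup] <- FALSE
  }
  out <- e[keep, , drop = FALSE]
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}
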