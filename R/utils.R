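#' Wrap angles to a half-open interval
#'
#' `wrap180()` maps angles to `(-180, 180]` (directions);
#' `wrap90()` maps mod-180 axial differences to `(-90, 90]`.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles.
#' @keywords internal
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' @rdname wrap180
#' @keywords internal
wrap90 <- function(x) {
  w <- x %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Rotate an image about its center
#'
#' Bilinear inverse-mapped rotation. Pixels sampled from outside the source
#' are set to `fill`. Used for equivariance checks of the orientation
#' analysis; positive angles rotate image content from the +x axis toward the
#' +y (downward row) axis.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param fill value for out-of-bounds samples (default: mean of `img`).
#' @return rotated matrix of the same dimensions.
#' @export
rotate_image <- function(img, angle_deg, fill = mean(img)) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), nc), nr, nc)
  dx <- col - cx; dy <- row - cy
  # inverse map: source coords of each destination pixel
  sx <- co * dx + si * dy + cx
  sy <- -si * dx + co * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- matrix(fill, nr, nc)
  ok <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  idx <- function(r, c) (c - 1L) * nr + r
  v00 <- img[idx(y0[ok], x0[ok])]
  v01 <- img[idx(y0[ok], x0[ok] + 1L)]
  v10 <- img[idx(y0[ok] + 1L, x0[ok])]
  v11 <- img[idx(y0[ok] + 1L, x0[ok] + 1L)]
  out[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) + v01 * fx[ok] * (1 - fy[ok]) +
    v10 * (1 - fx[ok]) * fy[ok] + v11 * fx[ok] * fy[ok]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
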