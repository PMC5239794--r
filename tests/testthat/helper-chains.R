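# Geometric fixtures and an independent exhaustive oracle for the contour
# mapper. Everything here is deliberately written from scratch (plain
# trigonometry, brute-force enumeration) so it can serve as an independent
# check on the package's greedy search.

# wrap an axial angle difference into (-90, 90]
.ww <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

# Cocircular chain of edge elements: orientations step by `step`, each
# displacement direction bisects the adjacent orientations.
make_chain <- function(step, spacing, n = 4, x0 = 0, y0 = 0, heading = 0) {
  o <- heading + step * (0:(n - 1))
  x <- y <- numeric(n)
  x[1] <- x0; y[1] <- y0
  for (i in seq_len(n - 1)) {
    dir <- (o[i] + step / 2) * pi / 180
    x[i + 1] <- x[i] + spacing * cos(dir)
    y[i + 1] <- y[i] + spacing * sin(dir)
  }
  data.frame(x = x, y = y, orientation_deg = o %% 180)
}

# Random edge field: a planted chain plus distractor edges kept at least
# `clearance` away from every planted element so no mixed chain can form.
random_field <- function(seed, n_distractors = 20, step = 20, spacing = 10,
                         clearance = 1.3 * spacing, planted = TRUE) {
  set.seed(seed)
  chain <- if (planted)
    make_chain(step, spacing, 4,
               x0 = runif(1, 30, 60), y0 = runif(1, 30, 60),
               heading = runif(1, 0, 180))
  else
    data.frame(x = numeric(0), y = numeric(0), orientation_deg = numeric(0))
  d <- list()
  while (length(d) < n_distractors) {
    p <- c(runif(1, 0, 100), runif(1, 0, 100))
    if (planted &&
        min(sqrt((chain$x - p[1])^2 + (chain$y - p[2])^2)) < clearance)
      next
    d[[length(d) + 1L]] <- data.frame(x = p[1], y = p[2],
                                      orientation_deg = runif(1, 0, 180))
  }
  field <- rbind(chain, do.call(rbind, d))
  rownames(field) <- NULL
  list(edges = field, chain = chain)
}

# The four mapping criteria, re-implemented directly for an ordered
# 4-tuple of row indices into `e`.
oracle_quad_valid <- function(e, idx, tol = 5) {
  x <- e$x[idx]; y <- e$y[idx]; o <- e$orientation_deg[idx]
  dx <- diff(x); dy <- diff(y)
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0)) return(FALSE)
  # equal spacing within one fifth, pairwise
  for (i in 1:2)
    if (abs(d[i + 1] - d[i]) > mean(d[i + (0:1)]) / 5) return(FALSE)
  # forward motion
  for (i in 1:2)
    if (dx[i] * dx[i + 1] + dy[i] * dy[i + 1] <= 0) return(FALSE)
  dir <- atan2(dy, dx) * 180 / pi
  phi <- .ww(dir - o[1:3])
  theta <- .ww(o[2:4] - o[1:3])
  if (any(abs(.ww(theta - 2 * phi)) > tol)) return(FALSE)
  if (any(abs(theta[2:3] - theta[1]) > tol)) return(FALSE)
  TRUE
}

# Exhaustive search over ordered 4-tuples, pruned through continuous
# pairs. Returns a list of index vectors (each also valid reversed; only
# one direction is stored, the one whose first index is smaller).
oracle_find_all <- function(e, tol = 5, d_max = 50.4) {
  n <- nrow(e)
  pairs <- list()
  for (i in seq_len(n)) {
    dx <- e$x - e$x[i]; dy <- e$y - e$y[i]
    d <- sqrt(dx^2 + dy^2)
    dir <- atan2(dy, dx) * 180 / pi
    phi <- .ww(dir - e$orientation_deg[i])
    theta <- .ww(e$orientation_deg - e$orientation_deg[i])
    ok <- which(d > 0 & d <= d_max & abs(.ww(theta - 2 * phi)) <= tol)
    pairs[[i]] <- ok
  }
  quads <- list()
  for (a in seq_len(n)) for (b in pairs[[a]]) {
    for (cc in pairs[[b]]) {
      if (cc == a) next
      for (dd in pairs[[cc]]) {
        if (dd == a || dd == b) next
        idx <- c(a, b, cc, dd)
        if (idx[1] > idx[4]) next  # store one direction only
        if (oracle_quad_valid(e, idx, tol)) quads[[length(quads) + 1L]] <- idx
      }
    }
  }
  quads
}

# Distance from a point to a polyline through the planted elements,
# extended by `ext` beyond each end along the local travel direction.
polyline_distance <- function(px, py, xs, ys, ext = 0) {
  if (ext > 0) {
    n <- length(xs)
    d1 <- atan2(ys[2] - ys[1], xs[2] - xs[1])
    dn <- atan2(ys[n] - ys[n - 1], xs[n] - xs[n - 1])
    xs <- c(xs[1] - ext * cos(d1), xs, xs[n] + ext * cos(dn))
    ys <- c(ys[1] - ext * sin(d1), ys, ys[n] + ext * sin(dn))
  }
  best <- Inf
  for (i in seq_len(length(xs) - 1)) {
    vx <- xs[i + 1] - xs[i]; vy <- ys[i + 1] - ys[i]
    t <- ((px - xs[i]) * vx + (py - ys[i]) * vy) / (vx^2 + vy^2)
    t <- min(1, max(0, t))
    best <- min(best, sqrt((xs[i] + t * vx - px)^2 + (ys[i] + t * vy - py)^2))
  }
  best
}

# Did the mapper recover a planted chain? A mapped contour counts as a
# recovery when its spacing is within one fifth of the planted spacing,
# its absolute step is within `step_tol` of the planted step, and every
# member lies within `dist_tol` of the planted curve.
chain_recovered <- function(contours, truth, step_tol = 5, dist_tol = 3) {
  mem <- attr(contours, "members")
  spc <- truth$spacing_px[1]
  step <- abs(truth$step_deg[1])
  for (id in contours$contour_id) {
    row <- contours[contours$contour_id == id, ]
    if (abs(row$spacing_px - spc) > spc / 5) next
    if (abs(abs(row$step_deg) - step) > step_tol) next
    m <- mem[mem$contour_id == id, ]
    dmax <- max(vapply(seq_len(nrow(m)), function(i)
      polyline_distance(m$x[i], m$y[i], truth$x, truth$y,
                        ext = 0.75 * spc), numeric(1)))
    if (dmax <= dist_tol) return(TRUE)
  }
  FALSE
}
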