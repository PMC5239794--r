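#' Geometry of an ordered edge pair
#'
#' For edge elements A and B, computes the center distance `d`, the
#' direction of B relative to A's orientation (`phi`) and the orientation
#' difference B - A (`theta`). Orientations are axial (180-degree periodic),
#' so both angles are wrapped to `(-90, 90]`; with that convention swapping
#' A and B negates `phi` and `theta` and leaves `d` unchanged.
#'
#' @param a,b single-row data frames (or lists) with `x`, `y`,
#'   `orientation_deg`.
#' @return list with `d`, `phi`, `theta` (degrees).
#' @examples
#' a <- list(x = 0, y = 0, orientation_deg = 0)
#' b <- list(x = 10, y = 0, orientation_deg = 0)
#' pair_geometry(a, b)  # collinear: phi = 0, theta = 0
#' @export
pair_geometry <- function(a, b) {
  g <- pair_geometry_vec(a$x, a$y, a$orientation_deg,
                         b$x, b$y, b$orientation_deg)
  if (any(g$d == 0)) stop("coincident element positions", call. = FALSE)
  list(d = g$d, phi = g$phi, theta = g$theta)
}

# Vectorized pair geometry from one reference element to many others.
pair_geometry_vec <- function(x0, y0, o0, x, y, o) {
  dx <- x - x0; dy <- y - y0
  d <- sqrt(dx^2 + dy^2)
  dir <- atan2(dy, dx) * 180 / pi
  list(d = d, phi = wrap90(dir - o0), theta = wrap90(o - o0),
       dir = dir)
}

#' Continuity test for an edge pair
#'
#' An ordered pair is continuous when its centers are equidistant from the
#' intersection of the lines through the two elements, which by the
#' exterior-angle relation requires the orientation difference to be twice
#' the relative direction: `|theta - 2 phi| <= tol_deg` (wrapped to the
#' axial range).
#'
#' @param g pair geometry from [pair_geometry()].
#' @param tol_deg angular tolerance in degrees (default 5).
#' @return logical.
#' @export
is_continuous <- function(g, tol_deg = 5) {
  abs(wrap90(g$theta - 2 * g$phi)) <= tol_deg
}

# The four mapping criteria applied to an ordered chain of edge rows
# (data frame with x, y, orientation_deg). Returns TRUE when the chain is a
# valid constant-curvature contour fragment:
#   1. exactly `n` members (checked by the caller);
#   2. every consecutive pair continuous (theta = 2 phi within tol);
#   3. consecutive spacings equal within +/- one fifth;
#   4. constant signed orientation step within +/- tol;
# plus forward motion (consecutive displacements within 90 degrees), which
# rules out chains that double back on themselves.
chain_valid <- function(chain, tol_deg = 5) {
  n <- nrow(chain)
  if (n < 2) return(FALSE)
  dx <- diff(chain$x); dy <- diff(chain$y)
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0)) return(FALSE)
  if (n > 2) {
    if (any(abs(diff(d)) > (d[-1] + d[-(n - 1)]) / 2 / 5)) return(FALSE)
    if (any(dx[-1] * dx[-(n - 1)] + dy[-1] * dy[-(n - 1)] <= 0)) return(FALSE)
  }
  dir <- atan2(dy, dx) * 180 / pi
  o <- chain$orientation_deg
  phi <- wrap90(dir - o[-n])
  theta <- wrap90(diff(o))
  if (any(abs(wrap90(theta - 2 * phi)) > tol_deg)) return(FALSE)
  if (n > 2 && any(abs(theta[-1] - theta[1]) > tol_deg)) return(FALSE)
  TRUE
}

chain_summary <- function(chain) {
  dx <- diff(chain$x); dy <- diff(chain$y)
  d <- sqrt(dx^2 + dy^2)
  theta <- wrap90(diff(chain$orientation_deg))
  list(spacing_px = mean(d), step_deg = mean(theta))
}

#' Map four-element constant-curvature contours among edge elements
#'
#' Greedy, unguided search, scanned coarse to fine over candidate spacings:
#' the outer loop runs from the largest candidate spacing down to the
#' smallest, and within each spacing edges are seeded in row-major order
#' (by `y`, then `x`), so large-scale contours are mapped everywhere before
#' any small-scale contour can claim their members. At each seed a chain is
#' grown on both sides by repeatedly attaching the edge that best satisfies
#' continuity (smallest `|theta - 2 phi|`, ties broken by smaller
#' distance), subject to the four mapping criteria: four members, pairwise
#' continuity, equal spacing within one fifth, and a constant signed
#' orientation step within `tol_deg`. An accepted contour is marked and its
#' members are removed from further seeding and growth.
#'
#' Member order is canonical: the endpoint with the smaller `y` (then
#' smaller `x`) comes first, which fixes the sign of `step_deg`.
#'
#' @param edges data frame with columns `x`, `y`, `orientation_deg`.
#' @param spacing_range_px integer candidate spacings to scan (default
#'   1 to 42 px).
#' @param tol_deg continuity and step tolerance in degrees.
#' @param mark_members if `TRUE` (default), members of accepted contours
#'   are removed both as seeds and as growth candidates; if `FALSE`, only
#'   as seeds.
#' @return an object of class `mapped_contours`: data frame with one row
#'   per contour (`contour_id`, `step_deg`, `spacing_px`, `length_bin`) and
#'   the member table as attribute `"members"` (columns `contour_id`,
#'   `position`, `x`, `y`, `orientation_deg`).
#' @export
find_contours <- function(edges, spacing_range_px = 1:42, tol_deg = 5,
                          mark_members = TRUE) {
  n <- nrow(edges)
  contours <- list()
  members <- list()
  if (n >= 4) {
    e <- edges[order(edges$y, edges$x), , drop = FALSE]
    rownames(e) <- NULL
    marked <- logical(n)
    spacings <- sort(unique(spacing_range_px), decreasing = TRUE)
    id <- 0L
    for (d0 in spacings) {
      for (s in seq_len(n)) {
        if (marked[s]) next
        avail <- if (mark_members) !marked else rep(TRUE, n)
        avail[s] <- FALSE
        if (sum(avail) < 3) next
        dist_s <- sqrt((e$x - e$x[s])^2 + (e$y - e$y[s])^2)
        cand <- which(avail & abs(dist_s - d0) <= d0 / 5)
        if (length(cand) == 0) next
        chain_idx <- grow_chain(e, s, cand, d0, avail, tol_deg)
        if (is.null(chain_idx)) next
        chain <- e[chain_idx, , drop = FALSE]
        if (!chain_valid(chain, tol_deg)) next
        # canonical order: head endpoint first in row-major order
        k <- nrow(chain)
        if (chain$y[1] > chain$y[k] ||
            (chain$y[1] == chain$y[k] && chain$x[1] > chain$x[k])) {
          chain_idx <- rev(chain_idx)
          chain <- chain[k:1, , drop = FALSE]
        }
        id <- id + 1L
        cs <- chain_summary(chain)
        contours[[id]] <- data.frame(contour_id = id,
                                     step_deg = cs$step_deg,
                                     spacing_px = cs$spacing_px)
        members[[id]] <- data.frame(contour_id = id, position = seq_len(k),
                                    x = chain$x, y = chain$y,
                                    orientation_deg = chain$orientation_deg)
        marked[chain_idx] <- TRUE
      }
    }
  }
  out <- if (length(contours)) do.call(rbind, contours) else
    data.frame(contour_id = integer(0), step_deg = numeric(0),
               spacing_px = numeric(0))
  out$length_bin <- length_bin(out$spacing_px)
  mem <- if (length(members)) do.call(rbind, members) else
    data.frame(contour_id = integer(0), position = integer(0),
               x = numeric(0), y = numeric(0), orientation_deg = numeric(0))
  attr(out, "members") <- mem
  class(out) <- c("mapped_contours", "data.frame")
  out
}

# Grow a chain of 4 around seed `s`, restricted to spacing window `d0`.
# Returns indices into `e` in path order, or NULL.
grow_chain <- function(e, s, cand, d0, avail, tol_deg) {
  # first partner: best continuity among the spacing window
  g <- pair_geometry_vec(e$x[s], e$y[s], e$orientation_deg[s],
                         e$x[cand], e$y[cand], e$orientation_deg[cand])
  dev <- abs(wrap90(g$theta - 2 * g$phi))
  ok <- which(dev <= tol_deg)
  if (length(ok) == 0) return(NULL)
  ord <- ok[order(dev[ok], g$d[ok])]
  for (first in ord) {
    b <- cand[first]
    chain <- c(s, b)
    spacing <- g$d[first]
    step <- g$theta[first]
    repeat {
      if (length(chain) == 4) return(chain)
      ext <- extend_chain(e, chain, spacing, step, avail, tol_deg,
                          tail = TRUE)
      if (is.null(ext))
        ext <- extend_chain(e, chain, spacing, step, avail, tol_deg,
                            tail = FALSE)
      if (is.null(ext)) break
      chain <- ext$chain
      spacing <- ext$spacing
    }
  }
  NULL
}

# One growth step at the tail (or head) of a chain. Returns NULL or an
# updated chain/spacing.
extend_chain <- function(e, chain, spacing, step, avail, tol_deg, tail) {
  idx <- if (tail) chain[length(chain)] else chain[1]
  prev <- if (tail) chain[length(chain) - 1] else chain[2]
  want_step <- if (tail) step else -step
  pool <- which(avail)
  pool <- setdiff(pool, chain)
  if (length(pool) == 0) return(NULL)
  dx <- e$x[pool] - e$x[idx]; dy <- e$y[pool] - e$y[idx]
  d <- sqrt(dx^2 + dy^2)
  win <- abs(d - spacing) <= spacing / 5
  if (!any(win)) return(NULL)
  pool <- pool[win]; dx <- dx[win]; dy <- dy[win]; d <- d[win]
  # forward motion: away from the rest of the chain
  fx <- e$x[idx] - e$x[prev]; fy <- e$y[idx] - e$y[prev]
  fwd <- dx * fx + dy * fy > 0
  if (!any(fwd)) return(NULL)
  pool <- pool[fwd]; dx <- dx[fwd]; dy <- dy[fwd]; d <- d[fwd]
  g <- pair_geometry_vec(e$x[idx], e$y[idx], e$orientation_deg[idx],
                         e$x[pool], e$y[pool], e$orientation_deg[pool])
  dev <- abs(wrap90(g$theta - 2 * g$phi))
  ok <- dev <= tol_deg & abs(g$theta - want_step) <= tol_deg
  if (!any(ok)) return(NULL)
  pick <- which(ok)[order(dev[ok], d[ok])][1]
  new_chain <- if (tail) c(chain, pool[pick]) else c(pool[pick], chain)
  k <- length(chain)
  new_spacing <- (spacing * (k - 1) + d[pick]) / k
  list(chain = new_chain, spacing = new_spacing)
}

#' Assign contour spacings to the study's length bins
#'
#' Bins by inter-element spacing rounded to the nearest pixel:
#' 1-8, 9-17, 18-24, 25-33, 34-42 px. Spacings outside 1-42 px map to
#' `"unbinned"`.
#'
#' @param spacing_px numeric vector of spacings.
#' @return factor of bin labels.
#' @export
length_bin <- function(spacing_px) {
  labs <- c("1-8", "9-17", "18-24", "25-33", "34-42")
  r <- round(spacing_px)
  out <- rep(NA_character_, length(r))
  out[r >= 1 & r <= 8] <- labs[1]
  out[r >= 9 & r <= 17] <- labs[2]
  out[r >= 18 & r <= 24] <- labs[3]
  out[r >= 25 & r <= 33] <- labs[4]
  out[r >= 34 & r <= 42] <- labs[5]
  out[is.na(out)] <- "unbinned"
  factor(out, levels = c(labs, "unbinned"))
}

#' Tabulate contour counts per (curvature class, length bin)
#'
#' Curvature classes are the absolute orientation step rounded to the
#' nearest 10 degrees (0, 10, ..., 40; larger steps are kept under their
#' own class).
#'
#' @param contours a `mapped_contours` object (or compatible data frame
#'   with `step_deg`, `spacing_px`).
#' @return data frame of counts per `curvature_class_deg` and `length_bin`.
#' @export
bin_contours <- function(contours) {
  if (nrow(contours) == 0) {
    g <- expand.grid(curvature_class_deg = seq(0, 40, 10),
                     length_bin = levels(length_bin(numeric(0))))
    g$n <- 0L
    return(g)
  }
  cls <- curvature_class(contours$step_deg)
  lb <- length_bin(contours$spacing_px)
  tab <- as.data.frame(table(curvature_class_deg = cls, length_bin = lb),
                       responseName = "n")
  tab$curvature_class_deg <- as.numeric(as.character(tab$curvature_class_deg))
  tab
}

curvature_class <- function(step_deg) {
  factor(round(abs(step_deg) / 10) * 10, levels = seq(0, 90, 10))
}

#' Record end elements of a mapped contour
#'
#' At each end of the contour, searches the edge table for elements at the
#' contour's spacing (within one fifth) whose pairing with the terminal
#' member is continuous and whose direction from the terminal member lies
#' within (-90, 90) degrees of the outward continuation (i.e. not doubling
#' back over the contour). The recorded orientation is relative to the
#' contour's curvature direction: positive values continue the curvature.
#' For a straight contour (step within `tol_deg` of 0) the raw signed
#' orientation difference is reported.
#'
#' @param contour one row of a `mapped_contours` result (with its members
#'   taken from the attribute), or the whole object (then all contours are
#'   processed).
#' @param edges the full edge table the contour was mapped from.
#' @param tol_deg continuity tolerance.
#' @return data frame with `contour_id`, `end` (`"head"`/`"tail"`),
#'   `orientation_rel_deg`, `x`, `y` of each qualifying end element.
#' @export
extract_end_elements <- function(contour, edges, tol_deg = 5) {
  members <- attr(contour, "members")
  if (is.null(members))
    stop("`contour` must carry a \"members\" attribute from find_contours()",
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(contour))) {
    cid <- contour$contour_id[i]
    mem <- members[members$contour_id == cid, ]
    mem <- mem[order(mem$position), ]
    k <- nrow(mem)
    step <- contour$step_deg[i]
    spacing <- contour$spacing_px[i]
    for (end in c("head", "tail")) {
      t_i <- if (end == "tail") k else 1L
      p_i <- if (end == "tail") k - 1L else 2L
      trav_step <- if (end == "tail") step else -step
      sgn <- if (abs(trav_step) > 1e-9) sign(trav_step) else 1
      tx <- mem$x[t_i]; ty <- mem$y[t_i]; to <- mem$orientation_deg[t_i]
      # exclude the contour's own members
      is_mem <- paste(edges$x, edges$y) %in% paste(mem$x, mem$y)
      pool <- edges[!is_mem, , drop = FALSE]
      if (nrow(pool) == 0) next
      dx <- pool$x - tx; dy <- pool$y - ty
      d <- sqrt(dx^2 + dy^2)
      win <- abs(d - spacing) <= spacing / 5 & d > 0
      if (!any(win)) next
      pool <- pool[win, , drop = FALSE]
      dx <- dx[win]; dy <- dy[win]
      fx <- tx - mem$x[p_i]; fy <- ty - mem$y[p_i]
      outward <- dx * fx + dy * fy > 0
      if (!any(outward)) next
      pool <- pool[outward, , drop = FALSE]
      g <- pair_geometry_vec(tx, ty, to, pool$x, pool$y,
                             pool$orientation_deg)
      keep <- abs(wrap90(g$theta - 2 * g$phi)) <= tol_deg
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        contour_id = cid, end = end,
        orientation_rel_deg = sgn * g$theta[keep],
        x = pool$x[keep], y = pool$y[keep])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contour_id = integer(0), end = character(0),
               orientation_rel_deg = numeric(0), x = numeric(0),
               y = numeric(0))
}
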