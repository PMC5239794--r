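#' Contour counts as a function of curvature class
#'
#' @param contours a `mapped_contours` result (or data frame with
#'   `step_deg`).
#' @param classes curvature classes to report (degrees).
#' @return data frame with `curvature_class_deg` and `n`.
#' @export
occurrence_by_curvature <- function(contours, classes = seq(0, 40, 10)) {
  cls <- as.numeric(as.character(curvature_class(contours$step_deg)))
  data.frame(curvature_class_deg = classes,
             n = vapply(classes, function(k) sum(cls == k, na.rm = TRUE),
                        integer(1)))
}

#' Normalized orientation distribution of contour end elements
#'
#' Histograms end-element orientations (relative to the curvature
#' direction) in 10-degree bins over (-90, 90], split by length bin, and
#' normalizes by the total number of contours of the curvature class, so
#' the values are proportions of occurrence comparable across classes.
#'
#' @param ends end-element records from [extract_end_elements()], joined
#'   with their contours' curvature class and length bin (columns
#'   `orientation_rel_deg`, `curvature_class_deg`, `length_bin`), or the
#'   raw records plus `contours` to join against.
#' @param contours optional `mapped_contours` used to look up class and
#'   length bin by `contour_id` and to supply per-class totals.
#' @param bin_width_deg histogram bin width (default 10).
#' @return data frame with `curvature_class_deg`, `length_bin`,
#'   `bin_center_deg`, `count`, `normalized_frequency`.
#' @export
end_orientation_distribution <- function(ends, contours = NULL,
                                         bin_width_deg = 10) {
  if (!is.null(contours)) {
    i <- match(ends$contour_id, contours$contour_id)
    ends$curvature_class_deg <-
      as.numeric(as.character(curvature_class(contours$step_deg[i])))
    ends$length_bin <- contours$length_bin[i]
    class_totals <- table(curvature_class(contours$step_deg))
  } else {
    class_totals <- NULL
  }
  req <- c("orientation_rel_deg", "curvature_class_deg", "length_bin")
  if (!all(req %in% names(ends)))
    stop("`ends` needs columns ", paste(req, collapse = ", "),
         " (or pass `contours`)", call. = FALSE)
  # bins centered on multiples of the bin width (the orientation sampling
  # grid), so a distribution peaked at a sampled orientation falls in the
  # middle of a bin rather than on an edge
  centers <- seq(-90, 90, by = bin_width_deg)
  breaks <- seq(-90 - bin_width_deg / 2, 90 + bin_width_deg / 2,
                by = bin_width_deg)
  out <- list()
  for (cls in sort(unique(ends$curvature_class_deg))) {
    sub <- ends[ends$curvature_class_deg == cls, ]
    total <- if (!is.null(class_totals))
      as.integer(class_totals[as.character(cls)]) else nrow(sub)
    if (is.na(total) || total == 0) total <- nrow(sub)
    for (lb in unique(as.character(sub$length_bin))) {
      v <- sub$orientation_rel_deg[as.character(sub$length_bin) == lb]
      v <- wrap90(v)
      cnt <- as.integer(table(cut(v, breaks = breaks,
                                  include.lowest = TRUE)))
      out[[length(out) + 1L]] <- data.frame(
        curvature_class_deg = cls, length_bin = lb,
        bin_center_deg = centers, count = cnt,
        normalized_frequency = cnt / total)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(curvature_class_deg = numeric(0), length_bin = character(0),
               bin_center_deg = numeric(0), count = integer(0),
               normalized_frequency = numeric(0))
}

#' Gaussian fit to an end-orientation distribution
#'
#' Applies the same Gaussian model used for the psychophysical tuning
#' curves, `Y = A * exp(-0.5 * (X - M)^2 / SD^2)`, to a normalized
#' frequency distribution. Flat or near-empty distributions are returned
#' with the degeneracy flag set rather than as errors.
#'
#' @param dist data frame with `bin_center_deg` and
#'   `normalized_frequency` (one curvature class / length bin at a time).
#' @return a `tuning_fit` (see [fit_gaussian_curve()]).
#' @export
fit_distribution_gaussian <- function(dist) {
  keep <- !is.na(dist$normalized_frequency)
  x <- dist$bin_center_deg[keep]
  y <- dist$normalized_frequency[keep]
  if (sum(y > 0) < 4) {
    return(structure(list(A = NA_real_, M = NA_real_, SD = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          degenerate = TRUE, n_points = length(x)),
                     class = "tuning_fit"))
  }
  fit_gaussian_curve(x, y, flag_floor = 1e-6)
}

#' Trend of distribution peaks across curvature classes
#'
#' Fits the exponential growth model `M = S * exp(K * X)` of the fitted
#' distribution peak `M` against curvature class `X`, by least squares.
#' `model = "linear"` instead fits a straight line (used for the
#' amplitude- and width-versus-length regressions).
#'
#' @param x predictor (curvature class in degrees, or length bin center).
#' @param y response (fitted Gaussian means, amplitudes or SDs).
#' @param model `"exponential"` or `"linear"`.
#' @return list with `model`, `parameters` (named: `S`, `K` or
#'   `intercept`, `slope`), `r_squared`, `converged`.
#' @export
fit_peak_trend <- function(x, y, model = c("exponential", "linear")) {
  model <- match.arg(model)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_
    return(list(model = "linear",
                parameters = c(intercept = unname(stats::coef(fit)[1]),
                               slope = unname(stats::coef(fit)[2])),
                r_squared = r2, converged = TRUE))
  }
  # log-linear start values when responses are positive
  st <- if (all(y > 0)) {
    lf <- stats::lm(log(y) ~ x)
    c(S = exp(unname(stats::coef(lf)[1])), K = unname(stats::coef(lf)[2]))
  } else c(S = max(abs(y)), K = 0.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ S * exp(K * x), start = as.list(st),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # the optimizer rejects an exact (zero-residual) start; if the
    # log-linear start already fits, report it directly
    resid0 <- y - st["S"] * exp(st["K"] * x)
    if (all(is.finite(resid0)) && sum(resid0^2) <= 1e-12 * sum(y^2)) {
      return(list(model = "exponential",
                  parameters = c(S = unname(st["S"]), K = unname(st["K"])),
                  r_squared = 1, converged = TRUE))
    }
    return(list(model = "exponential",
                parameters = c(S = NA_real_, K = NA_real_),
                r_squared = NA_real_, converged = FALSE))
  }
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(model = "exponential",
       parameters = c(S = unname(stats::coef(fit)["S"]),
                      K = unname(stats::coef(fit)["K"])),
       r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
       converged = TRUE)
}

#' Summarize end-element statistics of a mapped corpus
#'
#' Convenience aggregation: occurrence counts per curvature class, the
#' normalized end-orientation distributions, per-class Gaussian fits
#' (pooled over length bins), and the exponential peak-versus-angle trend
#' over the classes with non-degenerate fits.
#'
#' @param contours a `mapped_contours` result (rows from one or many
#'   images; `contour_id` must be unique).
#' @param ends matching [extract_end_elements()] records.
#' @param classes curvature classes to summarize.
#' @return list with `occurrence`, `distributions`, `class_fits`
#'   (data frame of A, M, SD, R2 per class), `peak_trend`.
#' @export
summarize_curvature_stats <- function(contours, ends,
                                      classes = seq(0, 40, 10)) {
  occ <- occurrence_by_curvature(contours, classes)
  dists <- end_orientation_distribution(ends, contours)
  fits <- list()
  for (cls in classes) {
    sub <- dists[dists$curvature_class_deg == cls, ]
    if (nrow(sub) == 0) next
    pooled <- stats::aggregate(cbind(count, normalized_frequency) ~
                                 bin_center_deg, data = sub, FUN = sum)
    f <- fit_distribution_gaussian(pooled)
    fits[[length(fits) + 1L]] <- data.frame(
      curvature_class_deg = cls, A = f$A, M = f$M, SD = f$SD,
      r_squared = f$r_squared, degenerate = f$degenerate)
  }
  class_fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(curvature_class_deg = numeric(0), A = numeric(0),
               M = numeric(0), SD = numeric(0), r_squared = numeric(0),
               degenerate = logical(0))
  good <- class_fits[!class_fits$degenerate & is.finite(class_fits$M), ]
  trend <- if (nrow(good) >= 3)
    fit_peak_trend(good$curvature_class_deg, good$M, "exponential")
  else NULL
  list(occurrence = occ, distributions = dists, class_fits = class_fits,
       peak_trend = trend)
}
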