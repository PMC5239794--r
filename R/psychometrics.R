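#' Logit transform of a proportion
#'
#' `log(p / (1 - p))` with `p` clamped to `[1/(2n), 1 - 1/(2n)]` so that
#' proportions of exactly 0 or 1 from `n` trials map to finite values.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param n number of trials behind each proportion (> 0).
#' @return numeric vector of logits.
#' @examples
#' logit_transform(0.5, 25)           # 0
#' logit_transform(1, 25)             # log(49)
#' @export
logit_transform <- function(p, n) {
  if (any(n <= 0)) stop("`n` must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  p <- clamp(p, 1 / (2 * n), 1 - 1 / (2 * n))
  log(p / (1 - p))
}

gaussian_curve <- function(x, A, M, SD) A * exp(-0.5 * (x - M)^2 / SD^2)

#' Least-squares Gaussian fit to tuning data
#'
#' Fits `Y = A * exp(-0.5 * (X - M)^2 / SD^2)` by Levenberg-Marquardt least
#' squares with multi-start initialization: M at the argmax of the data, A at
#' the maximum, SD at half the sampled range, plus jittered restarts. The
#' best (lowest-SSE) converged fit is kept.
#'
#' @param x predictor values (degrees).
#' @param y response values.
#' @param n_starts number of jittered restarts beyond the data-driven start.
#' @param flag_floor fits with `A` below this level (plus the sampled range
#'   rule) are flagged degenerate. Use `chance + 0.05` for proportion-correct
#'   data, or a small positive value for frequency data.
#' @return an object of class `tuning_fit`: list with `A`, `M`, `SD`
#'   (always positive), `r_squared`, `converged`, `degenerate`, `n_points`.
#' @export
fit_gaussian_curve <- function(x, y, n_starts = 5, flag_floor = 0.05) {
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct predictor levels", call. = FALSE)
  rng <- diff(range(x))
  starts <- list(c(A = max(y), M = x[which.max(y)], SD = rng / 2))
  # deterministic jitter pattern around the data-driven start
  jit <- seq(-0.3, 0.3, length.out = n_starts)
  for (k in seq_len(n_starts))
    starts[[k + 1]] <- c(A = max(y) * (1 + jit[k] / 2),
                         M = x[which.max(y)] + jit[k] * rng,
                         SD = rng / 2 * (1 + jit[k]))
  best <- NULL; best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-0.5 * (x - M)^2 / SD^2),
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  if (is.null(best)) {
    out <- list(A = NA_real_, M = NA_real_, SD = NA_real_,
                r_squared = NA_real_, converged = FALSE, degenerate = TRUE,
                n_points = length(x))
    return(structure(out, class = "tuning_fit"))
  }
  cf <- stats::coef(best)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_
  A <- unname(cf["A"]); M <- unname(cf["M"]); SD <- abs(unname(cf["SD"]))
  degenerate <- is.na(A) || A < flag_floor || SD > rng ||
    M < min(x) - rng / 2 || M > max(x) + rng / 2
  structure(list(A = A, M = M, SD = SD, r_squared = r2, converged = TRUE,
                 degenerate = degenerate, n_points = length(x)),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "<tuning_fit> A = %.3f, M = %.2f deg, SD = %.2f deg, R2 = %.3f%s\n",
    x$A, x$M, x$SD, x$r_squared,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Fit the Gaussian tuning model to a 2IFC response table
#'
#' Converts correct counts to proportion correct and fits
#' `Y = A * exp(-0.5 * (X - M)^2 / SD^2)` against end-element direction,
#' separately usable per contour angle. Fits whose amplitude is within 0.05
#' of chance, or whose SD exceeds the sampled direction range, are flagged
#' degenerate rather than rejected.
#'
#' @param table data frame with columns `end_direction_deg`, `n_trials`,
#'   `n_correct` (one contour-angle condition at a time).
#' @param chance chance proportion correct (0.5 for 2IFC).
#' @return a `tuning_fit` (see [fit_gaussian_curve()]).
#' @export
fit_gaussian_tuning <- function(table, chance = 0.5) {
  req <- c("end_direction_deg", "n_trials", "n_correct")
  if (!all(req %in% names(table)))
    stop("`table` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(table$n_trials <= 0) ||
      any(table$n_correct < 0 | table$n_correct > table$n_trials))
    stop("invalid trial counts", call. = FALSE)
  p <- table$n_correct / table$n_trials
  fit_gaussian_curve(table$end_direction_deg, p,
                     flag_floor = chance + 0.05)
}

#' Simulate a 2IFC observer on a condition grid
#'
#' For each condition row the probability of a correct response is the
#' Gaussian tuning surface evaluated at the condition's end direction,
#' floored at chance, and correct counts are drawn binomially.
#'
#' @param surface data frame with columns `contour_angle_deg`, `A`, `M`,
#'   `SD` (one row per contour angle); or a single-row surface applied to
#'   all conditions.
#' @param conditions data frame with columns `contour_angle_deg`,
#'   `end_direction_deg`.
#' @param n_trials trials per condition.
#' @param seed RNG seed; identical seeds give identical tables.
#' @param chance chance performance floor.
#' @return the conditions with added `n_trials`, `n_correct`,
#'   `p_true` columns.
#' @export
simulate_observer <- function(surface, conditions, n_trials, seed,
                              chance = 0.5) {
  if (n_trials <= 0) stop("`n_trials` must be > 0", call. = FALSE)
  if (nrow(surface) == 1 && !"contour_angle_deg" %in% names(surface)) {
    surface <- cbind(contour_angle_deg = unique(conditions$contour_angle_deg),
                     surface[rep(1, length(unique(conditions$contour_angle_deg))), ])
  }
  i <- match(conditions$contour_angle_deg, surface$contour_angle_deg)
  if (anyNA(i))
    stop("surface is missing some contour angles", call. = FALSE)
  p <- gaussian_curve(conditions$end_direction_deg,
                      surface$A[i], surface$M[i], surface$SD[i])
  p <- pmax(chance, p)
  if (any(p < 0 | p > 1))
    stop("tuning surface gives probabilities outside [0, 1]", call. = FALSE)
  out <- conditions
  out$n_trials <- n_trials
  out$n_correct <- with_seed(seed, stats::rbinom(length(p), n_trials, p))
  out$p_true <- p
  out
}
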