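#' Build and validate a pipeline run configuration
#'
#' Configurations are plain named lists (or YAML/JSON files parsed into
#' them). Unknown fields are rejected so typos fail before any compute.
#'
#' @param config named list, or path to a YAML/JSON file.
#' @param kind `"images"` or `"psychophysics"`.
#' @return validated config list with defaults filled in.
#' @export
validate_config <- function(config, kind = c("images", "psychophysics")) {
  kind <- match.arg(kind)
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or file path",
                             call. = FALSE)
  defaults <- if (kind == "images") {
    list(seed = 1L, n_images = 10L, image_dir = NULL, out_dir = NULL,
         threshold_frac = 0.1, tol_deg = 5, spacing_range_px = 1:42,
         chains_per_image = 4L, class_weights = c(5, 4, 3, 2, 1),
         spacing_px = c(20, 24, 28), end_offset_sd_deg = 12)
  } else {
    list(seed = 1L, experiment = 1L, n_trials = 200L, n_observers = 1L,
         out_dir = NULL, surface = NULL)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$image_dir) && !dir.exists(cfg$image_dir))
    stop("image_dir does not exist: ", cfg$image_dir, call. = FALSE)
  cfg
}

#' Run the image-statistics pipeline end to end
#'
#' For each input image (read from `image_dir`, or synthesized from the
#' default corpus manifest when `image_dir` is `NULL`): prepare, extract
#' edges, map constant-curvature contours, record end elements; then merge
#' across images and compute the summary statistics. Deterministic for a
#' fixed config.
#'
#' @param config see [validate_config()] (`kind = "images"`). Fields:
#'   `seed`, `n_images`, `image_dir`, `out_dir`, `threshold_frac`,
#'   `tol_deg`, `spacing_range_px`, plus corpus-manifest fields used when
#'   synthesizing.
#' @return list with `edges_per_image` (counts), `contours`, `ends`,
#'   `stats` (see [summarize_curvature_stats()]), `config`.
#' @export
run_image_pipeline <- function(config = list()) {
  cfg <- validate_config(config, "images")
  if (is.null(cfg$image_dir)) {
    manifest <- default_corpus_manifest(
      n_images = cfg$n_images, seed = cfg$seed,
      class_weights = cfg$class_weights, spacing_px = cfg$spacing_px,
      chains_per_image = cfg$chains_per_image,
      end_offset_sd_deg = cfg$end_offset_sd_deg)
    corpus <- generate_corpus(manifest)
    images <- lapply(corpus, `[[`, "image")
    names(images) <- sprintf("synthetic_%03d", seq_along(images))
  } else {
    files <- sort(list.files(cfg$image_dir, "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0)
      stop("no images found in ", cfg$image_dir, call. = FALSE)
    images <- lapply(files, read_image)
    names(images) <- basename(files)
  }
  all_contours <- list(); all_ends <- list(); n_edges <- integer(0)
  next_id <- 0L
  for (nm in names(images)) {
    prep <- prepare_image(images[[nm]])
    edges <- extract_edges(prep, threshold_frac = cfg$threshold_frac)
    n_edges[nm] <- nrow(edges)
    if (nrow(edges) < 4) next
    ctr <- find_contours(edges, spacing_range_px = cfg$spacing_range_px,
                         tol_deg = cfg$tol_deg)
    if (nrow(ctr) == 0) next
    ends <- extract_end_elements(ctr, edges, tol_deg = cfg$tol_deg)
    mem <- attr(ctr, "members")
    ctr$contour_id <- ctr$contour_id + next_id
    mem$contour_id <- mem$contour_id + next_id
    if (nrow(ends)) ends$contour_id <- ends$contour_id + next_id
    ctr$image <- nm
    attr(ctr, "members") <- mem
    next_id <- max(ctr$contour_id)
    all_contours[[nm]] <- ctr
    all_ends[[nm]] <- ends
  }
  contours <- merge_mapped_contours(all_contours)
  ends <- if (length(all_ends)) do.call(rbind, all_ends) else
    data.frame(contour_id = integer(0), end = character(0),
               orientation_rel_deg = numeric(0), x = numeric(0),
               y = numeric(0))
  rownames(ends) <- NULL
  stats <- summarize_curvature_stats(contours, ends)
  out <- list(edges_per_image = n_edges, contours = contours, ends = ends,
              stats = stats, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

merge_mapped_contours <- function(lst) {
  if (!length(lst)) {
    out <- data.frame(contour_id = integer(0), step_deg = numeric(0),
                      spacing_px = numeric(0))
    out$length_bin <- length_bin(numeric(0))
    out$image <- character(0)
    attr(out, "members") <- data.frame(contour_id = integer(0),
                                       position = integer(0),
                                       x = numeric(0), y = numeric(0),
                                       orientation_deg = numeric(0))
    class(out) <- c("mapped_contours", "data.frame")
    return(out)
  }
  mem <- do.call(rbind, lapply(lst, attr, "members"))
  out <- do.call(rbind, lapply(lst, function(x) as.data.frame(x)))
  rownames(out) <- rownames(mem) <- NULL
  attr(out, "members") <- mem
  class(out) <- c("mapped_contours", "data.frame")
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$contours),
                   file.path(out_dir, "contours.csv"), row.names = FALSE)
  utils::write.csv(attr(result$contours, "members"),
                   file.path(out_dir, "contour_members.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ends, file.path(out_dir, "ends.csv"),
                   row.names = FALSE)
  utils::write.csv(result$stats$occurrence,
                   file.path(out_dir, "occurrence.csv"), row.names = FALSE)
  utils::write.csv(result$stats$distributions,
                   file.path(out_dir, "distributions.csv"),
                   row.names = FALSE)
  utils::write.csv(result$stats$class_fits,
                   file.path(out_dir, "class_fits.csv"), row.names = FALSE)
  prov <- list(config = result$config,
               package_version = as.character(utils::packageVersion("curvestats")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}

#' Run the psychophysics pipeline end to end
#'
#' Simulates the requested number of observers on the experiment's
#' condition grid, fits the Gaussian tuning model per observer and contour
#' angle, and returns per-observer fits plus group means.
#'
#' @param config see [validate_config()] (`kind = "psychophysics"`):
#'   `seed`, `experiment`, `n_trials`, `n_observers`, `out_dir`,
#'   optional `surface`.
#' @return list with `responses` (all observers), `fits` (per observer and
#'   contour angle), `group` (mean A, M, SD per angle), `config`.
#' @export
run_psychophysics_pipeline <- function(config = list()) {
  cfg <- validate_config(config, "psychophysics")
  surface <- cfg$surface %||% default_tuning_surface()
  if (cfg$n_observers < 1) {
    warning("no observers requested; returning empty summary")
    return(list(responses = NULL, fits = NULL, group = NULL, config = cfg))
  }
  resp <- list(); fits <- list()
  for (obs in seq_len(cfg$n_observers)) {
    tab <- generate_responses(cfg$experiment, n_trials = cfg$n_trials,
                              seed = cfg$seed + obs * 1000L,
                              surface = surface)
    tab$observer <- obs
    resp[[obs]] <- tab
    if (cfg$experiment == 1) {
      for (ang in unique(tab$contour_angle_deg)) {
        sub <- tab[tab$contour_angle_deg == ang, ]
        f <- fit_gaussian_tuning(sub)
        fits[[length(fits) + 1L]] <- data.frame(
          observer = obs, contour_angle_deg = ang, A = f$A, M = f$M,
          SD = f$SD, r_squared = f$r_squared, degenerate = f$degenerate)
      }
    }
  }
  responses <- do.call(rbind, resp)
  fits <- if (length(fits)) do.call(rbind, fits) else NULL
  group <- if (!is.null(fits))
    stats::aggregate(cbind(A, M, SD) ~ contour_angle_deg,
                     data = fits[!fits$degenerate, ], FUN = mean)
  else NULL
  out <- list(responses = responses, fits = fits, group = group,
              config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(responses, file.path(cfg$out_dir, "responses.csv"),
                     row.names = FALSE)
    if (!is.null(fits))
      utils::write.csv(fits, file.path(cfg$out_dir, "fits.csv"),
                       row.names = FALSE)
  }
  out
}
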