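#' Run configuration for the analysis pipelines
#'
#' Bundles every tunable of the soma-quantification and apposition pipelines.
#' All thresholds actually applied are recorded per image in the run log, so
#' "optimized per image" settings stay auditable. The configuration (and the
#' master seed) is hashed into every artifact the pipelines write.
#'
#' @param pixel_size_nm Calibration expected of all input images (images carry
#'   their own; this is checked against them).
#' @param channels Named list mapping roles (`ev`, `mitochondria`,
#'   `soma_marker`) to channel names.
#' @param ev_threshold,mito_threshold,soma_threshold [threshold_spec()]s per
#'   role.
#' @param filter [size_shape_filter()] applied to EV puncta.
#' @param min_soma_area_um2 Minimum accepted soma area.
#' @param soma_selection Optional list (one integer vector per image) of soma
#'   labels to keep, reproducing manual verification.
#' @param roi_strategy,roi_margin_px Cellular-ROI construction for the Monte
#'   Carlo null (see [define_cell_roi()]).
#' @param mc_iterations Per-image Monte Carlo iterations (default 1000).
#' @param pooled_iterations Iterations for pooled binned enrichment (default
#'   10000).
#' @param thresholds_nm Cumulative apposition bins, nm.
#' @param seed Master seed; per-image substreams are derived from it.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(pixel_size_nm,
                       channels = list(ev = "ev", mitochondria = "mitochondria",
                                       soma_marker = "soma"),
                       ev_threshold = threshold_spec("otsu", pre_smooth_sigma_px = 1),
                       mito_threshold = threshold_spec("otsu", pre_smooth_sigma_px = 1),
                       soma_threshold = threshold_spec("otsu", pre_smooth_sigma_px = 2),
                       filter = size_shape_filter(),
                       min_soma_area_um2 = 50,
                       soma_selection = NULL,
                       roi_strategy = "hull_of_structures", roi_margin_px = 20,
                       mc_iterations = 1000, pooled_iterations = 10000,
                       thresholds_nm = c(0, 100, 200, 500, 1000),
                       seed = 1, output_dir = NULL) {
  stopifnot(pixel_size_nm > 0, mc_iterations >= 100, pooled_iterations >= 100)
  cfg <- structure(as.list(environment()), class = "run_config")
  cfg
}

.config_hash <- function(config) rlang::hash(unclass(config))

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.append_runlog <- function(log, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA), con)
}

.as_image <- function(x) {
  if (inherits(x, "calibrated_image")) return(x)
  if (inherits(x, "soma_field") || inherits(x, "apposition_field")) return(x$image)
  stop("inputs must be calibrated images or generated fields", call. = FALSE)
}

#' Soma-quantification pipeline
#'
#' For each image: detect somata from the marker channel, segment EV puncta
#' (threshold, label, measure, size/shape filter), assign puncta to somata by
#' centroid, and tabulate per-soma counts and densities. Across the dataset:
#' mean count +/- SEM, fraction of somata with any particle, and Pearson
#' correlations of count vs soma area and density vs soma area.
#'
#' @param images List of `calibrated_image`s (or generated `soma_field`s,
#'   whose rendered images are used — ground truth is never consulted).
#' @param config A [run_config()].
#' @return A `soma_pipeline_result`: `per_soma` (data frame across images),
#'   `mean_count`, `sem_count`, `fraction_of_somata_with_particles`,
#'   `n_somata`, `correlations` (list of `correlation_result`s), `run_log`,
#'   `config_hash`, `seed`.
#' @export
run_soma_pipeline <- function(images, config) {
  stopifnot(inherits(config, "run_config"))
  images <- lapply(images, .as_image)
  per_soma <- list()
  run_log <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!isTRUE(all.equal(img$pixel_size_nm, config$pixel_size_nm)))
      stop(sprintf("image %d: pixel size %.4g differs from config %.4g",
                   i, img$pixel_size_nm, config$pixel_size_nm), call. = FALSE)
    sel <- if (!is.null(config$soma_selection)) config$soma_selection[[i]] else NULL
    somata <- withCallingHandlers(
      detect_somata(img, config$channels$soma_marker, config$soma_threshold,
                    min_soma_area_um2 = config$min_soma_area_um2,
                    selection = sel),
      warning = function(w) invokeRestart("muffleWarning"))
    if (max(somata) == 0L) {
      if (!is.null(sel) && length(sel) == 0)
        stop(sprintf("image %d: empty soma selection", i), call. = FALSE)
      next
    }
    ev_mask <- threshold_channel(img, config$channels$ev, config$ev_threshold)
    particles <- filter_particles(
      extract_particles(label_connected(ev_mask, 8),
                        get_channel(img, config$channels$ev)),
      config$filter)
    assignment <- assign_particles_to_somata(particles, somata)
    sq <- summarize_somata(assignment, somata, particles)
    df <- sq$per_soma
    df$image_id <- i
    per_soma[[length(per_soma) + 1L]] <- df
    run_log[[length(run_log) + 1L]] <- list(
      stage = "soma_quant", image = i,
      ev_threshold = attr(ev_mask, "threshold"),
      n_somata = sq$n_somata, n_particles_kept = nrow(particles),
      removed = as.list(attr(particles, "removed")))
  }
  if (!length(per_soma)) stop("no somata detected in any image", call. = FALSE)
  per_soma <- do.call(rbind, per_soma)
  counts <- per_soma$particle_count
  res <- list(per_soma = per_soma,
              mean_count = mean(counts),
              sem_count = if (length(counts) > 1) stats::sd(counts) / sqrt(length(counts)) else NA_real_,
              fraction_of_somata_with_particles = mean(counts > 0),
              n_somata = nrow(per_soma),
              correlations = list(
                count_vs_area = tryCatch(
                  pearson_correlation(per_soma$soma_area_um2, counts),
                  error = function(e) NULL),
                density_vs_area = tryCatch(
                  pearson_correlation(per_soma$soma_area_um2,
                                      per_soma$particle_density_per_um2),
                  error = function(e) NULL)),
              run_log = run_log,
              config_hash = .config_hash(config), seed = config$seed)
  class(res) <- "soma_pipeline_result"
  if (!is.null(config$output_dir)) .write_soma_artifacts(res, config)
  res
}

.write_soma_artifacts <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$per_soma,
                   file.path(config$output_dir, "per_soma.csv"), row.names = FALSE)
  summ <- list(config_hash = res$config_hash, seed = res$seed,
               n_somata = res$n_somata, mean_count = res$mean_count,
               sem_count = res$sem_count,
               fraction_of_somata_with_particles = res$fraction_of_somata_with_particles,
               correlations = lapply(res$correlations, function(cr)
                 if (is.null(cr)) NULL else unclass(cr)))
  .write_json(summ, file.path(config$output_dir, "soma_summary.json"))
  logpath <- file.path(config$output_dir, "run_log.jsonl")
  for (entry in res$run_log)
    .append_runlog(c(entry, config_hash = res$config_hash, seed = res$seed), logpath)
}

#' @export
print.soma_pipeline_result <- function(x, ...) {
  cat(sprintf("<soma_pipeline_result> %d somata | mean %.3g +/- %.3g particles/cell | %.1f%% positive\n",
              x$n_somata, x$mean_count, x$sem_count,
              100 * x$fraction_of_somata_with_particles))
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    if (!is.null(cr))
      cat(sprintf("  %s: r = %.3f, p = %.4g (n = %d)\n", nm, cr$r, cr$p_two_sided, cr$n))
  }
  invisible(x)
}

#' EV-mitochondria apposition pipeline
#'
#' Per image: segment the EV and mitochondrial channels, measure edge-to-edge
#' distances, summarize cumulative apposition bins, and run the per-image
#' Monte Carlo proximity null. Per condition: pooled binned enrichment over
#' all images, the bimodality coefficient and 1- vs 2-component mixture
#' selection on the pooled distances. With exactly two conditions the pooled
#' edge distances are compared by Mann-Whitney U and the contact counts by
#' Fisher's exact test.
#'
#' @param conditions Named list of conditions; each a list of
#'   `calibrated_image`s or generated `apposition_field`s.
#' @param config A [run_config()].
#' @return An `apposition_pipeline_result` with per-image results, per-
#'   condition pooled results, and between-condition comparisons.
#' @export
run_apposition_pipeline <- function(conditions, config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named list", call. = FALSE)
  img_index <- 0L
  run_log <- list()
  cond_results <- lapply(names(conditions), function(cname) {
    fields <- list()
    per_image <- list()
    for (j in seq_along(conditions[[cname]])) {
      img_index <<- img_index + 1L
      img <- .as_image(conditions[[cname]][[j]])
      if (!isTRUE(all.equal(img$pixel_size_nm, config$pixel_size_nm)))
        stop("image pixel size differs from config", call. = FALSE)
      mito <- threshold_channel(img, config$channels$mitochondria,
                                config$mito_threshold, role = "mitochondria")
      ev_mask <- threshold_channel(img, config$channels$ev, config$ev_threshold)
      particles <- filter_particles(
        extract_particles(label_connected(ev_mask, 8),
                          get_channel(img, config$channels$ev)),
        config$filter)
      if (!nrow(particles)) {
        run_log[[length(run_log) + 1L]] <<- list(stage = "apposition",
                                                 condition = cname, image = j,
                                                 note = "no particles after filtering")
        next
      }
      pmask <- matrix(0, nrow(mito), ncol(mito))
      for (px in particle_coords(particles)) pmask[px] <- 1
      roi <- define_cell_roi(img, config$roi_strategy,
                             structure_masks = list(mito, binary_mask(pmask, img$pixel_size_nm)),
                             margin_px = config$roi_margin_px)
      records <- edge_to_edge_distances(particles, mito)
      mc <- monte_carlo_null(particles, mito, roi,
                             statistic = "mean_edge_distance",
                             thresholds_nm = config$thresholds_nm,
                             n_iterations = config$mc_iterations,
                             seed = .image_seed(config$seed, img_index))
      per_image[[length(per_image) + 1L]] <- list(
        condition = cname, image = j, records = records,
        summary = summarize_apposition(records, config$thresholds_nm),
        monte_carlo = mc)
      fields[[length(fields) + 1L]] <- list(particles = particles,
                                            organelle = mito, roi = roi)
      run_log[[length(run_log) + 1L]] <<- list(
        stage = "apposition", condition = cname, image = j,
        ev_threshold = attr(ev_mask, "threshold"),
        mito_threshold = attr(mito, "threshold"),
        n_particles = nrow(particles), mc_p = mc$empirical_p)
    }
    if (!length(fields))
      stop(sprintf("condition '%s': no analysable images", cname), call. = FALSE)
    edges <- unlist(lapply(per_image, function(pi) pi$records$edge_distance_nm))
    pooled <- pooled_enrichment(fields, thresholds_nm = config$thresholds_nm,
                                n_iterations = config$pooled_iterations,
                                seed = config$seed)
    list(per_image = per_image, edges = edges, pooled = pooled,
         summary = summarize_apposition(
           structure(data.frame(particle_id = seq_along(edges),
                                edge_distance_nm = edges,
                                centroid_distance_nm = NA_real_,
                                in_contact = edges == 0),
                     class = c("distance_records", "data.frame")),
           config$thresholds_nm),
         bimodality = if (length(edges) >= 4 && stats::sd(edges) > 0)
           bimodality_coefficient(edges) else NULL,
         mixture = if (length(edges) >= 20 && stats::sd(edges) > 0)
           select_mixture_model(edges, seed = config$seed) else NULL)
  })
  names(cond_results) <- names(conditions)
  comparisons <- NULL
  if (length(cond_results) == 2L) {
    ea <- cond_results[[1]]$edges; eb <- cond_results[[2]]$edges
    comparisons <- list(
      mann_whitney = mann_whitney(ea, eb),
      fisher_contact = fisher_exact(sum(ea == 0), length(ea),
                                    sum(eb == 0), length(eb)))
  }
  res <- structure(list(conditions = cond_results, comparisons = comparisons,
                        run_log = run_log,
                        config_hash = .config_hash(config), seed = config$seed),
                   class = "apposition_pipeline_result")
  if (!is.null(config$output_dir)) .write_apposition_artifacts(res, config)
  res
}

.write_apposition_artifacts <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cname in names(res$conditions))
    for (pi in res$conditions[[cname]]$per_image) {
      df <- as.data.frame(pi$records)
      df$condition <- cname; df$image_id <- pi$image
      rows[[length(rows) + 1L]] <- df
    }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$output_dir, "distances.csv"), row.names = FALSE)
  out <- list(config_hash = res$config_hash, seed = res$seed,
              conditions = lapply(res$conditions, function(cr) list(
                n_particles = length(cr$edges),
                mean_edge_nm = mean(cr$edges),
                bins = cr$summary$bins,
                pooled = list(statistic = cr$pooled$statistic_name,
                              observed = cr$pooled$observed,
                              empirical_p = cr$pooled$empirical_p,
                              bins = cr$pooled$bins),
                bimodality = if (!is.null(cr$bimodality)) unclass(cr$bimodality),
                mixture = if (!is.null(cr$mixture))
                  cr$mixture[c("bic_1", "bic_2", "delta_bic", "selected_components")])),
              comparisons = if (!is.null(res$comparisons))
                lapply(res$comparisons, unclass))
  .write_json(out, file.path(config$output_dir, "apposition_summary.json"))
  logpath <- file.path(config$output_dir, "run_log.jsonl")
  for (entry in res$run_log)
    .append_runlog(c(entry, config_hash = res$config_hash, seed = res$seed), logpath)
}

#' @export
print.apposition_pipeline_result <- function(x, ...) {
  for (cname in names(x$conditions)) {
    cr <- x$conditions[[cname]]
    cat(sprintf("condition '%s': %d particles, mean edge %.1f nm, contact %.1f%%, pooled p = %.4g\n",
                cname, length(cr$edges), mean(cr$edges),
                100 * mean(cr$edges == 0), cr$pooled$empirical_p))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("Mann-Whitney p = %.4g | Fisher contact p = %.4g\n",
                x$comparisons$mann_whitney$p_two_sided,
                x$comparisons$fisher_contact$p_two_sided))
  }
  invisible(x)
}
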