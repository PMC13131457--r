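#' Assign particles to somata by centroid location
#'
#' A particle belongs to the soma whose label covers the pixel containing its
#' centroid (`floor` of the real-valued centroid coordinates); a centroid over
#' background is unassigned. Each particle maps to at most one soma.
#'
#' @param particles A `particle_set`.
#' @param somata A soma `label_mask` of the same geometry.
#' @return Integer vector, one entry per particle: soma id, or `NA` if
#'   unassigned.
#' @export
assign_particles_to_somata <- function(particles, somata) {
  stopifnot(inherits(particles, "particle_set"), inherits(somata, "label_mask"))
  if (!identical(attr(particles, "image_dim"), dim(somata)[1:2]))
    stop("particles and somata come from different geometries", call. = FALSE)
  if (!nrow(particles)) return(integer(0))
  ri <- pmin(pmax(floor(particles$centroid_r), 1L), nrow(somata))
  ci <- pmin(pmax(floor(particles$centroid_c), 1L), ncol(somata))
  lab <- somata[cbind(ri, ci)]
  ifelse(lab > 0, lab, NA_integer_)
}

#' Per-soma punctum counts and densities
#'
#' Tabulates particles per soma (zeros included), particle density per square
#' micron of soma area, and dataset summaries: mean count, SEM (sample SD over
#' the square root of the number of somata) and the fraction of somata with at
#' least one particle.
#'
#' @param assignment Output of [assign_particles_to_somata()].
#' @param somata The soma `label_mask`.
#' @param particles The `particle_set` that was assigned.
#' @return A `soma_quant_result`: list with `per_soma` (data frame: `soma_id`,
#'   `soma_area_um2`, `particle_count`, `particle_density_per_um2`),
#'   `mean_count`, `sem_count`, `fraction_of_somata_with_particles`, `n_somata`.
#' @export
summarize_somata <- function(assignment, somata, particles) {
  K <- max(somata)
  if (K == 0L) stop("no somata to summarize", call. = FALSE)
  s <- .mask_pixel_size(somata)
  areas_px <- tabulate(somata[somata > 0], nbins = K)
  areas_um2 <- areas_px * (s / 1000)^2
  counts <- tabulate(assignment[!is.na(assignment)], nbins = K)
  per_soma <- data.frame(soma_id = seq_len(K), soma_area_um2 = areas_um2,
                         particle_count = counts,
                         particle_density_per_um2 = counts / areas_um2)
  structure(list(per_soma = per_soma,
                 mean_count = mean(counts),
                 sem_count = if (K > 1) stats::sd(counts) / sqrt(K) else NA_real_,
                 fraction_of_somata_with_particles = mean(counts > 0),
                 n_somata = K),
            class = "soma_quant_result")
}

#' @export
print.soma_quant_result <- function(x, ...) {
  cat(sprintf("<soma_quant_result> %d somata | mean %.3g +/- %.3g particles/cell | %.1f%% of somata positive\n",
              x$n_somata, x$mean_count, x$sem_count,
              100 * x$fraction_of_somata_with_particles))
  invisible(x)
}

#' Pearson correlation with exact t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `correlation_p_value()` exposes the p-value computation alone, for
#' recomputing a p from a reported `(r, n)` pair.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return A `correlation_result`: list with `r`, `n`, `t_statistic`,
#'   `p_two_sided`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = n,
                 t_statistic = unname(ct$statistic),
                 p_two_sided = ct$p.value),
            class = "correlation_result")
}

#' @rdname pearson_correlation
#' @param r Correlation coefficient in `(-1, 1)`.
#' @param n Sample size (`>= 3`).
#' @export
correlation_p_value <- function(r, n) {
  if (n < 3 || abs(r) >= 1) stop("need n >= 3 and |r| < 1", call. = FALSE)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Fraction of particles co-labeled in a second channel's mask
#'
#' A reference particle counts as co-labeled when its pixel set overlaps at
#' least one foreground pixel of the query mask.
#'
#' @param reference A non-empty `particle_set`.
#' @param query_mask A `binary_mask` of the same geometry.
#' @return Fraction in `[0, 1]`.
#' @export
colabel_fraction <- function(reference, query_mask) {
  stopifnot(inherits(reference, "particle_set"))
  if (!nrow(reference)) stop("co-label fraction undefined for an empty particle set",
                             call. = FALSE)
  if (!identical(attr(reference, "image_dim"), dim(query_mask)[1:2]))
    stop("geometry mismatch", call. = FALSE)
  hits <- vapply(particle_coords(reference),
                 function(px) any(query_mask[px] != 0), logical(1))
  mean(hits)
}

#' Total channel intensity, optionally within a mask
#'
#' @param image A `calibrated_image`.
#' @param channel Channel name.
#' @param within Optional `binary_mask` restricting the sum.
#' @return Sum of intensities.
#' @export
channel_total_intensity <- function(image, channel, within = NULL) {
  x <- get_channel(image, channel)
  if (is.null(within)) return(sum(x))
  if (!identical(dim(within)[1:2], dim(x))) stop("mask geometry mismatch", call. = FALSE)
  sum(x[within != 0])
}

#' Particle count per unit organelle mask area
#'
#' Counts particles whose pixel set overlaps the mask, divided by the mask
#' area in square microns.
#'
#' @param particles A `particle_set`.
#' @param organelle_mask A non-empty `binary_mask`.
#' @return Count per square micron.
#' @export
dots_per_mask_area <- function(particles, organelle_mask) {
  stopifnot(inherits(particles, "particle_set"))
  npx <- sum(organelle_mask != 0)
  if (npx == 0) stop("organelle mask is empty", call. = FALSE)
  s <- .mask_pixel_size(organelle_mask)
  area_um2 <- npx * (s / 1000)^2
  if (!nrow(particles)) return(0)
  hits <- vapply(particle_coords(particles),
                 function(px) any(organelle_mask[px] != 0), logical(1))
  sum(hits) / area_um2
}
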