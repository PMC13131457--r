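#' Edge-to-edge and centroid distances from particles to an organelle mask
#'
#' Distances are measured on the pixel grid. For each particle let `d_px` be
#' the minimum, over its pixels, of the exact Euclidean distance transform of
#' the organelle mask (0 on organelle pixels). A particle is *in contact*
#' (0 nm) when it overlaps the organelle or is 8-adjacent to it
#' (`d_px <= sqrt(2)`): adjacent pixels have zero boundary separation.
#' Otherwise the edge-to-edge distance is `(d_px - 1) * pixel_size_nm`, the
#' boundary gap between pixel squares. The centroid distance is the Euclidean
#' distance from the particle centroid to the nearest organelle pixel centre.
#'
#' @param particles A `particle_set`.
#' @param organelle A non-empty `binary_mask` of the same geometry.
#' @param pixel_size_nm Calibration; defaults to the particles' own.
#' @return A `distance_records` data frame: `particle_id`, `edge_distance_nm`,
#'   `centroid_distance_nm`, `in_contact`.
#' @export
edge_to_edge_distances <- function(particles, organelle,
                                   pixel_size_nm = attr(particles, "pixel_size_nm")) {
  stopifnot(inherits(particles, "particle_set"))
  if (!identical(attr(particles, "image_dim"), dim(organelle)[1:2]))
    stop("particles and organelle mask come from different geometries", call. = FALSE)
  org <- matrix(as.numeric(organelle != 0), nrow(organelle), ncol(organelle))
  if (sum(org) == 0) stop("organelle mask is empty", call. = FALSE)
  s <- as.numeric(pixel_size_nm)
  D <- .distance_to_mask(org)
  oidx <- which(org > 0)
  or <- (oidx - 1L) %% nrow(org) + 1L
  oc <- (oidx - 1L) %/% nrow(org) + 1L
  coords <- particle_coords(particles)
  n <- nrow(particles)
  d_px <- vapply(coords, function(px) min(D[px]), numeric(1))
  contact <- d_px <= sqrt(2) + 1e-9
  edge_nm <- ifelse(contact, 0, (d_px - 1) * s)
  cent_nm <- vapply(seq_len(n), function(i) {
    sqrt(min((or - particles$centroid_r[i])^2 + (oc - particles$centroid_c[i])^2)) * s
  }, numeric(1))
  structure(data.frame(particle_id = particles$id,
                       edge_distance_nm = edge_nm,
                       centroid_distance_nm = cent_nm,
                       in_contact = contact),
            pixel_size_nm = s,
            class = c("distance_records", "data.frame"))
}

# Exact Euclidean distance (px) from every pixel to the nearest mask pixel.
.distance_to_mask <- function(mask01) {
  d <- EBImage::distmap(1 - mask01, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask01), ncol(mask01))
}

#' Cumulative apposition summary of edge distances
#'
#' Fractions use `<=` semantics at each threshold; the contact fraction (at
#' 0 nm) is the fraction of particles with edge distance exactly 0, which the
#' larger bins subsume.
#'
#' @param records Output of [edge_to_edge_distances()] (at least one row).
#' @param thresholds_nm Cumulative bin thresholds in nm.
#' @return An `apposition_summary`: list with `n_particles`, `mean_edge_nm`,
#'   `median_edge_nm` and a data frame `bins` (`threshold_nm`, `fraction`).
#' @export
summarize_apposition <- function(records, thresholds_nm = c(0, 100, 200, 500, 1000)) {
  if (!nrow(records)) stop("no distance records", call. = FALSE)
  e <- records$edge_distance_nm
  bins <- data.frame(threshold_nm = thresholds_nm,
                     fraction = vapply(thresholds_nm, function(t) mean(e <= t), numeric(1)))
  structure(list(n_particles = length(e), mean_edge_nm = mean(e),
                 median_edge_nm = stats::median(e), bins = bins),
            class = "apposition_summary")
}

#' @export
print.apposition_summary <- function(x, ...) {
  cat(sprintf("<apposition_summary> n = %d | mean edge %.1f nm | median %.1f nm\n",
              x$n_particles, x$mean_edge_nm, x$median_edge_nm))
  for (i in seq_len(nrow(x$bins)))
    cat(sprintf("  %s %4g nm: %5.1f%%\n",
                if (x$bins$threshold_nm[i] == 0) "contact" else "<=",
                x$bins$threshold_nm[i], 100 * x$bins$fraction[i]))
  invisible(x)
}

# ---- Monte Carlo machinery ---------------------------------------------------

# Per-image preparation for randomized placement: distance map, particle shape
# groups, valid-centre sets and shape-min distance maps.
.mc_prepare_image <- function(particles, organelle, roi) {
  dims <- attr(particles, "image_dim")
  if (!identical(dims, dim(organelle)[1:2]) || !identical(dims, dim(roi)[1:2]))
    stop("particles, organelle and roi must share geometry", call. = FALSE)
  org <- matrix(as.numeric(organelle != 0), dims[1], dims[2])
  if (sum(org) == 0) stop("organelle mask is empty", call. = FALSE)
  roiL <- matrix(roi != 0, dims[1], dims[2])
  coords <- particle_coords(particles)
  for (px in coords)
    if (!all(roiL[px])) stop("an observed particle lies outside the ROI", call. = FALSE)
  D <- .distance_to_mask(org)
  anchors <- cbind(round(particles$centroid_r), round(particles$centroid_c))
  offs <- lapply(seq_along(coords), function(i)
    cbind(coords[[i]][, 1] - anchors[i, 1], coords[[i]][, 2] - anchors[i, 2]))
  sig <- vapply(offs, function(o) paste(o[order(o[, 1], o[, 2]), ], collapse = ","),
                character(1))
  groups <- split(seq_along(offs), sig)
  shapes <- lapply(groups, function(idx) {
    o <- offs[[idx[1]]]
    valid <- .shift_all_true(roiL, o)
    vidx <- which(valid)
    if (!length(vidx))
      stop("ROI too small to place a particle shape", call. = FALSE)
    list(particle_idx = idx, valid_idx = vidx,
         min_d = .shift_min(D, o))
  })
  list(shapes = shapes, n_particles = nrow(particles), D = D)
}

# M[c] = min over offsets of D[c + off], Inf-padded outside the image.
.shift_min <- function(D, offs) {
  nr <- nrow(D); nc <- ncol(D)
  m <- max(abs(offs)) + 1L
  P <- matrix(Inf, nr + 2L * m, nc + 2L * m)
  P[m + seq_len(nr), m + seq_len(nc)] <- D
  Reduce(pmin, lapply(seq_len(nrow(offs)), function(i)
    P[m + seq_len(nr) + offs[i, 1], m + seq_len(nc) + offs[i, 2], drop = FALSE]))
}

# V[c] = all offsets of the shape land on TRUE pixels of `mask` (in-bounds).
.shift_all_true <- function(mask, offs) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- max(abs(offs)) + 1L
  P <- matrix(FALSE, nr + 2L * m, nc + 2L * m)
  P[m + seq_len(nr), m + seq_len(nc)] <- mask
  Reduce(`&`, lapply(seq_len(nrow(offs)), function(i)
    P[m + seq_len(nr) + offs[i, 1], m + seq_len(nc) + offs[i, 2], drop = FALSE]))
}

# Null edge-distance matrix (n_iterations x n_particles) for one image: each
# particle's rigid pixel shape re-centred uniformly over its valid ROI centres.
.mc_null_edges <- function(prep, pixel_size_nm, n_iterations) {
  out <- matrix(NA_real_, n_iterations, prep$n_particles)
  for (sh in prep$shapes) {
    k <- length(sh$particle_idx)
    draw <- sample(length(sh$valid_idx), n_iterations * k, replace = TRUE)
    d <- sh$min_d[sh$valid_idx[draw]]
    out[, sh$particle_idx] <- matrix(d, n_iterations, k)
  }
  ifelse(out <= sqrt(2) + 1e-9, 0, (out - 1) * pixel_size_nm)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.image_seed <- function(master, i) as.integer((as.numeric(master) + 1000003 * i) %% 2147483647)

# Shared driver behind monte_carlo_null() and pooled_enrichment().
.mc_run <- function(fields, statistic, threshold_nm, thresholds_nm,
                    n_iterations, seed) {
  if (n_iterations < 100) stop("need n_iterations >= 100", call. = FALSE)
  s <- attr(fields[[1]]$particles, "pixel_size_nm")
  obs <- numeric(0)
  null_list <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (!isTRUE(all.equal(attr(f$particles, "pixel_size_nm"), s)))
      stop("all images must share one pixel size for pooling", call. = FALSE)
    prep <- .mc_prepare_image(f$particles, f$organelle, f$roi)
    rec <- edge_to_edge_distances(f$particles, f$organelle, s)
    obs <- c(obs, rec$edge_distance_nm)
    null_list[[i]] <- .with_seed(.image_seed(seed, i),
                                 .mc_null_edges(prep, s, n_iterations))
  }
  null_edges <- do.call(cbind, null_list)
  n_tot <- length(obs)

  obs_mean <- mean(obs)
  null_means <- rowMeans(null_edges)
  obs_frac <- vapply(thresholds_nm, function(t) mean(obs <= t), numeric(1))
  null_frac <- vapply(thresholds_nm, function(t) rowMeans(null_edges <= t),
                      numeric(n_iterations))
  if (is.null(dim(null_frac))) null_frac <- matrix(null_frac, nrow = n_iterations)
  exp_frac <- colMeans(null_frac)
  bins <- data.frame(
    threshold_nm = thresholds_nm,
    observed_fraction = obs_frac,
    expected_fraction = exp_frac,
    fold_enrichment = ifelse(exp_frac > 0, obs_frac / exp_frac, NA_real_),
    p_one_sided = vapply(seq_along(thresholds_nm), function(j)
      (1 + sum(null_frac[, j] >= obs_frac[j] - 1e-12)) / (1 + n_iterations),
      numeric(1)))

  if (statistic == "mean_edge_distance") {
    observed <- obs_mean
    null_vec <- null_means
    p <- (1 + sum(null_vec <= observed + 1e-9)) / (1 + n_iterations)
  } else {
    j <- match(threshold_nm, thresholds_nm)
    if (is.na(j)) {
      ofr <- mean(obs <= threshold_nm)
      nfr <- rowMeans(null_edges <= threshold_nm)
    } else {
      ofr <- obs_frac[j]; nfr <- null_frac[, j]
    }
    observed <- ofr
    null_vec <- nfr
    p <- (1 + sum(null_vec >= observed - 1e-12)) / (1 + n_iterations)
  }
  structure(list(statistic_name = if (statistic == "mean_edge_distance")
                   "mean_edge_distance" else sprintf("fraction_within_%gnm", threshold_nm),
                 observed = observed, null_mean = mean(null_vec),
                 null_sd = stats::sd(null_vec), n_iterations = n_iterations,
                 empirical_p = p, bins = bins, n_particles = n_tot,
                 n_images = length(fields), seed = seed),
            class = "monte_carlo_result")
}

#' Monte Carlo randomization null for particle-organelle proximity
#'
#' Tests whether observed particles lie closer to the organelle than expected
#' if placed at random inside the cellular ROI. Each iteration rigidly
#' translates every particle's segmented pixel shape so that its centroid is
#' uniform over ROI pixels at which the whole shape stays inside the ROI
#' (organelle geometry untouched; overlap with the organelle is allowed, as it
#' is for observed particles). The test is one-sided toward proximity: a
#' smaller mean edge distance, or a larger close fraction, counts as extreme.
#' The empirical p-value uses the add-one convention
#' `(1 + #extreme) / (1 + n_iterations)` and is therefore never zero.
#'
#' @param particles A `particle_set`.
#' @param organelle `binary_mask` of the organelle (fixed across iterations).
#' @param roi `binary_mask` of the cellular region of interest; every observed
#'   particle must lie inside it.
#' @param statistic `"mean_edge_distance"` or `"fraction_within_nm"`.
#' @param threshold_nm Distance threshold used when
#'   `statistic = "fraction_within_nm"`.
#' @param thresholds_nm Cumulative bins reported in the enrichment table.
#' @param n_iterations Number of random placements (>= 100; 1000 matches the
#'   per-image analysis, 10000 the pooled binned analysis).
#' @param seed Master seed; the same seed reproduces results bit-for-bit.
#' @return A `monte_carlo_result`: observed statistic, null mean/sd, add-one
#'   empirical p, and a per-bin table (observed, expected, fold enrichment,
#'   one-sided p per bin).
#' @export
monte_carlo_null <- function(particles, organelle, roi,
                             statistic = c("mean_edge_distance", "fraction_within_nm"),
                             threshold_nm = 100,
                             thresholds_nm = c(0, 100, 200, 500, 1000),
                             n_iterations = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  .mc_run(list(list(particles = particles, organelle = organelle, roi = roi)),
          statistic, threshold_nm, thresholds_nm, n_iterations, seed)
}

#' Pooled binned-distance enrichment over several images
#'
#' Observed cumulative bin fractions are pooled over all particles of all
#' images; each null iteration randomizes every image's particles within its
#' own ROI and pools the same way. With a single image and the same seed this
#' reduces exactly to [monte_carlo_null()].
#'
#' @param fields List of images, each a list with elements `particles`,
#'   `organelle`, `roi`.
#' @param statistic,threshold_nm,thresholds_nm,seed See [monte_carlo_null()].
#' @param n_iterations Default 10000 for binned enrichment.
#' @return A `monte_carlo_result`.
#' @export
pooled_enrichment <- function(fields, thresholds_nm = c(0, 100, 200, 500, 1000),
                              statistic = c("fraction_within_nm", "mean_edge_distance"),
                              threshold_nm = 100, n_iterations = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  if (!length(fields)) stop("need at least one image", call. = FALSE)
  .mc_run(fields, statistic, threshold_nm, thresholds_nm, n_iterations, seed)
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("<monte_carlo_result> %s: observed %.4g, null %.4g +/- %.4g, p = %.4g (%d iterations, %d particles, %d image(s))\n",
              x$statistic_name, x$observed, x$null_mean, x$null_sd,
              x$empirical_p, x$n_iterations, x$n_particles, x$n_images))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when `n1 * n2 <= 400` and there are no ties; otherwise
#' the normal approximation with mid-rank tie correction and continuity
#' correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A `group_comparison`: `test`, `statistic` (U), `p_two_sided`,
#'   `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) * length(group_b) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  structure(list(test = "mann_whitney_u", statistic = unname(wt$statistic),
                 p_two_sided = wt$p.value, exact = exact,
                 n_a = length(group_a), n_b = length(group_b)),
            class = "group_comparison")
}

#' Fisher's exact test on contact counts (two-sided)
#'
#' Compares contact proportions `contact_a / n_a` vs `contact_b / n_b`;
#' two-sided p sums hypergeometric point probabilities no larger than that of
#' the observed table.
#'
#' @param contact_a,n_a Contact count and total for group A.
#' @param contact_b,n_b Contact count and total for group B.
#' @return A `group_comparison` with the conditional odds-ratio estimate.
#' @export
fisher_exact <- function(contact_a, n_a, contact_b, n_b) {
  if (n_a < 1 || n_b < 1) stop("both groups need n >= 1", call. = FALSE)
  if (contact_a < 0 || contact_a > n_a || contact_b < 0 || contact_b > n_b)
    stop("need 0 <= contact <= n in each group", call. = FALSE)
  tbl <- matrix(c(contact_a, n_a - contact_a, contact_b, n_b - contact_b), nrow = 2)
  ft <- stats::fisher.test(tbl, alternative = "two.sided")
  structure(list(test = "fisher_exact", statistic = unname(ft$estimate),
                 p_two_sided = ft$p.value, n_a = n_a, n_b = n_b),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g (n = %d vs %d)\n",
              x$test, x$statistic, x$p_two_sided, x$n_a, x$n_b))
  invisible(x)
}
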