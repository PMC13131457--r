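#' Threshold specification
#'
#' Describes how a channel is binarized. `otsu` maximizes between-class
#' variance over 256 candidate levels; `percentile` uses the order statistic
#' at the given percentile (type-1 inverse-ECDF quantile); `absolute` uses a
#' fixed intensity. An optional Gaussian pre-smooth (sigma in pixels) is
#' applied before thresholding. Per-image "optimized" thresholds are
#' reproduced by supplying a percentile or absolute override per image; the
#' numeric threshold actually used is recorded on every mask for audit.
#'
#' @param method One of `"otsu"`, `"percentile"`, `"absolute"`.
#' @param percentile Percentile in (0, 100); required iff `method = "percentile"`.
#' @param absolute_value Threshold intensity; required iff `method = "absolute"`.
#' @param pre_smooth_sigma_px Gaussian sigma (px) applied before thresholding;
#'   0 disables smoothing.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("otsu", "percentile", "absolute"),
                           percentile = NULL, absolute_value = NULL,
                           pre_smooth_sigma_px = 0) {
  method <- match.arg(method)
  if (method == "percentile") {
    if (is.null(percentile) || percentile <= 0 || percentile >= 100)
      stop("percentile method needs `percentile` in (0, 100)", call. = FALSE)
  } else if (!is.null(percentile))
    stop("`percentile` only applies to method = 'percentile'", call. = FALSE)
  if (method == "absolute") {
    if (is.null(absolute_value) || !is.finite(absolute_value))
      stop("absolute method needs a finite `absolute_value`", call. = FALSE)
  } else if (!is.null(absolute_value))
    stop("`absolute_value` only applies to method = 'absolute'", call. = FALSE)
  if (pre_smooth_sigma_px < 0) stop("pre_smooth_sigma_px must be >= 0", call. = FALSE)
  structure(list(method = method, percentile = percentile,
                 absolute_value = absolute_value,
                 pre_smooth_sigma_px = pre_smooth_sigma_px),
            class = "threshold_spec")
}

# Exhaustive Otsu: maximize between-class variance over the 255 interior
# edges of a 256-level grid spanning the intensity range. Class statistics are
# exact (per-bin sums of the actual intensities, not bin midpoints).
.otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  span <- rng[2] - rng[1]
  q <- pmin(floor((v - rng[1]) / span * 256), 255)   # bin index 0..255
  cnt <- tabulate(q + 1L, 256L)
  sm <- vapply(split(v, factor(q, levels = 0:255)), sum, numeric(1))
  n <- length(v); tot <- sum(v)
  c0 <- cumsum(cnt)[1:255]; s0 <- cumsum(sm)[1:255]
  w0 <- c0 / n; w1 <- 1 - w0
  valid <- c0 > 0 & c0 < n
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (w0 * w1 * (s0 / c0 - (tot - s0) / (n - c0))^2)[valid]
  k <- which.max(bcv)
  rng[1] + k / 256 * span
}

.smooth_channel <- function(x, sigma) {
  if (sigma <= 0) return(x)
  m <- EBImage::gblur(x, sigma = sigma)
  matrix(as.numeric(m), nrow(x), ncol(x))
}

#' Threshold one channel of an image into a binary mask
#'
#' Foreground is `intensity > threshold` after optional smoothing. The
#' threshold value used is attached to the returned mask as attribute
#' `threshold`.
#'
#' @param image A `calibrated_image`.
#' @param channel Channel name.
#' @param spec A [threshold_spec()].
#' @param role Role tag for the mask.
#' @param allow_degenerate If the (smoothed) channel is constant, Otsu has no
#'   threshold; by default this errors, set `TRUE` to get an empty mask.
#' @return A `binary_mask` with attributes `threshold` and `method`.
#' @export
threshold_channel <- function(image, channel, spec = threshold_spec(),
                              role = "particle", allow_degenerate = FALSE) {
  stopifnot(inherits(spec, "threshold_spec"))
  x <- .smooth_channel(get_channel(image, channel), spec$pre_smooth_sigma_px)
  rng <- range(x)
  thr <- switch(spec$method,
    otsu = {
      if (rng[1] == rng[2]) {
        if (allow_degenerate) rng[2]   # empty mask: nothing exceeds max
        else stop("constant channel: Otsu threshold is degenerate", call. = FALSE)
      } else .otsu_threshold(x)
    },
    percentile = stats::quantile(x, spec$percentile / 100, type = 1, names = FALSE),
    absolute = spec$absolute_value)
  out <- binary_mask(x > thr, image$pixel_size_nm, role)
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "method") <- spec$method
  out
}

#' Size and shape filter for detected particles
#'
#' Retains particles with `min_area_um2 <= area <= max_area_um2`,
#' `solidity >= min_solidity` and `eccentricity <= max_eccentricity`.
#' Defaults select diffraction-limited to small puncta and reject elongated
#' fragments of labelled processes; all bounds are plain config values.
#'
#' @param min_area_um2,max_area_um2 Area window in square microns.
#' @param min_solidity Lower bound on solidity, in `[0, 1]`.
#' @param max_eccentricity Upper bound on eccentricity, in `[0, 1]`.
#' @return An object of class `size_shape_filter`.
#' @export
size_shape_filter <- function(min_area_um2 = 0.03, max_area_um2 = 1.5,
                              min_solidity = 0.6, max_eccentricity = 0.98) {
  if (!(min_area_um2 >= 0 && max_area_um2 > min_area_um2))
    stop("need 0 <= min_area_um2 < max_area_um2", call. = FALSE)
  if (min_solidity < 0 || min_solidity > 1 || max_eccentricity < 0 || max_eccentricity > 1)
    stop("solidity/eccentricity bounds must lie in [0, 1]", call. = FALSE)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_solidity = min_solidity, max_eccentricity = max_eccentricity),
            class = "size_shape_filter")
}

#' Apply a size/shape filter to a particle set
#'
#' @param particles A `particle_set`.
#' @param filter A [size_shape_filter()].
#' @return The filtered `particle_set`; the number of particles removed per
#'   reason is attached as attribute `removed` (a named integer vector).
#' @export
filter_particles <- function(particles, filter = size_shape_filter()) {
  stopifnot(inherits(particles, "particle_set"), inherits(filter, "size_shape_filter"))
  too_small <- particles$area_um2 < filter$min_area_um2
  too_large <- particles$area_um2 > filter$max_area_um2
  low_solidity <- particles$solidity < filter$min_solidity
  too_eccentric <- particles$eccentricity > filter$max_eccentricity
  keep <- !(too_small | too_large | low_solidity | too_eccentric)
  out <- .subset_particles(particles, which(keep))
  attr(out, "removed") <- c(too_small = sum(too_small), too_large = sum(too_large),
                            low_solidity = sum(low_solidity),
                            too_eccentric = sum(too_eccentric))
  out
}

#' Detect neuronal somata from a marker channel
#'
#' Threshold, then morphological opening and closing with a disc brush, hole
#' filling, a minimum-area filter, and connected-component labeling. "Manual
#' verification" of detected somata is reproduced as an explicit `selection`
#' of label ids to keep (never interactive), so runs are replayable.
#'
#' @param image A `calibrated_image`.
#' @param marker_channel Name of the soma marker channel.
#' @param spec Threshold spec for the marker channel.
#' @param min_soma_area_um2 Minimum accepted soma area.
#' @param fill_holes Fill enclosed holes after morphology (default `TRUE`).
#' @param morph_radius_px Disc radius for opening/closing.
#' @param selection Optional integer vector of label ids (as labeled after the
#'   size filter) to keep; labels are then renumbered consecutively.
#' @return A `label_mask` of somata (possibly empty, with a warning).
#' @export
detect_somata <- function(image, marker_channel,
                          spec = threshold_spec("otsu", pre_smooth_sigma_px = 2),
                          min_soma_area_um2 = 50, fill_holes = TRUE,
                          morph_radius_px = 2, selection = NULL) {
  mask <- threshold_channel(image, marker_channel, spec, role = "soma")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (morph_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * morph_radius_px + 1, shape = "disc")
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    m <- matrix(as.numeric(m), nrow(mask), ncol(mask))
  }
  if (fill_holes) m <- matrix(as.numeric(EBImage::fillHull(m)), nrow(mask), ncol(mask))
  labs <- label_connected(binary_mask(m, image$pixel_size_nm, "soma"), 8)
  um2_per_px <- (image$pixel_size_nm / 1000)^2
  areas <- tabulate(labs[labs > 0], nbins = max(0, max(labs)))
  keep <- which(areas * um2_per_px >= min_soma_area_um2)
  out <- matrix(0L, nrow(labs), ncol(labs))
  for (i in seq_along(keep)) out[labs == keep[i]] <- i
  if (!is.null(selection)) {
    sel <- intersect(seq_along(keep), selection)
    out2 <- matrix(0L, nrow(out), ncol(out))
    for (i in seq_along(sel)) out2[out == sel[i]] <- i
    out <- out2
  }
  if (max(out) == 0L) warning("no somata detected", call. = FALSE)
  label_mask(out, image$pixel_size_nm, "soma")
}

#' Delineate the cellular region of interest
#'
#' The ROI bounds random punctum placements in the Monte Carlo null. Three
#' strategies: threshold-and-fill a membrane channel; the convex hull of the
#' union of the mitochondrial and particle masks dilated by a margin
#' (computable from the analysed channels alone, the default); or a
#' user-supplied mask passed through after a dimension check.
#'
#' @param image A `calibrated_image` (used for calibration/dimensions).
#' @param strategy `"membrane_channel"`, `"hull_of_structures"` or `"user_mask"`.
#' @param membrane_channel Channel name (membrane strategy).
#' @param spec Threshold spec for the membrane channel.
#' @param structure_masks List of masks (mitochondria, particles) whose union
#'   is hulled (hull strategy).
#' @param margin_px Euclidean dilation margin for the hull, in pixels.
#' @param user_mask A `binary_mask` (user strategy).
#' @return A `binary_mask` with role `cell_roi`.
#' @export
define_cell_roi <- function(image,
                            strategy = c("hull_of_structures", "membrane_channel", "user_mask"),
                            membrane_channel = NULL, spec = threshold_spec(),
                            structure_masks = NULL, margin_px = 20,
                            user_mask = NULL) {
  strategy <- match.arg(strategy)
  dims <- dim(image$channels[[1]])[1:2]
  roi <- switch(strategy,
    membrane_channel = {
      if (is.null(membrane_channel)) stop("membrane_channel required", call. = FALSE)
      m <- threshold_channel(image, membrane_channel, spec, role = "cell_roi")
      matrix(as.numeric(EBImage::fillHull(matrix(as.numeric(m), dims[1], dims[2]))),
             dims[1], dims[2])
    },
    hull_of_structures = {
      if (is.null(structure_masks) || !length(structure_masks))
        stop("structure_masks required for hull_of_structures", call. = FALSE)
      u <- Reduce(`+`, lapply(structure_masks, function(m) {
        if (!identical(dim(m)[1:2], dims)) stop("mask dimensions differ from image", call. = FALSE)
        matrix(as.numeric(m != 0), dims[1], dims[2])
      }))
      hull <- .fill_convex_hull(u > 0)
      if (margin_px > 0) {
        d <- EBImage::distmap(1 - hull, metric = "euclidean")
        hull <- matrix(as.numeric(d <= margin_px), dims[1], dims[2])
      }
      hull
    },
    user_mask = {
      if (is.null(user_mask)) stop("user_mask required", call. = FALSE)
      if (!identical(dim(user_mask)[1:2], dims))
        stop("user_mask dimensions differ from image", call. = FALSE)
      matrix(as.numeric(user_mask != 0), dims[1], dims[2])
    })
  if (sum(roi) == 0)
    stop("cellular ROI is empty: Monte Carlo randomization cannot run", call. = FALSE)
  binary_mask(roi, image$pixel_size_nm, "cell_roi")
}

# Rasterized filled convex hull of the foreground pixel centres.
.fill_convex_hull <- function(fg) {
  idx <- which(fg)
  nr <- nrow(fg); nc <- ncol(fg)
  if (!length(idx)) return(matrix(0, nr, nc))
  r <- (idx - 1L) %% nr + 1L
  co <- (idx - 1L) %/% nr + 1L
  pts <- unique(cbind(r, co))
  draw_segment <- function(out, p, q) {
    n_steps <- max(abs(q - p)) * 2 + 1
    rr <- pmin(pmax(round(seq(p[1], q[1], length.out = n_steps)), 1), nr)
    cc <- pmin(pmax(round(seq(p[2], q[2], length.out = n_steps)), 1), nc)
    out[cbind(rr, cc)] <- 1
    out
  }
  if (nrow(pts) <= 2L) {
    out <- matrix(0, nr, nc)
    out[pts] <- 1
    if (nrow(pts) == 2L) out <- draw_segment(out, pts[1, ], pts[2, ])
    return(out)
  }
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # point-in-polygon (crossing number), vectorized over the full grid;
  # boundary pixels included via a half-pixel tolerance on the edge test
  gr <- rep(seq_len(nr), nc)
  gc <- rep(seq_len(nc), each = nr)
  inside <- rep(FALSE, nr * nc)
  nh <- length(hx)
  j <- nh
  for (i in seq_len(nh)) {
    cond <- ((hy[i] > gc) != (hy[j] > gc))
    xint <- (hx[j] - hx[i]) * (gc - hy[i]) / (hy[j] - hy[i]) + hx[i]
    inside <- xor(inside, cond & (gr < xint))
    j <- i
  }
  out <- matrix(as.numeric(inside), nr, nc)
  j <- nh
  for (i in seq_len(nh)) {          # hull boundary (covers collinear cases)
    out <- draw_segment(out, c(hx[j], hy[j]), c(hx[i], hy[i]))
    j <- i
  }
  out[cbind(r, co)] <- 1   # original foreground always included
  out
}
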