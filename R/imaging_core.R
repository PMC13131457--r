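#' Calibrated multi-channel image
#'
#' Container for a multi-channel 2-D fluorescence micrograph together with its
#' spatial calibration. Each channel is a numeric matrix (single plane) or a
#' 3-D array `rows x cols x planes` (Z-stack awaiting projection, see
#' [project_z()]). All coordinates in this package are 1-based `(row, col)`
#' with row increasing downward.
#'
#' @param channels Named list of numeric matrices (or 3-D arrays for Z-stacks),
#'   all with identical spatial dimensions; intensities must be finite and
#'   non-negative.
#' @param pixel_size_nm Positive scalar: physical edge length of one pixel in
#'   nanometres. There is no default: nm-scale results are meaningless without
#'   an explicit calibration, so the caller must always supply one.
#' @param source_id Free-text identifier carried through to result tables.
#' @return An object of class `calibrated_image`.
#' @seealso [read_image()], [project_z()]
#' @export
calibrated_image <- function(channels, pixel_size_nm, source_id = "") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must have unique non-empty names", call. = FALSE)
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same height x width", call. = FALSE)
  for (ch in channels) {
    if (!is.numeric(ch) || !(length(dim(ch)) %in% c(2L, 3L)))
      stop("each channel must be a numeric matrix or 3-D array", call. = FALSE)
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  structure(
    list(channels = channels, pixel_size_nm = as.numeric(pixel_size_nm),
         source_id = as.character(source_id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<calibrated_image> %dx%d px, %.3g nm/px, %d channel(s): %s%s\n",
              d[1], d[2], x$pixel_size_nm, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              if (is_zstack(x)) sprintf(" [Z-stack, %d planes]", d[3] %||% dim(x$channels[[1]])[3]) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname calibrated_image
#' @param image A `calibrated_image`.
#' @export
is_zstack <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  any(vapply(image$channels, function(ch) length(dim(ch)) == 3L && dim(ch)[3] > 1L,
             logical(1)))
}

#' Get one channel of a calibrated image as a matrix
#' @param image A `calibrated_image` (single plane).
#' @param channel Channel name.
#' @return Numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!channel %in% names(image$channels))
    stop(sprintf("channel '%s' not found (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  ch <- image$channels[[channel]]
  if (length(dim(ch)) == 3L) {
    if (dim(ch)[3] > 1L)
      stop("channel is a Z-stack; call project_z() first", call. = FALSE)
    ch <- ch[, , 1L]
  }
  ch
}

#' Binary and label masks
#'
#' `binary_mask()` wraps a `{0,1}` raster; `label_mask()` wraps an integer
#' raster in which 0 is background and k > 0 marks object k (labels are
#' consecutive from 1). Both carry the parent calibration as attributes.
#'
#' @param x Matrix (logical or numeric) to wrap.
#' @param pixel_size_nm Calibration inherited from the parent image.
#' @param role Purpose tag, one of `"particle"`, `"mitochondria"`, `"soma"`,
#'   `"cell_roi"`.
#' @return Integer matrix of class `binary_mask` / `label_mask`.
#' @export
binary_mask <- function(x, pixel_size_nm,
                        role = c("particle", "mitochondria", "soma", "cell_roi")) {
  role <- match.arg(role)
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  if (any(is.na(m))) stop("mask contains NA", call. = FALSE)
  structure(m, pixel_size_nm = as.numeric(pixel_size_nm), role = role,
            class = c("binary_mask", class(m)))
}

#' @rdname binary_mask
#' @export
label_mask <- function(x, pixel_size_nm,
                       role = c("particle", "mitochondria", "soma", "cell_roi")) {
  role <- match.arg(role)
  m <- matrix(as.integer(round(x)), nrow(x), ncol(x))
  if (any(is.na(m)) || any(m < 0)) stop("labels must be integers >= 0", call. = FALSE)
  labs <- sort(unique(m[m > 0]))
  if (length(labs) && !identical(labs, seq_along(labs)))
    stop("labels must be consecutive positive integers starting at 1", call. = FALSE)
  structure(m, pixel_size_nm = as.numeric(pixel_size_nm), role = role,
            class = c("label_mask", class(m)))
}

.mask_pixel_size <- function(mask) {
  s <- attr(mask, "pixel_size_nm")
  if (is.null(s)) stop("mask has no pixel_size_nm calibration", call. = FALSE)
  s
}

#' Read a calibrated image from a TIFF file
#'
#' Pages of the TIFF are interpreted as channels (and optionally Z-planes,
#' channel-fastest: page index = `(plane - 1) * n_channels + channel`).
#' Integer TIFF data (8/16-bit) are returned on their native integer scale;
#' 32-bit float data are returned as stored. Pixel size must be supplied
#' explicitly: the TIFF resolution tags are not trusted for nm-scale work.
#'
#' @param path Path to a single- or multi-page TIFF.
#' @param pixel_size_nm Positive scalar, nm per pixel edge.
#' @param channel_names Character vector naming the channels in file order.
#' @param n_planes Number of Z-planes per channel (default 1). The page count
#'   must equal `length(channel_names) * n_planes`.
#' @return A `calibrated_image`; a Z-stack if `n_planes > 1` (project with
#'   [project_z()] before analysis).
#' @export
read_image <- function(path, pixel_size_nm, channel_names, n_planes = 1L) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channel_names)
  if (length(pages) != n_ch * n_planes)
    stop(sprintf("TIFF has %d page(s) but %d channel(s) x %d plane(s) were declared",
                 length(pages), n_ch, n_planes), call. = FALSE)
  unscale <- function(p) {
    if (length(dim(p)) == 3L)
      stop("RGB/multi-sample TIFF pages are not supported; save channels as separate pages",
           call. = FALSE)
    bits <- attr(p, "bits.per.sample") %||% 32L
    fmt <- attr(p, "sample.format") %||% "uint"
    m <- unclass(p)
    attributes(m) <- list(dim = dim(p))
    if (identical(fmt, "uint") || bits %in% c(8L, 16L)) round(m * (2^bits - 1)) else m
  }
  mats <- lapply(pages, unscale)
  chans <- vector("list", n_ch)
  for (ci in seq_len(n_ch)) {
    idx <- (seq_len(n_planes) - 1L) * n_ch + ci
    chans[[ci]] <- if (n_planes == 1L) mats[[idx]] else
      array(unlist(mats[idx]), dim = c(dim(mats[[1]]), n_planes))
  }
  names(chans) <- channel_names
  calibrated_image(chans, pixel_size_nm, source_id = basename(path))
}

#' Write a calibrated image to a 16-bit multi-page TIFF
#'
#' Intensities must be integer-valued in `[0, 65535]` (camera ADU counts, as
#' produced by [render_channels()]); this keeps write/read round trips
#' bit-exact. Channels (and planes, channel-fastest) become pages.
#'
#' @param image A `calibrated_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  to_pages <- function(ch) {
    if (length(dim(ch)) == 3L) lapply(seq_len(dim(ch)[3]), function(p) ch[, , p])
    else list(ch)
  }
  planes <- lapply(image$channels, to_pages)
  n_planes <- length(planes[[1]])
  pages <- list()
  for (p in seq_len(n_planes))
    for (ci in seq_along(planes)) pages <- c(pages, list(planes[[ci]][[p]]))
  for (m in pages) {
    if (max(m) > 65535 || any(m != round(m)))
      stop("write_image() stores 16-bit TIFF: intensities must be integers in [0, 65535]",
           call. = FALSE)
  }
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read / write binary masks as 8-bit TIFF
#'
#' Masks are stored with foreground 255, background 0; any non-zero pixel
#' reads back as foreground.
#'
#' @param path TIFF path.
#' @param pixel_size_nm Calibration for the mask read.
#' @param role Mask role tag (see [binary_mask()]).
#' @return `read_mask()`: a `binary_mask`; `write_mask()`: `path` invisibly.
#' @export
read_mask <- function(path, pixel_size_nm, role = "particle") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  binary_mask(m > 0, pixel_size_nm, role)
}

#' @rdname read_mask
#' @param mask A `binary_mask`.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(ifelse(mask != 0, 1, 0), nrow(mask), ncol(mask)),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' Maximum-intensity Z-projection
#'
#' Collapses each channel of a Z-stack to a single plane by the pixelwise
#' maximum over planes. Single-plane images are returned unchanged. Only
#' maximum projection is offered: it is the standard choice for punctum
#' detection, and alternative projections would change every downstream
#' intensity statistic silently.
#'
#' @param stack A `calibrated_image` (stack or single plane).
#' @param method Projection method; only `"max"`.
#' @return A single-plane `calibrated_image`.
#' @export
project_z <- function(stack, method = "max") {
  stopifnot(inherits(stack, "calibrated_image"))
  method <- match.arg(method, "max")
  proj <- lapply(stack$channels, function(ch) {
    if (length(dim(ch)) == 2L) return(ch)
    if (dim(ch)[3] < 1L) stop("empty stack", call. = FALSE)
    planes <- lapply(seq_len(dim(ch)[3]),
                     function(p) matrix(ch[, , p], dim(ch)[1], dim(ch)[2]))
    Reduce(pmax, planes)
  })
  calibrated_image(proj, stack$pixel_size_nm, stack$source_id)
}

#' Label connected components of a binary mask
#'
#' Components are labeled 1..K in deterministic raster-scan order (the
#' component whose first pixel comes first in row-major order gets label 1).
#' Connectivity 8 (the default for punctate and filamentous structures) joins
#' diagonal neighbours; connectivity 4 does not.
#'
#' @param mask A `binary_mask` (or plain 0/1 matrix plus `pixel_size_nm`).
#' @param connectivity 4 or 8.
#' @param pixel_size_nm Required only if `mask` is a bare matrix.
#' @param role Role tag for the output.
#' @return A `label_mask`.
#' @export
label_connected <- function(mask, connectivity = 8,
                            pixel_size_nm = attr(mask, "pixel_size_nm"),
                            role = attr(mask, "role") %||% "particle") {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (is.null(pixel_size_nm)) stop("pixel_size_nm required", call. = FALSE)
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)          # 4-connectivity
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 8 && max(lab) > 1L)
    lab <- .merge_diagonal_labels(lab)
  lab <- .relabel_raster_order(lab)
  label_mask(lab, pixel_size_nm, role)
}

# Union-find merge of 4-connected labels that touch diagonally -> 8-connectivity.
.merge_diagonal_labels <- function(lab) {
  K <- max(lab)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(pairs)
  for (i in seq_len(nrow(pairs))) union_(pairs[i, 1], pairs[i, 2])
  roots <- vapply(seq_len(K), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

# Relabel so labels appear consecutively in row-major first-pixel order.
.relabel_raster_order <- function(lab) {
  fg <- which(lab > 0)
  if (!length(fg)) return(lab)
  nr <- nrow(lab)
  r <- (fg - 1L) %% nr + 1L
  co <- (fg - 1L) %/% nr + 1L
  ord <- order(r, co)                      # row-major scan
  first <- !duplicated(lab[fg][ord])
  map <- integer(max(lab))
  map[lab[fg][ord][first]] <- seq_len(sum(first))
  lab[fg] <- map[lab[fg]]
  lab
}

#' Extract per-particle measurements from a label mask
#'
#' One record per label: pixel area, area in square microns, intensity-
#' unweighted centroid, mean intensity, solidity (pixel area over the area of
#' the convex hull of the pixel squares) and eccentricity (from second central
#' moments of the pixel centres; 0 for a single pixel, 1 for a degenerate
#' collinear set).
#'
#' @param labels A `label_mask`.
#' @param intensity Numeric matrix of matching dimensions (the channel the
#'   particles were segmented from).
#' @return A `particle_set`: a data frame with columns `id`, `centroid_r`,
#'   `centroid_c`, `area_px`, `area_um2`, `mean_intensity`, `solidity`,
#'   `eccentricity`, carrying per-particle pixel coordinate sets and the
#'   calibration as attributes.
#' @export
extract_particles <- function(labels, intensity) {
  if (!identical(dim(labels)[1:2], dim(intensity)[1:2]))
    stop("labels and intensity must share dimensions", call. = FALSE)
  s <- .mask_pixel_size(labels)
  fg <- which(labels > 0)
  um2_per_px <- (s / 1000)^2
  if (!length(fg)) {
    ps <- data.frame(id = integer(), centroid_r = numeric(), centroid_c = numeric(),
                     area_px = integer(), area_um2 = numeric(),
                     mean_intensity = numeric(), solidity = numeric(),
                     eccentricity = numeric())
    return(.as_particle_set(ps, list(), s, dim(labels)[1:2]))
  }
  nr <- nrow(labels)
  r <- (fg - 1L) %% nr + 1L
  co <- (fg - 1L) %/% nr + 1L
  lb <- labels[fg]
  K <- max(lb)
  coords <- vector("list", K)
  sp <- split(seq_along(fg), lb)
  rows <- lapply(seq_len(K), function(k) {
    ii <- sp[[as.character(k)]]
    rr <- r[ii]; cc <- co[ii]
    coords[[k]] <<- cbind(row = rr, col = cc)
    a <- length(ii)
    data.frame(id = k, centroid_r = mean(rr), centroid_c = mean(cc),
               area_px = a, area_um2 = a * um2_per_px,
               mean_intensity = mean(intensity[cbind(rr, cc)]),
               solidity = a / .hull_area_px(rr, cc),
               eccentricity = .eccentricity(rr, cc))
  })
  .as_particle_set(do.call(rbind, rows), coords, s, dim(labels)[1:2])
}

.as_particle_set <- function(df, coords, pixel_size_nm, dims) {
  structure(df, pixel_coords = coords, pixel_size_nm = pixel_size_nm,
            image_dim = dims, class = c("particle_set", "data.frame"))
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), %.3g nm/px\n",
              nrow(x), attr(x, "pixel_size_nm")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' @rdname extract_particles
#' @param particles A `particle_set`.
#' @export
particle_coords <- function(particles) attr(particles, "pixel_coords")

#' Build a particle set from known pixel coordinates
#'
#' Constructs a `particle_set` directly from per-particle pixel coordinate
#' lists, bypassing segmentation. Used to assemble exactly controlled
#' configurations (worked examples, null-calibration draws); particles may
#' overlap each other.
#'
#' @param coords List of `k x 2` integer matrices of `(row, col)` pixel
#'   coordinates, one matrix per particle.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param pixel_size_nm Calibration.
#' @param intensity Optional intensity matrix for mean-intensity measurements.
#' @return A `particle_set`.
#' @export
particles_from_coords <- function(coords, dim, pixel_size_nm, intensity = NULL) {
  stopifnot(is.list(coords), length(coords) >= 1)
  um2_per_px <- (pixel_size_nm / 1000)^2
  rows <- lapply(seq_along(coords), function(i) {
    px <- coords[[i]]
    if (!is.matrix(px) || ncol(px) != 2 || nrow(px) < 1)
      stop("each element of coords must be a k x 2 matrix", call. = FALSE)
    if (any(px[, 1] < 1 | px[, 1] > dim[1] | px[, 2] < 1 | px[, 2] > dim[2]))
      stop("pixel coordinates out of bounds", call. = FALSE)
    data.frame(id = i, centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
               area_px = nrow(px), area_um2 = nrow(px) * um2_per_px,
               mean_intensity = if (is.null(intensity)) NA_real_ else
                 mean(intensity[px]),
               solidity = nrow(px) / .hull_area_px(px[, 1], px[, 2]),
               eccentricity = .eccentricity(px[, 1], px[, 2]))
  })
  .as_particle_set(do.call(rbind, rows),
                   lapply(coords, function(px) {
                     colnames(px) <- c("row", "col"); px
                   }),
                   pixel_size_nm, as.integer(dim))
}

# Area of the convex hull of the unit squares of the listed pixels.
.hull_area_px <- function(r, c) {
  if (length(r) == 1L) return(1)
  pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.eccentricity <- function(r, c) {
  if (length(r) == 1L) return(0)
  m <- cbind(r, c)
  cv <- stats::cov(m) * (length(r) - 1) / length(r)   # population moments
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Subset a particle_set by row index, keeping coordinate attributes in step.
.subset_particles <- function(particles, keep) {
  df <- as.data.frame(particles)[keep, , drop = FALSE]
  rownames(df) <- NULL
  .as_particle_set(df, particle_coords(particles)[keep],
                   attr(particles, "pixel_size_nm"), attr(particles, "image_dim"))
}
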