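#' Noise and rendering settings for synthetic micrographs
#'
#' Rendering applies, per channel: a constant background offset, a Gaussian
#' point-spread blur of the structure mask, Poisson shot noise on the scaled
#' intensities, additive Gaussian read noise, clipping at zero and rounding to
#' integer camera counts (ADU). Defaults emulate a well-exposed, deconvolved
#' confocal image: peak signal about 9x background with shot-noise-limited
#' statistics.
#'
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 = no blur).
#' @param background Background offset, ADU.
#' @param amplitude Structure amplitude above background, ADU.
#' @param poisson_scaling Photons per ADU for shot noise; 0 disables shot noise.
#' @param gaussian_sd Read-noise standard deviation, ADU (0 disables).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(psf_sigma_px = 1, background = 100, amplitude = 900,
                       poisson_scaling = 1, gaussian_sd = 10) {
  stopifnot(psf_sigma_px >= 0, background >= 0, amplitude > 0,
            poisson_scaling >= 0, gaussian_sd >= 0)
  structure(list(psf_sigma_px = psf_sigma_px, background = background,
                 amplitude = amplitude, poisson_scaling = poisson_scaling,
                 gaussian_sd = gaussian_sd), class = "noise_spec")
}

#' Render ground-truth masks into a noisy calibrated image
#'
#' @param masks Named list of 0/1 matrices (one per channel), shared geometry.
#' @param pixel_size_nm Calibration of the output image.
#' @param noise A [noise_spec()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param quantize Round to integer ADU (default `TRUE`; required for exact
#'   16-bit TIFF round trips).
#' @return A `calibrated_image`.
#' @export
render_channels <- function(masks, pixel_size_nm, noise = noise_spec(),
                            seed = NULL, quantize = TRUE) {
  render <- function() {
    chans <- lapply(masks, function(m) {
      x <- noise$background + noise$amplitude * matrix(as.numeric(m != 0), nrow(m), ncol(m))
      if (noise$psf_sigma_px > 0) x <- .smooth_channel(x, noise$psf_sigma_px)
      if (noise$poisson_scaling > 0)
        x <- stats::rpois(length(x), pmax(x, 0) * noise$poisson_scaling) / noise$poisson_scaling
      if (noise$gaussian_sd > 0) x <- x + stats::rnorm(length(x), 0, noise$gaussian_sd)
      x <- matrix(pmax(x, 0), nrow(m), ncol(m))
      if (quantize) round(x) else x
    })
    calibrated_image(chans, pixel_size_nm, source_id = "synthetic")
  }
  if (is.null(seed)) render() else .with_seed(seed, render())
}

# ---- distance plans ----------------------------------------------------------

#' Punctum distance plans for synthetic apposition fields
#'
#' Three ways to prescribe the true edge-to-edge distances of generated
#' puncta. `gap_plan()` places each punctum at an exact background gap (in
#' whole pixels) from the organelle. `contact_fraction_plan()` places an exact
#' count `round(f * n)` of puncta in contact (overlapping or 8-adjacent) and
#' the rest at edge distances drawn inside `far_gap_nm`.
#' `mixture_plan()` draws target distances from a Gaussian mixture (nm) and
#' places each punctum at the nearest realizable distance.
#'
#' @param gaps_px Integer vector of background gaps (pixels), one per punctum.
#' @return A `distance_plan` list.
#' @export
gap_plan <- function(gaps_px) {
  stopifnot(length(gaps_px) >= 1, all(gaps_px == round(gaps_px)), all(gaps_px >= 1))
  structure(list(type = "gaps", gaps_px = as.integer(gaps_px)), class = "distance_plan")
}

#' @rdname gap_plan
#' @param contact_fraction Fraction of puncta in contact, in `[0, 1]`.
#' @param far_gap_nm Length-2 range (nm) for the edge distances of
#'   non-contact puncta.
#' @export
contact_fraction_plan <- function(contact_fraction = 0.6, far_gap_nm = c(300, 1500)) {
  stopifnot(contact_fraction >= 0, contact_fraction <= 1,
            length(far_gap_nm) == 2, far_gap_nm[1] >= 0, far_gap_nm[2] > far_gap_nm[1])
  structure(list(type = "contact_fraction", contact_fraction = contact_fraction,
                 far_gap_nm = far_gap_nm), class = "distance_plan")
}

#' @rdname gap_plan
#' @param weights Mixture weights (sum 1).
#' @param means_nm Component mean distances, nm.
#' @param sd_nm Common component standard deviation, nm.
#' @export
mixture_plan <- function(weights = c(0.71, 0.29), means_nm = c(440, 2776),
                         sd_nm = 200) {
  stopifnot(length(weights) == length(means_nm), abs(sum(weights) - 1) < 1e-9,
            all(weights > 0), all(means_nm >= 0), sd_nm > 0)
  structure(list(type = "mixture", weights = weights, means_nm = means_nm,
                 sd_nm = sd_nm), class = "distance_plan")
}

#' Specification of a synthetic EV-mitochondria apposition field
#'
#' The mitochondrial network is a union of dilated self-avoiding random
#' walks; EV puncta are discs placed according to a [distance plan][gap_plan].
#' The default plan reproduces the neuronal study condition (60% of puncta in
#' direct contact with the network); `mixture_plan()` with its defaults
#' reproduces the endothelial condition (71%/29% mixture peaking at 440 and
#' 2776 nm).
#'
#' @param image_size_px Square image side, pixels.
#' @param pixel_size_nm Calibration (default 65 nm/px).
#' @param n_filaments,filament_width_px,filament_steps Mitochondrial network
#'   geometry: number, width (px) and length (steps) of the random walks.
#' @param n_puncta Number of EV puncta.
#' @param punctum_radius_px Punctum disc radius (0 = single pixel).
#' @param distance_plan A [distance plan][gap_plan].
#' @param noise A [noise_spec()].
#' @param seed Seed controlling the whole field.
#' @return An `apposition_field_spec` list.
#' @export
apposition_field_spec <- function(image_size_px = 256, pixel_size_nm = 65,
                                  n_filaments = 4, filament_width_px = 3,
                                  filament_steps = 200, n_puncta = 30,
                                  punctum_radius_px = 2,
                                  distance_plan = contact_fraction_plan(),
                                  noise = noise_spec(), seed = 1) {
  stopifnot(image_size_px >= 32, pixel_size_nm > 0, n_filaments >= 1,
            filament_steps >= 2, n_puncta >= 1, punctum_radius_px >= 0,
            inherits(distance_plan, "distance_plan"), inherits(noise, "noise_spec"))
  structure(as.list(environment()), class = "apposition_field_spec")
}

.disk_offsets <- function(r) {
  if (r <= 0) return(cbind(0L, 0L))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ])
}

# Self-avoiding 8-neighbour random walks with direction persistence,
# dilated to the requested width by an exact Euclidean disc.
.generate_filaments <- function(nr, nc, n_filaments, width_px, steps) {
  dirs <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1), dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  ang <- atan2(dirs[, 1], dirs[, 2])
  path <- matrix(FALSE, nr, nc)
  margin <- max(2L, ceiling(width_px / 2) + 1L)
  for (f in seq_len(n_filaments)) {
    trail <- matrix(FALSE, nr, nc)
    pos <- c(sample(margin:(nr - margin), 1), sample(margin:(nc - margin), 1))
    cur <- sample(8, 1)
    trail[pos[1], pos[2]] <- TRUE
    for (st in seq_len(steps)) {
      cand <- which(vapply(1:8, function(d) {
        p <- pos + dirs[d, ]
        p[1] >= margin && p[1] <= nr - margin && p[2] >= margin &&
          p[2] <= nc - margin && !trail[p[1], p[2]]
      }, logical(1)))
      if (!length(cand)) break
      dth <- ang[cand] - ang[cur]
      w <- exp(2 * cos(dth))
      cur <- cand[sample.int(length(cand), 1, prob = w)]
      pos <- pos + dirs[cur, ]
      trail[pos[1], pos[2]] <- TRUE
    }
    path <- path | trail
  }
  radius <- (width_px - 1) / 2
  if (radius > 0) {
    D <- .distance_to_mask(matrix(as.numeric(path), nr, nc))
    matrix(as.numeric(D <= radius + 1e-9), nr, nc)
  } else matrix(as.numeric(path), nr, nc)
}

#' Generate a ground-truthed apposition field
#'
#' Draws the mitochondrial network, places puncta so the distance plan is
#' satisfied exactly on the ground-truth masks (placement is validated against
#' the same pixel-grid edge-distance definition used by
#' [edge_to_edge_distances()]), and renders noisy channels `"mitochondria"`
#' and `"ev"`.
#'
#' @param spec An [apposition_field_spec()].
#' @param max_field_retries Regenerate the filament network up to this many
#'   times if the plan cannot be placed.
#' @return An `apposition_field`: list with `image` (`calibrated_image`),
#'   `mito_mask` (`binary_mask`), `puncta_labels` (`label_mask`), `truth`
#'   (data frame: `id`, `center_r`, `center_c`, `true_edge_nm`,
#'   `true_contact`) and `spec`.
#' @export
generate_apposition_field <- function(spec, max_field_retries = 5) {
  stopifnot(inherits(spec, "apposition_field_spec"))
  .with_seed(spec$seed, {
    for (try in seq_len(max_field_retries)) {
      out <- .try_place_field(spec)
      if (!is.null(out)) return(out)
    }
    stop("distance plan could not be realized within the image after retries",
         call. = FALSE)
  })
}

.try_place_field <- function(spec) {
  nr <- nc <- spec$image_size_px
  s <- spec$pixel_size_nm
  mito <- .generate_filaments(nr, nc, spec$n_filaments, spec$filament_width_px,
                              spec$filament_steps)
  if (sum(mito) == 0) return(NULL)
  offs <- .disk_offsets(spec$punctum_radius_px)
  D <- .distance_to_mask(mito)
  M <- .shift_min(D, offs)
  inb <- .shift_all_true(matrix(TRUE, nr, nc), offs)
  blocked <- matrix(FALSE, nr, nc)
  block_offs <- .disk_offsets(2 * spec$punctum_radius_px + 2)
  plan <- spec$distance_plan
  n <- spec$n_puncta

  # per-punctum candidate predicates on the shape-min distance map M
  targets <- switch(plan$type,
    gaps = {
      if (length(plan$gaps_px) != n)
        stop("gap_plan length must equal n_puncta", call. = FALSE)
      lapply(plan$gaps_px, function(g) list(kind = "exact", d = g + 1))
    },
    contact_fraction = {
      n_contact <- round(plan$contact_fraction * n)
      c(rep(list(list(kind = "contact")), n_contact),
        rep(list(list(kind = "range",
                      lo = plan$far_gap_nm[1], hi = plan$far_gap_nm[2])),
            n - n_contact))
    },
    mixture = {
      comp <- sample.int(length(plan$weights), n, replace = TRUE, prob = plan$weights)
      lapply(comp, function(j) list(kind = "target",
                                    t = stats::rnorm(1, plan$means_nm[j], plan$sd_nm)))
    })

  truth <- data.frame(id = integer(), center_r = integer(), center_c = integer(),
                      true_edge_nm = numeric(), true_contact = logical())
  centers <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    tg <- targets[[i]]
    base <- inb & !blocked
    cand <- switch(tg$kind,
      contact = which(base & M <= 1 + 1e-9),
      exact = which(base & abs(M - tg$d) < 1e-9),
      range = which(base & M > sqrt(2) + 1e-9 &
                      (M - 1) * s > tg$lo & (M - 1) * s <= tg$hi),
      target = {
        if (tg$t <= 0.5 * s) which(base & M <= 1 + 1e-9)
        else {
          idx <- which(base & M > sqrt(2) + 1e-9 &
                         abs((M - 1) * s - tg$t) <= 0.75 * s)
          if (!length(idx))
            idx <- which(base & M > sqrt(2) + 1e-9 &
                           abs((M - 1) * s - tg$t) <= 2 * s)
          idx
        }
      })
    if (!length(cand)) return(NULL)
    pick <- cand[sample.int(length(cand), 1)]
    pr <- (pick - 1L) %% nr + 1L
    pc <- (pick - 1L) %/% nr + 1L
    centers[i, ] <- c(pr, pc)
    contact <- M[pick] <= sqrt(2) + 1e-9
    truth <- rbind(truth, data.frame(
      id = i, center_r = pr, center_c = pc,
      true_edge_nm = if (contact) 0 else (M[pick] - 1) * s,
      true_contact = contact))
    br <- pr + block_offs[, 1]; bc <- pc + block_offs[, 2]
    ok <- br >= 1 & br <= nr & bc >= 1 & bc <= nc
    blocked[cbind(br[ok], bc[ok])] <- TRUE
  }

  puncta <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    rr <- centers[i, 1] + offs[, 1]; cc <- centers[i, 2] + offs[, 2]
    puncta[cbind(rr, cc)] <- i
  }
  image <- render_channels(list(mitochondria = mito, ev = puncta > 0), s, spec$noise)
  structure(list(image = image,
                 mito_mask = binary_mask(mito, s, "mitochondria"),
                 puncta_labels = label_mask(puncta, s, "particle"),
                 truth = truth, spec = spec),
            class = "apposition_field")
}

#' Specification of a synthetic soma field
#'
#' Elliptical somata in a marker channel, each holding a zero-inflated number
#' of EV puncta: with probability `positive_probability` the count is
#' `1 + Poisson(positive_mean - 1)` (a shifted Poisson with mean
#' `positive_mean`), otherwise 0, so the expected dataset mean is
#' `positive_probability * positive_mean`. The defaults reproduce the study
#' condition: 67% of cells positive with an overall mean of 4.2 puncta per
#' cell. A plain Poisson cannot produce that pair (at mean 4.2 it would leave
#' only ~1.5% of cells empty), hence the explicit zero inflation.
#'
#' @param image_size_px Square image side, pixels.
#' @param pixel_size_nm Calibration (default 200 nm/px, a low-magnification
#'   survey scale at which whole somata fit comfortably).
#' @param n_somata Somata per image.
#' @param semi_major_um,semi_minor_um Ranges for the ellipse semi-axes, microns.
#' @param positive_probability Probability a soma contains any puncta.
#' @param positive_mean Mean punctum count of positive somata (>= 1).
#' @param punctum_radius_px Punctum disc radius.
#' @param noise A [noise_spec()].
#' @param seed Seed controlling the whole field.
#' @return A `soma_field_spec` list.
#' @export
soma_field_spec <- function(image_size_px = 512, pixel_size_nm = 200,
                            n_somata = 10, semi_major_um = c(8, 12),
                            semi_minor_um = c(6, 9),
                            positive_probability = 0.67,
                            positive_mean = 4.2 / 0.67,
                            punctum_radius_px = 1, noise = noise_spec(),
                            seed = 1) {
  stopifnot(image_size_px >= 64, pixel_size_nm > 0, n_somata >= 1,
            positive_probability >= 0, positive_probability <= 1,
            positive_mean >= 1, punctum_radius_px >= 0,
            inherits(noise, "noise_spec"))
  structure(as.list(environment()), class = "soma_field_spec")
}

#' Generate a ground-truthed soma field
#'
#' @param spec A [soma_field_spec()].
#' @param max_retries Placement attempts per soma before declaring the field
#'   overcrowded.
#' @return A `soma_field`: list with `image` (channels `"soma"`, `"ev"`),
#'   `soma_labels`, `puncta_labels`, `soma_truth` (data frame: `soma_id`,
#'   `center_r`, `center_c`, `area_px`, `area_um2`, `true_count`),
#'   `puncta_truth` (`id`, `soma_id`, `center_r`, `center_c`) and `spec`.
#' @export
generate_soma_field <- function(spec, max_retries = 200) {
  stopifnot(inherits(spec, "soma_field_spec"))
  .with_seed(spec$seed, .generate_soma_field_impl(spec, max_retries))
}

.generate_soma_field_impl <- function(spec, max_retries) {
  nr <- nc <- spec$image_size_px
  s <- spec$pixel_size_nm
  px_per_um <- 1000 / s
  soma_labels <- matrix(0L, nr, nc)
  occ_d <- matrix(FALSE, nr, nc)   # somata dilated by the separation margin
  soma_rows <- list()
  for (k in seq_len(spec$n_somata)) {
    placed <- FALSE
    for (trial in seq_len(max_retries)) {
      a <- stats::runif(1, spec$semi_major_um[1], spec$semi_major_um[2]) * px_per_um
      b <- stats::runif(1, spec$semi_minor_um[1], spec$semi_minor_um[2]) * px_per_um
      th <- stats::runif(1, 0, pi)
      m <- ceiling(max(a, b)) + 2L
      if (2L * m >= min(nr, nc)) next
      cr <- sample(m:(nr - m), 1); cc <- sample(m:(nc - m), 1)
      rs <- (cr - m):(cr + m); cs <- (cc - m):(cc + m)
      dr <- outer(rs - cr, rep(1, length(cs)))
      dc <- outer(rep(1, length(rs)), cs - cc)
      u <- (dr * cos(th) + dc * sin(th)) / a
      v <- (-dr * sin(th) + dc * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      pix <- cbind(rs[row(inside)[inside]], cs[col(inside)[inside]])
      if (any(occ_d[pix])) next
      soma_labels[pix] <- k
      sub <- matrix(0, nr, nc); sub[pix] <- 1
      occ_d <- occ_d | (.distance_to_mask(sub) <= 8)
      soma_rows[[k]] <- data.frame(soma_id = k, center_r = mean(pix[, 1]),
                                   center_c = mean(pix[, 2]),
                                   area_px = nrow(pix),
                                   area_um2 = nrow(pix) * (s / 1000)^2)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("soma field overcrowded: could not place all somata", call. = FALSE)
  }
  soma_truth <- do.call(rbind, soma_rows)

  # zero-inflated punctum counts per soma
  pos <- stats::runif(spec$n_somata) < spec$positive_probability
  counts <- ifelse(pos, 1 + stats::rpois(spec$n_somata, spec$positive_mean - 1), 0L)
  soma_truth$true_count <- as.integer(counts)

  offs <- .disk_offsets(spec$punctum_radius_px)
  # separation margin: background gap > 4 px between puncta, so that the PSF
  # blur cannot merge neighbours above threshold
  block_offs <- .disk_offsets(2 * spec$punctum_radius_px + 5)
  puncta <- matrix(0L, nr, nc)
  blocked <- matrix(FALSE, nr, nc)
  prow <- list()
  pid <- 0L
  for (k in seq_len(spec$n_somata)) {
    if (counts[k] == 0) next
    sub <- matrix(as.numeric(soma_labels == k), nr, nc)
    depth <- matrix(as.numeric(EBImage::distmap(sub, metric = "euclidean")), nr, nc)
    eligible <- depth >= spec$punctum_radius_px + 2
    for (j in seq_len(counts[k])) {
      cand <- which(eligible & !blocked)
      if (!length(cand))
        stop("soma field overcrowded: punctum placement failed", call. = FALSE)
      pick <- cand[sample.int(length(cand), 1)]
      pr <- (pick - 1L) %% nr + 1L; pc <- (pick - 1L) %/% nr + 1L
      pid <- pid + 1L
      puncta[cbind(pr + offs[, 1], pc + offs[, 2])] <- pid
      prow[[pid]] <- data.frame(id = pid, soma_id = k, center_r = pr, center_c = pc)
      br <- pr + block_offs[, 1]; bc <- pc + block_offs[, 2]
      ok <- br >= 1 & br <= nr & bc >= 1 & bc <= nc
      blocked[cbind(br[ok], bc[ok])] <- TRUE
    }
  }
  puncta_truth <- if (pid) do.call(rbind, prow) else
    data.frame(id = integer(), soma_id = integer(),
               center_r = integer(), center_c = integer())
  image <- render_channels(list(soma = soma_labels > 0, ev = puncta > 0), s, spec$noise)
  structure(list(image = image,
                 soma_labels = label_mask(soma_labels, s, "soma"),
                 puncta_labels = label_mask(puncta, s, "particle"),
                 soma_truth = soma_truth, puncta_truth = puncta_truth,
                 spec = spec),
            class = "soma_field")
}
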