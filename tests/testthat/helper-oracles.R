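# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# iterative flood fill component count (queue-based), connectivity 4 or 8
flood_fill_count <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)) else
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  K <- 0L
  for (start in which(mask != 0)) {
    sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
    if (seen[sr, sc]) next
    K <- K + 1L
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        q <- p + nb[d, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] != 0 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  K
}

# all-pairs minimum pixel-centre distance between particle and organelle pixels
allpairs_min_dist_px <- function(particle_px, organelle_mask) {
  oidx <- which(organelle_mask != 0)
  or <- (oidx - 1L) %% nrow(organelle_mask) + 1L
  oc <- (oidx - 1L) %/% nrow(organelle_mask) + 1L
  min(sqrt(outer(particle_px[, 1], or, `-`)^2 + outer(particle_px[, 2], oc, `-`)^2))
}

# edge distance (nm) from the all-pairs minimum, by the contact definition
allpairs_edge_nm <- function(particle_px, organelle_mask, pixel_size_nm) {
  d <- allpairs_min_dist_px(particle_px, organelle_mask)
  if (d <= sqrt(2) + 1e-9) 0 else (d - 1) * pixel_size_nm
}

# exhaustive Otsu over the 255 interior edges of a 256-level grid, direct
# partition statistics from the raw data
exhaustive_otsu <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  cand <- rng[1] + (1:255) / 256 * (rng[2] - rng[1])
  bcv <- vapply(cand, function(t) {
    fg <- v > t
    w1 <- mean(fg); w0 <- 1 - w1
    if (w1 == 0 || w0 == 0) return(-Inf)
    w0 * w1 * (mean(v[fg]) - mean(v[!fg]))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
enum_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  u_obs <- u_of(a, b)
  pl <- mean(us <= u_obs + 1e-9)
  pu <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(pl, pu))
}

# two-sided Fisher p: sum of hypergeometric point probabilities not exceeding
# the observed table's (relative tolerance as in standard practice)
enum_fisher_p <- function(ka, na, kb, nb) {
  m <- ka + kb
  ks <- max(0, m - nb):min(na, m)
  probs <- stats::dhyper(ks, na, nb, m)
  p_obs <- stats::dhyper(ka, na, nb, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# type-2 (bias-corrected) skewness / excess kurtosis from raw moment formulas
moments_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(skewness = G1, excess_kurtosis = G2)
}

# fixture builders ------------------------------------------------------------

disk_px <- function(center, r) {
  g <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
  g <- g[g[, 1]^2 + g[, 2]^2 <= r^2 + 1e-9, , drop = FALSE]
  cbind(center[1] + g[, 1], center[2] + g[, 2])
}

# horizontal organelle bar plus single-pixel puncta at given background gaps
bar_and_gap_puncta <- function(gaps_px, pixel_size_nm = 31, nr = 48, nc = 96) {
  org <- matrix(0, nr, nc)
  org[20:24, 10:80] <- 1
  coords <- lapply(seq_along(gaps_px), function(i)
    cbind(24 + gaps_px[i] + 1, 10 + 8 * i))
  list(organelle = binary_mask(org, pixel_size_nm, "mitochondria"),
       particles = particles_from_coords(coords, c(nr, nc), pixel_size_nm))
}

random_apposition_fixture <- function(seed, nr = 64, nc = 64, pixel_size_nm = 65) {
  set.seed(seed)
  org <- matrix(rbinom(nr * nc, 1, 0.04), nr, nc)
  if (sum(org) == 0) org[sample(nr * nc, 3)] <- 1
  k <- sample(3:8, 1)
  coords <- lapply(seq_len(k), function(i)
    disk_px(c(sample(4:(nr - 4), 1), sample(4:(nc - 4), 1)), sample(0:2, 1)))
  list(organelle = binary_mask(org, pixel_size_nm, "mitochondria"),
       particles = particles_from_coords(coords, c(nr, nc), pixel_size_nm))
}
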