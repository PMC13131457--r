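make_soma_labels <- function(nr, nc, centers, radii, pixel_size_nm) {
  m <- matrix(0L, nr, nc)
  for (k in seq_along(radii)) m[disk_px(centers[[k]], radii[k])] <- k
  label_mask(m, pixel_size_nm, "soma")
}

test_that("centroid assignment matches point-in-label lookup", {
  somata <- make_soma_labels(64, 64, list(c(16, 16), c(44, 46)), c(10, 12), 200)
  p <- particles_from_coords(list(cbind(16, 16),        # inside soma 1
                                  cbind(44, 40),        # inside soma 2
                                  cbind(1, 1)),         # background
                             c(64, 64), 200)
  expect_equal(assign_particles_to_somata(p, somata), c(1L, 2L, NA))

  # sub-pixel centroid just outside a soma stays unassigned
  edge <- particles_from_coords(list(rbind(c(16, 27), c(16, 28))), c(64, 64), 200)
  expect_equal(edge$centroid_c, 27.5)
  expect_true(is.na(assign_particles_to_somata(edge, somata)))

  # random fields: assignment equals the brute-force lookup
  set.seed(9)
  for (i in 1:10) {
    k <- sample(5:15, 1)
    coords <- lapply(seq_len(k), function(j)
      disk_px(c(sample(5:60, 1), sample(5:60, 1)), sample(0:1, 1)))
    pp <- particles_from_coords(coords, c(64, 64), 200)
    got <- assign_particles_to_somata(pp, somata)
    want <- vapply(seq_len(k), function(j) {
      lab <- somata[floor(pp$centroid_r[j]), floor(pp$centroid_c[j])]
      if (lab > 0) lab else NA_integer_
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("per-soma summaries follow count and density definitions", {
  # one soma of exactly 100 um^2 (2500 px at 200 nm/px) holding 5 particles
  m <- matrix(0L, 80, 80)
  m[16:65, 16:65] <- 1L          # 50 x 50 px = 2500 px = 100 um^2
  somata <- label_mask(m, 200, "soma")
  p <- particles_from_coords(lapply(1:5, function(i) cbind(20 + i, 30)),
                             c(80, 80), 200)
  sq <- summarize_somata(assign_particles_to_somata(p, somata), somata, p)
  expect_equal(sq$per_soma$soma_area_um2, 100)
  expect_equal(sq$per_soma$particle_count, 5L)
  expect_equal(sq$per_soma$particle_density_per_um2, 0.05)
  expect_equal(sq$fraction_of_somata_with_particles, 1)

  # no particles anywhere
  sq0 <- summarize_somata(integer(0),  somata,
                          particles_from_coords(list(cbind(1, 1)), c(80, 80), 200)[0, ])
  expect_equal(sq0$per_soma$particle_count, 0L)
  expect_equal(sq0$fraction_of_somata_with_particles, 0)

  # conservation: total per-soma counts equal the number of assigned particles
  somata2 <- make_soma_labels(64, 64, list(c(16, 16), c(44, 46)), c(10, 12), 200)
  set.seed(10)
  coords <- lapply(1:20, function(j) cbind(sample(64, 1), sample(64, 1)))
  pp <- particles_from_coords(coords, c(64, 64), 200)
  asn <- assign_particles_to_somata(pp, somata2)
  sq2 <- summarize_somata(asn, somata2, pp)
  expect_equal(sum(sq2$per_soma$particle_count), sum(!is.na(asn)))
})

test_that("Pearson correlation uses the exact t-transform p-value", {
  # perfect linear relation
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)

  # p-values recomputed from (r, n) pairs; frozen from the closed form
  expect_equal(round(correlation_p_value(0.579, 32), 4), 0.0005)
  expect_equal(round(correlation_p_value(-0.040, 32), 4), 0.8279)

  # symmetry and affine invariance
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20)
  r1 <- pearson_correlation(a, b)
  r2 <- pearson_correlation(b, a)
  expect_equal(r1$r, r2$r)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
  r3 <- pearson_correlation(3 * a - 7, b / 2 + 1)
  expect_equal(r3$r, r1$r)
  # cor.test agrees with the closed-form transform
  expect_equal(r1$p_two_sided, correlation_p_value(r1$r, 20))

  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("co-label fraction equals the brute-force intersection test", {
  coords <- lapply(1:6, function(i) disk_px(c(8 * i, 20), 1))
  p <- particles_from_coords(coords, c(64, 64), 65)

  union_mask <- matrix(0, 64, 64)
  for (px in coords) union_mask[px] <- 1
  expect_equal(colabel_fraction(p, binary_mask(union_mask, 65)), 1)
  expect_equal(colabel_fraction(p, binary_mask(matrix(0, 64, 64), 65)), 0)
  expect_error(colabel_fraction(p[0, ], binary_mask(union_mask, 65)), "empty")

  set.seed(12)
  for (i in 1:10) {
    q <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
    got <- colabel_fraction(p, binary_mask(q, 65))
    want <- mean(vapply(coords, function(px) any(q[px] == 1), logical(1)))
    expect_equal(got, want)
  }
})

test_that("intensity sums and dots-per-area follow their masked definitions", {
  set.seed(13)
  x <- matrix(runif(64 * 64) * 50, 64, 64)
  img <- calibrated_image(list(green = x), 65)
  expect_equal(channel_total_intensity(img, "green"), sum(x))
  zero <- calibrated_image(list(green = matrix(0, 8, 8)), 65)
  expect_equal(channel_total_intensity(zero, "green"), 0)
  w <- binary_mask(matrix(rbinom(64 * 64, 1, 0.4), 64, 64), 65)
  expect_equal(channel_total_intensity(img, "green", within = w), sum(x[w == 1]))

  # 4 overlapping dots on a 2 um^2 mask -> 2 per um^2 (1000 nm/px: 1 um^2/px)
  om <- matrix(0, 32, 32); om[10:11, 10] <- 1
  omask <- binary_mask(om, 1000)
  dots <- particles_from_coords(list(cbind(10, 10), cbind(11, 10),
                                     cbind(10, 10), cbind(11, 10)),
                                c(32, 32), 1000)
  expect_equal(dots_per_mask_area(dots, omask), 2)
  far <- particles_from_coords(list(cbind(25, 25)), c(32, 32), 1000)
  expect_equal(dots_per_mask_area(far, omask), 0)
  expect_error(dots_per_mask_area(dots, binary_mask(matrix(0, 32, 32), 1000)),
               "empty")
})
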