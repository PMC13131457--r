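test_that("edge distances realize the pixel-grid contact definition", {
  # five single-pixel puncta at background gaps 1..5 px from a bar, 31 nm/px
  fx <- bar_and_gap_puncta(1:5, pixel_size_nm = 31)
  rec <- edge_to_edge_distances(fx$particles, fx$organelle)
  expect_equal(rec$edge_distance_nm, c(31, 62, 93, 124, 155))
  expect_equal(mean(rec$edge_distance_nm), 93)
  expect_false(any(rec$in_contact))

  # overlap and 8-adjacency are contact (0 nm)
  org <- binary_mask({m <- matrix(0, 16, 16); m[8, 8] <- 1; m}, 31, "mitochondria")
  p <- particles_from_coords(list(cbind(8, 8), cbind(9, 9), cbind(8, 10)),
                             c(16, 16), 31)
  rec2 <- edge_to_edge_distances(p, org)
  expect_equal(rec2$in_contact, c(TRUE, TRUE, FALSE))
  expect_equal(rec2$edge_distance_nm, c(0, 0, 31))
  expect_error(edge_to_edge_distances(p, binary_mask(matrix(0, 16, 16), 31)),
               "empty")
})

test_that("edge distances equal the all-pairs brute-force oracle on random fields", {
  for (seed in 1:25) {
    fx <- random_apposition_fixture(seed)
    rec <- edge_to_edge_distances(fx$particles, fx$organelle)
    want <- vapply(particle_coords(fx$particles), allpairs_edge_nm,
                   numeric(1), fx$organelle, 65)
    expect_equal(rec$edge_distance_nm, want)
    # invariants: contact iff 0; edge <= centroid distance
    expect_equal(rec$in_contact, rec$edge_distance_nm == 0)
    expect_true(all(rec$edge_distance_nm <= rec$centroid_distance_nm + 1e-9))
  }
})

test_that("edge distances are rigid-motion invariant and scale with pixel size", {
  fx <- random_apposition_fixture(99)
  rec <- edge_to_edge_distances(fx$particles, fx$organelle)

  # translation of everything by (3, 5)
  shift_px <- function(px) cbind(px[, 1] + 3, px[, 2] + 5)
  org_t <- matrix(0, 72, 72)
  idx <- which(fx$organelle != 0)
  org_t[cbind((idx - 1) %% 64 + 1 + 3, (idx - 1) %/% 64 + 1 + 5)] <- 1
  p_t <- particles_from_coords(lapply(particle_coords(fx$particles), shift_px),
                               c(72, 72), 65)
  rec_t <- edge_to_edge_distances(p_t, binary_mask(org_t, 65))
  expect_equal(rec_t$edge_distance_nm, rec$edge_distance_nm)

  # 90-degree rotation of everything: (r, c) -> (c, N + 1 - r)
  rot <- function(px, N = 64) cbind(px[, 2], N + 1 - px[, 1])
  oi <- which(fx$organelle != 0)
  org_px <- cbind((oi - 1) %% 64 + 1, (oi - 1) %/% 64 + 1)
  org_r <- matrix(0, 64, 64)
  org_r[rot(org_px)] <- 1
  p_r <- particles_from_coords(lapply(particle_coords(fx$particles), rot),
                               c(64, 64), 65)
  rec_r <- edge_to_edge_distances(p_r, binary_mask(org_r, 65))
  expect_equal(sort(rec_r$edge_distance_nm), sort(rec$edge_distance_nm))

  # doubling the pixel size doubles every nm distance
  p2 <- particles_from_coords(particle_coords(fx$particles), c(64, 64), 130)
  org2 <- binary_mask(matrix(as.numeric(fx$organelle != 0), 64, 64), 130)
  rec2 <- edge_to_edge_distances(p2, org2)
  expect_equal(rec2$edge_distance_nm, 2 * rec$edge_distance_nm)
  expect_equal(rec2$centroid_distance_nm, 2 * rec$centroid_distance_nm)
})

test_that("apposition summaries count cumulative bins correctly", {
  mk_rec <- function(e) structure(
    data.frame(particle_id = seq_along(e), edge_distance_nm = e,
               centroid_distance_nm = e + 50, in_contact = e == 0),
    class = c("distance_records", "data.frame"))

  # all in contact
  s1 <- summarize_apposition(mk_rec(rep(0, 7)))
  expect_true(all(s1$bins$fraction == 1))

  # constructed 60% contact field from the generator
  f <- generate_apposition_field(apposition_field_spec(
    n_puncta = 50, distance_plan = contact_fraction_plan(0.6, c(300, 1500)),
    seed = 17))
  parts <- extract_particles(f$puncta_labels, get_channel(f$image, "ev"))
  s2 <- summarize_apposition(edge_to_edge_distances(parts, f$mito_mask))
  expect_equal(s2$bins$fraction[s2$bins$threshold_nm == 0], 0.60)
  expect_equal(s2$bins$fraction[s2$bins$threshold_nm == 200], 0.60)

  # random records vs direct threshold counting; monotone in threshold
  set.seed(14)
  e <- round(runif(40, 0, 1200)); e[sample(40, 10)] <- 0
  s3 <- summarize_apposition(mk_rec(e))
  for (i in seq_len(nrow(s3$bins)))
    expect_equal(s3$bins$fraction[i], mean(e <= s3$bins$threshold_nm[i]))
  expect_true(all(diff(s3$bins$fraction) >= 0))
  expect_error(summarize_apposition(mk_rec(numeric(0))), "no distance")
})

test_that("Monte Carlo null is reproducible, bounded and pooling-consistent", {
  f <- generate_apposition_field(apposition_field_spec(seed = 41))
  parts <- extract_particles(f$puncta_labels, get_channel(f$image, "ev"))
  img <- f$image
  roi <- define_cell_roi(img, "hull_of_structures",
                         structure_masks = list(f$mito_mask,
                                                binary_mask(f$puncta_labels > 0, 65)),
                         margin_px = 20)

  mc1 <- monte_carlo_null(parts, f$mito_mask, roi, "mean_edge_distance",
                          n_iterations = 300, seed = 5)
  mc2 <- monte_carlo_null(parts, f$mito_mask, roi, "mean_edge_distance",
                          n_iterations = 300, seed = 5)
  expect_identical(mc1$empirical_p, mc2$empirical_p)
  expect_identical(mc1$bins, mc2$bins)

  # single-image pooled run with the same seed is the identical computation
  pe <- pooled_enrichment(list(list(particles = parts, organelle = f$mito_mask,
                                    roi = roi)),
                          statistic = "mean_edge_distance",
                          n_iterations = 300, seed = 5)
  expect_equal(pe$observed, mc1$observed)
  expect_identical(pe$bins, mc1$bins)
  expect_identical(pe$empirical_p, mc1$empirical_p)

  # maximal proximity: every particle overlaps the organelle -> floor p
  org <- matrix(0, 64, 64); org[30:34, 30:34] <- 1
  pc <- lapply(1:6, function(i) cbind(30 + (i %% 5), 30 + (i %/% 5)))
  pmax_parts <- particles_from_coords(pc, c(64, 64), 65)
  roi_all <- binary_mask(matrix(1, 64, 64), 65, "cell_roi")
  mc3 <- monte_carlo_null(pmax_parts, binary_mask(org, 65), roi_all,
                          "mean_edge_distance", n_iterations = 199, seed = 3)
  expect_equal(mc3$empirical_p, 1 / 200)

  # two images with disjoint particles: pooled observed fraction is the
  # particle-weighted mean of the per-image fractions
  f2 <- generate_apposition_field(apposition_field_spec(
    n_puncta = 20, distance_plan = contact_fraction_plan(0.2, c(300, 1200)),
    seed = 43))
  parts2 <- extract_particles(f2$puncta_labels, get_channel(f2$image, "ev"))
  roi2 <- define_cell_roi(f2$image, "hull_of_structures",
                          structure_masks = list(f2$mito_mask,
                                                 binary_mask(f2$puncta_labels > 0, 65)),
                          margin_px = 20)
  pe2 <- pooled_enrichment(list(
    list(particles = parts, organelle = f$mito_mask, roi = roi),
    list(particles = parts2, organelle = f2$mito_mask, roi = roi2)),
    n_iterations = 150, seed = 7)
  fr1 <- mean(edge_to_edge_distances(parts, f$mito_mask)$edge_distance_nm == 0)
  fr2 <- mean(edge_to_edge_distances(parts2, f2$mito_mask)$edge_distance_nm == 0)
  n1 <- nrow(parts); n2 <- nrow(parts2)
  expect_equal(pe2$bins$observed_fraction[pe2$bins$threshold_nm == 0],
               (n1 * fr1 + n2 * fr2) / (n1 + n2))

  # planted proximity is detected at the add-one floor
  pe3 <- pooled_enrichment(list(
    list(particles = parts, organelle = f$mito_mask, roi = roi)),
    n_iterations = 999, seed = 11)
  expect_lte(pe3$empirical_p, 0.001)
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small samples", {
  # U = 0 with complete separation: exact two-sided p = 0.1
  r <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 0.1)
  expect_true(r$exact)

  # identical samples -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)

  # enumeration oracle over every split size with n1 + n2 <= 10 (no ties)
  set.seed(15)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    for (rep in 1:2) {
      v <- sample(seq(0.01, 50, by = 0.37), n1 + n2)
      a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
      got <- mann_whitney(a, b)
      expect_equal(got$p_two_sided, enum_mann_whitney_p(a, b),
                   info = sprintf("n1=%d n2=%d", n1, n2))
      expect_gte(got$statistic, 0)
      expect_lte(got$statistic, n1 * n2)
    }
  }
})

test_that("Fisher's exact test equals hypergeometric enumeration on all small tables", {
  expect_equal(fisher_exact(5, 10, 5, 10)$p_two_sided, 1)
  expect_error(fisher_exact(3, 5, 0, 0), "n >= 1")
  expect_error(fisher_exact(6, 5, 1, 10), "0 <= contact")

  for (na in 1:9) for (nb in 1:(10 - na))
    for (ka in 0:na) for (kb in 0:nb)
      expect_equal(fisher_exact(ka, na, kb, nb)$p_two_sided,
                   enum_fisher_p(ka, na, kb, nb), tolerance = 1e-10,
                   info = sprintf("(%d/%d vs %d/%d)", ka, na, kb, nb))
})
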