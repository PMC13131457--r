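test_that("thresholding follows its method definitions", {
  # bimodal two-level image: Otsu separates the bright 10%
  set.seed(1)
  x <- matrix(10, 50, 50)
  bright <- sample(2500, 250)
  x[bright] <- 200
  img <- calibrated_image(list(ch = x), 65)
  m <- threshold_channel(img, "ch", threshold_spec("otsu"))
  expect_setequal(which(m != 0), bright)

  # percentile 99: exactly the 1% of pixels above the order statistic
  y <- matrix(5, 10, 10); y[42] <- 11   # exactly 1% of pixels exceed 5
  img2 <- calibrated_image(list(ch = y), 65)
  m2 <- threshold_channel(img2, "ch", threshold_spec("percentile", percentile = 99))
  expect_equal(which(m2 != 0), 42L)

  # Otsu equals the exhaustive between-class-variance oracle
  set.seed(6)
  for (i in 1:10) {
    z <- matrix(pmax(c(rnorm(2500, 30, 6), rnorm(1596, 150, 20)), 0), 64, 64)
    imgz <- calibrated_image(list(ch = z), 65)
    thr <- attr(threshold_channel(imgz, "ch", threshold_spec("otsu")), "threshold")
    expect_equal(thr, exhaustive_otsu(z), tolerance = 1e-12)
  }

  # constant channel: degenerate unless explicitly allowed
  flat <- calibrated_image(list(ch = matrix(3, 8, 8)), 65)
  expect_error(threshold_channel(flat, "ch", threshold_spec("otsu")), "degenerate")
  m3 <- threshold_channel(flat, "ch", threshold_spec("otsu"), allow_degenerate = TRUE)
  expect_equal(sum(m3), 0)

  # monotonicity: raising an absolute threshold never adds foreground
  set.seed(7)
  w <- matrix(runif(900) * 100, 30, 30)
  imgw <- calibrated_image(list(ch = w), 65)
  prev <- NULL
  for (t in c(10, 30, 50, 70, 90)) {
    cur <- which(threshold_channel(imgw, "ch",
                                   threshold_spec("absolute", absolute_value = t)) != 0)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("threshold_spec validates method-specific parameters", {
  expect_error(threshold_spec("percentile"), "percentile")
  expect_error(threshold_spec("absolute"), "absolute_value")
  expect_error(threshold_spec("otsu", percentile = 50), "only applies")
  expect_silent(threshold_spec("percentile", percentile = 99))
})

test_that("size/shape filtering equals brute-force predicate evaluation and is idempotent", {
  # boundary logic on a constructed set
  coords <- list(cbind(5, 5),                     # 1 px
                 disk_px(c(10, 10), 1),           # 5 px
                 disk_px(c(20, 20), 6))           # 113 px
  ps <- particles_from_coords(coords, c(40, 40), 180)  # 0.0324 um2/px
  f <- size_shape_filter(min_area_um2 = 0.05, max_area_um2 = 1.0,
                         min_solidity = 0, max_eccentricity = 1)
  kept <- filter_particles(ps, f)
  expect_equal(kept$id, 2L)   # 0.032 too small, 3.66 too large

  # identity filter keeps everything
  ident <- size_shape_filter(0, Inf, 0, 1)
  expect_equal(nrow(filter_particles(ps, ident)), 3)

  # random sets: retained rows equal the brute-force predicate, and the
  # filter is idempotent
  set.seed(8)
  for (i in 1:10) {
    mask <- matrix(rbinom(48 * 48, 1, 0.2), 48, 48)
    p <- extract_particles(label_connected(binary_mask(mask, 300), 8),
                           matrix(1, 48, 48))
    f2 <- size_shape_filter(0.05, 0.5, 0.55, 0.95)
    got <- filter_particles(p, f2)
    want <- which(p$area_um2 >= 0.05 & p$area_um2 <= 0.5 &
                    p$solidity >= 0.55 & p$eccentricity <= 0.95)
    expect_equal(got$id, p$id[want])
    again <- filter_particles(got, f2)
    expect_equal(as.data.frame(again), as.data.frame(got), ignore_attr = TRUE)
  }
})

test_that("soma detection recovers ellipse geometry and honours the selection list", {
  # one bright filled ellipse: area within 2% of pi*a*b
  nr <- 128
  m <- matrix(0, nr, nr)
  a <- 20; b <- 10
  for (r in 1:nr) for (co in 1:nr)
    if (((r - 64) / a)^2 + ((co - 64) / b)^2 <= 1) m[r, co] <- 1
  img <- calibrated_image(list(soma = 100 + 900 * m), 1000)  # 1 um/px
  det <- detect_somata(img, "soma", threshold_spec("otsu"), min_soma_area_um2 = 50,
                       morph_radius_px = 2)
  expect_equal(max(det), 1)
  expect_equal(sum(det == 1), pi * a * b, tolerance = 0.02)

  # empty selection reproduces "no soma passes manual verification"
  expect_warning(det0 <- detect_somata(img, "soma", threshold_spec("otsu"),
                                       min_soma_area_um2 = 50,
                                       selection = integer(0)),
                 "no somata")
  expect_equal(max(det0), 0)

  # generated field: one-to-one centroid match with ground truth within 2 px
  sf <- generate_soma_field(soma_field_spec(n_somata = 12, image_size_px = 640,
                                            seed = 21))
  det2 <- detect_somata(sf$image, "soma",
                        threshold_spec("otsu", pre_smooth_sigma_px = 2))
  expect_equal(max(det2), 12)
  p <- extract_particles(det2, get_channel(sf$image, "soma"))
  for (k in seq_len(12)) {
    dd <- sqrt((p$centroid_r - sf$soma_truth$center_r[k])^2 +
                 (p$centroid_c - sf$soma_truth$center_c[k])^2)
    expect_lt(min(dd), 2)
  }
})

test_that("cell ROI strategies satisfy their contracts", {
  img <- calibrated_image(list(ev = matrix(1, 64, 64)), 65)

  # user mask passthrough
  um <- binary_mask(matrix(rbinom(64 * 64, 1, 0.5), 64, 64), 65)
  roi <- define_cell_roi(img, "user_mask", user_mask = um)
  expect_equal(which(roi != 0), which(um != 0))

  # hull of two distant points contains both, dilated by the margin
  pm <- matrix(0, 64, 64); pm[10, 10] <- 1; pm[50, 55] <- 1
  roi2 <- define_cell_roi(img, "hull_of_structures",
                          structure_masks = list(binary_mask(pm, 65)),
                          margin_px = 3)
  expect_true(all(roi2[pm == 1] == 1))
  expect_true(roi2[7, 10] == 1)    # within 3 px of an endpoint
  expect_true(roi2[30, 32] == 1)   # on the segment between them

  # synthetic cell: ROI contains every mitochondrial and particle pixel
  f <- generate_apposition_field(apposition_field_spec(seed = 31))
  roi3 <- define_cell_roi(f$image, "hull_of_structures",
                          structure_masks = list(f$mito_mask,
                                                 binary_mask(f$puncta_labels > 0, 65)),
                          margin_px = 20)
  expect_true(all(roi3[f$mito_mask == 1] == 1))
  expect_true(all(roi3[unclass(f$puncta_labels) > 0] == 1))

  # an empty ROI is an analysis error
  expect_error(define_cell_roi(img, "hull_of_structures",
                               structure_masks = list(binary_mask(matrix(0, 64, 64), 65))),
               "empty")
})
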