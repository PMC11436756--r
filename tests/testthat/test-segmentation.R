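test_that("z and t maximum projections match per-pixel loop oracles", {
  # single plane -> identity
  cal <- calibration(0.1)
  m <- matrix(runif(12), 3, 4)
  st <- image_stack(array(m, c(1, 1, 1, 3, 4)), cal)
  expect_identical(max_project_z(st), m)
  expect_identical(max_project_t(st), m)

  # toy elementwise max over two 1x2 planes
  px <- array(0, c(1, 2, 1, 1, 2))
  px[1, 1, 1, , ] <- c(1, 5); px[1, 2, 1, , ] <- c(3, 2)
  expect_equal(as.vector(max_project_z(image_stack(px, cal))), c(3, 5))

  # random multi-z multi-t stack vs explicit loops
  set.seed(11)
  px <- array(runif(5 * 8 * 2 * 6 * 7), c(5, 8, 2, 6, 7))
  st <- image_stack(px, cal)
  for (ch in 1:2) {
    zproj <- max_project_z(st, ch, t = 3)
    for (y in 1:6) for (x in 1:7)
      expect_identical(zproj[y, x], max(px[3, , ch, y, x]))
    tproj <- max_project_t(st, ch)
    for (y in 1:6) for (x in 1:7)
      expect_identical(tproj[y, x], max(px[, , ch, y, x]))
  }
})

test_that("thresholding is strict and matches per-pixel comparison", {
  expect_equal(mask_area(threshold_mask(matrix(5, 4, 4), 5)), 0)
  m <- threshold_mask(matrix(c(1, 4, 9, 6), 2, 2), 4)
  expect_identical(m$pixels, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  set.seed(21)
  for (rep in 1:20) {
    img <- matrix(sample(0:10, 100, TRUE), 10, 10)
    thr <- sample(0:10, 1)
    expect_identical(threshold_mask(img, thr)$pixels, img > thr)
  }
})

test_that("higher thresholds give subset masks", {
  set.seed(22)
  img <- matrix(rnorm(400, 10, 5), 20, 20)
  lo <- threshold_mask(img, 8)$pixels
  hi <- threshold_mask(img, 12)$pixels
  expect_true(all(lo[hi]))
})

test_that("auto-threshold separates well-separated populations", {
  set.seed(31)
  img <- matrix(10, 20, 20)
  bright <- sample(400, 40)
  img[bright] <- 100
  thr <- auto_threshold(img)
  expect_gt(thr, 10); expect_lt(thr, 100)

  # bimodal Gaussian mixture: recall of true bright pixels >= 99%
  truth <- random_mask(50, 50, 0.3)
  img <- matrix(rnorm(2500, 20, 3), 50, 50)
  img[truth] <- rnorm(sum(truth), 120, 8)
  img <- pmax(img, 0)
  thr <- auto_threshold(img)
  found <- img > thr
  expect_gte(sum(found & truth) / sum(truth), 0.99)

  expect_error(auto_threshold(matrix(7, 5, 5)), "distinct")
})

test_that("size filter drops small components and recompacts labels", {
  # areas {2, 3, 5} with min 3 -> two components remain
  m <- matrix(FALSE, 10, 12)
  m[1, 1:2] <- TRUE          # area 2
  m[4, 4:6] <- TRUE          # area 3
  m[8, 2:6] <- TRUE          # area 5
  ps <- connected_components(m)
  expect_equal(sort(ps$components$area_px), c(2, 3, 5))
  f <- size_filter(ps, 3)
  expect_equal(sort(f$components$area_px), c(3, 5))
  expect_equal(f$components$id, 1:2)
  expect_equal(sum(f$labels > 0), 8)
  # min 1 -> identity
  expect_equal(size_filter(ps, 1)$components$area_px, ps$components$area_px)
  # random masks: surviving area multiset equals filter-then-relabel oracle
  set.seed(41)
  for (rep in 1:10) {
    mk <- random_mask(20, 20, 0.3)
    f <- size_filter(connected_components(mk), 3)
    areas <- oracle_area_multiset(oracle_label(mk))
    expect_equal(sort(f$components$area_px), areas[areas >= 3])
  }
})

test_that("mask smoothing is a 1-px closing: fills gaps, superset, idempotent", {
  # 1-px gap along x between two bars is bridged by the cross element
  m <- matrix(FALSE, 6, 7)
  m[2:4, 2] <- TRUE; m[2:4, 4] <- TRUE
  sm <- smooth_mask(m)
  expect_true(sm$pixels[3, 3])
  # square element bridges even two isolated pixels across a 1-px gap
  m2 <- matrix(FALSE, 5, 7)
  m2[3, 2] <- TRUE; m2[3, 4] <- TRUE
  expect_true(smooth_mask(m2, "square")$pixels[3, 3])
  # solid disk unchanged
  g <- pixel_grid_like <- expand.grid(y = 1:15, x = 1:15)
  disk <- matrix((g$y - 8)^2 + (g$x - 8)^2 <= 16, 15, 15)
  expect_identical(smooth_mask(disk)$pixels, disk)
  # superset + idempotence on random masks; equality with two-step oracle
  elem_cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  elem_sq <- matrix(1, 3, 3)
  set.seed(51)
  for (rep in 1:25) {
    mk <- random_mask(16, 16, 0.25)
    for (el in c("cross", "square")) {
      sm <- smooth_mask(mk, el)$pixels
      expect_true(all(sm[mk]))                       # extensive
      expect_identical(smooth_mask(sm, el)$pixels, sm)  # idempotent
      oracle <- oracle_close(mk, if (el == "cross") elem_cross else elem_sq)
      expect_identical(sm, oracle)
    }
  }
})

test_that("connected components match flood fill under both connectivities", {
  # diagonal touch: one component at 8-connectivity, two at 4
  m <- matrix(FALSE, 6, 6)
  m[2:3, 2:3] <- TRUE; m[4:5, 4:5] <- TRUE
  expect_equal(nrow(connected_components(m, 8)$components), 1)
  expect_equal(nrow(connected_components(m, 4)$components), 2)
  # empty mask
  expect_equal(nrow(connected_components(matrix(FALSE, 4, 4))$components), 0)
  # random masks: labeling equal up to permutation; areas conserve mask area
  set.seed(61)
  for (rep in 1:30) {
    mk <- random_mask(18, 18, 0.35)
    for (conn in c(4L, 8L)) {
      ps <- connected_components(mk, conn)
      lab_o <- oracle_label(mk, conn)
      expect_equal(max(ps$labels), max(lab_o))
      # same partition: each oracle component maps to exactly one label
      for (k in seq_len(max(lab_o)))
        expect_equal(length(unique(ps$labels[lab_o == k])), 1L)
      expect_equal(sum(ps$components$area_px), sum(mk))
      expect_equal(sort(ps$components$area_px), oracle_area_multiset(lab_o))
    }
  }
})

test_that("component centroids are means of member pixel coordinates", {
  m <- matrix(FALSE, 8, 8)
  m[2:3, 5:7] <- TRUE
  comp <- connected_components(m)$components
  expect_equal(comp$centroid_y, 2.5)
  expect_equal(comp$centroid_x, 6)
})

test_that("distance map equals all-pairs brute force and handles edge cases", {
  m <- matrix(FALSE, 6, 6); m[3, 3] <- TRUE
  dm <- distance_map(m, 0.1)
  expect_equal(dm[3, 3], 0)
  expect_equal(dm[3, 4], 0.1)        # 4-neighbour, 0.1 um/px
  expect_equal(dm[4, 4], 0.1 * sqrt(2))
  set.seed(71)
  for (rep in 1:20) {
    mk <- random_mask(15, 15, 0.1)
    if (!any(mk)) mk[8, 8] <- TRUE
    px_sz <- runif(1, 0.05, 0.3)
    expect_lt(max(abs(distance_map(mk, px_sz) -
                        oracle_distance_map(mk, px_sz))), 1e-6)
  }
  # symmetry under transposition for symmetric masks
  mk <- random_mask(12, 12, 0.15); mk <- mk | t(mk)
  expect_equal(distance_map(mk, 0.2), t(distance_map(t(mk), 0.2)))
  expect_warning(dm0 <- distance_map(matrix(FALSE, 4, 4), 0.1), "empty")
  expect_true(all(is.infinite(dm0)))
})
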