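test_that("background estimation recovers known offsets", {
  p <- paint_cell_image(cell_val = 50, comp_val = 50, background = 10)
  expect_equal(estimate_background(p$img, p$cell), 10)
  # user background ROI wins
  roi <- matrix(FALSE, 40, 40); roi[1:5, 1:5] <- TRUE
  p$img[1:5, 1:5] <- 7
  expect_equal(estimate_background(p$img, p$cell, background_roi = roi), 7)
  # noisy frame with known additive offset: within 2 standard errors
  set.seed(201)
  b <- 12
  img <- matrix(rpois(100 * 100, b), 100, 100)
  cell <- matrix(FALSE, 100, 100); cell[30:70, 30:70] <- TRUE
  img[cell] <- img[cell] + 80
  n_ext <- sum(!cell)
  est <- estimate_background(img, cell)
  expect_lt(abs(est - b), 2 * sqrt(b / n_ext) + 1e-9)
})

test_that("enrichment index follows both ratio conventions exactly", {
  # uniform cell -> mean-ratio index 1 for any compartment mask
  p <- paint_cell_image(cell_val = 10, comp_val = 10)
  r <- enrichment_index(p$img, p$comp, p$cell)
  expect_equal(r$index, 1.0)
  # 20 px at 30 inside a 400 px cell otherwise at 10:
  # mean-ratio 30 / 14, integrated-ratio 600 / 1400 (pixel-sum oracle)
  p <- paint_cell_image(cell_val = 10, comp_val = 30)
  r <- enrichment_index(p$img, p$comp, p$cell)
  expect_equal(r$index, 30 / 14, tolerance = 1e-12)
  ri <- enrichment_index(p$img, p$comp, p$cell, convention = "integrated-ratio")
  expect_equal(ri$index, 600 / 1400, tolerance = 1e-12)
  # empty compartment -> index 0 with flag
  expect_warning(r0 <- enrichment_index(p$img, matrix(FALSE, 40, 40), p$cell),
                 "empty")
  expect_equal(r0$index, 0); expect_true(r0$empty_mask)
  # zero cell signal after subtraction -> undefined
  expect_error(enrichment_index(matrix(5, 40, 40), p$comp, p$cell,
                                background = 5), "undefined")
})

test_that("mean-ratio index is gain- and background-invariant", {
  set.seed(211)
  p <- paint_cell_image(cell_val = 20, comp_val = 70)
  img <- p$img + matrix(rnorm(1600, 0, 1), 40, 40)
  img <- pmax(img, 0)
  base <- enrichment_index(img, p$comp, p$cell)$index
  scaled <- enrichment_index(img * 3.7, p$comp, p$cell)$index
  expect_equal(scaled, base, tolerance = 1e-12)
  offset <- enrichment_index(img + 25, p$comp, p$cell, background = 25)$index
  expect_equal(offset, base, tolerance = 1e-12)
})

test_that("mean-ratio is area-independent, integrated-ratio area-proportional", {
  mk_scene <- function(comp_px) {
    img <- matrix(0, 40, 40)
    cell <- matrix(FALSE, 40, 40); cell[1:20, 1:20] <- TRUE
    comp <- matrix(FALSE, 40, 40); comp[seq_len(comp_px)] <- TRUE
    img[cell] <- 10; img[comp] <- 40
    list(img = img, cell = cell, comp = comp)
  }
  s1 <- mk_scene(10); s2 <- mk_scene(20)
  m1 <- enrichment_index(s1$img, s1$comp, s1$cell)$index
  m2 <- enrichment_index(s2$img, s2$comp, s2$cell)$index
  # mean of compartment is 40 either way; cell mean shifts only slightly
  expect_equal(m1 * mean(s1$img[s1$cell]), m2 * mean(s2$img[s2$cell]),
               tolerance = 1e-12)
  i1 <- enrichment_index(s1$img, s1$comp, s1$cell,
                         convention = "integrated-ratio")$index
  i2 <- enrichment_index(s2$img, s2$comp, s2$cell,
                         convention = "integrated-ratio")$index
  expect_equal(i2 / i1, sum(s2$img[s2$comp]) / sum(s1$img[s1$comp]) *
                 sum(s1$img[s1$cell]) / sum(s2$img[s2$cell]), tolerance = 1e-12)
})

test_that("true-mask recovery is exact and Otsu-mask recovery close, over factors", {
  for (fac in c(1, 2, 4, 8)) {
    s <- simulate_static_scene(noiseless_scene(endosome_factor = fac,
                                               cilium_factor = fac,
                                               seed = 300 + fac))
    ac <- max_project_z(s$stack, 2)
    truth <- s$truth$enrichment$endosome$index[1]
    got <- enrichment_index(ac, s$truth$masks$endosomes, s$truth$masks$cell,
                            background = s$truth$config$background)$index
    expect_equal(got, truth, tolerance = 1e-6)
    cil <- cilia_enrichment(s$stack, s$truth$masks$cilium,
                            s$truth$masks$cell,
                            background = s$truth$config$background)
    expect_equal(cil$index, s$truth$enrichment$cilium$index[1],
                 tolerance = 1e-6)
    # estimated masks under camera noise (SNR >= 5): within 15%
    sn <- simulate_static_scene(scene_config(endosome_factor = fac,
                                             seed = 310 + fac))
    r <- endosome_enrichment(sn$stack, region_mask(sn$truth$masks$cell))
    expect_lt(abs(r$index - sn$truth$enrichment$endosome$index[1]) /
                sn$truth$enrichment$endosome$index[1], 0.15)
  }
})

test_that("marker-derived endosome masks match the painted truth", {
  s <- simulate_static_scene(noiseless_scene(endosome_factor = 4))
  marker <- max_project_z(s$stack, 1)
  cell <- region_mask(s$truth$masks$cell)
  # threshold between cell fill and endosome paint recovers the true mask
  m <- endosome_mask_from_marker(marker, cell, threshold = 100)
  expect_identical(m$pixels, s$truth$masks$endosomes)
  # marker uniformly below threshold -> empty mask, enrichment flagged 0
  m0 <- endosome_mask_from_marker(marker, cell, threshold = 1e5)
  expect_equal(mask_area(m0), 0)
  ac <- max_project_z(s$stack, 2)
  expect_warning(r <- enrichment_index(ac, m0, cell), "empty")
  expect_equal(r$index, 0)
})

test_that("puncta counting reproduces painted counts and the >= 10 rule", {
  for (n in c(0L, 10L, 12L)) {
    s <- simulate_static_scene(noiseless_scene(n_endosomes = n,
                                               endosome_factor = 5,
                                               seed = 400 + n))
    ac <- max_project_z(s$stack, 2)
    cls <- count_internal_puncta(ac, s$truth$masks$cell, threshold = 200)
    expect_equal(cls$n_puncta, n)
    expect_equal(cls$positive, n >= 10)
  }
})

test_that("population positivity percentages are exact", {
  cls <- data.frame(positive = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(fraction_positive(cls)$percent, 50.0)
  expect_equal(fraction_positive(data.frame(positive = rep(FALSE, 7)))$percent,
               0.0)
  # simulated population with known counts reproduces the exact percentage
  set.seed(421)
  counts <- c(3, 9, 10, 11, 18, 0, 14, 10, 7, 12)
  cls <- do.call(rbind, lapply(seq_along(counts), function(i) {
    s <- simulate_static_scene(noiseless_scene(n_endosomes = counts[i],
                                               endosome_factor = 5,
                                               soma_radii = c(30, 24),
                                               endosome_radius_range = c(2, 2.5),
                                               seed = 500 + i))
    count_internal_puncta(max_project_z(s$stack, 2), s$truth$masks$cell,
                          threshold = 200, cell_id = as.character(i))
  }))
  expect_equal(cls$n_puncta, counts)
  expect_equal(fraction_positive(cls)$percent, 100 * mean(counts >= 10))
})
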