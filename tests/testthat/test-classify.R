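test_that("PCA matches an independent eigendecomposition on a hand-built matrix", {
  set.seed(21)
  m <- matrix(rnorm(20), 5, 4)
  pca <- run_pca(m, 4)
  eg <- eigen(cov(m), symmetric = TRUE)
  expect_equal(pca$eigenvalues, eg$values[1:4], tolerance = 1e-10)
  # eigenvectors up to sign
  for (k in 1:4) {
    if (eg$values[k] < 1e-12) next
    dot <- abs(sum(pca$eigenvectors[, k] * eg$vectors[, k]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  # eigenvalues equal score variances; vectors orthonormal
  expect_equal(unname(apply(pca$scores, 2, var)), unname(pca$eigenvalues), tolerance = 1e-10)
  expect_equal(t(pca$eigenvectors) %*% pca$eigenvectors, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank reconstruction reproduces the centered data
  centered <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(pca$scores %*% t(pca$eigenvectors), unclass(centered),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("collinear spectra put 100% of variance on the first component", {
  base <- c(1, 2, 3, 4)
  m <- outer(seq(0.5, 2, length.out = 6), base)
  pca <- run_pca(m, 2)
  expect_equal(pca$explained_fraction[1], 1, tolerance = 1e-10)
  expect_error(run_pca(m[1:2, ], 3), "at least")
})

test_that("false-RGB channels are min-max rescaled scores in [0, 1]", {
  set.seed(22)
  g <- image_geometry(4 * 1.56, 4 * 1.56, 1.56)
  m <- matrix(rnorm(16 * 10), 16, 10)
  pca <- run_pca(m, 3)
  arr <- false_rgb(pca, g)
  expect_true(all(arr >= 0 & arr <= 1))
  for (k in 1:3) {
    expect_equal(min(arr[, , k]), 0)
    expect_equal(max(arr[, , k]), 1)
  }
  # scores land at their pixel's (row-major) grid position
  expect_equal(arr[1, 2, 1],
               unname((pca$scores[2, 1] - min(pca$scores[, 1])) / diff(range(pca$scores[, 1]))))
  # two separated spectral populations split along PC1
  m2 <- rbind(matrix(rnorm(8 * 10, 0, 0.1), 8, 10),
              matrix(rnorm(8 * 10, 3, 0.1), 8, 10))
  pca2 <- run_pca(m2, 3)
  ch <- false_rgb(pca2, g)[, , 1]
  ch_flat <- as.vector(t(ch))
  expect_gt(abs(mean(ch_flat[1:8]) - mean(ch_flat[9:16])), 0.5)
})

test_that("constant-score components trigger a zeroed channel with warning", {
  g <- image_geometry(2 * 1.56, 2 * 1.56, 1.56)
  pca <- structure(list(scores = cbind(rnorm(4), rnorm(4), rep(0, 4))),
                   class = "pca_result")
  expect_warning(arr <- false_rgb(pca, g), "constant")
  expect_true(all(arr[, , 3] == 0))
})

test_that("MRS construction averages raw spectra then detrends", {
  sc <- tiny_scene()
  img <- sc$image
  # one selected pixel: MRS is the detrend of that pixel
  sel1 <- data.frame(image_id = "image1", row = 3, col = 3, class = "fiber_G")
  mrs1 <- build_mrs(list(image1 = img), sel1)
  expect_equal(as.numeric(mrs1$spectra["fiber_G", ]),
               detrend(ir_spectrum(img$axis, img$cube[4, 4, ]))$values,
               tolerance = 1e-12)
  # two known pixels: hand-computed mean, then detrend
  sel2 <- data.frame(image_id = "image1", row = c(2, 3), col = c(2, 3),
                     class = "fiber_G")
  mrs2 <- build_mrs(list(image1 = img), sel2)
  hand <- (img$cube[3, 3, ] + img$cube[4, 4, ]) / 2
  expect_equal(as.numeric(mrs2$spectra["fiber_G", ]),
               detrend(ir_spectrum(img$axis, hand))$values, tolerance = 1e-12)
  expect_equal(unname(mrs2$provenance$counts["fiber_G"]), 2L)
  expect_error(build_mrs(list(image1 = img),
                         data.frame(image_id = "image1", row = 999, col = 0,
                                    class = "x")), "out of bounds")
  expect_error(build_mrs(list(image1 = img), sel1[0, ]), "empty")
})

test_that("spearman correlation equals an independent mid-rank Pearson", {
  expect_equal(spearman_cor(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 1)
  a <- c(0.3, 1.2, 2.2, 5, 7)
  expect_equal(spearman_cor(a, exp(-a)), -1)
  # 6-point vectors with ties vs the oracle
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 2, 1, 4, 4, 6)
  expect_equal(spearman_cor(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(spearman_cor(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(1:10, n, replace = TRUE) + rnorm(n, 0, 0.01 * (i %% 2))
    y <- sample(1:10, n, replace = TRUE)
    expect_equal(spearman_cor(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))))
})

test_that("spearman scores are invariant to strictly increasing transforms", {
  set.seed(24)
  ref <- rnorm(50)
  x <- rnorm(50)
  maps <- list(function(v) exp(v), function(v) v^3, function(v) 5 * v - 2,
               function(v) atan(v))
  base <- spearman_cor(x, ref)
  for (f in maps) expect_equal(spearman_cor(f(x), ref), base, tolerance = 1e-12)
})

test_that("the decision rule fires lumen, tie and argmax branches as specified", {
  sc <- rbind(c(0.85, 0.80, 0.70),     # all below 0.90 -> LUMEN
              c(0.950, 0.9495, 0.30),  # < 1% relative gap -> NA
              c(0.95, 0.20, 0.10),     # clear winner
              c(0.95, 0.95, 0.10))     # exact tie -> NA
  dec <- assign_from_scores(sc, c("a", "b", "c"))
  expect_equal(dec$label, c("LUMEN", "NA", "a", "NA"))
  expect_equal(dec$rule, c("LUMEN_THRESHOLD", "NA_TIE", "BEST_CLASS", "NA_TIE"))
  # tie_fraction 0: only exact ties yield NA
  dec0 <- assign_from_scores(sc, c("a", "b", "c"), tie_fraction = 0)
  expect_equal(dec0$label, c("LUMEN", "a", "a", "NA"))
})

test_that("a pixel identical to an MRS gets that class with score 1", {
  sc <- tiny_scene(noise_sd = 0, seed = 1)
  sel <- generate_selections(sc$truth, 5, seed = 2)
  mrs <- build_mrs(list(image1 = sc$image), sel)
  res <- assign_pixels(sc$image, mrs)
  # jitter-free clean classes: class pixels correlate ~1 with their own MRS
  models0 <- lapply(default_models("TW"), function(m) {
    m$amplitude_jitter <- 0; m
  })
  sc0 <- generate_scene(scene_spec(sc$image$geometry, layout = sc$truth$labels,
                                   noise_sd = 0, seed = 1), models0)
  sel0 <- generate_selections(sc0$truth, 5, seed = 2)
  mrs0 <- build_mrs(list(image1 = sc0$image), sel0)
  res0 <- assign_pixels(sc0$image, mrs0)
  i <- which(as.vector(t(sc0$truth$labels)) == "fiber_G")[1]
  expect_equal(unname(res0$scores[i, "fiber_G"]), 1, tolerance = 1e-12)
  expect_equal(res0$label_map$labels[sc0$truth$labels == "fiber_G"][1], "fiber_G")
})

test_that("axis mismatch and degenerate pixels are handled", {
  sc <- tiny_scene()
  sel <- generate_selections(sc$truth, 5, seed = 2)
  mrs <- build_mrs(list(image1 = sc$image), sel)
  other <- sc$image
  other$axis <- spectral_axis(1804, 854, 2)
  expect_error(assign_pixels(other, mrs), "axis")
  # a constant pixel spectrum is labelled lumen via the degenerate rule
  img <- sc$image
  img$cube[1, 1, ] <- 0.5
  res <- assign_pixels(img, mrs)
  expect_equal(res$label_map$labels[1, 1], "LUMEN")
  expect_equal(res$rule_fired[1, 1], "DEGENERATE")
})

test_that("raising the lumen threshold never rescues a lumen pixel", {
  sc <- tiny_scene()
  sel <- generate_selections(sc$truth, 10, seed = 3)
  mrs <- build_mrs(list(image1 = sc$image), sel)
  r1 <- assign_pixels(sc$image, mrs, lumen_threshold = 0.85)
  r2 <- assign_pixels(sc$image, mrs, lumen_threshold = 0.95)
  was_lumen <- r1$label_map$labels == "LUMEN"
  expect_true(all(r2$label_map$labels[was_lumen] == "LUMEN"))
})

test_that("evaluation reproduces hand-built confusion matrices", {
  g <- image_geometry(3 * 1.56, 3 * 1.56, 1.56)
  truth <- label_map(g, matrix(c("a", "a", "b", "b", "a", "b", "a", "b", "b"), 3, 3))
  perfect <- evaluate_assignment(truth, truth)
  expect_equal(unname(perfect$per_class), c(1, 1))
  swapped <- truth$labels
  swapped[3, 3] <- "a"   # one b -> a swap
  ev <- evaluate_assignment(label_map(g, swapped), truth)
  expect_equal(as.vector(ev$confusion), c(4, 1, 0, 4))
  expect_equal(unname(ev$per_class), c(1, 4 / 5))
  all_na <- label_map(g, matrix("NA", 3, 3))
  ev_na <- evaluate_assignment(all_na, truth)
  expect_equal(unname(ev_na$per_class[c("a", "b")]), c(0, 0))
  expect_equal(sum(ev_na$confusion[, "NA"]), 9)
  expect_error(evaluate_assignment(all_na, label_map(image_geometry(2 * 1.56, 2 * 1.56, 1.56),
                                                     matrix("a", 2, 2))), "mismatch")
})

test_that("assigned class composition tracks the generated geometry", {
  sc <- generate_scene(scene_spec())
  sel <- generate_selections(sc$truth, 90, seed = 42)
  mrs <- build_mrs(list(image1 = sc$image), sel)
  res <- assign_pixels(sc$image, mrs)
  for (cl in mrs$classes) {
    truth_frac <- mean(sc$truth$labels == cl)
    pred_frac <- mean(res$label_map$labels == cl)
    expect_lt(abs(truth_frac - pred_frac), 0.05)
  }
})
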