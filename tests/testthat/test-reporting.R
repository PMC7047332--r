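test_that("class-average spectra are pointwise pixel means", {
  sc <- tiny_scene()
  img <- sc$image
  avg <- class_average_spectra(img, sc$truth)
  expect_false(any(c("LUMEN", "NA") %in% names(avg)))
  m <- pixel_matrix(img)
  labs <- as.vector(t(sc$truth$labels))
  expect_equal(avg$fiber_G$values, colMeans(m[labs == "fiber_G", ]),
               tolerance = 1e-12)
  # a single-pixel class averages to that pixel's spectrum
  g <- img$geometry
  one <- sc$truth$labels
  one[one == "ray_S"] <- "fiber_S"
  one[20, 20] <- "ray_S"
  avg1 <- class_average_spectra(img, label_map(g, one))
  expect_equal(avg1$ray_S$values, img$cube[20, 20, ], tolerance = 1e-12)
})

test_that("class averages sit within 3 standard errors of the clean model", {
  sc <- tiny_scene(noise_sd = 0.01, seed = 7)
  avg <- class_average_spectra(sc$image, sc$truth)
  for (cl in names(avg)) {
    n <- sum(sc$truth$labels == cl)
    clean <- clean_spectrum(sc$models[[cl]], sc$image$axis)$values
    se <- sqrt(0.01^2 + (0.05 * clean)^2) / sqrt(n)  # noise + amplitude jitter
    frac_inside <- mean(abs(avg[[cl]]$values - clean) <= 3 * pmax(se, 0.01 / sqrt(n)))
    expect_gte(frac_inside, 0.99)
  }
})

test_that("loadings are eigenvector times eigenvalue with positive orientation", {
  set.seed(41)
  m <- matrix(rnorm(40), 10, 4)
  pca <- run_pca(m, 4)
  L <- pca_loadings(pca)
  eg <- eigen(cov(m), symmetric = TRUE)
  for (k in 1:4) {
    v <- eg$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(L[, k], v * eg$values[k], tolerance = 1e-8, ignore_attr = TRUE)
    expect_gt(L[which.max(abs(L[, k])), k], 0)
  }
  # unit eigenvalue: loading equals eigenvector; sqrt scaling differs by sqrt(ev)
  Ls <- pca_loadings(pca, scaling = "sqrt_eigenvalue")
  expect_equal(Ls[, 1], L[, 1] / sqrt(pca$eigenvalues[1]), tolerance = 1e-8)
  # zero eigenvalue (rank-deficient data) gives a zero loading vector
  flat <- rbind(c(1, 0), c(2, 0), c(3, 0))
  p2 <- run_pca(flat, 2)
  L2 <- pca_loadings(p2)
  expect_equal(L2[, 2], c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("heatmap columns are z-scaled and descale back to the raw matrix", {
  sc <- tiny_scene()
  sel <- generate_selections(sc$truth, 10, seed = 5)
  mrs <- build_mrs(list(image1 = sc$image), sel)
  res <- assign_pixels(sc$image, mrs)
  m <- pixel_matrix(sc$image)
  labs <- as.vector(t(sc$truth$labels))
  sets <- lapply(c("fiber_G", "fiber_S"), function(cl)
    class_spectra_set(cl, m[labs == cl, , drop = FALSE], sc$image$axis))
  dawns <- find_dawns(sets)
  # two "images" so rows exceed classes
  hm <- heatmap_matrix(list(im1 = sc$image, im2 = sc$image),
                       list(res, res), dawns)
  expect_equal(colMeans(hm$scaled), rep(0, ncol(hm$scaled)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(hm$scaled, 2, sd), rep(1, ncol(hm$scaled)),
               tolerance = 1e-10, ignore_attr = TRUE)
  descale <- sweep(sweep(hm$scaled, 2, apply(hm$raw, 2, sd), `*`),
                   2, colMeans(hm$raw), `+`)
  expect_equal(descale, hm$raw, tolerance = 1e-10)
})

test_that("correlation distances behave at the extremes and match brute force", {
  # perfectly correlated columns merge first at height 0; anticorrelated at 2
  raw <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
               d = c(1.5, 0.5, 3.2, 0.1))
  h <- irwall:::correlation_hclust(raw, margin = 2)
  expect_equal(min(h$height), 0, tolerance = 1e-12)
  first <- sort(h$merge[1, ])
  expect_equal(first, c(-2, -1))  # columns a and b
  d_ac <- 1 - cor(raw[, "b"], raw[, "c"])
  expect_equal(d_ac, 2, tolerance = 1e-12)
  # 4x4 fixture: linkage heights match a brute-force agglomeration trace
  set.seed(42)
  m <- matrix(rnorm(16), 4, 4)
  h2 <- irwall:::correlation_hclust(m, margin = 2)
  dm <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) dm[i, j] <- 1 - cor(m[, i], m[, j])
  expect_equal(h2$height, oracle_average_linkage_heights(dm), tolerance = 1e-10)
  # constant column: distance pinned at 1 with a warning
  mc <- cbind(m[, 1:2], rep(1, 4))
  expect_warning(h3 <- irwall:::correlation_hclust(mc, margin = 2), "constant")
})

test_that("absorbance images scale intensity over the shown classes", {
  sc <- tiny_scene()
  out <- absorbance_image(sc$image, sc$truth, 1316,
                          classes_shown = c("fiber_G", "fiber_S"))
  expect_equal(out$sigma_used, 1316)
  inten <- out$intensity[!is.na(out$intensity)]
  expect_equal(range(inten), c(0, 1))
  # G-layer pixels carry the stronger 1316 band than S pixels
  gmask <- sc$truth$labels == "fiber_G"; smask <- sc$truth$labels == "fiber_S"
  expect_gt(mean(out$intensity[gmask]), mean(out$intensity[smask]))
  # lumen black, NA white in the rendering
  lum <- which(sc$truth$labels == "LUMEN", arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(out$rgb[lum[1], lum[2], ]), c(0, 0, 0))
  expect_error(absorbance_image(sc$image, sc$truth, 500), "outside")
  # uniform absorbance renders uniformly
  img2 <- sc$image
  img2$cube[, , ] <- 0.3
  out2 <- absorbance_image(img2, sc$truth, 1316, classes_shown = "fiber_G")
  expect_equal(length(unique(out2$intensity[gmask])), 1)
  # a single bright pixel is the only one at full intensity
  img3 <- sc$image
  img3$cube[, , ] <- 0.1
  img3$cube[2, 2, ] <- 5
  out3 <- absorbance_image(img3, sc$truth, 1316, classes_shown = "fiber_G")
  expect_equal(out3$intensity[2, 2], 1)
  expect_equal(sum(out3$intensity[gmask] == 1), 1)
})

test_that("score-plot ellipses have the chi-square geometry and coverage", {
  # isotropic unit-variance class: circle of radius sqrt(qchisq(.95, 2))
  set.seed(43)
  n <- 20000
  scores <- cbind(rnorm(n), rnorm(n))
  pca <- structure(list(scores = scores), class = "pca_result")
  spd <- score_plot_data(pca, rep("a", n))
  e <- spd$ellipses$a
  r <- sqrt(rowSums(sweep(e$polygon, 2, e$center)^2))
  expect_equal(mean(r), sqrt(qchisq(0.95, 2)), tolerance = 0.05)
  expect_equal(sqrt(e$radius2), 2.4477, tolerance = 1e-3)
  # ~95% of simulated bivariate-normal points fall inside (+/- 1%)
  expect_equal(ellipse_coverage(spd, "a"), 0.95, tolerance = 0.011)
  # level 0 collapses the ellipse to the mean point
  spd0 <- score_plot_data(pca, rep("a", n), level = 0)
  expect_equal(max(abs(sweep(spd0$ellipses$a$polygon, 2, spd0$ellipses$a$center))),
               0, tolerance = 1e-10)
  # degenerate covariance is flagged
  line <- cbind(1:10, (1:10) * 2)
  pl <- structure(list(scores = line), class = "pca_result")
  expect_warning(spdl <- score_plot_data(pl, rep("a", 10)), "degenerate")
  expect_true(spdl$ellipses$a$degenerate)
  expect_error(score_plot_data(pca, rep("a", 5)), "length")
})
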