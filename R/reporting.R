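## Derived views: class-average spectra, PCA loadings, column-scaled heatmap
## matrices with correlation-distance dendrograms, single-wavenumber
## absorbance renderings and score-plot ellipses.

#' Class-average spectra of an assigned image
#'
#' Arithmetic mean spectrum over the pixels carrying each cell-wall label;
#' lumen and unassigned pixels are excluded.
#'
#' @param image an [hsi_image()].
#' @param assignment matching `assignment_result` (or any [label_map()]).
#' @param exclude labels to skip.
#' @return named list of [ir_spectrum()], one per non-empty class.
#' @export
class_average_spectra <- function(image, assignment, exclude = c("LUMEN", "NA")) {
  map <- if (inherits(assignment, "assignment_result")) assignment$label_map else assignment
  stopifnot(inherits(image, "hsi_image"), inherits(map, "label_map"))
  if (!geometries_equal(image$geometry, map$geometry))
    stop("assignment does not match image geometry")
  m <- pixel_matrix(image)
  labs <- as.vector(t(map$labels))
  classes <- setdiff(sort(unique(labs)), exclude)
  out <- list()
  for (cl in classes) {
    sel <- labs == cl
    if (!any(sel)) {
      warning(sprintf("class '%s' has no pixels; omitted", cl))
      next
    }
    out[[cl]] <- ir_spectrum(image$axis, colMeans(m[sel, , drop = FALSE]))
  }
  out
}

#' PCA loadings
#'
#' Loading vector k = eigenvector k x eigenvalue k (the product with the
#' variance, not its square root); the conventional square-root scaling is
#' available via `scaling = "sqrt_eigenvalue"`. Sign convention: the
#' largest-magnitude element of each eigenvector is made positive.
#'
#' @param pca a `pca_result`.
#' @param scaling `"eigenvalue"` (default) or `"sqrt_eigenvalue"`.
#' @return matrix (wavenumbers x components) of loadings.
#' @export
pca_loadings <- function(pca, scaling = c("eigenvalue", "sqrt_eigenvalue")) {
  stopifnot(inherits(pca, "pca_result"))
  scaling <- match.arg(scaling)
  vec <- pca$eigenvectors
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  fac <- if (scaling == "eigenvalue") pca$eigenvalues else sqrt(pca$eigenvalues)
  sweep(vec, 2, fac, `*`)
}

#' Heatmap matrix over passing DAWNs
#'
#' Rows are (image id x class) units, columns the distinct passing DAWN
#' wavenumbers. Each value is the mean absorbance of that image's pixels of
#' that class at that wavenumber. The display matrix is z-scaled per column;
#' dendrograms come from average-linkage hierarchical clustering with distance
#' 1 - Pearson correlation computed on the unscaled values (columns) and on
#' the unscaled rows.
#'
#' @param images named list of [hsi_image()].
#' @param assignments matching list of `assignment_result` (or label maps).
#' @param dawns a `dawn_table` with a filled `passes` column.
#' @param exclude labels excluded from rows.
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @return a `heatmap_input`: `raw`, `scaled`, `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`.
#' @export
heatmap_matrix <- function(images, assignments, dawns,
                           exclude = c("LUMEN", "NA"), linkage = "average") {
  if (inherits(images, "hsi_image")) {
    images <- list(image1 = images); assignments <- list(assignments)
  }
  if (is.null(names(images))) names(images) <- paste0("image", seq_along(images))
  sigmas <- sort(unique(dawns$sigma_cm[dawns$passes]), decreasing = TRUE)
  if (length(sigmas) < 2) stop("need at least 2 passing DAWN wavenumbers")
  rows <- list()
  for (i in seq_along(images)) {
    avg <- class_average_spectra(images[[i]], assignments[[i]], exclude)
    bands <- match_sigma(sigmas, images[[i]]$axis)
    for (cl in names(avg))
      rows[[paste(names(images)[i], cl, sep = ":")]] <- avg[[cl]]$values[bands]
  }
  if (length(rows) < 2) stop("need at least 2 (image x class) rows")
  raw <- do.call(rbind, rows)
  colnames(raw) <- sprintf("%.10g", sigmas)
  scaled <- scale_columns(raw)
  col_h <- correlation_hclust(raw, margin = 2, linkage = linkage)
  row_h <- correlation_hclust(raw, margin = 1, linkage = linkage)
  structure(list(raw = raw, scaled = scaled,
                 row_hclust = row_h, col_hclust = col_h,
                 row_order = row_h$order, col_order = col_h$order,
                 sigmas = sigmas),
            class = "heatmap_input")
}

match_sigma <- function(sigmas, axis) {
  vapply(sigmas, function(s) which.min(abs(as.numeric(axis) - s)), 1L)
}

scale_columns <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    out[, j] <- if (is.finite(s) && s > 0) (m[, j] - mean(m[, j])) / s else 0
  }
  out
}

correlation_hclust <- function(m, margin, linkage = "average") {
  x <- if (margin == 2) t(m) else m   # rows of x are the units clustered
  n <- nrow(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning("constant unit in correlation distance; distance set to 1")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (sds[i] == 0 || sds[j] == 0) 1
      else 1 - stats::cor(x[i, ], x[j, ])
  }
  rownames(d) <- rownames(x)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Single-wavenumber absorbance rendering
#'
#' Pixels of the selected classes are coloured in their class hue with
#' intensity proportional to the min-max scaled absorbance at the requested
#' wavenumber (nearest axis grid point, which is recorded); lumen renders
#' black, unassigned white, other classes in their flat palette colour.
#'
#' @param image an [hsi_image()].
#' @param assignment matching `assignment_result` or [label_map()].
#' @param sigma_cm requested wavenumber; must lie within the axis range.
#' @param classes_shown classes rendered with absorbance intensity.
#' @return list: `rgb` array (rows x cols x 3), `sigma_used`, `intensity`
#'   matrix (NA outside the shown classes).
#' @export
absorbance_image <- function(image, assignment, sigma_cm,
                             classes_shown = NULL) {
  map <- if (inherits(assignment, "assignment_result")) assignment$label_map else assignment
  stopifnot(inherits(image, "hsi_image"), inherits(map, "label_map"))
  wn <- as.numeric(image$axis)
  if (sigma_cm > max(wn) || sigma_cm < min(wn))
    stop(sprintf("sigma %.6g cm^-1 outside axis range [%.6g, %.6g]",
                 sigma_cm, min(wn), max(wn)))
  band <- which.min(abs(wn - sigma_cm))
  slab <- image$cube[, , band]
  labs <- map$labels
  if (is.null(classes_shown))
    classes_shown <- setdiff(sort(unique(as.vector(labs))), c("LUMEN", "NA"))
  shown <- labs %in% classes_shown
  intensity <- matrix(NA_real_, nrow(labs), ncol(labs))
  if (any(shown)) {
    v <- slab[shown]
    rng <- range(v)
    intensity[shown] <- if (diff(rng) == 0) 1 else (v - rng[1]) / diff(rng)
  }
  pal <- class_palette(sort(unique(as.vector(labs))))
  base_rgb <- grDevices::col2rgb(pal[labs]) / 255
  arr <- array(0, c(nrow(labs), ncol(labs), 3))
  for (k in 1:3) {
    ch <- matrix(base_rgb[k, ], nrow(labs), ncol(labs))
    ch[shown] <- ch[shown] * intensity[shown]
    arr[, , k] <- ch
  }
  list(rgb = arr, sigma_used = wn[band], intensity = intensity)
}

#' Score-plot data with normal-confidence ellipses
#'
#' Per class, the mean and covariance of the (PC1, PC2) scores and the
#' covariance ellipse at the chi-square(2 df) quantile of the requested
#' coverage level (95% of the data under a bivariate normal by default).
#'
#' @param pca a `pca_result` with >= 2 components.
#' @param labels per-observation class labels (length = rows of scores).
#' @param level coverage level in [0, 1).
#' @param components the two components plotted (default 1:2).
#' @return a `score_plot_data` list: `points` data frame (x, y, label) and
#'   `ellipses` — per class: `center`, `cov`, `radius2` (the chi-square
#'   quantile), `polygon` (100-point outline), `degenerate` flag.
#' @export
score_plot_data <- function(pca, labels, level = 0.95, components = c(1L, 2L)) {
  stopifnot(inherits(pca, "pca_result"))
  if (ncol(pca$scores) < max(components)) stop("not enough components")
  if (length(labels) != nrow(pca$scores))
    stop("labels length must match number of score rows")
  xy <- pca$scores[, components, drop = FALSE]
  points <- data.frame(x = xy[, 1], y = xy[, 2], label = as.character(labels))
  ell <- list()
  for (cl in sort(unique(points$label))) {
    sel <- points$label == cl
    if (sum(sel) < 3) stop(sprintf("class '%s' has fewer than 3 points", cl))
    ctr <- colMeans(xy[sel, , drop = FALSE])
    S <- stats::cov(xy[sel, , drop = FALSE])
    r2 <- stats::qchisq(level, df = 2)
    eg <- eigen(S, symmetric = TRUE)
    degenerate <- any(eg$values <= .Machine$double.eps * max(eg$values, 1))
    theta <- seq(0, 2 * pi, length.out = 100)
    axes_len <- sqrt(pmax(eg$values, 0) * r2)
    ring <- cbind(cos(theta) * axes_len[1], sin(theta) * axes_len[2]) %*% t(eg$vectors)
    poly <- sweep(ring, 2, ctr, `+`)
    ell[[cl]] <- list(center = ctr, cov = S, radius2 = r2,
                      polygon = poly, degenerate = degenerate)
    if (degenerate)
      warning(sprintf("class '%s' has a degenerate covariance; ellipse collapsed", cl))
  }
  structure(list(points = points, ellipses = ell, level = level),
            class = "score_plot_data")
}

#' Fraction of a class's points inside its confidence ellipse
#'
#' Convenience for calibration checks: squared Mahalanobis distance of each
#' point from its class mean compared against the ellipse's chi-square radius.
#'
#' @param spd a `score_plot_data`.
#' @param class_name class to evaluate.
#' @return fraction of that class's points inside (on-boundary counts as in).
#' @export
ellipse_coverage <- function(spd, class_name) {
  e <- spd$ellipses[[class_name]]
  if (is.null(e)) stop(sprintf("no ellipse for class '%s'", class_name))
  sel <- spd$points$label == class_name
  xy <- as.matrix(spd$points[sel, c("x", "y")])
  centered <- sweep(xy, 2, e$center)
  d2 <- rowSums((centered %*% solve(e$cov)) * centered)
  mean(d2 <= e$radius2)
}
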