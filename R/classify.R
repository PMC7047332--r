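## Pixel classification: PCA exploration, mean representative spectra (MRS)
## and the Spearman correlation-score assignment rule.

#' Principal component analysis of pixel spectra
#'
#' Mean-centered PCA with no variable scaling (raw spectra): singular-value
#' decomposition of the centered pixel-by-wavenumber matrix.
#'
#' @param spectra numeric matrix (pixels x wavenumbers), a list of
#'   [ir_spectrum()] on a shared axis, or an [hsi_image()].
#' @param n_components number of components to retain.
#' @return a `pca_result` with `scores`, `eigenvalues` (score variances),
#'   `eigenvectors` (unit-norm columns), `explained_fraction`, `center`.
#' @export
run_pca <- function(spectra, n_components = 3L) {
  m <- spectra_as_matrix(spectra)
  n_components <- as.integer(n_components)
  if (nrow(m) < n_components)
    stop(sprintf("need at least %d spectra for %d components, have %d",
                 n_components, n_components, nrow(m)))
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  k <- seq_len(min(n_components, ncol(fit$rotation)))
  structure(list(scores = fit$x[, k, drop = FALSE],
                 eigenvalues = fit$sdev[k]^2,
                 eigenvectors = fit$rotation[, k, drop = FALSE],
                 explained_fraction = fit$sdev[k]^2 / total_var,
                 center = fit$center,
                 total_variance = total_var),
            class = "pca_result")
}

spectra_as_matrix <- function(spectra) {
  if (inherits(spectra, "hsi_image")) return(pixel_matrix(spectra))
  if (is.matrix(spectra)) return(spectra)
  if (is.list(spectra) && all(vapply(spectra, inherits, TRUE, "ir_spectrum"))) {
    ax <- spectra[[1]]$axis
    ok <- vapply(spectra, function(s) axes_equal(s$axis, ax), TRUE)
    if (!all(ok)) stop("spectra do not share one axis")
    return(do.call(rbind, lapply(spectra, `[[`, "values")))
  }
  stop("cannot interpret 'spectra' as a collection of spectra")
}

#' False-RGB composite from PCA scores
#'
#' Red, green and blue channels are the pixel scores on PC1, PC2 and PC3,
#' each min-max rescaled to [0, 1] over the image.
#'
#' @param pca a `pca_result` with >= 3 components whose scores cover the grid.
#' @param geometry an [image_geometry()].
#' @param channel_order indices of the components mapped to (R, G, B).
#' @return numeric array (n_rows, n_cols, 3) in [0, 1].
#' @export
false_rgb <- function(pca, geometry, channel_order = c(1L, 2L, 3L)) {
  stopifnot(inherits(pca, "pca_result"), inherits(geometry, "image_geometry"))
  if (ncol(pca$scores) < max(channel_order)) stop("need at least 3 components")
  if (nrow(pca$scores) != geometry$n_pixels)
    stop("score rows do not match geometry pixel count")
  arr <- array(0, c(geometry$n_rows, geometry$n_cols, 3))
  for (k in 1:3) {
    v <- pca$scores[, channel_order[k]]
    rng <- range(v)
    if (diff(rng) == 0) {
      warning(sprintf("component %d has constant scores; channel set to 0",
                      channel_order[k]))
      ch <- rep(0, length(v))
    } else ch <- (v - rng[1]) / diff(rng)
    arr[, , k] <- matrix(ch, geometry$n_rows, geometry$n_cols, byrow = TRUE)
  }
  arr
}

#' Build mean representative spectra (MRS)
#'
#' For each cell-wall class, averages the raw spectra of the selected pixels
#' and detrends the average. The reference protocol selects 90 pixels per
#' class (30 in one image of each of three biological replicates).
#'
#' @param images a named list of [hsi_image()] (names are image ids), or a
#'   single image.
#' @param selections data frame with columns `image_id`, `row`, `col`
#'   (0-based), `class`.
#' @param degree detrend polynomial degree.
#' @return an `mrs_library`: `classes`, `axis`, `spectra` (class x wavenumber
#'   matrix, detrended), `provenance` (the selections, with a per-class count).
#' @export
build_mrs <- function(images, selections, degree = 2L) {
  if (inherits(images, "hsi_image")) images <- list(image1 = images)
  if (is.null(names(images)) || any(names(images) == ""))
    stop("images must be a named list (names are image ids)")
  need <- c("image_id", "row", "col", "class")
  if (!all(need %in% names(selections)))
    stop("selections must have columns image_id,row,col,class")
  if (nrow(selections) == 0) stop("selections table is empty")
  axis <- images[[1]]$axis
  for (im in images) if (!axes_equal(im$axis, axis)) stop("images do not share one axis")
  classes <- sort(unique(as.character(selections$class)))
  spectra <- matrix(NA_real_, length(classes), length(axis),
                    dimnames = list(classes, NULL))
  counts <- integer(length(classes)); names(counts) <- classes
  for (cl in classes) {
    sel <- selections[selections$class == cl, , drop = FALSE]
    acc <- matrix(NA_real_, nrow(sel), length(axis))
    for (i in seq_len(nrow(sel))) {
      id <- as.character(sel$image_id[i])
      if (!id %in% names(images)) stop(sprintf("unknown image id '%s' in selections", id))
      im <- images[[id]]
      r <- sel$row[i] + 1L; cc <- sel$col[i] + 1L
      if (r < 1 || r > im$geometry$n_rows || cc < 1 || cc > im$geometry$n_cols)
        stop(sprintf("selection out of bounds: image %s, row %d, col %d",
                     id, sel$row[i], sel$col[i]))
      acc[i, ] <- im$cube[r, cc, ]
    }
    mean_raw <- colMeans(acc)
    spectra[cl, ] <- detrend_matrix(matrix(mean_raw, 1), axis, degree)
    counts[cl] <- nrow(sel)
  }
  structure(list(classes = classes, axis = axis, spectra = spectra,
                 provenance = list(selections = selections, counts = counts),
                 degree = degree),
            class = "mrs_library")
}

#' @export
print.mrs_library <- function(x, ...) {
  cat(sprintf("<mrs_library> %d classes (%s); %s pixels\n", length(x$classes),
              paste(x$classes, collapse = ", "),
              paste(x$provenance$counts, collapse = "/")))
  invisible(x)
}

## ---- Spearman correlation ------------------------------------------------

midranks <- function(v) rank(v, ties.method = "average")

#' Spearman rank correlation of two spectra
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns `NA`
#' when either input has zero rank variance (constant vector); callers treat
#' that as an undefined score.
#'
#' @param a,b numeric vectors or [ir_spectrum()] of equal length >= 3.
#' @return correlation in [-1, 1], or `NA`.
#' @export
spearman_cor <- function(a, b) {
  if (inherits(a, "ir_spectrum")) a <- a$values
  if (inherits(b, "ir_spectrum")) b <- b$values
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 3) stop("need at least 3 points")
  ra <- midranks(a); rb <- midranks(b)
  ra <- ra - mean(ra); rb <- rb - mean(rb)
  den <- sqrt(sum(ra^2) * sum(rb^2))
  if (den == 0) return(NA_real_)
  sum(ra * rb) / den
}

## Spearman of every row of m against every row of ref, via standardized ranks.
## Rows with zero rank variance yield NA scores.
spearman_matrix <- function(m, ref) {
  std_ranks <- function(x) {
    r <- t(apply(x, 1, midranks))
    r <- r - rowMeans(r)
    nrm <- sqrt(rowSums(r^2))
    bad <- nrm == 0
    nrm[bad] <- 1
    list(z = r / nrm, bad = bad)
  }
  a <- std_ranks(m); b <- std_ranks(ref)
  s <- a$z %*% t(b$z)
  s[a$bad, ] <- NA_real_
  s[, b$bad] <- NA_real_
  s
}

## ---- assignment ----------------------------------------------------------

#' Apply the correlation-score decision rule to a score matrix
#'
#' Lumen when every class score is below `lumen_threshold`; not assigned
#' (`"NA"`) when the top two scores differ by less than `tie_fraction` of the
#' best score (relative difference); otherwise the argmax class. `NA` scores
#' count as minus infinity.
#'
#' @param scores numeric matrix (pixels x classes) of correlation scores.
#' @param classes class names, one per score column.
#' @param lumen_threshold,tie_fraction see [assign_pixels()].
#' @return list of `label` and `rule` character vectors (one entry per row).
#' @export
assign_from_scores <- function(scores, classes = colnames(scores),
                               lumen_threshold = 0.90, tie_fraction = 0.01) {
  scores <- as.matrix(scores)
  if (length(classes) != ncol(scores)) stop("one class name per score column")
  sc <- scores
  sc[is.na(sc)] <- -Inf
  best_idx <- max.col(sc, ties.method = "first")
  best <- sc[cbind(seq_len(nrow(sc)), best_idx)]
  second <- apply(sc, 1, function(v) sort(v, decreasing = TRUE)[2])
  is_lumen <- best < lumen_threshold
  # exact ties are always "indistinguishable", even at tie_fraction = 0
  tie <- !is_lumen & is.finite(second) &
    (best == second | (best - second) < tie_fraction * abs(best))
  label <- character(nrow(sc)); rule <- character(nrow(sc))
  label[is_lumen] <- "LUMEN"; rule[is_lumen] <- "LUMEN_THRESHOLD"
  label[tie] <- "NA"; rule[tie] <- "NA_TIE"
  rest <- !is_lumen & !tie
  label[rest] <- classes[best_idx[rest]]; rule[rest] <- "BEST_CLASS"
  list(label = label, rule = rule)
}

#' Assign pixels to cell-wall classes by correlation score
#'
#' Each pixel spectrum is detrended and its Spearman correlation against every
#' MRS computed. A pixel is lumen when all scores fall below
#' `lumen_threshold`; it is not assigned (`"NA"`) when the best and
#' second-best scores differ by less than `tie_fraction` of the best
#' (relative difference); otherwise it takes the class of the highest score.
#' Degenerate (zero-variance) pixel spectra are labelled lumen.
#'
#' @param image an [hsi_image()] on the MRS axis.
#' @param mrs an `mrs_library` from [build_mrs()].
#' @param lumen_threshold correlation below which (for all classes) a pixel is
#'   lumen; default 0.90.
#' @param tie_fraction relative score difference below which the top two
#'   classes are considered tied; default 0.01 (1%).
#' @return an `assignment_result`: `label_map`, `scores` (pixel x class),
#'   `rule_fired` per pixel (`BEST_CLASS`, `LUMEN_THRESHOLD`, `NA_TIE`,
#'   `DEGENERATE`), and the thresholds used.
#' @export
assign_pixels <- function(image, mrs, lumen_threshold = 0.90, tie_fraction = 0.01) {
  stopifnot(inherits(image, "hsi_image"), inherits(mrs, "mrs_library"))
  if (!axes_equal(image$axis, mrs$axis))
    stop("image axis does not match MRS axis")
  g <- image$geometry
  m <- pixel_matrix(image)
  sds <- apply(m, 1, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  scores <- matrix(NA_real_, nrow(m), length(mrs$classes),
                   dimnames = list(NULL, mrs$classes))
  if (any(!degenerate)) {
    dm <- detrend_matrix(m[!degenerate, , drop = FALSE], image$axis, mrs$degree)
    scores[!degenerate, ] <- spearman_matrix(dm, mrs$spectra)
  }
  dec <- assign_from_scores(scores, mrs$classes, lumen_threshold, tie_fraction)
  labels <- dec$label
  rule <- dec$rule
  labels[degenerate] <- "LUMEN"; rule[degenerate] <- "DEGENERATE"
  lab_mat <- matrix(labels, g$n_rows, g$n_cols, byrow = TRUE)
  legend <- stats::setNames(c(mrs$classes, "lumen", "not assigned"),
                            c(mrs$classes, "LUMEN", "NA"))
  structure(list(label_map = label_map(g, lab_mat, legend),
                 scores = scores,
                 rule_fired = matrix(rule, g$n_rows, g$n_cols, byrow = TRUE),
                 lumen_threshold = lumen_threshold,
                 tie_fraction = tie_fraction),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  print(x$label_map)
  invisible(x)
}

#' Evaluate an assignment against ground truth
#'
#' @param predicted,truth [label_map()] objects on the same geometry.
#' @return list with `confusion` (truth x predicted counts, all labels
#'   including LUMEN and NA) and `per_class` (fraction of each truth class
#'   receiving its own label).
#' @export
evaluate_assignment <- function(predicted, truth) {
  stopifnot(inherits(predicted, "label_map"), inherits(truth, "label_map"))
  if (!geometries_equal(predicted$geometry, truth$geometry))
    stop("geometry mismatch between predicted and truth maps")
  labs <- sort(unique(c(as.vector(predicted$labels), as.vector(truth$labels))))
  confusion <- table(factor(as.vector(truth$labels), levels = labs),
                     factor(as.vector(predicted$labels), levels = labs))
  names(dimnames(confusion)) <- c("truth", "predicted")
  totals <- rowSums(confusion)
  acc <- ifelse(totals > 0, diag(as.matrix(confusion)) / totals, NA_real_)
  list(confusion = confusion,
       per_class = stats::setNames(as.numeric(acc), labs))
}
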