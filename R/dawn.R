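## Differentially absorbed wavenumber (DAWN) detection: pairwise Wilcoxon
## rank-sum tests per wavenumber, Bonferroni correction, local-maximum gating
## and compound annotation.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Exact when both samples have at most `exact_max` observations and there are
#' no ties (null distribution of the Mann-Whitney U statistic); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max largest per-sample size for the exact computation.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8L) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx <= exact_max && ny <= exact_max) {
    p <- if (U > nx * ny / 2) stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
         else stats::pwilcox(U, nx, ny)
    return(min(2 * p, 1))
  }
  N <- nx + ny
  z <- U - nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- (nx * ny / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)  # all values identical
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
}

#' Pooled per-class spectra set
#'
#' All pixel spectra assigned to one cell-wall class, with their mean
#' spectrum. Used as the sample populations of the DAWN scan and as the
#' spectra on which local maxima are identified.
#'
#' @param class_name class label.
#' @param members numeric matrix (pixels x wavenumbers) of raw absorbances.
#' @param axis the shared [spectral_axis()].
#' @return a `class_spectra_set`.
#' @export
class_spectra_set <- function(class_name, members, axis) {
  members <- as.matrix(members)
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(wavenumbers = axis)
  if (ncol(members) != length(axis)) stop("member columns must match axis length")
  if (nrow(members) == 0) stop(sprintf("class '%s' has no member spectra", class_name))
  structure(list(class_name = class_name, members = members, axis = axis,
                 mean_spectrum = colMeans(members)),
            class = "class_spectra_set")
}

#' Pool assigned pixels into per-class spectra sets
#'
#' @param images an [hsi_image()] or named list of them.
#' @param assignments matching `assignment_result` (or list of them).
#' @param exclude labels never pooled (default lumen and unassigned).
#' @return named list of [class_spectra_set()].
#' @export
pool_class_spectra <- function(images, assignments, exclude = c("LUMEN", "NA")) {
  if (inherits(images, "hsi_image")) {
    images <- list(images); assignments <- list(assignments)
  }
  if (length(images) != length(assignments))
    stop("images and assignments must pair up")
  axis <- images[[1]]$axis
  pools <- list()
  for (i in seq_along(images)) {
    m <- pixel_matrix(images[[i]])
    labs <- as.vector(t(assignments[[i]]$label_map$labels))
    for (cl in setdiff(unique(labs), exclude)) {
      block <- m[labs == cl, , drop = FALSE]
      pools[[cl]] <- rbind(pools[[cl]], block)
    }
  }
  lapply(stats::setNames(names(pools), names(pools)),
         function(cl) class_spectra_set(cl, pools[[cl]], axis))
}

#' Scan all class pairs for differentially absorbed wavenumbers
#'
#' At every wavenumber and every unordered class pair, performs a two-sided
#' Wilcoxon rank-sum test on the per-pixel absorbances, then Bonferroni-adjusts
#' the p-values. The default adjustment family is the set of class pairs at
#' each wavenumber (mirroring a per-wavenumber pairwise test call); the
#' `"global"` family multiplies by pairs x wavenumbers.
#'
#' @param sets list of [class_spectra_set()] on one axis (>= 2 classes).
#' @param alpha significance cut-off on the adjusted p-value (default 0.001).
#' @param family Bonferroni family: `"per_wavenumber_pairs"` or `"global"`.
#' @return a `dawn_table` data frame: `sigma_cm`, `class_a`, `class_b`,
#'   `p_raw`, `p_adj`, plus placeholder columns `is_local_max`,
#'   `near_local_max`, `passes` (filled by [filter_dawns()]) and `annotations`
#'   (filled by [annotate_dawns()]). The `alpha` and `family` used are stored
#'   as attributes.
#' @export
pairwise_dawn_scan <- function(sets, alpha = 0.001,
                               family = c("per_wavenumber_pairs", "global")) {
  family <- match.arg(family)
  if (length(sets) < 2) stop("need at least 2 classes")
  axis <- sets[[1]]$axis
  for (s in sets) if (!axes_equal(s$axis, axis)) stop("sets do not share one axis")
  nm <- vapply(sets, `[[`, "", "class_name")
  usable <- vapply(sets, function(s) nrow(s$members) >= 2, TRUE)
  if (any(!usable))
    warning(sprintf("class(es) with < 2 members skipped: %s",
                    paste(nm[!usable], collapse = ", ")))
  idx <- which(usable)
  if (length(idx) < 2) stop("fewer than 2 classes with >= 2 members")
  pairs <- utils::combn(idx, 2)
  n_pairs <- ncol(pairs)
  wn <- as.numeric(axis)
  rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- sets[[pairs[1, k]]]; b <- sets[[pairs[2, k]]]
    p <- vapply(seq_along(wn), function(j)
      wilcoxon_rank_sum(a$members[, j], b$members[, j]), 0)
    rows[[k]] <- data.frame(sigma_cm = wn, class_a = a$class_name,
                            class_b = b$class_name, p_raw = p)
  }
  out <- do.call(rbind, rows)
  factor_n <- if (family == "per_wavenumber_pairs") n_pairs else n_pairs * length(wn)
  out$p_adj <- pmin(1, out$p_raw * factor_n)
  out$is_local_max <- NA
  out$near_local_max <- NA
  out$passes <- out$p_adj < alpha  # provisional until local-maximum gating
  out$annotations <- ""
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  attr(out, "n_comparisons") <- factor_n
  class(out) <- c("dawn_table", "data.frame")
  out
}

#' Local maxima of a spectrum
#'
#' A wavenumber sigma is a local maximum when its absorbance exceeds the
#' absorbance at sigma - `delta_cm` and sigma + `delta_cm`. Axis endpoints
#' (lacking one neighbour) are excluded. Distances are physical (cm^-1), so
#' non-default axis steps behave correctly; `delta_cm` must be a multiple of
#' the axis step.
#'
#' @param values numeric vector of absorbances on `axis` (or an
#'   [ir_spectrum()], in which case `axis` is taken from it).
#' @param axis a [spectral_axis()].
#' @param delta_cm neighbour distance in cm^-1 (default 2).
#' @return numeric vector of wavenumbers that are local maxima.
#' @export
local_maxima <- function(values, axis = NULL, delta_cm = 2) {
  if (inherits(values, "ir_spectrum")) {
    axis <- values$axis; values <- values$values
  }
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(wavenumbers = axis)
  step <- axis_step(axis)
  k <- delta_cm / step
  if (abs(k - round(k)) > 1e-9)
    stop("delta_cm must be a multiple of the axis step")
  k <- as.integer(round(k))
  if (k < 1) stop("delta_cm must be at least one axis step")
  n <- length(values)
  if (n < 2 * k + 1) return(numeric(0))
  i <- (k + 1):(n - k)
  hit <- values[i] > values[i - k] & values[i] > values[i + k]
  as.numeric(axis)[i[hit]]
}

#' Gate DAWNs on proximity to a spectral local maximum
#'
#' A scan row survives when its wavenumber lies within `window_cm` of a local
#' maximum of the class-mean spectrum of either class in the pair (option
#' `"both"` requires both classes). `passes` becomes
#' `near_local_max & p_adj < alpha`.
#'
#' @param table a `dawn_table` from [pairwise_dawn_scan()].
#' @param maxima named list: per class, the wavenumbers of its mean-spectrum
#'   local maxima (see [local_maxima()]).
#' @param window_cm proximity window in cm^-1 (default 3).
#' @param rule `"either"` (default) or `"both"`.
#' @param alpha cut-off; defaults to the one stored on the table.
#' @return the table with `is_local_max`, `near_local_max`, `passes` filled.
#' @export
filter_dawns <- function(table, maxima, window_cm = 3,
                         rule = c("either", "both"), alpha = NULL) {
  rule <- match.arg(rule)
  if (is.null(alpha)) alpha <- attr(table, "alpha")
  if (is.null(alpha)) alpha <- 0.001
  near_of <- function(cl, sigma) {
    mx <- maxima[[cl]]
    if (is.null(mx) || length(mx) == 0) return(rep(FALSE, length(sigma)))
    vapply(sigma, function(s) any(abs(s - mx) <= window_cm), TRUE)
  }
  at_of <- function(cl, sigma) {
    mx <- maxima[[cl]]
    if (is.null(mx) || length(mx) == 0) return(rep(FALSE, length(sigma)))
    vapply(sigma, function(s) any(abs(s - mx) <= 1e-9), TRUE)
  }
  near <- matrix(FALSE, nrow(table), 2)
  atmax <- matrix(FALSE, nrow(table), 2)
  for (side in 1:2) {
    cls <- if (side == 1) table$class_a else table$class_b
    for (cl in unique(cls)) {
      sel <- cls == cl
      near[sel, side] <- near_of(cl, table$sigma_cm[sel])
      atmax[sel, side] <- at_of(cl, table$sigma_cm[sel])
    }
  }
  table$near_local_max <- if (rule == "either") near[, 1] | near[, 2] else near[, 1] & near[, 2]
  table$is_local_max <- if (rule == "either") atmax[, 1] | atmax[, 2] else atmax[, 1] & atmax[, 2]
  table$passes <- table$near_local_max & table$p_adj < alpha
  attr(table, "alpha") <- alpha
  attr(table, "window_cm") <- window_cm
  table
}

#' Built-in cell-wall band-assignment table
#'
#' Mid-IR band assignments for wood cell-wall polymers (cellulose, crystalline
#' cellulose, hemicelluloses/acetylated xylans, lignins, pectins, proteins)
#' compiled from the plant cell-wall literature; each entry is a wavenumber
#' range with a compound class and vibration description.
#'
#' @param path optional CSV (`low_cm,high_cm,compound,description,notes`)
#'   replacing the built-in table.
#' @return data frame with those five columns.
#' @export
band_assignment_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "band_assignments.csv", package = "irwall",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("low_cm", "high_cm", "compound", "description", "notes")
  if (!all(need %in% names(df)))
    stop("band table must have columns low_cm,high_cm,compound,description,notes")
  if (any(df$low_cm > df$high_cm)) stop("malformed band range: low_cm > high_cm")
  df
}

#' Annotate DAWNs with cell-wall compound classes
#'
#' Each row gains every band-table entry whose range overlaps its wavenumber
#' (semicolon-joined `compound (description)` strings); rows overlapping no
#' entry are annotated `"unassigned"`.
#'
#' @param table a `dawn_table`.
#' @param bands a band table from [band_assignment_table()].
#' @return the annotated table.
#' @export
annotate_dawns <- function(table, bands = band_assignment_table()) {
  ann <- vapply(table$sigma_cm, function(s) {
    hit <- bands$low_cm <= s & s <= bands$high_cm
    if (!any(hit)) return("unassigned")
    paste(sprintf("%s (%s)", bands$compound[hit], bands$description[hit]),
          collapse = "; ")
  }, "")
  table$annotations <- ann
  table
}

#' Write / read a DAWN table as TSV
#'
#' @param table a `dawn_table`.
#' @param path TSV path.
#' @return `read_dawn_table` returns the table; `write_dawn_table` its path,
#'   invisibly.
#' @export
write_dawn_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dawn_table
#' @export
read_dawn_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("dawn_table", "data.frame")
  df
}

#' Full DAWN pipeline on pooled class sets
#'
#' Scan, local-maximum gating on the class-mean spectra, and annotation.
#'
#' @inheritParams pairwise_dawn_scan
#' @inheritParams filter_dawns
#' @param bands band table for annotation (`NULL` to skip).
#' @param delta_cm local-maximum neighbour distance (cm^-1).
#' @return an annotated, filtered `dawn_table`.
#' @export
find_dawns <- function(sets, alpha = 0.001,
                       family = c("per_wavenumber_pairs", "global"),
                       window_cm = 3, delta_cm = 2, rule = c("either", "both"),
                       bands = band_assignment_table()) {
  tab <- pairwise_dawn_scan(sets, alpha = alpha, family = family)
  maxima <- lapply(sets, function(s) local_maxima(s$mean_spectrum, s$axis, delta_cm))
  names(maxima) <- vapply(sets, `[[`, "", "class_name")
  tab <- filter_dawns(tab, maxima, window_cm = window_cm, rule = rule, alpha = alpha)
  if (!is.null(bands)) tab <- annotate_dawns(tab, bands)
  tab
}
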