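#' Spectral axis
#'
#' An ordered wavenumber grid (cm^-1) shared by all spectra in a cube. Stored
#' high-to-low (1,800 -> 850 by default) following mid-IR plotting convention;
#' spacing must be uniform.
#'
#' @param from,to wavenumber endpoints in cm^-1; `from` is the high end.
#' @param step grid spacing in cm^-1 (positive). The default 2 cm^-1 is the
#'   digital sampling interval; instrument optical resolution is a separate
#'   matter and does not constrain the grid.
#' @param wavenumbers optional explicit grid (overrides `from`/`to`/`step`);
#'   must be strictly monotone with uniform spacing.
#' @return an object of class `spectral_axis`: a numeric vector of wavenumbers
#'   with a `step` attribute.
#' @examples
#' ax <- spectral_axis()
#' length(ax) # 476
#' @export
spectral_axis <- function(from = 1800, to = 850, step = 2, wavenumbers = NULL) {
  if (is.null(wavenumbers)) {
    if (step <= 0) stop("step must be positive")
    wavenumbers <- seq(from, to, by = if (from >= to) -step else step)
  }
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2) stop("spectral axis needs at least 2 points")
  d <- diff(wavenumbers)
  if (any(d == 0) || length(unique(sign(d))) != 1)
    stop("spectral axis must be strictly monotone")
  rel <- abs(d - d[1]) / abs(d[1])
  if (any(rel > 1e-9)) stop("spectral axis spacing must be uniform")
  structure(wavenumbers, step = abs(d[1]), class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.6g to %.6g cm^-1, step %.6g cm^-1\n",
              length(x), x[1], x[length(x)], attr(x, "step")))
  invisible(x)
}

axis_step <- function(axis) attr(axis, "step")

axes_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol * pmax(1, abs(as.numeric(a))))
}

#' Single absorbance spectrum
#'
#' @param axis a [spectral_axis()].
#' @param values absorbance values (AU), one per axis point, all finite.
#' @return an object of class `ir_spectrum` with elements `axis` and `values`.
#' @export
ir_spectrum <- function(axis, values) {
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(wavenumbers = axis)
  values <- as.numeric(values)
  if (length(values) != length(axis))
    stop(sprintf("spectrum length (%d) does not match axis length (%d)",
                 length(values), length(axis)))
  if (!all(is.finite(values))) stop("spectrum values must all be finite")
  structure(list(axis = axis, values = values), class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, absorbance range [%.4g, %.4g] AU\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Image geometry
#'
#' Field of view and pixel raster of one hyperspectral acquisition. The default
#' (100 x 100) um^2 field at (1.56 x 1.56) um^2 pixels gives a 64 x 64 grid,
#' i.e. 4,096 pixels.
#'
#' @param field_width_um,field_height_um field of view in micrometers.
#' @param pixel_size_um square pixel edge in micrometers.
#' @return an `image_geometry` list with `n_rows`, `n_cols`, `n_pixels`.
#' @export
image_geometry <- function(field_width_um = 100, field_height_um = 100,
                           pixel_size_um = 1.56) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  # tolerance guards against 4.68 / 1.56 = 2.9999... style float artifacts
  n_cols <- floor(field_width_um / pixel_size_um + 1e-9)
  n_rows <- floor(field_height_um / pixel_size_um + 1e-9)
  if (n_cols < 1 || n_rows < 1) stop("field smaller than one pixel")
  structure(list(field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 pixel_size_um = pixel_size_um,
                 n_cols = n_cols, n_rows = n_rows,
                 n_pixels = n_rows * n_cols),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %g x %g um^2 field, %g um pixels -> %d x %d = %d pixels\n",
              x$field_width_um, x$field_height_um, x$pixel_size_um,
              x$n_rows, x$n_cols, x$n_pixels))
  invisible(x)
}

geometries_equal <- function(a, b) a$n_rows == b$n_rows && a$n_cols == b$n_cols

## ---- preprocessing transforms -------------------------------------------

snv_values <- function(v, what = "spectrum") {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zero-variance %s: SNV undefined", what))
  (v - mean(v)) / s
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes a spectrum to mean 0 and unit sample standard deviation,
#' removing per-pixel multiplicative scatter and offset effects.
#'
#' @param spectrum an [ir_spectrum()] with at least 3 points and non-zero
#'   variance.
#' @return the standardized `ir_spectrum`.
#' @export
snv <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (length(spectrum$values) < 3) stop("SNV needs at least 3 points")
  ir_spectrum(spectrum$axis, snv_values(spectrum$values))
}

## Degree-d polynomial design matrix over the axis, centered/scaled to [-1, 1]
## for conditioning (identical fit in exact arithmetic).
poly_basis <- function(axis, degree) {
  w <- as.numeric(axis)
  u <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  stats::poly(u, degree = degree, raw = TRUE, simple = TRUE)
}

detrend_matrix <- function(m, axis, degree = 2L) {
  # rows = spectra; SNV per row, then remove per-row least-squares polynomial
  s <- apply(m, 1, stats::sd)
  if (any(!is.finite(s) | s == 0))
    stop(sprintf("zero-variance spectrum at row index %s: detrend undefined",
                 paste(which(!is.finite(s) | s == 0), collapse = ", ")))
  z <- (m - rowMeans(m)) / s
  X <- if (degree == 0) matrix(1, length(axis), 1) else cbind(1, poly_basis(axis, degree))
  # residual maker applied to each row: z - z X (X'X)^-1 X'
  coef <- t(qr.solve(qr(X), t(z)))
  z - coef %*% t(X)
}

#' Detrend transform (SNV + polynomial baseline removal)
#'
#' Applies SNV, then subtracts the least-squares polynomial of the given
#' degree fitted against wavenumber. This is the standard detrending used to
#' remove curvilinear baseline drift before correlation-based classification;
#' both reference (MRS) and pixel spectra must pass through it.
#'
#' @param spectrum an [ir_spectrum()].
#' @param degree polynomial degree (default 2).
#' @return the detrended `ir_spectrum`.
#' @export
detrend <- function(spectrum, degree = 2L) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be >= 0")
  if (length(spectrum$values) <= degree + 1)
    stop("spectrum too short for requested polynomial degree")
  out <- detrend_matrix(matrix(spectrum$values, nrow = 1), spectrum$axis, degree)
  ir_spectrum(spectrum$axis, as.numeric(out))
}

#' Savitzky-Golay smoothing
#'
#' Optional local polynomial smoothing for noise reduction. A spectrum that is
#' globally a polynomial of order <= `polyorder` passes through unchanged.
#'
#' @param spectrum an [ir_spectrum()].
#' @param window odd window length (> polyorder).
#' @param polyorder local polynomial order.
#' @return the smoothed `ir_spectrum`.
#' @export
smooth_spectrum <- function(spectrum, window = 9L, polyorder = 2L) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2 == 0 || window <= polyorder)
    stop("window must be odd and greater than polyorder")
  if (window > length(spectrum$values)) stop("window longer than spectrum")
  ir_spectrum(spectrum$axis,
              signal::sgolayfilt(spectrum$values, p = polyorder, n = window))
}

#' Write / read a spectrum as two-column text
#'
#' Plain-text serialization (wavenumber, absorbance) with full double
#' precision, so the axis round-trips bit-exactly.
#'
#' @param spectrum an [ir_spectrum()].
#' @param path file path.
#' @return `read_spectrum` returns an `ir_spectrum`; `write_spectrum` its path,
#'   invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  df <- data.frame(wavenumber = sprintf("%.17g", as.numeric(spectrum$axis)),
                   absorbance = sprintf("%.17g", spectrum$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("wavenumber", "absorbance") %in% names(df)))
    stop("spectrum file must have columns wavenumber, absorbance")
  ir_spectrum(spectral_axis(wavenumbers = df$wavenumber), df$absorbance)
}
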