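#' Hyperspectral absorbance image
#'
#' A 2-D pixel grid where every pixel carries a full absorbance spectrum on a
#' shared [spectral_axis()]. The cube is stored as a numeric array indexed
#' (row, col, band); pixel coordinates are 0-based, row-major, origin top-left
#' in all file formats and tables.
#'
#' @param geometry an [image_geometry()].
#' @param axis a [spectral_axis()].
#' @param cube numeric array of dimension (n_rows, n_cols, axis length), all
#'   values finite.
#' @param metadata free-form named list (sample id, wood type, notes ...).
#' @return an object of class `hsi_image`.
#' @export
hsi_image <- function(geometry, axis, cube, metadata = list()) {
  stopifnot(inherits(geometry, "image_geometry"))
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(wavenumbers = axis)
  cube <- as.array(cube)
  want <- c(geometry$n_rows, geometry$n_cols, length(axis))
  if (length(dim(cube)) != 3 || any(dim(cube) != want))
    stop(sprintf("cube dimensions (%s) do not match geometry/axis (%s)",
                 paste(dim(cube), collapse = "x"), paste(want, collapse = "x")))
  if (!all(is.finite(cube))) stop("cube contains non-finite absorbance values")
  structure(list(geometry = geometry, axis = axis, cube = cube,
                 metadata = metadata), class = "hsi_image")
}

#' @export
print.hsi_image <- function(x, ...) {
  cat(sprintf("<hsi_image> %d x %d pixels x %d bands (%.6g-%.6g cm^-1)\n",
              x$geometry$n_rows, x$geometry$n_cols, length(x$axis),
              as.numeric(x$axis)[1], as.numeric(x$axis)[length(x$axis)]))
  invisible(x)
}

#' Flatten a cube to a pixel-by-band matrix
#'
#' Rows follow 0-based row-major pixel order: pixel index = row * n_cols + col.
#'
#' @param image an [hsi_image()].
#' @return numeric matrix (n_pixels x n_bands).
#' @export
pixel_matrix <- function(image) {
  stopifnot(inherits(image, "hsi_image"))
  g <- image$geometry
  m <- matrix(aperm(image$cube, c(2, 1, 3)), nrow = g$n_rows * g$n_cols)
  m
}

#' Per-pixel class label map
#'
#' @param geometry an [image_geometry()].
#' @param labels character matrix (n_rows x n_cols) of category codes; the
#'   reserved codes `"LUMEN"` and `"NA"` denote lumen and unassigned pixels.
#' @param legend named character vector mapping every used code to a
#'   human-readable class name.
#' @return an object of class `label_map`.
#' @export
label_map <- function(geometry, labels, legend = NULL) {
  stopifnot(inherits(geometry, "image_geometry"))
  labels <- as.matrix(labels)
  if (!all(dim(labels) == c(geometry$n_rows, geometry$n_cols)))
    stop("labels dimensions do not match geometry")
  storage.mode(labels) <- "character"
  used <- sort(unique(as.vector(labels)))
  if (is.null(legend)) legend <- stats::setNames(used, used)
  missing <- setdiff(used, names(legend))
  if (length(missing))
    stop(sprintf("legend is missing used code(s): %s", paste(missing, collapse = ", ")))
  structure(list(geometry = geometry, labels = labels, legend = legend),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_map> %d x %d pixels; %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  invisible(x)
}

## ---- cube formats --------------------------------------------------------

#' Read a hyperspectral cube
#'
#' Supported formats: `"native"` (single-file lossless archive written by
#' [write_cube()]), `"envi"` (text header alongside raw band-sequential
#' little-endian float64 binary) and `"long_table"` (CSV with header
#' `row,col,wavenumber,absorbance`; rows in any order, but the grid must be
#' complete). Readers reject inconsistent inputs; they never silently repair.
#'
#' @param path file path (for `envi`, the binary path; the header is
#'   `<path>.hdr`).
#' @param format one of `"native"`, `"envi"`, `"long_table"`.
#' @param pixel_size_um pixel edge used to reconstruct geometry for formats
#'   that do not store it (envi, long_table).
#' @return an [hsi_image()].
#' @export
read_cube <- function(path, format = c("native", "envi", "long_table"),
                      pixel_size_um = 1.56) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  switch(format,
         native = {
           obj <- readRDS(path)
           if (!inherits(obj, "hsi_image")) stop("native file does not hold a hyperspectral image")
           hsi_image(obj$geometry, obj$axis, obj$cube, obj$metadata)
         },
         envi = read_cube_envi(path, pixel_size_um),
         long_table = read_cube_long(path, pixel_size_um))
}

#' Write a hyperspectral cube
#'
#' @param image an [hsi_image()].
#' @param path output path.
#' @param format see [read_cube()].
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, format = c("native", "envi", "long_table")) {
  stopifnot(inherits(image, "hsi_image"))
  format <- match.arg(format)
  switch(format,
         native = saveRDS(image, path),
         envi = write_cube_envi(image, path),
         long_table = write_cube_long(image, path))
  invisible(path)
}

write_cube_envi <- function(image, path) {
  g <- image$geometry
  wl <- paste(sprintf("%.10g", as.numeric(image$axis)), collapse = ", ")
  lines <- c("ENVI",
             sprintf("samples = %d", g$n_cols),
             sprintf("lines = %d", g$n_rows),
             sprintf("bands = %d", length(image$axis)),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 5",
             "interleave = bsq",
             "byte order = 0",
             "wavelength units = cm-1",
             sprintf("pixel size = {%.10g, %.10g}", g$pixel_size_um, g$pixel_size_um),
             sprintf("wavelength = {%s}", wl))
  meta <- image$metadata
  if (length(meta))
    lines <- c(lines, sprintf("description = {%s}",
                              paste(sprintf("%s: %s", names(meta),
                                            vapply(meta, as.character, "")), collapse = "; ")))
  writeLines(lines, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band by band, row-major within band
  for (b in seq_len(length(image$axis)))
    writeBin(as.vector(t(image$cube[, , b])), con, size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path)) stop(sprintf("missing ENVI header: %s", hdr_path))
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?m)^%s\\s*=\\s*([^\\{\\n]+)$", key), txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NA_character_)
    trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(sprintf("%s\\s*=\\s*\\{([^}]*)\\}", key), txt))[[1]]
    if (length(m) < 2) return(NA_character_)
    m[2]
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       byte_order = as.integer(get_scalar("byte order")),
       pixel_size = get_block("pixel size"),
       wavelength = get_block("wavelength"))
}

read_cube_envi <- function(path, pixel_size_um) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  if (any(is.na(c(h$samples, h$lines, h$bands))))
    stop("ENVI header lacks samples/lines/bands")
  if (!is.na(h$data_type) && h$data_type != 5)
    stop(sprintf("unsupported ENVI data type %d (only 5 = float64)", h$data_type))
  if (!is.na(h$interleave) && h$interleave != "bsq")
    stop(sprintf("unsupported interleave '%s' (only bsq)", h$interleave))
  if (is.na(h$wavelength)) stop("ENVI header lacks a wavelength list")
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != h$bands)
    stop(sprintf("header wavelength count (%d) does not match bands (%d)",
                 length(wl), h$bands))
  if (!is.na(h$pixel_size)) {
    ps <- as.numeric(strsplit(h$pixel_size, ",")[[1]])
    if (length(ps) >= 1 && is.finite(ps[1])) pixel_size_um <- ps[1]
  }
  n <- h$samples * h$lines * h$bands
  expected_bytes <- 8 * n
  actual <- file.info(path)$size
  if (actual != expected_bytes)
    stop(sprintf("ENVI data size mismatch: header implies %d bytes, file has %d",
                 expected_bytes, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8,
                 endian = if (identical(h$byte_order, 1L)) "big" else "little")
  cube <- array(NA_real_, c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    block <- raw[((b - 1) * per_band + 1):(b * per_band)]
    cube[, , b] <- matrix(block, nrow = h$lines, byrow = TRUE)
  }
  geom <- image_geometry(h$samples * pixel_size_um, h$lines * pixel_size_um,
                         pixel_size_um)
  hsi_image(geom, spectral_axis(wavenumbers = wl), cube)
}

write_cube_long <- function(image, path) {
  g <- image$geometry
  wl <- as.numeric(image$axis)
  idx <- expand.grid(col = seq_len(g$n_cols) - 1L, row = seq_len(g$n_rows) - 1L,
                     band = seq_along(wl))
  df <- data.frame(row = idx$row, col = idx$col,
                   wavenumber = sprintf("%.17g", wl[idx$band]),
                   absorbance = sprintf("%.17g",
                                        image$cube[cbind(idx$row + 1L, idx$col + 1L, idx$band)]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_cube_long <- function(path, pixel_size_um) {
  df <- utils::read.csv(path)
  need <- c("row", "col", "wavenumber", "absorbance")
  if (!all(need %in% names(df)))
    stop("long table must have columns row,col,wavenumber,absorbance")
  wl <- sort(unique(df$wavenumber), decreasing = TRUE)
  rows <- sort(unique(df$row)); cols <- sort(unique(df$col))
  n_rows <- max(rows) + 1L; n_cols <- max(cols) + 1L
  if (!identical(as.integer(rows), seq_len(n_rows) - 1L) ||
      !identical(as.integer(cols), seq_len(n_cols) - 1L))
    stop("long table pixel coordinates must cover a full 0-based grid")
  expected <- n_rows * n_cols * length(wl)
  if (nrow(df) != expected) {
    # locate one example gap for the message
    key <- paste(df$row, df$col, df$wavenumber)
    full <- expand.grid(row = rows, col = cols, wavenumber = wl)
    fkey <- paste(full$row, full$col, full$wavenumber)
    gap <- setdiff(fkey, key)[1]
    stop(sprintf("long table incomplete: %d rows, expected %d; e.g. missing (row col wavenumber) = %s",
                 nrow(df), expected, gap))
  }
  axis <- spectral_axis(wavenumbers = wl)
  band_of <- match(df$wavenumber, wl)
  cube <- array(NA_real_, c(n_rows, n_cols, length(wl)))
  cube[cbind(df$row + 1L, df$col + 1L, band_of)] <- df$absorbance
  if (anyNA(cube)) stop("long table has duplicated coordinates leaving gaps")
  geom <- image_geometry(n_cols * pixel_size_um, n_rows * pixel_size_um, pixel_size_um)
  hsi_image(geom, axis, cube)
}

## ---- label maps ----------------------------------------------------------

#' Default class palette
#'
#' Fixed rendering palette: fiber S-layers red, fiber G-layer blue, vessel
#' S-layers green, ray S-layers tan, lumen black, unassigned white.
#'
#' @param codes character vector of codes to cover; unknown codes get greys.
#' @return named vector of hex colors.
#' @export
class_palette <- function(codes) {
  base <- c(fiber_S = "#CC2222", fiber_G = "#2244CC", vessel_S = "#22AA44",
            ray_S = "#D2B48C", LUMEN = "#000000", "NA" = "#FFFFFF")
  out <- base[codes]
  extra <- is.na(out)
  if (any(extra))
    out[extra] <- grDevices::grey.colors(sum(extra), start = 0.35, end = 0.75)
  stats::setNames(out, codes)
}

#' Write / read a label map
#'
#' Writes a CSV of `row,col,code` (0-based, row-major) plus a `<path>.legend.csv`
#' sidecar (`code,class`), and an indexed PNG (`<path>.png`) using the fixed
#' class palette.
#'
#' @param map a [label_map()].
#' @param path CSV path.
#' @param png whether to also emit the PNG rendering.
#' @return `read_label_map` returns a `label_map`; `write_label_map` the CSV
#'   path, invisibly.
#' @export
write_label_map <- function(map, path, png = TRUE) {
  stopifnot(inherits(map, "label_map"))
  g <- map$geometry
  idx <- expand.grid(col = seq_len(g$n_cols) - 1L, row = seq_len(g$n_rows) - 1L)
  df <- data.frame(row = idx$row, col = idx$col,
                   code = map$labels[cbind(idx$row + 1L, idx$col + 1L)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(code = names(map$legend), class = unname(map$legend)),
                   paste0(path, ".legend.csv"), row.names = FALSE, quote = FALSE)
  if (png) {
    pal <- class_palette(sort(unique(as.vector(map$labels))))
    rgb <- grDevices::col2rgb(pal[map$labels]) / 255
    arr <- array(0, c(g$n_rows, g$n_cols, 3))
    for (k in 1:3) arr[, , k] <- matrix(rgb[k, ], g$n_rows, g$n_cols)
    png::writePNG(arr, paste0(path, ".png"))
  }
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "integer", "character"),
                        na.strings = character())
  if (!all(c("row", "col", "code") %in% names(df)))
    stop("label map CSV must have columns row,col,code")
  leg_path <- paste0(path, ".legend.csv")
  legend <- NULL
  if (file.exists(leg_path)) {
    ldf <- utils::read.csv(leg_path, colClasses = "character",
                           na.strings = character())
    legend <- stats::setNames(ldf$class, ldf$code)
  }
  n_rows <- max(df$row) + 1L; n_cols <- max(df$col) + 1L
  if (nrow(df) != n_rows * n_cols) stop("label map CSV does not cover the full grid")
  labels <- matrix(NA_character_, n_rows, n_cols)
  labels[cbind(df$row + 1L, df$col + 1L)] <- df$code
  if (!is.null(legend)) {
    unknown <- setdiff(unique(df$code), names(legend))
    if (length(unknown))
      stop(sprintf("label map uses code(s) absent from legend: %s",
                   paste(unknown, collapse = ", ")))
  }
  geom <- image_geometry(n_cols * 1.56, n_rows * 1.56, 1.56)
  label_map(geom, labels, legend)
}
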