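## Synthetic hyperspectral scenes with known per-pixel labels and known
## spectral structure, for validating every pipeline stage without
## instrument data.

#' Class spectrum model
#'
#' A cell-wall class's clean spectrum: a sum of Gaussian absorption bands over
#' a polynomial baseline. Gaussian shapes are used (rather than Lorentzian or
#' Voigt) so band centers are analytically the local maxima the detection
#' stage must find.
#'
#' @param class_name class label.
#' @param bands data frame with columns `center` (cm^-1), `width` (Gaussian sd,
#'   cm^-1, > 0), `amplitude` (AU, >= 0).
#' @param baseline numeric coefficients (length <= 3) of a polynomial in the
#'   normalized wavenumber u in [-1, 1] (constant, linear, quadratic).
#' @param amplitude_jitter relative sd of per-pixel, per-band amplitude
#'   variation.
#' @return a `class_spectrum_model`.
#' @export
class_spectrum_model <- function(class_name, bands,
                                 baseline = c(0.02, 0, 0),
                                 amplitude_jitter = 0.05) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
  if (any(bands$width <= 0)) stop("band widths must be positive")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be non-negative")
  baseline <- c(baseline, rep(0, 3 - length(baseline)))[1:3]
  structure(list(class_name = class_name, bands = bands, baseline = baseline,
                 amplitude_jitter = amplitude_jitter),
            class = "class_spectrum_model")
}

norm_u <- function(axis) {
  w <- as.numeric(axis)
  2 * (w - min(w)) / (max(w) - min(w)) - 1
}

## Per-band unit Gaussian profiles over the axis (bands x wavenumbers).
band_profiles <- function(model, axis) {
  w <- as.numeric(axis)
  t(vapply(seq_len(nrow(model$bands)), function(b)
    exp(-(w - model$bands$center[b])^2 / (2 * model$bands$width[b]^2)),
    numeric(length(w))))
}

baseline_values <- function(model, axis) {
  u <- norm_u(axis)
  model$baseline[1] + model$baseline[2] * u + model$baseline[3] * u^2
}

#' Clean (noise-free) class spectrum
#'
#' @param model a [class_spectrum_model()].
#' @param axis a [spectral_axis()].
#' @return an [ir_spectrum()].
#' @export
clean_spectrum <- function(model, axis = spectral_axis()) {
  prof <- band_profiles(model, axis)
  ir_spectrum(axis, as.numeric(model$bands$amplitude %*% prof) +
                baseline_values(model, axis))
}

#' Default class spectrum models per wood type
#'
#' Band inventories emulate the qualitative contrasts of poplar wood
#' cell-wall mid-IR spectra: the tension-wood (TW) fiber G-layer lacks the
#' lignin aromatic bands at 1,594 and 1,506 cm^-1, carries a strong
#' crystalline-cellulose double band at 1,336/1,316 cm^-1 plus bands at 1,200
#' and 1,052 cm^-1, and is weak at the acetylated-xylan bands 1,736 and
#' 1,236 cm^-1 where S-layers absorb strongly. Amplitudes are simulator
#' choices, set so detrended class spectra are distinct but confusable
#' (pairwise Spearman roughly 0.5-0.85).
#'
#' @param wood_type `"NW"`, `"OW"` or `"TW"`.
#' @param amplitude_jitter relative per-pixel band-amplitude sd for all
#'   classes.
#' @return named list of [class_spectrum_model()]; TW includes `fiber_G`.
#' @export
default_models <- function(wood_type = c("TW", "NW", "OW"),
                           amplitude_jitter = 0.05) {
  wood_type <- match.arg(wood_type)
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  fiber_S <- class_spectrum_model("fiber_S", b(
    1736, 8, 0.30,   1594, 9, 0.22,   1506, 7, 0.25,   1462, 8, 0.14,
    1424, 8, 0.12,   1372, 7, 0.13,   1336, 6, 0.08,   1316, 6, 0.06,
    1236, 9, 0.30,   1160, 7, 0.12,   1110, 9, 0.14,   1052, 8, 0.18,
    1034, 9, 0.38,    898, 7, 0.05),
    baseline = c(0.05, -0.01, 0.02), amplitude_jitter = amplitude_jitter)
  fiber_G <- class_spectrum_model("fiber_G", b(
    1736, 8, 0.06,   1462, 8, 0.11,   1424, 8, 0.16,   1372, 7, 0.14,
    1336, 6, 0.26,   1316, 6, 0.24,   1236, 9, 0.08,   1200, 7, 0.18,
    1160, 7, 0.20,   1110, 9, 0.12,   1052, 8, 0.34,   1034, 9, 0.40,
     898, 7, 0.10),
    baseline = c(0.05, -0.01, 0.02), amplitude_jitter = amplitude_jitter)
  vessel_S <- class_spectrum_model("vessel_S", b(
    1736, 8, 0.40,   1594, 9, 0.06,   1506, 7, 0.08,   1460, 8, 0.22,
    1424, 8, 0.06,   1374, 7, 0.22,   1336, 6, 0.06,   1316, 6, 0.05,
    1236, 9, 0.38,   1160, 7, 0.06,   1110, 9, 0.24,   1052, 8, 0.12,
    1034, 9, 0.48,    970, 9, 0.14,    898, 7, 0.03),
    baseline = c(0.045, -0.012, 0.022), amplitude_jitter = amplitude_jitter)
  ray_S <- class_spectrum_model("ray_S", b(
    1736, 8, 0.24,   1652, 10, 0.12,  1594, 9, 0.18,   1548, 8, 0.10,
    1506, 7, 0.20,   1462, 8, 0.13,   1424, 8, 0.12,   1372, 7, 0.13,
    1336, 6, 0.10,   1316, 6, 0.08,   1236, 9, 0.24,   1200, 7, 0.06,
    1160, 7, 0.13,   1110, 9, 0.13,   1052, 8, 0.18,   1034, 9, 0.36,
     898, 7, 0.06),
    baseline = c(0.055, -0.01, 0.019), amplitude_jitter = amplitude_jitter)
  models <- list(fiber_S = fiber_S, vessel_S = vessel_S, ray_S = ray_S)
  if (wood_type == "TW") models$fiber_G <- fiber_G
  models[sort(names(models))]
}

#' Scene specification
#'
#' @param geometry an [image_geometry()].
#' @param wood_type preset layout (`"NW"`, `"OW"`, `"TW"`), ignored when
#'   `layout` is given.
#' @param layout optional explicit character label raster matching the
#'   geometry (codes must be model class names or `"LUMEN"`).
#' @param noise_sd i.i.d. Gaussian absorbance noise sd (AU) added per pixel
#'   and wavenumber.
#' @param seed integer seed; identical (spec, models) give bit-identical
#'   scenes.
#' @param axis the [spectral_axis()] of the scene.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(geometry = image_geometry(), wood_type = "TW",
                       layout = NULL, noise_sd = 0.01, seed = 42L,
                       axis = spectral_axis()) {
  if (!is.null(layout)) {
    layout <- as.matrix(layout)
    if (!all(dim(layout) == c(geometry$n_rows, geometry$n_cols)))
      stop("explicit layout raster does not match geometry")
  } else wood_type <- match.arg(wood_type, c("TW", "NW", "OW"))
  structure(list(geometry = geometry, wood_type = wood_type, layout = layout,
                 noise_sd = noise_sd, seed = as.integer(seed), axis = axis),
            class = "scene_spec")
}

## Preset label raster: fiber tiles (S ring, lumen; TW adds a G ring), one
## horizontal ray band, three vessels stamped on top.
preset_layout <- function(geometry, wood_type) {
  nr <- geometry$n_rows; nc <- geometry$n_cols
  lab <- matrix("fiber_S", nr, nc)
  tile <- 16L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    i <- (r - 1L) %% tile; j <- (cc - 1L) %% tile
    if (wood_type == "TW") {
      in_lumen <- i >= 5 && i <= 10 && j >= 5 && j <= 10
      in_g <- !in_lumen && i >= 2 && i <= 13 && j >= 2 && j <= 13
      lab[r, cc] <- if (in_lumen) "LUMEN" else if (in_g) "fiber_G" else "fiber_S"
    } else {
      lo <- if (wood_type == "NW") 4 else 5
      hi <- if (wood_type == "NW") 11 else 10
      in_lumen <- i >= lo && i <= hi && j >= lo && j <= hi
      lab[r, cc] <- if (in_lumen) "LUMEN" else "fiber_S"
    }
  }
  # ray band
  ray_rows <- intersect(29:32, seq_len(nr))
  lab[ray_rows, ] <- "ray_S"
  # vessels: wall for 4 < r <= 8.5, lumen inside
  centers <- list(c(12, 44), c(44, 12), c(54, 54))
  for (ct in centers) {
    if (ct[1] > nr || ct[2] > nc) next
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      d <- sqrt((r - ct[1])^2 + (cc - ct[2])^2)
      if (d <= 4) lab[r, cc] <- "LUMEN"
      else if (d <= 8.5) lab[r, cc] <- "vessel_S"
    }
  }
  lab
}

## Evaluate expr with a private RNG stream; global .Random.seed untouched.
with_scene_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic hyperspectral scene
#'
#' Each cell-wall pixel's spectrum is its class clean spectrum with per-pixel,
#' per-band amplitude jitter, plus the class baseline and i.i.d. Gaussian
#' noise; lumen pixels carry baseline and noise only. Identical (spec,
#' models) reproduce bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @param models named list of [class_spectrum_model()] (default:
#'   [default_models()] for the spec's wood type).
#' @return list: `image` ([hsi_image()]), `truth` ([label_map()]),
#'   `models`, `spec`.
#' @export
generate_scene <- function(spec, models = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(models)) models <- default_models(spec$wood_type)
  lab <- if (!is.null(spec$layout)) spec$layout else preset_layout(spec$geometry, spec$wood_type)
  used <- setdiff(unique(as.vector(lab)), "LUMEN")
  missing <- setdiff(used, names(models))
  if (length(missing))
    stop(sprintf("layout uses class(es) with no model: %s", paste(missing, collapse = ", ")))
  axis <- spec$axis
  g <- spec$geometry
  nb <- length(axis)
  labs_flat <- as.vector(t(lab))   # row-major pixel order
  cube_flat <- matrix(0, g$n_pixels, nb)
  lumen_base <- baseline_values(class_spectrum_model("LUMEN",
                  data.frame(center = 1000, width = 10, amplitude = 0),
                  baseline = c(0.02, 0, 0)), axis)
  with_scene_rng(spec$seed, {
    for (cl in sort(used)) {
      sel <- which(labs_flat == cl)
      mdl <- models[[cl]]
      prof <- band_profiles(mdl, axis)
      amps <- matrix(mdl$bands$amplitude, length(sel), nrow(mdl$bands), byrow = TRUE)
      if (mdl$amplitude_jitter > 0)
        amps <- amps * pmax(0, 1 + matrix(stats::rnorm(length(amps), 0, mdl$amplitude_jitter),
                                          nrow(amps)))
      base <- baseline_values(mdl, axis)
      cube_flat[sel, ] <- amps %*% prof +
        matrix(base, length(sel), nb, byrow = TRUE)
    }
    lum <- which(labs_flat == "LUMEN")
    if (length(lum))
      cube_flat[lum, ] <- matrix(lumen_base, length(lum), nb, byrow = TRUE)
    if (spec$noise_sd > 0)
      cube_flat <- cube_flat + matrix(stats::rnorm(length(cube_flat), 0, spec$noise_sd),
                                      nrow(cube_flat))
  })
  cube <- array(NA_real_, c(g$n_rows, g$n_cols, nb))
  for (b in seq_len(nb))
    cube[, , b] <- matrix(cube_flat[, b], g$n_rows, g$n_cols, byrow = TRUE)
  legend <- stats::setNames(c(sort(used), "lumen"), c(sort(used), "LUMEN"))
  list(image = hsi_image(g, axis, cube,
                         metadata = list(wood_type = spec$wood_type,
                                         noise_sd = spec$noise_sd,
                                         seed = spec$seed)),
       truth = label_map(g, lab, legend),
       models = models, spec = spec)
}

#' Interior (non-boundary) pixel mask
#'
#' A pixel is interior when every in-grid 4-neighbour carries the same label.
#' Boundary pixels sit at class interfaces, where mixed signal makes
#' assignment intrinsically ambiguous; recovery metrics exclude them.
#'
#' @param map a [label_map()].
#' @return logical matrix, `TRUE` for interior pixels.
#' @export
interior_pixels <- function(map) {
  stopifnot(inherits(map, "label_map"))
  lab <- map$labels
  nr <- nrow(lab); nc <- ncol(lab)
  same <- function(a, b) is.na(a) == is.na(b) & (is.na(a) | a == b)
  up    <- rbind(lab[1, , drop = FALSE], lab[-nr, , drop = FALSE])
  down  <- rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE])
  left  <- cbind(lab[, 1, drop = FALSE], lab[, -nc, drop = FALSE])
  right <- cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE])
  same(lab, up) & same(lab, down) & same(lab, left) & same(lab, right)
}

#' Sample labelled training pixels from ground truth
#'
#' Uniform random sample without replacement of `n_per_class` interior pixels
#' per class, emulating manual selection of representative pixels (the
#' reference protocol uses 90 per class).
#'
#' @param truth a [label_map()].
#' @param n_per_class pixels per class (default 90).
#' @param seed integer seed for reproducibility.
#' @param image_id id recorded in the output table.
#' @param exclude labels never sampled.
#' @return data frame `image_id,row,col,class` (0-based coordinates).
#' @export
generate_selections <- function(truth, n_per_class = 90L, seed = 42L,
                                image_id = "image1",
                                exclude = c("LUMEN", "NA")) {
  stopifnot(inherits(truth, "label_map"))
  interior <- interior_pixels(truth)
  classes <- setdiff(sort(unique(as.vector(truth$labels))), exclude)
  rows <- list()
  with_scene_rng(seed, {
    for (cl in classes) {
      idx <- which(truth$labels == cl & interior, arr.ind = TRUE)
      if (nrow(idx) < n_per_class)
        stop(sprintf("class '%s' has only %d interior pixels; %d requested",
                     cl, nrow(idx), n_per_class))
      pick <- idx[sample.int(nrow(idx), n_per_class), , drop = FALSE]
      rows[[cl]] <- data.frame(image_id = image_id,
                               row = pick[, 1] - 1L, col = pick[, 2] - 1L,
                               class = cl)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a scene spec as a flat key-value text config
#'
#' Keys: `wood_type`, `noise_sd`, `seed`, `field_width_um`, `field_height_um`,
#' `pixel_size_um`, `axis_from`, `axis_to`, `axis_step`.
#'
#' @param spec a [scene_spec()] (presets only; explicit rasters are not
#'   serialized).
#' @param path file path.
#' @return `read_scene_spec` returns a `scene_spec`; `write_scene_spec` its
#'   path, invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$layout)) stop("explicit layout rasters are not serialized")
  g <- spec$geometry; wn <- as.numeric(spec$axis)
  writeLines(c(sprintf("wood_type = %s", spec$wood_type),
               sprintf("noise_sd = %.17g", spec$noise_sd),
               sprintf("seed = %d", spec$seed),
               sprintf("field_width_um = %.17g", g$field_width_um),
               sprintf("field_height_um = %.17g", g$field_height_um),
               sprintf("pixel_size_um = %.17g", g$pixel_size_um),
               sprintf("axis_from = %.17g", wn[1]),
               sprintf("axis_to = %.17g", wn[length(wn)]),
               sprintf("axis_step = %.17g", axis_step(spec$axis))),
             path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  kv <- read_config(path)
  geom <- image_geometry(as.numeric(kv$field_width_um %||% 100),
                         as.numeric(kv$field_height_um %||% 100),
                         as.numeric(kv$pixel_size_um %||% 1.56))
  axis <- spectral_axis(as.numeric(kv$axis_from %||% 1800),
                        as.numeric(kv$axis_to %||% 850),
                        as.numeric(kv$axis_step %||% 2))
  scene_spec(geometry = geom, wood_type = kv$wood_type %||% "TW",
             noise_sd = as.numeric(kv$noise_sd %||% 0.01),
             seed = as.integer(as.numeric(kv$seed %||% 42)), axis = axis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop(sprintf("malformed config line: %s", ln))
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}
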