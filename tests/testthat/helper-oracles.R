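# Independent oracles and small fixture builders shared across tests.

rand_spectrum <- function(axis = spectral_axis(), sd = 1) {
  ir_spectrum(axis, rnorm(length(axis), sd = sd))
}

# Least-squares polynomial removal solved through the raw normal equations
# on uncentered wavenumber powers (a deliberately different numerical route
# from the package's scaled-basis QR fit).
oracle_detrend <- function(values, wavenumbers, degree = 2) {
  z <- (values - mean(values)) / sd(values)
  X <- outer(wavenumbers, 0:degree, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  as.numeric(z - X %*% beta)
}

# Mid-ranks computed by counting (not via rank()), then the textbook Pearson
# formula.
oracle_midranks <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, 0)
}
oracle_spearman <- function(a, b) {
  ra <- oracle_midranks(a); rb <- oracle_midranks(b)
  n <- length(ra)
  num <- sum(ra * rb) - n * mean(ra) * mean(rb)
  den <- sqrt((sum(ra^2) - n * mean(ra)^2) * (sum(rb^2) - n * mean(rb)^2))
  num / den
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n+m, n)
# placements of the first sample's ranks.
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  placements <- utils::combn(nx + ny, nx)
  U_all <- colSums(matrix(seq_len(nx + ny)[placements], nrow = nx)) -
    nx * (nx + 1) / 2
  center <- nx * ny / 2
  mean(abs(U_all - center) >= abs(U_obs - center))
}

# Brute-force average-linkage agglomeration returning merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Tiny scene used where a full 64x64 field is unnecessary.
tiny_scene <- function(noise_sd = 0.005, seed = 11, n = 24) {
  geom <- image_geometry(n * 1.56, n * 1.56, 1.56)
  models <- default_models("TW")
  lab <- matrix("fiber_S", n, n)
  lab[1:8, 1:12] <- "fiber_G"
  lab[17:24, 1:8] <- "vessel_S"
  lab[17:24, 17:24] <- "ray_S"
  lab[10:14, 14:20] <- "LUMEN"
  generate_scene(scene_spec(geom, layout = lab, noise_sd = noise_sd, seed = seed),
                 models)
}
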