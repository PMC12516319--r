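# Shared fixtures and independent oracles. Scenes are memoised so the
# expensive skeleton/binning work is done once per test run.

.scene_cache <- new.env(parent = emptyenv())

capsuleScene <- function(a = 200, r = 50, curvature = 0, psz = 2,
                         seed = 1, noise = 0, rotation = 0) {
  key <- paste("cap", a, r, curvature, psz, seed, noise, rotation, sep = "|")
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- makeOrganoidMask(
      centerline_length_um = a, cap_radius_um = r, curvature = curvature,
      pixel_size_um = psz, rotation_deg = rotation,
      boundary_noise_px = noise, seed = seed)
  .scene_cache[[key]]
}

profileScene <- function(a = 200, r = 50, curvature = 0, psz = 2, seed = 1) {
  key <- paste("prof", a, r, curvature, psz, seed, sep = "|")
  if (is.null(.scene_cache[[key]])) {
    sc <- capsuleScene(a, r, curvature, psz, seed)
    ax <- medialAxis(sc$mask)
    bn <- makeBins(splitContour(sc$mask, ax), sc$mask, ax)
    .scene_cache[[key]] <- list(scene = sc, axis = ax, binning = bn)
  }
  .scene_cache[[key]]
}

# exhaustive entropy search, the independent oracle for kapurThreshold
bruteKapur <- function(counts) {
  p <- counts / sum(counts)
  L <- length(p)
  best <- -Inf
  bi <- NA_integer_
  for (t in seq_len(L - 1L)) {
    Pb <- sum(p[1:t]); Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    pb <- p[1:t][p[1:t] > 0] / Pb
    pf <- p[(t + 1L):L][p[(t + 1L):L] > 0] / Pf
    H <- -sum(pb * log(pb)) - sum(pf * log(pf))
    if (H > best + 1e-12) { best <- H; bi <- t }
  }
  bi
}

# brute-force double-loop time-averaged MSD
bruteMSD <- function(track, dims = 3) {
  p <- as.matrix(track[, c("x", "y", "z")[seq_len(dims)]])
  n <- nrow(p)
  vapply(seq_len(n - 1L), function(k) {
    acc <- 0
    for (i in seq_len(n - k)) acc <- acc + sum((p[i + k, ] - p[i, ])^2)
    acc / (n - k)
  }, numeric(1))
}

logisticProfile <- function(x, midpoint, steepness = 20, baseline = 0.05,
                            direction = "rising") {
  s <- if (direction == "falling") -1 else 1
  baseline + 1 / (1 + exp(-s * steepness * (x - midpoint)))
}

# analytic truth for the capsule used throughout: EI of a capsule with
# half-length a and cap radius r
capsuleEI <- function(a, r) {
  A <- 2 * r * a + pi * r^2
  P <- 2 * a + 2 * pi * r
  1 - 4 * pi * A / P^2
}

makeTrack <- function(id, n, dt = 20, fun = function(t) cbind(t, 0, 0)) {
  t <- (seq_len(n) - 1) * dt
  p <- fun(t)
  data.frame(track_id = id, t = t, x = p[, 1], y = p[, 2], z = p[, 3])
}
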