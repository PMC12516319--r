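# Internal planar-geometry helpers. Convention throughout the package:
# image matrices are indexed [row = y, col = x]; the centre of pixel
# (i, j) sits at physical coordinates x = (j - 1) * pixel_size_um,
# y = (i - 1) * pixel_size_um. Polylines and polygons are n x 2
# matrices with columns (x, y) in micrometres.

segLengths <- function(p) {
  d <- diff(p)
  sqrt(rowSums(d^2))
}

polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(segLengths(p))
}

cumArc <- function(p) c(0, cumsum(segLengths(p)))

#' @noRd
#' Resample a polyline to n points equidistant in arc length,
#' preserving the exact endpoints.
resamplePolyline <- function(p, n) {
  s <- cumArc(p)
  L <- s[length(s)]
  if (L <= 0) stop("cannot resample a zero-length polyline")
  # drop duplicated vertices so approx() sees strictly increasing s
  keep <- c(TRUE, diff(s) > 0)
  p <- p[keep, , drop = FALSE]
  s <- s[keep]
  si <- seq(0, L, length.out = n)
  cbind(
    stats::approx(s, p[, 1], xout = si)$y,
    stats::approx(s, p[, 2], xout = si)$y
  )
}

#' @noRd
#' Centred moving average with shrinking windows at the ends, so the
#' smoothed polyline keeps the same number of points and its endpoints
#' move only as far as their half-window allows.
smoothPolyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (window <= 1L || n < 3L) return(p)
  h <- window %/% 2L
  out <- p
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  out
}

polygonArea <- function(p) {
  abs(pracma::polyarea(p[, 1], p[, 2]))
}

#' @noRd
#' Area centroid of a simple polygon (closed or open representation).
polygonCentroid <- function(p) {
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @noRd
#' Ensure a closed polygon (first row == last row), counter-clockwise.
closePolygon <- function(p) {
  if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
  if (pracma::polyarea(p[, 1], p[, 2]) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

#' @noRd
#' First intersection of the ray origin + t * dir (t > 0) with a closed
#' polygon; returns the point, or NULL when the ray misses.
rayPolygonIntersect <- function(origin, dir, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # solve origin + t*dir = a + u*e, 0 <= u <= 1, t > 0
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  ok <- abs(den) > 1e-12
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  t <- (wx * (-ey) - wy * (-ex)) / den
  u <- (dir[1] * wy - dir[2] * wx) / den
  hit <- ok & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(hit)) return(NULL)
  tmin <- min(t[hit])
  c(origin[1] + tmin * dir[1], origin[2] + tmin * dir[2])
}

#' @noRd
#' Nearest point on a polyline for each query point; returns arc-length
#' parameter s and distance. Vectorised over polyline segments.
nearestOnPolyline <- function(path, q) {
  a <- path[-nrow(path), , drop = FALSE]
  b <- path[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1e-300
  s0 <- cumArc(path)
  nq <- nrow(q)
  bestD2 <- rep(Inf, nq)
  bestS <- numeric(nq)
  for (k in seq_len(nrow(a))) {
    wx <- q[, 1] - a[k, 1]; wy <- q[, 2] - a[k, 2]
    u <- (wx * ex[k] + wy * ey[k]) / len2[k]
    u <- pmin(1, pmax(0, u))
    dx <- wx - u * ex[k]; dy <- wy - u * ey[k]
    d2 <- dx^2 + dy^2
    better <- d2 < bestD2
    if (any(better)) {
      bestD2[better] <- d2[better]
      bestS[better] <- s0[k] + u[better] * sqrt(len2[k])
    }
  }
  list(s = bestS, dist = sqrt(bestD2))
}

#' @noRd
#' Do segments p1-p2 and p3-p4 properly intersect?
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' @noRd
#' Physical (x, y) coordinates of the centres of TRUE pixels.
pixelCenters <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 1) * pixel_size_um, y = (idx[, 1] - 1) * pixel_size_um)
}

#' @noRd
#' Bilinear interpolation of a matrix at fractional (row, col)
#' positions; out-of-range queries clamp to the border.
bilinearAt <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

rotationMatrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
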