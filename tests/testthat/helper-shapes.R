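# Shape fixtures and independent geometric oracles. Masks are built by
# direct pixel-centre inequalities (not via package internals) so that
# tests check the package against genuinely independent constructions.

# Filled disk mask: pixel centres within radius r of (cr, cc) (0-based).
make_disk_mask <- function(n, r, cr = n / 2, cc = n / 2) {
  m <- matrix(0, n, n)
  rr <- row(m) - 0.5; ccol <- col(m) - 0.5
  m[(rr - cr)^2 + (ccol - cc)^2 <= r^2] <- 1
  m
}

# Filled axis-aligned ellipse mask with semi-axes (a, b) along (row, col).
make_ellipse_mask <- function(n, a, b, cr = n / 2, cc = n / 2) {
  m <- matrix(0, n, n)
  rr <- row(m) - 0.5; ccol <- col(m) - 0.5
  m[((rr - cr) / a)^2 + ((ccol - cc) / b)^2 <= 1] <- 1
  m
}

# Regular k-pointed star polygon (closed ring, 0-based coords).
star_polygon <- function(outer, inner, k = 5, cr = 0, cc = 0) {
  ang <- seq(0, 2 * pi, length.out = 2 * k + 1)[1:(2 * k)] - pi / 2
  rad <- rep(c(outer, inner), k)
  xy <- cbind(cr + rad * cos(ang), cc + rad * sin(ang))
  rbind(xy, xy[1, ])
}

# Rasterize a star-shaped (radial) region given a radius function r(theta).
rasterize_radial <- function(n, rfun, cr = n / 2, cc = n / 2) {
  m <- matrix(0, n, n)
  rr <- row(m) - 0.5 - cr; ccol <- col(m) - 0.5 - cc
  th <- atan2(ccol, rr)
  m[sqrt(rr^2 + ccol^2) <= rfun(th)] <- 1
  m
}

# Random smooth Fourier blob: radius function plus its dense polyline.
fourier_blob <- function(seed, r0 = 40, n_harm = 4, amp = 0.12) {
  set.seed(seed)
  k <- 2:(n_harm + 1)
  a <- runif(n_harm, 0, amp)
  ph <- runif(n_harm, 0, 2 * pi)
  rfun <- function(th) r0 * (1 + colSums(a * cos(outer(k, th) +  ph)))
  th <- seq(0, 2 * pi, length.out = 20001)
  ring <- cbind(rfun(th) * cos(th), rfun(th) * sin(th))
  list(rfun = rfun, ring = ring)
}

# Polygon area, perimeter, centroid and central second moments by exact
# Green's-theorem formulas on the (dense) ring -- the analytic oracle.
polygon_oracle <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  xi <- x[-n]; yi <- y[-n]; xj <- x[-1]; yj <- y[-1]
  cr <- xi * yj - xj * yi
  A <- sum(cr) / 2
  cx <- sum((xi + xj) * cr) / (6 * A)
  cy <- sum((yi + yj) * cr) / (6 * A)
  Ixx <- sum((xi^2 + xi * xj + xj^2) * cr) / 12
  Iyy <- sum((yi^2 + yi * yj + yj^2) * cr) / 12
  Ixy <- sum((xi * yj + 2 * xi * yi + 2 * xj * yj + xj * yi) * cr) / 24
  mu20 <- Ixx / A - cx^2
  mu02 <- Iyy / A - cy^2
  mu11 <- Ixy / A - cx * cy
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  list(area = abs(A),
       perimeter = sum(sqrt(rowSums(diff(ring)^2))),
       centroid = c(cx, cy),
       mu = c(mu20 = mu20, mu02 = mu02, mu11 = mu11),
       axes_full = 4 * sqrt(pmax(ev, 0)))
}

# Numerical complete-elliptic-integral ellipse perimeter (oracle for
# Ramanujan's approximation): P = 4 a E(e).
ellipse_perimeter_oracle <- function(major, minor) {
  a <- major / 2; b <- minor / 2
  e2 <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                           rel.tol = 1e-12)$value
}

# Synthetic two-peak line profile: Gaussian bumps at the given positions.
two_peak_profile <- function(gap_um, amp = c(100, 90), sigma_um = 0.4,
                             pad_um = 6, step_um = 0.05) {
  p1 <- pad_um; p2 <- pad_um + gap_um
  len <- p2 + pad_um
  pos <- seq(0, len, by = step_um)
  v <- amp[1] * exp(-(pos - p1)^2 / (2 * sigma_um^2)) +
       amp[2] * exp(-(pos - p2)^2 / (2 * sigma_um^2))
  structure(list(pos_um = pos, intensity = v, corrected = v,
                 length_um = len), class = "line_scan")
}

# FWHM of the highest bump in a profile by half-maximum crossing
# interpolation (independent peak-shape oracle).
fwhm_oracle <- function(pos, v) {
  i <- which.max(v)
  half <- (v[i] + min(v)) / 2
  left <- max(which(v[1:i] < half))
  right <- i - 1 + min(which(v[i:length(v)] < half))
  xl <- approx(v[c(left, left + 1)], pos[c(left, left + 1)], xout = half)$y
  xr <- approx(v[c(right - 1, right)], pos[c(right - 1, right)], xout = half)$y
  xr - xl
}
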