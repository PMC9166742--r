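## Internal helpers shared across modules.
##
## Coordinate convention (all modules): (row, col), 0-based, origin at the
## top-left image corner, half-open pixel intervals. The centre of the pixel
## stored at R index [i, j] is (i - 0.5, j - 0.5). Physical units are obtained
## by multiplying by pixel_size_um.

#' @keywords internal
#' @noRd
stop_mlq <- function(msg, class, ...) {
  stop(structure(class = c(class, "monolayerq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Run code with a private RNG state seeded from `seed`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_mlq("seed must be a single finite number", "invalid_parameter")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Close a polygon ring (first vertex repeated at the end).
#' @keywords internal
#' @noRd
close_ring <- function(xy) {
  if (!isTRUE(all(xy[1L, ] == xy[nrow(xy), ]))) xy <- rbind(xy, xy[1L, ])
  xy
}

#' Signed area of a closed ring by the shoelace formula.
#' Positive when the ring is counterclockwise in (row, col) axes.
#' @keywords internal
#' @noRd
ring_signed_area <- function(xy) {
  xy <- close_ring(xy)
  n <- nrow(xy)
  sum(xy[-n, 1L] * xy[-1L, 2L] - xy[-1L, 1L] * xy[-n, 2L]) / 2
}

#' Polyline length of a closed ring.
#' @keywords internal
#' @noRd
ring_perimeter <- function(xy) {
  xy <- close_ring(xy)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Cumulative arc length along a closed ring, starting at 0.
#' @keywords internal
#' @noRd
ring_arclength <- function(xy) {
  xy <- close_ring(xy)
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

#' Resample a closed ring at uniform arc-length steps.
#'
#' Returns positions (arc length from the first vertex), interpolated (row,
#' col) coordinates, and unit tangents. The last sample stops short of the
#' full perimeter so samples tile the ring without duplicating the start.
#' @keywords internal
#' @noRd
resample_ring <- function(xy, step) {
  xy <- close_ring(xy)
  s <- ring_arclength(xy)
  P <- s[length(s)]
  if (P <= 0) stop_mlq("degenerate ring with zero perimeter", "degenerate_geometry")
  pos <- seq(0, P, by = step)
  if (length(pos) > 1L && (P - pos[length(pos)]) < step / 2)
    pos <- pos[-length(pos)]
  r <- approx(s, xy[, 1L], xout = pos, rule = 2)$y
  c_ <- approx(s, xy[, 2L], xout = pos, rule = 2)$y
  ## central-difference tangent on the circularly continued samples
  n <- length(pos)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  tr <- r[ip] - r[im]; tc <- c_[ip] - c_[im]
  nrm <- sqrt(tr^2 + tc^2); nrm[nrm == 0] <- 1
  list(arc = pos, row = r, col = c_, trow = tr / nrm, tcol = tc / nrm,
       perimeter = P)
}

#' Bilinear interpolation of an image at sub-pixel (row, col) points.
#' Points are in the 0-based pixel-centre convention; values outside the
#' image are clamped to the edge.
#' @keywords internal
#' @noRd
interp_bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  ## convert to pixel-centre index space (centre of img[i,j] at i-0.5)
  ri <- pmin(pmax(row + 0.5, 1), nr)
  ci <- pmin(pmax(col + 0.5, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  i00 <- img[cbind(r0, c0)];     i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

#' Rolling minimum with a centred window (edge-truncated).
#' @keywords internal
#' @noRd
rolling_min <- function(x, half_window) {
  n <- length(x)
  h <- max(0L, as.integer(half_window))
  vapply(seq_len(n), function(i)
    min(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Centred moving average (edge-truncated).
#' @keywords internal
#' @noRd
moving_average <- function(x, half_window) {
  n <- length(x)
  h <- max(0L, as.integer(half_window))
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Local maxima of a vector (plateau-aware: the centre index of each
#' plateau that is strictly higher than both neighbours).
#' @keywords internal
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  ## collapse plateaus to runs
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  idx <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      idx <- c(idx, as.integer(floor((starts[j] + ends[j]) / 2)))
    }
  }
  idx
}

#' Rasterize a filled polygon (0-based row/col ring) into a binary mask.
#' A pixel is foreground when its centre lies inside the ring.
#' @keywords internal
#' @noRd
rasterize_polygon <- function(xy, nrow_px, ncol_px) {
  xy <- close_ring(xy)
  rr <- matrix(rep((1:nrow_px) - 0.5, ncol_px), nrow_px, ncol_px)
  cc <- matrix(rep((1:ncol_px) - 0.5, each = nrow_px), nrow_px, ncol_px)
  inside <- point_in_polygon(as.vector(rr), as.vector(cc), xy)
  matrix(as.numeric(inside), nrow_px, ncol_px)
}

#' Even-odd point-in-polygon test, vectorised over points.
#' @keywords internal
#' @noRd
point_in_polygon <- function(pr, pc, xy) {
  xy <- close_ring(xy)
  n <- nrow(xy) - 1L
  inside <- logical(length(pr))
  for (k in seq_len(n)) {
    r1 <- xy[k, 1L]; c1 <- xy[k, 2L]
    r2 <- xy[k + 1L, 1L]; c2 <- xy[k + 1L, 2L]
    crosses <- ((c1 > pc) != (c2 > pc))
    if (any(crosses)) {
      t <- (pc[crosses] - c1) / (c2 - c1)
      rx <- r1 + t * (r2 - r1)
      inside[crosses] <- xor(inside[crosses], rx > pr[crosses])
    }
  }
  inside
}

#' Disk offsets (integer row/col) of radius r pixels.
#' @keywords internal
#' @noRd
disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}
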