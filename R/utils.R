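# Internal numerical helpers shared across modules.
#
# Raster convention: matrices are indexed [row, col] (R, 1-based internally);
# all user-facing coordinates are 0-based with pixel centres at integers,
# x = col - 1, y = row - 1. Contours are n x 2 matrices with columns (x, y).

# Shift a matrix by (dr, dc) with replicate (Neumann) border handling, so that
# out[i, j] = m[i - dr, j - dc] clamped to the grid.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central-difference gradient; x runs along columns, y along rows.
grad_central <- function(m) {
  gx <- (shift_mat(m, 0L, -1L) - shift_mat(m, 0L, 1L)) / 2
  gy <- (shift_mat(m, -1L, 0L) - shift_mat(m, 1L, 0L)) / 2
  list(x = gx, y = gy)
}

# Divergence of the vector field (u, v) by central differences.
div_central <- function(u, v) {
  (shift_mat(u, 0L, -1L) - shift_mat(u, 0L, 1L)) / 2 +
    (shift_mat(v, -1L, 0L) - shift_mat(v, 1L, 0L)) / 2
}

# 8-neighbourhood (3x3) grayscale dilation / erosion via shifted maxima.
dilate8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}

erode8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmin(out, shift_mat(m, dr, dc))
  }
  out
}

# 8-connected flood fill of `mask` (logical matrix) from `seed` (logical).
flood_fill8 <- function(mask, seed) {
  cur <- seed & mask
  repeat {
    nxt <- (dilate8(cur * 1) > 0) & mask
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate borders.
gaussian_blur2d <- function(m, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, 0L, i - r - 1L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_mat(out, i - r - 1L, 0L)
  out2
}

# 1-D Gaussian smoothing with reflect boundary handling.
gaussian_smooth1d <- function(x, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  # reflect indices about the ends (no repeated edge sample)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  idx <- pmin(pmax(idx, 1L), n)
  xp <- x[idx]
  out <- numeric(n)
  for (i in seq_along(k)) out <- out + k[i] * xp[seq_len(n) + (i - 1L)]
  out
}

# Shoelace signed area of an n x 2 polygon (closed implicitly).
poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

poly_perimeter <- function(p, closed = TRUE) {
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  s <- sum(d)
  if (closed) s <- s + sqrt((p[1, 1] - p[nrow(p), 1])^2 + (p[1, 2] - p[nrow(p), 2])^2)
  s
}

# Minimum distance from each query point to a polyline/polygon (point-to-segment).
# pts: n x 2; poly: m x 2. Returns length-n vector.
points_min_dist <- function(pts, poly, closed = TRUE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (nrow(poly) == 1)
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  ax <- poly[, 1]; ay <- poly[, 2]
  if (closed) {
    bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  } else {
    bx <- ax[-1]; by <- ay[-1]; ax <- ax[-length(ax)]; ay <- ay[-length(ay)]
  }
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  el2[el2 < 1e-24] <- 1e-24
  n <- nrow(pts); m <- length(ax)
  # outer products: n x m
  dx <- outer(pts[, 1], ax, "-"); dy <- outer(pts[, 2], ay, "-")
  t <- sweep(dx, 2, ex, "*") + sweep(dy, 2, ey, "*")
  t <- sweep(t, 2, el2, "/")
  t[t < 0] <- 0; t[t > 1] <- 1
  px <- sweep(t, 2, ex, "*") - dx
  py <- sweep(t, 2, ey, "*") - dy
  d2 <- px^2 + py^2
  sqrt(apply(d2, 1, min))
}

# Even-odd rule point-in-polygon test, vectorised over points.
points_in_poly <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  inside <- logical(n)
  m <- nrow(poly)
  j <- m
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
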