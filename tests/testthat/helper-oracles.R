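# Independent reference implementations used as oracles. These are written
# as plain scalar loops / dense sums, deliberately sharing no code with the
# package internals they check.

# Replicate-border lookup.
ref_at <- function(m, i, j) {
  m[min(max(i, 1L), nrow(m)), min(max(j, 1L), ncol(m))]
}

# Dense 2-D Gaussian convolution with replicate borders (direct double sum).
ref_gaussian_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); w <- w / sum(w)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + w[a + r + 1] * w[b + r + 1] * ref_at(m, i + a, j + b)
    out[i, j] <- acc
  }
  out
}

# Scalar-loop edge indicator: g = 1 / (1 + |grad(G*I)|), central differences.
ref_edge_indicator <- function(m, sigma) {
  sm <- ref_gaussian_blur(m, sigma)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    gx <- (ref_at(sm, i, j + 1) - ref_at(sm, i, j - 1)) / 2
    gy <- (ref_at(sm, i + 1, j) - ref_at(sm, i - 1, j)) / 2
    out[i, j] <- 1 / (1 + sqrt(gx^2 + gy^2))
  }
  out
}

# Stencil-by-stencil scalar reference of one level-set update (no prior).
ref_evolve_step <- function(phi, g, p) {
  nr <- nrow(phi); nc <- ncol(phi)
  # Neumann boundary condition
  phi[1, ] <- phi[2, ]; phi[nr, ] <- phi[nr - 1, ]
  phi[, 1] <- phi[, 2]; phi[, nc] <- phi[, nc - 1]
  dpf <- function(s) {
    if (s < 1e-10) return(1)
    if (s <= 1) sin(2 * pi * s) / (2 * pi * s) else (s - 1) / s
  }
  dirac <- function(x) if (abs(x) <= p$epsilon)
    (1 + cos(pi * x / p$epsilon)) / (2 * p$epsilon) else 0
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx[i, j] <- (ref_at(phi, i, j + 1) - ref_at(phi, i, j - 1)) / 2
    gy[i, j] <- (ref_at(phi, i + 1, j) - ref_at(phi, i - 1, j)) / 2
  }
  s <- sqrt(gx^2 + gy^2)
  u1 <- matrix(0, nr, nc); v1 <- matrix(0, nr, nc)
  u2 <- matrix(0, nr, nc); v2 <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dp <- dpf(s[i, j])
    u1[i, j] <- dp * gx[i, j]; v1[i, j] <- dp * gy[i, j]
    sf <- max(s[i, j], 1e-10)
    u2[i, j] <- g[i, j] * gx[i, j] / sf; v2[i, j] <- g[i, j] * gy[i, j] / sf
  }
  out <- phi
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    reg <- (ref_at(u1, i, j + 1) - ref_at(u1, i, j - 1)) / 2 +
           (ref_at(v1, i + 1, j) - ref_at(v1, i - 1, j)) / 2
    edg <- (ref_at(u2, i, j + 1) - ref_at(u2, i, j - 1)) / 2 +
           (ref_at(v2, i + 1, j) - ref_at(v2, i - 1, j)) / 2
    d <- dirac(phi[i, j])
    out[i, j] <- phi[i, j] + p$timestep *
      (p$mu * reg + p$lam * d * edg + p$alpha * g[i, j] * d)
  }
  out
}

# Brute-force symmetric mean contour distance: scalar loops over points and
# segments.
ref_seg_dist <- function(px, py, x1, y1, x2, y2) {
  ex <- x2 - x1; ey <- y2 - y1
  l2 <- ex^2 + ey^2
  if (l2 < 1e-24) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * ex + (py - y1) * ey) / l2
  t <- min(max(t, 0), 1)
  sqrt((px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2)
}

ref_point_to_poly <- function(px, py, poly, closed = TRUE) {
  n <- nrow(poly)
  best <- Inf
  last <- if (closed) n else n - 1
  for (i in seq_len(last)) {
    j <- if (i == n) 1 else i + 1
    best <- min(best, ref_seg_dist(px, py, poly[i, 1], poly[i, 2],
                                   poly[j, 1], poly[j, 2]))
  }
  best
}

ref_mean_contour_distance <- function(pa, pb) {
  da <- vapply(seq_len(nrow(pa)), function(i)
    ref_point_to_poly(pa[i, 1], pa[i, 2], pb, closed = nrow(pb) >= 3), numeric(1))
  db <- vapply(seq_len(nrow(pb)), function(i)
    ref_point_to_poly(pb[i, 1], pb[i, 2], pa, closed = nrow(pa) >= 3), numeric(1))
  (sum(da) + sum(db)) / (nrow(pa) + nrow(pb))
}

ref_dice <- function(a, b) {
  av <- as.logical(a); bv <- as.logical(b)
  if (sum(av) + sum(bv) == 0) return(1)
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

# A 128x128 dark-disk study image with analytic truth.
make_disk_case <- function(n = 128, radius = 30, seed_radius = 12,
                           dark = 0.1, bright = 0.9) {
  ctr <- (n - 1) / 2
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(rep(0:(n - 1), each = n), n, n)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  ang <- seq(0, 2 * pi, length.out = 361)[-1]
  list(image = ifelse(r <= radius, dark, bright),
       truth = r <= radius,
       seed = r <= seed_radius,
       circle = contour(cbind(x = ctr + radius * cos(ang),
                              y = ctr + radius * sin(ang))))
}

# Single-chamber weak-boundary phantom at maximum expansion.
make_gap_phantom <- function(seed, gap_fraction = 0.25) {
  generate_phantom(phantom_spec(
    height = 96, width = 128, n_frames = 1,
    chambers = list(chamber_spec(center = c(55, 64),
                                 base_semi_axes = c(22, 16), phase = pi / 2)),
    gap_fraction = gap_fraction, speckle_strength = 0.1, rng_seed = seed))
}

gap_base_shape <- function() chamber_spec(center = c(55, 64),
                                          base_semi_axes = c(22, 16),
                                          phase = pi / 2)
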