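#' Specify a beating chamber for the synthetic phantom
#'
#' A chamber is a dark elliptical lumen surrounded by a bright wall, whose
#' semi-axes are modulated sinusoidally in time:
#' `a(t) = a * (1 + beat_amplitude * sin(2*pi*beat_frequency*t + phase))`
#' (and likewise for `b`). Normal Drosophila hearts beat at about 4-6 beats/s.
#'
#' @param center numeric `(row, col)` centre in 0-based pixel coordinates.
#' @param base_semi_axes numeric `(a, b)`: semi-axis along columns (x) and
#'   along rows (y), in pixels.
#' @param beat_frequency beats per second.
#' @param beat_amplitude fractional semi-axis modulation in `[0, 1)`.
#' @param phase phase offset in radians.
#' @return an object of class `chamber_spec`.
#' @export
chamber_spec <- function(center, base_semi_axes, beat_frequency = 5,
                         beat_amplitude = 0.15, phase = 0) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop_param("center", "must be finite (row, col)")
  if (length(base_semi_axes) != 2 || any(base_semi_axes <= 0))
    stop_param("base_semi_axes", "must be two positive lengths")
  if (beat_frequency <= 0) stop_param("beat_frequency", "must be > 0")
  if (beat_amplitude < 0 || beat_amplitude >= 1)
    stop_param("beat_amplitude", "must lie in [0, 1) so semi-axes stay positive")
  structure(list(center = as.numeric(center),
                 base_semi_axes = as.numeric(base_semi_axes),
                 beat_frequency = beat_frequency,
                 beat_amplitude = beat_amplitude,
                 phase = phase),
            class = "chamber_spec")
}

#' Specify a synthetic OCT-like beating-heart phantom
#'
#' The phantom emulates the salient appearance of a Drosophila B-mode OCT
#' recording: a bright horizontal dorsal ("back") stripe, multiplicative
#' speckled tissue beneath it, and dark low-intensity chamber lumens ringed by
#' bright walls. An optional contiguous angular arc of each wall can be erased
#' to lumen intensity (a "weak boundary"), by default on the lower half of the
#' chamber where real recordings lose contrast.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames (>= 1).
#' @param frame_rate frames per second (the reference system runs at 100).
#' @param chambers list of [chamber_spec()] objects.
#' @param back_row 0-based row of the top of the bright dorsal stripe.
#' @param tissue_level,lumen_level mean tissue and lumen intensities on the
#'   `[0, 1]` scale; lumens must be darker than tissue.
#' @param speckle_strength standard deviation of the unit-mean multiplicative
#'   (gamma) speckle; 0 disables noise.
#' @param gap_fraction fraction of the wall perimeter erased, in `[0, 1)`.
#' @param rng_seed integer seed; output is deterministic given the spec.
#' @param wall_level,wall_thickness,background_level,back_thickness
#'   appearance constants of the wall ring, the region above the back stripe,
#'   and the stripe thickness.
#' @param gap_center angular centre of the erased arc in radians; `pi/2`
#'   points toward increasing row (the lower wall).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 96, width = 160, n_frames = 200,
                         frame_rate = 100, chambers = NULL, back_row = 16,
                         tissue_level = 0.55, lumen_level = 0.05,
                         speckle_strength = 0.1, gap_fraction = 0,
                         rng_seed = 1, wall_level = 0.95, wall_thickness = 4,
                         background_level = 0.05, back_thickness = 3,
                         gap_center = pi / 2) {
  if (is.null(chambers)) {
    chambers <- list(
      chamber_spec(center = c(0.58 * height, 0.20 * width),
                   base_semi_axes = c(0.085 * width, 0.14 * height)),
      chamber_spec(center = c(0.58 * height, 0.50 * width),
                   base_semi_axes = c(0.075 * width, 0.12 * height)),
      chamber_spec(center = c(0.58 * height, 0.80 * width),
                   base_semi_axes = c(0.075 * width, 0.12 * height)))
  }
  if (height < 8 || width < 8) stop_param("height/width", "frames must be at least 8 x 8")
  if (n_frames < 1) stop_param("n_frames", "must be >= 1")
  if (frame_rate <= 0) stop_param("frame_rate", "must be > 0")
  if (!length(chambers) || !all(vapply(chambers, inherits, TRUE, "chamber_spec")))
    stop_param("chambers", "must be a non-empty list of chamber_spec objects")
  if (back_row < 0 || back_row >= height - 1) stop_param("back_row", "outside the frame")
  if (lumen_level >= tissue_level)
    stop_param("lumen_level", "chamber lumens must be darker than tissue (lumen_level < tissue_level)")
  if (speckle_strength < 0) stop_param("speckle_strength", "must be >= 0")
  if (gap_fraction < 0 || gap_fraction >= 1) stop_param("gap_fraction", "must lie in [0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 chambers = chambers, back_row = back_row,
                 tissue_level = tissue_level, lumen_level = lumen_level,
                 speckle_strength = speckle_strength,
                 gap_fraction = gap_fraction, rng_seed = as.integer(rng_seed),
                 wall_level = wall_level, wall_thickness = wall_thickness,
                 background_level = background_level,
                 back_thickness = back_thickness, gap_center = gap_center),
            class = "phantom_spec")
}

chamber_axes_at <- function(ch, t) {
  f <- 1 + ch$beat_amplitude * sin(2 * pi * ch$beat_frequency * t + ch$phase)
  ch$base_semi_axes * f
}

#' Generate a synthetic beating-chamber sequence with ground truth
#'
#' Renders every frame of the phantom described by `spec` and returns the
#' image sequence together with per-frame, per-chamber binary truth masks,
#' analytic (sub-pixel) truth contours sampled uniformly in parameter angle,
#' and the true beat count `floor(beat_frequency * n_frames / frame_rate)`
#' per chamber.
#'
#' @param spec a [phantom_spec()].
#' @param contour_points number of points in each analytic truth contour.
#' @return an object of class `phantom`: list with `sequence`
#'   (an [image_sequence()]), `truth_masks` (list per chamber of
#'   height x width x n_frames logical arrays), `truth_contours` (list per
#'   chamber of per-frame [contour()]s), `true_beat_counts`, and `spec`.
#' @export
generate_phantom <- function(spec, contour_points = 120) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; nf <- spec$n_frames
  rows <- matrix(seq_len(h) - 1, h, w)          # y, 0-based
  cols <- matrix(rep(seq_len(w) - 1, each = h), h, w)  # x, 0-based
  base <- matrix(spec$tissue_level, h, w)
  base[rows < spec$back_row] <- spec$background_level
  in_back <- rows >= spec$back_row & rows < spec$back_row + spec$back_thickness
  base[in_back] <- spec$wall_level

  nch <- length(spec$chambers)
  frames <- vector("list", nf)
  masks <- lapply(seq_len(nch), function(i) array(FALSE, dim = c(h, w, nf)))
  contours <- lapply(seq_len(nch), function(i) vector("list", nf))
  theta <- seq(0, 2 * pi, length.out = contour_points + 1)[-1]

  speckle <- NULL
  if (spec$speckle_strength > 0) {
    s2 <- spec$speckle_strength^2
    speckle <- with_seed(spec$rng_seed,
      array(stats::rgamma(h * w * nf, shape = 1 / s2, rate = 1 / s2),
            dim = c(h, w, nf)))
  }

  half_arc <- pi * spec$gap_fraction
  for (m in seq_len(nf)) {
    t <- (m - 1) / spec$frame_rate
    fr <- base
    for (k in seq_len(nch)) {
      ch <- spec$chambers[[k]]
      ax <- chamber_axes_at(ch, t)          # (a: cols, b: rows)
      dy <- rows - ch$center[1]; dx <- cols - ch$center[2]
      q <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2)
      qo <- sqrt((dx / (ax[1] + spec$wall_thickness))^2 +
                 (dy / (ax[2] + spec$wall_thickness))^2)
      wall <- q > 1 & qo <= 1
      fr[wall] <- spec$wall_level
      if (spec$gap_fraction > 0) {
        ang <- atan2(dy / ax[2], dx / ax[1])
        dang <- atan2(sin(ang - spec$gap_center), cos(ang - spec$gap_center))
        fr[wall & abs(dang) <= half_arc] <- spec$lumen_level
      }
      lumen <- q <= 1
      fr[lumen] <- spec$lumen_level
      masks[[k]][, , m] <- lumen
      contours[[k]][[m]] <- contour(cbind(x = ch$center[2] + ax[1] * cos(theta),
                                          y = ch$center[1] + ax[2] * sin(theta)))
    }
    if (!is.null(speckle)) fr <- pmin(pmax(fr * speckle[, , m], 0), 1)
    frames[[m]] <- fr
  }

  counts <- vapply(spec$chambers, function(ch)
    as.integer(floor(ch$beat_frequency * nf / spec$frame_rate)), integer(1))

  structure(list(
    sequence = image_sequence(frames, spec$frame_rate,
                              source_path = "<phantom>"),
    truth_masks = masks,
    truth_contours = contours,
    true_beat_counts = counts,
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<phantom: %d frames %dx%d @ %g fps, %d chamber(s), true beats: %s>\n",
              s$n_frames, s$height, s$width, s$frame_rate, length(s$chambers),
              paste(x$true_beat_counts, collapse = ", ")))
  invisible(x)
}

# Equal-arc-length sampling of the ellipse boundary of a chamber_spec,
# starting at the ventral-most (maximum y) point, counter-clockwise in the
# stored (x, y) frame.
ellipse_arc_points <- function(ch, n_points, t = 0) {
  ax <- chamber_axes_at(ch, t)
  th <- seq(0, 2 * pi, length.out = 4096 + 1)[-1]
  p <- cbind(ch$center[2] + ax[1] * cos(th), ch$center[1] + ax[2] * sin(th))
  resample_closed(p, n_points)
}

#' Generate a one-parameter family of training contours
#'
#' Draws closed contours from an explicitly constructed family: a mean
#' ellipse (equal-arc-length sampled, starting at the ventral-most point,
#' counter-clockwise) plus scalar multiples of a fixed smooth radial
#' deformation mode (a `cos(2*theta)` elongation pattern, unit-normalised in
#' the stacked 2n-dimensional coordinate space) plus small isotropic jitter.
#' Because the dominant mode is known analytically, the family supports exact
#' PCA-recovery tests.
#'
#' @param n_contours number of contours (>= 2; a covariance needs two).
#' @param n_points points per contour (>= 3).
#' @param base_shape a [chamber_spec()] giving the mean ellipse.
#' @param variation_scale standard deviation (pixels, in mode units) of the
#'   scalar mode coefficients.
#' @param rng_seed integer seed.
#' @param jitter_sd standard deviation (pixels) of per-coordinate isotropic
#'   jitter, emulating landmark placement error; small relative to the mode
#'   scale so the family's dominant mode stays recoverable.
#' @return an object of class `contour_family`: list with `contours` (list of
#'   [contour()]s), `mean` (n x 2), `mode` (n x 2, unit norm when stacked),
#'   and `coefficients`.
#' @export
generate_training_contours <- function(n_contours, n_points, base_shape,
                                       variation_scale, rng_seed = 1,
                                       jitter_sd = 0.04) {
  if (n_contours < 2)
    stop_param("n_contours", "at least 2 contours are required (covariance undefined)")
  if (n_points < 3) stop_param("n_points", "must be >= 3")
  stopifnot(inherits(base_shape, "chamber_spec"))
  mean_pts <- ellipse_arc_points(base_shape, n_points)
  ctr <- poly_centroid(mean_pts)
  dx <- mean_pts[, 1] - ctr[1]; dy <- mean_pts[, 2] - ctr[2]
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  r[r < 1e-9] <- 1e-9
  mode <- cbind(dx / r, dy / r) * cos(2 * th)   # radial elongation pattern
  mode <- mode / sqrt(sum(mode^2))              # unit norm in stacked space
  out <- with_seed(rng_seed, {
    b <- stats::rnorm(n_contours, sd = 1) * variation_scale
    cts <- lapply(seq_len(n_contours), function(i) {
      p <- mean_pts + b[i] * mode
      if (jitter_sd > 0)
        p <- p + matrix(stats::rnorm(2L * n_points, sd = jitter_sd), n_points, 2)
      contour(p)
    })
    list(b = b, cts = cts)
  })
  structure(list(contours = out$cts, mean = mean_pts, mode = mode,
                 coefficients = out$b),
            class = "contour_family")
}

#' @export
print.contour_family <- function(x, ...) {
  cat(sprintf("<contour_family: %d contours x %d points>\n",
              length(x$contours), nrow(x$mean)))
  invisible(x)
}
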