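# Distance-regularized level-set evolution.
#
# The chamber contour is the zero level set of a scalar field phi (negative
# inside). The field descends the energy
#
#   E(phi) = mu * R_p(phi) + lam * L_g(phi) + alpha * A_g(phi)
#
# where R_p penalises deviation of |grad phi| from a signed-distance profile
# through the double-well potential p, L_g is the geodesic length of the zero
# contour weighted by the edge indicator g, and A_g the g-weighted area of
# the inside region. The explicit Euler gradient flow is
#
#   phi <- phi + dt * [ mu * div(d_p(|grad phi|) grad phi)
#                       + lam * delta_eps(phi) * div(g grad phi / |grad phi|)
#                       + alpha * g * delta_eps(phi) ]
#
# With alpha < 0 the inside region expands; alpha > 0 shrinks it.

#' Double-well regularization potential and its derivative ratio
#'
#' `double_well()` evaluates the potential with minima exactly at `s = 0` and
#' `s = 1`:
#' `p(s) = (1/(2*pi)^2) * (1 - cos(2*pi*s))` for `s <= 1`, and
#' `p(s) = (s - 1)^2 / 2` for `s >= 1`.
#' `double_well_dp()` evaluates `d_p(s) = p'(s)/s`, continuous with the
#' removable singularity at `s = 0` taken by limit (`d_p(0) = 1`).
#'
#' @param s nonnegative gradient magnitude(s).
#' @return numeric vector of the same length.
#' @export
double_well <- function(s) {
  if (any(s < 0)) stop("double_well is defined for s >= 0", call. = FALSE)
  ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, (s - 1)^2 / 2)
}

#' @rdname double_well
#' @export
double_well_dp <- function(s) {
  if (any(s < 0)) stop("double_well_dp is defined for s >= 0", call. = FALSE)
  out <- ifelse(s <= 1, sin(2 * pi * s) / (2 * pi), s - 1)
  small <- s < 1e-10
  r <- ifelse(small, 1, out / ifelse(small, 1, s))
  r
}

#' Smoothed Dirac delta
#'
#' `delta_eps(x) = (1/(2*eps)) * (1 + cos(pi*x/eps))` for `|x| <= eps`,
#' 0 elsewhere.
#'
#' @param x numeric.
#' @param epsilon smoothing half-width in pixels.
#' @export
dirac_eps <- function(x, epsilon) {
  ifelse(abs(x) <= epsilon, (1 + cos(pi * x / epsilon)) / (2 * epsilon), 0)
}

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|)` pointwise, with the gradient taken by
#' central differences on the Gaussian-smoothed image; `g` lies in `(0, 1]`
#' and dips at intensity edges, halting contour motion there.
#'
#' @param frame intensity matrix on the `[0, 1]` scale.
#' @param sigma Gaussian standard deviation in pixels.
#' @return matrix of the same size.
#' @export
edge_indicator <- function(frame, sigma = 1.5) {
  if (sigma <= 0) stop_param("sigma", "must be > 0")
  sm <- gaussian_blur2d(frame, sigma)
  gr <- grad_central(sm)
  1 / (1 + sqrt(gr$x^2 + gr$y^2))
}

#' Evolution parameter set
#'
#' Defaults are calibrated on the bundled phantoms (on the `[0, 1]` intensity
#' scale the edge indicator stays close to 1, so the balloon force `alpha`
#' must be small relative to the geodesic attraction `lam * |grad g|`, and the
#' explicit scheme needs `timestep * lam * delta_max` modest for stability).
#'
#' @param mu weight of the distance regularizer (> 0); `timestep * mu < 0.25`
#'   is required for stability.
#' @param lam weight of the geodesic length term (> 0).
#' @param alpha signed weight of the area (balloon) term; negative expands
#'   the inside region, positive shrinks it.
#' @param sigma Gaussian std (pixels) for the edge indicator.
#' @param epsilon Dirac/Heaviside smoothing half-width (pixels).
#' @param timestep explicit Euler step.
#' @param max_iters iteration cap.
#' @param conv_tol convergence threshold on the L-infinity norm of the field
#'   update.
#' @param conv_window number of consecutive sub-threshold iterations required.
#' @param c0 magnitude of the binary initialization.
#' @return a list of class `evolution_params`.
#' @export
evolution_params <- function(mu = 0.2, lam = 5, alpha = -0.6, sigma = 1.0,
                             epsilon = 1.5, timestep = 0.5, max_iters = 1000,
                             conv_tol = 2e-3, conv_window = 5, c0 = 2) {
  if (mu <= 0) stop_param("mu", "must be > 0")
  if (lam <= 0) stop_param("lam", "must be > 0")
  if (sigma <= 0) stop_param("sigma", "must be > 0")
  if (epsilon <= 0) stop_param("epsilon", "must be > 0")
  if (timestep * mu >= 0.25)
    stop_param("timestep", "stability requires timestep * mu < 0.25")
  structure(list(mu = mu, lam = lam, alpha = alpha, sigma = sigma,
                 epsilon = epsilon, timestep = timestep,
                 max_iters = as.integer(max_iters), conv_tol = conv_tol,
                 conv_window = as.integer(conv_window), c0 = c0),
            class = "evolution_params")
}

#' Initialize a level-set field from a seed region
#'
#' Binary initialization: `-c0` inside the seed region, `+c0` outside
#' (negative-inside convention).
#'
#' @param seed_region logical (or 0/1) matrix; must be nonempty.
#' @param c0 magnitude.
#' @return numeric matrix (the level-set field).
#' @export
initialize_field <- function(seed_region, c0 = 2) {
  if (!any(seed_region > 0)) stop("empty seed region", call. = FALSE)
  matrix(ifelse(seed_region > 0, -c0, c0), nrow(seed_region), ncol(seed_region))
}

# Copy the first interior ring onto the border (Neumann boundary condition).
neumann_bc <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  phi[1, ] <- phi[2, ]; phi[nr, ] <- phi[nr - 1, ]
  phi[, 1] <- phi[, 2]; phi[, nc] <- phi[, nc - 1]
  phi
}

#' One explicit level-set evolution step
#'
#' Applies one explicit-Euler update of the distance-regularized gradient
#' flow (see the package vignette for the exact stencil). The gradient
#' magnitude in the normal direction is floored at `1e-10` before division.
#'
#' @param field level-set matrix (negative inside).
#' @param g edge-indicator matrix of matching dimensions.
#' @param params an [evolution_params()].
#' @param extra_force optional additional force matrix added inside the
#'   timestep (used by the shape prior).
#' @param alpha_scale multiplier on the area (balloon) force for this step;
#'   the shape prior substitutes its distance force for the balloon while
#'   active.
#' @return updated field matrix.
#' @export
evolve_step <- function(field, g, params, extra_force = NULL, alpha_scale = 1) {
  if (!all(dim(field) == dim(g)))
    stop("field and edge indicator dimensions differ", call. = FALSE)
  phi <- neumann_bc(field)
  gr <- grad_central(phi)
  s <- sqrt(gr$x^2 + gr$y^2)
  dp <- double_well_dp(s)
  reg <- div_central(dp * gr$x, dp * gr$y)
  sf <- pmax(s, 1e-10)
  nx <- gr$x / sf; ny <- gr$y / sf
  edge <- div_central(g * nx, g * ny)
  dirac <- dirac_eps(phi, params$epsilon)
  upd <- params$mu * reg + params$lam * dirac * edge +
    alpha_scale * params$alpha * g * dirac
  if (!is.null(extra_force)) upd <- upd + extra_force
  out <- phi + params$timestep * upd
  if (!all(is.finite(out)))
    stop(sprintf("numerical instability: non-finite field values (max |phi| = %g)",
                 max(abs(out[is.finite(out)]), 0)), call. = FALSE)
  out
}

#' Area of the inside region
#'
#' Number of pixels with a negative field value.
#'
#' @param field level-set matrix.
#' @return area in pixels squared.
#' @export
region_area <- function(field) sum(field < 0)

#' Extract the zero-level contour(s)
#'
#' Sub-pixel contours of the zero level set by marching squares (linear
#' interpolation along grid edges). Closed contours are oriented
#' counter-clockwise in the (x, y) frame.
#'
#' @param field level-set matrix with both signs present.
#' @return list of [contour()] objects.
#' @export
zero_level_contour <- function(field) {
  if (all(field >= 0) || all(field <= 0))
    stop("degenerate field: no zero crossing (single-signed field)", call. = FALSE)
  cls <- grDevices::contourLines(x = seq_len(nrow(field)) - 1,
                                 y = seq_len(ncol(field)) - 1,
                                 z = field, levels = 0)
  lapply(cls, function(cl) {
    closed <- cl$x[1] == cl$x[length(cl$x)] && cl$y[1] == cl$y[length(cl$y)]
    ct <- contour(cbind(x = cl$y, y = cl$x), closed = closed)
    if (closed) orient_ccw(ct) else ct
  })
}

#' Run the level-set evolution to convergence
#'
#' Iterates [evolve_step()] until the L-infinity norm of the field update
#' stays below `conv_tol` for `conv_window` consecutive iterations, or
#' `max_iters` is reached. Deterministic: no randomness is involved.
#'
#' @param field initial level-set matrix (see [initialize_field()]).
#' @param frame intensity matrix.
#' @param params an [evolution_params()].
#' @param g optional precomputed edge indicator (otherwise derived from
#'   `frame` with `params$sigma`).
#' @return an object of class `levelset_fit`: list with `field`, `converged`,
#'   `iterations`, and `log` (data frame with per-iteration `max_update` and
#'   zero-set `area`).
#' @export
evolve <- function(field, frame, params = evolution_params(), g = NULL) {
  if (is.null(g)) g <- edge_indicator(frame, params$sigma)
  run_evolution(field, g, params, force_fn = NULL, frame = frame)
}

# Shared driver for evolve() and evolve_with_prior(). force_fn(phi) returns
# an extra force matrix (or NULL) computed per outer iteration; when it
# returns a force, the balloon term is suspended for that step (the shape
# force is the motive force while the prior is active).
run_evolution <- function(field, g, params, force_fn = NULL, frame = NULL) {
  phi <- field
  max_upd <- numeric(0); areas <- integer(0)
  streak <- 0L; converged <- FALSE; it <- 0L
  active_scale <- if (is.null(params$beta)) 0
                  else max(0, 1 - params$beta / params$beta_full)
  while (it < params$max_iters) {
    it <- it + 1L
    extra <- if (is.null(force_fn)) NULL else force_fn(phi)
    nphi <- evolve_step(phi, g, params, extra_force = extra,
                        alpha_scale = if (is.null(extra)) 1 else active_scale)
    # convergence is judged on the interface band, where the contour lives;
    # far from the zero set the regularizer keeps rebuilding the distance
    # profile long after the contour has stopped moving
    band <- abs(phi) <= params$epsilon
    u <- if (any(band)) max(abs(nphi[band] - phi[band])) else max(abs(nphi - phi))
    max_upd[it] <- u; areas[it] <- region_area(nphi)
    phi <- nphi
    streak <- if (u < params$conv_tol) streak + 1L else 0L
    if (streak >= params$conv_window) { converged <- TRUE; break }
  }
  structure(list(field = phi, converged = converged, iterations = it,
                 log = data.frame(iteration = seq_len(it),
                                  max_update = max_upd, area = areas),
                 params = params, frame = frame),
            class = "levelset_fit")
}

#' @export
print.levelset_fit <- function(x, ...) {
  cat(sprintf("<levelset_fit: %d iterations, %s, inside area %d px>\n",
              x$iterations, if (x$converged) "converged" else "iteration cap",
              region_area(x$field)))
  invisible(x)
}

#' @export
plot.levelset_fit <- function(x, frame = NULL, ...) {
  img <- if (!is.null(frame)) frame else x$frame
  if (is.null(img)) img <- matrix(0, nrow(x$field), ncol(x$field))
  graphics::image(x = seq_len(ncol(img)) - 1, y = seq_len(nrow(img)) - 1,
                  z = t(img)[, rev(seq_len(nrow(img)))],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "x", ylab = "y (flipped)", ...)
  cts <- tryCatch(zero_level_contour(x$field), error = function(e) list())
  for (ct in cts) {
    p <- contour_points(ct)
    graphics::lines(p[, 1], nrow(img) - 1 - p[, 2], col = "green", lwd = 2)
  }
  invisible(x)
}
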