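test_that("double-well potential matches its closed forms", {
  expect_equal(double_well(0), 0)
  expect_equal(double_well(1), 0)
  expect_equal(double_well(2), 0.5)
  expect_equal(double_well(0.5), 2 / (2 * pi)^2)
  # both branches agree at s = 1, minima only at 0 and 1
  s <- seq(0, 3, by = 0.01)
  p <- double_well(s)
  expect_true(all(p >= 0))
  expect_lt(abs(double_well(1 - 1e-9) - double_well(1 + 1e-9)), 1e-8)
  expect_error(double_well(-0.1), "s >= 0")
})

test_that("d_p = p'/s is continuous with d_p(0) = 1", {
  expect_equal(double_well_dp(0), 1)
  expect_equal(double_well_dp(1e-9), 1, tolerance = 1e-6)
  expect_equal(double_well_dp(1), 0)
  expect_equal(double_well_dp(2), 0.5)
  expect_lt(abs(double_well_dp(1 - 1e-8) - double_well_dp(1 + 1e-8)), 1e-6)
  expect_error(double_well_dp(-1), "s >= 0")
})

test_that("edge indicator is 1 on constants, bounded, and matches the dense oracle", {
  expect_equal(edge_indicator(matrix(0.7, 15, 15), 1.5),
               matrix(1, 15, 15))
  img <- matrix(0.2, 18, 24); img[, 13:24] <- 0.9
  g <- edge_indicator(img, 1.5)
  expect_true(all(g > 0) && all(g <= 1))
  ref <- ref_edge_indicator(img, 1.5)
  expect_lt(max(abs(g - ref)), 1e-10)
  # minimized along the step
  expect_true(which.min(g[9, ]) %in% c(12, 13))
})

test_that("binary initialization honours the negative-inside convention", {
  seed <- matrix(FALSE, 10, 10); seed[4:5, 6:7] <- TRUE
  phi <- initialize_field(seed, c0 = 2)
  expect_equal(sum(phi == -2), 4)
  expect_equal(sum(phi == 2), 96)
  expect_equal(region_area(phi), 4)
  expect_error(initialize_field(matrix(FALSE, 5, 5)), "empty")
})

test_that("an exact signed-distance plane is a fixed point of the regularizer", {
  p <- evolution_params(lam = 1e-8, alpha = 0)
  phi <- matrix(rep(seq_len(20) - 10.5, 20), 20, 20)  # phi = y - c, |grad| = 1
  g <- matrix(1, 20, 20)
  out <- evolve_step(phi, g, p)
  # interior comparison: the step first imposes the Neumann border condition
  expect_lt(max(abs((out - phi)[2:19, 2:19])), 1e-6)
})

test_that("the sign of alpha sets the motion direction of a circular front", {
  n <- 40
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(rep(0:(n - 1), each = n), n, n)
  phi0 <- sqrt((rows - 19.5)^2 + (cols - 19.5)^2) - 10
  g <- matrix(1, n, n)
  grow <- phi0; shrink <- phi0
  for (i in 1:20) {
    grow <- evolve_step(grow, g, evolution_params(alpha = -0.8, lam = 1e-8))
    shrink <- evolve_step(shrink, g, evolution_params(alpha = 0.8, lam = 1e-8))
  }
  expect_gt(region_area(grow), region_area(phi0))
  expect_lt(region_area(shrink), region_area(phi0))
})

test_that("the length term never lengthens the zero contour on a uniform image", {
  n <- 48
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(rep(0:(n - 1), each = n), n, n)
  # wavy star-like front
  th <- atan2(rows - 23.5, cols - 23.5)
  phi <- sqrt((rows - 23.5)^2 + (cols - 23.5)^2) - (12 + 3 * cos(5 * th))
  g <- matrix(1, n, n)
  p <- evolution_params(alpha = 1e-9, lam = 4)
  lens <- numeric(30)
  for (i in 1:30) {
    phi <- evolve_step(phi, g, p)
    lens[i] <- sum(vapply(zero_level_contour(phi), function(ct)
      flybeat:::poly_perimeter(ct$points, ct$closed), numeric(1)))
  }
  expect_true(all(diff(lens) <= 1e-6))
})

test_that("vectorised update agrees with the scalar stencil oracle to 1e-10", {
  p <- evolution_params()
  for (s in 1:10) {
    set.seed(s)
    phi <- matrix(rnorm(256, sd = 2), 16, 16)
    g <- ref_gaussian_blur(matrix(runif(256), 16, 16), 1)
    g <- 0.2 + 0.8 * g / max(g)
    expect_lt(max(abs(evolve_step(phi, g, p) - ref_evolve_step(phi, g, p))),
              1e-10)
  }
})

test_that("zero-level contours are sub-pixel accurate, CCW, and guarded", {
  n <- 64
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(rep(0:(n - 1), each = n), n, n)
  phi <- sqrt((rows - 31.5)^2 + (cols - 31.5)^2) - 10
  cts <- zero_level_contour(phi)
  expect_length(cts, 1)
  per <- flybeat:::poly_perimeter(cts[[1]]$points)
  expect_lt(abs(per - 2 * pi * 10) / (2 * pi * 10), 0.01)
  expect_lt(abs(region_area(phi) - pi * 100) / (pi * 100), 0.02)
  expect_gt(flybeat:::poly_signed_area(cts[[1]]$points), 0)
  expect_error(zero_level_contour(matrix(1, 5, 5)), "degenerate")
})

test_that("evolution converges on the analytic disk and is deterministic", {
  cs <- make_disk_case()
  p <- evolution_params(max_iters = 1500)
  fit <- evolve(initialize_field(cs$seed, p$c0), cs$image, p)
  expect_true(fit$converged)
  expect_gt(dice(fit$field < 0, cs$truth), 0.95)
  md <- mean_contour_distance(zero_level_contour(fit$field)[[1]], cs$circle)
  expect_lt(md, 1.5)
  fit2 <- evolve(initialize_field(cs$seed, p$c0), cs$image, p)
  expect_identical(fit$field, fit2$field)
  expect_identical(fit$log, fit2$log)
})

test_that("with conv_tol = Inf the loop exits after conv_window iterations", {
  cs <- make_disk_case(n = 32, radius = 10, seed_radius = 5)
  p <- evolution_params(conv_tol = Inf, conv_window = 5)
  fit <- evolve(initialize_field(cs$seed, p$c0), cs$image, p)
  expect_equal(fit$iterations, 5L)
  expect_true(fit$converged)
})

test_that("the field stays bounded under the stability condition", {
  ph <- generate_phantom(phantom_spec(height = 48, width = 64, n_frames = 1,
                                      speckle_strength = 0.1, rng_seed = 9,
                                      chambers = list(chamber_spec(c(30, 32),
                                                                   c(10, 8)))))
  fr <- ph$sequence$frames[[1]]
  p <- evolution_params(conv_tol = 0, max_iters = 1000)
  expect_lt(p$timestep * p$mu, 0.25)
  seed <- ph$truth_masks[[1]][, , 1]
  fit <- evolve(initialize_field(seed, p$c0), fr, p)
  expect_equal(fit$iterations, 1000L)
  expect_lt(max(abs(fit$field)), 50)
  expect_error(evolution_params(timestep = 2), "timestep")
})
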