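test_that("resampling spaces landmarks equally in arc length", {
  sq <- contour(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  rs <- resample_contour(sq, 4)$points
  # equal arc gaps of perimeter/4 = 1.0 along the polygon
  pos <- vapply(seq_len(4), function(i) {
    # arc position of each resampled point along the square, by projection
    d <- ref_point_to_poly(rs[i, 1], rs[i, 2], sq$points)
    d
  }, numeric(1))
  expect_true(all(pos < 1e-9))   # all points lie on the polygon
  gaps <- sqrt(rowSums((rs - rbind(rs[-1, ], rs[1, ]))^2))
  # consecutive points are separated by 1.0 of arc; chords crossing a corner
  # measure sqrt(0.5), others 1.0
  expect_true(all(abs(gaps - 1) < 1e-9 | abs(gaps - sqrt(0.5)) < 1e-9))
  expect_error(resample_contour(contour(cbind(c(0, 1, 2), c(0, 1, 0)),
                                        closed = FALSE), 10), "closed")
})

test_that("resampling preserves an ellipse perimeter and is idempotent", {
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  ell <- cbind(x = 20 * cos(th), y = 12 * sin(th))
  per0 <- flybeat:::poly_perimeter(ell)
  rs <- resample_contour(contour(ell), 45)
  expect_lt(abs(flybeat:::poly_perimeter(rs$points) - per0) / per0, 0.01)
  # an equally spaced ventral-start circle resamples to itself
  ang <- pi / 2 + seq(0, 2 * pi, length.out = 46)[-46]
  circ <- cbind(x = 10 + 5 * cos(ang), y = 10 + 5 * sin(ang))
  back <- flybeat:::resample_closed(circ, 45)
  expect_lt(max(abs(back - circ)), 1e-9)
})

test_that("shape-model training has the documented dimensions and guards", {
  base <- gap_base_shape()
  fam <- generate_training_contours(28, 45, base, variation_scale = 2,
                                    rng_seed = 1)
  mod <- train_shape_model(fam, 45)
  expect_equal(dim(mod$components), c(90L, 1L))
  expect_equal(mod$n_training, 28L)
  expect_equal(sum(mod$components[, 1]^2), 1, tolerance = 1e-12)
  expect_true(all(diff(mod$eigenvalues) <= 1e-9))
  mod2 <- train_shape_model(fam, 45, n_retained = 2)
  expect_equal(crossprod(mod2$components), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(train_shape_model(fam$contours[1], 45), "at least 2")
})

test_that("identical training contours give the degenerate model", {
  ct <- resample_contour(contour(cbind(x = 10 * cos(seq(0.1, 2 * pi, 0.1)),
                                       y = 6 * sin(seq(0.1, 2 * pi, 0.1)))), 45)
  mod <- train_shape_model(list(ct, ct, ct), 45, n_retained = 0)
  expect_lt(max(mod$eigenvalues), 1e-18)
  cent <- sweep(resample_contour(ct, 45)$points, 2,
                colMeans(resample_contour(ct, 45)$points))
  expect_equal(mod$mean_contour, cent, tolerance = 1e-9, ignore_attr = TRUE)
  # rank guard names the rank
  expect_error(train_shape_model(list(ct, ct, ct), 45, n_retained = 1),
               "rank is 0")
})

test_that("PCA recovers an injected deformation mode from 28 x 45 contours", {
  base <- gap_base_shape()
  fam <- generate_training_contours(28, 45, base, variation_scale = 2.5,
                                    rng_seed = 7)
  mod <- train_shape_model(fam, 45, resample = FALSE)
  cosv <- abs(sum(mod$components[, 1] * as.numeric(t(fam$mode))))
  expect_gt(cosv, 0.99)
  expect_gt(mod$eigenvalues[1] / sum(mod$eigenvalues), 0.95)
  # held-out contour reconstructed from the fitted coefficient
  mod27 <- train_shape_model(fam$contours[1:27], 45, resample = FALSE)
  pr <- predict(mod27, fam$contours[[28]], resample = FALSE)
  held <- sweep(fam$contours[[28]]$points, 2,
                colMeans(fam$contours[[28]]$points))
  err <- mean(sqrt(rowSums((pr$contour$points - held)^2)))
  expect_lt(err, 0.5)
})

test_that("shape models serialize to JSON and back", {
  fam <- generate_training_contours(10, 45, gap_base_shape(), 2, rng_seed = 2)
  mod <- train_shape_model(fam, 45)
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_model(mod, path)
  back <- read_shape_model(path)
  expect_equal(back$mean_contour, mod$mean_contour, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$components, mod$components, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$eigenvalues, mod$eigenvalues, tolerance = 1e-12)
  expect_equal(back$n_training, 10L)
})

test_that("model alignment matches area and centroid, idempotently", {
  ang <- pi / 2 + seq(0, 2 * pi, length.out = 46)[-46]
  circ <- contour(cbind(x = cos(ang), y = sin(ang)))
  mod <- train_shape_model(list(circ, circ), 45, n_retained = 0)
  n <- 80
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(rep(0:(n - 1), each = n), n, n)
  phi <- sqrt((rows - 41)^2 + (cols - 37)^2) - 17.8
  al <- align_model(mod, phi)
  r <- sqrt(region_area(phi) / pi)   # circle radius carrying the region area
  rads <- sqrt((al$points[, 1] - 37)^2 + (al$points[, 2] - 41)^2)
  expect_lt(max(abs(rads - r)) / r, 0.01)
  ctr <- flybeat:::poly_centroid(al$points)
  idx <- which(phi < 0, arr.ind = TRUE)
  expect_lt(abs(ctr[1] - (mean(idx[, 2]) - 1)), 1e-6)
  expect_lt(abs(ctr[2] - (mean(idx[, 1]) - 1)), 1e-6)
  # realigning the aligned contour is a no-op beyond float noise
  mod2 <- mod; mod2$mean_contour <- al$points
  al2 <- align_model(mod2, phi)
  expect_lt(max(abs(al2$points - al$points)), 1e-9)
})

test_that("shape distance is signed by the level-set side and metrically exact", {
  ang <- pi / 2 + seq(0, 2 * pi, length.out = 181)[-181]
  model_ct <- contour(cbind(x = 40 + 10 * cos(ang), y = 40 + 10 * sin(ang)))
  n <- 80
  rows <- matrix(0:(n - 1), n, n); cols <- matrix(rep(0:(n - 1), each = n), n, n)
  phi <- sqrt((rows - 40)^2 + (cols - 40)^2) - 8   # current region: radius 8
  # a point on the model contour has distance 0
  expect_lt(abs(shape_distance(c(50, 40), model_ct, phi)), 1e-6)
  # 3-4-5 triangle against a single far segment
  seg <- contour(cbind(x = c(3, 3, 3.001), y = c(4, 100, 100)), closed = FALSE)
  expect_equal(abs(shape_distance(c(0, 0), seg, phi + 100)), 5,
               tolerance = 1e-6)
  # between the contours (radius 9): outside current region -> positive
  expect_gt(shape_distance(c(40 + 9, 40), model_ct, phi), 0)
  # inside the current region (radius 7): negative
  expect_lt(shape_distance(c(40 + 7, 40), model_ct, phi), 0)
  # magnitudes match a dense-sampling oracle on query circles inside/outside
  # the current region (radius 8, where the sign is well defined)
  for (qr in c(8.4, 12.2)) {
    q <- cbind(40 + qr * cos(ang[c(1, 40, 90, 140)]),
               40 + qr * sin(ang[c(1, 40, 90, 140)]))
    d <- abs(shape_distance(q, model_ct, phi))
    ref <- vapply(seq_len(nrow(q)), function(i)
      ref_point_to_poly(q[i, 1], q[i, 2], model_ct$points), numeric(1))
    expect_lt(max(abs(d - ref)), 1e-3)
  }
})

test_that("beta = 0 and an infinite threshold reduce exactly to the baseline", {
  ph <- make_gap_phantom(1)
  fr <- ph$sequence$frames[[1]]
  seeds <- detect_chamber_seeds(fr, detect_back(fr))
  phi0 <- initialize_field(seeds[[1]]$seed_region, 2)
  fam <- generate_training_contours(28, 45, gap_base_shape(), 2.5, rng_seed = 3)
  mod <- train_shape_model(fam, 45, resample = FALSE)
  p <- evolution_params(max_iters = 120)
  base <- evolve(phi0, fr, p)
  z <- evolve_with_prior(phi0, fr, mod, prior_params(beta = 0, max_iters = 120))
  expect_identical(z$field, base$field)
  expect_warning(
    inf <- evolve_with_prior(phi0, fr, mod,
                             prior_params(beta = 0.5, area_threshold = Inf,
                                          max_iters = 120)),
    "never activated")
  expect_identical(inf$field, base$field)
  expect_false(inf$prior_activated)
})

test_that("final contours converge to the baseline's as beta -> 0", {
  ph <- make_gap_phantom(0)
  fr <- ph$sequence$frames[[1]]
  seeds <- detect_chamber_seeds(fr, detect_back(fr))
  phi0 <- initialize_field(seeds[[1]]$seed_region, 2)
  fam <- generate_training_contours(28, 45, gap_base_shape(), 2.5, rng_seed = 3)
  mod <- train_shape_model(fam, 45, resample = FALSE)
  base <- evolve(phi0, fr, evolution_params())
  tiny <- suppressWarnings(evolve_with_prior(
    phi0, fr, mod,
    prior_params(beta = 1e-6,
                 area_threshold = 0.5 * sum(ph$truth_masks[[1]][, , 1]))))
  md <- mean_contour_distance(zero_level_contour(base$field)[[1]],
                              zero_level_contour(tiny$field)[[1]])
  expect_lt(md, 0.5)
})

test_that("with no edges the active prior is the attractor of the zero set", {
  base <- chamber_spec(center = c(40, 48), base_semi_axes = c(16, 12))
  fam <- generate_training_contours(20, 45, base, variation_scale = 1,
                                    rng_seed = 5)
  mod <- train_shape_model(fam, 45, resample = FALSE)
  img <- matrix(0.5, 80, 96)
  seedm <- matrix(FALSE, 80, 96); seedm[30:50, 38:58] <- TRUE
  pp <- prior_params(beta = 0.5, lam = 1, area_threshold = 0, max_iters = 250)
  fit <- evolve_with_prior(initialize_field(seedm, 2), img, mod, pp)
  expect_true(fit$prior_activated)
  al <- align_model(mod, fit$field)
  md <- mean_contour_distance(zero_level_contour(fit$field)[[1]], al)
  expect_lt(md, 1)
})

test_that("the prior repairs the weak-boundary leak on a gap phantom", {
  ph <- make_gap_phantom(5)
  fr <- ph$sequence$frames[[1]]
  truth <- ph$truth_masks[[1]][, , 1]
  seeds <- detect_chamber_seeds(fr, detect_back(fr))
  phi0 <- initialize_field(seeds[[1]]$seed_region, 2)
  fam <- generate_training_contours(28, 45, gap_base_shape(), 2.5, rng_seed = 100)
  mod <- train_shape_model(fam, 45, resample = FALSE)
  base <- evolve(phi0, fr, evolution_params())
  prior <- evolve_with_prior(phi0, fr, mod,
                             prior_params(beta = 0.5,
                                          area_threshold = 0.5 * sum(truth)))
  expect_gt(dice(prior$field < 0, truth), 0.85)
  expect_gt(dice(prior$field < 0, truth), dice(base$field < 0, truth))
})
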