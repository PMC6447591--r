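test_that("reconstruction smoothing is bounded, flat-invariant and kills impulses", {
  flat <- matrix(0.4, 20, 20)
  expect_equal(reconstruct_smooth(flat, 3), flat)
  set.seed(7)
  img <- matrix(0.5 + 0.05 * rnorm(400), 20, 20)
  sm <- reconstruct_smooth(img, 2)
  expect_lte(max(sm), max(img) + 1e-12)
  expect_gte(min(sm), min(img) - 1e-12)
  # single dark impulse removed by opening/closing by reconstruction
  imp <- matrix(0.6, 24, 24); imp[12, 12] <- 0.05
  sm2 <- reconstruct_smooth(imp, 3)
  expect_gte(min(sm2), 0.6 - 1e-9)
  expect_error(reconstruct_smooth(imp, 20), "radius")
})

test_that("back detection finds the dominant bright stripe", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 96, n_frames = 1,
                                      back_row = 20, speckle_strength = 0.1,
                                      chambers = list(chamber_spec(c(45, 48),
                                                                   c(12, 9)))))
  est <- detect_back(ph$sequence$frames[[1]])
  expect_lte(abs(est - 20), 1)
  expect_error(detect_back(matrix(0.5, 40, 40)), "no back")
  # two stripes (thicker than the smoothing disk): the brighter one wins,
  # matching a brute-force row-mean argmax
  img <- matrix(0.2, 60, 60)
  img[14:20, ] <- 0.9
  img[40:46, ] <- 0.6
  expect_lte(abs(detect_back(img) - (which.max(rowMeans(img)) - 1)), 1)
})

test_that("seed detection recovers each chamber of noise-free phantoms", {
  for (nch in 1:5) {
    chs <- lapply(seq_len(nch), function(k)
      chamber_spec(center = c(52, 20 + 38 * (k - 1)), base_semi_axes = c(12, 10)))
    sp <- phantom_spec(height = 96, width = 40 + 38 * (nch - 1) + 20,
                       n_frames = 1, chambers = chs, speckle_strength = 0)
    ph <- generate_phantom(sp)
    fr <- ph$sequence$frames[[1]]
    seeds <- detect_chamber_seeds(fr, detect_back(fr))
    expect_length(seeds, nch)
    # minima inside the true lumens, seeds ordered anterior -> posterior
    for (k in seq_len(nch)) {
      loc <- seeds[[k]]$minimum_location
      expect_true(ph$truth_masks[[k]][loc["row"] + 1, loc["col"] + 1, 1])
    }
    expect_equal(vapply(seeds, function(s) s$label, ""),
                 sprintf("C%d", seq_len(nch)))
  }
})

test_that("sub-radius impulse noise never changes the seed count", {
  sp <- phantom_spec(height = 80, width = 120, n_frames = 1,
                     speckle_strength = 0,
                     chambers = list(chamber_spec(c(48, 40), c(13, 10)),
                                     chamber_spec(c(48, 85), c(12, 9))))
  ph <- generate_phantom(sp)
  fr0 <- ph$sequence$frames[[1]]
  n0 <- length(detect_chamber_seeds(fr0, detect_back(fr0)))
  expect_equal(n0, 2)
  set.seed(11)
  for (draw in 1:10) {
    fr <- fr0
    # a 1-pixel dark speck in the tissue, smaller than the smoothing disk
    i <- sample(70:78, 1); j <- sample(5:115, 1)
    fr[i, j] <- 0.02
    seeds <- detect_chamber_seeds(fr, detect_back(fr))
    expect_length(seeds, 2)
  }
})

test_that("seed screening enforces the back-distance band", {
  sp <- phantom_spec(height = 96, width = 64, n_frames = 1,
                     speckle_strength = 0, back_row = 40,
                     chambers = list(chamber_spec(c(70, 32), c(12, 10))))
  ph <- generate_phantom(sp)
  fr <- ph$sequence$frames[[1]]
  # a dark basin above the back row must be ignored
  fr[10:16, 20:30] <- 0.03
  seeds <- detect_chamber_seeds(fr, detect_back(fr))
  expect_length(seeds, 1)
  expect_gt(seeds[[1]]$minimum_location["row"], 40)
  # an over-restrictive band rejects everything, naming the reasons
  expect_error(
    detect_chamber_seeds(fr, detect_back(fr),
                         detection_params(d_min = 1, d_max = 5)),
    "rejected")
})

test_that("seed regions are connected and contain their minimum", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 96, n_frames = 1,
                                      speckle_strength = 0.1, rng_seed = 2,
                                      chambers = list(chamber_spec(c(42, 48),
                                                                   c(13, 10)))))
  fr <- ph$sequence$frames[[1]]
  seeds <- detect_chamber_seeds(fr, detect_back(fr))
  s <- seeds[[1]]
  expect_true(s$seed_region[s$minimum_location["row"] + 1,
                            s$minimum_location["col"] + 1])
  one <- matrix(FALSE, nrow(fr), ncol(fr))
  one[which(s$seed_region)[1]] <- TRUE
  expect_equal(sum(flybeat:::flood_fill8(s$seed_region, one)),
               sum(s$seed_region))
  expect_s3_class(s$initial_contour, "contour")
})
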