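# End-to-end orchestration: detect chambers on the first frame, segment every
# frame (warm-starting each chamber from its previous contour), convert the
# per-frame areas to beat counts, and optionally evaluate against truth masks.

#' Pipeline configuration
#'
#' Every parameter has a default; the resolved configuration is serialized
#' into the run's output directory for provenance.
#'
#' @param detection a [detection_params()].
#' @param evolution an [evolution_params()].
#' @param beta,area_threshold shape-prior weight and switching area; with
#'   `area_threshold = NULL` the threshold is set per chamber to 1.3 x the
#'   median area of a first no-prior pass (two-pass scheme).
#' @param heartbeat_sigma area-smoothing sigma in frames; `NULL` means
#'   `frame_rate / 50`.
#' @param min_prominence peak prominence gate; `NULL` for 1% of range.
#' @param warm_erode radius (pixels) by which the previous frame's mask is
#'   eroded before seeding the next frame (chambers move little between
#'   frames at 100 fps, so a slightly shrunk previous contour is a valid
#'   interior seed even during contraction).
#' @param crop_margin each chamber is evolved on a window extending this many
#'   pixels beyond its seed bounding box (the level-set update itself stays
#'   full-grid within the window); the margin bounds how far a contour can
#'   travel from its seed in one frame, which is small at 100 fps.
#' @param assoc_max_dist maximum centroid jump (pixels) before a chamber is
#'   re-detected.
#' @param max_gap longest run of lost frames whose areas are linearly
#'   interpolated; longer gaps drop the chamber from counting.
#' @param independent_frames segment every frame from fresh detection instead
#'   of warm-starting.
#' @param rng_seed recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return a list of class `flybeat_config`.
#' @export
flybeat_config <- function(detection = detection_params(),
                           evolution = evolution_params(),
                           beta = 0.5, area_threshold = NULL,
                           heartbeat_sigma = NULL, min_prominence = NULL,
                           warm_erode = 2, crop_margin = 16,
                           assoc_max_dist = 15, max_gap = 5,
                           independent_frames = FALSE, rng_seed = 1) {
  structure(list(detection = detection, evolution = evolution, beta = beta,
                 area_threshold = area_threshold,
                 heartbeat_sigma = heartbeat_sigma,
                 min_prominence = min_prominence, warm_erode = warm_erode,
                 crop_margin = crop_margin,
                 assoc_max_dist = assoc_max_dist, max_gap = max_gap,
                 independent_frames = independent_frames,
                 rng_seed = rng_seed), class = "flybeat_config")
}

erode_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  out <- EBImage::erode(mask * 1, EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                                     shape = "disc"))
  matrix(out > 0, nrow(mask), ncol(mask))
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

# Segment every frame of a sequence for the chambers seeded on frame 1.
# th: per-chamber area thresholds (Inf disables the prior).
segment_pass <- function(seq, seeds, config, model = NULL,
                         th = rep(Inf, length(seeds))) {
  nf <- length(seq$frames); nch <- length(seeds)
  d <- dim(seq$frames[[1]])
  masks <- lapply(seq_len(nch), function(k) array(NA, dim = c(d, nf)))
  lost <- matrix(FALSE, nf, nch)
  prev_mask <- lapply(seeds, function(s) NULL)
  use_prior <- !is.null(model) && config$beta > 0
  crop_window <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    mg <- config$crop_margin
    list(r = max(1L, min(idx[, 1]) - mg):min(d[1], max(idx[, 1]) + mg),
         c = max(1L, min(idx[, 2]) - mg):min(d[2], max(idx[, 2]) + mg))
  }
  for (m in seq_len(nf)) {
    frame <- seq$frames[[m]]
    fresh <- NULL
    for (k in seq_len(nch)) {
      seed_mask <- NULL
      if (m == 1L || config$independent_frames) {
        if (m == 1L) seed_mask <- seeds[[k]]$seed_region
      } else if (!is.null(prev_mask[[k]])) {
        er <- erode_mask(prev_mask[[k]], config$warm_erode)
        if (any(er)) seed_mask <- er
      }
      if (is.null(seed_mask)) {
        # (re-)detect on this frame and associate by nearest centroid
        if (is.null(fresh)) fresh <- tryCatch(
          detect_chamber_seeds(frame, detect_back(frame, config$detection$radius,
                                                  config$detection$contrast_margin),
                               config$detection),
          error = function(e) list())
        ref <- seeds[[k]]$centroid
        if (length(fresh)) {
          dists <- vapply(fresh, function(s)
            sqrt(sum((s$centroid - ref)^2)), numeric(1))
          if (min(dists) <= config$assoc_max_dist)
            seed_mask <- fresh[[which.min(dists)]]$seed_region
        }
      }
      if (is.null(seed_mask)) { lost[m, k] <- TRUE; prev_mask[[k]] <- NULL; next }
      win <- crop_window(seed_mask)
      sub_frame <- frame[win$r, win$c, drop = FALSE]
      g <- edge_indicator(sub_frame, config$evolution$sigma)
      phi <- initialize_field(seed_mask[win$r, win$c, drop = FALSE],
                              config$evolution$c0)
      fit <- if (use_prior && is.finite(th[k])) {
        pp <- do.call(prior_params, c(list(beta = config$beta,
                                           area_threshold = th[k]),
                                      unclass(config$evolution)))
        suppressWarnings(evolve_with_prior(phi, sub_frame, model, pp, g = g))
      } else {
        evolve(phi, sub_frame, config$evolution, g = g)
      }
      mk <- matrix(FALSE, d[1], d[2])
      mk[win$r, win$c] <- fit$field < 0
      if (!any(mk) ||
          (!is.null(prev_mask[[k]]) && !config$independent_frames &&
           sqrt(sum((mask_centroid(mk) - mask_centroid(prev_mask[[k]]))^2)) >
             config$assoc_max_dist)) {
        lost[m, k] <- TRUE; prev_mask[[k]] <- NULL; next
      }
      masks[[k]][, , m] <- mk
      prev_mask[[k]] <- mk
    }
  }
  list(masks = masks, lost = lost)
}

interpolate_areas <- function(a, max_gap) {
  na <- is.na(a)
  if (!any(na)) return(list(areas = a, dropped = FALSE))
  r <- rle(na)
  if (any(r$values & r$lengths > max_gap) || na[1] || na[length(a)])
    return(list(areas = a, dropped = TRUE))
  ok <- which(!na)
  a[na] <- stats::approx(ok, a[ok], xout = which(na))$y
  list(areas = a, dropped = FALSE)
}

#' Run the full heartbeat-counting pipeline
#'
#' Detects the back stripe and chamber seeds on frame 1, segments every frame
#' (warm-started from the previous frame unless `independent_frames`),
#' converts per-chamber areas to beat counts, and optionally evaluates
#' against truth masks. When a shape `model` is supplied with
#' `area_threshold = NULL`, a first no-prior pass fixes each chamber's
#' switching threshold at 1.3 x its median area before the prior pass.
#'
#' @param seq an [image_sequence()].
#' @param config a [flybeat_config()].
#' @param model optional [train_shape_model()] result enabling the shape
#'   prior.
#' @param truth_masks optional per-chamber truth mask arrays for evaluation.
#' @param out_dir optional output directory; masks (TIFF), contours and
#'   areas (CSV), heartbeat results and the resolved config (JSON) are
#'   written there.
#' @return object of class `flybeat_run`: seeds, per-chamber mask arrays,
#'   [area_series()] list, [count_heartbeats()] results, optional
#'   `metrics_report`, and the resolved config.
#' @export
run_pipeline <- function(seq, config = flybeat_config(), model = NULL,
                         truth_masks = NULL, out_dir = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  frame1 <- seq$frames[[1]]
  back <- detect_back(frame1, config$detection$radius,
                      config$detection$contrast_margin)
  seeds <- detect_chamber_seeds(frame1, back, config$detection)
  nch <- length(seeds); nf <- length(seq$frames)

  th <- rep(Inf, nch)
  if (!is.null(model) && config$beta > 0) {
    if (is.null(config$area_threshold)) {
      base <- segment_pass(seq, seeds, config, model = NULL)
      th <- vapply(seq_len(nch), function(k) {
        a <- apply(base$masks[[k]], 3, function(m) if (anyNA(m)) NA else sum(m))
        1.3 * stats::median(a, na.rm = TRUE)
      }, numeric(1))
    } else th <- rep(config$area_threshold, nch)
  }

  pass <- segment_pass(seq, seeds, config, model = model, th = th)

  areas <- vector("list", nch); beats <- vector("list", nch)
  dropped <- logical(nch)
  hb_sigma <- if (is.null(config$heartbeat_sigma)) seq$frame_rate / 50
              else config$heartbeat_sigma
  for (k in seq_len(nch)) {
    a <- apply(pass$masks[[k]], 3, function(m) if (anyNA(m)) NA_real_ else sum(m))
    ia <- interpolate_areas(a, config$max_gap)
    if (ia$dropped) {
      warning(sprintf("chamber %s lost for more than %d consecutive frames; dropped from counting",
                      seeds[[k]]$label, config$max_gap), call. = FALSE)
      dropped[k] <- TRUE
      next
    }
    areas[[k]] <- area_series(ia$areas, seq$frame_rate,
                              gaussian_sigma = hb_sigma,
                              min_prominence = config$min_prominence)
    beats[[k]] <- count_heartbeats(areas[[k]])
  }

  metrics <- NULL
  if (!is.null(truth_masks)) {
    pred <- lapply(pass$masks, function(mk) { mk[is.na(mk)] <- FALSE; mk > 0 })
    metrics <- evaluate_sequence(pred, truth_masks, seq$frame_rate)
  }

  run <- structure(list(back_row = back, seeds = seeds, masks = pass$masks,
                        lost = pass$lost, areas = areas, heartbeats = beats,
                        dropped = dropped, metrics = metrics, config = config,
                        area_thresholds = th, out_dir = out_dir),
                   class = "flybeat_run")
  if (!is.null(out_dir)) write_run(run, seq, out_dir)
  run
}

write_run <- function(run, seq, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nch <- length(run$seeds)
  for (k in seq_len(nch)) {
    mk <- run$masks[[k]]; mk[is.na(mk)] <- 0
    save_masks(mk, file.path(out_dir, sprintf("masks_%s.tif", run$seeds[[k]]$label)))
    if (!is.null(run$areas[[k]]))
      write_area_table(run$areas[[k]],
                       file.path(out_dir, sprintf("areas_%s.csv", run$seeds[[k]]$label)))
  }
  cts <- lapply(seq_len(nch), function(k)
    lapply(seq_len(dim(run$masks[[k]])[3]), function(m) {
      mk <- run$masks[[k]][, , m]
      if (anyNA(mk) || !any(mk > 0)) NULL else mask_boundary_contour(mk > 0)
    }))
  write_contours(cts, file.path(out_dir, "contours.csv"))
  hb <- lapply(seq_len(nch), function(k) {
    b <- run$heartbeats[[k]]
    if (is.null(b)) list(label = run$seeds[[k]]$label, dropped = TRUE)
    else list(label = run$seeds[[k]]$label, beat_count = b$beat_count,
              duration = b$duration, rate = b$rate, peak_frames = b$peak_frames)
  })
  jsonlite::write_json(hb, file.path(out_dir, "heartbeats.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(serialize_config(run$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

serialize_config <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

#' @export
print.flybeat_run <- function(x, ...) {
  cat(sprintf("<flybeat_run: back row %d, %d chamber(s)>\n", x$back_row,
              length(x$seeds)))
  for (k in seq_along(x$seeds)) {
    b <- x$heartbeats[[k]]
    if (is.null(b)) cat(sprintf("  %s: dropped\n", x$seeds[[k]]$label))
    else cat(sprintf("  %s: %d beats, %.2f beats/s\n",
                     x$seeds[[k]]$label, b$beat_count, b$rate))
  }
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Compare baseline and shape-prior segmentation
#'
#' Runs the no-prior (`beta = 0`) and with-prior segmentations on the same
#' sequence and reports per-frame Dice and mean contour distance against the
#' truth masks for both methods.
#'
#' @param seq an [image_sequence()].
#' @param truth_masks per-chamber truth mask arrays.
#' @param model a [train_shape_model()] result.
#' @param config a [flybeat_config()].
#' @param out_dir optional directory for the comparison CSV.
#' @return object of class `method_comparison`: `per_frame` data frame with
#'   columns `frame, chamber, method, dice, mean_distance` and a `summary`
#'   by method.
#' @export
compare_methods <- function(seq, truth_masks, model,
                            config = flybeat_config(), out_dir = NULL) {
  if (is.null(truth_masks)) stop("truth masks are required", call. = FALSE)
  cfg0 <- config; cfg0$beta <- 0
  base <- run_pipeline(seq, cfg0, model = NULL, truth_masks = truth_masks)
  with <- run_pipeline(seq, config, model = model, truth_masks = truth_masks)
  pf <- rbind(cbind(base$metrics$per_frame, method = "baseline"),
              cbind(with$metrics$per_frame, method = "prior"))
  pf <- pf[, c("frame", "chamber", "method", "dice", "mean_distance")]
  summary <- do.call(rbind, lapply(split(pf, pf$method), function(s)
    data.frame(method = s$method[1], dice_mean = mean(s$dice),
               dist_mean = mean(s$mean_distance, na.rm = TRUE))))
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pf, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  structure(list(per_frame = pf, summary = summary,
                 baseline = base, prior = with), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$summary)
  invisible(x)
}
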