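# Automatic chamber seed detection.
#
# Chamber lumens backscatter little light and sit low on the grayscale, so
# they appear as regional minima. Raw minima are noise-sensitive; the frame is
# first smoothed by opening-by-reconstruction followed by
# closing-by-reconstruction (peaks, then valley walls), and surviving minima
# are screened by their vertical distance to the bright dorsal "back" stripe.

geodesic_reconstruct <- function(marker, mask, op = c("dilate", "erode"),
                                 max_iter = 100000L) {
  op <- match.arg(op)
  brush <- EBImage::makeBrush(3, shape = "box")
  cur <- marker
  for (i in seq_len(max_iter)) {
    nxt <- if (op == "dilate") pmin(EBImage::dilate(cur, brush), mask)
           else pmax(EBImage::erode(cur, brush), mask)
    nxt <- matrix(nxt, nrow(mask), ncol(mask))
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
  cur
}

#' Morphological-reconstruction smoothing
#'
#' Applies opening-by-reconstruction followed by closing-by-reconstruction
#' with a disk structuring element. The opening flattens bright peaks smaller
#' than the disk; the closing flattens dark pits, so spurious 1-pixel minima
#' vanish while large basins keep their exact boundaries. The output is
#' bounded by the input's intensity range.
#'
#' @param frame numeric intensity matrix.
#' @param radius disk radius in pixels (>= 1, and at most half the smaller
#'   image dimension).
#' @return smoothed intensity matrix.
#' @export
reconstruct_smooth <- function(frame, radius = 3) {
  if (radius < 1) stop_param("radius", "must be >= 1")
  if (radius > min(dim(frame)) / 2)
    stop_param("radius", "larger than half the image's smaller dimension")
  disk <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  er <- matrix(EBImage::erode(frame, disk), nrow(frame), ncol(frame))
  opened <- geodesic_reconstruct(er, frame, "dilate")
  di <- matrix(EBImage::dilate(opened, disk), nrow(frame), ncol(frame))
  geodesic_reconstruct(di, opened, "erode")
}

#' Detect the dorsal back stripe
#'
#' Returns the 0-based row maximizing the row-wise mean intensity of the
#' reconstruction-smoothed frame. The stripe must exceed the global mean
#' intensity by `contrast_margin`, otherwise detection fails.
#'
#' @param frame intensity matrix.
#' @param radius smoothing radius passed to [reconstruct_smooth()].
#' @param contrast_margin minimum excess of the best row mean over the global
#'   mean, on the `[0, 1]` intensity scale.
#' @return 0-based row index of the stripe.
#' @export
detect_back <- function(frame, radius = 3, contrast_margin = 0.1) {
  if (!length(frame)) stop("empty frame", call. = FALSE)
  sm <- reconstruct_smooth(frame, radius)
  rm <- rowMeans(sm)
  if (max(rm) - mean(sm) < contrast_margin)
    stop("no back found: no row exceeds the global mean by the contrast margin",
         call. = FALSE)
  which.max(rm) - 1L
}

#' Detection parameter set
#'
#' @param radius reconstruction-smoothing disk radius (pixels).
#' @param h basin tolerance: a seed region is the connected component of
#'   pixels within `h` of its regional minimum (on the `[0, 1]` scale).
#' @param d_min,d_max accepted band of vertical distance (pixels) from a
#'   basin centroid to the back row.
#' @param min_area minimum basin area in pixels.
#' @param contrast_margin back-detection contrast margin.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(radius = 3, h = 0.05, d_min = 8, d_max = 80,
                             min_area = 30, contrast_margin = 0.1) {
  structure(list(radius = radius, h = h, d_min = d_min, d_max = d_max,
                 min_area = min_area, contrast_margin = contrast_margin),
            class = "detection_params")
}

mask_boundary_contour <- function(mask) {
  cls <- grDevices::contourLines(x = seq_len(nrow(mask)) - 1,
                                 y = seq_len(ncol(mask)) - 1,
                                 z = mask * 1, levels = 0.5)
  if (!length(cls)) return(NULL)
  lens <- vapply(cls, function(cl) length(cl$x), numeric(1))
  cl <- cls[[which.max(lens)]]
  orient_ccw(contour(cbind(x = cl$y, y = cl$x)))
}

# Regional minima (8-connectivity) of a grayscale matrix: equal-value plateau
# components whose outer neighbours are all strictly higher. Plateaus touching
# the image border are treated as background (the open tissue field), not
# minima. Returns a list of logical plateau masks, sorted by depth.
regional_minima8 <- function(m, tol = 1e-9) {
  cand <- m <= erode8(m) + tol
  comps <- list()
  remaining <- cand
  nr <- nrow(m); nc <- ncol(m)
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE; border[, c(1, nc)] <- TRUE
  while (any(remaining)) {
    idx <- which(remaining)
    seed_idx <- idx[which.min(m[idx])]
    val <- m[seed_idx]
    seed <- matrix(FALSE, nr, nc); seed[seed_idx] <- TRUE
    plateau <- flood_fill8(abs(m - val) <= tol, seed)
    remaining <- remaining & !plateau
    if (any(plateau & border)) next
    outer_nb <- (dilate8(plateau * 1) > 0) & !plateau
    if (all(m[outer_nb] > val + tol)) comps[[length(comps) + 1L]] <- plateau
  }
  comps[order(vapply(comps, function(cp) min(m[cp]), numeric(1)))]
}

#' Detect chamber seed regions
#'
#' Extracts the regional minima (8-connectivity) of the
#' reconstruction-smoothed frame, grows each into its basin (the connected
#' component of pixels within `h` of the minimum), and keeps basins whose
#' centroid lies `d_min`-`d_max` rows below the back stripe and whose area
#' reaches `min_area`. Overlapping basins keep the deeper minimum. Seeds are
#' returned sorted by column (anterior to posterior) and labelled `C1, C2, ...`.
#'
#' @param frame intensity matrix.
#' @param back_row 0-based back-stripe row from [detect_back()].
#' @param params a [detection_params()].
#' @return list of `chamber_seed` objects with fields `label`,
#'   `minimum_location` (0-based `(row, col)`), `seed_region` (logical
#'   matrix), and `initial_contour`.
#' @export
detect_chamber_seeds <- function(frame, back_row, params = detection_params()) {
  if (back_row < 0 || back_row >= nrow(frame))
    stop_param("back_row", "outside the frame")
  sm <- reconstruct_smooth(frame, params$radius)
  rows0 <- matrix(seq_len(nrow(sm)) - 1, nrow(sm), ncol(sm))
  comps <- regional_minima8(sm)
  # minima at or above the back row are not chambers
  comps <- Filter(function(cp) mean(rows0[cp]) > back_row, comps)

  claimed <- matrix(FALSE, nrow(sm), ncol(sm))
  seeds <- list(); rejected <- character()
  for (cp in comps) {
    if (any(claimed & cp)) next            # shallower minimum inside an accepted basin
    mval <- min(sm[cp])
    basin <- flood_fill8(sm <= mval + params$h, cp)
    area <- sum(basin)
    cen_row <- mean(rows0[basin])
    cen_col <- mean(matrix(rep(seq_len(ncol(sm)) - 1, each = nrow(sm)),
                           nrow(sm), ncol(sm))[basin])
    dist <- cen_row - back_row
    loc <- which(cp & sm == mval, arr.ind = TRUE)[1, ]
    if (dist < params$d_min || dist > params$d_max) {
      rejected <- c(rejected, sprintf(
        "minimum at (%d,%d): back distance %.1f outside [%g, %g]",
        loc[1] - 1L, loc[2] - 1L, dist, params$d_min, params$d_max))
      next
    }
    if (area < params$min_area) {
      rejected <- c(rejected, sprintf(
        "minimum at (%d,%d): basin area %d below %g",
        loc[1] - 1L, loc[2] - 1L, area, params$min_area))
      next
    }
    claimed <- claimed | basin
    seeds[[length(seeds) + 1L]] <- structure(list(
      label = NA_character_,
      minimum_location = c(row = unname(loc[1]) - 1L, col = unname(loc[2]) - 1L),
      seed_region = basin,
      initial_contour = mask_boundary_contour(basin),
      minimum_value = mval,
      centroid = c(row = cen_row, col = cen_col),
      area = area), class = "chamber_seed")
  }
  if (!length(seeds))
    stop(paste0("no chamber seeds found; rejected candidates:\n  ",
                paste(rejected, collapse = "\n  ")), call. = FALSE)
  ordc <- order(vapply(seeds, function(s) s$centroid["col"], numeric(1)))
  seeds <- seeds[ordc]
  for (i in seq_along(seeds)) seeds[[i]]$label <- sprintf("C%d", i)
  seeds
}

#' @export
print.chamber_seed <- function(x, ...) {
  cat(sprintf("<chamber_seed %s: min at (%d,%d), area %d px>\n", x$label,
              x$minimum_location[1], x$minimum_location[2], x$area))
  invisible(x)
}
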