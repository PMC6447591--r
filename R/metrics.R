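# Segmentation evaluation: Dice area overlap and the symmetric mean contour
# distance (average nearest-point distance between two contours, in pixels).

#' Dice coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' identical (Dice 1).
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of equal dimensions.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask dimensions differ", call. = FALSE)
  a <- mask_a > 0; b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Symmetric mean contour distance
#'
#' `[sum_{s in A} d(s, B) + sum_{s in B} d(s, A)] / (|A| + |B|)` with
#' point-to-set distance taken as the minimum Euclidean distance to the other
#' contour's polyline (point-to-segment, not vertex-only).
#'
#' @param contour_a,contour_b [contour()] objects or n x 2 point matrices
#'   (closed polygons when >= 3 points).
#' @return mean distance in pixels.
#' @export
mean_contour_distance <- function(contour_a, contour_b) {
  pa <- contour_points(contour_a); pb <- contour_points(contour_b)
  if (!nrow(pa) || !nrow(pb)) stop("empty contour", call. = FALSE)
  closed_a <- nrow(pa) >= 3; closed_b <- nrow(pb) >= 3
  da <- points_min_dist(pa, pb, closed = closed_b)
  db <- points_min_dist(pb, pa, closed = closed_a)
  (sum(da) + sum(db)) / (nrow(pa) + nrow(pb))
}

#' Evaluate a segmented sequence against ground truth
#'
#' Computes per-frame, per-chamber Dice and mean contour distance (contours
#' traced from the masks by marching squares) and aggregates them as
#' mean and standard deviation per chamber.
#'
#' @param pred_masks,truth_masks a height x width x n array (one chamber) or
#'   a list of such arrays (one per chamber), aligned frame by frame.
#' @param frame_rate optional frames per second, recorded in the report.
#' @return object of class `metrics_report`: `per_frame` data frame
#'   (`frame, chamber, dice, mean_distance`) and `summary` data frame
#'   (`chamber, dice_mean, dice_sd, dist_mean, dist_sd`).
#' @export
evaluate_sequence <- function(pred_masks, truth_masks, frame_rate = NA) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  pred <- as_list(pred_masks); truth <- as_list(truth_masks)
  if (length(pred) != length(truth))
    stop("pred and truth chamber counts differ", call. = FALSE)
  rows <- list()
  for (k in seq_along(pred)) {
    dp <- dim(pred[[k]]); dt <- dim(truth[[k]])
    if (!identical(dp, dt))
      stop(sprintf("chamber %d: pred and truth dimensions differ", k), call. = FALSE)
    nf <- if (length(dp) == 3) dp[3] else 1L
    for (m in seq_len(nf)) {
      pm <- if (length(dp) == 3) pred[[k]][, , m] else pred[[k]]
      tm <- if (length(dp) == 3) truth[[k]][, , m] else truth[[k]]
      d <- dice(pm, tm)
      cp <- mask_boundary_contour(pm > 0)
      ct <- mask_boundary_contour(tm > 0)
      md <- if (is.null(cp) || is.null(ct)) NA_real_
            else mean_contour_distance(cp, ct)
      rows[[length(rows) + 1L]] <-
        data.frame(frame = m, chamber = k, dice = d, mean_distance = md)
    }
  }
  per_frame <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_frame, per_frame$chamber), function(s)
    data.frame(chamber = s$chamber[1],
               dice_mean = mean(s$dice), dice_sd = stats::sd(s$dice),
               dist_mean = mean(s$mean_distance, na.rm = TRUE),
               dist_sd = stats::sd(s$mean_distance, na.rm = TRUE))))
  rownames(agg) <- NULL
  structure(list(per_frame = per_frame, summary = agg,
                 frame_rate = frame_rate), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation (per chamber, mean +/- sd over frames)\n")
  cat(sprintf("%-10s %-22s %s\n", "Chamber", "Dice", "Mean distance (px)"))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("%-10s %.2f +/- %.2f           %.2f +/- %.2f\n",
                paste0("C", s$chamber), s$dice_mean,
                ifelse(is.na(s$dice_sd), 0, s$dice_sd),
                s$dist_mean, ifelse(is.na(s$dist_sd), 0, s$dist_sd)))
  }
  invisible(x)
}
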