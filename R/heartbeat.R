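# Heartbeat counting from per-frame chamber areas.
#
# The chamber-area series is Gaussian-smoothed to suppress small-amplitude
# noise, local peaks are flagged on interior samples (the discrete analogue
# of S' = 0 and S'' < 0), and the beat count is the number of flagged peaks;
# rate = count * frame_rate / M.

#' Gaussian smoothing of an area series
#'
#' 1-D Gaussian convolution with reflect boundary handling.
#'
#' @param areas numeric series of length >= 3.
#' @param gaussian_sigma kernel standard deviation in frames (> 0).
#' @return smoothed series of the same length.
#' @export
smooth_series <- function(areas, gaussian_sigma) {
  if (length(areas) < 3) stop("area series must have at least 3 samples", call. = FALSE)
  if (gaussian_sigma <= 0) stop_param("gaussian_sigma", "must be > 0")
  gaussian_smooth1d(areas, gaussian_sigma)
}

#' Detect local peaks in a smoothed series
#'
#' Flags interior samples with a strict rise and a weak fall
#' (`S[k] > S[k-1]` and `S[k] >= S[k+1]`), so plateaus are counted once at
#' their first frame; endpoints are never peaks. Candidates whose prominence
#' (height above the higher of the two neighbouring valleys) falls below
#' `min_prominence` are discarded; set `min_prominence = 0` for the literal
#' curvature rule.
#'
#' @param smoothed numeric series of length >= 3.
#' @param min_prominence absolute prominence threshold; the default is 1% of
#'   the series range.
#' @return integer 0/1 vector of the same length.
#' @export
detect_peaks <- function(smoothed, min_prominence = 0.01 * diff(range(smoothed))) {
  m <- length(smoothed)
  if (m < 3) stop("series must have at least 3 samples", call. = FALSE)
  flags <- integer(m)
  k <- 2:(m - 1)
  cand <- k[smoothed[k] > smoothed[k - 1] & smoothed[k] >= smoothed[k + 1]]
  if (length(cand) && min_prominence > 0) {
    keep <- vapply(cand, function(i) {
      peak_prominence(smoothed, i) >= min_prominence
    }, logical(1))
    cand <- cand[keep]
  }
  flags[cand] <- 1L
  flags
}

# Topographic prominence of smoothed[i]: height above the higher of the two
# key saddles, i.e. the minima between the peak and the nearest higher ground
# on each side (series ends when no higher ground exists).
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1) {
    higher <- which(x[seq_len(i - 1)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:(i - 1)])
  } else -Inf
  right <- if (i < length(x)) {
    higher <- which(x[(i + 1):length(x)] > h)
    hi <- if (length(higher)) i + min(higher) - 1L else length(x)
    min(x[(i + 1):hi])
  } else -Inf
  h - max(left, right)
}

#' Bundle an area series
#'
#' @param areas per-frame chamber areas (pixels squared).
#' @param frame_rate frames per second.
#' @param gaussian_sigma smoothing sigma in frames; default `frame_rate / 50`
#'   (2 frames at 100 fps).
#' @param min_prominence see [detect_peaks()]; `NULL` for the 1%-of-range
#'   default.
#' @param smoothed,peak_flags precomputed values (used when reloading from
#'   disk); computed when `NULL`.
#' @return object of class `area_series` with fields `areas`, `smoothed`,
#'   `peak_flags`, `frame_rate`.
#' @export
area_series <- function(areas, frame_rate, gaussian_sigma = frame_rate / 50,
                        min_prominence = NULL, smoothed = NULL,
                        peak_flags = NULL) {
  if (frame_rate <= 0) stop_param("frame_rate", "must be > 0")
  if (is.null(smoothed)) smoothed <- smooth_series(areas, gaussian_sigma)
  if (is.null(peak_flags)) {
    peak_flags <- if (is.null(min_prominence)) detect_peaks(smoothed)
                  else detect_peaks(smoothed, min_prominence)
  }
  stopifnot(length(smoothed) == length(areas),
            length(peak_flags) == length(areas))
  structure(list(areas = as.numeric(areas), smoothed = as.numeric(smoothed),
                 peak_flags = as.integer(peak_flags), frame_rate = frame_rate),
            class = "area_series")
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf("<area_series: %d frames @ %g fps, %d peak(s)>\n",
              length(x$areas), x$frame_rate, sum(x$peak_flags)))
  invisible(x)
}

#' Count heartbeats from an area series
#'
#' `beat_count = sum(peak_flags)`;
#' `rate = beat_count * frame_rate / M` beats per second.
#'
#' @param series an [area_series()].
#' @return object of class `heartbeat_result` with `beat_count`, `duration`
#'   (s), `rate` (beats/s), and `peak_frames` (1-based frame indices).
#' @export
count_heartbeats <- function(series) {
  stopifnot(inherits(series, "area_series"))
  m <- length(series$areas)
  n <- sum(series$peak_flags)
  structure(list(beat_count = as.integer(n),
                 duration = m / series$frame_rate,
                 rate = n * series$frame_rate / m,
                 peak_frames = which(series$peak_flags == 1L)),
            class = "heartbeat_result")
}

#' @export
print.heartbeat_result <- function(x, ...) {
  cat(sprintf("<heartbeat_result: %d beats in %.2f s = %.2f beats/s>\n",
              x$beat_count, x$duration, x$rate))
  invisible(x)
}

#' @export
plot.heartbeat_result <- function(x, series = NULL, ...) {
  if (is.null(series)) stop("pass the area_series used for counting", call. = FALSE)
  graphics::plot(seq_along(series$areas), series$areas, type = "l",
                 col = "grey60", xlab = "frame", ylab = "area (px^2)",
                 main = sprintf("%d beats, %.2f beats/s", x$beat_count, x$rate), ...)
  graphics::lines(seq_along(series$smoothed), series$smoothed, col = "black")
  graphics::points(x$peak_frames, series$smoothed[x$peak_frames],
                   col = "red", pch = 19)
  invisible(x)
}
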