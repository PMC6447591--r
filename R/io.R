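# Sequence, mask, contour and table I/O.
#
# Images and masks travel as multi-page TIFF (PNG accepted for single frames
# in directories); areas and contours as CSV; structured reports as JSON.
# Intensities are normalized to [0, 1] at load by the container's bit depth.

#' Create an image sequence
#'
#' @param frames list of numeric matrices (grayscale intensities in `[0, 1]`),
#'   all of identical dimensions.
#' @param frame_rate frames per second (> 0).
#' @param source_path provenance string.
#' @return object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_rate, source_path = NA_character_) {
  if (!length(frames)) stop("empty image sequence", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  if (frame_rate <= 0) stop_param("frame_rate", "must be > 0")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("frame intensities must lie in [0, 1]", call. = FALSE)
  structure(list(frames = frames, frame_rate = frame_rate,
                 source_path = source_path),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence: %d frames %dx%d @ %g fps (%.2f s)%s>\n",
              length(x$frames), d[1], d[2], x$frame_rate,
              length(x$frames) / x$frame_rate,
              if (is.na(x$source_path)) "" else paste0(", ", x$source_path)))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)

read_one_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                                          c(1, 2), mean)
  img
}

#' Load an image sequence
#'
#' `path` may be a multi-page TIFF or a directory of lexicographically
#' ordered single-frame TIFF/PNG images. Intensities are normalized to
#' `[0, 1]` by the container's bit depth.
#'
#' @param path file or directory.
#' @param frame_rate frames per second.
#' @return an [image_sequence()].
#' @export
load_sequence <- function(path, frame_rate) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("empty image directory", call. = FALSE)
    frames <- lapply(files, read_one_frame)
  } else if (file.exists(path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (!length(frames)) stop("empty TIFF container", call. = FALSE)
    frames <- lapply(frames, to_gray)
  } else stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed dimensions", call. = FALSE)
  image_sequence(frames, frame_rate, source_path = path)
}

#' Save an image sequence as multi-page TIFF
#'
#' @param seq an [image_sequence()].
#' @param path output file.
#' @param bits bits per sample (8 or 16).
#' @export
save_sequence <- function(seq, path, bits = 16) {
  tiff::writeTIFF(lapply(seq$frames, function(f) pmin(pmax(f, 0), 1)),
                  path, bits.per.sample = bits)
  invisible(path)
}

#' Save / load binary mask stacks
#'
#' Masks are written as 8-bit multi-page TIFF with values 0/255; the round
#' trip is bit-exact.
#'
#' @param masks height x width x n logical/numeric array, or list of matrices.
#' @param path TIFF file.
#' @export
save_masks <- function(masks, path) {
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  if (!is.list(masks)) masks <- list(masks)
  tiff::writeTIFF(lapply(masks, function(m) (m > 0) * 1), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' @rdname save_masks
#' @return `load_masks()` returns a height x width x n logical array.
#' @export
load_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(FALSE, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- to_gray(pages[[i]]) > 0.5
  arr
}

contours_to_df <- function(contours) {
  if (inherits(contours, "contour")) contours <- list(list(contours))
  if (inherits(contours[[1]], "contour")) contours <- list(contours)
  # contours: list over chambers of list over frames
  do.call(rbind, lapply(seq_along(contours), function(k) {
    do.call(rbind, lapply(seq_along(contours[[k]]), function(m) {
      ct <- contours[[k]][[m]]
      if (is.null(ct)) return(NULL)
      p <- contour_points(ct)
      data.frame(frame = m, chamber = k, point_index = seq_len(nrow(p)),
                 x = p[, 1], y = p[, 2])
    }))
  }))
}

#' Write / read contours as CSV
#'
#' Columns `frame, chamber, point_index, x, y`; coordinates stored to six
#' decimal places (frames and chambers are 1-based indices).
#'
#' @param contours a [contour()], a per-frame list of contours, or a
#'   per-chamber list of per-frame lists; alternatively a data frame already
#'   in the output layout.
#' @param path CSV file.
#' @export
write_contours <- function(contours, path) {
  df <- if (is.data.frame(contours)) contours else contours_to_df(contours)
  df$x <- round(df$x, 6); df$y <- round(df$y, 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @return `read_contours()` returns the data frame; `df_to_contours()`
#'   rebuilds the nested per-chamber, per-frame contour lists.
#' @export
read_contours <- function(path) {
  utils::read.csv(path)
}

#' @rdname write_contours
#' @param df a data frame as returned by `read_contours()`.
#' @export
df_to_contours <- function(df) {
  lapply(sort(unique(df$chamber)), function(k) {
    sub <- df[df$chamber == k, ]
    lapply(sort(unique(sub$frame)), function(m) {
      p <- sub[sub$frame == m, ]
      p <- p[order(p$point_index), ]
      contour(cbind(x = p$x, y = p$y))
    })
  })
}

#' Write / read a chamber-area table as CSV
#'
#' One data row per frame with columns `frame, area, smoothed, peak`; areas
#' are stored at full double precision.
#'
#' @param series an [area_series()].
#' @param path CSV file.
#' @export
write_area_table <- function(series, path) {
  stopifnot(inherits(series, "area_series"))
  df <- data.frame(frame = seq_along(series$areas),
                   area = formatC(series$areas, digits = 17, format = "g"),
                   smoothed = formatC(series$smoothed, digits = 17, format = "g"),
                   peak = as.integer(series$peak_flags))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_area_table
#' @param frame_rate frames per second of the stored series.
#' @export
read_area_table <- function(path, frame_rate) {
  df <- utils::read.csv(path)
  area_series(as.numeric(df$area), frame_rate,
              smoothed = as.numeric(df$smoothed),
              peak_flags = as.integer(df$peak))
}
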