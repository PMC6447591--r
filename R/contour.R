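#' Create a contour object
#'
#' A contour is an ordered list of sub-pixel points in the package's raster
#' coordinate convention: 0-based, `x` along columns and `y` along rows, with
#' pixel centres at integer coordinates. Closed contours do not repeat their
#' first point.
#'
#' @param points numeric n x 2 matrix (columns `x`, `y`) or data frame.
#' @param closed logical; closed contours need at least 3 points.
#' @return an object of class `contour`.
#' @export
contour <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("contour points must be an n x 2 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  if (nrow(points) >= 2) {
    d <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
    if (any(d < 1e-12)) points <- points[c(TRUE, d >= 1e-12), , drop = FALSE]
    if (closed && nrow(points) >= 2) {
      # drop a repeated closing point
      if (sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-12)
        points <- points[-nrow(points), , drop = FALSE]
    }
  }
  if (closed && nrow(points) < 3)
    stop("a closed contour needs at least 3 distinct points", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, closed = closed), class = "contour")
}

as_contour <- function(x, closed = TRUE) {
  if (inherits(x, "contour")) x else contour(x, closed = closed)
}

contour_points <- function(x) if (inherits(x, "contour")) x$points else as.matrix(x)

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, %s>\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Orient a closed contour counter-clockwise (positive shoelace area in the
# stored (x, y) frame).
orient_ccw <- function(ct) {
  p <- contour_points(ct)
  if (poly_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  contour(p, closed = TRUE)
}
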