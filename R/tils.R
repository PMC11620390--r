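#' Lymphocyte area from its diameter
#'
#' Circular-cell model: \eqn{\pi (d/2)^2}. The conventional 8 um diameter
#' gives 50.3 um^2 (1 d.p.).
#'
#' @param d diameter in micrometers.
#' @return Area in square micrometers (unrounded).
#' @examples
#' round(lymphocyte_area(8), 1)  # 50.3
#' @export
lymphocyte_area <- function(d) {
  if (!is.numeric(d) || any(d <= 0)) stop("diameter must be positive")
  pi * (d / 2)^2
}

#' Stromal TILs score from one observer's mask and points
#'
#' The TILs score T is the fraction of stromal area occupied by lymphocytes:
#' the summed lymphocyte areas of cells whose centers fall in stroma, over
#' the stromal area. Each lymphocyte contributes a fixed nominal area
#' (default 50.3 um^2, a circle of 8 um diameter); the stromal area is the
#' stroma pixel count times the squared pixel size. A point is "in stroma"
#' iff its center pixel (coordinates rounded to the nearest pixel) is stroma.
#'
#' @param mask H x W binary stroma matrix (1 = stroma).
#' @param points m x 2 matrix (or data frame) of lymphocyte centers,
#'   0-based pixel coordinates (x = column, y = row).
#' @param pixel_size_um micrometers per pixel side (default 0.23, the
#'   calibration of a 3000 x 3000 px field covering ~0.476 mm^2).
#' @param lymph_area_um2 nominal per-lymphocyte area; default
#'   \code{lymphocyte_area(8)}.
#' @return A list of class \code{tils_result}: \code{T} (score, uncapped; a
#'   warning is raised above 1), \code{stromal_area_um2}, \code{count}
#'   (in-stroma lymphocytes), \code{excluded} (points outside stroma).
#' @export
tils_score <- function(mask, points, pixel_size_um = 0.23,
                       lymph_area_um2 = lymphocyte_area(8)) {
  stopifnot(pixel_size_um > 0, lymph_area_um2 > 0)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (is.null(points)) points <- matrix(numeric(0), 0, 2)
  n_stroma <- sum(mask == 1L)
  if (n_stroma == 0L) stop("no stroma to score: mask has zero stromal pixels")
  inside <- logical(nrow(points))
  if (nrow(points)) {
    col <- round(points[, 1]) + 1L  # x -> column, 0-based -> 1-based
    row <- round(points[, 2]) + 1L
    ok <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
    inside[ok] <- mask[cbind(row[ok], col[ok])] == 1L
  }
  L <- sum(inside)
  area <- n_stroma * pixel_size_um^2
  T <- L * lymph_area_um2 / area
  if (T > 1) warning("TILs score exceeds 1 (lymphocyte area exceeds stroma)")
  structure(list(T = T, stromal_area_um2 = area, count = L,
                 excluded = nrow(points) - L,
                 pixel_size_um = pixel_size_um,
                 lymph_area_um2 = lymph_area_um2),
            class = "tils_result")
}

#' @export
print.tils_result <- function(x, ...) {
  cat(sprintf("TILs score T = %.4f  (%d lymphocytes in %.0f um^2 stroma, %d outside)\n",
              x$T, x$count, x$stromal_area_um2, x$excluded))
  invisible(x)
}

#' Per-observer TILs scores for one image
#'
#' Applies \code{\link{tils_score}} observer-wise: observer i's own stromal
#' mask with observer i's own lymphocyte points.
#'
#' @param stack a \code{\link{mask_stack}}.
#' @param points a \code{\link{point_sets}} for the same image and observers.
#' @param pixel_size_um micrometers per pixel side.
#' @param lymph_area_um2 nominal per-lymphocyte area.
#' @return Named numeric vector of T values, one per observer.
#' @export
tils_per_observer <- function(stack, points, pixel_size_um = 0.23,
                              lymph_area_um2 = lymphocyte_area(8)) {
  stopifnot(inherits(stack, "mask_stack"), inherits(points, "point_sets"),
            length(stack$masks) == length(points$points))
  out <- vapply(seq_along(stack$masks), function(i) {
    tils_score(stack$masks[[i]], points$points[[i]],
               pixel_size_um = pixel_size_um,
               lymph_area_um2 = lymph_area_um2)$T
  }, numeric(1))
  names(out) <- stack$observer_ids
  out
}
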