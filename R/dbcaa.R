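#' Distance from a point to the nearest point of a set
#'
#' @param p numeric length-2 vector \code{(x, y)}.
#' @param pts m x 2 matrix of points; if empty, \code{Inf} is returned (an
#'   empty set never matches).
#' @return Minimum Euclidean distance from \code{p} to \code{pts}.
#' @examples
#' nearest_point_distance(c(0, 0), rbind(c(3, 4)))  # 5
#' @export
nearest_point_distance <- function(p, pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(Inf)
  sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
}

# For every row of a, the squared distance to its nearest row of b.
# Vectorized all-pairs computation; both inputs are m x 2 matrices.
min_sq_dist <- function(a, b) {
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  apply(d2, 1, min)
}

#' Distance-Based Cell Agreement Algorithm (DBCAA)
#'
#' Ground-truth-free agreement over per-observer cell-center points. For each
#' point P of observer i, the agreement counter \eqn{a_k^i} counts the other
#' observers j whose nearest point to P lies within the expected lymphocyte
#' diameter \code{D_L}. The agreement score is the sum of all counters over a
#' normalizing constant: \code{normalization = "max_match"} divides by
#' \eqn{(N-1)\sum_i m_i} so identical annotations score exactly 1;
#' \code{normalization = "paper"} divides by \eqn{N \sum_i m_i}, under which
#' perfect agreement scores \eqn{(N-1)/N}. Matching is one-to-many: several
#' points of one observer may match the same point of another.
#'
#' @param points a \code{\link{point_sets}} object (N >= 2 observers).
#' @param D_L match radius: the expected lymphocyte diameter, in pixels.
#' @param normalization \code{"max_match"} (default) or \code{"paper"}.
#' @param strict logical; \code{TRUE} (default) counts a match when the
#'   distance is strictly below \code{D_L}, \code{FALSE} also at equality.
#' @return A list of class \code{dbcaa_result}: \code{score} (M_L),
#'   \code{counters} (per-observer list of per-point agreement counts in
#'   \code{0..N-1}), \code{per_observer} (summed counters), \code{N},
#'   \code{total_points}, \code{D_L}, \code{normalization}.
#' @export
dbcaa <- function(points, D_L, normalization = c("max_match", "paper"),
                  strict = TRUE) {
  stopifnot(inherits(points, "point_sets"), D_L > 0)
  normalization <- match.arg(normalization)
  N <- length(points$points)
  if (N < 2L) stop("DBCAA needs at least 2 observers")
  if (any(points$counts == 0L))
    warning("observer(s) with no points contribute nothing and never match")
  counters <- vector("list", N)
  thr2 <- D_L^2
  for (i in seq_len(N)) {
    ci <- points$points[[i]]
    a <- integer(nrow(ci))
    if (nrow(ci)) {
      for (j in seq_len(N)[-i]) {
        d2 <- min_sq_dist(ci, points$points[[j]])
        a <- a + if (strict) as.integer(d2 < thr2) else as.integer(d2 <= thr2)
      }
    }
    counters[[i]] <- a
  }
  total <- sum(points$counts)
  if (total == 0L) stop("no points in any observer; DBCAA undefined")
  Z <- switch(normalization, max_match = (N - 1) * total, paper = N * total)
  structure(list(score = sum(unlist(counters)) / Z,
                 counters = counters,
                 per_observer = vapply(counters, sum, numeric(1)),
                 N = N, total_points = total, D_L = D_L,
                 normalization = normalization, strict = strict),
            class = "dbcaa_result")
}

#' @export
print.dbcaa_result <- function(x, ...) {
  cat(sprintf("DBCAA: M_L = %.4f  (N = %d, points = %d, D_L = %g px, %s)\n",
              x$score, x$N, x$total_points, x$D_L, x$normalization))
  invisible(x)
}

#' Plot per-point agreement counts
#'
#' Draws every observer's points in a distinct color, labelled with their
#' agreement counters, mirroring the usual visual QC of DBCAA output.
#'
#' @param x a \code{\link{dbcaa}} result.
#' @param points the \code{\link{point_sets}} the result was computed from.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.dbcaa_result <- function(x, points, ...) {
  all_pts <- do.call(rbind, points$points)
  cols <- c("red", "green3", "cyan3", "gold", "purple", "orange")
  if (is.null(all_pts) || nrow(all_pts) == 0L) {
    plot.new()
    title("DBCAA agreement counts (no points)")
    return(invisible(x))
  }
  plot(NA, xlim = range(all_pts[, 1]), ylim = rev(range(all_pts[, 2])),
       xlab = "x (px)", ylab = "y (px)",
       main = sprintf("DBCAA agreement counts (M_L = %.3f)", x$score), ...)
  for (i in seq_along(points$points)) {
    p <- points$points[[i]]
    if (!nrow(p)) next
    graphics::points(p[, 1], p[, 2], col = cols[(i - 1) %% length(cols) + 1],
                     pch = 19)
    graphics::text(p[, 1], p[, 2], labels = x$counters[[i]], pos = 3,
                   cex = 0.8)
  }
  invisible(x)
}

#' Convert a lymphocyte diameter in micrometers to a pixel match radius
#'
#' @param diameter_um lymphocyte diameter in micrometers (default 8).
#' @param pixel_size_um micrometers per pixel side.
#' @return The diameter in pixels, for use as \code{D_L} in \code{\link{dbcaa}}.
#' @export
dl_pixels <- function(diameter_um = 8, pixel_size_um) {
  stopifnot(diameter_um > 0, pixel_size_um > 0)
  diameter_um / pixel_size_um
}
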