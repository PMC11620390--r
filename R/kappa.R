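#' Per-pixel agreement count table
#'
#' Treats each pixel of the image as a rating subject and counts, for the two
#' categories non-stroma (0) and stroma (1), how many observers assigned the
#' pixel to each. Pixels flagged in the exclusion mask (either the stack's own
#' or the one supplied here) are dropped from the universe.
#'
#' @param stack a \code{\link{mask_stack}}.
#' @param exclusion optional logical matrix; \code{TRUE} pixels are excluded.
#' @return A list of class \code{count_table} with integer vectors \code{n0},
#'   \code{n1} (per-pixel vote counts summing to N), the pixel universe size
#'   \code{M}, observer count \code{N}, \code{K = 2}, and \code{keep}, the
#'   logical map of retained pixels.
#' @export
build_count_table <- function(stack, exclusion = NULL) {
  stopifnot(inherits(stack, "mask_stack"))
  N <- length(stack$masks)
  votes <- Reduce(`+`, stack$masks)
  keep <- matrix(TRUE, nrow(votes), ncol(votes))
  if (!is.null(stack$exclusion)) keep <- keep & !stack$exclusion
  if (!is.null(exclusion)) keep <- keep & !exclusion
  if (!any(keep)) stop("all pixels are excluded; empty agreement universe")
  n1 <- as.integer(votes[keep])
  structure(list(n0 = N - n1, n1 = n1, M = length(n1), N = N, K = 2L,
                 keep = keep),
            class = "count_table")
}

# Core weighted Fleiss computation shared by FK (unit weights) and BWFK.
# n is an M x K matrix of counts, w a length-M weight vector with sum(w) = M.
kappa_from_counts <- function(n, w, method, DT = NA_real_) {
  M <- nrow(n)
  N <- sum(n[1, ])
  if (N < 2L) stop("Fleiss' kappa needs at least 2 observers")
  p_obs <- (sum(w * n^2) - M * N) / (M * N * (N - 1))
  p_j <- colSums(w * n) / (M * N)
  p_exp <- sum(p_j^2)
  degenerate <- FALSE
  if (p_exp >= 1 - 1e-15) {
    # single category everywhere: operationally perfect agreement
    kappa <- 1
    degenerate <- TRUE
  } else {
    kappa <- (p_obs - p_exp) / (1 - p_exp)
  }
  structure(list(kappa = kappa, p_observed = p_obs, p_expected = p_exp,
                 method = method, DT = DT, M = M, N = N,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' Fleiss' kappa over a pixel-wise agreement count table
#'
#' Chance-corrected agreement of N observers assigning M pixels to K = 2
#' categories: \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)} with
#' \eqn{\bar P = (\sum_i \sum_j n_{ij}^2 - MN) / (MN(N-1))} and
#' \eqn{\bar P_e = \sum_j p_j^2}, \eqn{p_j = \sum_i n_{ij} / (MN)}.
#'
#' @param table a \code{\link{build_count_table}} result, or a
#'   \code{\link{mask_stack}} (converted internally).
#' @return A \code{kappa_result} with fields \code{kappa}, \code{p_observed},
#'   \code{p_expected}, \code{method = "FK"}, and \code{degenerate}, set when
#'   the expected agreement is 1 (single category everywhere) and the
#'   conventional ratio is undefined; such stacks report \code{kappa = 1}.
#' @export
fleiss_kappa <- function(table) {
  if (inherits(table, "mask_stack")) table <- build_count_table(table)
  stopifnot(inherits(table, "count_table"))
  n <- cbind(table$n0, table$n1)
  kappa_from_counts(n, rep(1, table$M), method = "FK")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s: kappa = %.4f  (P_obs = %.4f, P_exp = %.4f, M = %d, N = %d",
              x$method, x$kappa, x$p_observed, x$p_expected, x$M, x$N))
  if (!is.na(x$DT)) cat(sprintf(", DT = %g", x$DT))
  if (isTRUE(x$degenerate)) cat(", degenerate")
  cat(")\n")
  invisible(x)
}

#' Extract the stroma boundary of a binary mask
#'
#' A boundary pixel is a stroma pixel with at least one non-stroma neighbour
#' among its 4-connected neighbours. The image border itself does not create
#' boundary (masks are padded with their own edge values).
#'
#' @param mask H x W matrix in {0, 1}.
#' @return Logical H x W matrix marking boundary pixels.
#' @export
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  # pad by edge replication so the frame edge is not treated as a boundary
  up    <- mask[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- mask[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  left  <- mask[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- mask[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  mask == 1L & (up == 0L | down == 0L | left == 0L | right == 0L)
}

#' Boundary-distance weight map for BWFK
#'
#' For each observer the stroma boundary is extracted and an exact Euclidean
#' distance transform gives every pixel's distance to the nearest boundary
#' pixel. The N distance images are averaged pixel-wise, flattened by clipping
#' at the threshold \code{DT} (so pixels further than \code{DT} from any
#' boundary contribute equally), and normalized so the weights sum to the
#' number of pixels in the universe: \eqn{w'_i = M w_i / \sum_j w_j}. Pixels
#' on a boundary (distance 0) keep weight 0; near-boundary disagreement is
#' thereby down-weighted.
#'
#' @param stack a \code{\link{mask_stack}}.
#' @param DT flattening threshold in pixels (default 100).
#' @param clip one of \code{"after_mean"} (default: average the per-observer
#'   distance maps, then clip the mean at \code{DT}) or \code{"before_mean"}
#'   (clip each observer's map first).
#' @param keep optional logical matrix restricting the universe (as from
#'   \code{\link{build_count_table}}).
#' @return A list of class \code{weight_map}: \code{raw} (mean clipped
#'   distances, H x W), \code{w} (normalized weight vector over the universe),
#'   \code{keep}, \code{DT}.
#' @export
boundary_weights <- function(stack, DT = 100, clip = c("after_mean", "before_mean"),
                             keep = NULL) {
  stopifnot(inherits(stack, "mask_stack"), DT > 0)
  clip <- match.arg(clip)
  d <- dim(stack$masks[[1]])
  acc <- matrix(0, d[1], d[2])
  for (m in stack$masks) {
    if (all(m == m[1])) {
      # no boundary at all: constant mask contributes the flat distance DT
      warning("mask without boundary (constant 0 or 1); using distance DT")
      dist <- matrix(as.double(DT), d[1], d[2])
    } else {
      b <- mask_boundary(m)
      dist <- EBImage::distmap(matrix(as.double(!b), d[1], d[2]))
      dist <- matrix(as.double(dist), d[1], d[2])
      if (clip == "before_mean") dist <- pmin(dist, DT)
    }
    acc <- acc + dist
  }
  raw <- acc / length(stack$masks)
  if (clip == "after_mean") raw <- pmin(raw, DT)
  if (is.null(keep)) keep <- matrix(TRUE, d[1], d[2])
  w <- as.double(raw[keep])
  s <- sum(w)
  if (s == 0) stop("all boundary weights are zero; cannot normalize")
  w <- length(w) * w / s
  structure(list(raw = raw, w = w, keep = keep, DT = DT), class = "weight_map")
}

#' Boundary-Weighted Fleiss' Kappa (BWFK)
#'
#' Fleiss' kappa with per-pixel weights derived from the flattened mean
#' boundary distance transform (\code{\link{boundary_weights}}), so that
#' disagreements close to the annotation boundaries — where precise
#' delineation is inherently hard — contribute less:
#' \eqn{\bar P^w = (\sum_j \sum_i w'_i n_{ij}^2 - MN)/(MN(N-1))},
#' \eqn{\bar P_e^w = \sum_j (p_j^w)^2} with
#' \eqn{p_j^w = \sum_i w'_i n_{ij}/(MN)}, and
#' \eqn{\kappa^w = (\bar P^w - \bar P_e^w)/(1 - \bar P_e^w)}.
#'
#' @inheritParams boundary_weights
#' @param exclusion optional logical matrix of pixels to exclude.
#' @param weights optional precomputed \code{weight_map} (must match the
#'   universe); supplying a uniform map reproduces plain Fleiss' kappa.
#' @return A \code{kappa_result} with \code{method = "BWFK"}.
#' @export
bwfk <- function(stack, DT = 100, exclusion = NULL,
                 clip = c("after_mean", "before_mean"), weights = NULL) {
  tab <- build_count_table(stack, exclusion = exclusion)
  if (is.null(weights))
    weights <- boundary_weights(stack, DT = DT, clip = clip, keep = tab$keep)
  stopifnot(inherits(weights, "weight_map"))
  w <- weights$w
  if (length(w) != tab$M)
    stop("weight map does not match the pixel universe")
  n <- cbind(tab$n0, tab$n1)
  kappa_from_counts(n, w, method = "BWFK", DT = weights$DT)
}

#' Agreement maps and the max agreement map
#'
#' Per-pixel counts of stroma and non-stroma votes across observers, and
#' their pixel-wise maximum. Disagreement shows up as max-map values below N;
#' in practice these concentrate along the stromal boundaries.
#'
#' @param stack a \code{\link{mask_stack}}.
#' @return A list of class \code{agreement_maps}: \code{stroma},
#'   \code{nonstroma}, \code{max} (H x W integer matrices), \code{N}.
#' @export
agreement_maps <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  N <- length(stack$masks)
  stroma <- Reduce(`+`, stack$masks)
  nonstroma <- N - stroma
  structure(list(stroma = stroma, nonstroma = nonstroma,
                 max = pmax(stroma, nonstroma), N = N),
            class = "agreement_maps")
}

#' Render an agreement map to a color-coded PNG
#'
#' Counts are mapped to a fixed blue-to-red ramp (0 votes = dark blue,
#' N votes = dark red).
#'
#' @param maps an \code{\link{agreement_maps}} result.
#' @param which one of \code{"max"}, \code{"stroma"}, \code{"nonstroma"}.
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
render_agreement_map <- function(maps, which = c("max", "stroma", "nonstroma"),
                                 path) {
  which <- match.arg(which)
  m <- maps[[which]]
  pal <- grDevices::colorRampPalette(c("#08306B", "#F7FBFF", "#67000D"))(maps$N + 1)
  rgb <- grDevices::col2rgb(pal[m + 1L]) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nrow(m), ncol(m))
  png::writePNG(arr, path)
  invisible(path)
}
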