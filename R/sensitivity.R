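#' Translate a binary mask
#'
#' Shifts a mask by integer pixel offsets; vacated pixels take the fill
#' value (default non-stroma) and the image dimensions are unchanged.
#'
#' @param mask H x W matrix in {0, 1}.
#' @param dx,dy integer shifts in pixels (positive dx moves content right,
#'   positive dy moves it down).
#' @param fill value for vacated pixels (default 0 = non-stroma).
#' @return The shifted mask.
#' @export
shift_mask <- function(mask, dx, dy, fill = 0L) {
  h <- nrow(mask); w <- ncol(mask)
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (abs(dx) >= w || abs(dy) >= h)
    stop("shift magnitude must be smaller than the image size")
  out <- matrix(as.integer(fill), h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

# Uniform random direction rounded to integer offsets of magnitude ~ s.
random_offset <- function(s) {
  theta <- stats::runif(1, 0, 2 * pi)
  c(dx = round(s * cos(theta)), dy = round(s * sin(theta)))
}

#' Mask shift test: FK vs BWFK robustness to boundary displacement
#'
#' Simulates small delineation errors by displacing observers' masks by a
#' random direction at each shift magnitude and recording plain and
#' boundary-weighted Fleiss' kappa together with the BWFK gain,
#' \code{100 * (BWFK - FK) / FK}. Because the induced disagreement is a band
#' around the annotation boundary, BWFK (which down-weights near-boundary
#' pixels up to the flattening threshold DT) degrades more slowly than FK.
#'
#' @param stack a \code{\link{mask_stack}} (the unshifted annotations).
#' @param shifts vector of shift magnitudes in pixels.
#' @param DT BWFK flattening threshold (default 100).
#' @param seed RNG seed; the curve is deterministic given (input, seed).
#' @param mode \code{"all"} (default: every observer displaced independently
#'   per trial) or \code{"one"} (only the first observer displaced).
#' @param trials random displacement draws per shift magnitude; FK and BWFK
#'   are averaged over trials (default 1). Averaging plays the role the
#'   repeated images of a multi-image study play in smoothing the curve.
#' @return A data frame of class \code{shift_test} with columns
#'   \code{shift}, \code{fk}, \code{bwfk}, \code{gain_pct} (computed from
#'   the averaged kappas).
#' @export
mask_shift_test <- function(stack, shifts, DT = 100, seed = 1,
                            mode = c("all", "one"), trials = 1) {
  stopifnot(inherits(stack, "mask_stack"), trials >= 1)
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- data.frame(shift = shifts, fk = NA_real_, bwfk = NA_real_,
                    gain_pct = NA_real_)
  for (r in seq_along(shifts)) {
    s <- shifts[r]
    idx <- if (mode == "one") 1L else seq_along(stack$masks)
    fk_t <- bw_t <- numeric(trials)
    for (t in seq_len(trials)) {
      masks <- stack$masks
      if (s > 0) {
        for (i in idx) {
          off <- random_offset(s)
          masks[[i]] <- shift_mask(masks[[i]], off["dx"], off["dy"])
        }
      }
      shifted <- mask_stack(masks, observer_ids = stack$observer_ids,
                            image_id = stack$image_id,
                            exclusion = stack$exclusion)
      fk_t[t] <- fleiss_kappa(shifted)$kappa
      bw_t[t] <- bwfk(shifted, DT = DT)$kappa
      if (s == 0) {  # no randomness at zero shift
        fk_t <- rep(fk_t[1], trials); bw_t <- rep(bw_t[1], trials)
        break
      }
    }
    res$fk[r] <- mean(fk_t)
    res$bwfk[r] <- mean(bw_t)
    res$gain_pct[r] <- 100 * (res$bwfk[r] - res$fk[r]) / res$fk[r]
  }
  class(res) <- c("shift_test", "data.frame")
  attr(res, "seed") <- seed
  attr(res, "DT") <- DT
  res
}

#' @export
plot.shift_test <- function(x, ...) {
  graphics::matplot(x$shift, cbind(x$fk, x$bwfk), type = "b", pch = c(1, 19),
                    lty = 1, col = c("gray40", "firebrick"),
                    xlab = "Shift (px)", ylab = "Kappa",
                    main = "Mask shift test: FK vs BWFK", ...)
  graphics::legend("topright", c("FK", "BWFK"), pch = c(1, 19),
                   col = c("gray40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

# Perturb each point by a random direction with magnitude uniform in
# [0, level] (Euclidean bound), so two matched points can separate by at
# most 2*level.
perturb_points <- function(pts, level) {
  if (nrow(pts) == 0L || level <= 0) return(pts)
  m <- nrow(pts)
  theta <- stats::runif(m, 0, 2 * pi)
  r <- stats::runif(m, 0, level)
  pts + cbind(r * cos(theta), r * sin(theta))
}

#' Point shift test: DBCAA robustness to coordinate perturbation
#'
#' At each perturbation level every point of every observer is displaced in
#' a random direction by a random magnitude up to the level, and the DBCAA
#' score is recomputed. For well-separated perfect-agreement annotations the
#' score stays flat while twice the level is below the match radius D_L
#' (matched pairs cannot separate past D_L), then declines — the inflection
#' reflects D_L, the expected lymphocyte diameter.
#'
#' @param points a \code{\link{point_sets}} object.
#' @param levels perturbation magnitudes in pixels (e.g. \code{1:50}).
#' @param D_L DBCAA match radius in pixels.
#' @param seed RNG seed.
#' @param normalization passed to \code{\link{dbcaa}}.
#' @return A data frame of class \code{point_perturb} with columns
#'   \code{level} and \code{score}.
#' @export
point_shift_test <- function(points, levels, D_L, seed = 1,
                             normalization = "max_match") {
  stopifnot(inherits(points, "point_sets"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  score <- vapply(levels, function(lv) {
    moved <- lapply(points$points, perturb_points, level = lv)
    ps <- point_sets(moved, observer_ids = points$observer_ids,
                     image_id = points$image_id)
    dbcaa(ps, D_L = D_L, normalization = normalization)$score
  }, numeric(1))
  res <- data.frame(level = levels, score = score)
  class(res) <- c("point_perturb", "data.frame")
  attr(res, "seed") <- seed
  attr(res, "D_L") <- D_L
  res
}

#' Point lost test: DBCAA robustness to missed detections
#'
#' At each loss fraction f, \code{floor(f * m_i)} points are removed
#' uniformly at random from each observer and DBCAA is recomputed. For a
#' perfect-agreement configuration with well-separated cells the expected
#' score under max_match normalization is \code{((1 - f) N - 1)/(N - 1)}:
#' each surviving point matches the surviving fraction of the other
#' observers' copies.
#'
#' @param points a \code{\link{point_sets}} object.
#' @param fractions loss fractions in (0, 1) (e.g. \code{seq(0.01, 0.5, 0.01)}).
#' @param D_L DBCAA match radius in pixels.
#' @param seed RNG seed.
#' @param normalization passed to \code{\link{dbcaa}}.
#' @return A data frame of class \code{point_perturb} with columns
#'   \code{level} (the fraction) and \code{score}.
#' @export
point_lost_test <- function(points, fractions, D_L, seed = 1,
                            normalization = "max_match") {
  stopifnot(inherits(points, "point_sets"))
  if (any(fractions < 0 | fractions >= 1))
    stop("loss fractions must lie in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  score <- vapply(fractions, function(f) {
    kept <- lapply(points$points, function(p) {
      drop <- floor(f * nrow(p))
      if (drop == 0L) return(p)
      p[-sample.int(nrow(p), drop), , drop = FALSE]
    })
    if (sum(vapply(kept, nrow, integer(1))) == 0L)
      stop("loss fraction removed every point; DBCAA undefined")
    ps <- point_sets(kept, observer_ids = points$observer_ids,
                     image_id = points$image_id)
    dbcaa(ps, D_L = D_L, normalization = normalization)$score
  }, numeric(1))
  res <- data.frame(level = fractions, score = score)
  class(res) <- c("point_perturb", "data.frame")
  attr(res, "seed") <- seed
  attr(res, "D_L") <- D_L
  res
}

#' @export
plot.point_perturb <- function(x, ...) {
  plot(x$level, x$score, type = "b", pch = 19, col = "firebrick",
       xlab = "Perturbation level", ylab = "DBCAA score",
       main = "DBCAA sensitivity", ...)
  invisible(x)
}
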