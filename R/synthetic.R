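#' Configuration for the synthetic multi-observer annotation generator
#'
#' The generator emulates the structure of a clinical TILs annotation study:
#' per-image binary stromal masks annotated by several observers whose
#' disagreements concentrate along the stromal boundaries, and per-observer
#' lymphocyte center points subject to positional jitter, missed cells and
#' false positives. The default calibration follows a 40x H&E field digitized
#' at 0.23 um/px; the clinical-scale profile is a 3000 x 3000 px field
#' (~0.476 mm^2) with four observers and roughly 2,000 lymphocytes per image
#' (~4,200 cells/mm^2), while the default 512 px size keeps simulation
#' studies quick at the same per-area conditions.
#'
#' @param H,W image size in pixels (default 512).
#' @param n_observers number of observers (default 4).
#' @param stroma_fraction target fraction of stromal pixels (default 0.45).
#' @param length_scale smoothing length of the latent stroma texture, pixels
#'   (default 40).
#' @param boundary_amplitude per-observer boundary perturbation amplitude in
#'   pixels (default 5); observers' masks differ from truth only within this
#'   distance of the true boundary.
#' @param density lymphocyte density, cells per mm^2 (default 4200).
#' @param jitter_sd per-observer positional jitter SD in pixels (default 2).
#' @param miss_rate probability an observer misses a true cell (default 0.1).
#' @param fp_rate expected false positives per true cell (default 0.05).
#' @param pixel_size_um micrometers per pixel side (default 0.23).
#' @param min_spacing_um hard-core spacing between true cells, micrometers
#'   (default 8, one lymphocyte diameter).
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(H = 512, W = 512, n_observers = 4,
                         stroma_fraction = 0.45, length_scale = 40,
                         boundary_amplitude = 5, density = 4200,
                         jitter_sd = 2, miss_rate = 0.1, fp_rate = 0.05,
                         pixel_size_um = 0.23, min_spacing_um = 8) {
  stopifnot(H > 0, W > 0, n_observers >= 2,
            stroma_fraction >= 0, stroma_fraction <= 1,
            boundary_amplitude >= 0, density >= 0,
            jitter_sd >= 0, miss_rate >= 0, miss_rate <= 1, fp_rate >= 0,
            pixel_size_um > 0, min_spacing_um >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Smooth Gaussian random field on an H x W grid, standardized to unit sd.
# White noise is low-passed by a Gaussian transfer function in the Fourier
# domain (periodic convolution), which works for any length scale relative
# to the image size.
smooth_field <- function(H, W, length_scale) {
  f <- matrix(stats::rnorm(H * W), H, W)
  if (length_scale > 0) {
    fy <- (seq_len(H) - 1); fy <- ifelse(fy > H / 2, fy - H, fy) / H
    fx <- (seq_len(W) - 1); fx <- ifelse(fx > W / 2, fx - W, fx) / W
    G <- exp(-2 * pi^2 * length_scale^2 *
               (outer(fy^2, rep(1, W)) + outer(rep(1, H), fx^2)))
    f <- Re(stats::fft(stats::fft(f) * G, inverse = TRUE)) / (H * W)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate a latent ground-truth mask and lymphocyte points
#'
#' The stroma mask is a low-pass Gaussian random field thresholded at the
#' empirical quantile that hits the target stroma fraction; lymphocytes are
#' placed inside the stroma by a hard-core (dart-throwing) point process with
#' minimum spacing of one lymphocyte diameter.
#'
#' @param config a \code{\link{synth_config}}.
#' @param seed RNG seed.
#' @return A list of class \code{synth_truth}: \code{mask} (H x W 0/1
#'   matrix), \code{points} (m x 2 matrix of (x, y), 0-based pixel
#'   coordinates), \code{config}.
#' @export
generate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- config$H; W <- config$W
  if (config$stroma_fraction >= 1) {
    mask <- matrix(1L, H, W)
  } else if (config$stroma_fraction <= 0) {
    mask <- matrix(0L, H, W)
  } else {
    f <- smooth_field(H, W, config$length_scale)
    thr <- stats::quantile(f, 1 - config$stroma_fraction, names = FALSE)
    mask <- matrix(as.integer(f > thr), H, W)
  }
  # expected cell count from physical density
  area_mm2 <- H * W * (config$pixel_size_um / 1000)^2
  n_target <- round(config$density * area_mm2)
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (n_target > 0) {
    stroma_idx <- which(mask == 1L)
    if (length(stroma_idx) == 0L && n_target > 0)
      stop("cannot place lymphocytes: mask has no stroma")
    spacing_px <- config$min_spacing_um / config$pixel_size_um
    # feasibility guard: hard cores must fit in the stromal area
    if (n_target * pi * (spacing_px / 2)^2 > 1.2 * length(stroma_idx))
      stop("infeasible lymphocyte density ", config$density,
           "/mm^2 for spacing ", config$min_spacing_um,
           " um: hard cores exceed the stromal area")
    kept <- matrix(NA_real_, n_target, 2)
    n_kept <- 0L
    attempts <- 0L
    max_attempts <- 80L * n_target
    sp2 <- spacing_px^2
    while (n_kept < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      idx <- stroma_idx[sample.int(length(stroma_idx), 1L)]
      y <- (idx - 1L) %% H        # row - 1
      x <- (idx - 1L) %/% H       # col - 1
      # sub-pixel position within the chosen stroma pixel
      x <- x + stats::runif(1) - 0.5
      y <- y + stats::runif(1) - 0.5
      if (n_kept > 0L) {
        d2 <- (kept[seq_len(n_kept), 1] - x)^2 + (kept[seq_len(n_kept), 2] - y)^2
        if (min(d2) < sp2) next
      }
      n_kept <- n_kept + 1L
      kept[n_kept, ] <- c(x, y)
    }
    if (n_kept < n_target)
      warning("placed ", n_kept, " of ", n_target,
              " lymphocytes before the attempt budget ran out")
    pts <- kept[seq_len(n_kept), , drop = FALSE]
    if (nrow(pts)) {
      pts[, 1] <- pmin(pmax(pts[, 1], 0), W - 1)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), H - 1)
    }
    colnames(pts) <- c("x", "y")
  }
  structure(list(mask = mask, points = pts, config = config),
            class = "synth_truth")
}

#' Generate per-observer annotations from a ground truth
#'
#' Each observer's mask is the truth deformed by a signed smooth random
#' radius field bounded by the boundary amplitude: the truth's signed
#' boundary distance (positive inside stroma) is perturbed and re-thresholded,
#' so all disagreement is confined to a band around the true boundary —
#' the regime in which boundary-weighted agreement measures operate. Each
#' observer's points are the truth points minus Bernoulli misses, plus
#' Gaussian jitter, plus uniform in-frame false positives.
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param seed RNG seed.
#' @return A list with \code{stack} (a \code{\link{mask_stack}}) and
#'   \code{points} (a \code{\link{point_sets}}).
#' @export
generate_observers <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synth_truth"))
  cfg <- truth$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- cfg$H; W <- cfg$W
  amp <- cfg$boundary_amplitude
  signed <- NULL
  if (amp > 0 && !all(truth$mask == truth$mask[1])) {
    din <- matrix(as.double(EBImage::distmap(matrix(as.double(truth$mask), H, W))), H, W)
    dout <- matrix(as.double(EBImage::distmap(matrix(as.double(1 - truth$mask), H, W))), H, W)
    signed <- din - dout  # > 0 inside stroma, <= 0 outside
  }
  masks <- vector("list", cfg$n_observers)
  pts <- vector("list", cfg$n_observers)
  for (k in seq_len(cfg$n_observers)) {
    if (is.null(signed)) {
      masks[[k]] <- truth$mask
    } else {
      r <- smooth_field(H, W, cfg$length_scale / 2) * (amp / 2)
      r <- pmin(pmax(r, -amp), amp)
      masks[[k]] <- matrix(as.integer(signed + r > 0), H, W)
    }
    p <- truth$points
    if (nrow(p)) {
      keep <- stats::runif(nrow(p)) >= cfg$miss_rate
      p <- p[keep, , drop = FALSE]
      if (nrow(p) && cfg$jitter_sd > 0) {
        p <- p + matrix(stats::rnorm(2 * nrow(p), sd = cfg$jitter_sd),
                        ncol = 2)
      }
    }
    n_fp <- stats::rpois(1, cfg$fp_rate * nrow(truth$points))
    if (n_fp > 0) {
      fp <- cbind(stats::runif(n_fp, 0, W - 1), stats::runif(n_fp, 0, H - 1))
      p <- rbind(p, fp)
    }
    if (nrow(p)) {
      p[, 1] <- pmin(pmax(p[, 1], 0), W - 1)
      p[, 2] <- pmin(pmax(p[, 2], 0), H - 1)
    }
    colnames(p) <- c("x", "y")
    pts[[k]] <- p
  }
  ids <- paste0("obs", seq_len(cfg$n_observers))
  list(stack = mask_stack(masks, observer_ids = ids),
       points = suppressWarnings(
         point_sets(pts, observer_ids = ids, frame = c(W, H))))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes \code{n_images} independent synthetic images — per-observer mask
#' PNGs and point CSVs — plus a YAML manifest, in the formats the readers of
#' this package consume. Per-image variability is introduced by drawing the
#' stroma fraction, boundary amplitude and miss rate around their configured
#' values, so agreement genuinely varies across images. Fully reproducible
#' from the seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @param n_images number of images.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return The \code{dataset_manifest}, invisibly; the manifest file is
#'   \code{file.path(dir, "manifest.yaml")}.
#' @export
generate_dataset <- function(config, n_images, dir, seed = 1) {
  stopifnot(inherits(config, "synth_config"), n_images >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs_ids <- paste0("obs", seq_len(config$n_observers))
  images <- list()
  if (n_images > 0) {
    # derive independent per-image sub-seeds from the master seed
    sub_seeds <- sample.int(.Machine$integer.max, 2L * n_images)
    for (i in seq_len(n_images)) {
      cfg_i <- config
      cfg_i$stroma_fraction <- min(0.9, max(0.1,
        config$stroma_fraction + stats::runif(1, -0.1, 0.1)))
      cfg_i$boundary_amplitude <- config$boundary_amplitude *
        stats::runif(1, 0.5, 1.5)
      cfg_i$miss_rate <- min(0.9, config$miss_rate * stats::runif(1, 0.5, 1.5))
      truth <- generate_truth(cfg_i, seed = sub_seeds[2L * i - 1L])
      obs <- generate_observers(truth, seed = sub_seeds[2L * i])
      img_id <- sprintf("img%03d", i)
      mask_paths <- file.path(dir, sprintf("%s_%s_mask.png", img_id, obs_ids))
      pt_paths <- file.path(dir, sprintf("%s_%s_points.csv", img_id, obs_ids))
      for (k in seq_along(obs_ids))
        write_mask(obs$stack$masks[[k]], mask_paths[k])
      write_point_sets(obs$points, pt_paths)
      images[[img_id]] <- list(
        masks = stats::setNames(as.list(basename(mask_paths)), obs_ids),
        points = stats::setNames(as.list(basename(pt_paths)), obs_ids))
    }
  }
  man <- list(pixel_size_um = config$pixel_size_um, observers = obs_ids,
              images = images)
  write_manifest(man, file.path(dir, "manifest.yaml"))
  invisible(validate_manifest(man, dir))
}
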