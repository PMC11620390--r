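#' Load a dataset described by a manifest into memory
#'
#' @param manifest a \code{dataset_manifest} (or a path to one).
#' @param category_map optional \code{\link{category_map}} for multi-class
#'   mask images.
#' @return A named list of images, each a list with \code{stack} and
#'   \code{points}, plus attribute \code{pixel_size_um}.
#' @export
load_dataset <- function(manifest, category_map = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  obs <- as.character(manifest$observers)
  out <- lapply(names(manifest$images), function(id) {
    img <- manifest$images[[id]]
    list(stack = read_mask_stack(unlist(img$masks[obs]),
                                 category_map = category_map,
                                 observer_ids = obs, image_id = id),
         points = read_point_sets(unlist(img$points[obs]),
                                  observer_ids = obs, image_id = id))
  })
  names(out) <- names(manifest$images)
  attr(out, "pixel_size_um") <- manifest$pixel_size_um
  out
}

#' Run the full agreement framework over a dataset
#'
#' The end-to-end workflow: for each image, pixel-wise Fleiss' kappa and
#' BWFK over the observers' stromal masks (M_S), the DBCAA score over their
#' lymphocyte points (M_L), and each observer's TILs score; at dataset
#' level, the ICC of the TILs score matrix (M_T), Bland-Altman limits of
#' agreement with the mean, and — when enough images are available — the
#' cross-measure correlation test over random image subgroups.
#'
#' @param dataset a \code{dataset_manifest}, a manifest path, or an
#'   in-memory list as returned by \code{\link{load_dataset}} (each element
#'   holding \code{stack} and \code{points}).
#' @param pixel_size_um micrometers per pixel; taken from the manifest when
#'   available.
#' @param DT BWFK flattening threshold, pixels.
#' @param lymph_diameter_um expected lymphocyte diameter (default 8 um);
#'   converted to the DBCAA match radius via \code{pixel_size_um}.
#' @param normalization DBCAA normalization.
#' @param subgroup_size,repeats,seed correlation-test parameters; the test
#'   is skipped (with NULL result) when the dataset has fewer images than
#'   \code{subgroup_size}.
#' @return An \code{agreement_report}: \code{per_image} data frame (FK,
#'   BWFK, DBCAA per image), \code{tils} (images x observers matrix),
#'   \code{icc}, \code{loam} limits, \code{correlation} matrix, and the
#'   resolved \code{config}.
#' @export
run_framework <- function(dataset, pixel_size_um = NULL, DT = 100,
                          lymph_diameter_um = 8,
                          normalization = "max_match",
                          subgroup_size = 10, repeats = 50, seed = 1) {
  if (is.character(dataset) || inherits(dataset, "dataset_manifest"))
    dataset <- load_dataset(dataset)
  if (is.null(pixel_size_um)) pixel_size_um <- attr(dataset, "pixel_size_um")
  if (is.null(pixel_size_um))
    stop("pixel_size_um must be given (not present in the dataset)")
  n_img <- length(dataset)
  if (n_img == 0L) stop("empty dataset")
  D_L <- dl_pixels(lymph_diameter_um, pixel_size_um)
  obs_ids <- dataset[[1]]$stack$observer_ids
  per_image <- data.frame(image_id = names(dataset) %||%
                            sprintf("img%03d", seq_len(n_img)),
                          fk = NA_real_, bwfk = NA_real_, dbcaa = NA_real_)
  tils <- matrix(NA_real_, n_img, length(obs_ids),
                 dimnames = list(per_image$image_id, obs_ids))
  for (i in seq_len(n_img)) {
    img <- dataset[[i]]
    per_image$fk[i] <- fleiss_kappa(img$stack)$kappa
    per_image$bwfk[i] <- bwfk(img$stack, DT = DT)$kappa
    per_image$dbcaa[i] <- dbcaa(img$points, D_L = D_L,
                                normalization = normalization)$score
    tils[i, ] <- tils_per_observer(img$stack, img$points,
                                   pixel_size_um = pixel_size_um)
  }
  icc_res <- if (n_img >= 2L) icc(tils) else NULL
  loam_res <- bland_altman_loam(tils)
  corr <- NULL
  if (n_img >= subgroup_size && repeats > 0) {
    corr <- correlation_test(per_image$bwfk, per_image$dbcaa, tils,
                             subgroup_size = subgroup_size,
                             repeats = repeats, seed = seed)
  }
  structure(list(
    per_image = cbind(per_image, as.data.frame(tils_cols(tils))),
    tils = tils,
    icc = if (!is.null(icc_res)) icc_res$icc else NA_real_,
    icc_degenerate = if (!is.null(icc_res)) icc_res$degenerate else NA,
    loam = list(mean_diff = loam_res$mean_diff, lower = loam_res$lower,
                upper = loam_res$upper, outliers = loam_res$outliers),
    correlation = if (!is.null(corr)) corr$r else NULL,
    config = list(pixel_size_um = pixel_size_um, DT = DT,
                  lymph_diameter_um = lymph_diameter_um, D_L_px = D_L,
                  normalization = normalization,
                  subgroup_size = subgroup_size, repeats = repeats,
                  seed = seed, observers = obs_ids)),
    class = "agreement_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tils_cols <- function(tils) {
  out <- as.data.frame(tils)
  names(out) <- paste0("tils_", colnames(tils))
  rownames(out) <- NULL
  out
}

#' Compare human observers against externally supplied observers
#'
#' Treats externally produced annotations (e.g. an AI model's stromal mask
#' and cell detections) as additional observers and recomputes the three
#' agreement measures over the union, so model-vs-pathologist concordance is
#' measured with the same instruments as inter-pathologist concordance.
#'
#' @param dataset in-memory dataset list (see \code{\link{load_dataset}}).
#' @param extra named list: one element per extra observer, each a list with
#'   \code{masks} (per-image list of H x W 0/1 matrices, in dataset order)
#'   and \code{points} (per-image list of coordinate matrices).
#' @param provenance character vector labelling each extra observer
#'   (default \code{"model"}).
#' @param ... passed to \code{\link{run_framework}}.
#' @return An \code{agreement_report}; \code{config$provenance} labels every
#'   observer as \code{"human"} or its supplied provenance.
#' @export
compare_observer_sets <- function(dataset, extra, provenance = NULL, ...) {
  stopifnot(length(extra) >= 1L)
  if (is.null(provenance)) provenance <- rep("model", length(extra))
  extra_ids <- names(extra) %||% paste0("ext", seq_along(extra))
  merged <- lapply(seq_along(dataset), function(i) {
    img <- dataset[[i]]
    d <- dim(img$stack$masks[[1]])
    masks <- img$stack$masks
    pts <- img$points$points
    for (e in seq_along(extra)) {
      m <- extra[[e]]$masks[[i]]
      if (!identical(dim(m), d))
        stop("extra observer ", extra_ids[e], " mask frame mismatch on image ",
             img$stack$image_id)
      masks <- c(masks, list(m))
      p <- extra[[e]]$points[[i]]
      if (is.null(p) || length(p) == 0L) {
        warning("extra observer ", extra_ids[e],
                " has no points on image ", img$stack$image_id)
        p <- matrix(numeric(0), 0, 2)
      }
      pts <- c(pts, list(p))
    }
    ids <- c(img$stack$observer_ids, extra_ids)
    list(stack = mask_stack(masks, observer_ids = ids,
                            image_id = img$stack$image_id),
         points = suppressWarnings(point_sets(pts, observer_ids = ids,
                                              image_id = img$points$image_id)))
  })
  names(merged) <- names(dataset)
  attr(merged, "pixel_size_um") <- attr(dataset, "pixel_size_um")
  rep_out <- run_framework(merged, ...)
  rep_out$config$provenance <- c(
    stats::setNames(rep("human", length(dataset[[1]]$stack$observer_ids)),
                    dataset[[1]]$stack$observer_ids),
    stats::setNames(provenance, extra_ids))
  rep_out
}
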