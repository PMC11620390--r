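#' Category map for multi-class annotation labels
#'
#' Describes how integer label codes in annotation images map onto the binary
#' stroma / non-stroma categories used by the agreement measures, and which
#' codes (typically "other" regions: necrosis, fat, debris) are excluded from
#' the pixel universe entirely.
#'
#' @param stroma integer codes to treat as stroma (default 1).
#' @param exclude integer codes to drop from the pixel universe (default none).
#'   Excluded pixels contribute neither agreement nor disagreement.
#' @param labels optional named integer vector documenting the full code table,
#'   e.g. \code{c(other = 0, stroma = 1, tumor = 2)}.
#' @return An object of class \code{category_map}.
#' @examples
#' cm <- category_map(stroma = 1, exclude = 0,
#'                    labels = c(other = 0, stroma = 1, tumor = 2))
#' @export
category_map <- function(stroma = 1L, exclude = integer(), labels = NULL) {
  stroma <- as.integer(stroma)
  exclude <- as.integer(exclude)
  if (length(stroma) < 1L) stop("at least one stroma code is required")
  if (any(stroma %in% exclude))
    stop("stroma codes must be distinct from excluded codes")
  structure(list(stroma = stroma, exclude = exclude, labels = labels),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat("Category map: stroma codes {", paste(x$stroma, collapse = ", "),
      "}, excluded codes {", paste(x$exclude, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

read_mask_file <- function(path) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '", ext, "' for ", path, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale channels
  img
}

#' Read a stack of per-observer stromal masks
#'
#' Reads one binary mask image per observer for a single tissue image,
#' binarizes them through a \code{\link{category_map}}, and checks that all
#' masks share dimensions. Accepts 8-bit grayscale images (any value > 0 is
#' foreground) or indexed-label images interpreted through the category map.
#'
#' @param paths character vector of mask file paths (PNG or TIFF), one per
#'   observer.
#' @param category_map a \code{\link{category_map}}; ignored for plain binary
#'   or grayscale masks unless the image carries more than two label codes.
#' @param observer_ids observer labels; defaults to file basenames.
#' @param image_id identifier of the underlying tissue image.
#' @return A \code{\link{mask_stack}}.
#' @export
read_mask_stack <- function(paths, category_map = NULL, observer_ids = NULL,
                            image_id = "image") {
  if (length(paths) < 2L) stop("a mask stack needs at least 2 observers")
  if (is.null(observer_ids))
    observer_ids <- tools::file_path_sans_ext(basename(paths))
  raw <- lapply(paths, read_mask_file)
  dims <- vapply(raw, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mask dimension mismatch across observers: ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  masks <- vector("list", length(raw))
  exclusion <- NULL
  for (k in seq_along(raw)) {
    img <- raw[[k]]
    # readPNG/readTIFF scale 8-bit to [0,1]; recover integer label codes
    codes <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    ucodes <- sort(unique(as.vector(codes)))
    if (identical(ucodes, c(0L, 255L)) || identical(ucodes, 0L) ||
        identical(ucodes, 255L) || is.null(category_map)) {
      m <- matrix(as.integer(codes > 0L), nrow(codes), ncol(codes))
    } else {
      known <- c(category_map$stroma, category_map$exclude,
                 if (!is.null(category_map$labels)) unname(category_map$labels))
      unknown <- setdiff(ucodes, known)
      if (length(unknown) && !is.null(category_map$labels))
        stop("unknown label codes in ", paths[k], ": ",
             paste(unknown, collapse = ", "))
      m <- matrix(as.integer(codes %in% category_map$stroma),
                  nrow(codes), ncol(codes))
      if (length(category_map$exclude)) {
        ex <- codes %in% category_map$exclude
        if (any(ex)) {
          if (is.null(exclusion))
            exclusion <- matrix(FALSE, nrow(codes), ncol(codes))
          exclusion <- exclusion | matrix(ex, nrow(codes), ncol(codes))
        }
      }
    }
    masks[[k]] <- m
  }
  mask_stack(masks, observer_ids = observer_ids, image_id = image_id,
             exclusion = exclusion)
}

#' Construct a mask stack from in-memory matrices
#'
#' The container for aligned per-observer binary stromal masks of one image:
#' value 1 marks stroma, 0 marks non-stroma. All masks must share dimensions
#' and hold only 0/1 values.
#'
#' @param masks list of H x W integer matrices in {0, 1} (rows = y, cols = x).
#' @param observer_ids observer labels (default \code{obs1..obsN}).
#' @param image_id image identifier.
#' @param exclusion optional H x W logical matrix; \code{TRUE} pixels are
#'   removed from the agreement universe (e.g. regions marked "other").
#' @return An object of class \code{mask_stack} with fields \code{masks},
#'   \code{observer_ids}, \code{image_id}, \code{exclusion}.
#' @export
mask_stack <- function(masks, observer_ids = NULL, image_id = "image",
                       exclusion = NULL) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("'masks' must be a list of at least 2 matrices")
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!is.matrix(m) || !identical(dim(m), d))
      stop("all masks must be matrices of identical dimensions")
    if (!all(m %in% c(0L, 1L)))
      stop("mask values must be exactly 0 or 1")
  }
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "integer"; m
  })
  if (is.null(observer_ids)) observer_ids <- paste0("obs", seq_along(masks))
  if (length(observer_ids) != length(masks))
    stop("observer_ids length must match number of masks")
  if (!is.null(exclusion) && !identical(dim(exclusion), d))
    stop("exclusion mask dimensions must match the masks")
  structure(list(masks = masks, observer_ids = as.character(observer_ids),
                 image_id = image_id, exclusion = exclusion),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat("Mask stack '", x$image_id, "': ", length(x$masks), " observers, ",
      d[1], "x", d[2], " pixels", sep = "")
  if (!is.null(x$exclusion))
    cat(", ", sum(x$exclusion), " excluded pixels", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.mask_stack <- function(x) dim(x$masks[[1]])

read_point_file <- function(path) {
  if (!file.exists(path)) stop("point file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    pts <- jsonlite::fromJSON(path)
    if (length(pts) == 0L) {
      warning("empty point file: ", path)
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
    }
    if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y")])
    pts <- matrix(as.numeric(pts), ncol = 2,
                  dimnames = list(NULL, c("x", "y")))
  } else {
    df <- utils::read.csv(path)
    if (nrow(df) == 0L) {
      warning("empty point file: ", path)
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
    }
    if (!all(c("x", "y") %in% names(df)))
      stop("point CSV must have columns 'x' and 'y': ", path)
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
                 !is.finite(suppressWarnings(as.numeric(df$y))))
    if (length(bad))
      stop("non-numeric coordinate in ", path, " at row ", bad[1])
    pts <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  }
  if (anyNA(pts) || any(!is.finite(pts)))
    stop("non-finite coordinate in ", path)
  pts
}

#' Read per-observer lymphocyte point annotations
#'
#' Each file holds one observer's cell-center coordinates: a CSV with header
#' \code{x,y}, or a JSON array of \code{[x, y]} pairs. Coordinates are 0-based
#' pixels, x = column, y = row. File order is preserved.
#'
#' @param paths one point file per observer.
#' @param observer_ids observer labels; defaults to file basenames.
#' @param image_id image identifier.
#' @param frame optional \code{c(W, H)} bounding frame for validation.
#' @return A \code{\link{point_sets}} object.
#' @export
read_point_sets <- function(paths, observer_ids = NULL, image_id = "image",
                            frame = NULL) {
  if (is.null(observer_ids))
    observer_ids <- tools::file_path_sans_ext(basename(paths))
  pts <- lapply(paths, read_point_file)
  point_sets(pts, observer_ids = observer_ids, image_id = image_id,
             frame = frame)
}

#' Construct per-observer point sets from in-memory coordinates
#'
#' @param points list of m_i x 2 matrices (or data frames) of \code{(x, y)}
#'   pixel coordinates, one element per observer. Empty observers are allowed.
#' @param observer_ids observer labels.
#' @param image_id image identifier.
#' @param frame optional \code{c(W, H)}; when given, all coordinates must lie
#'   in \code{[0, W) x [0, H)}.
#' @return An object of class \code{point_sets}; duplicate points within one
#'   observer are permitted but raise a warning.
#' @export
point_sets <- function(points, observer_ids = NULL, image_id = "image",
                       frame = NULL) {
  if (!is.list(points)) stop("'points' must be a list, one element per observer")
  points <- lapply(points, function(p) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
    if (length(p) == 0L)
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
    p <- matrix(as.numeric(p), ncol = 2)
    colnames(p) <- c("x", "y")
    if (any(!is.finite(p))) stop("point coordinates must be finite")
    p
  })
  if (is.null(observer_ids)) observer_ids <- paste0("obs", seq_along(points))
  if (length(observer_ids) != length(points))
    stop("observer_ids length must match number of point sets")
  if (!is.null(frame)) {
    for (k in seq_along(points)) {
      p <- points[[k]]
      if (nrow(p) && (any(p[, 1] < 0 | p[, 1] >= frame[1]) ||
                      any(p[, 2] < 0 | p[, 2] >= frame[2])))
        stop("points of observer ", observer_ids[k], " fall outside the ",
             frame[1], "x", frame[2], " frame")
    }
  }
  for (k in seq_along(points)) {
    p <- points[[k]]
    if (nrow(p) > 1L && anyDuplicated(p))
      warning("duplicate points within observer ", observer_ids[k])
  }
  structure(list(points = points, counts = vapply(points, nrow, integer(1)),
                 observer_ids = as.character(observer_ids),
                 image_id = image_id, frame = frame),
            class = "point_sets")
}

#' @export
print.point_sets <- function(x, ...) {
  cat("Point sets '", x$image_id, "': ", length(x$points),
      " observers, counts [", paste(x$counts, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Write point sets to CSV files
#'
#' @param points a \code{\link{point_sets}} object.
#' @param paths one CSV path per observer.
#' @return Invisibly, the paths written.
#' @export
write_point_sets <- function(points, paths) {
  stopifnot(inherits(points, "point_sets"),
            length(paths) == length(points$points))
  for (k in seq_along(paths)) {
    utils::write.csv(as.data.frame(points$points[[k]]), paths[k],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Write a binary mask as a PNG image
#'
#' @param mask H x W matrix in {0, 1}.
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.double(mask != 0L), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read or write a dataset manifest
#'
#' A manifest groups, per image, the mask path and point file of every
#' observer, together with the physical calibration. YAML and JSON are
#' supported; every image must list the same observer set and
#' \code{pixel_size_um} must be positive.
#'
#' @param path manifest file (.yaml/.yml or .json).
#' @return A list with fields \code{pixel_size_um}, \code{observers},
#'   \code{images} (named list of per-image \code{masks} and \code{points}
#'   path lists), of class \code{dataset_manifest}.
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  man <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_manifest(man, dirname(path))
}

validate_manifest <- function(man, base = ".") {
  if (is.null(man$pixel_size_um) || man$pixel_size_um <= 0)
    stop("manifest must state a positive pixel_size_um")
  obs <- as.character(man$observers)
  if (length(obs) < 2L) stop("manifest must list at least 2 observers")
  for (id in names(man$images)) {
    img <- man$images[[id]]
    for (fld in c("masks", "points")) {
      got <- names(img[[fld]])
      if (!setequal(got, obs))
        stop("image ", id, " does not list the same observer set for ", fld)
      img[[fld]] <- lapply(img[[fld]], function(p)
        if (file.exists(p)) p else file.path(base, p))
      man$images[[id]] <- img
    }
  }
  structure(man, class = "dataset_manifest")
}

#' @rdname read_manifest
#' @param manifest a \code{dataset_manifest} (or compatible list).
#' @export
write_manifest <- function(manifest, path) {
  man <- unclass(manifest)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(man, path)
  else jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}

#' Write an agreement report to JSON and CSV
#'
#' Serializes a report produced by \code{\link{run_framework}} (or assembled
#' by hand) to a machine-readable JSON file and, alongside it, a per-image
#' CSV table of the stromal (M_S), lymphocyte (M_L) agreement values. The JSON
#' round-trips losslessly through \code{\link{read_agreement_report}}.
#'
#' @param report an \code{agreement_report} (a list with a \code{per_image}
#'   data frame and optional dataset-level fields).
#' @param path output JSON path; the CSV is written next to it with extension
#'   \code{.csv}.
#' @return Invisibly, the JSON path.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", na = "null")
  csv <- sub("\\.json$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  per_image <- report$per_image
  if (is.null(per_image))
    per_image <- data.frame(image_id = character(0))
  utils::write.csv(per_image, csv, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agreement_report
#' @export
read_agreement_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(rep$per_image))
    rep$per_image <- as.data.frame(rep$per_image)
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  n <- if (is.null(x$per_image)) 0L else nrow(x$per_image)
  cat("Agreement report:", n, "images\n")
  if (n) print(utils::head(x$per_image, 10))
  invisible(x)
}
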