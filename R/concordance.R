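#' Intraclass correlation coefficient for a score matrix
#'
#' Reliability of continuous scores (e.g. per-image TILs scores) across
#' raters, from the two-way ANOVA mean-squares decomposition of a complete
#' subjects x raters matrix. The default variant is two-way random effects,
#' absolute agreement, single rater — ICC(2,1):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares. The consistency variant ICC(3,1) drops the rater
#' variance term.
#'
#' @param scores n x k numeric matrix, rows = subjects (images), columns =
#'   raters (observers); no missing cells.
#' @param model \code{"two_way_random_absolute_single"} (default) or
#'   \code{"two_way_mixed_consistency_single"}.
#' @return A list of class \code{icc_result}: \code{icc}, \code{model},
#'   mean squares \code{MSR}, \code{MSC}, \code{MSE}, \code{n}, \code{k},
#'   and \code{degenerate} (TRUE when all scores are identical, reported as
#'   ICC = 1).
#' @export
icc <- function(scores, model = c("two_way_random_absolute_single",
                                  "two_way_mixed_consistency_single")) {
  model <- match.arg(model)
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix must be complete (no missing cells)")
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("ICC needs at least 2 subjects and 2 raters")
  if (max(scores) - min(scores) == 0) {
    return(structure(list(icc = 1, model = model, MSR = 0, MSC = 0, MSE = 0,
                          n = n, k = k, degenerate = TRUE),
                     class = "icc_result"))
  }
  grand <- mean(scores)
  row_m <- rowMeans(scores)
  col_m <- colMeans(scores)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((scores - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- switch(model,
    two_way_random_absolute_single =
      (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)),
    two_way_mixed_consistency_single =
      (MSR - MSE) / (MSR + (k - 1) * MSE))
  structure(list(icc = val, model = model, MSR = MSR, MSC = MSC, MSE = MSE,
                 n = n, k = k, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f  (%s, n = %d subjects, k = %d raters%s)\n",
              x$icc, x$model, x$n, x$k,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Bland-Altman limits of agreement with the mean (LOAM)
#'
#' Multi-observer extension of the Bland-Altman plot: for each (subject,
#' observer) cell the difference from the subject's observer-mean is taken,
#' and the limits of agreement are set at the mean difference plus/minus 1.96
#' standard deviations of those differences — the range expected to contain
#' about 95% of observer-minus-mean differences under normality.
#'
#' @param scores n x k matrix, rows = subjects, columns = observers (k >= 2).
#' @return A list of class \code{loam_result}: \code{mean_diff},
#'   \code{sd_diff}, \code{upper}, \code{lower}, \code{data} (data frame with
#'   per-cell subject mean, difference, subject and observer indices), and
#'   \code{outliers} (count of differences outside the limits).
#' @export
bland_altman_loam <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (k < 2L) stop("LOAM needs at least 2 observers")
  subj_mean <- rowMeans(scores)
  diffs <- scores - subj_mean
  d <- as.vector(diffs)
  md <- mean(d)
  sdd <- stats::sd(d)
  upper <- md + 1.96 * sdd
  lower <- md - 1.96 * sdd
  dat <- data.frame(subject = rep(seq_len(n), times = k),
                    observer = rep(seq_len(k), each = n),
                    mean = rep(subj_mean, times = k),
                    difference = d)
  structure(list(mean_diff = md, sd_diff = sdd, upper = upper, lower = lower,
                 data = dat, outliers = sum(d > upper | d < lower)),
            class = "loam_result")
}

#' @export
print.loam_result <- function(x, ...) {
  cat(sprintf("LOAM: mean diff = %.4g, limits [%.4g, %.4g], %d outlier(s) of %d\n",
              x$mean_diff, x$lower, x$upper, x$outliers, nrow(x$data)))
  invisible(x)
}

#' @export
plot.loam_result <- function(x, ...) {
  plot(x$data$mean, x$data$difference, pch = 19, col = x$data$observer,
       xlab = "Subject mean score", ylab = "Difference from subject mean",
       main = "Bland-Altman (limits of agreement with the mean)", ...)
  graphics::abline(h = x$mean_diff, col = "darkgreen", lty = 3)
  graphics::abline(h = c(x$lower, x$upper), col = "red", lty = 3)
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Sample linear correlation between two equal-length vectors, with the
#' domain checks the agreement workflow needs (length >= 3, nonzero
#' variance).
#'
#' @param x,y numeric vectors of equal length.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("Pearson correlation needs at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Cross-measure correlation test over random image subgroups
#'
#' Examines how the three agreement measures co-vary across random subsets of
#' a dataset: for each repeat, \code{subgroup_size} images are sampled
#' without replacement; the subgroup's stromal agreement M_S and lymphocyte
#' agreement M_L are the means of the per-image BWFK and DBCAA values, and
#' its TILs-score agreement M_T is the ICC of the subgroup's images x
#' observers TILs matrix. Pearson correlations are then taken across repeats.
#'
#' @param ms per-image stromal agreement values (e.g. BWFK), length n_images.
#' @param ml per-image lymphocyte agreement values (e.g. DBCAA score).
#' @param tils n_images x n_observers TILs score matrix.
#' @param subgroup_size images per subgroup (default 10).
#' @param repeats number of random subgroups (default 50).
#' @param seed RNG seed; the test is a pure function of its inputs and seed.
#' @param icc_model passed to \code{\link{icc}}.
#' @return A list of class \code{correlation_test}: \code{triples} (repeats x
#'   3 data frame of M_S, M_L, M_T), \code{r} (3 x 3 Pearson matrix),
#'   \code{subgroup_size}, \code{repeats}, \code{seed}, \code{degenerate}
#'   (TRUE when any measure has zero variance across repeats; its
#'   correlations are reported as NA).
#' @export
correlation_test <- function(ms, ml, tils, subgroup_size = 10, repeats = 50,
                             seed = 1,
                             icc_model = "two_way_random_absolute_single") {
  tils <- as.matrix(tils)
  n <- length(ms)
  stopifnot(length(ml) == n, nrow(tils) == n)
  if (n < subgroup_size) stop("fewer images than the subgroup size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tri <- matrix(NA_real_, repeats, 3,
                dimnames = list(NULL, c("M_S", "M_L", "M_T")))
  for (r in seq_len(repeats)) {
    idx <- sample.int(n, subgroup_size)
    tri[r, 1] <- mean(ms[idx])
    tri[r, 2] <- mean(ml[idx])
    tri[r, 3] <- icc(tils[idx, , drop = FALSE], model = icc_model)$icc
  }
  sds <- apply(tri, 2, stats::sd)
  degenerate <- any(sds == 0)
  rmat <- matrix(NA_real_, 3, 3, dimnames = list(colnames(tri), colnames(tri)))
  diag(rmat) <- 1
  for (a in 1:2) for (b in (a + 1):3) {
    if (sds[a] > 0 && sds[b] > 0)
      rmat[a, b] <- rmat[b, a] <- pearson_r(tri[, a], tri[, b])
  }
  structure(list(triples = as.data.frame(tri), r = rmat,
                 subgroup_size = subgroup_size, repeats = repeats,
                 seed = seed, degenerate = degenerate),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Correlation test: %d repeats of %d images%s\n", x$repeats,
              x$subgroup_size, if (x$degenerate) " (degenerate)" else ""))
  print(round(x$r, 3))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
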