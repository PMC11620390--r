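# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops over rater pairs, all-pairs distance
# scans) so they share no code path with the package implementations.

# Fleiss' kappa recomputed from a raw rating matrix (raters x subjects of
# 0/1 votes) by counting agreeing rater pairs per subject.
oracle_fleiss <- function(ratings) {
  N <- nrow(ratings); M <- ncol(ratings)
  pairs <- utils::combn(N, 2)
  P_i <- vapply(seq_len(M), function(i) {
    agree <- 0L
    for (p in seq_len(ncol(pairs)))
      agree <- agree + as.integer(ratings[pairs[1, p], i] == ratings[pairs[2, p], i])
    agree / ncol(pairs)
  }, numeric(1))
  P_bar <- mean(P_i)
  p_j <- vapply(0:1, function(cat) mean(ratings == cat), numeric(1))
  P_e <- sum(p_j^2)
  if (P_e >= 1) return(1)
  (P_bar - P_e) / (1 - P_e)
}

# DBCAA by literal all-pairs scan, no vectorized shortcut.
oracle_dbcaa <- function(pts_list, D_L, Z_mode = "max_match") {
  N <- length(pts_list)
  total <- sum(vapply(pts_list, nrow, integer(1)))
  a_sum <- 0L
  for (i in seq_len(N)) {
    ci <- pts_list[[i]]
    if (!nrow(ci)) next
    for (k in seq_len(nrow(ci))) {
      for (j in seq_len(N)[-i]) {
        cj <- pts_list[[j]]
        if (!nrow(cj)) next
        dmin <- Inf
        for (l in seq_len(nrow(cj))) {
          d <- sqrt(sum((ci[k, ] - cj[l, ])^2))
          if (d < dmin) dmin <- d
        }
        if (dmin < D_L) a_sum <- a_sum + 1L
      }
    }
  }
  Z <- if (Z_mode == "max_match") (N - 1) * total else N * total
  a_sum / Z
}

# ICC(2,1) from stats::aov mean squares (independent ANOVA route).
oracle_icc21 <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  df <- data.frame(y = as.vector(scores),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Per-pixel distance to the nearest boundary pixel by exhaustive search.
oracle_boundary_dist <- function(boundary) {
  bidx <- which(boundary, arr.ind = TRUE)
  out <- matrix(Inf, nrow(boundary), ncol(boundary))
  for (r in seq_len(nrow(boundary))) {
    for (c in seq_len(ncol(boundary))) {
      out[r, c] <- sqrt(min((bidx[, 1] - r)^2 + (bidx[, 2] - c)^2))
    }
  }
  out
}

# Random N-observer mask stack containing both categories.
random_stack <- function(N = 4, h = 20, w = 25, p = 0.5) {
  repeat {
    masks <- lapply(seq_len(N), function(i)
      matrix(rbinom(h * w, 1L, p), h, w))
    votes <- Reduce(`+`, masks)
    if (any(votes > 0) && any(votes < N)) break
  }
  mask_stack(masks)
}

# Perfect-agreement, well-separated point grid shared by N observers.
grid_points <- function(N = 4, nx = 10, ny = 10, spacing = 100) {
  g <- as.matrix(expand.grid(x = seq(0, by = spacing, length.out = nx),
                             y = seq(0, by = spacing, length.out = ny)))
  point_sets(rep(list(g), N))
}

# A blob mask: union of a few discs, guaranteed non-degenerate.
blob_mask <- function(h, w, centers, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    m[(rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radius^2] <- 1L
  }
  m
}
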