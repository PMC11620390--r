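test_that("count tables tally stroma votes per pixel and honor exclusions", {
  m1 <- matrix(c(1L, 0L, 1L), 1, 3)
  m2 <- matrix(c(1L, 0L, 0L), 1, 3)
  tab <- build_count_table(mask_stack(list(m1, m2)))
  expect_identical(tab$n1, c(2L, 0L, 1L))
  expect_identical(tab$n0 + tab$n1, rep(2L, 3))
  expect_identical(tab$M, 3L)
  # exclusion shrinks the universe
  ex <- matrix(c(FALSE, TRUE, FALSE), 1, 3)
  tab2 <- build_count_table(mask_stack(list(m1, m2)), exclusion = ex)
  expect_identical(tab2$M, 2L)
  expect_error(build_count_table(mask_stack(list(m1, m2)),
                                 exclusion = matrix(TRUE, 1, 3)),
               "excluded")
})

test_that("fleiss_kappa reproduces hand-worked values and degenerate conventions", {
  # 3-pixel toy: rows (2,0),(0,2),(1,1), N = 2 -> P = 2/3, Pe = 1/2, k = 1/3
  st <- mask_stack(list(matrix(c(1L, 0L, 1L), 1, 3),
                        matrix(c(1L, 0L, 0L), 1, 3)))
  res <- fleiss_kappa(st)
  expect_equal(res$p_observed, 2 / 3, tolerance = 1e-15)
  expect_equal(res$p_expected, 1 / 2, tolerance = 1e-15)
  expect_equal(res$kappa, 1 / 3, tolerance = 1e-15)
  # identical non-degenerate masks: kappa = 1
  m <- matrix(rbinom(100, 1L, 0.5), 10, 10)
  expect_equal(fleiss_kappa(mask_stack(list(m, m, m)))$kappa, 1)
  # complete disagreement N = 2: P = 0, kappa = -Pe/(1-Pe)
  st2 <- mask_stack(list(matrix(c(1L, 0L), 1, 2), matrix(c(0L, 1L), 1, 2)))
  res2 <- fleiss_kappa(st2)
  expect_equal(res2$p_observed, 0)
  expect_equal(res2$kappa, -res2$p_expected / (1 - res2$p_expected))
  # single category everywhere: degenerate, reported as 1
  ones <- matrix(1L, 5, 5)
  res3 <- fleiss_kappa(mask_stack(list(ones, ones)))
  expect_true(res3$degenerate)
  expect_equal(res3$kappa, 1)
})

test_that("fleiss_kappa matches the brute-force pairwise oracle on random stacks", {
  set.seed(42)
  for (rep in 1:100) {
    N <- sample(2:5, 1)
    h <- sample(5:40, 1); w <- sample(5:40, 1)
    st <- random_stack(N, h, w, p = runif(1, 0.2, 0.8))
    ratings <- t(vapply(st$masks, as.vector, integer(h * w)))
    expect_equal(fleiss_kappa(st)$kappa, oracle_fleiss(ratings),
                 tolerance = 1e-12)
  }
})

test_that("kappa is invariant to observer order and category relabeling", {
  set.seed(7)
  st <- random_stack(4, 30, 30)
  k0 <- fleiss_kappa(st)$kappa
  bw0 <- bwfk(st, DT = 10)$kappa
  perm <- mask_stack(st$masks[c(3, 1, 4, 2)])
  expect_equal(fleiss_kappa(perm)$kappa, k0, tolerance = 1e-12)
  expect_equal(bwfk(perm, DT = 10)$kappa, bw0, tolerance = 1e-12)
  flipped <- mask_stack(lapply(st$masks, function(m) 1L - m))
  expect_equal(fleiss_kappa(flipped)$kappa, k0, tolerance = 1e-12)
})

test_that("kappa decreases monotonically with salt-and-pepper noise on one observer", {
  set.seed(13)
  base <- blob_mask(64, 64, rbind(c(20, 20), c(45, 40)), 14)
  rates <- c(0.02, 0.1, 0.3)
  k <- vapply(rates, function(r) {
    set.seed(101)
    noisy <- base
    flip <- which(runif(length(base)) < r)
    noisy[flip] <- 1L - noisy[flip]
    fleiss_kappa(mask_stack(list(base, base, base, noisy)))$kappa
  }, numeric(1))
  expect_true(all(diff(k) < 0))
  expect_true(all(k < 1))
})

test_that("boundary extraction marks stroma pixels adjacent to non-stroma, not the frame", {
  m <- matrix(0L, 6, 6); m[3:4, 3:4] <- 1L
  b <- mask_boundary(m)
  expect_true(all(b[3:4, 3:4]))       # 2x2 blob: every pixel is boundary
  expect_false(any(b[m == 0L]))       # boundary only on stroma pixels
  ones <- matrix(1L, 5, 5)
  expect_false(any(mask_boundary(ones)))  # frame edge creates no boundary
})

test_that("boundary weight maps match geometry and a brute-force distance oracle", {
  # single straight vertical boundary shared by all observers
  m <- matrix(0L, 16, 32); m[, 17:32] <- 1L
  st <- mask_stack(list(m, m, m))
  wm <- boundary_weights(st, DT = 8)
  # stroma side: distance to boundary column (17), clipped at DT
  expect_equal(wm$raw[1, 17], 0)
  expect_equal(wm$raw[5, 20], 3)
  expect_equal(wm$raw[5, 30], 8)  # clipped (raw would be 13)
  expect_equal(wm$raw[5, 10], 7)  # non-stroma side counts too
  # normalization: weights sum to M
  expect_equal(sum(wm$w), length(wm$w), tolerance = 1e-9 * length(wm$w))
  # brute-force oracle on a 64x64 instance with two offset boundaries
  m1 <- matrix(0L, 64, 64); m1[, 25:64] <- 1L
  m2 <- matrix(0L, 64, 64); m2[, 35:64] <- 1L
  st2 <- mask_stack(list(m1, m2))
  wm2 <- boundary_weights(st2, DT = 1e9)  # no clipping
  d1 <- oracle_boundary_dist(mask_boundary(m1))
  d2 <- oracle_boundary_dist(mask_boundary(m2))
  expect_equal(wm2$raw, (d1 + d2) / 2, tolerance = 1e-12)
})

test_that("constant masks get the flat DT distance with a warning", {
  ones <- matrix(1L, 10, 10)
  m <- matrix(0L, 10, 10); m[4:7, 4:7] <- 1L
  expect_warning(wm <- boundary_weights(mask_stack(list(ones, m)), DT = 5),
                 "no boundary|without boundary")
  expect_true(all(wm$raw <= 5))
})

test_that("BWFK with uniform weights equals FK exactly, and matches on random stacks", {
  set.seed(101)
  for (rep in 1:50) {
    st <- random_stack(sample(2:4, 1), sample(8:24, 1), sample(8:24, 1))
    tab <- build_count_table(st)
    uni <- structure(list(raw = matrix(1, dim(st)[1], dim(st)[2]),
                          w = rep(1, tab$M), keep = tab$keep, DT = 100),
                     class = "weight_map")
    expect_equal(bwfk(st, weights = uni)$kappa, fleiss_kappa(st)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("BWFK exceeds FK when disagreement is confined to a narrow boundary band", {
  # shared boundary; observers disagree only within 5 px of it
  m_base <- matrix(0L, 96, 96); m_base[, 49:96] <- 1L
  set.seed(3)
  masks <- lapply(1:4, function(i) {
    m <- m_base
    off <- sample(-2:2, 96, replace = TRUE)  # jitter boundary column by <= 2
    for (r in 1:96) {
      cut <- 49 + off[r]
      m[r, ] <- 0L; m[r, cut:96] <- 1L
    }
    m
  })
  st <- mask_stack(masks)
  k_fk <- fleiss_kappa(st)$kappa
  k_bw <- bwfk(st, DT = 100)$kappa
  expect_lt(k_fk, 1)
  expect_gt(k_bw, k_fk)  # strict improvement
})

test_that("agreement maps count votes and their pixel-wise maximum", {
  m <- matrix(rbinom(64, 1L, 0.5), 8, 8)
  st <- mask_stack(list(m, m, m, m))
  am <- agreement_maps(st)
  expect_true(all(am$max == 4L))
  expect_true(all(am$stroma + am$nonstroma == 4L))
  # checkerboard disagreement, N = 2: max map constant 1
  a <- matrix(rep(c(0L, 1L), 18), 6, 6)
  st2 <- mask_stack(list(a, 1L - a))
  expect_true(all(agreement_maps(st2)$max == 1L))
  # a split vote shows up as max = N/2
  b <- matrix(0L, 2, 2); c2 <- matrix(0L, 2, 2); c2[1, 1] <- 1L
  am3 <- agreement_maps(mask_stack(list(b, c2, b, c2)))
  expect_identical(am3$max[1, 1], 2L)
})

test_that("rendered agreement maps are valid PNGs with the fixed palette", {
  tmp <- withr::local_tempdir()
  st <- mask_stack(list(matrix(1L, 4, 4), matrix(0L, 4, 4)))
  p <- render_agreement_map(agreement_maps(st), "max", file.path(tmp, "m.png"))
  img <- png::readPNG(p)
  expect_identical(dim(img), c(4L, 4L, 3L))
})
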