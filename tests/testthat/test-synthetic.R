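test_that("generate_truth hits the target stroma fraction and spacing constraint", {
  cfg <- synth_config(H = 256, W = 256, stroma_fraction = 0.5)
  tr <- generate_truth(cfg, seed = 2)
  frac <- mean(tr$mask)
  expect_gte(frac, 0.48); expect_lte(frac, 0.52)
  # hard-core spacing: pairwise distances >= one lymphocyte diameter
  if (nrow(tr$points) > 1) {
    d <- as.matrix(dist(tr$points))
    diag(d) <- Inf
    expect_gte(min(d), cfg$min_spacing_um / cfg$pixel_size_um - 1e-9)
  }
  # all points lie in stroma
  idx <- cbind(round(tr$points[, 2]) + 1, round(tr$points[, 1]) + 1)
  expect_true(all(tr$mask[idx] == 1L))
  # boundary cases
  expect_true(all(generate_truth(synth_config(H = 64, W = 64,
    stroma_fraction = 1), seed = 1)$mask == 1L))
  expect_identical(nrow(generate_truth(synth_config(H = 64, W = 64,
    density = 0), seed = 1)$points), 0L)
  expect_error(generate_truth(synth_config(H = 64, W = 64, density = 3e5),
                              seed = 1), "infeasible")
})

test_that("noise-free observers reproduce the truth and the perfect-agreement chain", {
  cfg <- synth_config(H = 128, W = 128, boundary_amplitude = 0,
                      jitter_sd = 0, miss_rate = 0, fp_rate = 0)
  tr <- generate_truth(cfg, seed = 3)
  obs <- generate_observers(tr, seed = 4)
  for (m in obs$stack$masks) expect_identical(m, tr$mask)
  expect_equal(fleiss_kappa(obs$stack)$kappa, 1)
  expect_equal(bwfk(obs$stack, DT = 50)$kappa, 1)
  expect_equal(dbcaa(obs$points, D_L = 20)$score, 1)
})

test_that("boundary perturbation localizes disagreement near the true boundary", {
  cfg <- synth_config(H = 256, W = 256, boundary_amplitude = 5)
  tr <- generate_truth(cfg, seed = 5)
  obs <- generate_observers(tr, seed = 6)
  votes <- Reduce(`+`, obs$stack$masks)
  disagree <- votes > 0 & votes < length(obs$stack$masks)
  b <- mask_boundary(tr$mask)
  dist_to_b <- matrix(as.double(EBImage::distmap(
    matrix(as.double(!b), 256, 256))), 256, 256)
  frac_near <- mean(dist_to_b[disagree] <= cfg$boundary_amplitude + 2)
  expect_gte(frac_near, 0.9)
  # disagreement exists and BWFK > FK in this regime
  expect_gt(sum(disagree), 0)
  expect_gt(bwfk(obs$stack, DT = 100)$kappa, fleiss_kappa(obs$stack)$kappa)
})

test_that("miss rate thins points binomially and BWFK-FK gain grows with amplitude", {
  cfg <- synth_config(H = 256, W = 256, miss_rate = 0.5, jitter_sd = 0,
                      fp_rate = 0, density = 20000, min_spacing_um = 2)
  tr <- generate_truth(cfg, seed = 7)
  obs <- generate_observers(tr, seed = 8)
  m0 <- nrow(tr$points)
  expect_gt(m0, 50)
  for (cnt in obs$points$counts) {
    expect_gt(cnt, qbinom(1e-5, m0, 0.5))
    expect_lt(cnt, qbinom(1 - 1e-5, m0, 0.5))
  }
  # monotone agreement degradation across miss rates
  scores <- vapply(c(0, 0.2, 0.4), function(mr) {
    cfg_i <- synth_config(H = 128, W = 128, miss_rate = mr, jitter_sd = 0,
                          fp_rate = 0, density = 20000, min_spacing_um = 2)
    tr_i <- generate_truth(cfg_i, seed = 9)
    dbcaa(generate_observers(tr_i, seed = 10)$points, D_L = 10)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  # gain increases with boundary amplitude (3-level grid, fixed seeds)
  gains <- vapply(c(1, 4, 10), function(a) {
    cfg_a <- synth_config(H = 256, W = 256, boundary_amplitude = a)
    tr_a <- generate_truth(cfg_a, seed = 11)
    st <- generate_observers(tr_a, seed = 12)$stack
    bwfk(st, DT = 100)$kappa - fleiss_kappa(st)$kappa
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("generate_dataset writes a loadable, seed-reproducible dataset", {
  tmp <- withr::local_tempdir()
  cfg <- synth_config(H = 96, W = 96, n_observers = 4, density = 8000,
                      min_spacing_um = 4)
  man <- generate_dataset(cfg, n_images = 3, dir = file.path(tmp, "d1"),
                          seed = 21)
  expect_length(man$images, 3)
  expect_length(list.files(file.path(tmp, "d1"), pattern = "mask\\.png$"), 12)
  expect_length(list.files(file.path(tmp, "d1"), pattern = "points\\.csv$"), 12)
  ds <- load_dataset(file.path(tmp, "d1", "manifest.yaml"))
  expect_length(ds, 3)
  expect_identical(dim(ds[[1]]$stack), c(96L, 96L))
  # byte-identical regeneration from the same seed
  generate_dataset(cfg, n_images = 3, dir = file.path(tmp, "d2"), seed = 21)
  f1 <- list.files(file.path(tmp, "d1"), pattern = "csv$", full.names = TRUE)
  f2 <- list.files(file.path(tmp, "d2"), pattern = "csv$", full.names = TRUE)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # empty dataset
  man0 <- generate_dataset(cfg, n_images = 0, dir = file.path(tmp, "d0"),
                           seed = 1)
  expect_length(man0$images, 0)
})
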