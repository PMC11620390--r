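test_that("nearest_point_distance is an exact Euclidean minimum", {
  expect_equal(nearest_point_distance(c(0, 0), rbind(c(3, 4))), 5)
  expect_equal(nearest_point_distance(c(1, 2), rbind(c(9, 9), c(1, 2))), 0)
  expect_equal(nearest_point_distance(c(0, 0),
                                      rbind(c(3, 4), c(1, 0), c(10, 10))), 1)
  expect_identical(nearest_point_distance(c(0, 0),
                                          matrix(numeric(0), 0, 2)), Inf)
})

test_that("dbcaa reproduces the worked two-observer example under both normalizations", {
  ps <- point_sets(list(rbind(c(0, 0), c(100, 100)),
                        rbind(c(3, 4), c(200, 200))))
  res <- dbcaa(ps, D_L = 10)
  expect_identical(unlist(res$counters), c(1L, 0L, 1L, 0L))
  expect_equal(res$score, 0.5)
  expect_equal(dbcaa(ps, D_L = 10, normalization = "paper")$score, 0.25)
})

test_that("perfect agreement scores 1 under max_match and (N-1)/N under the literal formula", {
  ps <- grid_points(N = 4, nx = 5, ny = 5, spacing = 50)
  expect_equal(dbcaa(ps, D_L = 10)$score, 1)
  expect_equal(dbcaa(ps, D_L = 10, normalization = "paper")$score, 3 / 4)
  # no inter-observer distance below D_L -> score 0
  far <- point_sets(list(rbind(c(0, 0)), rbind(c(100, 0)), rbind(c(0, 100))))
  expect_equal(dbcaa(far, D_L = 10)$score, 0)
})

test_that("dbcaa equals the literal all-pairs brute force on random instances", {
  set.seed(21)
  for (rep in 1:8) {
    N <- sample(2:5, 1)
    pts <- lapply(seq_len(N), function(i) {
      m <- sample(5:60, 1)
      cbind(runif(m, 0, 300), runif(m, 0, 300))
    })
    ps <- point_sets(pts)
    D_L <- runif(1, 5, 40)
    expect_identical(dbcaa(ps, D_L = D_L)$score,
                     oracle_dbcaa(pts, D_L, "max_match"))
    expect_identical(dbcaa(ps, D_L = D_L, normalization = "paper")$score,
                     oracle_dbcaa(pts, D_L, "paper"))
  }
})

test_that("dbcaa is invariant to observer order and rigid motion of all sets", {
  set.seed(5)
  pts <- lapply(1:4, function(i) cbind(runif(30, 0, 200), runif(30, 0, 200)))
  ps <- point_sets(pts)
  s0 <- dbcaa(ps, D_L = 15)$score
  expect_equal(dbcaa(point_sets(pts[c(4, 2, 1, 3)]), D_L = 15)$score, s0)
  theta <- 0.7; R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- lapply(pts, function(p) sweep(p %*% R, 2, c(-50, 31.5), `+`))
  expect_equal(dbcaa(point_sets(moved), D_L = 15)$score, s0, tolerance = 1e-12)
})

test_that("dbcaa is monotone non-decreasing in D_L", {
  set.seed(9)
  pts <- lapply(1:3, function(i) cbind(runif(40, 0, 150), runif(40, 0, 150)))
  ps <- point_sets(pts)
  scores <- vapply(c(2, 5, 10, 20, 40, 80), function(d)
    dbcaa(ps, D_L = d)$score, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("strict and non-strict threshold differ exactly at ties", {
  ps <- point_sets(list(rbind(c(0, 0)), rbind(c(10, 0))))
  expect_equal(dbcaa(ps, D_L = 10, strict = TRUE)$score, 0)
  expect_equal(dbcaa(ps, D_L = 10, strict = FALSE)$score, 1)
})

test_that("empty observers warn and never match; all-empty is fatal", {
  ps <- suppressWarnings(point_sets(list(rbind(c(0, 0), c(5, 5)),
                                         matrix(numeric(0), 0, 2))))
  expect_warning(res <- dbcaa(ps, D_L = 10), "no points")
  expect_equal(res$score, 0)
  empty <- point_sets(list(matrix(numeric(0), 0, 2),
                           matrix(numeric(0), 0, 2)))
  expect_error(suppressWarnings(dbcaa(empty, D_L = 10)), "no points")
})

test_that("counters stay within 0..N-1 and the plot method runs", {
  set.seed(2)
  pts <- lapply(1:4, function(i) cbind(runif(15, 0, 50), runif(15, 0, 50)))
  ps <- point_sets(pts)
  res <- dbcaa(ps, D_L = 12)
  expect_true(all(unlist(res$counters) >= 0L & unlist(res$counters) <= 3L))
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(res, ps); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("micrometer diameters convert to pixel match radii", {
  expect_equal(dl_pixels(8, 0.23), 8 / 0.23)
  expect_equal(dl_pixels(8, 0.5), 16)
  expect_error(dl_pixels(8, 0), "pixel_size_um > 0")
})
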