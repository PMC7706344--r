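# Point-cloud I/O, segmentation, ground elevation, crop height.

test_that("XYZ CSV round-trips preserve coordinates and order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "0.1,0.2,0.3", "1.5,0.0,0.9", "2.0,3.0,0.0"), path)
  cl <- read_cloud(path)
  expect_equal(cl$x, c(0.1, 1.5, 2.0))
  expect_equal(cl$z, c(0.3, 0.9, 0.0))

  cl2 <- withr::with_seed(1, random_cloud(100, plot_rect(0, 1.08, 0, 1)))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cloud(cl2, p2)
  back <- read_cloud(p2)
  expect_equal(back$x, cl2$x, tolerance = 1e-6)
  expect_equal(back$y, cl2$y, tolerance = 1e-6)
  expect_equal(back$z, cl2$z, tolerance = 1e-6)
})

test_that("malformed CSV rows are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "0.1,0.2,0.3", "0.4,0.5,oops"), path)
  expect_error(read_cloud(path), "line 3", class = "phenolidar_parse_error")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), p2)
  expect_error(read_cloud(p2), class = "phenolidar_parse_error")
})

test_that("LAS 1.2 round-trips at millimetre precision", {
  cl <- withr::with_seed(2, random_cloud(200, plot_rect(10, 11.08, 5, 6)))
  path <- withr::local_tempfile(fileext = ".las")
  write_cloud(cl, path, format = "las")
  back <- read_cloud(path, format = "las")
  expect_equal(nrow(back), 200)
  expect_equal(back$x, cl$x, tolerance = 1e-3)
  expect_equal(back$z, cl$z, tolerance = 1e-3)
  # not a LAS file
  p2 <- withr::local_tempfile(fileext = ".las")
  writeLines("x,y,z", p2)
  expect_error(read_cloud(p2, format = "las"),
               class = "phenolidar_format_error")
})

test_that("segmentation is half-open and matches a brute-force filter", {
  rect <- plot_rect(0, 1, 0, 1)
  edge <- point_cloud(c(0, 1, 0.5, 0.999), c(0.5, 0.5, 1, 0.999),
                      c(0.1, 0.1, 0.1, 0.1))
  kept <- segment_plot(edge, rect)
  expect_equal(nrow(kept), 2)     # x = 1 and y = 1 fall outside
  expect_equal(kept$x, c(0, 0.999))

  cl <- withr::with_seed(3, random_cloud(100, plot_rect(0, 2, 0, 1)))
  left <- plot_rect(0, 1, 0, 1)
  expect_equal(as.data.frame(segment_plot(cl, left)),
               as.data.frame(cl[brute_segment(cl, left), ]),
               ignore_attr = TRUE)
  # rect covering everything is the identity
  all_rect <- plot_rect(-1, 3, -1, 2)
  expect_equal(segment_plot(cl, all_rect)$z, cl$z)
})

test_that("a disjoint tiling of rectangles partitions the points", {
  cl <- withr::with_seed(4, random_cloud(500, plot_rect(0, 2, 0, 2)))
  total <- 0
  for (i in 0:1) for (j in 0:1) {
    total <- total + nrow(segment_plot(cl, plot_rect(i, i + 1, j, j + 1)))
  }
  expect_equal(total, 500)
})

test_that("an empty segment signals a distinct empty-plot condition", {
  cl <- point_cloud(1, 1, 1)
  expect_warning(out <- segment_plot(cl, plot_rect(5, 6, 5, 6)),
                 class = "phenolidar_empty_plot")
  expect_equal(nrow(out), 0)
})

test_that("ground elevation is the mean of the modal height bin", {
  cl <- withr::with_seed(5, {
    z <- c(rnorm(1000, 0, 0.002), rnorm(200, 0.80, 0.002))
    point_cloud(runif(1200), runif(1200), z)
  })
  g <- estimate_ground(cl, 0.01)
  expect_lt(abs(g$ground_z), 0.005)
  # translation equivariance (exact)
  g10 <- estimate_ground(point_cloud(cl$x, cl$y, cl$z + 10), 0.01)
  expect_equal(g10$ground_z, g$ground_z + 10)
})

test_that("ground mode ties break toward the lower bin", {
  z <- c(rep(0.005, 50), rep(0.505, 50))   # equal counts, bins 0 and 50
  cl <- point_cloud(seq_along(z), seq_along(z), z)
  g <- estimate_ground(cl, 0.01)
  expect_equal(g$ground_z, 0.005)
  expect_equal(g$n_ground_points, 50)
  expect_error(estimate_ground(point_cloud(), 0.01),
               class = "phenolidar_validation_error")
})

test_that("ground estimation matches a brute-force histogram scan", {
  withr::with_seed(6, {
    for (i in 1:200) {
      n <- sample(5:60, 1)
      z <- runif(n, -0.2, 0.8)
      cl <- point_cloud(seq_len(n), seq_len(n), z)
      g <- estimate_ground(cl, 0.01)
      expect_equal(g$ground_z, brute_ground(z, 0.01))
    }
  })
})

test_that("crop height is the mean of the top-95th-percentile set minus ground", {
  g <- list(ground_z = 0.2, bin_width = 0.01)
  flat <- point_cloud(1:5, 1:5, rep(1.2, 5))
  expect_equal(crop_height(flat, g), 1.0)

  # 20-point ladder: P95 interpolates between the 19th and 20th order
  # statistics, leaving only the 1.00 m point at or above it
  ladder <- point_cloud(1:20, 1:20, seq(0.05, 1.00, by = 0.05))
  g0 <- list(ground_z = 0, bin_width = 0.01)
  expect_equal(crop_height(ladder, g0), 1.0)
  # hand-check the percentile itself
  zs <- sort(ladder$z)
  idx <- 1 + 0.95 * 19
  p95 <- zs[19] + (idx - 19) * (zs[20] - zs[19])
  expect_equal(mean(zs[zs >= p95]), 1.0)
})

test_that("crop height is invariant to vertical translation and point order", {
  cl <- withr::with_seed(7, random_cloud(200, plot_rect(0, 1, 0, 1), z_max = 1))
  g <- list(ground_z = 0.0, bin_width = 0.01)
  h <- crop_height(cl, g)
  shifted <- point_cloud(cl$x, cl$y, cl$z + 3.7)
  gs <- list(ground_z = 3.7, bin_width = 0.01)
  expect_equal(crop_height(shifted, gs), h, tolerance = 1e-12)
  perm <- withr::with_seed(8, sample(nrow(cl)))
  expect_equal(crop_height(cl[perm, ], g), h)
})

test_that("small negative heights clamp to zero, larger ones warn", {
  g <- list(ground_z = 1.0, bin_width = 0.01)
  near <- point_cloud(1:5, 1:5, rep(0.995, 5))
  expect_equal(crop_height(near, g, exclude_ground = FALSE), 0)
  far <- point_cloud(1:5, 1:5, rep(0.5, 5))
  expect_warning(h <- crop_height(far, g, exclude_ground = FALSE),
                 class = "phenolidar_data_quality")
  expect_equal(h, 0)
  expect_error(crop_height(point_cloud(), g),
               class = "phenolidar_validation_error")
})
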