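# Trial-design, truth, scan and destructive-sampling generators.

test_that("rcbd designs have exactly genotypes x replicates plots, unique keys", {
  d <- simulate_design(20, "rcbd", list(reps = 3), rng_seed = 1)
  expect_equal(nrow(d), 60)
  expect_equal(mean_replication(d), 3)
  expect_false(anyDuplicated(d$plot_id) > 0)
  expect_false(anyDuplicated(paste(d$row, d$col)) > 0)
  # every genotype appears exactly once per replicate block
  tab <- table(d$genotype, d$replicate)
  expect_true(all(tab == 1))
})

test_that("partial-replicate designs meet the plot budget and replication range", {
  d <- simulate_design(98, "partial_rep",
                       list(n_plots = 240, rep_range = c(1, 4)), rng_seed = 5)
  expect_equal(nrow(d), 240)
  counts <- table(d$genotype)
  expect_true(all(counts >= 1 & counts <= 4))
  expect_lt(abs(mean_replication(d) - 240 / 98), 0.01)

  d2 <- simulate_design(41, "partial_rep",
                        list(n_plots = 64, rep_range = c(1, 2)), rng_seed = 5)
  expect_equal(nrow(d2), 64)
  expect_equal(round(mean_replication(d2), 1), 1.6)
})

test_that("degenerate or oversized designs are rejected", {
  expect_error(simulate_design(1, "rcbd", list(reps = 3)),
               class = "phenolidar_sizing_error")
  expect_error(simulate_design(10, "rcbd", list(reps = 3),
                               field_shape = c(2, 2)),
               class = "phenolidar_sizing_error")
  expect_error(simulate_design(10, "partial_rep",
                               list(n_plots = 5, rep_range = c(1, 2))),
               class = "phenolidar_sizing_error")
})

test_that("designs and truths are bit-identical under the same seed", {
  d1 <- simulate_design(15, "partial_rep",
                        list(n_plots = 40, rep_range = c(1, 4)), rng_seed = 42)
  d2 <- simulate_design(15, "partial_rep",
                        list(n_plots = 40, rep_range = c(1, 4)), rng_seed = 42)
  expect_identical(d1, d2)
  t1 <- simulate_truth(d1, rng_seed = 7)
  t2 <- simulate_truth(d2, rng_seed = 7)
  expect_identical(t1, t2)
  s1 <- simulate_scan(d1, t1, "2016-09-01", scan_config(), rng_seed = 9)
  s2 <- simulate_scan(d1, t1, "2016-09-01", scan_config(), rng_seed = 9)
  expect_identical(s1, s2)
  a1 <- simulate_agb(d1, t1, "2016-09-01", 0.3, rng_seed = 3)
  a2 <- simulate_agb(d1, t1, "2016-09-01", 0.3, rng_seed = 3)
  expect_identical(a1, a2)
})

test_that("zero genotypic variance gives identical genotype effects", {
  d <- simulate_design(10, "rcbd", list(reps = 2), rng_seed = 1)
  vs <- default_variance_spec()
  vs$traits$generic$sigma2_g <- 0
  tr <- simulate_truth(d, vs, rng_seed = 2)
  expect_true(all(tr$genotypes$generic_effect == 0))
})

test_that("negative variance settings are rejected", {
  d <- simulate_design(5, "rcbd", list(reps = 2), rng_seed = 1)
  vs <- default_variance_spec()
  vs$traits$generic$sigma2_g <- -1
  expect_error(simulate_truth(d, vs), class = "phenolidar_validation_error")
  vs2 <- default_variance_spec()
  vs2$genotype$height_sd <- -0.1
  expect_error(simulate_truth(d, vs2), class = "phenolidar_validation_error")
})

test_that("genotype effect draws have the requested variance (law of large numbers)", {
  d <- simulate_design(10000, "rcbd", list(reps = 1),
                       field_shape = c(100, 100), rng_seed = 11)
  tr <- simulate_truth(d, rng_seed = 12)   # generic trait: sigma2_g = 1
  v <- var(tr$genotypes$generic_effect)
  expect_gte(v, 0.95)
  expect_lte(v, 1.05)
})

test_that("phenology always has GS31 before GS65", {
  d <- simulate_design(50, "rcbd", list(reps = 1), rng_seed = 1)
  vs <- default_variance_spec()
  vs$genotype$phenology_sd <- 10        # stress the ordering constraint
  tr <- simulate_truth(d, vs, rng_seed = 3)
  expect_true(all(tr$genotypes$gs65 > tr$genotypes$gs31))
})

test_that("every beam yields exactly one return, never below terrain minus 3 sd", {
  d <- simulate_design(4, "rcbd", list(reps = 2), rng_seed = 2)
  tr <- simulate_truth(d, rng_seed = 3)
  cfg <- scan_config(beam_spacing = 0.05)
  clouds <- simulate_scan(d, tr, "2016-09-08", cfg, rng_seed = 4)
  for (i in seq_len(nrow(d))) {
    rect <- design_rect(d, i)
    nb <- floor((rect$x_max - rect$x_min) / cfg$beam_spacing) *
      floor((rect$y_max - rect$y_min) / cfg$beam_spacing)
    cl <- clouds[[d$plot_id[i]]]
    expect_equal(nrow(cl), nb)
    expect_equal(sort(cl$beam_id), seq_len(nb))
    terrain <- tr$plots$terrain_z[tr$plots$plot_id == d$plot_id[i]]
    expect_gte(min(cl$z), terrain - 3 * cfg$z_noise_sd - 1e-12)
  }
})

test_that("opaque canopies yield no ground returns; bare soil only ground returns", {
  d <- simulate_design(2, "rcbd", list(reps = 1), rng_seed = 2)
  tr <- simulate_truth(d, rng_seed = 3)
  # opaque: enormous extinction, no gap beams, no noise
  cfg <- scan_config(beam_spacing = 0.05, extinction = 1e6,
                     ground_fraction = 0, z_noise_sd = 0)
  clouds <- simulate_scan(d, tr, "2016-09-08", cfg, rng_seed = 4)
  for (pid in d$plot_id) {
    terrain <- tr$plots$terrain_z[tr$plots$plot_id == pid]
    dz <- clouds[[pid]]$z - terrain
    # an opaque canopy transmits nothing: every return is either a soil
    # return through an inter-row gap or sits in the top canopy layer
    expect_true(all(dz < 0.001 | dz > max(dz) - 0.011))
    expect_gt(max(dz), 0.2)
    # gap returns are limited to the uncovered soil fraction
    expect_lt(mean(dz < 0.001), 0.15)
  }
  # bare soil: zero canopy density
  tr0 <- tr
  tr0$genotypes$density <- 0
  clouds0 <- simulate_scan(d, tr0, "2016-09-08", cfg, rng_seed = 4)
  for (pid in d$plot_id) {
    terrain <- tr$plots$terrain_z[tr$plots$plot_id == pid]
    expect_true(all(abs(clouds0[[pid]]$z - terrain) < 1e-12))
  }
})

test_that("single-layer interception counts are binomial", {
  withr::with_seed(99, {
    hits <- simulate_interception(500, 0.3)
    n_hit <- sum(hits == 1)
    expect_lt(abs(n_hit - 150), 3 * sqrt(500 * 0.3 * 0.7))
  })
})

test_that("AGB noise follows the 1/sqrt(quadrat area) law", {
  d <- simulate_design(10, "rcbd", list(reps = 2), rng_seed = 1)
  tr <- simulate_truth(d, rng_seed = 2)
  date <- tr$sowing_date + 108
  mu <- phenolidar:::expected_agb(d, tr, date)
  big <- simulate_agb(d, tr, date, 1.08, rng_seed = 77)
  small <- simulate_agb(d, tr, date, 0.3, rng_seed = 77)
  # same seed, same standard normal draws: deviations scale exactly
  ratio <- (big$value - mu) / (small$value - mu)
  expect_equal(ratio, rep(sqrt(0.3 / 1.08), length(ratio)), tolerance = 1e-10)
})

test_that("noiseless AGB equals its deterministic expectation", {
  d <- simulate_design(8, "rcbd", list(reps = 2), rng_seed = 1)
  tr <- simulate_truth(d, rng_seed = 2)
  date <- tr$sowing_date + 100
  obs <- simulate_agb(d, tr, date, 0.3, noise_coef = 0, rng_seed = 5)
  expect_equal(obs$value, phenolidar:::expected_agb(d, tr, date))
})

test_that("empirical AGB noise sd matches the configured sd (Monte Carlo)", {
  d <- simulate_design(1000, "rcbd", list(reps = 2),
                       field_shape = c(45, 45), rng_seed = 21)
  tr <- simulate_truth(d, rng_seed = 22)
  date <- tr$sowing_date + 108            # large crop: truncation at 0 moot
  mu <- phenolidar:::expected_agb(d, tr, date)
  coef <- tr$variance_spec$observation$agb_noise_coef
  sd_cfg <- coef * sqrt(pmax(mu, 0.05)) / sqrt(0.3)
  obs <- simulate_agb(d, tr, date, 0.3, rng_seed = 23)
  zscores <- (obs$value - mu) / sd_cfg
  expect_lt(abs(sd(zscores) - 1), 0.05)
})

test_that("water-limited scenario scales growth by 0.6 and noise by 2", {
  d <- simulate_design(10, "rcbd", list(reps = 2), rng_seed = 1)
  ww <- simulate_truth(d, scenario = "well_watered", rng_seed = 9)
  wl <- simulate_truth(d, scenario = "water_limited", rng_seed = 9)
  expect_equal(wl$genotypes$growth_rate, 0.6 * ww$genotypes$growth_rate)
  expect_equal(wl$noise_mult, 2)
})

test_that("the generator reports the implied true repeatability", {
  d <- simulate_design(10, "rcbd", list(reps = 3), rng_seed = 1)
  vs <- default_variance_spec()
  vs$traits$generic <- list(sigma2_g = 2, sigma2_e = 1)
  tr <- simulate_truth(d, vs, rng_seed = 2)
  expect_equal(true_repeatability(tr, "generic", 3), 2 / (2 + 1 / 3))
  expect_error(true_repeatability(tr, "nope", 3),
               class = "phenolidar_validation_error")
})
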