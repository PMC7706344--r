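# Variance components, repeatability, BLUPs, correlations, regression.

test_that("repeatability follows the variance-component formula exactly", {
  expect_equal(repeatability(1, 1, 2), 2 / 3)
  expect_equal(repeatability(0, 5, 3), 0)
  expect_equal(repeatability(2, 0, 3), 1)
  expect_error(repeatability(1, 1, 0), class = "phenolidar_validation_error")
  expect_error(repeatability(-1, 1, 2), class = "phenolidar_validation_error")
})

test_that("repeatability is monotone in each variance component", {
  grid_g <- seq(0.1, 5, length.out = 12)
  grid_e <- seq(0.1, 5, length.out = 12)
  grid_n <- c(1, 1.6, 2, 2.45, 3, 5)
  for (e in grid_e) for (n in grid_n) {
    r <- vapply(grid_g, repeatability, numeric(1), sigma2_e = e, nrep = n)
    expect_true(all(diff(r) > 0))
    expect_true(all(r >= 0 & r <= 1))
  }
  for (g in grid_g) for (n in grid_n) {
    r <- vapply(grid_e, function(e) repeatability(g, e, n), numeric(1))
    expect_true(all(diff(r) < 0))
  }
  for (g in grid_g) for (e in grid_e) {
    r <- vapply(grid_n, function(n) repeatability(g, e, n), numeric(1))
    expect_true(all(diff(r) > 0))
  }
})

test_that("constant observations give a zero-variance decomposition", {
  withr::with_seed(30, {
    d <- grid_design(letters[1:4], 3)
    tr <- data.frame(plot_id = d$plot_id, value = 7)
    vc <- fit_random_effects(tr, d)
    expect_equal(vc$sigma2_g, 0)
    expect_equal(vc$sigma2_e, 0)
    expect_equal(vc$rho, 0)
    expect_true(all(vc$blups == 0))
    expect_match(vc$convergence, "degenerate")
  })
})

test_that("balanced one-way components match the expected-mean-squares solution", {
  withr::with_seed(31, {
    d <- grid_design(c("A", "B", "C"), 2)
    values <- c(A = 10.0, B = 12.1, C = 14.2)[d$genotype] +
      c(0.2, -0.2, -0.3, 0.3, 0.25, -0.25)
    tr <- data.frame(plot_id = d$plot_id, value = values)
    vc <- fit_random_effects(tr, d, spatial = "none")
    oracle <- ems_oneway(values, d$genotype)
    expect_equal(vc$sigma2_g, oracle$sigma2_g, tolerance = 1e-4)
    expect_equal(vc$sigma2_e, oracle$sigma2_e, tolerance = 1e-4)
    expect_equal(vc$nrep, 2)
    expect_equal(vc$rho,
                 oracle$sigma2_g / (oracle$sigma2_g + oracle$sigma2_e / 2),
                 tolerance = 1e-4)
  })
})

test_that("variance-component estimation recovers the generator truth", {
  # moderate-size check; the full-scale recovery runs in the acceptance suite
  withr::with_seed(32, {
    d <- simulate_design(50, "rcbd", list(reps = 3), rng_seed = 1)
    vs <- default_variance_spec()
    vs$traits$generic <- list(sigma2_g = 2, sigma2_e = 1)
    rhos <- s2gs <- numeric(60)
    for (i in 1:60) {
      tr <- simulate_truth(d, vs, rng_seed = 1000 + i)
      obs <- simulate_trait(d, tr, rng_seed = 2000 + i)
      vc <- fit_random_effects(obs, d, spatial = "none")
      rhos[i] <- vc$rho
      s2gs[i] <- vc$sigma2_g
    }
    expect_lt(abs(mean(rhos) - 2 / (2 + 1 / 3)), 0.05)
    expect_lt(abs(mean(s2gs) - 2), 0.2)
  })
})

test_that("BLUPs shrink toward zero and sum to zero", {
  withr::with_seed(33, {
    d <- grid_design(sprintf("g%02d", 1:15), 3)
    eff <- rnorm(15, 0, 1.5)
    names(eff) <- sprintf("g%02d", 1:15)
    tr <- data.frame(plot_id = d$plot_id,
                     value = 10 + eff[d$genotype] + rnorm(45, 0, 1))
    vc <- fit_random_effects(tr, d, spatial = "none")
    raw_means <- tapply(tr$value, d$genotype, mean)
    expect_lte(var(vc$blups), var(raw_means))
    expect_lt(abs(sum(vc$blups)), 1e-8 * sd(tr$value) * length(vc$blups))
  })
})

test_that("BLUP correlations handle exact linear relations and p-values", {
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4.5)
  expect_equal(correlate_blups(a, 2 * a)$r, 1)
  expect_equal(correlate_blups(a, -a)$r, -1)
  expect_equal(correlate_blups(a, 2 * a)$p_value, 0)
  expect_error(correlate_blups(a[1:2], a[1:2]),
               class = "phenolidar_sample_size_error")
  # only the shared genotypes enter
  b <- c(g2 = 5, g3 = 1, g4 = 2, g9 = 100)
  expect_equal(correlate_blups(a, b)$n, 3)

  withr::with_seed(34, {
    x <- rnorm(20); y <- 0.4 * x + rnorm(20)
    names(x) <- names(y) <- sprintf("g%02d", 1:20)
    res <- correlate_blups(x, y)
    tstat <- res$r * sqrt((20 - 2) / (1 - res$r^2))
    p_quad <- 2 * integrate(dt, lower = abs(tstat), upper = Inf, df = 18)$value
    expect_equal(res$p_value, p_quad, tolerance = 1e-6)
  })
})

test_that("significance stars follow the published thresholds", {
  expect_equal(p_stars(c(5e-5, 5e-4, 5e-3, 0.03, 0.2)),
               c("****", "***", "**", "*", ""))
  expect_equal(correlate_blups(c(a = 1, b = 2, c = 3),
                               c(a = 2, b = 4, c = 6))$stars, "****")
})

test_that("between-event ICC is the BLUP correlation across events", {
  withr::with_seed(35, {
    d <- grid_design(sprintf("g%02d", 1:12), 2)
    e1 <- as.Date("2016-08-08"); e2 <- as.Date("2016-09-08")
    eff <- rnorm(12, 0, 2); names(eff) <- sprintf("g%02d", 1:12)
    mk <- function(ev, noise_sd) {
      data.frame(plot_id = d$plot_id, genotype = d$genotype, date = ev,
                 trait = "agb",
                 value = eff[d$genotype] + rnorm(24, 0, noise_sd))
    }
    same <- rbind(mk(e1, 0.001), mk(e2, 0.001))
    same$value[25:48] <- same$value[1:24]      # identical values both events
    icc <- icc_between_events(trait_table(same), d, "agb", e1, e2)
    expect_equal(icc$r, 1, tolerance = 1e-6)
    expect_error(icc_between_events(trait_table(same), d, "agb", e1,
                                    as.Date("2020-01-01")),
                 class = "phenolidar_missing_event")
  })
})

test_that("independent traits give near-zero ICC (null simulation)", {
  withr::with_seed(36, {
    d <- grid_design(sprintf("g%03d", 1:200), 1)
    e1 <- as.Date("2016-08-08"); e2 <- as.Date("2016-09-08")
    ok <- 0
    for (s in 1:8) {
      tt <- rbind(
        data.frame(plot_id = d$plot_id, genotype = d$genotype, date = e1,
                   trait = "x", value = rnorm(200)),
        data.frame(plot_id = d$plot_id, genotype = d$genotype, date = e2,
                   trait = "x", value = rnorm(200)))
      icc <- tryCatch(
        icc_between_events(trait_table(tt), d, "x", e1, e2,
                           spatial = "none"),
        phenolidar_validation_error = function(e) NULL)
      # a zero genotype-variance fit (constant BLUPs) is the strongest
      # form of "no between-event association"
      if (is.null(icc) || abs(icc$r) < 0.2) ok <- ok + 1
    }
    expect_gte(ok, 7)
  })
})

test_that("raw regression matches the normal-equations solution", {
  expect_equal(regress_raw(2 * (1:5) + 1, 1:5)$slope, 2)
  expect_equal(regress_raw(2 * (1:5) + 1, 1:5)$intercept, 1)
  expect_equal(regress_raw(2 * (1:5) + 1, 1:5)$r, 1)
  expect_equal(regress_raw(rep(3, 5), 1:5)$slope, 0)
  expect_error(regress_raw(1:5, rep(1, 5)),
               class = "phenolidar_validation_error")
  expect_error(regress_raw(1:2, 1:2), class = "phenolidar_sample_size_error")
  withr::with_seed(37, {
    x <- runif(50, 0, 3)
    y <- 1.5 + 2.2 * x + rnorm(50, 0, 0.4)
    fit <- regress_raw(y, x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
    expect_equal(fit$intercept, mean(y) - fit$slope * mean(x),
                 tolerance = 1e-12)
  })
})
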