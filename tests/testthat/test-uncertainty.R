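test_that("log-normal moment matching preserves the arithmetic mean exactly", {
  # degenerate no-dispersion limit
  p0 <- lognormal_params(5, 0)
  expect_equal(p0$sigma_log, 0)
  expect_equal(p0$mu_log, log(5))
  expect_equal(p0$k, 0)
  # closed-form example: mean 1, sd 0.15
  p1 <- lognormal_params(1, 0.15)
  expect_equal(p1$sigma_log, sqrt(log(1.0225)))
  expect_equal(p1$k, -log(sqrt(1.0225)))
  # analytic mean and sd match the targets exactly across a grid
  for (m in c(0.2, 1, 7, 450)) {
    for (cv in c(0.05, 0.15, 0.5, 1.2)) {
      pp <- lognormal_params(m, cv * m)
      expect_equal(exp(pp$mu_log + pp$sigma_log^2 / 2), m)
      an_var <- (exp(pp$sigma_log^2) - 1) * exp(2 * pp$mu_log + pp$sigma_log^2)
      expect_equal(sqrt(an_var), cv * m)
      expect_equal(pp$k, -pp$sigma_log^2 / 2)
    }
  }
  expect_error(lognormal_params(0, 1), "target_mean")
  expect_error(lognormal_params(-2, 1), "target_mean")
})

test_that("numerical-optimization mode agrees with the closed form", {
  for (m in c(0.5, 10)) {
    a <- lognormal_params(m, 0.3 * m)
    b <- lognormal_params(m, 0.3 * m, method = "optimize")
    expect_equal(b$mu_log, a$mu_log, tolerance = 1e-6)
    expect_equal(b$sigma_log, a$sigma_log)
  }
})

test_that("empirical draw moments converge to the specified targets", {
  set.seed(11)
  pp <- lognormal_params(10, 3)
  x <- rlnorm(1e5, pp$mu_log, pp$sigma_log)
  expect_lt(abs(mean(x) - 10) / 10, 0.01)

  specs <- data.frame(
    variable = c("a", "b", "c"),
    family = c("normal", "normal", "lognormal"),
    mean = c(100, 0.3, 8), sd = c(15, 0.045, 2.4),
    stringsAsFactors = FALSE
  )
  d <- draw_inputs(specs, 1e5, seed = 12)
  expect_lt(abs(mean(d$a) - 100) / 100, 0.01)
  expect_lt(abs(mean(d$b) - 0.3) / 0.3, 0.01)
  expect_lt(abs(mean(d$c) - 8) / 8, 0.01)
  expect_true(all(d$c > 0))
})

test_that("draw_inputs honours degenerate and determinism contracts", {
  specs <- data.frame(
    variable = c("x", "y"), family = c("normal", "lognormal"),
    mean = c(4, 2), sd = c(0, 0), stringsAsFactors = FALSE
  )
  d <- draw_inputs(specs, 1, seed = 3)
  expect_equal(d$x, 4)
  expect_equal(d$y, 2)
  specs$sd <- c(1, 0.5)
  d1 <- draw_inputs(specs, 500, seed = 99)
  d2 <- draw_inputs(specs, 500, seed = 99)
  expect_identical(d1, d2)
  expect_named(attr(d1, "clipped"), c("x", "y"))
  bad <- specs; bad$family[1] <- "gamma"
  expect_error(draw_inputs(bad, 10), "unknown distribution family")
})

test_that("zero-dispersion Monte Carlo collapses to the point estimate", {
  p <- make_test_provinces()[1, ]
  p$sd_simp <- 0
  r <- mc_province(p, model_constants(beta = 0), n_sims = 50, seed = 1)
  expect_equal(r$half_width_95, 0)
  expect_equal(unique(r$draws[, "c_total"]), r$point$c_total)
  expect_error(mc_province(p, model_constants(), n_sims = 1), "n_sims")
})

test_that("MC totals are unbiased, seed-deterministic, and pool-consistent", {
  p <- make_test_provinces()[1, ]
  r1 <- mc_province(p, n_sims = 10000, seed = 21)
  r2 <- mc_province(p, n_sims = 10000, seed = 21)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$half_width_95, r2$half_width_95)
  # relative deviation of the MC mean from the point estimate < 2%
  expect_lt(abs(r1$mean - r1$point$c_total) / r1$point$c_total, 0.02)
  # Var(total) equals the variance of the summed per-draw pools exactly
  summed <- rowSums(r1$draws[, c("c_veg", "c_soil", "c_human", "c_building")])
  expect_equal(var(summed), var(r1$draws[, "c_total"]))
})

test_that("a vegetation-only province has the three-factor product CV (~26%)", {
  p <- make_veg_only_province()
  r <- mc_province(p, n_sims = 10000, seed = 5)
  cv <- r$sd / r$mean
  # product of three independent 15%-CV factors: sqrt(1.0225^3 - 1) = 0.261
  expect_gt(cv, 0.23)
  expect_lt(cv, 0.29)
})

test_that("half-widths increase with the uncertainty coefficient beta", {
  p <- make_test_provinces()[1, ]
  hw <- vapply(c(0.05, 0.15, 0.30), function(b) {
    mc_province(p, model_constants(beta = b), n_sims = 4000, seed = 8)$half_width_95
  }, numeric(1))
  expect_true(all(diff(hw) > 0))
})

test_that("combining provinces sums draws and adds variances", {
  p <- make_test_provinces()
  res <- mc_provinces(p, n_sims = 6000, seed = 31)
  comb <- combine_provinces(res)
  # identity for a single province
  expect_identical(combine_provinces(res[1]), res[[1]])
  # draws summed index-wise
  expect_equal(comb$draws[, "c_total"],
               res[[1]]$draws[, "c_total"] + res[[2]]$draws[, "c_total"] +
                 res[[3]]$draws[, "c_total"])
  # independence: combined SD ~ sqrt(sum s_i^2) within MC error
  s_ind <- sqrt(sum(vapply(res, function(r) r$sd^2, numeric(1))))
  expect_lt(abs(comb$sd - s_ind) / s_ind, 0.05)
  # mismatched n_sims rejected
  other <- mc_province(p[1, ], n_sims = 1000, seed = 2)
  expect_error(combine_provinces(list(res[[1]], other)), "n_sims")
})

test_that("per-province substreams are stable when provinces are added", {
  p <- make_test_provinces()
  r_all <- mc_provinces(p, n_sims = 500, seed = 77)
  r_sub <- mc_provinces(p[1:2, ], n_sims = 500, seed = 77)
  expect_identical(r_all[["A"]]$draws, r_sub[["A"]]$draws)
  expect_identical(r_all[["B"]]$draws, r_sub[["B"]]$draws)
})
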