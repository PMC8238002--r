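test_that("constant observations give all-zero variance components and flat BLUPs", {
  d <- expand.grid(hybrid = paste0("H", 1:5), year = 1:2, rep = 1:2)
  d$value <- 50
  fit <- fit_mixed_model(d)
  expect_lt(fit$sigma2_H, 1e-8)
  expect_lt(fit$sigma2_HY, 1e-8)
  expect_lt(fit$sigma2_eps, 1e-8)
  expect_lt(max(abs(hybrid_blups(fit)$effect)), 1e-6)
  expect_equal(fit$mu, 50, tolerance = 1e-8)
})

test_that("REML components on one balanced trial match the closed-form ANOVA estimators", {
  # independent oracle: in a balanced two-way design the REML estimates of a
  # variance-component model equal the method-of-moments estimators from the
  # expected mean squares (when all estimates are interior)
  sim <- simulate_trial(n_hybrids = 120, seed = 41)
  fit <- fit_mixed_model(sim$records)
  d <- sim$records
  n <- 120; y <- 2; r <- 2
  gm <- mean(d$value)
  hyb_m <- tapply(d$value, d$hybrid, mean)
  hy_key <- paste(d$hybrid, d$year, sep = ".")
  cell_m <- tapply(d$value, hy_key, mean)
  yr_key <- paste(d$year, d$rep, sep = ".")
  yr_m <- tapply(d$value, yr_key, mean)
  year_m <- tapply(d$value, d$year, mean)
  # residuals after removing hybrid x year cell means and rep-within-year
  resid <- d$value - cell_m[hy_key] - yr_m[yr_key] + year_m[as.character(d$year)]
  df_e <- n * y * r - n * y - y * (r - 1)
  ms_e <- sum(resid^2) / df_e
  # hybrid and interaction mean squares from cell means
  ms_h <- y * r * sum((hyb_m - gm)^2) / (n - 1)
  cell_tbl <- unique(data.frame(h = as.character(d$hybrid),
                                yr = as.character(d$year), key = hy_key))
  dev_hy <- cell_m[cell_tbl$key] - hyb_m[cell_tbl$h] -
    year_m[cell_tbl$yr] + gm
  ms_hy <- r * sum(dev_hy^2) / ((n - 1) * (y - 1))
  s2_hy_hat <- (ms_hy - ms_e) / r
  s2_h_hat <- (ms_h - ms_hy) / (y * r)
  expect_equal(fit$sigma2_eps, ms_e, tolerance = 0.02)
  expect_equal(fit$sigma2_HY, s2_hy_hat, tolerance = 0.05)
  expect_equal(fit$sigma2_H, s2_h_hat, tolerance = 0.05)
})

test_that("BLUPs shrink toward zero relative to hybrid-mean deviations", {
  sim <- simulate_trial(n_hybrids = 80, seed = 42)
  fit <- fit_mixed_model(sim$records)
  b <- hybrid_blups(fit)
  hyb_m <- tapply(sim$records$value, sim$records$hybrid, mean)
  dev <- hyb_m[b$hybrid] - mean(sim$records$value)
  expect_true(all(abs(b$effect) <= abs(dev) + 1e-6))
  # and track the true effects at the theoretical accuracy sqrt(H2_entry)
  tr <- sim$truth$hybrid_effects
  rho <- cor(b$effect[match(tr$hybrid, b$hybrid)], tr$effect)
  expect_equal(rho, sqrt(2 / 2.75), tolerance = 0.08)
})

test_that("a single-year trial drops the interaction and still fits", {
  sim <- simulate_trial(n_hybrids = 40, years = 1, sigma2_HY = 0, seed = 43)
  fit <- fit_mixed_model(sim$records)
  expect_identical(fit$sigma2_HY, 0)
  expect_identical(fit$n_years, 1L)
  h <- heritability(fit)
  expect_true(h$H2_entry >= h$H2_plot)
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- simulate_trial(n_hybrids = 20, seed = 44)
  fit <- fit_mixed_model(sim$records, trait = "PHTYLD")
  td <- tidy(fit)
  expect_identical(td$term, c("sigma2_H", "sigma2_HY", "sigma2_eps", "mu"))
  gl <- glance(fit)
  expect_identical(gl$trait, "PHTYLD")
  expect_identical(gl$n_hybrids, 20L)
  expect_true(is.logical(gl$converged))
})

test_that("fewer than two hybrids is an error", {
  d <- data.frame(hybrid = "H1", year = c(1, 1, 2, 2), rep = c(1, 2, 1, 2),
                  value = rnorm(4))
  expect_error(fit_mixed_model(d), "2 hybrids")
})
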