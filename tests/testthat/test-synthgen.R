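test_that("rendering is deterministic: same seed gives byte-identical output", {
  a <- render_ear(ear_spec(seed = 30))
  b <- render_ear(ear_spec(seed = 30))
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  c_ <- render_ear(ear_spec(seed = 31))
  expect_false(identical(a$rgb, c_$rgb))
})

test_that("full abortion renders no kernel pixels and zero kernel count", {
  r <- render_ear(ear_spec(abortion_frac = 1, seed = 32))
  expect_false(any(r$labels == 3L))
  expect_identical(r$truth$n_visible_kernels, 0L)
  expect_equal(r$truth$PHTKPE * 0, 0)  # defined, finite
})

test_that("no abortion and no scatter puts the first kernels at the very tip zone boundary", {
  r <- render_ear(ear_spec(abortion_frac = 0.1, scatter_frac = 0, seed = 33))
  # first kernel pixel row should sit at ~10% of the ear length
  ker_rows <- which(rowSums(r$labels == 3L) > 0)
  expect_equal(min(ker_rows) / nrow(r$labels), 0.1, tolerance = 0.05)
  expect_identical(r$truth$TKERAB, 10)
})

test_that("closed-form silhouette truths agree with numeric quadrature", {
  sp <- ear_spec(taper_power = 3.5, kernels_per_row = 0, length_cm = 17,
                 max_width_cm = 5.1, seed = 34)
  tr <- render_ear(sp)$truth
  wfun <- function(s) {
    u <- 1 - s / 17
    5.1 * (1 - u^3.5)^(1 / 3.5)
  }
  area_num <- integrate(wfun, 0, 17, rel.tol = 1e-10)$value
  vol_num <- integrate(function(s) pi * (wfun(s) / 2)^2, 0, 17,
                       rel.tol = 1e-10)$value
  expect_equal(tr$EARAREA, area_num, tolerance = 1e-8)
  expect_equal(tr$EARVOL, vol_num, tolerance = 1e-8)
  expect_equal(tr$EARBOX, area_num / (17 * 5.1), tolerance = 1e-8)
})

test_that("crown-coverage KERFIL truth equals the analytic grid coverage", {
  sp <- ear_spec(scatter_frac = 0, seed = 35)
  r <- render_ear(sp)
  n_sites <- sp$visible_rows * sp$kernels_per_row
  cover <- 100 * n_sites * (pi * 0.87 * 0.46 / 4) / r$truth$EARAREA
  expect_equal(r$truth$KERFIL, cover, tolerance = 1e-10)
  # and the rendered label image matches that coverage closely
  kerfil_px <- 100 * sum(r$labels == 3L) / sum(r$labels > 1L)
  expect_equal(kerfil_px, cover, tolerance = 0.02)
})

test_that("touching crowns are rejected as invalid specs", {
  expect_error(render_ear(ear_spec(kernels_per_row = 25)), "touch")
  expect_error(render_ear(ear_spec(visible_rows = 12)), "touch")
})

test_that("scenes order ears left to right with an exactly sized ruler bar", {
  sc <- render_scene(lapply(1:5, function(i) ear_spec(seed = 40 + i)),
                     px_per_cm = 20, ruler_length_cm = 15)
  expect_identical(nrow(sc$truth), 5L)
  expect_identical(sc$truth$ear, 1:5)
  expect_identical(sc$ruler_bar_px, 300)
  # ruler strip must classify as background-ish, not as an ear: extraction
  # sees exactly 5 ears
  ears <- extract_ear_instances(sc$labels, 20)
  expect_length(ears, 5)
})

test_that("trial simulation honours the generative model", {
  # all variances zero: Y is exactly the fixed structure
  s0 <- simulate_trial(n_hybrids = 10, sigma2_H = 0, sigma2_HY = 0,
                       sigma2_eps = 0, mu = 100,
                       year_effects = c(-5, 5), seed = 50)
  d <- s0$records
  y1r1 <- d$value[d$year == 2017 & d$rep == 1]
  expect_true(all(y1r1 == y1r1[1]))
  expect_equal(mean(d$value), 100)
  # drawn hybrid effects have the requested variance (law of large numbers)
  s1 <- simulate_trial(n_hybrids = 10000, years = 1, reps = 1,
                       sigma2_H = 2, sigma2_eps = 0.5, seed = 51)
  expect_equal(var(s1$truth$hybrid_effects$effect), 2, tolerance = 0.05)
  # determinism
  expect_identical(simulate_trial(seed = 52)$records,
                   simulate_trial(seed = 52)$records)
  expect_false(identical(simulate_trial(seed = 52)$records$value,
                         simulate_trial(seed = 53)$records$value))
})

test_that("balanced design: every hybrid appears once per year x rep cell", {
  s <- simulate_trial(n_hybrids = 30, seed = 54)
  tab <- table(s$records$hybrid, s$records$year, s$records$rep)
  expect_true(all(tab == 1))
})
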