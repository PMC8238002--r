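test_that("watershed recovers a dense non-touching crown grid within 2%", {
  # ~280 visible crowns: 10 tracks x 28 per row needs smaller crowns
  sp <- ear_spec(visible_rows = 10, kernels_per_row = 28,
                 crown_major_cm = 0.58, crown_minor_cm = 0.40,
                 max_width_cm = 5.6, scatter_frac = 0, abortion_frac = 0.03,
                 seed = 5)
  re <- rendered_ear(sp)
  expect_identical(re$truth$n_visible_kernels, 280L)
  k <- detect_kernels(re$ear)
  expect_lte(abs(nrow(k) - 280) / 280, 0.02)
})

test_that("a fully aborted ear yields zero kernels without error", {
  re <- rendered_ear(ear_spec(abortion_frac = 1, seed = 6))
  expect_false(any(re$ear$kernel_mask))
  k <- detect_kernels(re$ear)
  expect_identical(nrow(k), 0L)
  s <- summarize_kernel_geometry(k)
  expect_identical(s$n_kernels, 0L)
  expect_true(is.na(s$mean_area_cm2))
})

test_that("watershed regions live inside the kernel mask and are disjoint", {
  re <- rendered_ear(ear_spec(seed = 7))
  k <- detect_kernels(re$ear)
  # total segmented area cannot exceed the kernel-class area
  expect_lte(sum(k$area_cm2), sum(re$ear$kernel_mask) / 20^2 + 1e-9)
  # crowns are non-touching by construction: one region per crown, so the
  # count matches the number of connected components exactly
  cc <- EBImage::bwlabel(matrix(as.integer(re$ear$kernel_mask),
                                nrow(re$ear$kernel_mask)))
  expect_identical(nrow(k), max(cc))
})

test_that("crown geometry is recovered within 5% of the generator ellipse", {
  re <- rendered_ear(ear_spec(seed = 8))
  s <- summarize_kernel_geometry(detect_kernels(re$ear))
  expect_equal(s$mean_major_cm, 0.87, tolerance = 0.05)
  expect_equal(s$mean_minor_cm, 0.46, tolerance = 0.05)
  expect_equal(s$mean_feret_max_cm, 0.87, tolerance = 0.05)
  expect_equal(s$mean_feret_min_cm, 0.46, tolerance = 0.05)
  expect_equal(s$mean_area_cm2, pi * 0.87 * 0.46 / 4, tolerance = 0.05)
  expect_equal(s$mean_perimeter_cm, re$truth$KERPER, tolerance = 0.05)
})

test_that("doubling resolution changes cm-unit kernel geometry by < 2%", {
  sp <- ear_spec(seed = 9, color_jitter_sd = 0)
  s1 <- summarize_kernel_geometry(detect_kernels(rendered_ear(sp, 20)$ear))
  s2 <- summarize_kernel_geometry(detect_kernels(rendered_ear(sp, 40)$ear))
  expect_identical(s1$n_kernels, s2$n_kernels)
  for (col in c("mean_area_cm2", "mean_major_cm", "mean_minor_cm",
                "mean_perimeter_cm")) {
    expect_equal(s2[[col]] / s1[[col]], 1, tolerance = 0.02)
  }
})

test_that("kernel summary is the arithmetic mean of per-kernel geometry", {
  k <- tibble::tibble(kernel = 1:2,
                      centroid_x_cm = c(1, 2), centroid_y_cm = c(5, 6),
                      area_cm2 = c(0.3, 0.5), major_cm = c(0.8, 0.9),
                      minor_cm = c(0.4, 0.5), feret_max_cm = c(0.85, 0.95),
                      feret_min_cm = c(0.42, 0.52),
                      perimeter_cm = c(1.9, 2.1))
  s <- summarize_kernel_geometry(k)
  expect_equal(s$mean_area_cm2, 0.4)
  expect_equal(s$mean_diameter_cm, mean(c((0.85 + 0.42) / 2, (0.95 + 0.52) / 2)))
  s1 <- summarize_kernel_geometry(k[1, ])
  expect_equal(s1$mean_area_cm2, 0.3)
  expect_equal(s1$mean_major_cm, 0.8)
})

test_that("count recovery over a generator sweep has mean |relative error| <= 2%", {
  set.seed(31)
  errs <- vapply(1:6, function(i) {
    rows <- sample(7:10, 1); kpr <- sample(14:24, 1)
    sp <- ear_spec(visible_rows = rows, kernels_per_row = kpr,
                   crown_major_cm = 0.60, crown_minor_cm = 0.42,
                   track_extent_frac = 0.8,
                   length_cm = runif(1, 16, 22),
                   max_width_cm = runif(1, 5.0, 5.8),
                   abortion_frac = runif(1, 0.04, 0.12),
                   scatter_frac = runif(1, 0, 0.08), seed = 100 + i)
    re <- rendered_ear(sp)
    n_true <- re$truth$n_visible_kernels
    abs(nrow(detect_kernels(re$ear)) - n_true) / n_true
  }, numeric(1))
  expect_lte(mean(errs), 0.02)
})
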