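# a synthetic kernel table laid out as a uniform R x K grid
grid_kernels <- function(R = 8, K = 18, length_cm = 19, width_cm = 4.4,
                         kw = 0.46, kl = 0.87) {
  x <- seq(-width_cm / 2, width_cm / 2, length.out = R)
  pitch <- length_cm / K
  y <- (seq_len(K) - 0.5) * pitch
  tibble::tibble(
    kernel = seq_len(R * K),
    centroid_x_cm = rep(x, each = K) + 2.5,
    centroid_y_cm = rep(y, times = R),
    area_cm2 = pi * kl * kw / 4, major_cm = kl, minor_cm = kw,
    feret_max_cm = kl, feret_min_cm = kw, perimeter_cm = 2.1)
}

sil_for <- function(length_cm = 19, width_cm = 5) {
  tibble::tibble(EARLGT = length_cm, EARWTH = width_cm)
}

fill_zero <- tibble::tibble(KERFIL = 50, SCTTER = 0, TKERAB = 0,
                            abortion_cob_pct = 50)

test_that("8 visible row tracks with factor 2 give PHTKR = 16", {
  k <- grid_kernels(R = 8, K = 18)
  km <- kernel_trait_means(k, 19)
  cy <- count_and_yield_traits(rect_ear(19, 5, 10), k, sil_for(), fill_zero, km)
  expect_equal(cy$PHTKR, 16)
})

test_that("a uniform grid with no scatter or abortion recovers PHTKPE = 2 R K within 5%", {
  for (RK in list(c(8, 18), c(7, 25), c(10, 14))) {
    k <- grid_kernels(R = RK[1], K = RK[2])
    km <- kernel_trait_means(k, 19)
    cy <- count_and_yield_traits(rect_ear(19, 5, 10), k, sil_for(), fill_zero, km)
    expect_equal(cy$PHTKPE, 2 * RK[1] * RK[2],
                 tolerance = 0.05)
  }
})

test_that("PHTYLD = KERWGT x PHTKPE holds exactly, and zero kernels degrade cleanly", {
  k <- grid_kernels()
  km <- kernel_trait_means(k, 19)
  cy <- count_and_yield_traits(rect_ear(19, 5, 10), k, sil_for(), fill_zero, km)
  expect_identical(cy$PHTYLD, cy$KERWGT * cy$PHTKPE)
  cy0 <- count_and_yield_traits(rect_ear(19, 5, 10), k[0, ], sil_for(),
                                fill_zero, kernel_trait_means(k[0, ], 19))
  expect_identical(cy0$PHTKR, 0)
  expect_identical(cy0$PHTYLD, 0)
  expect_true(is.na(cy0$KERWGT))
})

test_that("scatter scales the per-ear kernel count multiplicatively", {
  k <- grid_kernels()
  km <- kernel_trait_means(k, 19)
  f0 <- fill_zero
  f1 <- dplyr::mutate(fill_zero, SCTTER = 10)
  cy0 <- count_and_yield_traits(rect_ear(19, 5, 10), k, sil_for(), f0, km)
  cy1 <- count_and_yield_traits(rect_ear(19, 5, 10), k, sil_for(), f1, km)
  expect_equal(cy1$PHTKPE / cy0$PHTKPE, 0.9)
})

test_that("full per-ear trait table keeps the yield identity and trait order", {
  re <- rendered_ear(ear_spec(seed = 22))
  tr <- compute_ear_traits(re$ear)
  expect_identical(tr$PHTYLD, tr$KERWGT * tr$PHTKPE)
  expect_true(all(ep_trait_names() %in% names(tr)))
  expect_true(tr$KERMIND <= tr$KERMEAND && tr$KERMEAND <= tr$KERMAXD)
  # end-to-end: counts and yield magnitudes against generator truth
  expect_equal(tr$PHTKR, re$truth$PHTKR, tolerance = 0.01)
  expect_equal(tr$PHTKPR, re$truth$PHTKPR, tolerance = 0.05)
  expect_equal(tr$TKERAB, re$truth$TKERAB, tolerance = 0.05)
})

test_that("plot aggregation averages traits and uses the n-1 variance", {
  re <- rendered_ear(ear_spec(seed = 23))
  tr <- compute_ear_traits(re$ear)
  ears10 <- dplyr::bind_rows(replicate(10, tr, simplify = FALSE))
  agg <- aggregate_plot(ears10, "P1")
  expect_identical(agg$n_ears, 10L)
  expect_equal(agg$PHTYLD, tr$PHTYLD)
  expect_equal(agg$PHTYLD_var, 0)
  two <- dplyr::bind_rows(dplyr::mutate(tr, PHTYLD = 150),
                          dplyr::mutate(tr, PHTYLD = 170))
  expect_equal(aggregate_plot(two, "P2")$PHTYLD_var, 200)
  expect_true(is.na(aggregate_plot(tr, "P3")$PHTYLD_var))
  expect_error(aggregate_plot(tr[0, ], "P4"), "empty")
  # missing values are excluded from means, not zero-filled
  mixed <- dplyr::bind_rows(dplyr::mutate(tr, KERARE = NA_real_),
                            dplyr::mutate(tr, KERARE = 0.4))
  expect_equal(aggregate_plot(mixed, "P5")$KERARE, 0.4)
})
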