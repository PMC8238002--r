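test_that("exemplar colours map to their own class and ties break by class order", {
  tpl <- base_template()
  clf <- fit_pixel_classifier(tpl)
  expect_equal(predict_pixel_class(clf, as.matrix(tpl[, 1:3])),
               tpl$class)
  # a colour exactly equidistant from two centroids gets the earlier class:
  # move two centroids symmetrically around a probe in Lab by construction
  tpl2 <- tibble::tibble(R = c(0, 100, 255), G = c(0, 100, 255),
                         B = c(0, 100, 255),
                         class = c("background", "cob", "kernel"))
  clf2 <- fit_pixel_classifier(tpl2)
  # grey ramp: the probe equal to the cob exemplar is nearer cob than others
  expect_identical(predict_pixel_class(clf2, matrix(c(100, 100, 100), 1)),
                   "cob")
  # probe identical distance to all three is impossible on a ramp; check the
  # documented order via a degenerate template where two classes coincide
  tpl3 <- tibble::tibble(R = c(10, 10, 200), G = c(10, 10, 200),
                         B = c(10, 10, 200),
                         class = c("background", "cob", "kernel"))
  clf3 <- fit_pixel_classifier(tpl3)
  expect_identical(predict_pixel_class(clf3, matrix(c(10, 10, 10), 1)),
                   "background")
})

test_that("classifier equals brute-force nearest-centroid on random colours", {
  clf <- fit_pixel_classifier(base_template())
  set.seed(42)
  cols <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  got <- predict_pixel_class(clf, cols)
  lab <- grDevices::convertColor(cols / 255, from = "sRGB", to = "Lab")
  brute <- apply(lab, 1, function(p) {
    d <- colSums((t(clf$centroids) - p)^2)
    c("background", "cob", "kernel")[which.min(d)]
  })
  expect_identical(got, unname(brute))
})

test_that("a missing template class raises a configuration error naming it", {
  tpl <- base_template()[1:2, ]
  expect_error(fit_pixel_classifier(tpl), "kernel")
})

test_that("uniform background image classifies entirely as background, deterministically", {
  clf <- fit_pixel_classifier(base_template())
  img <- array(rep(c(40, 40, 48) / 255, each = 30 * 20), c(30, 20, 3))
  lab1 <- classify_pixels(img, clf)
  expect_true(all(lab1 == 1L))
  expect_identical(dim(lab1), dim(img)[1:2])
  expect_identical(lab1, classify_pixels(img, clf))
})

test_that("synthetic scene pixels classify at >= 99% accuracy against ground truth", {
  sc <- render_scene(list(ear_spec(seed = 11), ear_spec(seed = 12)),
                     include_ruler = FALSE)
  clf <- fit_pixel_classifier(synth_pixel_template(ear_spec(seed = 11)))
  lab <- classify_pixels(sc$rgb, clf)
  expect_gte(mean(lab == sc$labels), 0.99)
})
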