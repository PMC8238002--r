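#' Read a pixel template table
#'
#' A pixel template holds labelled exemplar pixels used to train the
#' supervised background / cob / kernel classifier. The file is a CSV with
#' columns `R`, `G`, `B` (0-255) and `class` (one of `"background"`, `"cob"`,
#' `"kernel"`).
#'
#' @param path Path to the template CSV.
#' @return A tibble with columns `R`, `G`, `B`, `class`.
#' @export
read_pixel_template <- function(path) {
  tpl <- readr::read_csv(path, show_col_types = FALSE)
  validate_pixel_template(tpl)
}

#' @noRd
validate_pixel_template <- function(template) {
  template <- as_tibble(template)
  need <- c("R", "G", "B", "class")
  miss <- setdiff(need, names(template))
  if (length(miss)) {
    abort(paste0("Pixel template is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(template$class), EP_CLASSES)
  if (length(bad)) {
    abort(paste0("Unknown pixel class(es) in template: ",
                 paste(bad, collapse = ", ")))
  }
  for (cl in EP_CLASSES) {
    if (!any(template$class == cl)) {
      abort(sprintf("Pixel template has no exemplar for class '%s'.", cl))
    }
  }
  template
}

#' Fit the supervised pixel classifier
#'
#' Trains a nearest-centroid classifier in CIELAB space from labelled exemplar
#' pixels. Each class (background, cob, kernel) is represented by the centroid
#' of its exemplars after conversion from sRGB to CIELAB; a query colour is
#' assigned to the class with the smallest Euclidean distance to its centroid.
#' Distance ties are broken by the fixed class order
#' background < cob < kernel.
#'
#' @param template A data frame with columns `R`, `G`, `B` (0-255) and
#'   `class`, with at least one exemplar per class (see
#'   [read_pixel_template()]).
#' @return An object of class `pixel_classifier`.
#' @examples
#' tpl <- tibble::tibble(
#'   R = c(20, 150, 230), G = c(20, 75, 190), B = c(30, 50, 60),
#'   class = c("background", "cob", "kernel"))
#' clf <- fit_pixel_classifier(tpl)
#' predict_pixel_class(clf, matrix(c(230, 190, 60), ncol = 3))
#' @export
fit_pixel_classifier <- function(template) {
  template <- validate_pixel_template(template)
  lab <- rgb_to_lab(as.matrix(template[, c("R", "G", "B")]) / 255)
  centroids <- t(vapply(EP_CLASSES, function(cl) {
    colMeans(lab[template$class == cl, , drop = FALSE])
  }, numeric(3)))
  structure(
    list(centroids = centroids, classes = EP_CLASSES,
         n_exemplars = table(factor(template$class, EP_CLASSES))),
    class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier> nearest CIELAB centroid\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' Predict pixel classes for raw colours
#'
#' @param classifier A [fit_pixel_classifier()] object.
#' @param rgb An n x 3 matrix of colours, 0-255 or [0,1].
#' @return Character vector of class labels.
#' @export
predict_pixel_class <- function(classifier, rgb) {
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3L) abort("`rgb` must have three columns.")
  if (nrow(rgb) && max(rgb) > 1) rgb <- rgb / 255
  lab <- rgb_to_lab(rgb)
  classifier$classes[lab_argmin_class(lab, classifier$centroids)]
}

# Row-wise argmin of distance to class centroids with first-wins tie-break.
#' @noRd
lab_argmin_class <- function(lab, centroids) {
  best_d <- rep(Inf, nrow(lab))
  best_k <- rep(1L, nrow(lab))
  for (k in seq_len(nrow(centroids))) {
    d <- (lab[, 1] - centroids[k, 1])^2 +
         (lab[, 2] - centroids[k, 2])^2 +
         (lab[, 3] - centroids[k, 3])^2
    better <- d < best_d          # strict: ties keep the earlier class
    best_d[better] <- d[better]
    best_k[better] <- k
  }
  best_k
}

#' Classify every pixel of an image
#'
#' Applies the supervised classifier pixel-wise, then (optionally) median
#' smoothing of the integer label image to suppress isolated misclassified
#' pixels, mimicking the light spatial filtering of ear-photometry platforms.
#'
#' @param image H x W x 3 RGB array (0-255 integers or [0,1] doubles).
#' @param classifier A [fit_pixel_classifier()] object.
#' @param smooth_radius Median filter radius in pixels applied to the label
#'   image; `0` disables smoothing. Default 1.
#' @return An integer label matrix (H x W) with values 1 = background,
#'   2 = cob, 3 = kernel and attribute `classes`.
#' @export
classify_pixels <- function(image, classifier, smooth_radius = 1L) {
  a <- as_rgb_array(image)
  h <- dim(a)[1]; w <- dim(a)[2]
  lab <- rgb_to_lab(cbind(as.vector(a[, , 1]), as.vector(a[, , 2]),
                          as.vector(a[, , 3])))
  labels <- matrix(lab_argmin_class(lab, classifier$centroids), h, w)
  if (smooth_radius >= 1 && h > 2 * smooth_radius && w > 2 * smooth_radius) {
    sm <- EBImage::medianFilter(labels / 3, as.integer(smooth_radius))
    labels <- matrix(as.integer(round(sm * 3)), h, w)
    labels[labels < 1L] <- 1L; labels[labels > 3L] <- 3L
  }
  storage.mode(labels) <- "integer"
  attr(labels, "classes") <- EP_CLASSES
  labels
}

#' Calibrate the pixel-to-centimetre scale from a ruler image
#'
#' Length measurements are calibrated against a reference image containing a
#' high-contrast bar of known physical length. The bar is found by Otsu
#' thresholding of the grey image (the side of the threshold with fewer pixels
#' is taken as the bar), keeping the largest connected component, and
#' measuring its longest bounding-box extent in pixels.
#'
#' @param ruler_image RGB array of the ruler image.
#' @param known_length_cm Physical bar length in centimetres (> 0).
#' @return A one-row tibble with columns `px_per_cm`, `bar_px`,
#'   `known_length_cm`.
#' @export
calibrate_scale <- function(ruler_image, known_length_cm) {
  ep_stopifnot_scalar_num(known_length_cm, "known_length_cm", positive = TRUE)
  a <- as_rgb_array(ruler_image)
  grey <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
  if (max(grey) - min(grey) < 0.05) {
    abort("Calibration failed: no bar-like region found in the ruler image.")
  }
  thr <- EBImage::otsu(grey, range = range(grey))
  fg <- grey > thr
  if (sum(fg) > length(fg) / 2) fg <- !fg   # bar is the minority phase
  cc <- EBImage::bwlabel(matrix(as.integer(fg), nrow(fg)))
  sizes <- tabulate(cc[cc > 0])
  if (!length(sizes)) {
    abort("Calibration failed: no bar-like region found in the ruler image.")
  }
  bar <- cc == which.max(sizes)
  bb <- mask_bbox(bar)
  ext_r <- bb$r1 - bb$r0 + 1L
  ext_c <- bb$c1 - bb$c0 + 1L
  long <- max(ext_r, ext_c); short <- min(ext_r, ext_c)
  if (long < 3 * short) {
    abort("Calibration failed: largest foreground region is not bar-like (aspect < 3).")
  }
  tibble(px_per_cm = long / known_length_cm, bar_px = long,
         known_length_cm = known_length_cm)
}
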