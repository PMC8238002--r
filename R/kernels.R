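#' Delineate kernel crowns on an ear
#'
#' Marker-controlled watershed segmentation of the kernel-class mask of an
#' aligned ear. The Euclidean distance transform of the kernel mask is
#' smoothed with a Gaussian; its regional maxima, thinned so that no two
#' markers are closer than `min_separation_frac` times the expected kernel
#' width, seed a watershed (region growing constrained to the kernel mask).
#' Each region becomes one kernel-crown instance; regions with physical area
#' outside `[min_area_cm2, max_area_cm2]` are discarded.
#'
#' @param ear An [ear_instance()].
#' @param expected_kernel_width_cm Expected crown width (cm) used to scale the
#'   marker separation. Default 0.46.
#' @param min_separation_frac Minimum marker separation as a fraction of the
#'   expected kernel width. Default 0.6.
#' @param smooth_sigma_px Gaussian sigma (px) applied to the distance
#'   transform before peak finding, at the reference resolution of
#'   20 px/cm; internally rescaled with the actual calibration. Default 1.
#' @param min_area_cm2,max_area_cm2 Physical area bounds for a valid crown.
#'   Defaults 0.05 and 1.5 cm2.
#' @return A tibble with one row per detected kernel: `kernel` (id),
#'   `centroid_x_cm`, `centroid_y_cm` (ear frame: x transverse from the left
#'   mask edge, y axial from the tip), `area_cm2`, `major_cm`, `minor_cm`,
#'   `feret_max_cm`, `feret_min_cm`, `perimeter_cm`. Empty kernel mask (fully
#'   aborted ear) gives zero rows.
#' @export
detect_kernels <- function(ear,
                           expected_kernel_width_cm = 0.46,
                           min_separation_frac = 0.6,
                           smooth_sigma_px = 1,
                           min_area_cm2 = 0.05,
                           max_area_cm2 = 1.5) {
  stopifnot(inherits(ear, "ear_instance"))
  empty <- tibble(kernel = integer(), centroid_x_cm = numeric(),
                  centroid_y_cm = numeric(), area_cm2 = numeric(),
                  major_cm = numeric(), minor_cm = numeric(),
                  feret_max_cm = numeric(), feret_min_cm = numeric(),
                  perimeter_cm = numeric())
  km <- ear$kernel_mask
  if (!any(km)) return(empty)
  ppc <- ear$px_per_cm

  dm <- EBImage::imageData(EBImage::distmap(matrix(as.integer(km), nrow(km))))
  sigma <- smooth_sigma_px * ppc / 20
  sm <- if (sigma > 0.05) {
    EBImage::imageData(EBImage::gblur(dm, sigma = sigma))
  } else dm

  # regional maxima via grayscale dilation with a disc of the marker radius
  sep_px <- max(1, round(min_separation_frac * expected_kernel_width_cm * ppc))
  brush_size <- 2L * as.integer(sep_px) + 1L
  mx <- EBImage::imageData(
    EBImage::dilate(sm, EBImage::makeBrush(brush_size, "disc")))
  peaks <- (abs(sm - mx) < 1e-9) & km & (dm > 0.5)
  if (!any(peaks)) return(empty)
  seeds <- EBImage::bwlabel(matrix(as.integer(peaks), nrow(peaks)))

  regions <- EBImage::imageData(EBImage::propagate(
    x = sm, seeds = seeds, mask = matrix(as.integer(km), nrow(km))))
  regions[!km] <- 0

  measure_regions(regions, ppc, min_area_cm2, max_area_cm2, empty)
}

# Shape measurements for labelled kernel regions -> tidy tibble.
#' @noRd
measure_regions <- function(regions, ppc, min_area_cm2, max_area_cm2, empty) {
  ids <- sort(unique(regions[regions > 0]))
  if (!length(ids)) return(empty)
  sh <- EBImage::computeFeatures.shape(regions)
  mo <- EBImage::computeFeatures.moment(regions)
  # computeFeatures returns rows for labels 1..max present; index by id
  area_cm2 <- sh[ids, "s.area"] / ppc^2
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    idx <- which(regions == id, arr.ind = TRUE)
    fer <- feret_diameters(idx)
    tibble(
      kernel = i,
      # computeFeatures on a [row,col] matrix reports cx along rows (axial,
      # from tip) and cy along cols (transverse); map to the ear frame.
      centroid_x_cm = mean(idx[, 2]) / ppc,
      centroid_y_cm = mean(idx[, 1]) / ppc,
      area_cm2 = area_cm2[i],
      major_cm = mo[id, "m.majoraxis"] / ppc,
      minor_cm = mo[id, "m.majoraxis"] *
        sqrt(1 - mo[id, "m.eccentricity"]^2) / ppc,
      feret_max_cm = fer[1] / ppc,
      feret_min_cm = fer[2] / ppc,
      # crowns are convex: hull polygon length, offset out by the half-pixel
      # border (adds exactly pi for a convex shape)
      perimeter_cm = (convex_perimeter(idx) + pi) / ppc)
  })
  out <- bind_rows(rows)
  out <- out[out$area_cm2 >= min_area_cm2 & out$area_cm2 <= max_area_cm2, ,
             drop = FALSE]
  out$kernel <- seq_len(nrow(out))
  out
}

# Convex-hull polygon length (px) of a pixel-centre set.
#' @noRd
convex_perimeter <- function(idx) {
  pts <- unique(idx)
  if (nrow(pts) < 3L) return(2 * (nrow(pts) - 1))
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d <- rbind(diff(hull), hull[1, ] - hull[nrow(hull), ])
  sum(sqrt(rowSums(d^2)))
}

# Max and min Feret diameters (px) of a pixel set from its convex hull.
# Max: largest pairwise hull-vertex distance (+1 px for pixel extent).
# Min: smallest projection width over hull edge normals.
#' @noRd
feret_diameters <- function(idx) {
  pts <- unique(idx)
  if (nrow(pts) == 1L) return(c(1, 1))
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(hull)
  if (n == 2L) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(c(d + 1, 1))
  }
  dmax <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (hull[-seq_len(i), 1, drop = TRUE] - hull[i, 1])^2 +
          (hull[-seq_len(i), 2, drop = TRUE] - hull[i, 2])^2
    dmax <- max(dmax, d2)
  }
  dmax <- sqrt(dmax)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    dmin <- min(dmin, max(proj) - min(proj))
  }
  # +1: convert between lattice-point span and pixel-box extent
  c(dmax + 1, dmin + 1)
}

#' Summarise per-ear kernel geometry
#'
#' Per-ear means of crown area, axes, Feret diameters and perimeter. An empty
#' kernel table (fully aborted ear) yields `n_kernels = 0` and missing values.
#'
#' @param kernels Tibble from [detect_kernels()].
#' @return One-row tibble: `n_kernels`, `mean_area_cm2`, `mean_major_cm`,
#'   `mean_minor_cm`, `mean_feret_max_cm`, `mean_feret_min_cm`,
#'   `mean_perimeter_cm`, `mean_diameter_cm` (per-kernel mean of the two
#'   Feret diameters, averaged over kernels).
#' @export
summarize_kernel_geometry <- function(kernels) {
  if (!nrow(kernels)) {
    return(tibble(n_kernels = 0L, mean_area_cm2 = NA_real_,
                  mean_major_cm = NA_real_, mean_minor_cm = NA_real_,
                  mean_feret_max_cm = NA_real_, mean_feret_min_cm = NA_real_,
                  mean_perimeter_cm = NA_real_, mean_diameter_cm = NA_real_))
  }
  tibble(
    n_kernels = nrow(kernels),
    mean_area_cm2 = mean(kernels$area_cm2),
    mean_major_cm = mean(kernels$major_cm),
    mean_minor_cm = mean(kernels$minor_cm),
    mean_feret_max_cm = mean(kernels$feret_max_cm),
    mean_feret_min_cm = mean(kernels$feret_min_cm),
    mean_perimeter_cm = mean(kernels$perimeter_cm),
    mean_diameter_cm = mean((kernels$feret_max_cm + kernels$feret_min_cm) / 2))
}
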