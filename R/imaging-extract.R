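#' Construct an ear instance from class masks
#'
#' Low-level constructor used by [extract_ear_instances()] and by code that
#' builds ears directly from labelled patches. The ear mask is the union of
#' the cob and kernel masks; the two class masks must be disjoint.
#'
#' @param kernel_mask,cob_mask Logical matrices of identical shape.
#' @param px_per_cm Pixels per centimetre (> 0).
#' @param angle Rotation (radians) that was applied to align the ear.
#' @param bbox Half-open bounding box in the source image,
#'   `c(r0, r1, c0, c1)`, or `NULL`.
#' @param ear_index Left-to-right ordinal of the ear in its scene.
#' @return An object of class `ear_instance`.
#' @export
ear_instance <- function(kernel_mask, cob_mask, px_per_cm, angle = 0,
                         bbox = NULL, ear_index = 1L) {
  stopifnot(is.logical(kernel_mask), is.logical(cob_mask),
            identical(dim(kernel_mask), dim(cob_mask)))
  ep_stopifnot_scalar_num(px_per_cm, "px_per_cm", positive = TRUE)
  if (any(kernel_mask & cob_mask)) {
    abort("kernel_mask and cob_mask must be disjoint.")
  }
  structure(
    list(ear_mask = kernel_mask | cob_mask,
         kernel_mask = kernel_mask,
         cob_mask = cob_mask,
         px_per_cm = px_per_cm,
         angle = angle,
         bbox = bbox,
         ear_index = as.integer(ear_index)),
    class = "ear_instance")
}

#' @export
print.ear_instance <- function(x, ...) {
  cat(sprintf(
    "<ear_instance #%d> %d x %d px @ %.2f px/cm; area %.1f cm2 (%.0f%% kernel)\n",
    x$ear_index, nrow(x$ear_mask), ncol(x$ear_mask), x$px_per_cm,
    sum(x$ear_mask) / x$px_per_cm^2,
    100 * sum(x$kernel_mask) / max(1, sum(x$ear_mask))))
  invisible(x)
}

#' Extract individual ears from a classified scene
#'
#' Takes the per-pixel label image of a scene of ears photographed side by
#' side and returns one aligned [ear_instance()] per ear. Foreground
#' (cob or kernel) pixels are closed morphologically, split into connected
#' components, filtered by minimum physical area, ordered left to right by
#' centroid column, and rotated so that the principal axis of each mask is
#' vertical with the tip (the end with the smaller mean width) up.
#'
#' Pixels absorbed into an ear by the morphological closing that were not
#' classified as kernel are assigned to the cob mask, so that the kernel and
#' cob masks always partition the ear mask.
#'
#' @param labels Integer label matrix from [classify_pixels()].
#' @param calibration One-row data frame with `px_per_cm` (from
#'   [calibrate_scale()]), or a single number.
#' @param min_area_cm2 Minimum physical ear area; smaller components are
#'   discarded. Default 10 cm2.
#' @param closing_radius Radius (px) of the disc used for morphological
#'   closing. Default 3.
#' @return A list of `ear_instance` objects (possibly empty, with a warning).
#' @export
extract_ear_instances <- function(labels, calibration, min_area_cm2 = 10,
                                  closing_radius = 3L) {
  px_per_cm <- if (is.data.frame(calibration)) calibration$px_per_cm[[1]]
               else calibration
  ep_stopifnot_scalar_num(px_per_cm, "px_per_cm", positive = TRUE)
  fg <- matrix(as.integer(labels > 1L), nrow(labels))
  if (closing_radius >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    fg <- EBImage::closing(fg, brush)
  }
  cc <- EBImage::bwlabel(fg)
  n_cc <- max(cc)
  if (n_cc == 0) {
    warn("No ears found in scene.")
    return(list())
  }
  min_px <- min_area_cm2 * px_per_cm^2
  keep <- which(tabulate(cc[cc > 0], n_cc) >= min_px)
  if (!length(keep)) {
    warn("No ears left after minimum-area filtering.")
    return(list())
  }
  # order left to right by centroid column
  cent_col <- vapply(keep, function(k) mean(which(cc == k, arr.ind = TRUE)[, 2]),
                     numeric(1))
  keep <- keep[order(cent_col)]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    comp <- cc == keep[i]
    bb <- mask_bbox(comp)
    crop <- comp[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
    lab_crop <- labels[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
    # 0 outside the component; closed-in unlabelled pixels count as cob
    cls <- matrix(0L, nrow(crop), ncol(crop))
    cls[crop] <- ifelse(lab_crop[crop] == 3L, 3L, 2L)
    aligned <- align_ear_labels(cls)
    out[[i]] <- ear_instance(
      kernel_mask = aligned$labels == 3L,
      cob_mask = aligned$labels == 2L,
      px_per_cm = px_per_cm,
      angle = aligned$angle,
      bbox = c(r0 = bb$r0 - 1L, r1 = bb$r1, c0 = bb$c0 - 1L, c1 = bb$c1),
      ear_index = i)
  }
  out
}

# Rotate a cropped component label matrix (0 / 2 / 3) so its principal axis is
# vertical, tip (narrow end) up; returns list(labels, angle).
#' @noRd
align_ear_labels <- function(cls) {
  idx <- which(cls > 0L, arr.ind = TRUE)
  v <- principal_axis(idx)
  theta <- atan2(v[2], v[1])   # angle of major axis from the row (vertical) axis
  rot <- rotate_nn(cls, -theta, fill = 0L)
  bb <- mask_bbox(rot > 0L)
  rot <- rot[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
  angle <- theta
  # tip up: compare mean occupied width over the outer 10% of length
  occ <- rot > 0L
  wid <- apply(occ, 1, function(r) {
    w <- which(r); if (length(w)) max(w) - min(w) + 1L else 0L
  })
  span <- which(wid > 0)
  k <- max(1L, floor(0.10 * length(span)))
  top <- mean(wid[span[seq_len(k)]])
  bot <- mean(wid[span[seq(length(span) - k + 1L, length(span))]])
  if (top > bot) {
    rot <- rot[rev(seq_len(nrow(rot))), , drop = FALSE]
    angle <- angle + pi
  }
  list(labels = rot, angle = angle)
}

# Unit eigenvector (dr, dc) of the coordinate covariance, dr >= 0.
#' @noRd
principal_axis <- function(idx) {
  if (nrow(idx) < 2L) return(c(1, 0))
  cv <- stats::cov(idx)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v
  v
}
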