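# Internal helpers shared across the imaging stack.

# Pixel class codes; order is the documented tie-break order.
EP_CLASSES <- c("background", "cob", "kernel")

#' @noRd
ep_stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# Coerce an RGB image to a [0,1] double array [row, col, channel].
# Accepts H x W x 3 arrays in [0,1] or integer 0..255, or an EBImage Image
# (stored x,y -> transposed back to row, col).
#' @noRd
as_rgb_array <- function(image) {
  if (inherits(image, "Image")) {
    a <- EBImage::imageData(image)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a <- aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    return(a)
  }
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort("`image` must be an H x W x 3 RGB array (three channels exactly).")
  }
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) {
    abort("`image` must have at least one row and one column.")
  }
  a <- image * 1.0
  if (max(a, na.rm = TRUE) > 1) a <- a / 255
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

# sRGB [0,1] n x 3 matrix -> CIELAB n x 3 matrix.
#' @noRd
rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

# Bounding box of TRUE cells of a logical matrix: list(r0, r1, c0, c1), or NULL.
#' @noRd
mask_bbox <- function(mask) {
  rr <- which(rowSums(mask) > 0)
  cc <- which(colSums(mask) > 0)
  if (!length(rr)) return(NULL)
  list(r0 = min(rr), r1 = max(rr), c0 = min(cc), c1 = max(cc))
}

# Nearest-neighbour rotation of an integer/logical matrix about its centre.
# `angle` in radians, counter-clockwise in (row, col) coordinates; cells that
# map outside the source get `fill`. Output canvas is enlarged to hold the
# rotated content.
#' @noRd
rotate_nn <- function(m, angle, fill = 0L) {
  if (abs(angle) < 1e-12) return(m)
  h <- nrow(m); w <- ncol(m)
  ca <- cos(angle); sa <- sin(angle)
  hw <- abs(ca) * h + abs(sa) * w
  ww <- abs(sa) * h + abs(ca) * w
  H <- ceiling(hw); W <- ceiling(ww)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  CR <- (H + 1) / 2; CC <- (W + 1) / 2
  out_r <- rep(seq_len(H), times = W) - CR
  out_c <- rep(seq_len(W), each = H) - CC
  # inverse map: rotate output coords by -angle back into source frame
  src_r <- round(ca * out_r + sa * out_c + cr)
  src_c <- round(-sa * out_r + ca * out_c + cc)
  ok <- src_r >= 1L & src_r <= h & src_c >= 1L & src_c <= w
  out <- matrix(fill, H, W)
  out[ok] <- m[cbind(src_r[ok], src_c[ok])]
  out
}

# Perimeter (in pixels) of a binary mask via EBImage shape features.
#' @noRd
mask_perimeter_px <- function(mask) {
  if (!any(mask)) return(0)
  f <- EBImage::computeFeatures.shape(matrix(as.integer(mask), nrow(mask)))
  sum(f[, "s.perimeter"])
}

#' @noRd
sig_code <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}
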