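# Synthetic ear renderer: scenes with known geometry, kernel grids, abortion
# and scatter, plus a ruler bar, giving closed-form ground truth for the
# whole imaging stack.

# run code with a private RNG stream; global .Random.seed is untouched
#' @noRd
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic ear
#'
#' Parameters of one rendered maize ear. The silhouette is a half
#' superellipse: the half-width at axial position `s` (cm from the tip) is
#' `(max_width_cm/2) * (1 - u^n)^(1/n)` with `u = 1 - s/length_cm` and
#' `n = taper_power`, so all silhouette traits have closed forms. Kernel
#' crowns are ellipses with the major axis along the ear axis, laid on a
#' `visible_rows` x `kernels_per_row` grid over the non-aborted span; a
#' `scatter_frac` fraction of grid sites is removed (seeded), and the distal
#' `abortion_frac` of the length is bare cob.
#'
#' Defaults portray a typical dried Corn-Belt dent ear (about 19 x 5.2 cm,
#' 16 total kernel rows of which 8 face the camera, 18 kernels per row,
#' crowns 0.87 x 0.46 cm).
#'
#' @param length_cm,max_width_cm Ear length and maximum width (cm).
#' @param taper_power Superellipse exponent; larger is boxier. Default 8.
#' @param visible_rows Kernel-row tracks facing the camera. Default 8.
#' @param kernels_per_row Kernel sites per track. Default 18.
#' @param crown_major_cm,crown_minor_cm Crown ellipse axes (cm); the major
#'   axis runs along the ear axis. Defaults 0.87 and 0.46.
#' @param abortion_frac Fraction of length (from the tip) with aborted,
#'   kernel-free cob. Default 0.05.
#' @param scatter_frac Fraction of kernel sites lost to scatter. Default 0.03.
#' @param track_extent_frac Fraction of the maximum width spanned by the row
#'   tracks. Default 0.85.
#' @param kernel_color,cob_color,background_color RGB triples (0-255).
#' @param color_jitter_sd Per-pixel Gaussian colour jitter SD (0-255 scale).
#' @param seed Integer seed for scatter sites and colour jitter.
#' @return A list of class `ear_spec`.
#' @export
ear_spec <- function(length_cm = 19, max_width_cm = 5.2, taper_power = 8,
                     visible_rows = 8, kernels_per_row = 18,
                     crown_major_cm = 0.87, crown_minor_cm = 0.46,
                     abortion_frac = 0.05, scatter_frac = 0.03,
                     track_extent_frac = 0.85,
                     kernel_color = c(230, 190, 60),
                     cob_color = c(150, 75, 50),
                     background_color = c(40, 40, 48),
                     color_jitter_sd = 5, seed = 1L) {
  spec <- list(length_cm = length_cm, max_width_cm = max_width_cm,
               taper_power = taper_power, visible_rows = visible_rows,
               kernels_per_row = kernels_per_row,
               crown_major_cm = crown_major_cm,
               crown_minor_cm = crown_minor_cm,
               abortion_frac = abortion_frac, scatter_frac = scatter_frac,
               track_extent_frac = track_extent_frac,
               kernel_color = kernel_color, cob_color = cob_color,
               background_color = background_color,
               color_jitter_sd = color_jitter_sd, seed = as.integer(seed))
  with(spec, {
    stopifnot(length_cm > 0, max_width_cm > 0, taper_power > 0,
              visible_rows >= 1, kernels_per_row >= 0,
              crown_major_cm > 0, crown_minor_cm > 0,
              abortion_frac >= 0, abortion_frac <= 1,
              scatter_frac >= 0, scatter_frac <= 1,
              track_extent_frac > 0, track_extent_frac <= 1)
  })
  class(spec) <- "ear_spec"
  spec
}

# silhouette half-width (cm) at axial position s (cm from tip)
#' @noRd
ear_half_width <- function(spec, s) {
  u <- pmin(pmax(1 - s / spec$length_cm, 0), 1)
  n <- spec$taper_power
  (spec$max_width_cm / 2) * (1 - u^n)^(1 / n)
}

# \int_0^1 (1 - u^n)^(m) du = B(1/n, m + 1) / n
#' @noRd
superellipse_integral <- function(n, m) {
  beta(1 / n, m + 1) / n
}

# kernel site table: one row per surviving crown (axial s, transverse x from
# ear midline), plus the removed scatter sites flagged
#' @noRd
ear_kernel_sites <- function(spec) {
  R <- spec$visible_rows; K <- spec$kernels_per_row
  if (K == 0 || spec$abortion_frac >= 1) {
    return(tibble(s_cm = numeric(), x_cm = numeric(),
                  track = integer(), scattered = logical()))
  }
  L <- spec$length_cm
  a <- spec$abortion_frac
  maj <- spec$crown_major_cm
  span <- L * (1 - a)
  if (K == 1) {
    s <- L * a + span / 2
  } else {
    # first crown tangent to the abortion boundary, last tangent to the butt
    pitch <- (span - maj) / (K - 1)
    s <- L * a + maj / 2 + (seq_len(K) - 1) * pitch
  }
  E <- spec$track_extent_frac * spec$max_width_cm
  x <- -E / 2 + (seq_len(R) - 0.5) * (E / R)
  sites <- tibble(
    s_cm = rep(s, times = R),
    x_cm = rep(x, each = K),
    track = rep(seq_len(R), each = K),
    scattered = FALSE)
  n_sct <- round(spec$scatter_frac * nrow(sites))
  if (n_sct > 0) {
    drop <- with_seed(spec$seed, sample(nrow(sites), n_sct))
    sites$scattered[drop] <- TRUE
  }
  sites
}

# verify every crown lies strictly inside the silhouette and crowns cannot
# touch; abort with a spec error otherwise
#' @noRd
validate_crown_layout <- function(spec, sites) {
  if (!nrow(sites)) return(invisible(TRUE))
  maj <- spec$crown_major_cm; mnr <- spec$crown_minor_cm
  K <- spec$kernels_per_row
  if (K > 1) {
    pitch <- (spec$length_cm * (1 - spec$abortion_frac) - maj) / (K - 1)
    if (maj >= pitch) {
      abort(sprintf(
        "ear_spec error: crown major axis (%.2f cm) >= axial pitch (%.2f cm); crowns would touch. Reduce kernels_per_row or crown size.",
        maj, pitch))
    }
  }
  if (spec$visible_rows > 1) {
    spacing <- spec$track_extent_frac * spec$max_width_cm / spec$visible_rows
    if (mnr >= spacing) {
      abort(sprintf(
        "ear_spec error: crown minor axis (%.2f cm) >= track spacing (%.2f cm); crowns would touch. Reduce visible_rows or crown size.",
        mnr, spacing))
    }
  }
  th <- seq(0, 2 * pi, length.out = 33)
  for (i in seq_len(nrow(sites))) {
    bs <- sites$s_cm[i] + (maj / 2) * cos(th)
    bx <- abs(sites$x_cm[i] + (mnr / 2) * sin(th))
    if (any(bx > ear_half_width(spec, bs) - 1e-9)) {
      abort(sprintf(
        "ear_spec error: crown at s=%.2f cm, x=%.2f cm extends outside the ear silhouette. Reduce track_extent_frac, visible_rows or crown size.",
        sites$s_cm[i], sites$x_cm[i]))
    }
  }
  invisible(TRUE)
}

#' Render one synthetic ear
#'
#' Rasterises an [ear_spec()] at the requested resolution and returns the RGB
#' patch, the ground-truth label patch (1 = background, 2 = cob, 3 = kernel)
#' and a one-row tibble of true trait values computed in closed form from the
#' spec (silhouette integrals of the superellipse profile, crown ellipse
#' geometry, and the realised kernel-site table).
#'
#' @param spec An [ear_spec()].
#' @param px_per_cm Rendering resolution. Default 20.
#' @return List with elements `rgb` (H x W x 3 array in `[0,1]`), `labels`
#'   (H x W integer matrix), `truth` (one-row tibble), `sites` (kernel site
#'   tibble).
#' @export
render_ear <- function(spec, px_per_cm = 20) {
  stopifnot(inherits(spec, "ear_spec"))
  ep_stopifnot_scalar_num(px_per_cm, "px_per_cm", positive = TRUE)
  sites <- ear_kernel_sites(spec)
  validate_crown_layout(spec, sites)
  live <- sites[!sites$scattered, , drop = FALSE]

  L <- spec$length_cm; W <- spec$max_width_cm
  H <- ceiling(L * px_per_cm); Wpx <- ceiling(W * px_per_cm)
  s <- (seq_len(H) - 0.5) / px_per_cm           # axial, cm from tip (row 1)
  x <- (seq_len(Wpx) - 0.5) / px_per_cm - W / 2 # transverse, cm from midline
  hw <- ear_half_width(spec, s)
  inside <- outer(hw, abs(x), `>=`)
  labels <- matrix(1L, H, Wpx)
  labels[inside] <- 2L

  maj2 <- spec$crown_major_cm / 2; mnr2 <- spec$crown_minor_cm / 2
  for (i in seq_len(nrow(live))) {
    rr <- which(abs(s - live$s_cm[i]) <= maj2)
    cc <- which(abs(x - live$x_cm[i]) <= mnr2)
    if (!length(rr) || !length(cc)) next
    ds <- (s[rr] - live$s_cm[i]) / maj2
    dx <- (x[cc] - live$x_cm[i]) / mnr2
    ell <- outer(ds^2, dx^2, `+`) <= 1
    sub <- labels[rr, cc, drop = FALSE]
    sub[ell] <- 3L
    labels[rr, cc] <- sub
  }

  cols <- rbind(spec$background_color, spec$cob_color, spec$kernel_color) / 255
  rgb <- array(0, c(H, Wpx, 3))
  jit <- spec$color_jitter_sd / 255
  noise <- if (jit > 0) {
    with_seed(spec$seed + 1L, array(rnorm(H * Wpx * 3, 0, jit), c(H, Wpx, 3)))
  } else array(0, c(H, Wpx, 3))
  for (ch in 1:3) {
    base <- matrix(cols[labels, ch], H, Wpx)
    rgb[, , ch] <- pmin(pmax(base + noise[, , ch], 0), 1)
  }

  list(rgb = rgb, labels = labels,
       truth = ear_truth(spec, sites), sites = sites)
}

# closed-form true traits for a spec and its realised kernel sites
#' @noRd
ear_truth <- function(spec, sites) {
  L <- spec$length_cm; W <- spec$max_width_cm; n <- spec$taper_power
  a <- spec$abortion_frac
  maj <- spec$crown_major_cm; mnr <- spec$crown_minor_cm
  live <- sites[!sites$scattered, , drop = FALSE]
  n_vis <- nrow(live)

  I1 <- superellipse_integral(n, 1 / n)
  I2 <- superellipse_integral(n, 2 / n)
  area <- W * L * I1
  vol <- pi * (W / 2)^2 * L * I2

  # central 10% band mean width and tip-region quantities (numeric quadrature)
  wfun <- function(ss) 2 * ear_half_width(spec, ss)
  cw <- stats::integrate(wfun, 0.45 * L, 0.55 * L,
                         rel.tol = 1e-10)$value / (0.1 * L)
  tip_len <- 0.2 * L
  tip_area <- stats::integrate(wfun, 0, tip_len, rel.tol = 1e-10)$value
  tip_base_w <- wfun(tip_len)
  # silhouette arc length (fine polyline; slope is unbounded at the tip) + butt
  ss <- seq(0, L, length.out = 20001L)
  hh <- ear_half_width(spec, ss)
  per <- 2 * sum(sqrt(diff(ss)^2 + diff(hh)^2)) + W

  ker_area <- pi * maj * mnr / 4
  abort_area <- stats::integrate(wfun, 0, a * L, rel.tol = 1e-10)$value
  kerfil <- 100 * n_vis * ker_area / area
  sctter <- 100 * (area - abort_area - n_vis * ker_area) / area
  tkerab <- 100 * a

  # Ramanujan II ellipse perimeter
  aa <- maj / 2; bb <- mnr / 2
  h <- ((aa - bb) / (aa + bb))^2
  ker_per <- pi * (aa + bb) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))

  kercc <- sum(live$s_cm >= 0.25 * L & live$s_cm <= 0.75 * L)
  R <- spec$visible_rows; K <- spec$kernels_per_row
  phtkr <- 2 * R
  phtkpr <- K
  phtkpe <- phtkr * phtkpr * (1 - sctter / 100)
  kerwgt <- 0.8 * ker_area
  tibble(
    EARLGT = L, EARWTH = W, EARCW = cw, EARAREA = area, EARPER = per,
    EARBOX = I1, EARVOL = vol,
    EARTR = 100 * tip_area / (tip_len * tip_base_w),
    ETB = 100 * tip_area / (tip_len * tip_base_w),
    KERFIL = kerfil, SCTTER = sctter, TKERAB = tkerab,
    KERARE = ker_area, KERLEN = maj, KERWTH = mnr, KERMAXD = maj,
    KERMIND = mnr, KERMEAND = (maj + mnr) / 2, KERPER = ker_per,
    KERCC = kercc, PHTKR = phtkr, PHTKPR = phtkpr, PHTKPE = phtkpe,
    KERWGT = kerwgt, PHTYLD = kerwgt * phtkpe,
    n_visible_kernels = n_vis)
}

#' Render a calibration ruler image
#'
#' A single high-contrast horizontal bar of exactly
#' `round(length_cm * px_per_cm)` pixels on the scene background.
#'
#' @param length_cm Physical bar length (cm).
#' @param px_per_cm Rendering resolution.
#' @param bar_height_cm Bar height. Default 0.5 cm.
#' @param margin_cm Border margin. Default 1 cm.
#' @param background_color,bar_color RGB triples (0-255).
#' @return List with `rgb` array and `bar_px` (true bar length in pixels).
#' @export
render_ruler <- function(length_cm, px_per_cm = 20, bar_height_cm = 0.5,
                         margin_cm = 1,
                         background_color = c(40, 40, 48),
                         bar_color = c(100, 100, 100)) {
  ep_stopifnot_scalar_num(length_cm, "length_cm", positive = TRUE)
  bar_px <- round(length_cm * px_per_cm)
  bar_h <- max(2L, round(bar_height_cm * px_per_cm))
  m <- max(2L, round(margin_cm * px_per_cm))
  H <- bar_h + 2L * m; W <- bar_px + 2L * m
  rgb <- array(rep(background_color / 255, each = H * W), c(H, W, 3))
  for (ch in 1:3) {
    rgb[(m + 1):(m + bar_h), (m + 1):(m + bar_px), ch] <- bar_color[ch] / 255
  }
  list(rgb = rgb, bar_px = bar_px)
}

#' Render a multi-ear scene
#'
#' Lays out several synthetic ears left to right (tips up) with margins on a
#' uniform background, optionally adds a ruler bar in a reserved strip below
#' the ears, and returns the composite image, the ground-truth label image,
#' and the per-ear ground-truth table keyed by left-to-right index.
#'
#' @param specs List of [ear_spec()] objects (or a single one).
#' @param px_per_cm Rendering resolution. Default 20.
#' @param margin_cm Margin around and between ears. Default 1 cm.
#' @param ruler_length_cm Ruler bar length; `0` or `include_ruler = FALSE`
#'   omits it. Default 15.
#' @param include_ruler Draw the ruler strip? Default TRUE.
#' @return List with `rgb`, `labels`, `truth` (tibble, one row per ear with
#'   column `ear` = left-to-right index), `px_per_cm`, `ruler_bar_px`.
#' @export
render_scene <- function(specs, px_per_cm = 20, margin_cm = 1,
                         ruler_length_cm = 15, include_ruler = TRUE) {
  if (inherits(specs, "ear_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  ears <- lapply(specs, render_ear, px_per_cm = px_per_cm)
  m <- max(2L, round(margin_cm * px_per_cm))
  hs <- vapply(ears, function(e) nrow(e$labels), integer(1))
  ws <- vapply(ears, function(e) ncol(e$labels), integer(1))
  ruler_h <- if (include_ruler && ruler_length_cm > 0) {
    max(2L, round(0.5 * px_per_cm)) + m
  } else 0L
  H <- m + max(hs) + m + ruler_h
  W <- m + sum(ws + m)
  if (include_ruler && ruler_length_cm > 0) {
    bar_px <- round(ruler_length_cm * px_per_cm)
    if (bar_px + 2L * m > W) {
      abort("Scene layout overflow: ruler bar wider than the scene; add ears, increase margins, or shorten the ruler.")
    }
  }
  bg <- specs[[1]]$background_color
  labels <- matrix(1L, H, W)
  rgb <- array(rep(bg / 255, each = H * W), c(H, W, 3))
  c0 <- m
  truth <- vector("list", length(ears))
  for (i in seq_along(ears)) {
    e <- ears[[i]]
    rr <- (m + 1):(m + hs[i]); cc <- (c0 + 1):(c0 + ws[i])
    labels[rr, cc] <- e$labels
    for (ch in 1:3) rgb[rr, cc, ch] <- e$rgb[, , ch]
    truth[[i]] <- mutate(e$truth, ear = i, .before = 1)
    c0 <- c0 + ws[i] + m
  }
  ruler_bar_px <- NA_integer_
  if (include_ruler && ruler_length_cm > 0) {
    ruler_bar_px <- round(ruler_length_cm * px_per_cm)
    bar_h <- max(2L, round(0.5 * px_per_cm))
    rr <- (H - ruler_h + 1):(H - ruler_h + bar_h)
    cc <- (m + 1):(m + ruler_bar_px)
    for (ch in 1:3) rgb[rr, cc, ch] <- c(100, 100, 100)[ch] / 255
  }
  list(rgb = rgb, labels = labels, truth = bind_rows(truth),
       px_per_cm = px_per_cm, ruler_bar_px = ruler_bar_px)
}

#' Pixel template matching the synthetic colour scheme
#'
#' Convenience exemplar table for [fit_pixel_classifier()]: a few seeded,
#' jittered samples of each class colour of an [ear_spec()].
#'
#' @param spec An [ear_spec()].
#' @param n_per_class Exemplars per class. Default 25.
#' @return Tibble with columns `R`, `G`, `B`, `class`.
#' @export
synth_pixel_template <- function(spec = ear_spec(), n_per_class = 25) {
  cols <- list(background = spec$background_color, cob = spec$cob_color,
               kernel = spec$kernel_color)
  with_seed(spec$seed + 2L, {
    bind_rows(lapply(names(cols), function(cl) {
      base <- matrix(rep(cols[[cl]], each = n_per_class), n_per_class)
      jit <- matrix(rnorm(3 * n_per_class, 0, spec$color_jitter_sd),
                    n_per_class)
      v <- pmin(pmax(base + jit, 0), 255)
      tibble(R = v[, 1], G = v[, 2], B = v[, 3], class = cl)
    }))
  })
}
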