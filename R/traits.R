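#' Trait-model parameters
#'
#' Constants of the parametric models that turn segmented geometry into
#' predicted counts and weights. All are configurable; defaults are chosen to
#' give realistic dent-maize magnitudes.
#'
#' @param weight_per_area Kernel weight per unit crown area (g cm-2).
#'   Default 0.8 (a 0.31 cm2 crown weighs about 0.25 g).
#' @param tip_fraction Distal fraction of ear length treated as the tip
#'   region for the tip-shape traits. Default 0.20.
#' @param central_band Central fraction of ear length used for the kernel
#'   central count. Default 0.50.
#' @param visible_to_total_factor Multiplier from camera-facing kernel rows
#'   to total rows (a single view sees about half the circumference).
#'   Default 2.
#' @param central_width_band Central fraction of length for the ear central
#'   width. Default 0.10.
#' @return A list of class `trait_model_params`.
#' @export
trait_model_params <- function(weight_per_area = 0.8, tip_fraction = 0.20,
                               central_band = 0.50,
                               visible_to_total_factor = 2,
                               central_width_band = 0.10) {
  stopifnot(weight_per_area > 0, tip_fraction > 0, tip_fraction < 1,
            central_band > 0, central_band < 1,
            visible_to_total_factor > 0,
            central_width_band > 0, central_width_band < 1)
  structure(list(weight_per_area = weight_per_area,
                 tip_fraction = tip_fraction,
                 central_band = central_band,
                 visible_to_total_factor = visible_to_total_factor,
                 central_width_band = central_width_band),
            class = "trait_model_params")
}

#' Axial width profile of an aligned ear
#'
#' Width of the ear mask at every pixel row of the aligned frame, in
#' centimetres: `(rightmost - leftmost + 1)` occupied columns times cm/px.
#' Rows inside the ear span with no mask pixels get width 0.
#'
#' @param ear An [ear_instance()].
#' @return Tibble with columns `row` (1 = tip end), `pos_cm` (axial position
#'   of the row centre from the top of the mask) and `width_cm`.
#' @export
axial_width_profile <- function(ear) {
  stopifnot(inherits(ear, "ear_instance"))
  m <- ear$ear_mask
  wid <- apply(m, 1, function(r) {
    w <- which(r)
    if (length(w)) max(w) - min(w) + 1L else 0L
  })
  tibble(row = seq_len(nrow(m)),
         pos_cm = (seq_len(nrow(m)) - 0.5) / ear$px_per_cm,
         width_cm = wid / ear$px_per_cm)
}

#' Ear silhouette traits
#'
#' Shape traits of the whole-ear mask: length, widths, area, perimeter,
#' boxiness, solid-of-revolution volume and the tip-shape ratios.
#'
#' * `EARLGT` - axial extent of the mask (cm).
#' * `EARWTH` - maximum width (cm).
#' * `EARCW` - mean width over the central `central_width_band` of length.
#' * `EARAREA` - mask area (cm2).
#' * `EARPER` - mask boundary length (cm).
#' * `EARBOX` - `EARAREA / (EARLGT * EARWTH)`, in (0, 1].
#' * `EARVOL` - sum over rows of `pi * (w/2)^2 * dx` (cm3), treating the
#'   silhouette as a solid of revolution.
#' * `EARTR` - 100 x tip mask area / tip-region bounding-rectangle area.
#' * `ETB` - 100 x tip mask area / (tip length x width at the tip-region
#'   base). The tip region is the distal `tip_fraction` of the length.
#'
#' A degenerate mask (axial extent < 2 px) returns all values missing.
#'
#' @param ear An [ear_instance()].
#' @param profile Output of [axial_width_profile()]; computed if missing.
#' @param params A [trait_model_params()].
#' @return One-row tibble of the silhouette traits.
#' @export
silhouette_traits <- function(ear, profile = NULL,
                              params = trait_model_params()) {
  if (is.null(profile)) profile <- axial_width_profile(ear)
  ppc <- ear$px_per_cm
  occ <- which(profile$width_cm > 0)
  na_out <- tibble(EARLGT = NA_real_, EARWTH = NA_real_, EARCW = NA_real_,
                   EARAREA = NA_real_, EARPER = NA_real_, EARBOX = NA_real_,
                   EARVOL = NA_real_, EARTR = NA_real_, ETB = NA_real_)
  if (length(occ) < 2L) return(na_out)
  span <- occ[1]:occ[length(occ)]
  w <- profile$width_cm[span]
  n <- length(span)
  earlgt <- n / ppc
  earwth <- max(w)
  cb <- params$central_width_band
  mid <- (n + 1) / 2
  half <- max(1, round(cb * n / 2))
  cidx <- max(1, floor(mid - half + 0.5)):min(n, ceiling(mid + half - 0.5))
  earcw <- mean(w[cidx])
  eararea <- sum(ear$ear_mask) / ppc^2
  earper <- mask_perimeter_px(ear$ear_mask) / ppc
  earbox <- eararea / (earlgt * earwth)
  earvol <- sum(pi * (w / 2)^2) / ppc
  # tip region: distal tip_fraction of the span, tip at row 1
  tf <- params$tip_fraction
  k <- max(1L, round(tf * n))
  tip_rows <- span[seq_len(k)]
  tip_mask <- ear$ear_mask[profile$row %in% tip_rows, , drop = FALSE]
  tip_area <- sum(tip_mask) / ppc^2
  tip_len <- k / ppc
  tip_maxw <- max(profile$width_cm[tip_rows])
  base_w <- profile$width_cm[tip_rows[k]]
  eartr <- if (tip_maxw > 0) 100 * tip_area / (tip_len * tip_maxw) else NA_real_
  etb <- if (base_w > 0) 100 * tip_area / (tip_len * base_w) else NA_real_
  tibble(EARLGT = earlgt, EARWTH = earwth, EARCW = earcw, EARAREA = eararea,
         EARPER = earper, EARBOX = earbox, EARVOL = earvol,
         EARTR = eartr, ETB = etb)
}

#' Kernel fill, scatter and tip-abortion traits
#'
#' Partitions the ear area into filled kernel area, scatter losses outside
#' the aborted tip, and the aborted tip zone:
#'
#' * `KERFIL` - 100 x kernel-class area / ear area.
#' * `TKERAB` - 100 x (contiguous tip length with no kernel pixels in any
#'   column) / `EARLGT`.
#' * `SCTTER` - 100 x cob-class area outside the abortion zone / ear area.
#'
#' The identity `KERFIL + SCTTER + abortion-zone cob share = 100` holds
#' exactly.
#'
#' @inheritParams silhouette_traits
#' @return One-row tibble with `KERFIL`, `SCTTER`, `TKERAB` and
#'   `abortion_cob_pct` (the third member of the partition).
#' @export
fill_traits <- function(ear, profile = NULL, params = trait_model_params()) {
  if (is.null(profile)) profile <- axial_width_profile(ear)
  occ <- which(profile$width_cm > 0)
  if (!length(occ)) {
    return(tibble(KERFIL = NA_real_, SCTTER = NA_real_, TKERAB = NA_real_,
                  abortion_cob_pct = NA_real_))
  }
  span <- occ[1]:occ[length(occ)]
  ear_area <- sum(ear$ear_mask)
  ker_rows <- rowSums(ear$kernel_mask)[span]
  first_k <- which(ker_rows > 0)[1]
  n_abort <- if (is.na(first_k)) length(span) else first_k - 1L
  abort_rows <- if (n_abort > 0) span[seq_len(n_abort)] else integer()
  cob_abort <- sum(ear$cob_mask[abort_rows, , drop = FALSE])
  kerfil <- 100 * sum(ear$kernel_mask) / ear_area
  abort_pct <- 100 * cob_abort / ear_area
  # complement form: equal to 100 * cob-outside-abortion / ear_area in exact
  # arithmetic, and makes the three-way partition identity float-exact
  sctter <- 100 - kerfil - abort_pct
  tkerab <- 100 * n_abort / length(span)
  tibble(KERFIL = kerfil, SCTTER = sctter, TKERAB = tkerab,
         abortion_cob_pct = abort_pct)
}

#' Kernel geometry trait means
#'
#' Aggregates per-kernel crown geometry into the per-ear kernel traits:
#' `KERARE` (mean area), `KERLEN` (mean major axis), `KERWTH` (mean minor
#' axis), `KERMAXD`/`KERMIND` (mean max/min Feret diameters), `KERMEAND`
#' (mean of the per-kernel Feret midrange), `KERPER` (mean perimeter) and
#' `KERCC` (kernels whose centroid lies within the central `central_band` of
#' ear length).
#'
#' @param kernels Tibble from [detect_kernels()].
#' @param ear_length_cm Ear length used for the central band.
#' @param params A [trait_model_params()].
#' @return One-row tibble. Zero kernels give missing geometry and
#'   `KERCC = 0`.
#' @export
kernel_trait_means <- function(kernels, ear_length_cm,
                               params = trait_model_params()) {
  if (!nrow(kernels)) {
    return(tibble(KERARE = NA_real_, KERLEN = NA_real_, KERWTH = NA_real_,
                  KERMAXD = NA_real_, KERMIND = NA_real_,
                  KERMEAND = NA_real_, KERPER = NA_real_, KERCC = 0L))
  }
  cb <- params$central_band
  lo <- (0.5 - cb / 2) * ear_length_cm
  hi <- (0.5 + cb / 2) * ear_length_cm
  tibble(
    KERARE = mean(kernels$area_cm2),
    KERLEN = mean(kernels$major_cm),
    KERWTH = mean(kernels$minor_cm),
    KERMAXD = mean(kernels$feret_max_cm),
    KERMIND = mean(kernels$feret_min_cm),
    KERMEAND = mean((kernels$feret_max_cm + kernels$feret_min_cm) / 2),
    KERPER = mean(kernels$perimeter_cm),
    KERCC = sum(kernels$centroid_y_cm >= lo & kernels$centroid_y_cm <= hi))
}

# cluster sorted 1-d positions into tracks with a minimum separation; returns
# integer track id per position (input order preserved)
#' @noRd
cluster_tracks <- function(pos, min_sep) {
  o <- order(pos)
  id <- integer(length(pos))
  tr <- 1L
  last <- pos[o[1]]
  id[o[1]] <- tr
  for (i in seq_along(o)[-1]) {
    if (pos[o[i]] - last >= min_sep) {
      tr <- tr + 1L
      last <- pos[o[i]]
    }
    id[o[i]] <- tr
  }
  id
}

#' Kernel count and yield traits
#'
#' Predicts whole-ear kernel counts and grain yield from the single-view
#' geometry (roughly half the kernels face the camera):
#'
#' * visible rows = distinct transverse kernel tracks crossing the central
#'   transect (centroids within half a kernel width of mid-length, clustered
#'   with minimum separation 0.6 x `KERWTH`); `PHTKR` = visible rows x
#'   `visible_to_total_factor`.
#' * `PHTKPR` = non-aborted length / axial kernel pitch, where the pitch is
#'   the median axial centroid gap within kernel-row tracks (falling back to
#'   the mean axial crown extent when no track has two kernels).
#' * `PHTKPE` = `PHTKR x PHTKPR x (1 - SCTTER/100)`.
#' * `KERWGT` = `weight_per_area x KERARE`; `PHTYLD = KERWGT x PHTKPE`
#'   exactly, by construction.
#'
#' @param ear An [ear_instance()].
#' @param kernels Tibble from [detect_kernels()].
#' @param silhouette One-row tibble from [silhouette_traits()].
#' @param fill One-row tibble from [fill_traits()].
#' @param kernel_means One-row tibble from [kernel_trait_means()].
#' @param params A [trait_model_params()].
#' @return One-row tibble with `PHTKR`, `PHTKPR`, `PHTKPE`, `KERWGT`,
#'   `PHTYLD`. Zero kernels give zero counts and yield with `KERWGT` missing.
#' @export
count_and_yield_traits <- function(ear, kernels, silhouette, fill,
                                   kernel_means,
                                   params = trait_model_params()) {
  if (!nrow(kernels)) {
    return(tibble(PHTKR = 0, PHTKPR = 0, PHTKPE = 0,
                  KERWGT = NA_real_, PHTYLD = 0))
  }
  kw <- kernel_means$KERWTH
  earlgt <- silhouette$EARLGT
  # transverse tracks over all kernels: used for the axial pitch and for the
  # visible row count at the central transect
  min_sep <- 0.6 * kw
  track_all <- cluster_tracks(kernels$centroid_x_cm, min_sep)
  gaps <- unlist(lapply(split(kernels$centroid_y_cm, track_all), function(y) {
    if (length(y) >= 2) diff(sort(y)) else numeric()
  }), use.names = FALSE)
  pitch <- if (length(gaps)) median(gaps) else mean(kernels$feret_max_cm)

  # central transect band: at least half a kernel width, widened to cover one
  # axial pitch so the band cannot fall between kernel rows (tracks are
  # counted once however many of their kernels enter the band)
  mid <- earlgt / 2
  band <- max(0.5 * kw, 0.6 * pitch)
  central <- abs(kernels$centroid_y_cm - mid) <= band + 1e-12
  n_rows_vis <- if (any(central)) {
    length(unique(track_all[central]))
  } else 0L
  phtkr <- n_rows_vis * params$visible_to_total_factor
  filled_len <- earlgt * (1 - fill$TKERAB / 100)
  phtkpr <- if (pitch > 0) filled_len / pitch else 0
  phtkpe <- phtkr * phtkpr * (1 - fill$SCTTER / 100)
  kerwgt <- params$weight_per_area * kernel_means$KERARE
  tibble(PHTKR = phtkr, PHTKPR = phtkpr, PHTKPE = phtkpe,
         KERWGT = kerwgt, PHTYLD = kerwgt * phtkpe)
}

#' All 25 ear-photometry traits for one ear
#'
#' Runs kernel detection (unless a kernel table is supplied) and composes
#' [silhouette_traits()], [fill_traits()], [kernel_trait_means()] and
#' [count_and_yield_traits()] into the full per-ear trait record.
#'
#' @param ear An [ear_instance()].
#' @param kernels Optional precomputed [detect_kernels()] table.
#' @param params A [trait_model_params()].
#' @param ... Passed to [detect_kernels()].
#' @return One-row tibble with `ear` (index) and the 25 traits in
#'   [ep_trait_names()] order, plus `abortion_cob_pct` and `n_kernels`.
#' @export
compute_ear_traits <- function(ear, kernels = NULL,
                               params = trait_model_params(), ...) {
  stopifnot(inherits(ear, "ear_instance"))
  if (is.null(kernels)) kernels <- detect_kernels(ear, ...)
  profile <- axial_width_profile(ear)
  sil <- silhouette_traits(ear, profile, params)
  fil <- fill_traits(ear, profile, params)
  km <- kernel_trait_means(kernels, sil$EARLGT, params)
  cy <- count_and_yield_traits(ear, kernels, sil, fil, km, params)
  out <- dplyr::bind_cols(
    tibble(ear = ear$ear_index),
    cy[, c("PHTYLD", "PHTKPE", "KERWGT")],
    sil[, c("EARAREA", "EARBOX", "EARCW", "EARLGT", "EARPER", "EARTR",
            "EARVOL", "EARWTH", "ETB")],
    km[, c("KERARE", "KERCC")],
    fil[, "KERFIL", drop = FALSE],
    km[, c("KERLEN", "KERMAXD", "KERMEAND", "KERMIND", "KERPER", "KERWTH")],
    cy[, c("PHTKR", "PHTKPR")],
    fil[, c("SCTTER", "TKERAB")],
    fil[, "abortion_cob_pct", drop = FALSE],
    tibble(n_kernels = nrow(kernels)))
  out
}

#' Aggregate ear traits to plot level
#'
#' Arithmetic mean of every trait over the ears of a plot (missing values
#' excluded per trait) plus the within-plot sample variance (n - 1
#' denominator) of `PHTYLD`, which is missing for single-ear plots.
#'
#' @param ears Tibble of per-ear trait rows ([compute_ear_traits()] output).
#' @param plot_id Plot identifier recorded in the output.
#' @return One-row tibble: `plot`, `n_ears`, the 25 trait means, and
#'   `PHTYLD_var`.
#' @export
aggregate_plot <- function(ears, plot_id = NA_character_) {
  if (!nrow(ears)) abort("Cannot aggregate an empty ear-trait table.")
  traits <- intersect(ep_trait_names(), names(ears))
  means <- summarise(ears,
                     across(dplyr::all_of(traits), ~mean(.x, na.rm = TRUE)))
  means[vapply(means, is.nan, logical(1))] <- NA_real_
  v <- if (nrow(ears) >= 2) var(ears$PHTYLD) else NA_real_
  dplyr::bind_cols(tibble(plot = plot_id, n_ears = nrow(ears)),
                   means, tibble(PHTYLD_var = v))
}
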