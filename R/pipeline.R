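# Pipeline composition and tabular I/O: config-driven analyze/stats runs.

#' Read a run configuration
#'
#' YAML configuration binding the pipeline together. Recognised fields:
#' `images` (directory or file list), `template` (pixel-template CSV),
#' `ruler` (list: `image`, `length_cm`), `output_dir`, `seed`, segmentation
#' parameters (`min_area_cm2`, `closing_radius`, `smooth_radius`), detection
#' parameters (`expected_kernel_width_cm`, `min_separation_frac`,
#' `smooth_sigma_px`, `min_kernel_area_cm2`, `max_kernel_area_cm2`), trait
#' model constants (any argument of [trait_model_params()]), and statistics
#' options (`alpha`, `k_max`, `trial`, `groups_by`).
#'
#' @param path YAML file path.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @noRd
cfg_get <- function(config, name, default) {
  config[[name]] %||% default
}

#' Read an ear-scene image
#'
#' PNG, JPEG or TIFF via `EBImage::readImage`, returned as an H x W x 3
#' array in `[0, 1]`.
#'
#' @param path Image file path.
#' @return RGB array.
#' @export
read_scene_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image not found: %s", path))
  as_rgb_array(EBImage::readImage(path))
}

#' Run the full photometry pipeline over a directory of images
#'
#' For every image: classify pixels, extract and align ears, delineate
#' kernels, compute the 25 traits per ear, and aggregate to plot level (one
#' image = one plot, identified by the file name). Writes
#' `ear_traits.csv` and `plot_traits.csv` to the output directory and logs
#' ears found per image. Unreadable images are skipped with a logged error;
#' the run fails only if every image fails.
#'
#' @param config A `run_config` list (or path to a YAML file). Must provide
#'   `images`, `template` and `ruler` (`image` + `length_cm`), or a
#'   `px_per_cm` value in place of the ruler.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `ears` and `plots` tibbles.
#' @export
run_analyze <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  images <- config$images
  if (length(images) == 1 && dir.exists(images)) {
    images <- sort(list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                              ignore.case = TRUE, full.names = TRUE))
  }
  if (!length(images)) abort("No input images found.")
  tpl <- read_pixel_template(config$template)
  clf <- fit_pixel_classifier(tpl)
  cal <- if (!is.null(config$ruler)) {
    calibrate_scale(read_scene_image(config$ruler$image),
                    config$ruler$length_cm)
  } else if (!is.null(config$px_per_cm)) {
    tibble(px_per_cm = config$px_per_cm, bar_px = NA_real_,
           known_length_cm = NA_real_)
  } else {
    abort("Config must provide either `ruler` (image + length_cm) or `px_per_cm`.")
  }
  params <- do.call(trait_model_params, config[intersect(
    names(config), names(formals(trait_model_params)))])

  ear_rows <- list(); plot_rows <- list(); n_fail <- 0L
  for (img_path in images) {
    plot_id <- sub("\\.[^.]+$", "", basename(img_path))
    res <- tryCatch({
      img <- read_scene_image(img_path)
      labels <- classify_pixels(img, clf,
                                smooth_radius = cfg_get(config, "smooth_radius", 1L))
      ears <- extract_ear_instances(
        labels, cal,
        min_area_cm2 = cfg_get(config, "min_area_cm2", 10),
        closing_radius = cfg_get(config, "closing_radius", 3L))
      if (!length(ears)) {
        inform(sprintf("[%s] no ears found; skipped.", plot_id))
        NULL
      } else {
        traits <- bind_rows(lapply(ears, function(e) {
          k <- detect_kernels(
            e,
            expected_kernel_width_cm = cfg_get(config, "expected_kernel_width_cm", 0.46),
            min_separation_frac = cfg_get(config, "min_separation_frac", 0.6),
            smooth_sigma_px = cfg_get(config, "smooth_sigma_px", 1),
            min_area_cm2 = cfg_get(config, "min_kernel_area_cm2", 0.05),
            max_area_cm2 = cfg_get(config, "max_kernel_area_cm2", 1.5))
          compute_ear_traits(e, kernels = k, params = params)
        }))
        traits <- mutate(traits, plot = plot_id, .before = 1)
        if (!quiet) {
          inform(sprintf("[%s] %d ear(s) processed.", plot_id, nrow(traits)))
        }
        list(ears = traits, plot = aggregate_plot(traits, plot_id))
      }
    }, error = function(e) {
      inform(sprintf("[%s] FAILED: %s", plot_id, conditionMessage(e)))
      n_fail <<- n_fail + 1L
      NULL
    })
    if (!is.null(res)) {
      ear_rows[[length(ear_rows) + 1L]] <- res$ears
      plot_rows[[length(plot_rows) + 1L]] <- res$plot
    }
  }
  if (!length(ear_rows)) {
    abort(sprintf("All %d image(s) failed or contained no ears.",
                  length(images)))
  }
  ears <- bind_rows(ear_rows)
  plots <- bind_rows(plot_rows)
  out_dir <- cfg_get(config, "output_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trait_table(ears, file.path(out_dir, "ear_traits.csv"))
    write_trait_table(plots, file.path(out_dir, "plot_traits.csv"))
  }
  invisible(list(ears = ears, plots = plots))
}

#' Run the trial statistics over a trait table
#'
#' For every trait column: fit the testcross mixed model, predict hybrid
#' BLUPs and estimate entry-mean and plot-mean heritability; then compare
#' heterotic groups on the BLUPs (ANOVA + Tukey letters), and run the trait
#' PCA and Ward/Ball-Hall clustering on the hybrid x trait BLUP matrix.
#' Traits with fewer than 2 hybrids or zero variance are skipped with a
#' warning.
#'
#' @param trial Data frame with columns `hybrid`, `year`, `rep`, optionally
#'   `heterotic_group`, and one column per trait; or a `run_config` whose
#'   `trial` field names a CSV to read.
#' @param traits Trait columns to analyse; default: all numeric columns
#'   except the design columns.
#' @param alpha Significance level for the group comparison. Default 0.05.
#' @param k_max Largest cluster number examined. Default 10.
#' @param output_dir If given, writes `blups.csv`, `heritability.csv`,
#'   `group_comparison.csv`, `pca_loadings.csv`, `clusters.csv`.
#' @return Invisibly, list with `fits`, `heritability`, `blups`, `groups`,
#'   `pca`, `clusters`.
#' @export
run_stats <- function(trial, traits = NULL, alpha = 0.05, k_max = 10,
                      output_dir = NULL) {
  if (inherits(trial, "run_config") || (is.character(trial) && length(trial) == 1)) {
    cfg <- if (is.character(trial)) read_run_config(trial) else trial
    alpha <- cfg_get(cfg, "alpha", alpha)
    k_max <- cfg_get(cfg, "k_max", k_max)
    output_dir <- cfg_get(cfg, "output_dir", output_dir)
    trial <- readr::read_csv(cfg$trial, show_col_types = FALSE)
  }
  stopifnot(is.data.frame(trial),
            all(c("hybrid", "year", "rep") %in% names(trial)))
  design_cols <- c("hybrid", "year", "rep", "plot", "tester",
                   "heterotic_group", "origin", "stand_count")
  if (is.null(traits)) {
    traits <- setdiff(names(trial)[vapply(trial, is.numeric, logical(1))],
                      design_cols)
  }
  if (!length(traits)) abort("No trait columns to analyse.")

  fits <- list(); her <- list(); blup_tbls <- list()
  for (tr in traits) {
    d <- tibble(hybrid = trial$hybrid, year = trial$year, rep = trial$rep,
                value = as.numeric(trial[[tr]]))
    d <- d[is.finite(d$value), , drop = FALSE]
    if (length(unique(d$hybrid)) < 2 || sd(d$value) == 0) {
      warn(sprintf("Trait %s skipped (needs >= 2 hybrids and variation).", tr))
      next
    }
    fit <- fit_mixed_model(d, trait = tr)
    fits[[tr]] <- fit
    her[[tr]] <- mutate(heritability(fit), trait = tr, .before = 1)
    blup_tbls[[tr]] <- mutate(hybrid_blups(fit), trait = tr, .before = 1)
  }
  if (!length(fits)) abort("No trait could be analysed.")
  heritability_tbl <- bind_rows(her)
  blups_long <- bind_rows(blup_tbls)
  blup_wide <- tidyr::pivot_wider(blups_long[, c("trait", "hybrid", "blup")],
                                  names_from = "trait", values_from = "blup")

  groups <- NULL
  if ("heterotic_group" %in% names(trial)) {
    grp_map <- dplyr::distinct(trial, .data$hybrid, .data$heterotic_group)
    groups <- lapply(names(fits), function(tr) {
      d <- left_join(hybrid_blups(fits[[tr]]), grp_map, by = "hybrid")
      gc <- compare_groups(d, value = "blup", group = "heterotic_group",
                           alpha = alpha)
      mutate(tidy(gc), trait = tr, .before = 1)
    })
    groups <- bind_rows(groups)
  }

  pca <- NULL; clusters <- NULL
  if (length(fits) >= 3) {
    pca <- trait_pca(blup_wide)
    clusters <- cluster_traits(blup_wide, k_max = k_max)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_trait_table(blup_wide, file.path(output_dir, "blups.csv"))
    write_trait_table(heritability_tbl, file.path(output_dir, "heritability.csv"))
    if (!is.null(groups)) {
      write_trait_table(groups, file.path(output_dir, "group_comparison.csv"))
    }
    if (!is.null(pca)) {
      write_trait_table(tidy(pca), file.path(output_dir, "pca_loadings.csv"))
      write_trait_table(tidy(clusters), file.path(output_dir, "clusters.csv"))
    }
  }
  invisible(list(fits = fits, heritability = heritability_tbl,
                 blups = blup_wide, groups = groups, pca = pca,
                 clusters = clusters))
}

#' Write a trait table as CSV
#'
#' UTF-8 CSV with a fixed, deterministic column order (trait columns in
#' [ep_trait_names()] order when present), missing values as empty fields
#' and rows in input order.
#'
#' @param rows Data frame to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  bad <- names(rows)[vapply(rows, function(x) is.list(x), logical(1))]
  if (length(bad)) {
    abort(paste0("Cannot write list column(s): ", paste(bad, collapse = ", ")))
  }
  traits_present <- intersect(ep_trait_names(), names(rows))
  other <- setdiff(names(rows), traits_present)
  rows <- rows[, c(other, traits_present), drop = FALSE]
  readr::write_csv(rows, path, na = "")
  invisible(path)
}
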