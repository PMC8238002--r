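#' Compare heterotic groups by ANOVA and Tukey HSD
#'
#' One-way ANOVA of hybrid BLUPs across groups. If the ANOVA is significant
#' at `alpha`, a Tukey HSD test assigns compact letters (the group with the
#' largest mean is lettered `"a"`); otherwise all groups share one letter.
#' Groups with fewer than 2 observations are excluded with a warning.
#'
#' @param data Data frame with the response and grouping columns.
#' @param value,group Column names (strings). Defaults `"blup"`, `"group"`.
#' @param alpha Significance level for the ANOVA gate and the letters.
#'   Default 0.05.
#' @return A list of class `group_comparison`: `table` (per-group tibble
#'   with `n`, `mean`, `min`, `max`, `letter`), `F`, `p`, `sig` (ns / * /
#'   ** / ***), `alpha`.
#' @export
compare_groups <- function(data, value = "blup", group = "group",
                           alpha = 0.05) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  d <- tibble(y = as.numeric(data[[value]]),
              g = factor(data[[group]]))
  d <- d[is.finite(d$y), , drop = FALSE]
  sizes <- table(d$g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("Excluding group(s) with n < 2: ",
                paste(small, collapse = ", ")))
    d <- d[!(d$g %in% small), , drop = FALSE]
  }
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2) abort("Need at least 2 groups with n >= 2.")

  fit <- aov(y ~ g, data = d)
  an <- anova(fit)
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]

  stats_tbl <- d |>
    group_by(.data$g) |>
    summarise(n = dplyr::n(), mean = mean(.data$y),
              min = min(.data$y), max = max(.data$y), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean))

  if (is.finite(p) && p < alpha) {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    cld <- multcomp::cld(glht_fit, level = alpha)
    letters_by_group <- cld$mcletters$Letters[as.character(stats_tbl$g)]
    stats_tbl$letter <- remap_letters(letters_by_group)
  } else {
    stats_tbl$letter <- "a"
  }
  names(stats_tbl)[1] <- "group"
  stats_tbl$group <- as.character(stats_tbl$group)
  structure(list(table = stats_tbl, F = Fv, p = p, sig = sig_code(p),
                 alpha = alpha),
            class = "group_comparison")
}

# Relabel compact letters so that scanning groups in table order (descending
# mean) assigns "a" first; sharing structure is preserved.
#' @noRd
remap_letters <- function(lets) {
  map <- character()
  for (s in lets) {
    for (ch in strsplit(s, "")[[1]]) {
      if (!ch %in% names(map)) map[ch] <- letters[length(map) + 1L]
    }
  }
  vapply(lets, function(s) {
    paste(sort(map[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.3f, p = %.3g (%s)\n", x$F, x$p, x$sig))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  mutate(x$table, F = x$F, p = x$p, sig = x$sig)
}

#' Compare within-plot yield variance between origins
#'
#' Two-sided Welch comparison of the within-plot grain-yield variance between
#' plot origins (e.g. temperate vs tropical testcrosses), each year analysed
#' separately because the number of ears sampled per plot differs between
#' years. Years with a single origin are skipped with a warning.
#'
#' @param plot_summaries Data frame with columns `year`, `origin` and the
#'   within-plot variance column named by `variance`.
#' @param variance Variance column name. Default `"PHTYLD_var"`.
#' @return Tibble with one row per year x origin: group mean variance and n,
#'   plus the per-year `t`, `p` and significance code.
#' @export
within_plot_variance_test <- function(plot_summaries,
                                      variance = "PHTYLD_var") {
  stopifnot(is.data.frame(plot_summaries),
            all(c("year", "origin") %in% names(plot_summaries)),
            variance %in% names(plot_summaries))
  d <- tibble(year = plot_summaries$year,
              origin = factor(plot_summaries$origin),
              v = as.numeric(plot_summaries[[variance]]))
  d <- d[is.finite(d$v), , drop = FALSE]
  out <- list()
  for (yr in sort(unique(d$year))) {
    dy <- d[d$year == yr, , drop = FALSE]
    dy$origin <- droplevels(dy$origin)
    if (nlevels(dy$origin) < 2) {
      warn(sprintf("Year %s has a single origin; skipped.", as.character(yr)))
      next
    }
    tt <- t.test(v ~ origin, data = dy)
    sm <- dy |>
      group_by(.data$origin) |>
      summarise(mean_var = mean(.data$v), n = dplyr::n(), .groups = "drop")
    out[[length(out) + 1L]] <- mutate(
      sm, year = yr, t = unname(tt$statistic), p = tt$p.value,
      sig = sig_code(tt$p.value), .before = 1)
  }
  if (!length(out)) {
    return(tibble(year = character(), t = numeric(), p = numeric(),
                  sig = character(), origin = factor(), mean_var = numeric(),
                  n = integer()))
  }
  bind_rows(out)
}
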