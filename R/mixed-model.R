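#' Fit the multi-year testcross mixed model
#'
#' REML fit of the standard two-year testcross model for one trait:
#' \deqn{Y_{ijk} = \mu + H_i + Yr_j + HYr_{ij} + R(Yr)_{jk} + \varepsilon_{ijk}}
#' with the hybrid effect \eqn{H_i} and the hybrid-by-year interaction
#' \eqn{HYr_{ij}} random, and year and rep-within-year fixed. Fitted with
#' `lme4::lmer` using sum-to-zero contrasts so the intercept is the grand
#' mean in balanced data. With a single year the interaction is not
#' estimable: it is fixed at zero and the model degrades to
#' `value ~ rep + (1 | hybrid)`.
#'
#' @param records Data frame with columns `hybrid`, `year`, `rep`, `value`
#'   (one trait). At least 2 hybrids.
#' @param trait Optional trait name stored in the fit.
#' @return An object of class `mm_fit`: variance components `sigma2_H`,
#'   `sigma2_HY`, `sigma2_eps`, grand mean `mu`, BLUP table, the underlying
#'   `lmerMod`, and a `converged` flag. Non-convergence is flagged, never
#'   silently replaced.
#' @export
fit_mixed_model <- function(records, trait = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("hybrid", "year", "rep", "value") %in% names(records)))
  d <- tibble(hybrid = factor(records$hybrid),
              year = factor(records$year),
              rep = factor(records$rep),
              value = as.numeric(records$value))
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nlevels(droplevels(d$hybrid)) < 2) {
    abort("Need at least 2 hybrids to fit the mixed model.")
  }
  d$hybrid <- droplevels(d$hybrid)
  multi_year <- nlevels(droplevels(d$year)) > 1
  form <- if (multi_year) {
    value ~ year + year:rep + (1 | hybrid) + (1 | hybrid:year)
  } else {
    value ~ rep + (1 | hybrid)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE, control = ctrl,
               contrasts = fixed_sum_contrasts(d, multi_year)),
    message = function(m) invokeRestart("muffleMessage"))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[[1]] else 0
  }
  sigma2_H <- getv("hybrid")
  sigma2_HY <- if (multi_year) getv("hybrid:year") else 0
  sigma2_eps <- getv("Residual")

  mm <- stats::model.matrix(fit)
  mu <- mean(mm %*% lme4::fixef(fit))
  re <- lme4::ranef(fit)$hybrid
  blups <- tibble(hybrid = rownames(re),
                  effect = re[["(Intercept)"]],
                  blup = mu + re[["(Intercept)"]])

  structure(
    list(trait = trait, sigma2_H = sigma2_H, sigma2_HY = sigma2_HY,
         sigma2_eps = sigma2_eps, mu = mu, blups = blups,
         n_hybrids = nlevels(d$hybrid),
         n_years = nlevels(droplevels(d$year)),
         n_reps = nlevels(droplevels(d$rep)),
         converged = conv, model = fit),
    class = "mm_fit")
}

#' @noRd
fixed_sum_contrasts <- function(d, multi_year) {
  out <- list()
  if (multi_year && nlevels(droplevels(d$year)) > 1) {
    out$year <- stats::contr.sum(nlevels(droplevels(d$year)))
  }
  if (!multi_year && nlevels(droplevels(d$rep)) > 1) {
    out$rep <- stats::contr.sum(nlevels(droplevels(d$rep)))
  }
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit%s> %d hybrids, %d year(s) x %d rep(s)%s\n",
              if (is.na(x$trait)) "" else paste0(" ", x$trait),
              x$n_hybrids, x$n_years, x$n_reps,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  sigma2_H = %.4g, sigma2_HY = %.4g, sigma2_eps = %.4g, mu = %.4g\n",
              x$sigma2_H, x$sigma2_HY, x$sigma2_eps, x$mu))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_mixed_model
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("sigma2_H", "sigma2_HY", "sigma2_eps", "mu"),
         estimate = c(x$sigma2_H, x$sigma2_HY, x$sigma2_eps, x$mu))
}

#' @rdname fit_mixed_model
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(trait = x$trait, sigma2_H = x$sigma2_H, sigma2_HY = x$sigma2_HY,
         sigma2_eps = x$sigma2_eps, mu = x$mu, n_hybrids = x$n_hybrids,
         n_years = x$n_years, n_reps = x$n_reps, converged = x$converged)
}

#' Hybrid BLUPs from a fitted model
#'
#' @param fit An `mm_fit` object.
#' @return Tibble with `hybrid`, `effect` (BLUP deviation) and `blup`
#'   (grand mean + deviation).
#' @export
hybrid_blups <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  fit$blups
}

#' Broad-sense heritability from variance components
#'
#' Entry-mean and plot-mean broad-sense heritability:
#' \deqn{H^2_{entry} = \sigma^2_H / (\sigma^2_H + \sigma^2_{HY}/y +
#'   \sigma^2_\varepsilon/(y r))}
#' \deqn{H^2_{plot} = \sigma^2_H / (\sigma^2_H + \sigma^2_{HY} +
#'   \sigma^2_\varepsilon)}
#' with `y` years and `r` reps per year. The entry-mean value is never
#' smaller than the plot-mean value for `y, r >= 1`. All-zero components
#' give missing values.
#'
#' @param fit An `mm_fit` object, or a list/one-row data frame with
#'   `sigma2_H`, `sigma2_HY`, `sigma2_eps`.
#' @param y Number of years; defaults to the fit's.
#' @param r Reps per year; defaults to the fit's.
#' @return One-row tibble: `H2_entry`, `H2_plot`, `y`, `r`.
#' @export
heritability <- function(fit, y = NULL, r = NULL) {
  if (inherits(fit, "mm_fit")) {
    y <- y %||% fit$n_years
    r <- r %||% fit$n_reps
    s2h <- fit$sigma2_H; s2hy <- fit$sigma2_HY; s2e <- fit$sigma2_eps
  } else {
    s2h <- fit$sigma2_H; s2hy <- fit$sigma2_HY; s2e <- fit$sigma2_eps
    if (is.null(y) || is.null(r)) abort("Supply `y` and `r`.")
  }
  stopifnot(y >= 1, r >= 1, s2h >= 0, s2hy >= 0, s2e >= 0)
  tot <- s2h + s2hy + s2e
  if (tot <= 0) {
    warn("All variance components are zero; heritability is undefined.")
    return(tibble(H2_entry = NA_real_, H2_plot = NA_real_, y = y, r = r))
  }
  tibble(H2_entry = s2h / (s2h + s2hy / y + s2e / (y * r)),
         H2_plot = s2h / tot, y = y, r = r)
}
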