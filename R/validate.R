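#' Validate predicted traits against reference measurements
#'
#' Pearson correlation and least-squares line between an image-predicted
#' trait and its manually measured reference, optionally adjusting for a
#' covariate (e.g. stand count for combine yield): with a covariate the
#' model `reference ~ predicted + covariate` is fitted and the reported
#' correlation is between the reference and its fitted values.
#'
#' @param data Data frame holding the paired observations.
#' @param predicted,reference,covariate Column names (strings). `covariate`
#'   is optional.
#' @return One-row tibble: `n`, `r`, `slope`, `intercept`, `used_covariate`.
#'   Zero variance in either variable gives `r = NA` with a warning.
#' @export
validate_prediction <- function(data, predicted, reference,
                                covariate = NULL) {
  stopifnot(is.data.frame(data), predicted %in% names(data),
            reference %in% names(data))
  p <- as.numeric(data[[predicted]])
  f <- as.numeric(data[[reference]])
  cv <- if (!is.null(covariate)) {
    stopifnot(covariate %in% names(data))
    as.numeric(data[[covariate]])
  } else NULL
  ok <- is.finite(p) & is.finite(f) & (if (is.null(cv)) TRUE else is.finite(cv))
  p <- p[ok]; f <- f[ok]; if (!is.null(cv)) cv <- cv[ok]
  n <- length(p)
  if (n < 3) abort("Need at least 3 paired observations.")
  if (sd(p) == 0 || sd(f) == 0) {
    warn("Zero variance in predicted or reference values; correlation undefined.")
    return(tibble(n = n, r = NA_real_, slope = NA_real_,
                  intercept = NA_real_, used_covariate = !is.null(cv)))
  }
  if (is.null(cv)) {
    fit <- lm(f ~ p)
    r <- cor(p, f)
  } else {
    fit <- lm(f ~ p + cv)
    r <- cor(f, fitted(fit))
  }
  tibble(n = n, r = r, slope = unname(coef(fit)["p"]),
         intercept = unname(coef(fit)[1]), used_covariate = !is.null(cv))
}
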