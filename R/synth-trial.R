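#' Simulate a balanced multi-year testcross trial
#'
#' Draws plot-level observations from the generative form of the testcross
#' mixed model:
#' \deqn{Y_{ijk} = \mu + H_i + Yr_j + HYr_{ij} + R(Yr)_{jk} + \varepsilon_{ijk}}
#' with hybrid effects \eqn{H_i \sim N(0, \sigma^2_H)}, interactions
#' \eqn{HYr_{ij} \sim N(0, \sigma^2_{HY})} and residuals
#' \eqn{\varepsilon \sim N(0, \sigma^2_\varepsilon)}; year and
#' rep-within-year effects are fixed constants. The design is balanced:
#' every hybrid appears in every year x rep cell.
#'
#' Defaults portray a grain-yield-like trait (grand mean 150 g per ear, two
#' years, two reps).
#'
#' @param n_hybrids Number of hybrids. Default 200.
#' @param years Number of years. Default 2.
#' @param reps Reps per year. Default 2.
#' @param mu Grand mean. Default 150.
#' @param year_effects Fixed year effects (length `years`, sum 0 by
#'   default).
#' @param rep_effects Fixed rep-within-year effects, a `years x reps`
#'   matrix or single value recycled; default small +/- offsets.
#' @param sigma2_H,sigma2_HY,sigma2_eps Variance components. Defaults
#'   2, 1, 1.
#' @param seed Integer seed.
#' @return List with `records` (tibble: `hybrid`, `year`, `rep`, `plot`,
#'   `value`) and `truth` (list: `hybrid_effects` tibble, the fixed effects
#'   and the variance components).
#' @export
simulate_trial <- function(n_hybrids = 200, years = 2, reps = 2, mu = 150,
                           year_effects = NULL, rep_effects = NULL,
                           sigma2_H = 2, sigma2_HY = 1, sigma2_eps = 1,
                           seed = 1L) {
  stopifnot(n_hybrids >= 2, years >= 1, reps >= 1,
            sigma2_H >= 0, sigma2_HY >= 0, sigma2_eps >= 0)
  if (is.null(year_effects)) {
    year_effects <- if (years == 1) 0 else
      seq(-4, 4, length.out = years)
  }
  stopifnot(length(year_effects) == years)
  if (is.null(rep_effects)) {
    rep_effects <- matrix(rep(if (reps == 1) 0 else
      seq(-1.5, 1.5, length.out = reps), each = years), years, reps)
  } else if (length(rep_effects) == 1) {
    rep_effects <- matrix(rep_effects, years, reps)
  }
  stopifnot(identical(dim(rep_effects), c(as.integer(years), as.integer(reps))) ||
            all(dim(rep_effects) == c(years, reps)))

  with_seed(seed, {
    H <- rnorm(n_hybrids, 0, sqrt(sigma2_H))
    HY <- matrix(rnorm(n_hybrids * years, 0, sqrt(sigma2_HY)),
                 n_hybrids, years)
    hyb_ids <- sprintf("H%04d", seq_len(n_hybrids))
    grid <- expand.grid(hybrid = seq_len(n_hybrids), year = seq_len(years),
                        rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
    eps <- rnorm(nrow(grid), 0, sqrt(sigma2_eps))
    value <- mu + H[grid$hybrid] + year_effects[grid$year] +
      HY[cbind(grid$hybrid, grid$year)] +
      rep_effects[cbind(grid$year, grid$rep)] + eps
    records <- tibble(
      hybrid = hyb_ids[grid$hybrid],
      year = 2016L + grid$year,
      rep = grid$rep,
      plot = sprintf("Y%d-R%d-%s", grid$year, grid$rep, hyb_ids[grid$hybrid]),
      value = value)
    list(records = records,
         truth = list(
           hybrid_effects = tibble(hybrid = hyb_ids, effect = H),
           year_effects = year_effects, rep_effects = rep_effects,
           mu = mu, sigma2_H = sigma2_H, sigma2_HY = sigma2_HY,
           sigma2_eps = sigma2_eps))
  })
}
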