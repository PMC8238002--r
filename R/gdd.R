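#' Daily growing degree days
#'
#' Thermal time for one day with a 10 degC base: the maximum and minimum
#' temperatures are first capped into `[10, 30]` degC independently, then
#' `GDD = (tmax + tmin) / 2 - 10`. Output is therefore always in `[0, 20]`.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature (degC);
#'   vectorised, `tmax >= tmin` element-wise (checked before capping).
#' @return Numeric vector of daily GDD (degC day).
#' @examples
#' daily_gdd(30, 10)  # 10
#' daily_gdd(40, 5)   # caps to (30, 10) -> 10
#' daily_gdd(20, 12)  # 6
#' @export
daily_gdd <- function(tmax, tmin) {
  if (length(tmax) != length(tmin)) {
    abort("`tmax` and `tmin` must have the same length.")
  }
  if (any(is.na(tmax) | is.na(tmin))) {
    abort("`tmax`/`tmin` must not contain missing values.")
  }
  if (any(tmax < tmin)) {
    abort("`tmax` must be >= `tmin` for every day.")
  }
  tmax <- pmin(pmax(tmax, 10), 30)
  tmin <- pmin(pmax(tmin, 10), 30)
  (tmax + tmin) / 2 - 10
}

#' Accumulated growing degree days between two dates
#'
#' Sums [daily_gdd()] over every day from planting to the event date,
#' inclusive of both endpoints. The weather table must cover the whole
#' interval with no gaps.
#'
#' @param weather Data frame with columns `date` (Date or coercible),
#'   `tmin`, `tmax`.
#' @param planting,event Planting and event dates (Date or coercible);
#'   `event >= planting`.
#' @return Accumulated GDD (scalar).
#' @export
accumulate_gdd <- function(weather, planting, event) {
  stopifnot(is.data.frame(weather),
            all(c("date", "tmin", "tmax") %in% names(weather)))
  planting <- as.Date(planting); event <- as.Date(event)
  if (event < planting) abort("`event` must not precede `planting`.")
  days <- seq(planting, event, by = "day")
  wdate <- as.Date(weather$date)
  idx <- match(days, wdate)
  if (anyNA(idx)) {
    abort(paste0("Weather series has gaps; missing date(s): ",
                 paste(format(days[is.na(idx)]), collapse = ", ")))
  }
  sum(daily_gdd(weather$tmax[idx], weather$tmin[idx]))
}

#' Anthesis-silking interval
#'
#' ASI between the anthesis date (AD) and silking date (SD), measured both in
#' accumulated GDD (difference of the accumulations from planting) and in
#' days.
#'
#' @param weather Weather table as in [accumulate_gdd()].
#' @param planting,anthesis,silking Dates.
#' @return One-row tibble: `ad_gdd`, `sd_gdd`, `asi_gdd`, `asi_days`.
#' @export
asi_interval <- function(weather, planting, anthesis, silking) {
  ad <- accumulate_gdd(weather, planting, anthesis)
  sd_ <- accumulate_gdd(weather, planting, silking)
  tibble(ad_gdd = ad, sd_gdd = sd_, asi_gdd = sd_ - ad,
         asi_days = as.numeric(as.Date(silking) - as.Date(anthesis)))
}
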