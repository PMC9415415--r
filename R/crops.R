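#' Define a crop phenology entry
#'
#' Describes the canopy-cover trajectory of one crop over the Spring-Summer
#' cycle. Annual crops (corn, bean) rise logistically from sowing towards
#' `peak_cover`, senesce late in the season, and drop to bare soil at harvest.
#' Perennials (alfalfa) carry a `cut_interval`: cover follows a sawtooth,
#' regrowing from a residual stubble after each cut.
#'
#' @param crop_name Label, e.g. "corn".
#' @param sowing_window Length-2 integer vector of day-of-year bounds
#'   (earliest, latest) for sowing; for perennials it bounds the random cut
#'   phase anchor instead.
#' @param season_length Days from sowing to end of the crop's cycle.
#' @param harvest_day Day-of-year after which the plot is bare (`NA` for
#'   crops standing to the end of their season).
#' @param cut_interval Days between cuts (perennials only, `NA` otherwise).
#' @param peak_cover Maximum fractional canopy cover, in (0, 1].
#' @param rise_rate Logistic growth steepness, 1/day.
#' @param rise_mid Days from sowing (or cut) to half-maximal cover.
#' @param senescence_rate Exponential decay rate after `senescence_start`,
#'   1/day.
#' @param senescence_start Days from sowing at which senescence begins.
#' @param residual_cover Stubble cover immediately after a cut (perennials).
#' @return A list of class `"crop_calendar_entry"`.
#' @export
crop_calendar_entry <- function(crop_name, sowing_window, season_length,
                                harvest_day = NA, cut_interval = NA,
                                peak_cover = 0.9, rise_rate = 0.1,
                                rise_mid = 40, senescence_rate = 0.03,
                                senescence_start = season_length * 0.8,
                                residual_cover = 0) {
  stopifnot(length(sowing_window) == 2, sowing_window[1] <= sowing_window[2])
  if (!(peak_cover > 0 && peak_cover <= 1)) stop("peak_cover must lie in (0, 1]")
  if (!is.na(cut_interval) && cut_interval <= 0) stop("cut_interval must be positive")
  structure(list(
    crop_name = crop_name, sowing_window = as.integer(sowing_window),
    season_length = season_length, harvest_day = harvest_day,
    cut_interval = cut_interval, peak_cover = peak_cover,
    rise_rate = rise_rate, rise_mid = rise_mid,
    senescence_rate = senescence_rate, senescence_start = senescence_start,
    residual_cover = residual_cover
  ), class = "crop_calendar_entry")
}

#' Default crop phenologies for the irrigation-module scenario
#'
#' Calibrated qualitatively to the cropping pattern of a central-Mexican
#' irrigation module: corn sown through April-mid May and standing to the end
#' of September; bean sown in April and harvested in early July at grain
#' filling; alfalfa as an established perennial cut roughly every eight weeks;
#' plus a generic short-cycle "other" class.
#'
#' Day-of-year anchors: the cycle runs April (DOY ~91) to September (DOY
#' ~273); bean harvest_day 186 is 5 July.
#'
#' @return Named list of [crop_calendar_entry()] objects
#'   (corn, alfalfa, bean, other).
#' @export
default_crop_calendar <- function() {
  list(
    corn = crop_calendar_entry(
      "corn", sowing_window = c(91, 135), season_length = 175,
      harvest_day = 273, peak_cover = 0.95, rise_rate = 0.09, rise_mid = 50,
      senescence_rate = 0.02, senescence_start = 130
    ),
    alfalfa = crop_calendar_entry(
      "alfalfa", sowing_window = c(35, 91), season_length = 365,
      cut_interval = 56, peak_cover = 0.9, rise_rate = 0.18, rise_mid = 22,
      residual_cover = 0.08
    ),
    bean = crop_calendar_entry(
      "bean", sowing_window = c(91, 120), season_length = 95,
      harvest_day = 186, peak_cover = 0.85, rise_rate = 0.14, rise_mid = 32,
      senescence_rate = 0.04, senescence_start = 75
    ),
    other = crop_calendar_entry(
      "other", sowing_window = c(91, 160), season_length = 100,
      peak_cover = 0.7, rise_rate = 0.12, rise_mid = 30,
      senescence_rate = 0.05, senescence_start = 70
    )
  )
}

# Normalized logistic rise: 0 exactly at d = 0, approaching 1 for large d.
logistic_rise <- function(d, rate, mid) {
  base <- stats::plogis(-rate * mid)
  pmax(0, (stats::plogis(rate * (d - mid)) - base) / (1 - base))
}

#' Simulate fractional canopy cover on a date
#'
#' Total function of dates: returns 0 before sowing and after harvest, a
#' logistic rise to peak cover during growth, exponential senescence late in
#' the season for annuals, and an exactly periodic sawtooth (period
#' `cut_interval`) for perennials, measured from the plot's cut anchor
#' (`sowing_date`).
#'
#' @param entry A [crop_calendar_entry()].
#' @param sowing_date `Date` of sowing (annuals) or cut-schedule anchor
#'   (perennials).
#' @param query_date `Date` (vectorized) at which cover is evaluated.
#' @return Numeric vector of cover fractions in \[0, 1\].
#' @export
simulate_cover <- function(entry, sowing_date, query_date) {
  stopifnot(inherits(entry, "crop_calendar_entry"))
  sowing_date <- as.Date(sowing_date)
  query_date <- as.Date(query_date)
  d <- as.numeric(query_date - sowing_date)

  if (!is.na(entry$cut_interval)) {
    # perennial: cover depends only on days since the most recent cut
    phase <- d %% entry$cut_interval
    cover <- entry$residual_cover +
      (entry$peak_cover - entry$residual_cover) *
        logistic_rise(phase, entry$rise_rate, entry$rise_mid)
    return(pmin(1, pmax(0, cover)))
  }

  cover <- entry$peak_cover * logistic_rise(d, entry$rise_rate, entry$rise_mid)
  sen <- d > entry$senescence_start
  cover[sen] <- cover[sen] *
    exp(-entry$senescence_rate * (d[sen] - entry$senescence_start))
  cover[d < 0 | d > entry$season_length] <- 0
  if (!is.na(entry$harvest_day)) {
    doy <- as.integer(format(query_date, "%j"))
    cover[doy > entry$harvest_day] <- 0
  }
  pmin(1, pmax(0, cover))
}
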