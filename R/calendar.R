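#' Build an acquisition calendar
#'
#' An acquisition calendar lists the candidate satellite overpass dates for a
#' crop cycle together with a per-date cloud flag. Analysis is restricted to
#' cloud-free dates; cloudy dates are dropped as whole scenes (no per-plot
#' partial masking).
#'
#' @param dates `Date` vector of overpass dates, strictly increasing.
#' @param cloudy Logical vector, one flag per date (`TRUE` = scene discarded).
#' @return A data.frame with columns `date` and `cloudy`, class
#'   `"acquisition_calendar"`.
#' @export
acquisition_calendar <- function(dates, cloudy = rep(FALSE, length(dates))) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("calendar dates contain NA")
  if (length(dates) > 1 && any(diff(dates) <= 0)) {
    stop("calendar dates must be strictly increasing")
  }
  if (length(cloudy) != length(dates)) stop("one cloudy flag per date is required")
  cal <- data.frame(date = dates, cloudy = as.logical(cloudy))
  class(cal) <- c("acquisition_calendar", "data.frame")
  cal
}

#' Regular 5-day overpass cadence with random cloud outages
#'
#' Generates the Sentinel-2 revisit pattern (one candidate scene every five
#' days) over a date range and marks each scene cloudy independently with the
#' given probability.
#'
#' @param from,to Date range (inclusive start).
#' @param cadence_days Days between overpasses (default 5).
#' @param cloud_prob Probability that a scene is cloudy, in \[0, 1\].
#' @param seed Integer seed for the cloud draw.
#' @return An [acquisition_calendar()].
#' @export
regular_calendar <- function(from, to, cadence_days = 5, cloud_prob = 0,
                             seed = 1) {
  if (cloud_prob < 0 || cloud_prob > 1) stop("cloud_prob must lie in [0, 1]")
  dates <- seq(as.Date(from), as.Date(to), by = cadence_days)
  set.seed(as.integer(seed))
  cloudy <- stats::runif(length(dates)) < cloud_prob
  acquisition_calendar(dates, cloudy)
}

#' The 2019 Tepatepec-style acquisition calendar
#'
#' The April-September 2019 5-day overpass pattern with 27 usable cloud-free
#' scenes: all six scenes in April, May and August, four each in June and
#' July, and a single September scene. The cloud-free subset is chosen so the
#' scene-matching worked examples (analysis on 6 July with 15/30/60-day lags)
#' resolve to 21 June, 6 June and 7 May.
#'
#' @return An [acquisition_calendar()] with 33 dates, 27 of them cloud-free.
#' @export
calendar_2019 <- function() {
  used <- as.Date(c(
    "2019-04-02", "2019-04-07", "2019-04-12", "2019-04-17", "2019-04-22", "2019-04-27",
    "2019-05-02", "2019-05-07", "2019-05-12", "2019-05-17", "2019-05-22", "2019-05-27",
    "2019-06-06", "2019-06-11", "2019-06-16", "2019-06-21",
    "2019-07-01", "2019-07-06", "2019-07-21", "2019-07-26",
    "2019-08-05", "2019-08-10", "2019-08-15", "2019-08-20", "2019-08-25", "2019-08-30",
    "2019-09-04"
  ))
  cloudy_dates <- as.Date(c(
    "2019-06-01", "2019-06-26",
    "2019-07-11", "2019-07-16", "2019-07-31",
    "2019-09-09"
  ))
  all_dates <- sort(c(used, cloudy_dates))
  acquisition_calendar(all_dates, all_dates %in% cloudy_dates)
}

#' The 2020 test-cycle acquisition calendar
#'
#' The next-cycle validation calendar: usable scenes every 15 days from late
#' April through early September 2020, anchored so that the evaluation dates
#' 6 May, 21 May, 5 June and 20 June are available with the lag partners each
#' combination requires (e.g. on 6 May only the 15-day-lag scheme can be
#' formed, from the 21 April scene).
#'
#' @return An [acquisition_calendar()]; intermediate 5-day overpasses are
#'   present but flagged cloudy.
#' @export
calendar_2020 <- function() {
  all_dates <- seq(as.Date("2020-04-06"), as.Date("2020-09-03"), by = 5)
  used <- seq(as.Date("2020-04-21"), as.Date("2020-09-03"), by = 15)
  acquisition_calendar(all_dates, !(all_dates %in% used))
}

#' Cloud-free dates of a calendar
#'
#' @param calendar An [acquisition_calendar()].
#' @return `Date` vector of the usable scene dates, ascending.
#' @export
cloudfree_dates <- function(calendar) {
  stopifnot(inherits(calendar, "acquisition_calendar") || is.data.frame(calendar))
  sort(as.Date(calendar$date[!calendar$cloudy]))
}
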