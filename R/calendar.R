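#' Observation calendar
#'
#' Event times are minutes since the onset of the observation period, so the
#' calendar only needs to know which weekday the observation started on to
#' classify any minute as weekday or weekend. Day `d` of the study covers
#' minutes `[d * 1440, (d + 1) * 1440)`.
#'
#' @param start_weekday Weekday on which minute 0 falls: integer 0--6
#'   (0 = Monday, 5 = Saturday, 6 = Sunday) or an English weekday name.
#'
#' @return A `rem_calendar` object (a list with `start_weekday` and
#'   `minutes_per_day`).
#' @examples
#' cal <- rem_calendar("Monday")
#' is_weekend(5 * 1440 + 10, cal) # Saturday
#' @export
rem_calendar <- function(start_weekday = 0L) {
  days <- c(
    "monday", "tuesday", "wednesday", "thursday",
    "friday", "saturday", "sunday"
  )
  if (is.character(start_weekday)) {
    idx <- match(tolower(start_weekday), days)
    if (is.na(idx)) {
      abort(paste0("unknown weekday name: ", start_weekday))
    }
    start_weekday <- idx - 1L
  }
  start_weekday <- as.integer(start_weekday)
  if (is.na(start_weekday) || start_weekday < 0L || start_weekday > 6L) {
    abort("start_weekday must be an integer in 0..6 (0 = Monday)")
  }
  structure(
    list(start_weekday = start_weekday, minutes_per_day = 1440),
    class = "rem_calendar"
  )
}

#' @param t Time in minutes since observation onset (non-negative).
#' @param calendar A [rem_calendar()].
#' @rdname rem_calendar
#' @export
is_weekend <- function(t, calendar = rem_calendar()) {
  if (any(t < 0)) {
    abort("t must be non-negative")
  }
  day <- floor(t / calendar$minutes_per_day)
  ((calendar$start_weekday + day) %% 7) %in% c(5, 6)
}
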