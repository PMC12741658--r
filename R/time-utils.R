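# Shared time arithmetic: the Europe/Helsinki reference zone, ISO-8601 parsing
# and the 3 PM-to-3 PM study-day window.
#
# All instants in the package are POSIXct (absolute epoch seconds) carrying the
# Europe/Helsinki tzone attribute for display. Window-relative minutes are
# elapsed minutes since the window's 15:00 local start; they are the only scale
# on which onset/offset arithmetic (means, deviations, differences) is done,
# because clock times wrap at midnight.

#' @keywords internal
HELSINKI_TZ <- "Europe/Helsinki"

#' Parse ISO-8601 timestamps into Helsinki-zone instants
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an explicit numeric UTC offset
#' (`+0200`, `+02:00`) or `Z`, or naive timestamps when `assume_tz` supplies
#' the zone they are expressed in. A `T` or space separator is accepted.
#' Conversion never moves an instant on the absolute timeline; only the
#' display zone becomes Europe/Helsinki.
#'
#' @param x character vector of timestamps.
#' @param assume_tz optional Olson zone name applied to naive timestamps.
#' @return POSIXct vector (tzone Europe/Helsinki); unparseable non-blank
#'   entries raise an error naming the offending value, blank entries become
#'   `NA` (removed later by [drop_missing()]).
#' @export
parse_instants <- function(x, assume_tz = NULL) {
  x <- as.character(x)
  out <- .POSIXct(rep(NA_real_, length(x)), tz = HELSINKI_TZ)
  blank <- is.na(x) | !nzchar(trimws(x))
  if (all(blank)) return(out)
  y <- trimws(x[!blank])
  y <- sub("T", " ", y, fixed = TRUE)
  y <- sub("Z$", "+0000", y)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  shaped <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2} [0-9]{2}:[0-9]{2}:[0-9]{2}", y)
  if (!all(shaped)) {
    stop("unparseable timestamp: '", y[!shaped][1], "'", call. = FALSE)
  }
  has_offset <- grepl("[+-][0-9]{4}$", y)
  sec <- rep(NA_real_, length(y))
  if (any(has_offset)) {
    p <- as.POSIXct(strptime(y[has_offset], "%Y-%m-%d %H:%M:%S%z", tz = "UTC"))
    sec[has_offset] <- as.numeric(p)
  }
  if (any(!has_offset)) {
    if (is.null(assume_tz)) {
      bad <- y[!has_offset][1]
      stop("naive timestamp '", bad, "' has no zone offset and no assume_tz ",
           "was supplied", call. = FALSE)
    }
    p <- as.POSIXct(strptime(y[!has_offset], "%Y-%m-%d %H:%M:%S",
                             tz = assume_tz))
    sec[!has_offset] <- as.numeric(p)
  }
  if (anyNA(sec)) {
    bad <- y[which(is.na(sec))[1]]
    stop("unparseable timestamp: '", bad, "'", call. = FALSE)
  }
  out[!blank] <- .POSIXct(sec, tz = HELSINKI_TZ)
  out
}

#' Format instants as ISO-8601 with numeric offset
#' @param x POSIXct vector.
#' @return character vector like `"2019-01-02T00:00:00+0200"`.
#' @export
format_instants <- function(x) {
  attr(x, "tzone") <- HELSINKI_TZ
  out <- format(x, "%Y-%m-%dT%H:%M:%S%z")
  out[is.na(x)] <- NA_character_
  out
}

#' Start of the 3 PM-to-3 PM window containing an instant
#'
#' Study days run from 15:00 local wall-clock to 15:00 the next day, half-open
#' `[15:00 D, 15:00 D+1)`. An instant before 15:00 therefore belongs to the
#' previous calendar date's window. DST transitions (03:00/04:00 in Finland)
#' never touch the 15:00 boundary, so windows partition the timeline.
#'
#' @param t POSIXct vector.
#' @return POSIXct vector of window starts (15:00 Helsinki local).
#' @export
window_start_of <- function(t) {
  lt <- as.POSIXlt(t, tz = HELSINKI_TZ)
  d <- as.Date(format(lt, "%Y-%m-%d"))
  before3pm <- lt$hour < 15L
  d[before3pm] <- d[before3pm] - 1L
  as.POSIXct(paste(format(d), "15:00:00"), tz = HELSINKI_TZ)
}

#' Assign an instant to its study day
#'
#' @param t POSIXct vector (Helsinki-local instants).
#' @return `Date` vector: the calendar date on which the enclosing
#'   3 PM-to-3 PM window starts.
#' @export
assign_day_window <- function(t) {
  as.Date(format(window_start_of(t), "%Y-%m-%d"))
}

#' 15:00 window start for a study day
#' @param study_day `Date` vector.
#' @return POSIXct window starts.
#' @export
study_day_start <- function(study_day) {
  as.POSIXct(paste(format(as.Date(study_day)), "15:00:00"), tz = HELSINKI_TZ)
}

#' Window-relative minutes of an instant
#'
#' Minutes elapsed since the 15:00 start of the window `anchor` belongs to
#' (default: the instant's own window). Offsets of episodes that started the
#' previous evening are measured against the onset's window, so they exceed
#' 540 (midnight) monotonically rather than wrapping.
#'
#' @param t POSIXct vector.
#' @param anchor POSIXct vector whose windows define the origin.
#' @return numeric minutes.
#' @export
window_rel_min <- function(t, anchor = t) {
  as.numeric(difftime(t, window_start_of(anchor), units = "mins"))
}

#' Render window-relative minutes as wall-clock "HH:MM"
#' @param rel_min numeric minutes since a 15:00 window start.
#' @return character clock strings.
#' @export
rel_min_to_clock <- function(rel_min) {
  m <- (900 + round(rel_min)) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
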