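# Ingest: read, validate, timezone-standardize and completeness-filter the
# four raw delimited streams.
#
# CSV schemas (version 1):
#   actigraph.csv    participant,timestamp,label    label in ACTIVE/REST/REST-S
#   bed.csv          participant,timestamp,status   status in 0/1/2/3
#   screen.csv       participant,timestamp,event    event in on/off/lock/unlock
#   ema.csv          participant,date,category      the seven TST categories
#   demographics.csv participant,age,sex,meq,group
# Timestamps are ISO-8601 with zone offset, or naive plus `assume_tz`.

#' The seven categorical total-sleep-time responses
#' @export
EMA_CATEGORIES <- c("under 5 hours", "5-6 hours", "6-7 hours", "7-8 hours",
                    "8-9 hours", "9-10 hours", "over 10 hours")

STREAM_SCHEMAS <- list(
  actigraph = list(value_col = "label",
                   values = c("ACTIVE", "REST", "REST-S"),
                   strict_increasing = TRUE),
  bed = list(value_col = "status", values = c("0", "1", "2", "3"),
             strict_increasing = TRUE),
  screen = list(value_col = "event", values = c("on", "off", "lock", "unlock"),
                strict_increasing = FALSE),
  ema = list(value_col = "category", values = NULL,  # filled below
             strict_increasing = TRUE)
)
STREAM_SCHEMAS$ema$values <- EMA_CATEGORIES

#' Read and validate one raw stream
#'
#' Parses a delimited file against one of the four stream schemas, validates
#' the categorical value column against its closed set (an unknown value is a
#' hard error naming the row), parses timestamps (unparseable non-blank
#' timestamps are a hard error; blank values/timestamps become `NA` for
#' [drop_missing()] to count and remove), and sorts by participant and time.
#' For the strictly sampled streams (actigraph, bed) duplicate
#' participant-timestamp rows keep the first occurrence with a warning; the
#' screen log may legitimately contain coincident events and is left as is.
#' EMA keeps the first response per participant-date.
#'
#' @param path CSV file path.
#' @param schema_name one of `"actigraph"`, `"bed"`, `"screen"`, `"ema"`.
#' @param assume_tz Olson zone applied to naive timestamps (default `NULL`:
#'   naive timestamps are an error).
#' @return a validated, sorted data.frame; timestamps as Helsinki-zone
#'   POSIXct (`ema` carries a `date` column instead). Attribute
#'   `schema` records the schema name.
#' @export
read_stream <- function(path, schema_name, assume_tz = NULL) {
  schema_name <- match.arg(schema_name, names(STREAM_SCHEMAS))
  sch <- STREAM_SCHEMAS[[schema_name]]
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  time_col <- if (schema_name == "ema") "date" else "timestamp"
  expected <- c("participant", time_col, sch$value_col)
  df <- as.data.frame(data.table::fread(path, colClasses = "character",
                                        showProgress = FALSE))
  if (!all(expected %in% names(df))) {
    stop("file ", path, " lacks required columns ",
         paste(setdiff(expected, names(df)), collapse = ", "),
         " for schema '", schema_name, "'", call. = FALSE)
  }
  df <- df[expected]
  validate_stream_values(df, sch, path)
  if (schema_name == "ema") {
    blank <- !nzchar(trimws(df$date))
    df$date[blank] <- NA
    d <- as.Date(df$date)
    if (any(is.na(d) & !is.na(df$date))) {
      stop("unparseable date in ", path, " at row ",
           which(is.na(d) & !is.na(df$date))[1], call. = FALSE)
    }
    df$date <- d
    df <- df[order(df$participant, df$date), , drop = FALSE]
    dup <- duplicated(df[c("participant", "date")]) & !is.na(df$date)
    if (any(dup)) {
      warning(sum(dup), " duplicate participant-date EMA responses; ",
              "keeping first", call. = FALSE)
      df <- df[!dup, , drop = FALSE]
    }
  } else {
    df$timestamp <- parse_instants(df$timestamp, assume_tz = assume_tz)
    df <- df[order(df$participant, df$timestamp), , drop = FALSE]
    if (sch$strict_increasing) {
      dup <- duplicated(df[c("participant", "timestamp")]) &
        !is.na(df$timestamp)
      if (any(dup)) {
        warning(sum(dup), " duplicate timestamps in ", schema_name,
                " stream; keeping first", call. = FALSE)
        df <- df[!dup, , drop = FALSE]
      }
    }
    if (schema_name == "bed") {
      df$status <- suppressWarnings(as.integer(df$status))
    }
  }
  blank_val <- if (is.character(df[[sch$value_col]])) {
    !nzchar(trimws(df[[sch$value_col]])) & !is.na(df[[sch$value_col]])
  } else rep(FALSE, nrow(df))
  df[[sch$value_col]][blank_val] <- NA
  rownames(df) <- NULL
  attr(df, "schema") <- schema_name
  df
}

validate_stream_values <- function(df, sch, path) {
  v <- trimws(df[[sch$value_col]])
  known <- v %in% sch$values | is.na(v) | !nzchar(v)
  if (!all(known)) {
    row <- which(!known)[1]
    stop("unknown ", sch$value_col, " value '", v[row], "' in ", path,
         " at row ", row, call. = FALSE)
  }
  invisible(TRUE)
}

#' Standardize a stream's timestamps to Europe/Helsinki
#'
#' Instants are absolute; this changes only the display zone, never the
#' position on the timeline. Naive (non-POSIXct) timestamp columns are an
#' error -- parse them with [parse_instants()] first, supplying `assume_tz`
#' if the source was naive.
#'
#' @param stream data.frame with a POSIXct `timestamp` column.
#' @return the stream with `tzone` set to Europe/Helsinki.
#' @export
standardize_timezone <- function(stream) {
  if (is.null(stream$timestamp)) return(stream)  # ema has no timestamps
  if (!inherits(stream$timestamp, "POSIXct")) {
    stop("timestamps are not zone-aware instants; parse them with ",
         "parse_instants(), supplying assume_tz for naive sources",
         call. = FALSE)
  }
  attr(stream$timestamp, "tzone") <- HELSINKI_TZ
  stream
}

#' Remove incomplete rows from a stream
#'
#' Drops rows whose timestamp/date or value column is missing, recording the
#' number removed in attribute `n_dropped`.
#'
#' @param stream a stream from [read_stream()].
#' @return the filtered stream.
#' @export
drop_missing <- function(stream) {
  sch_name <- attr(stream, "schema")
  value_col <- setdiff(names(stream), c("participant", "timestamp", "date"))[1]
  time_col <- if ("timestamp" %in% names(stream)) "timestamp" else "date"
  bad <- is.na(stream[[time_col]]) | is.na(stream[[value_col]])
  if (is.character(stream[[value_col]])) {
    bad <- bad | !nzchar(trimws(stream[[value_col]]))
  }
  out <- stream[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- sch_name
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Write a stream back to CSV
#'
#' Inverse of [read_stream()]: `read -> write -> read` is a fixed point.
#'
#' @param stream stream data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_stream <- function(stream, path) {
  df <- stream
  if (!is.null(df$timestamp) && inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- format_instants(df$timestamp)
  }
  if (!is.null(df$date)) df$date <- format(df$date)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a directory of raw stream files
#'
#' Convenience wrapper: reads whichever of `actigraph.csv`, `bed.csv`,
#' `screen.csv`, `ema.csv` and `demographics.csv` exist under `dir`, applying
#' [standardize_timezone()] and [drop_missing()] to each stream.
#'
#' @param dir directory containing the CSV files.
#' @param assume_tz passed to [read_stream()].
#' @return list with `streams` (named list), `demographics` (or `NULL`) and
#'   `dropped` (named counts of removed incomplete rows).
#' @export
read_stream_dir <- function(dir, assume_tz = NULL) {
  streams <- list()
  dropped <- integer()
  for (s in names(STREAM_SCHEMAS)) {
    f <- file.path(dir, paste0(s, ".csv"))
    if (file.exists(f)) {
      st <- read_stream(f, s, assume_tz = assume_tz)
      st <- standardize_timezone(st)
      st <- drop_missing(st)
      dropped[s] <- attr(st, "n_dropped")
      streams[[s]] <- st
    }
  }
  if (!length(streams)) stop("no stream files found in ", dir, call. = FALSE)
  demf <- file.path(dir, "demographics.csv")
  demographics <- if (file.exists(demf)) {
    as.data.frame(data.table::fread(demf, showProgress = FALSE))
  }
  list(streams = streams, demographics = demographics, dropped = dropped)
}
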