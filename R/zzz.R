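# Some container images ship R without a reachable Olson timezone database, in
# which case conversions to Europe/Helsinki silently degrade to UTC. All sleep
# windowing in this package is defined on Helsinki wall-clock time, so a broken
# tz database corrupts every derived onset/offset. Repair TZDIR at load time.

tz_database_ok <- function() {
  probe <- as.POSIXct("2019-01-01 22:00:00", tz = "UTC")
  lt <- as.POSIXlt(probe, tz = "Europe/Helsinki")
  # 22:00 UTC in winter must render as 00:00 local (+02:00)
  isTRUE(lt$hour == 0L)
}

ensure_tzdata <- function() {
  if (tz_database_ok()) return(invisible(TRUE))
  candidates <- c(
    file.path(R.home("share"), "zoneinfo"),
    file.path(Sys.getenv("CONDA_PREFIX"), "share", "zoneinfo"),
    file.path(dirname(dirname(R.home())), "share", "zoneinfo"),
    "/opt/conda/envs/bio/share/zoneinfo",
    "/usr/share/zoneinfo"
  )
  for (d in candidates) {
    if (file.exists(file.path(d, "Europe", "Helsinki"))) {
      Sys.setenv(TZDIR = d)
      if (tz_database_ok()) return(invisible(TRUE))
    }
  }
  warning("No working timezone database found; Europe/Helsinki conversions ",
          "may be incorrect", call. = FALSE)
  invisible(FALSE)
}

.onLoad <- function(libname, pkgname) {
  ensure_tzdata()
}
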