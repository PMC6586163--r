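# Pressure-trace CSV I/O.
#
# Format: optional '#'-prefixed header lines carrying event metadata
# (key: value), then a CSV with columns time_s, pressure_mpa.  Time is
# re-based so the annotated event is at t = 0.

#' Write a pressure trace to CSV
#'
#' @param trace a `pressure_trace` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# event_kind: %s", attr(trace, "event_kind")),
    sprintf("# event_magnitude_mpa: %.10g", attr(trace, "event_magnitude")),
    "# time_origin: event"), con)
  utils::write.table(as.data.frame(trace), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pressure trace from CSV
#'
#' Reads the two-column trace format written by [write_pressure_trace()];
#' `#` comment lines carry the event annotation.  The time axis is
#' re-based to start at 0.
#'
#' @param path file path.
#' @return a `pressure_trace` object.
#' @export
read_pressure_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kind <- sub("^# *event_kind: *", "", grep("event_kind:", meta_lines, value = TRUE))
  mag <- sub("^# *event_magnitude_mpa: *", "",
             grep("event_magnitude_mpa:", meta_lines, value = TRUE))
  df <- utils::read.csv(textConnection(grep("^#", lines, invert = TRUE,
                                            value = TRUE)))
  if (!all(c("time_s", "pressure_mpa") %in% names(df)))
    stop("trace CSV must have columns time_s, pressure_mpa", call. = FALSE)
  .new_trace(df$time_s - df$time_s[1], df$pressure_mpa,
             if (length(kind)) kind else "unknown",
             if (length(mag)) as.numeric(mag) else NA_real_)
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("Pressure trace: %d samples over %.1f s, event %s (%.4g MPa)\n",
              nrow(x), max(x$time_s), attr(x, "event_kind"),
              attr(x, "event_magnitude")))
  utils::head(as.data.frame(x))
}
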