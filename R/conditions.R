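# Typed conditions so callers (and tests) can distinguish failure modes.

stop_envlink <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "envlink_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

format_error     <- function(msg, ...) stop_envlink("envlink_format_error", msg, ...)
schema_error     <- function(msg, ...) stop_envlink("envlink_schema_error", msg, ...)
grid_error       <- function(msg, ...) stop_envlink("envlink_grid_error", msg, ...)
validation_error <- function(msg, ...) stop_envlink("envlink_validation_error", msg, ...)
ambiguity_error  <- function(msg, ...) stop_envlink("envlink_ambiguity_error", msg, ...)
geometry_error   <- function(msg, ...) stop_envlink("envlink_geometry_error", msg, ...)
nesting_error    <- function(msg, ...) stop_envlink("envlink_nesting_error", msg, ...)
uplift_error     <- function(msg, ...) stop_envlink("envlink_uplift_error", msg, ...)
config_error     <- function(msg, ...) stop_envlink("envlink_config_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict ISO 8601 calendar-date parser.  Sub-daily timestamps and
# out-of-range components are rejected, never coerced.
parse_iso_date <- function(x, context = "date") {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date(format=) NAs impossible dates such as month 13 or Feb 30
  bad <- which(is.na(d) | !ok)
  if (length(bad) > 0L) {
    validation_error(sprintf(
      "unparseable %s %s at row %d (expected ISO 8601 YYYY-MM-DD)",
      context, dQuote(x[bad[1L]]), bad[1L]
    ), rows = bad)
  }
  d
}
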