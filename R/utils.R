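# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse ISO 8601 timestamps to minute resolution
#'
#' Accepts "YYYY-mm-dd HH:MM", "YYYY-mm-ddTHH:MM" (optionally with seconds,
#' which are truncated) and bare dates. All times are timezone-naive and
#' interpreted on one clock (UTC internally).
#'
#' @param x character vector.
#' @return POSIXct (UTC), NA where unparseable.
#' @keywords internal
parse_timestamp <- function(x) {
  x <- sub("T", " ", trimws(as.character(x)), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss))
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss))
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d", tz = "UTC"))
  # truncate to whole minutes
  as.POSIXct(floor(as.numeric(out) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = "UTC")

# integer minutes elapsed from `origin`
minutes_from <- function(t, origin) {
  as.integer(round(as.numeric(difftime(t, origin, units = "mins"))))
}

# run `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
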