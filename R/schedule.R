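#' Construct a validated service schedule
#'
#' A schedule is an ordered collection of service legs — scheduled trips
#' between two locations with minute-resolution departure and arrival
#' timestamps and an optional carrying capacity — together with the
#' observation window that bounds them.
#'
#' @param legs data.frame with columns \code{leg_id}, \code{origin},
#'   \code{destination}, \code{depart_time}, \code{arrive_time} (POSIXct or
#'   ISO 8601 strings) and optionally \code{capacity}, \code{provider}.
#' @param window_start,window_end observation window bounds; inferred as
#'   \code{[min depart, max arrive]} when omitted (only possible with at
#'   least one leg).
#' @return an object of class \code{"schedule"}.
#' @export
schedule <- function(legs, window_start = NULL, window_end = NULL) {
  required <- c("leg_id", "origin", "destination", "depart_time", "arrive_time")
  miss <- setdiff(required, names(legs))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  legs <- as.data.frame(legs, stringsAsFactors = FALSE)
  if (!inherits(legs$depart_time, "POSIXct"))
    legs$depart_time <- parse_timestamp(legs$depart_time)
  if (!inherits(legs$arrive_time, "POSIXct"))
    legs$arrive_time <- parse_timestamp(legs$arrive_time)
  if (anyNA(legs$depart_time) || anyNA(legs$arrive_time))
    stop("unparseable timestamp in legs")
  legs$leg_id <- as.character(legs$leg_id)
  legs$origin <- as.character(legs$origin)
  legs$destination <- as.character(legs$destination)
  if (is.null(legs$capacity)) legs$capacity <- rep(NA_real_, nrow(legs))
  legs$capacity <- as.numeric(legs$capacity)
  if (is.null(legs$provider)) legs$provider <- rep(NA_character_, nrow(legs))
  if (nrow(legs)) {
    if (any(legs$arrive_time <= legs$depart_time))
      stop("every leg must have arrive_time strictly after depart_time")
    if (any(legs$origin == legs$destination))
      stop("self-loop legs (origin == destination) are not admitted")
    if (any(!is.na(legs$capacity) & legs$capacity < 0))
      stop("capacity must be non-negative")
  }
  if (is.null(window_start)) {
    if (!nrow(legs)) stop("window must be given explicitly for an empty schedule")
    window_start <- min(legs$depart_time)
  }
  if (is.null(window_end)) {
    if (!nrow(legs)) stop("window must be given explicitly for an empty schedule")
    window_end <- max(legs$arrive_time)
  }
  if (!inherits(window_start, "POSIXct")) window_start <- parse_timestamp(window_start)
  if (!inherits(window_end, "POSIXct")) window_end <- parse_timestamp(window_end)
  if (is.na(window_start) || is.na(window_end) || window_start >= window_end)
    stop("window_start must precede window_end")
  if (nrow(legs) &&
      (any(legs$depart_time < window_start) || any(legs$arrive_time > window_end)))
    stop("all legs must lie within [window_start, window_end]")
  legs$depart_min <- minutes_from(legs$depart_time, window_start)
  legs$arrive_min <- minutes_from(legs$arrive_time, window_start)
  rownames(legs) <- NULL
  structure(
    list(legs = legs, window_start = window_start, window_end = window_end,
         rejected = data.frame(line = integer(), reason = character())),
    class = "schedule")
}

#' Read a service timetable from CSV
#'
#' Expected columns (exact names, remappable via \code{col_map}):
#' \code{leg_id, origin, destination, depart_time, arrive_time} plus optional
#' \code{capacity} and \code{provider}. Timestamps are ISO 8601 at minute
#' resolution. Rows violating leg invariants (non-positive duration,
#' self-loop origin == destination, unparseable timestamp, negative capacity,
#' outside an explicitly supplied window) are rejected individually; their
#' file line numbers and reasons are kept in the returned object's
#' \code{rejected} field.
#'
#' @param path CSV file path.
#' @param window optional length-2 vector (POSIXct or ISO 8601 strings); when
#'   absent the window is inferred as \code{[min depart, max arrive]} over the
#'   accepted rows.
#' @param col_map optional named character vector mapping the standard column
#'   names to the names used in the file, e.g.
#'   \code{c(origin = "from_port")} — useful for third-party exports whose
#'   layout differs.
#' @return a \code{"schedule"} object; see [schedule()].
#' @export
read_schedule <- function(path, window = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  required <- c("leg_id", "origin", "destination", "depart_time", "arrive_time")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("schedule file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) stop("schedule file contains no data rows")

  dep <- parse_timestamp(raw$depart_time)
  arr <- parse_timestamp(raw$arrive_time)
  cap <- if ("capacity" %in% names(raw)) {
    suppressWarnings(as.numeric(ifelse(raw$capacity == "", NA, raw$capacity)))
  } else rep(NA_real_, nrow(raw))
  cap_given <- if ("capacity" %in% names(raw)) raw$capacity != ""
               else rep(FALSE, nrow(raw))

  win <- NULL
  if (!is.null(window)) {
    win <- if (inherits(window, "POSIXct")) window else parse_timestamp(window)
    if (length(win) != 2 || anyNA(win)) stop("window must be two valid timestamps")
  }

  reason <- rep(NA_character_, nrow(raw))
  bad_dep <- is.na(dep)
  bad_arr <- is.na(arr)
  reason[bad_dep | bad_arr] <- "unparseable timestamp"
  ok <- is.na(reason)
  reason[ok & arr <= dep] <- "arrive_time not strictly after depart_time"
  ok <- is.na(reason)
  reason[ok & raw$origin == raw$destination] <-
    "self-loop leg (origin equals destination)"
  ok <- is.na(reason)
  if ("capacity" %in% names(raw)) {
    bad_cap <- ok & cap_given & (is.na(cap) | cap < 0)
    reason[bad_cap] <- "capacity not a non-negative number"
    ok <- is.na(reason)
  }
  if (!is.null(win)) {
    reason[ok & (dep < win[1] | arr > win[2])] <- "leg outside observation window"
    ok <- is.na(reason)
  }

  rejected <- data.frame(line = which(!ok) + 1L,  # +1 for the header row
                         reason = reason[!ok], stringsAsFactors = FALSE)
  if (!any(ok))
    stop("no valid service legs in ", path, " (",
         nrow(rejected), " row(s) rejected)")

  legs <- data.frame(
    leg_id = raw$leg_id[ok], origin = raw$origin[ok],
    destination = raw$destination[ok],
    depart_time = dep[ok], arrive_time = arr[ok],
    capacity = cap[ok],
    provider = if ("provider" %in% names(raw)) raw$provider[ok] else NA_character_,
    stringsAsFactors = FALSE)
  sched <- schedule(legs,
                    window_start = if (is.null(win)) NULL else win[1],
                    window_end = if (is.null(win)) NULL else win[2])
  sched$rejected <- rejected
  sched
}

#' Write a schedule back to CSV
#'
#' Inverse of [read_schedule()]: the written file round-trips to a field-wise
#' equal schedule. Timestamps are written as ISO 8601 to the minute; absent
#' capacities/providers as empty cells.
#'
#' @param x a \code{"schedule"} object.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "schedule"))
  out <- data.frame(
    leg_id = x$legs$leg_id, origin = x$legs$origin,
    destination = x$legs$destination,
    depart_time = format_timestamp(x$legs$depart_time),
    arrive_time = format_timestamp(x$legs$arrive_time),
    capacity = ifelse(is.na(x$legs$capacity), "",
                      format(x$legs$capacity, trim = TRUE, scientific = FALSE)),
    provider = ifelse(is.na(x$legs$provider), "", x$legs$provider),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.schedule <- function(x, ...) {
  cat("Service schedule:", nrow(x$legs), "legs,",
      length(unique(c(x$legs$origin, x$legs$destination))), "locations\n")
  cat("Window:", format_timestamp(x$window_start), "to",
      format_timestamp(x$window_end), "\n")
  if (nrow(x$rejected))
    cat("Rejected on read:", nrow(x$rejected), "row(s)\n")
  invisible(x)
}

#' Build a symmetric location-pair distance table
#'
#' @param loc_a,loc_b location identifiers (character vectors of equal length).
#' @param distance positive distances (nautical miles in the maritime
#'   application).
#' @return an object of class \code{"distance_table"}.
#' @export
distance_table <- function(loc_a, loc_b, distance) {
  loc_a <- as.character(loc_a); loc_b <- as.character(loc_b)
  distance <- as.numeric(distance)
  if (length(loc_a) != length(loc_b) || length(loc_a) != length(distance))
    stop("loc_a, loc_b and distance must have equal length")
  if (any(is.na(distance) | distance <= 0))
    stop("all distances must be positive")
  if (any(loc_a == loc_b))
    stop("distance entries must relate two distinct locations")
  key <- paste(pmin(loc_a, loc_b), pmax(loc_a, loc_b), sep = "\r")
  # collapse consistent duplicates; conflicting duplicates are an error
  agg_min <- tapply(distance, key, min)
  agg_max <- tapply(distance, key, max)
  conflict <- names(agg_min)[agg_min != agg_max]
  if (length(conflict))
    stop("conflicting duplicate distance for pair(s): ",
         paste(gsub("\r", "-", conflict), collapse = ", "))
  keys <- names(agg_min)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  entries <- data.frame(
    loc_a = vapply(parts, `[`, "", 1L),
    loc_b = vapply(parts, `[`, "", 2L),
    distance = as.numeric(agg_min),
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "distance_table")
}

#' Read a symmetric distance table from CSV
#'
#' Columns: \code{loc_a, loc_b, nautical_miles}. Lookup is symmetric;
#' duplicated pairs with equal distance collapse silently, conflicting
#' duplicates raise a consistency error, non-positive distances are row
#' errors.
#'
#' @param path CSV file path.
#' @return a \code{"distance_table"}.
#' @export
read_distance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("loc_a", "loc_b", "nautical_miles")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("distance file is missing required column(s): ",
         paste(miss, collapse = ", "))
  d <- suppressWarnings(as.numeric(raw$nautical_miles))
  bad <- which(is.na(d) | d <= 0)
  if (length(bad))
    stop("non-positive or unparseable distance on data row(s): ",
         paste(bad, collapse = ", "))
  distance_table(raw$loc_a, raw$loc_b, d)
}

#' Look up the distance between two locations
#'
#' @param dt a \code{"distance_table"}.
#' @param a,b location identifiers (vectorised).
#' @return numeric distances; NA where the pair is absent.
#' @export
distance_lookup <- function(dt, a, b) {
  stopifnot(inherits(dt, "distance_table"))
  a <- as.character(a); b <- as.character(b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(dt$entries$loc_a, dt$entries$loc_b, sep = "\r")
  dt$entries$distance[match(key, tab_key)]
}

#' @export
print.distance_table <- function(x, ...) {
  cat("Distance table:", nrow(x$entries), "location pairs\n")
  invisible(x)
}

#' Write a per-location metric table as a ranking CSV
#'
#' One row per location, one column per metric. Rows are sorted by the first
#' metric column, descending, with ties broken by location name ascending, so
#' identical inputs always produce byte-identical files.
#'
#' @param table data.frame whose first column is \code{location} followed by
#'   one or more numeric metric columns.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metric_table <- function(table, path) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!nrow(table)) stop("metric table is empty")
  if (names(table)[1] != "location")
    stop("first column must be 'location'")
  if (ncol(table) < 2) stop("metric table needs at least one metric column")
  ord <- order(-table[[2]], table$location)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
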