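# Synthetic timetables: a deterministic 4-port worked example used throughout
# the documentation and tests, and a seeded random generator emulating the
# shape of consolidated multi-provider ferry schedules (recurring legs over a
# 14-day window, leg durations from hours to days, port reuse across routes).

#' The 4-port worked-example schedule
#'
#' A small deterministic timetable over ports P1..P4 whose space-time network
#' exercises every rule of the abstraction. With the default (30, 180) minute
#' switching window, the waits of 60 min at P2 and 120 min at P3 admit
#' switches, so exactly three admissible paths leave P1's departure position:
#' the single leg to P2, its extension to P3, and the full chain to P4. The
#' second departure from P3 sits 270 min after the arrival there — outside
#' the default window but inside a widened upper bound of 360 min, which
#' \emph{adds} a fourth path from P1 (and a third from P2), illustrating how
#' the upper bound drives connectivity.
#'
#' @return list with components \code{schedule}, \code{distances} (symmetric
#'   nautical-mile table for the three served pairs) and \code{config} (the
#'   default binary [build_config()]).
#' @examples
#' toy <- toy_schedule()
#' coef(spread_potential(toy$schedule, toy$config))
#' @export
toy_schedule <- function() {
  base <- as.POSIXct("2015-08-03 00:00", tz = "UTC")
  mins <- function(m) base + 60 * m
  legs <- data.frame(
    leg_id = c("L1", "L2", "L3", "L4"),
    origin = c("P1", "P2", "P3", "P3"),
    destination = c("P2", "P3", "P4", "P4"),
    depart_time = mins(c(120, 300, 690, 840)),
    arrive_time = mins(c(240, 570, 780, 900)),
    capacity = c(350, 500, 420, 280),
    provider = "toy",
    stringsAsFactors = FALSE)
  sched <- schedule(legs, window_start = base, window_end = mins(960))
  dists <- distance_table(c("P1", "P2", "P3"), c("P2", "P3", "P4"),
                          c(100, 150, 80))
  list(schedule = sched, distances = dists, config = build_config())
}

#' Generate a random synthetic timetable
#'
#' Draws a set of directed routes (ordered port pairs) and schedules
#' \code{departures_per_route} legs on each, with departure times uniform
#' over the window at minute resolution, leg durations and capacities uniform
#' over their ranges, and a symmetric distance for every served pair. With
#' \code{weekly = TRUE} departures are drawn as a 7-day template repeated
#' across the window, matching the periodic structure of real liner
#' timetables. Defaults mirror the shape of a two-week consolidated European
#' ferry dataset: 125 ports, 210 routes, legs lasting two hours to two days.
#'
#' @param n_ports number of ports (>= 2).
#' @param n_routes number of directed routes; at most
#'   \code{n_ports * (n_ports - 1)}.
#' @param window_days observation window length in days.
#' @param departures_per_route scheduled departures per route (per template
#'   week when \code{weekly = TRUE}).
#' @param leg_duration_range leg duration range in minutes.
#' @param capacity_range carrying-capacity range (units, e.g. lane metres or
#'   passengers).
#' @param distance_range port-pair distance range in nautical miles.
#' @param weekly repeat a 7-day departure template across the window.
#' @param seed integer RNG seed; the caller's RNG state is left untouched.
#' @return list with components \code{schedule} and \code{distances}.
#' @export
generate_schedule <- function(n_ports = 125, n_routes = 210,
                              window_days = 14, departures_per_route = 5,
                              leg_duration_range = c(120, 2880),
                              capacity_range = c(100, 2500),
                              distance_range = c(20, 1500),
                              weekly = FALSE, seed = 1) {
  stopifnot(n_ports >= 2, n_routes >= 1, window_days >= 1,
            departures_per_route >= 1,
            leg_duration_range[1] <= leg_duration_range[2],
            capacity_range[1] <= capacity_range[2],
            distance_range[1] <= distance_range[2],
            leg_duration_range[1] >= 1,
            leg_duration_range[2] < window_days * 1440)
  if (n_routes > n_ports * (n_ports - 1))
    stop("n_routes exceeds the number of distinct ordered port pairs")
  with_seed(seed, {
    ports <- sprintf("PORT%03d", seq_len(n_ports))
    # sample distinct ordered pairs by index
    pair_idx <- sample.int(n_ports * (n_ports - 1), n_routes)
    o_idx <- (pair_idx - 1L) %/% (n_ports - 1L) + 1L
    d_off <- (pair_idx - 1L) %% (n_ports - 1L) + 1L
    d_idx <- ifelse(d_off >= o_idx, d_off + 1L, d_off)
    origins <- ports[o_idx]; dests <- ports[d_idx]

    window_min <- window_days * 1440L
    rows <- vector("list", n_routes)
    for (r in seq_len(n_routes)) {
      dur <- round(stats::runif(departures_per_route,
                                leg_duration_range[1], leg_duration_range[2]))
      if (weekly) {
        tmpl_span <- min(7L * 1440L, window_min)
        tmpl <- floor(stats::runif(departures_per_route,
                                   0, pmax(1, tmpl_span - dur)))
        reps <- seq(0L, window_min - 1L, by = 7L * 1440L)
        dep <- as.vector(outer(tmpl, reps, `+`))
        dur <- rep(dur, length(reps))
        keep <- dep + dur <= window_min
        dep <- dep[keep]; dur <- dur[keep]
      } else {
        dep <- floor(stats::runif(departures_per_route,
                                  0, pmax(1, window_min - dur)))
      }
      cap <- round(stats::runif(length(dep),
                                capacity_range[1], capacity_range[2]))
      rows[[r]] <- data.frame(
        origin = origins[r], destination = dests[r],
        depart = dep, arrive = dep + dur, capacity = cap,
        provider = sprintf("PROV%02d", (r - 1L) %% 18L + 1L),
        stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, rows)
    base <- as.POSIXct("2015-08-03 00:00", tz = "UTC")
    legs <- data.frame(
      leg_id = sprintf("L%05d", seq_len(nrow(all_rows))),
      origin = all_rows$origin, destination = all_rows$destination,
      depart_time = base + 60 * all_rows$depart,
      arrive_time = base + 60 * all_rows$arrive,
      capacity = all_rows$capacity, provider = all_rows$provider,
      stringsAsFactors = FALSE)
    sched <- schedule(legs, window_start = base,
                      window_end = base + 60 * window_min)
    pairs <- unique(data.frame(a = pmin(origins, dests),
                               b = pmax(origins, dests),
                               stringsAsFactors = FALSE))
    dists <- distance_table(pairs$a, pairs$b,
                            round(stats::runif(nrow(pairs),
                                               distance_range[1],
                                               distance_range[2]), 1))
    list(schedule = sched, distances = dists)
  })
}
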