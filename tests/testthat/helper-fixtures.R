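# In-code fixtures shared across test files. All times minute-resolution,
# anchored at an arbitrary August 2015 origin.

t0 <- as.POSIXct("2015-08-03 00:00", tz = "UTC")

# quick schedule builder from minute offsets
mk_schedule <- function(origin, destination, dep_min, arr_min,
                        capacity = NA_real_, window_min = NULL) {
  legs <- data.frame(
    leg_id = sprintf("L%02d", seq_along(origin)),
    origin = origin, destination = destination,
    depart_time = t0 + 60 * dep_min, arrive_time = t0 + 60 * arr_min,
    capacity = capacity, stringsAsFactors = FALSE)
  schedule(legs,
           window_start = t0,
           window_end = t0 + 60 * (window_min %||% (max(arr_min) + 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the two-leg chain used in the worked spread-potential examples:
# A -> B over (0, 60), B -> C over (120, 240); the 60-min wait at B is
# admissible under the default (30, 180) window
chain_schedule <- function() {
  mk_schedule(c("A", "B"), c("B", "C"), c(0, 120), c(60, 240),
              capacity = c(10, 20))
}

# seeded random small instance: <= 8 ports, <= 25 legs
rand_small <- function(seed) {
  set.seed(seed)
  n_ports <- sample(3:8, 1)
  n_routes <- sample(2:min(8, n_ports * (n_ports - 1)), 1)
  deps <- sample(1:3, 1)
  generate_schedule(n_ports = n_ports, n_routes = n_routes,
                    window_days = 3, departures_per_route = deps,
                    leg_duration_range = c(30, 600),
                    capacity_range = c(50, 500),
                    distance_range = c(10, 400),
                    seed = seed * 7 + 1)
}
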