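#' Configuration for the space-time network abstraction
#'
#' Controls how a schedule is abstracted into the weighted directed
#' space-time graph and how the path engine aggregates it.
#'
#' @param t_lower,t_upper waiting-time bounds in minutes for switching links:
#'   an arrival at a port connects to a later departure from the same port
#'   only when the gap lies \emph{strictly} between the two bounds. Defaults
#'   30 and 180 — a traveller can feasibly switch within 30 minutes and is
#'   willing to wait up to 3 hours.
#' @param weight_mode how crossing links are weighted: \code{"binary"} (every
#'   leg weighs 1), \code{"capacity"} (the leg's carrying capacity, times
#'   \code{capacity_scale}), or \code{"distance"} (a distance proxy between
#'   the two ports, requiring a distance table).
#' @param switch_weight weight placed on switching links. Defaults to exactly
#'   0 — the limit of a minimum positive weight approaching zero — so that
#'   binary Spread Potential values stay integral; any small positive epsilon
#'   may be configured instead.
#' @param capacity_scale positive multiplier applied to capacities, e.g. a
#'   basic-reproduction-number adjustment in epidemiological use.
#' @param consecutive_only if TRUE, each arrival connects only to the
#'   \emph{next} departure from the port (if admissible) rather than to every
#'   admissible later departure; exposed for sensitivity analysis.
#' @param count_dangling_switch if TRUE, candidate paths terminating on a
#'   switching link are counted as paths in their own right; the default
#'   (FALSE) terminates every path on a crossing link, since a dangling wait
#'   transmits nothing beyond its prefix.
#' @param max_path_len guard on path length in crossing links; the default
#'   (number of ports) can never bind because admissible paths visit each
#'   port at most once. Engines flag \code{truncated} rather than fail when
#'   a smaller guard trips.
#' @return an object of class \code{"build_config"}.
#' @export
build_config <- function(t_lower = 30, t_upper = 180,
                         weight_mode = c("binary", "capacity", "distance"),
                         switch_weight = 0, capacity_scale = 1,
                         consecutive_only = FALSE,
                         count_dangling_switch = FALSE,
                         max_path_len = NULL) {
  weight_mode <- match.arg(weight_mode)
  t_lower <- as.numeric(t_lower); t_upper <- as.numeric(t_upper)
  if (is.na(t_lower) || is.na(t_upper) || t_lower < 0 || t_lower >= t_upper)
    stop("time bounds must satisfy 0 <= t_lower < t_upper")
  if (switch_weight < 0) stop("switch_weight must be non-negative")
  if (capacity_scale <= 0) stop("capacity_scale must be positive")
  structure(
    list(t_lower = t_lower, t_upper = t_upper, weight_mode = weight_mode,
         switch_weight = switch_weight, capacity_scale = capacity_scale,
         consecutive_only = isTRUE(consecutive_only),
         count_dangling_switch = isTRUE(count_dangling_switch),
         max_path_len = max_path_len),
    class = "build_config")
}

#' @export
print.build_config <- function(x, ...) {
  cat("Space-time network configuration\n")
  cat("  switching window: (", x$t_lower, ", ", x$t_upper, ") min, strict\n",
      sep = "")
  cat("  weight mode:", x$weight_mode,
      if (x$weight_mode == "capacity") paste0("(scale ", x$capacity_scale, ")"),
      "\n")
  cat("  switch weight:", x$switch_weight, "\n")
  invisible(x)
}

#' Derive the position set of a schedule
#'
#' A position is a timed enter/exit event at a location: one EXIT per
#' distinct (origin, departure minute) and one ENTER per distinct
#' (destination, arrival minute). Events shared by several legs merge into a
#' single position.
#'
#' @param sched a \code{"schedule"}.
#' @return data.frame with columns \code{id}, \code{location}, \code{time}
#'   (integer minutes from window start), \code{kind} ("EXIT"/"ENTER") and a
#'   human-readable \code{label}.
#' @export
build_positions <- function(sched) {
  stopifnot(inherits(sched, "schedule"))
  legs <- sched$legs
  if (!nrow(legs)) {
    return(data.frame(id = integer(), location = character(),
                      time = integer(), kind = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  ev <- rbind(
    data.frame(location = legs$origin, time = legs$depart_min,
               kind = "EXIT", stringsAsFactors = FALSE),
    data.frame(location = legs$destination, time = legs$arrive_min,
               kind = "ENTER", stringsAsFactors = FALSE))
  ev <- unique(ev)
  ev <- ev[order(ev$time, ev$location, ev$kind), , drop = FALSE]
  ev$id <- seq_len(nrow(ev))
  ev$label <- sprintf(
    "p_%s.%s", ev$location,
    format_timestamp(sched$window_start + 60 * ev$time))
  rownames(ev) <- NULL
  ev[, c("id", "location", "time", "kind", "label")]
}

pos_key <- function(location, time, kind) paste(location, time, kind, sep = "\r")

#' Build the crossing links of a space-time network
#'
#' One directed link per scheduled leg, from the EXIT position at the origin
#' to the ENTER position at the destination, weighted per the configured
#' mode.
#'
#' @param sched a \code{"schedule"}.
#' @param config a [build_config()].
#' @param distances \code{"distance_table"}, required for
#'   \code{weight_mode = "distance"}.
#' @param positions positions as returned by [build_positions()]; computed
#'   when omitted.
#' @return data.frame with columns \code{src}, \code{dst} (position ids),
#'   \code{weight}, \code{leg_id}.
#' @export
build_crossing_links <- function(sched, config = build_config(),
                                 distances = NULL, positions = NULL) {
  stopifnot(inherits(sched, "schedule"), inherits(config, "build_config"))
  if (is.null(positions)) positions <- build_positions(sched)
  legs <- sched$legs
  if (!nrow(legs)) {
    return(data.frame(src = integer(), dst = integer(),
                      weight = numeric(), leg_id = character(),
                      stringsAsFactors = FALSE))
  }
  key <- pos_key(positions$location, positions$time, positions$kind)
  src <- positions$id[match(pos_key(legs$origin, legs$depart_min, "EXIT"), key)]
  dst <- positions$id[match(pos_key(legs$destination, legs$arrive_min, "ENTER"), key)]
  weight <- switch(
    config$weight_mode,
    binary = rep(1, nrow(legs)),
    capacity = {
      if (anyNA(legs$capacity))
        stop("capacity weight mode requires a capacity on every leg; missing for leg(s): ",
             paste(legs$leg_id[is.na(legs$capacity)], collapse = ", "))
      legs$capacity * config$capacity_scale
    },
    distance = {
      if (is.null(distances))
        stop("distance weight mode requires a distance table")
      d <- distance_lookup(distances, legs$origin, legs$destination)
      if (anyNA(d)) {
        bad <- which(is.na(d))[1]
        stop("no distance for pair ", legs$origin[bad], "-",
             legs$destination[bad])
      }
      d
    })
  data.frame(src = src, dst = dst, weight = weight, leg_id = legs$leg_id,
             stringsAsFactors = FALSE)
}

#' Build the switching (waiting) links of a space-time network
#'
#' For every port, a link from each ENTER position to each strictly later
#' EXIT position at the same port whose waiting gap lies strictly inside the
#' configured \code{(t_lower, t_upper)} window. Only arrival-to-departure
#' pairs are connected: ENTER-ENTER and EXIT-EXIT pairs have no boarding
#' semantics.
#'
#' @param positions positions as returned by [build_positions()].
#' @param config a [build_config()].
#' @return data.frame with columns \code{src}, \code{dst}, \code{weight}.
#' @export
build_switching_links <- function(positions, config = build_config()) {
  stopifnot(inherits(config, "build_config"))
  out_src <- integer(); out_dst <- integer()
  for (loc in unique(positions$location)) {
    ent <- positions[positions$location == loc & positions$kind == "ENTER", ]
    ext <- positions[positions$location == loc & positions$kind == "EXIT", ]
    if (!nrow(ent) || !nrow(ext)) next
    ext <- ext[order(ext$time), , drop = FALSE]
    for (i in seq_len(nrow(ent))) {
      gap <- ext$time - ent$time[i]
      ok <- gap > config$t_lower & gap < config$t_upper
      if (config$consecutive_only) {
        nxt <- which(gap > 0)[1]            # first departure after the arrival
        ok <- ok & seq_along(gap) == (if (is.na(nxt)) 0L else nxt)
      }
      if (any(ok)) {
        out_src <- c(out_src, rep(ent$id[i], sum(ok)))
        out_dst <- c(out_dst, ext$id[ok])
      }
    }
  }
  data.frame(src = out_src, dst = out_dst,
             weight = rep(config$switch_weight, length(out_src)))
}

#' Abstract a weighted directed space-time network from a schedule
#'
#' Assembles positions, crossing links and switching links into the
#' time-expanded graph on which Spread Potential is defined. Every link
#' strictly increases time, so the result is acyclic by construction.
#'
#' @inheritParams build_crossing_links
#' @return an object of class \code{"stnet"} with fields \code{positions},
#'   \code{crossing}, \code{switching}, \code{ports}, \code{config},
#'   \code{window_start}, \code{window_end}.
#' @seealso [spread_potential()], [enumerate_paths()], [as_igraph()]
#' @export
build_network <- function(sched, config = build_config(), distances = NULL) {
  stopifnot(inherits(sched, "schedule"))
  positions <- build_positions(sched)
  crossing <- build_crossing_links(sched, config, distances, positions)
  switching <- build_switching_links(positions, config)
  structure(
    list(positions = positions, crossing = crossing, switching = switching,
         ports = sort(unique(c(sched$legs$origin, sched$legs$destination))),
         config = config,
         window_start = sched$window_start, window_end = sched$window_end),
    class = "stnet")
}

#' @export
print.stnet <- function(x, ...) {
  cat("Space-time network:", length(x$ports), "ports,",
      nrow(x$positions), "positions,",
      nrow(x$crossing), "crossing links,",
      nrow(x$switching), "switching links\n")
  cat("  switching window (", x$config$t_lower, ", ", x$config$t_upper,
      ") min, weights: ", x$config$weight_mode, "\n", sep = "")
  invisible(x)
}

#' Positions of a space-time network
#'
#' @param net an \code{"stnet"}.
#' @return the positions data.frame (id, location, time, kind, label).
#' @export
positions <- function(net) {
  stopifnot(inherits(net, "stnet"))
  net$positions
}

#' Convert a space-time network to an igraph graph
#'
#' Vertices are positions (named by label), edges are crossing and switching
#' links with \code{weight} and \code{type} attributes. Useful for structural
#' checks (e.g. the network is always a DAG) and for plotting.
#'
#' @param net an \code{"stnet"}.
#' @return an \code{igraph} directed graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "stnet"))
  edges <- rbind(
    if (nrow(net$crossing))
      data.frame(from = net$crossing$src, to = net$crossing$dst,
                 weight = net$crossing$weight, type = "crossing"),
    if (nrow(net$switching))
      data.frame(from = net$switching$src, to = net$switching$dst,
                 weight = net$switching$weight, type = "switching"))
  g <- igraph::make_empty_graph(n = nrow(net$positions), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = net$positions$label)
  g <- igraph::set_vertex_attr(g, "location", value = net$positions$location)
  g <- igraph::set_vertex_attr(g, "time", value = net$positions$time)
  g <- igraph::set_vertex_attr(g, "kind", value = net$positions$kind)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                           weight = edges$weight, type = edges$type)
  }
  g
}
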