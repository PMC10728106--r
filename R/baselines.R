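# Comparison measures on static (snapshot) and snapshot-series abstractions:
# node strength / out-strength, PageRank, temporal degree, temporal closeness.

#' Aggregate a schedule into a static snapshot graph
#'
#' Sums all leg realizations in the observation window per ordered port pair:
#' binary weighting counts legs, distance weighting sums the port-pair
#' distance once per leg. This is the "snapshot" abstraction that temporal
#' measures are designed to improve upon.
#'
#' @param sched a \code{"schedule"}.
#' @param weight_mode \code{"binary"} or \code{"distance"}.
#' @param distances \code{"distance_table"} when \code{weight_mode} is
#'   \code{"distance"}.
#' @return object of class \code{"snapshot_graph"}: list with \code{edges}
#'   (data.frame \code{src}, \code{dst}, \code{weight}) and \code{nodes}.
#' @export
aggregate_snapshot <- function(sched, weight_mode = c("binary", "distance"),
                               distances = NULL) {
  stopifnot(inherits(sched, "schedule"))
  weight_mode <- match.arg(weight_mode)
  legs <- sched$legs
  nodes <- sort(unique(c(legs$origin, legs$destination)))
  if (!nrow(legs)) {
    return(structure(list(edges = data.frame(src = character(),
                                             dst = character(),
                                             weight = numeric()),
                          nodes = nodes, weight_mode = weight_mode),
                     class = "snapshot_graph"))
  }
  w <- if (weight_mode == "binary") rep(1, nrow(legs)) else {
    if (is.null(distances)) stop("distance weighting requires a distance table")
    d <- distance_lookup(distances, legs$origin, legs$destination)
    if (anyNA(d)) {
      bad <- which(is.na(d))[1]
      stop("no distance for pair ", legs$origin[bad], "-", legs$destination[bad])
    }
    d
  }
  key <- paste(legs$origin, legs$destination, sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    src = vapply(parts, `[`, "", 1L),
    dst = vapply(parts, `[`, "", 2L),
    weight = as.numeric(agg), stringsAsFactors = FALSE)
  edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, weight_mode = weight_mode),
            class = "snapshot_graph")
}

#' @export
print.snapshot_graph <- function(x, ...) {
  cat("Snapshot graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges (", x$weight_mode, "weights )\n")
  invisible(x)
}

#' Node strength on a snapshot graph
#'
#' Sum of incident edge weights per node: out-strength (throughput set for
#' further distribution), in-strength, or their total.
#'
#' @param g a \code{"snapshot_graph"}.
#' @param direction \code{"total"}, \code{"out"} or \code{"in"}.
#' @return named numeric vector over all nodes (zeros included).
#' @export
node_strength <- function(g, direction = c("total", "out", "in")) {
  stopifnot(inherits(g, "snapshot_graph"))
  direction <- match.arg(direction)
  out <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    if (direction %in% c("out", "total")) {
      s <- tapply(g$edges$weight, g$edges$src, sum)
      out[names(s)] <- out[names(s)] + s
    }
    if (direction %in% c("in", "total")) {
      s <- tapply(g$edges$weight, g$edges$dst, sum)
      out[names(s)] <- out[names(s)] + s
    }
  }
  out
}

#' PageRank on a snapshot graph
#'
#' Weighted directed PageRank with uniform teleportation; dangling mass is
#' redistributed uniformly. Computed with \pkg{igraph}'s exact solver. The
#' returned vector sums to 1.
#'
#' @param g a \code{"snapshot_graph"}.
#' @param damping damping factor, default 0.85 as in the original
#'   formulation.
#' @return named numeric vector over all nodes.
#' @export
pagerank <- function(g, damping = 0.85) {
  stopifnot(inherits(g, "snapshot_graph"))
  if (!length(g$nodes)) stop("empty graph")
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("src", "dst", "weight")],
    directed = TRUE, vertices = data.frame(name = g$nodes))
  pr <- igraph::page_rank(ig, damping = damping,
                          weights = if (nrow(g$edges)) igraph::E(ig)$weight
                                    else NULL)$vector
  pr[g$nodes]
}

#' Parse a schedule into a series of equal-interval snapshot graphs
#'
#' The observation window is cut into \code{ceiling(window / interval)}
#' intervals (days by default); each leg is assigned to the snapshot
#' containing its departure. All snapshots share the full node set so that
#' per-node series line up.
#'
#' @param sched a \code{"schedule"}.
#' @param interval interval length in minutes (default 1440 = one day).
#' @param weight_mode \code{"binary"} or \code{"distance"}.
#' @param distances distance table for distance weighting.
#' @return object of class \code{"snapshot_series"}: list with
#'   \code{snapshots} (list of \code{"snapshot_graph"}), \code{nodes},
#'   \code{interval}.
#' @export
snapshot_series <- function(sched, interval = 1440,
                            weight_mode = c("binary", "distance"),
                            distances = NULL) {
  stopifnot(inherits(sched, "schedule"))
  weight_mode <- match.arg(weight_mode)
  window_min <- minutes_from(sched$window_end, sched$window_start)
  n_snap <- as.integer(ceiling(window_min / interval))
  legs <- sched$legs
  nodes <- sort(unique(c(legs$origin, legs$destination)))
  idx <- pmin(legs$depart_min %/% as.integer(interval), n_snap - 1L) + 1L
  snaps <- lapply(seq_len(n_snap), function(s) {
    sub <- legs[idx == s, , drop = FALSE]
    g <- if (nrow(sub)) {
      sub_sched <- sched
      sub_sched$legs <- sub
      aggregate_snapshot(sub_sched, weight_mode, distances)
    } else {
      structure(list(edges = data.frame(src = character(), dst = character(),
                                        weight = numeric()),
                     nodes = nodes, weight_mode = weight_mode),
                class = "snapshot_graph")
    }
    g$nodes <- nodes
    g
  })
  structure(list(snapshots = snaps, nodes = nodes, interval = interval,
                 weight_mode = weight_mode),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat("Snapshot series:", length(x$snapshots), "snapshots of",
      x$interval, "min,", length(x$nodes), "nodes\n")
  invisible(x)
}

#' Temporal degree over a snapshot series
#'
#' The mean over snapshots of a node's degree (binary: number of incident
#' directed edges, in plus out) or strength (weighted generalization: sum of
#' incident edge weights). Empty snapshots contribute 0.
#'
#' @param series a \code{"snapshot_series"}.
#' @param weighted use snapshot strength instead of edge counts.
#' @return named numeric vector over all nodes.
#' @export
temporal_degree <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "snapshot_series"))
  acc <- stats::setNames(numeric(length(series$nodes)), series$nodes)
  for (g in series$snapshots) {
    if (!nrow(g$edges)) next
    w <- if (weighted) g$edges$weight else rep(1, nrow(g$edges))
    s <- tapply(w, g$edges$src, sum)
    acc[names(s)] <- acc[names(s)] + s
    s <- tapply(w, g$edges$dst, sum)
    acc[names(s)] <- acc[names(s)] + s
  }
  acc / length(series$snapshots)
}

# Binary temporal distances from source v at start snapshot s:
# number of snapshot steps to earliest arrival, multi-hop traversal within a
# snapshot being free. Returns vector over nodes; Inf = never reached.
temporal_dist_binary <- function(series, v, s) {
  nodes <- series$nodes
  S <- length(series$snapshots)
  delta <- stats::setNames(rep(Inf, length(nodes)), nodes)
  reached <- stats::setNames(logical(length(nodes)), nodes)
  reached[v] <- TRUE
  delta[v] <- 0
  for (t in s:S) {
    e <- series$snapshots[[t]]$edges
    if (nrow(e)) {
      repeat {
        new <- reached[e$src] & !reached[e$dst]
        if (!any(new)) break
        hit <- unique(e$dst[new])
        reached[hit] <- TRUE
        delta[hit] <- t - s + 1
      }
    }
    if (all(reached)) break
  }
  delta
}

# Weighted temporal distances: (snapshots waited) + accumulated inverse-weight
# path cost, the reached set carrying its costs forward across snapshots.
temporal_dist_weighted <- function(series, v, s) {
  nodes <- series$nodes
  S <- length(series$snapshots)
  cost <- stats::setNames(rep(Inf, length(nodes)), nodes)  # edge-cost part
  best <- stats::setNames(rep(Inf, length(nodes)), nodes)  # full temporal dist
  cost[v] <- 0
  best[v] <- 0
  for (t in s:S) {
    e <- series$snapshots[[t]]$edges
    if (nrow(e)) {
      ec <- 1 / e$weight
      repeat {  # Bellman relaxation within the snapshot
        cand <- cost[e$src] + ec
        improved <- cand < cost[e$dst] - 1e-12
        if (!any(improved)) break
        for (i in which(improved))
          cost[e$dst[i]] <- min(cost[e$dst[i]], cand[i])
      }
    }
    best <- pmin(best, (t - s) + cost)
  }
  best
}

#' Temporal closeness over a snapshot series
#'
#' For each source node \eqn{v}: the average over start snapshots \eqn{s} and
#' over targets \eqn{u \neq v} of \eqn{1/\Delta_s(v, u)}, where
#' \eqn{\Delta_s(v,u)} is the temporal distance moving forward through
#' snapshots \eqn{s..S} and \eqn{1/\infty := 0}. In the binary formulation
#' \eqn{\Delta} is the number of snapshot steps to earliest arrival
#' (multi-hop traversal within a single snapshot is free). The weighted
#' variant takes the inverse of link weights as within-snapshot traversal
#' costs: \eqn{\Delta} is the number of whole snapshots waited plus the
#' accumulated inverse-weight path cost. Values are normalized by the number
#' of start snapshots and by \eqn{n - 1} possible targets so they are
#' comparable across network sizes.
#'
#' @param series a \code{"snapshot_series"}.
#' @param weighted use the inverse-weight cost variant.
#' @return named numeric vector over all nodes.
#' @export
temporal_closeness <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "snapshot_series"))
  nodes <- series$nodes
  n <- length(nodes)
  if (n < 2) stop("temporal closeness needs at least 2 nodes")
  S <- length(series$snapshots)
  acc <- stats::setNames(numeric(n), nodes)
  distfun <- if (weighted) temporal_dist_weighted else temporal_dist_binary
  for (v in nodes) {
    for (s in seq_len(S)) {
      delta <- distfun(series, v, s)
      contrib <- 1 / delta[names(delta) != v]
      acc[v] <- acc[v] + sum(contrib[is.finite(contrib)])
    }
  }
  acc / (S * (n - 1))
}

#' Pearson correlation of two metric vectors
#'
#' Plain Pearson r; when both vectors are named they are aligned on the names
#' of \code{x} first. Errors on zero variance rather than returning NA, since
#' a degenerate metric column is an upstream problem.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("metric vectors cover different locations")
    y <- y[names(x)]
  }
  if (length(x) != length(y) || length(x) < 2)
    stop("need two equal-length vectors of length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}
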