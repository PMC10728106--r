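# Core engine: admissible temporal paths and their weight sums.
#
# An admissible path starts at an EXIT position with a crossing link, never
# visits a port twice (entering a port marks it visited; the paired same-port
# EXIT reached via one switching link is exempt, otherwise no path could
# continue past a switch), and by default terminates on a crossing link.
# Spread Potential of a port is the sum over all admissible paths rooted at
# any of its EXIT positions of the path's total link weight; every admissible
# prefix ending on a crossing link is a path in its own right.

# Shared DFS accumulator. `link_ok` optionally masks crossing links (used by
# the seeding simulator); with all links active this computes SP exactly.
sp_accumulate <- function(net, exits, link_ok = NULL) {
  pos <- net$positions; cr <- net$crossing; sw <- net$switching
  ports <- net$ports
  nport <- length(ports)
  maxlen <- net$config$max_path_len %||% nport
  dangle <- isTRUE(net$config$count_dangling_switch)
  port_of <- match(pos$location, ports)
  if (is.null(link_ok)) link_ok <- rep(TRUE, nrow(cr))

  # deterministic adjacency: children ordered by arrival time, then location
  cr_from <- rep(list(integer()), nrow(pos))
  if (nrow(cr)) {
    ord <- order(cr$src, pos$time[cr$dst], pos$location[cr$dst], cr$leg_id)
    cr_o <- cr[ord, , drop = FALSE]
    idx <- split(seq_len(nrow(cr))[ord], cr_o$src)
    cr_from[as.integer(names(idx))] <- idx
  }
  sw_from <- rep(list(integer()), nrow(pos))
  if (nrow(sw)) {
    ord <- order(sw$src, pos$time[sw$dst])
    sw_o <- sw[ord, , drop = FALSE]
    idx <- split(seq_len(nrow(sw))[ord], sw_o$src)
    sw_from[as.integer(names(idx))] <- idx
  }

  cr_dst <- cr$dst; cr_w <- cr$weight
  sw_dst <- sw$dst; sw_w <- sw$weight

  total <- 0; npaths <- 0L; truncated <- FALSE
  visited <- logical(nport)
  walk <- function(exit_id, cum, depth) {
    for (ci in cr_from[[exit_id]]) {
      if (!link_ok[ci]) next
      d <- cr_dst[ci]
      pt <- port_of[d]
      if (visited[pt]) next
      if (depth >= maxlen) { truncated <<- TRUE; next }
      w <- cum + cr_w[ci]
      total <<- total + w
      npaths <<- npaths + 1L
      visited[pt] <<- TRUE
      for (si in sw_from[[d]]) {
        w2 <- w + sw_w[si]
        if (dangle) { total <<- total + w2; npaths <<- npaths + 1L }
        walk(sw_dst[si], w2, depth + 1L)
      }
      visited[pt] <<- FALSE
    }
  }
  for (e in exits) {
    visited[] <- FALSE
    visited[port_of[e]] <- TRUE
    walk(e, 0, 0L)
  }
  list(sp = total, n_paths = npaths, truncated = truncated)
}

resolve_start <- function(net, start) {
  pos <- net$positions
  if (is.numeric(start)) {
    start <- as.integer(start)
    if (!start %in% pos$id) stop("position id ", start, " not in network")
  } else {
    hit <- which(pos$label == start & pos$kind == "EXIT")
    if (!length(hit)) {
      if (start %in% pos$label)
        stop("start position ", start, " is not an EXIT position")
      stop("position ", start, " not found in network")
    }
    start <- pos$id[hit[1]]
  }
  if (pos$kind[pos$id == start] != "EXIT")
    stop("paths must start at an EXIT position")
  start
}

#' Enumerate admissible temporal paths from a departure position
#'
#' Yields every admissible path rooted at the given EXIT position, including
#' every admissible prefix as a path of its own, in deterministic
#' extension-first order (a path precedes all of its extensions; siblings are
#' ordered by arrival time then location name).
#'
#' @param net an \code{"stnet"}.
#' @param start an EXIT position, given as integer position id or label.
#' @param max_path_len optional guard on crossing-link count per path;
#'   overrides the network config.
#' @return a list of paths, each a list with \code{positions} (labels),
#'   \code{link_types}, \code{link_weights} and \code{weight} (their sum);
#'   attribute \code{"truncated"} reports whether the guard tripped.
#' @examples
#' toy <- toy_schedule()
#' net <- build_network(toy$schedule, toy$config)
#' p <- positions(net)
#' start <- p$id[p$location == "P1" & p$kind == "EXIT"][1]
#' length(enumerate_paths(net, start))  # 3 admissible paths
#' @export
enumerate_paths <- function(net, start, max_path_len = NULL) {
  stopifnot(inherits(net, "stnet"))
  start <- resolve_start(net, start)
  pos <- net$positions; cr <- net$crossing; sw <- net$switching
  ports <- net$ports
  maxlen <- max_path_len %||% net$config$max_path_len %||% length(ports)
  dangle <- isTRUE(net$config$count_dangling_switch)
  port_of <- match(pos$location, ports)

  cr_from <- rep(list(integer()), nrow(pos))
  if (nrow(cr)) {
    ord <- order(cr$src, pos$time[cr$dst], pos$location[cr$dst], cr$leg_id)
    cr_o <- cr[ord, , drop = FALSE]
    idx <- split(seq_len(nrow(cr))[ord], cr_o$src)
    cr_from[as.integer(names(idx))] <- idx
  }
  sw_from <- rep(list(integer()), nrow(pos))
  if (nrow(sw)) {
    ord <- order(sw$src, pos$time[sw$dst])
    sw_o <- sw[ord, , drop = FALSE]
    idx <- split(seq_len(nrow(sw))[ord], sw_o$src)
    sw_from[as.integer(names(idx))] <- idx
  }

  paths <- list()
  truncated <- FALSE
  visited <- logical(length(ports))
  emit <- function(labs, types, wts) {
    paths[[length(paths) + 1L]] <<- list(
      positions = labs, link_types = types, link_weights = wts,
      weight = sum(wts))
  }
  walk <- function(exit_id, labs, types, wts, depth) {
    for (ci in cr_from[[exit_id]]) {
      d <- cr$dst[ci]
      pt <- port_of[d]
      if (visited[pt]) next
      if (depth >= maxlen) { truncated <<- TRUE; next }
      labs2 <- c(labs, pos$label[d])
      types2 <- c(types, "crossing")
      wts2 <- c(wts, cr$weight[ci])
      emit(labs2, types2, wts2)
      visited[pt] <<- TRUE
      for (si in sw_from[[d]]) {
        ex2 <- sw$dst[si]
        labs3 <- c(labs2, pos$label[ex2])
        types3 <- c(types2, "switching")
        wts3 <- c(wts2, sw$weight[si])
        if (dangle) emit(labs3, types3, wts3)
        walk(ex2, labs3, types3, wts3, depth + 1L)
      }
      visited[pt] <<- FALSE
    }
  }
  visited[port_of[start]] <- TRUE
  walk(start, pos$label[pos$id == start], character(), numeric(), 0L)
  attr(paths, "truncated") <- truncated
  paths
}

#' Total weight of an enumerated temporal path
#'
#' Sum of all link weights along the path, switching links included (which
#' contribute 0 under the default switch weight).
#'
#' @param path one element of the list returned by [enumerate_paths()].
#' @return numeric scalar.
#' @export
path_weight <- function(path) sum(path$link_weights)

#' Format a temporal path in arrow notation
#'
#' @param path one element of [enumerate_paths()] output.
#' @return single string, e.g. \code{"p_CALAIS.2015-08-03T08:00 -> ..."}.
#' @export
format_path <- function(path) paste(path$positions, collapse = " -> ")

#' Spread Potential of every port in a schedule
#'
#' The central estimator of the package. The schedule is abstracted into a
#' weighted directed space-time network (positions, crossing links for legs,
#' waiting-gated switching links), and each port's Spread Potential is the
#' sum, over all admissible temporal paths rooted at the port's EXIT
#' positions, of the weights on the path's links. Admissible paths cannot
#' begin with a switching link and never visit a port twice (including a
#' return to the start).
#'
#' In binary mode with the default switch weight of 0 the value has a direct
#' reading: each admissible path of \eqn{m} crossing links contributes
#' \eqn{m}, so SP counts path-leg incidences — a port scores highly when many
#' long onward journeys can begin there.
#'
#' @param x a \code{"schedule"} or a prebuilt \code{"stnet"}.
#' @param config a [build_config()]; ignored when \code{x} is already a
#'   network.
#' @param distances optional \code{"distance_table"} for
#'   \code{weight_mode = "distance"}.
#' @param ... passed to methods.
#' @return an object of class \code{"spread_potential"} with components
#'   \code{table} (data.frame: \code{location}, \code{sp}, \code{n_paths},
#'   \code{truncated}, ranked by sp descending, ties broken by name),
#'   \code{network}, \code{config} and \code{call}. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{plot} and \code{simulate}.
#' @examples
#' toy <- toy_schedule()
#' fit <- spread_potential(toy$schedule, toy$config)
#' coef(fit)             # named SP values, ranked
#' @seealso [simulate.spread_potential()], [compare_metrics()]
#' @export
spread_potential <- function(x, ...) UseMethod("spread_potential")

#' @rdname spread_potential
#' @export
spread_potential.schedule <- function(x, config = build_config(),
                                      distances = NULL, ...) {
  net <- build_network(x, config, distances)
  out <- spread_potential.stnet(net, ...)
  out$call <- match.call()
  out
}

#' @rdname spread_potential
#' @export
spread_potential.stnet <- function(x, ...) {
  pos <- x$positions
  res <- lapply(x$ports, function(p) {
    exits <- pos$id[pos$location == p & pos$kind == "EXIT"]
    sp_accumulate(x, exits)
  })
  tab <- data.frame(
    location = x$ports,
    sp = vapply(res, `[[`, 0, "sp"),
    n_paths = vapply(res, `[[`, 0L, "n_paths"),
    truncated = vapply(res, `[[`, FALSE, "truncated"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$sp, tab$location), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, network = x, config = x$config,
                 call = match.call()),
            class = "spread_potential")
}

#' @export
print.spread_potential <- function(x, n = 10L, ...) {
  cat("Spread Potential (", x$config$weight_mode, " weights, switching window (",
      x$config$t_lower, ", ", x$config$t_upper, ") min)\n", sep = "")
  tab <- utils::head(x$table, n)
  print(tab, row.names = FALSE)
  if (nrow(x$table) > n)
    cat("... and", nrow(x$table) - n, "more port(s)\n")
  if (any(x$table$truncated))
    cat("warning: path-length guard tripped for",
        sum(x$table$truncated), "port(s)\n")
  invisible(x)
}

#' @export
summary.spread_potential <- function(object, ...) {
  net <- object$network
  structure(
    list(table = object$table, config = object$config,
         n_ports = length(net$ports), n_positions = nrow(net$positions),
         n_crossing = nrow(net$crossing), n_switching = nrow(net$switching),
         total_paths = sum(object$table$n_paths)),
    class = "summary.spread_potential")
}

#' @export
print.summary.spread_potential <- function(x, ...) {
  cat("Spread Potential summary\n")
  cat("  ports:", x$n_ports, " positions:", x$n_positions,
      " crossing:", x$n_crossing, " switching:", x$n_switching, "\n")
  cat("  admissible paths enumerated:", x$total_paths, "\n")
  print(x$config)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.spread_potential <- function(object, ...) {
  stats::setNames(object$table$sp, object$table$location)
}

#' @export
plot.spread_potential <- function(x, n = 15L, ...) {
  tab <- utils::head(x$table, n)
  graphics::barplot(rev(tab$sp), names.arg = rev(tab$location), horiz = TRUE,
                    las = 1, xlab = "Spread Potential",
                    main = paste0("Top ", nrow(tab), " ports (",
                                  x$config$weight_mode, " weights)"), ...)
  invisible(x)
}

#' Per-port metric table from a Spread Potential fit
#'
#' @param fit a \code{"spread_potential"} object.
#' @param metric column name for the SP values (default \code{"SP"}).
#' @return data.frame \code{location}, \code{<metric>} suitable for
#'   [write_metric_table()].
#' @export
sp_metric_table <- function(fit, metric = "SP") {
  stopifnot(inherits(fit, "spread_potential"))
  out <- data.frame(location = fit$table$location, v = fit$table$sp,
                    stringsAsFactors = FALSE)
  names(out)[2] <- metric
  out
}
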