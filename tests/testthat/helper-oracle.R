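# Independent brute-force oracles. These deliberately avoid the package's
# network representation: the SP oracle recurses directly over schedule legs
# (a crossing link per leg, a switch wherever the waiting gap fits), and the
# temporal-closeness oracle walks the snapshot sequence with igraph
# reachability. They share no code with the production engines.

oracle_sp <- function(sched, config, distances = NULL) {
  legs <- sched$legs
  w <- switch(config$weight_mode,
              binary = rep(1, nrow(legs)),
              capacity = legs$capacity * config$capacity_scale,
              distance = distance_lookup(distances, legs$origin,
                                         legs$destination))
  ports <- sort(unique(c(legs$origin, legs$destination)))
  sp <- stats::setNames(numeric(length(ports)), ports)
  npath <- stats::setNames(integer(length(ports)), ports)
  n <- nrow(legs)
  extend <- function(last, visited, cum) {
    tot <- 0
    for (j in seq_len(n)) {
      if (legs$origin[j] != legs$destination[last]) next
      gap <- legs$depart_min[j] - legs$arrive_min[last]
      if (!(gap > config$t_lower && gap < config$t_upper)) next
      if (legs$destination[j] %in% visited) next
      wj <- cum + config$switch_weight + w[j]
      npath[legs$origin[start_i]] <<- npath[legs$origin[start_i]] + 1L
      tot <- tot + wj + extend(j, c(visited, legs$destination[j]), wj)
    }
    tot
  }
  start_i <- 0L
  for (i in seq_len(n)) {
    start_i <- i
    vis <- c(legs$origin[i], legs$destination[i])
    npath[legs$origin[i]] <- npath[legs$origin[i]] + 1L
    sp[legs$origin[i]] <- sp[legs$origin[i]] + w[i] + extend(i, vis, w[i])
  }
  list(sp = sp, n_paths = npath)
}

oracle_tc_binary <- function(series) {
  nodes <- series$nodes
  S <- length(series$snapshots)
  n <- length(nodes)
  acc <- stats::setNames(numeric(n), nodes)
  for (v in nodes) {
    for (s in seq_len(S)) {
      reached <- v
      for (t in s:S) {
        e <- series$snapshots[[t]]$edges
        if (!nrow(e)) next
        g <- igraph::graph_from_data_frame(
          e[, c("src", "dst")], directed = TRUE,
          vertices = data.frame(name = nodes))
        d <- igraph::distances(g, v = reached, mode = "out")
        newly <- setdiff(colnames(d)[apply(is.finite(d), 2, any)], reached)
        if (length(newly))
          acc[v] <- acc[v] + length(newly) / (t - s + 1)
        reached <- union(reached, newly)
      }
    }
  }
  acc / (S * (n - 1))
}
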