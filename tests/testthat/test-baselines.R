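test_that("snapshot aggregation sums link realizations per ordered pair", {
  s <- mk_schedule(c("A", "A", "A", "B"), c("B", "B", "B", "A"),
                   c(0, 100, 200, 300), c(60, 160, 260, 360))
  g <- aggregate_snapshot(s, "binary")
  expect_equal(g$edges$weight[g$edges$src == "A"], 3)
  expect_equal(g$edges$weight[g$edges$src == "B"], 1)  # no symmetrization
  expect_equal(nrow(g$edges), 2)

  dt <- distance_table("A", "B", 100)
  gw <- aggregate_snapshot(s, "distance", dt)
  expect_equal(gw$edges$weight[gw$edges$src == "A"], 300)
  expect_error(aggregate_snapshot(s, "distance", distance_table("A", "C", 5)),
               "A-B")
})

test_that("node strength sums incident weights by direction", {
  s <- mk_schedule(c("A", "A", "A"), c("B", "C", "D"),
                   c(0, 10, 20), c(60, 70, 80))
  dt <- distance_table(c("A", "A", "A"), c("B", "C", "D"), c(2, 2, 2))
  g <- aggregate_snapshot(s, "distance", dt)
  expect_equal(node_strength(g, "out")[["A"]], 6)
  expect_equal(node_strength(g, "in")[["A"]], 0)
  expect_equal(node_strength(g, "in")[["B"]], 2)
  # total == in + out elementwise
  expect_equal(node_strength(g, "total"),
               node_strength(g, "in") + node_strength(g, "out"))
})

test_that("pagerank matches a closed-form linear solve with dangling mass", {
  # chain A -> B -> C, C dangling; damping 0.85
  s <- mk_schedule(c("A", "B"), c("B", "C"), c(0, 100), c(60, 160))
  g <- aggregate_snapshot(s, "binary")
  pr <- pagerank(g, damping = 0.85)
  # oracle: x = (1-d)/n + d * (M + dangling/n)' x, solved exactly
  d <- 0.85; n <- 3
  M <- matrix(0, n, n, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M["A", "B"] <- 1; M["B", "C"] <- 1; M["C", ] <- 1 / n
  x <- solve(diag(n) - d * t(M), rep((1 - d) / n, n))
  expect_equal(unname(pr[c("A", "B", "C")]), unname(x), tolerance = 1e-8)

  # trivial symmetric and degenerate cases
  s2 <- mk_schedule(c("A", "B"), c("B", "A"), c(0, 100), c(60, 160))
  expect_equal(unname(pagerank(aggregate_snapshot(s2, "binary"))),
               c(0.5, 0.5))
})

test_that("pagerank is a probability vector on random instances", {
  for (seed in c(2, 6, 10)) {
    gen <- rand_small(seed)
    for (mode in c("binary", "distance")) {
      g <- aggregate_snapshot(gen$schedule, mode, gen$distances)
      pr <- pagerank(g)
      expect_equal(sum(pr), 1, tolerance = 1e-10)
      expect_true(all(pr > 0))
    }
  }
})

test_that("snapshot parsing assigns legs to departure-day intervals", {
  s <- mk_schedule(c("A", "A", "B"), c("B", "B", "A"),
                   c(100, 1440, 2000), c(700, 2000, 2600),
                   window_min = 3 * 1440)
  ser <- snapshot_series(s, interval = 1440)
  expect_length(ser$snapshots, 3)
  expect_equal(nrow(ser$snapshots[[1]]$edges), 1)
  expect_equal(nrow(ser$snapshots[[2]]$edges), 2)  # both day-2 departures
  expect_equal(nrow(ser$snapshots[[3]]$edges), 0)
})

test_that("temporal degree is the mean snapshot degree (or strength)", {
  # A<->B active every day for 3 days: degree 2 per snapshot
  s <- mk_schedule(rep(c("A", "B"), 3), rep(c("B", "A"), 3),
                   c(0, 100, 1440, 1540, 2880, 2980),
                   c(60, 160, 1500, 1600, 2940, 3040),
                   window_min = 3 * 1440)
  ser <- snapshot_series(s, interval = 1440)
  td <- temporal_degree(ser)
  expect_equal(td[["A"]], 2)
  expect_equal(td[["B"]], 2)

  # a port active once in 14 days with degree 4 averages 4/14
  legs <- data.frame(origin = c("X", "X", "Y", "Z"),
                     destination = c("Y", "Z", "X", "X"),
                     dep = c(10, 20, 30, 40), arr = c(100, 110, 120, 130))
  s2 <- mk_schedule(legs$origin, legs$destination, legs$dep, legs$arr,
                    window_min = 14 * 1440)
  td2 <- temporal_degree(snapshot_series(s2, interval = 1440))
  expect_equal(td2[["X"]], 4 / 14)

  # when all activity falls in one snapshot, temporal degree is the static
  # degree divided by the snapshot count
  g <- aggregate_snapshot(s2, "binary")
  static_deg <- node_strength(g, "total")
  expect_equal(td2, static_deg / 14)

  # weighted variant uses snapshot strength
  dt <- distance_table(c("X", "X"), c("Y", "Z"), c(10, 30))
  tdw <- temporal_degree(snapshot_series(s2, interval = 1440, "distance", dt),
                         weighted = TRUE)
  expect_equal(tdw[["X"]], (10 + 30 + 10 + 30) / 14)
})

test_that("temporal closeness follows the snapshot-step distance", {
  # A->B present in each of 3 daily snapshots: Delta_s(A,B) = 1 for every
  # start, so A's closeness is mean(1) over starts / (n-1 targets)
  s <- mk_schedule(rep("A", 3), rep("B", 3),
                   c(0, 1440, 2880), c(60, 1500, 2940),
                   window_min = 3 * 1440)
  ser <- snapshot_series(s, interval = 1440)
  tc <- temporal_closeness(ser)
  expect_equal(tc[["A"]], 1)
  expect_equal(tc[["B"]], 0)   # B never reaches A

  # an edge first appearing in the last snapshot: Delta grows for earlier
  # starts: 3, 2, 1 -> mean of 1/3, 1/2, 1
  s2 <- mk_schedule("A", "B", 2 * 1440 + 10, 2 * 1440 + 100,
                    window_min = 3 * 1440)
  tc2 <- temporal_closeness(snapshot_series(s2, interval = 1440))
  expect_equal(tc2[["A"]], mean(c(1 / 3, 1 / 2, 1)))
})

test_that("temporal closeness agrees with the igraph snapshot-walk oracle", {
  for (seed in c(1, 3, 5, 8)) {
    set.seed(seed * 13)
    n <- sample(3:6, 1)
    gen <- generate_schedule(n_ports = n, n_routes = min(2 * n, n * (n - 1)),
                             window_days = 5, departures_per_route = 2,
                             leg_duration_range = c(30, 900),
                             seed = seed + 100)
    ser <- snapshot_series(gen$schedule, interval = 1440)
    expect_equal(temporal_closeness(ser), oracle_tc_binary(ser),
                 info = paste("seed", seed))
  }
})

test_that("weighted temporal closeness uses inverse-weight traversal costs", {
  # single snapshot, single edge of weight 2: Delta_w = 1/2, closeness = 2
  s <- mk_schedule("A", "B", 0, 60, window_min = 1440)
  dt <- distance_table("A", "B", 2)
  ser <- snapshot_series(s, interval = 1440, "distance", dt)
  tcw <- temporal_closeness(ser, weighted = TRUE)
  expect_equal(tcw[["A"]], 2)
  # heavier links mean shorter temporal distance, hence larger closeness
  dt2 <- distance_table("A", "B", 8)
  ser2 <- snapshot_series(s, interval = 1440, "distance", dt2)
  expect_gt(temporal_closeness(ser2, weighted = TRUE)[["A"]], tcw[["A"]])
})

test_that("pearson behaves on exact linear relationships and degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, 2 * x), 1)
  expect_error(pearson(x, c(1, 1, 1)), "zero variance")
  expect_error(pearson(x, c(1, 2)), "equal-length")
  # named vectors align on names
  a <- c(A = 1, B = 2, C = 3)
  b <- c(C = 30, A = 10, B = 20)
  expect_equal(pearson(a, b), 1)
})
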