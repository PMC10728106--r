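test_that("the worked 4-port example enumerates its three paths in extension order", {
  toy <- toy_schedule()
  net <- build_network(toy$schedule, toy$config)
  p <- positions(net)
  start <- p$id[p$location == "P1" & p$kind == "EXIT"]
  paths <- enumerate_paths(net, start)
  expect_length(paths, 3)
  # each successive path extends the previous one
  for (i in 2:3) {
    prev <- paths[[i - 1]]$positions
    expect_identical(paths[[i]]$positions[seq_along(prev)], prev)
  }
  expect_equal(vapply(paths, path_weight, 0), c(1, 2, 3))
  expect_equal(vapply(paths, function(x) length(x$positions), 0L),
               c(2, 4, 6))
  expect_false(attr(paths, "truncated"))
  # starting from an ENTER position is a contract error
  ent <- p$id[p$kind == "ENTER"][1]
  expect_error(enumerate_paths(net, ent), "EXIT")
})

test_that("shrinking the upper bound below the first wait leaves one path", {
  toy <- toy_schedule()
  net <- build_network(toy$schedule, build_config(t_lower = 30, t_upper = 50))
  p <- positions(net)
  start <- p$id[p$location == "P1" & p$kind == "EXIT"]
  expect_length(enumerate_paths(net, start), 1)
})

test_that("path weights sum all link weights, switching included", {
  toy <- toy_schedule()
  # distance weights with a positive epsilon on switches
  cfg <- build_config(weight_mode = "distance", switch_weight = 0.001)
  net <- build_network(toy$schedule, cfg, toy$distances)
  p <- positions(net)
  start <- p$id[p$location == "P1" & p$kind == "EXIT"]
  paths <- enumerate_paths(net, start)
  expect_equal(path_weight(paths[[1]]), 100)
  expect_equal(path_weight(paths[[2]]), 100 + 0.001 + 150)
  expect_equal(path_weight(paths[[3]]), 100 + 0.001 + 150 + 0.001 + 80)
})

test_that("spread potential matches exhaustive hand enumeration on the chain", {
  sch <- chain_schedule()   # A->B (0,60), B->C (120,240); wait 60 at B
  sp <- coef(spread_potential(sch, build_config(30, 180)))
  expect_equal(sp, c(A = 3, B = 1, C = 0))

  # with the wait infeasible the switch disappears
  sp2 <- coef(spread_potential(sch, build_config(30, 50)))
  expect_equal(sp2[["A"]], 1)

  # a port with arrivals only has no outgoing paths
  fit <- spread_potential(sch, build_config())
  expect_equal(fit$table$n_paths[fit$table$location == "C"], 0)
  expect_equal(fit$table$sp[fit$table$location == "C"], 0)

  # disconnected legs each contribute their own unit
  s2 <- mk_schedule(c("A", "C"), c("B", "D"), c(0, 0), c(60, 60))
  expect_equal(coef(spread_potential(s2, build_config())),
               c(A = 1, C = 1, B = 0, D = 0))
})

test_that("worked-example SP values hold in all three weight modes", {
  toy <- toy_schedule()
  expect_equal(coef(spread_potential(toy$schedule, toy$config)),
               c(P1 = 6, P2 = 3, P3 = 2, P4 = 0))
  expect_equal(
    coef(spread_potential(toy$schedule,
                          build_config(weight_mode = "distance"),
                          toy$distances)),
    c(P1 = 680, P2 = 380, P3 = 160, P4 = 0))
  expect_equal(
    coef(spread_potential(toy$schedule,
                          build_config(weight_mode = "capacity"))),
    c(P1 = 2470, P2 = 1420, P3 = 700, P4 = 0))
  # widening the upper bound adds the late P3 departure to upstream paths
  expect_equal(coef(spread_potential(toy$schedule, build_config(30, 360))),
               c(P1 = 9, P2 = 5, P3 = 2, P4 = 0))
})

test_that("counting dangling switches is a different, larger statistic", {
  toy <- toy_schedule()
  off <- spread_potential(toy$schedule, toy$config)
  on <- spread_potential(toy$schedule,
                         build_config(count_dangling_switch = TRUE))
  expect_equal(coef(off)[["P1"]], 6)
  expect_equal(coef(on)[["P1"]], 9)   # prefixes re-counted at each switch
  expect_gt(sum(on$table$n_paths), sum(off$table$n_paths))
})

test_that("every proper crossing-terminated prefix of a path is enumerated", {
  for (seed in c(2, 5, 9)) {
    gen <- rand_small(seed)
    net <- build_network(gen$schedule, build_config())
    p <- positions(net)
    exits <- p$id[p$kind == "EXIT"]
    for (e in exits[seq_len(min(4, length(exits)))]) {
      paths <- enumerate_paths(net, e)
      keys <- vapply(paths, function(x) paste(x$positions, collapse = ">"), "")
      for (pp in paths) {
        k <- length(pp$link_types)
        for (cut in which(pp$link_types == "crossing")) {
          if (cut == k) next
          prefix <- paste(pp$positions[seq_len(cut + 1)], collapse = ">")
          expect_true(prefix %in% keys)
        }
      }
    }
  }
})

test_that("production SP equals the brute-force oracle on seeded instances", {
  for (seed in 1:12) {
    gen <- rand_small(seed)
    for (mode in c("binary", "distance", "capacity")) {
      cfg <- build_config(weight_mode = mode)
      fit <- spread_potential(gen$schedule, cfg, gen$distances)
      orc <- oracle_sp(gen$schedule, cfg, gen$distances)
      expect_equal(coef(fit)[sort(names(orc$sp))], orc$sp[sort(names(orc$sp))],
                   info = paste("seed", seed, mode))
      got_n <- stats::setNames(fit$table$n_paths, fit$table$location)
      expect_equal(got_n[sort(names(orc$n_paths))],
                   orc$n_paths[sort(names(orc$n_paths))],
                   info = paste("seed", seed, mode, "path counts"))
    }
    # positive epsilon switch weight must also agree
    cfg_eps <- build_config(switch_weight = 0.25)
    fit <- spread_potential(gen$schedule, cfg_eps)
    orc <- oracle_sp(gen$schedule, cfg_eps)
    expect_equal(coef(fit)[sort(names(orc$sp))], orc$sp[sort(names(orc$sp))],
                 info = paste("seed", seed, "epsilon switch"))
  }
})

test_that("SP decomposes over links weighted by path multiplicity", {
  toy <- toy_schedule()
  for (cfg in list(toy$config, build_config(weight_mode = "distance"))) {
    net <- build_network(toy$schedule, cfg, toy$distances)
    p <- positions(net)
    fit <- spread_potential(net)
    for (port in net$ports) {
      exits <- p$id[p$location == port & p$kind == "EXIT"]
      counts <- numeric(0)
      for (e in exits) {
        for (pp in enumerate_paths(net, e)) {
          steps <- paste(pp$positions[-length(pp$positions)],
                         pp$positions[-1], sep = "->")
          for (i in seq_along(steps))
            counts[steps[i]] <- sum(counts[steps[i]], pp$link_weights[i],
                                    na.rm = TRUE)
        }
      }
      expect_equal(sum(counts), coef(fit)[[port]])
    }
  }
})

test_that("adding a leg or widening the window never lowers any port's SP", {
  for (seed in c(1, 4, 7)) {
    gen <- rand_small(seed)
    base <- coef(spread_potential(gen$schedule, build_config(45, 120)))
    wide <- coef(spread_potential(gen$schedule, build_config(30, 300)))
    expect_true(all(wide[names(base)] >= base))

    # append one extra leg between two existing ports
    legs <- gen$schedule$legs
    extra <- legs[1, ]
    extra$leg_id <- "EXTRA"
    extra$depart_time <- legs$depart_time[1] + 3600
    extra$arrive_time <- legs$arrive_time[1] + 3600
    aug <- schedule(rbind(legs[, names(extra)], extra),
                    window_start = gen$schedule$window_start,
                    window_end = max(gen$schedule$window_end,
                                     extra$arrive_time))
    more <- coef(spread_potential(aug, build_config(45, 120)))
    expect_true(all(more[names(base)] >= base))
  }
})

test_that("binary SP with zero switch weight is integral", {
  for (seed in c(3, 8)) {
    gen <- rand_small(seed)
    sp <- coef(spread_potential(gen$schedule, build_config()))
    expect_equal(sp, round(sp))
    fit <- spread_potential(gen$schedule, build_config())
    expect_true(all((fit$table$sp == 0) == (fit$table$n_paths == 0)))
  }
})

test_that("a tight path-length guard truncates and flags instead of failing", {
  toy <- toy_schedule()
  cfg <- build_config(max_path_len = 1)
  fit <- spread_potential(toy$schedule, cfg)
  expect_true(any(fit$table$truncated))
  expect_equal(coef(fit)[["P1"]], 1)   # only the single-leg path survives
  net <- build_network(toy$schedule, toy$config)
  p <- positions(net)
  start <- p$id[p$location == "P1" & p$kind == "EXIT"]
  paths <- enumerate_paths(net, start, max_path_len = 1)
  expect_length(paths, 1)
  expect_true(attr(paths, "truncated"))
})

test_that("the fitted object exposes the standard accessor surface", {
  toy <- toy_schedule()
  fit <- spread_potential(toy$schedule, toy$config)
  expect_s3_class(fit, "spread_potential")
  expect_named(coef(fit))
  expect_output(print(fit), "Spread Potential")
  s <- summary(fit)
  expect_equal(s$n_ports, 4)
  expect_equal(s$total_paths, sum(fit$table$n_paths))
  expect_output(print(s), "admissible paths")
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
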