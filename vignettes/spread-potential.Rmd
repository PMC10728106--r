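---
title: "Spread Potential on schedule-based space-time networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spread Potential on schedule-based space-time networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadpot)
```

## The abstraction

A timetable row — a *leg* — says that a vessel leaves port `A` at minute
`t1` and reaches port `B` at minute `t2`. `spreadpot` expands a collection
of such rows into a space-time network whose nodes are *positions*: the act
of exiting or entering a port at a precise minute. Identical events merge
(two sailings leaving a port in the same minute share one EXIT position);
positions are otherwise distinguished by port, minute and kind.

Two link families connect positions, and both strictly increase time, so
the network is a DAG by construction:

* **Crossing links** — one per leg, EXIT at the origin to ENTER at the
  destination. Their weight carries the spread proxy: `1` in the binary
  abstraction, the leg's carrying capacity (optionally scaled, e.g. by a
  basic reproduction number) when capacities are known, or a symmetric
  port-pair distance when capacity data are unavailable and the
  larger-vessels-on-longer-routes heuristic is acceptable.
* **Switching links** — ENTER at a port to a later EXIT at the same port,
  existing only when the waiting gap lies **strictly** inside
  `(t_lower, t_upper)`. The bounds are problem knobs with units of minutes:
  the lower bound is the least time needed to make a connection, the upper
  the longest wait a carrier would tolerate while still counting as "on the
  path". Defaults are 30 and 180 minutes, a plausible ferry connection
  window. Every arrival connects to *every* admissible later departure, not
  only the next one — a traveller can board any feasible sailing; a
  `consecutive_only` flag restricts to the next departure for sensitivity
  analysis. ENTER–ENTER and EXIT–EXIT pairs are never connected: they have
  no boarding semantics.

Switching links carry weight 0 by default. Conceptually the weight is a
minimum positive value approaching zero — enough to make the link exist
without distorting path weight sums — and taking the limit exactly keeps
binary Spread Potential values integral. A positive epsilon remains
available via `switch_weight` for users who want switch traversals visible
in the sums.

## The statistic

An *admissible path* starts at an EXIT position with a crossing link,
alternates crossings and feasible switches, and never visits a port twice —
entering a port marks it visited, with one exemption: the same-port EXIT
reached by the immediate switching link, without which no path could ever
continue past a wait. Every prefix of an admissible path that ends on a
crossing link is an admissible path in its own right and is counted
separately.

The Spread Potential of a port is the sum, over all EXIT positions of that
port and all admissible paths rooted there, of the weights on each path's
links. A port with arrivals only scores 0: a path cannot begin with a
switching link.

**Termination convention.** Paths end on crossing links. A candidate
"path" ending on a switch transmits nothing beyond its crossing prefix,
and counting such danglers would re-count every prefix once per outgoing
switch — a materially different (larger) statistic. Because the choice is
substantive, it is exposed as `count_dangling_switch` (default off); both
conventions produce integral binary values, so integrality cannot
discriminate between them.

**Engine.** Recursive depth-first traversal over the DAG carrying the
visited-port set, accumulating (weight-sum, path-count) pairs on the fly;
full paths are materialized only by `enumerate_paths()`. Children are
visited in (arrival time, location name) order, so results and path
listings are deterministic. Worst-case path counts are exponential in
principle; since admissible paths visit each port at most once, depth is
bounded by the port count, and a `max_path_len` guard (default: the port
count, which never binds) marks results `truncated` rather than failing if
a tighter guard is set.

## Baseline measures

For comparison on the same schedule, `compare_metrics()` assembles:

* **Node strength / out-strength** and **PageRank** on the aggregated
  snapshot (all leg realizations summed per ordered port pair; binary
  counts or distance sums). PageRank uses damping 0.85 and uniform
  teleportation — the conventional parameters, both exposed — computed by
  `igraph`'s exact solver, with dangling mass redistributed uniformly.
* **Temporal degree**: the mean over daily snapshots of a node's degree
  (weighted: strength). The day parsing matches sailing durations, which
  run from hours to days.
* **Temporal closeness**: for source `v`, the mean over start snapshots `s`
  and targets `u` of `1/Δ_s(v,u)`, with `1/∞ = 0`. Binary `Δ` is the
  number of snapshot steps to earliest arrival, multi-hop traversal within
  a snapshot being free. The original formulation's exact normalization and
  weighted generalization are not fully specified in the sources this
  package draws on, so the reconstruction is documented and deliberate:
  values are normalized by the `S` start snapshots and `n − 1` targets, and
  the weighted variant takes inverse link weights as within-snapshot
  traversal costs, `Δ_w` = whole snapshots waited + accumulated
  inverse-weight path cost, the reached set carrying its costs forward.
  Weighted `1/Δ_w` can exceed 1 on heavy single-snapshot links; only
  relative comparisons are meaningful. `compare_metrics()` records the
  formulas used in its `meta` field.

Correlations between metric vectors are plain Pearson (`pearson()`), which
is invariant to the divide-by-maximum standardization used for plotting, so
the `standardized` table affects displays only.

## The synthetic generator

`generate_schedule()` emulates the shape of a consolidated multi-provider
ferry timetable: directed routes between reused ports, several departures
per route across a multi-week window, leg durations from two hours to two
days, capacities and symmetric nautical-mile distances drawn uniformly from
realistic ranges, and an optional weekly-recurrence mode that repeats a
7-day departure template, matching liner periodicity. Defaults mirror a
two-week European ferry dataset's scale (125 ports, 210 routes); tests and
the acceptance script run smaller instances (up to 8 ports / 25 legs for
exact brute-force cross-checks, 40 ports / 960 legs for the correlation
panel) so the exponential-path cross-validation stays exhaustive and fast.

What the generator does **not** emulate: the heavy-tailed port-degree
distribution of real shipping, geographic clustering, provider-specific
route structure, or capacity–distance correlation. Passing tests therefore
demonstrate correctness of the computation on schedule-shaped data, not
calibration of the measure on real traffic.

## The seeding simulator

The simulator gives the statistic an operational reading. In each
replicate every crossing link — a scheduled sailing — independently carries
the item with probability `p`; a path realizes if all its sailings carry;
the outbreak size seeded at a port is the total weight over realized
admissible paths from its EXIT positions. The draw is per sailing and
shared across branches within a replicate; replicate `r` uses RNG
substream `seed + r`, so extending the replicate count preserves earlier
replicates and runs at different `p` under one seed share random numbers,
making mean outbreak size monotone in `p` replicate by replicate. At
`p = 1` the traversal is exactly the SP accumulation, so the simulator
reduces to SP by construction — that identity is a correctness check of
the shared path structure, while `p < 1` runs (validated by rank
correlation against SP) probe whether the ranking survives thinning. No
transmission model beyond per-link Bernoulli is implied: this is a
validation harness, not an epidemic model — no compartments, recovery, or
within-vessel mixing.

## Numerical and degenerate-input choices

* Timestamps are timezone-naive ISO 8601 at minute resolution, stored as
  integer minutes from the window start; all arithmetic is exact integer
  arithmetic on minutes.
* Both switching bounds are strict inequalities; a gap exactly equal to a
  bound yields no link.
* Ranking ties are broken by location name ascending, making every written
  table byte-deterministic.
* Rows violating leg invariants (non-positive duration, self-loops — which
  the space-time abstraction renders meaningless — bad timestamps,
  negative capacities) are rejected per row with line diagnostics rather
  than failing the file; an all-invalid file is an error.
* An empty schedule yields an empty network and an empty ranking; a port
  with arrivals only scores 0 with 0 paths; `sp == 0` iff `n_paths == 0`
  (with nonnegative weights).
* Degenerate variance in correlation inputs is an error for `pearson()`
  (a degenerate metric column is an upstream problem) but a reported `NA`
  in `validate_ranking()` (an all-zero outbreak at `p = 0` is a legitimate
  simulation outcome).

## Known limitations

* A vessel occupying a port between arrival and departure is represented
  only by the two point events and the gated switch; there is no
  continuous-time interval semantics.
* Path enumeration is exact, not sampled; on networks far denser than
  liner schedules (many switches per arrival and long windows) run time
  grows with the admissible-path count.
* The distance weight is a proxy for capacity resting on the
  scale-economies assumption; where real capacities exist, use them.
* Temporal closeness values depend on the documented reconstruction above
  and on the chosen parsing interval; cross-study comparisons should match
  both before comparing numbers.
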