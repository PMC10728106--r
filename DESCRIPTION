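Package: spreadpot
Title: Spread Potential Centrality for Schedule-Based Space-Time Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted directed space-time (time-expanded) networks from
    service timetables (one node per timed enter/exit event at a location,
    crossing links for scheduled legs, waiting-time-gated switching links) and
    ranks locations by their Spread Potential: the sum of link weights over all
    admissible temporal paths rooted at each location's departure events.
    Includes static and temporal baseline centralities (node strength,
    out-strength, PageRank on the aggregated snapshot, temporal degree and
    temporal closeness on daily snapshot series), Pearson comparison of metric
    vectors, a synthetic timetable generator emulating multi-provider ferry
    schedules, and a stochastic seeding simulator for in-silico validation of
    the rankings.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
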