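test_that("exogenous pair statistics encode similarity with female/young reference", {
  fx <- table1_fixture()
  rs <- build_risk_set(fx$actors)
  both_male <- stat_category_pair(rs, fx$actors, "gender", "both_level", "male")
  mixed <- stat_category_pair(rs, fx$actors, "gender", "mixed")
  pair <- function(a, b) which(rs$actor1 == min(a, b) & rs$actor2 == max(a, b))
  expect_equal(both_male[pair("Ben", "Chris")], 1) # male-male
  expect_equal(mixed[pair("Ben", "Chris")], 0)
  expect_equal(both_male[pair("Anne", "Ben")], 0) # mixed
  expect_equal(mixed[pair("Anne", "Ben")], 1)
  expect_equal(both_male[pair("Anne", "Emma")], 0) # reference: both female
  expect_equal(mixed[pair("Anne", "Emma")], 0)
  expect_error(stat_category_pair(rs, fx$actors, "gender", "both_level", "x"), "level")
  expect_error(stat_category_pair(rs, fx$actors, "nope", "mixed"), "attribute")
})

test_that("trait extremes take the pair min/max and are symmetric", {
  actors <- make_actors(4, traits = "extraversion")
  actors$extraversion <- c(-1.2, 0.5, 0.5, 2.0)
  rs <- build_risk_set(actors)
  lo <- stat_trait_extreme(rs, actors, "extraversion", "min")
  hi <- stat_trait_extreme(rs, actors, "extraversion", "max")
  expect_equal(lo[1], -1.2) # pair (a01, a02)
  expect_equal(hi[1], 0.5)
  tied <- which(rs$i1 == 2 & rs$i2 == 3)
  expect_equal(lo[tied], hi[tied]) # equal scores degenerate to min = max
  expect_true(all(lo <= hi))
  expect_error(stat_trait_extreme(rs, actors, "openness", "min"), "attribute")
})

test_that("weekend indicator follows calendar arithmetic", {
  mon <- rem_calendar("Monday")
  expect_equal(stat_weekend(100, mon), 0)
  expect_equal(stat_weekend(5 * 1440 + 10, mon), 1) # day 5 = Saturday
  expect_equal(stat_weekend(7 * 1440 + 1, mon), 0) # wraps to Monday
  sat <- rem_calendar("Saturday")
  expect_equal(stat_weekend(100, sat), 1)
  expect_error(stat_weekend(-1, mon), "non-negative")
})

test_that("group indicator reflects the observed event context", {
  expect_equal(stat_group(3), 1)
  expect_equal(stat_group(2), 0)
})

test_that("inertia weights past events by ln(duration)/(group size - 1)", {
  actors <- make_actors(4)
  rs <- build_risk_set(actors)
  expect_equal(stat_inertia(dyadic_tbl(numeric(0), character(0), character(0)), rs, 10),
    rep(0, 6)
  )
  h <- dyadic_tbl(5, "a01", "a02", duration = 30)
  v <- stat_inertia(h, rs, 10)
  expect_equal(v[1], log(30)) # 3.4012...
  expect_equal(sum(v != 0), 1)
  # the same event inside a 4-person group counts ln(30)/3
  h4 <- dyadic_tbl(5, "a01", "a02", duration = 30, group_size = 4L)
  expect_equal(stat_inertia(h4, rs, 10)[1], log(30) / 3)
  # unweighted variant counts events
  expect_equal(stat_inertia(h4, rs, 10, weighted = FALSE)[1], 1)
  # history at or after t is ignored
  expect_equal(stat_inertia(h, rs, 5)[1], 0)
  # window restriction drops older events
  expect_equal(stat_inertia(h, rs, 10, window_start = 6)[1], 0)
})

test_that("shared partners counts distinct third parties, never the own dyad", {
  actors <- make_actors(4) # a01..a04
  rs <- build_risk_set(actors)
  h <- dyadic_tbl(
    c(1, 2, 3), c("a01", "a02", "a02"), c("a03", "a03", "a04")
  )
  v <- stat_shared_partners(h, rs, 10)
  pair <- function(a, b) which(rs$actor1 == min(a, b) & rs$actor2 == max(a, b))
  expect_equal(v[pair("a01", "a02")], 1) # via a03
  expect_equal(v[pair("a03", "a04")], 1) # via a02
  expect_equal(v[pair("a01", "a04")], 0)
  # repeated events of the own dyad never count as shared partners
  own <- dyadic_tbl(c(1, 2), c("a01", "a01"), c("a02", "a02"))
  expect_equal(stat_shared_partners(own, rs, 10)[pair("a01", "a02")], 0)
  expect_equal(stat_shared_partners(dyadic_tbl(
    numeric(0), character(0), character(0)
  ), rs, 10), rep(0, 6))
})

test_that("typed statistics restrict to the entry's own setting and partition", {
  actors <- make_actors(4)
  rs_t <- build_risk_set(actors, c("leisure", "study"))
  rs_u <- build_risk_set(actors)
  h <- dyadic_tbl(
    c(1, 2, 3), c("a01", "a01", "a02"), c("a02", "a03", "a03"),
    setting = c("leisure", "study", "study"), duration = c(30, 20, 15)
  )
  ti <- stat_type_inertia(h, rs_t, 10)
  entry <- function(a, b, ty) {
    which(rs_t$actor1 == min(a, b) & rs_t$actor2 == max(a, b) & rs_t$type == ty)
  }
  expect_equal(ti[entry("a01", "a02", "leisure")], log(30))
  expect_equal(ti[entry("a01", "a02", "study")], 0)
  # per-type values sum to the untyped inertia
  iu <- stat_inertia(h, rs_u, 10)
  by_dyad <- rowsum(ti, rs_t$dyad)[, 1]
  expect_equal(unname(by_dyad), iu, tolerance = 1e-12)

  tsp <- stat_type_shared_partners(h, rs_t, 10)
  expect_equal(tsp[entry("a01", "a02", "study")], 1) # via a03, study only
  expect_equal(tsp[entry("a01", "a02", "leisure")], 0)
  # within-type counts never exceed the untyped count
  spu <- stat_shared_partners(h, rs_u, 10)
  expect_true(all(tsp <= spu[rs_t$dyad]))
  expect_error(stat_type_inertia(h, rs_u, 10), "typed risk set")
})

test_that("type dummy splits a typed risk set and complements sum to one", {
  actors <- tibble::tibble(actor_id = sprintf("s%03d", 1:126))
  rs <- build_risk_set(actors, c("leisure", "study"))
  study <- stat_type_dummy(rs, "study")
  expect_equal(sum(study), 7875)
  leisure <- stat_type_dummy(rs, "leisure")
  expect_equal(study + leisure, rep(1, 15750))
  expect_error(stat_type_dummy(build_risk_set(actors), "study"), "typed")
  expect_error(stat_type_dummy(rs, "work"), "unknown")
})

test_that("per-event scaling standardizes with the sample SD", {
  expect_equal(scale_per_event(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(scale_per_event(rep(4, 5)), rep(0, 5))
  expect_equal(
    scale_per_event(c(0, 0, 6)),
    c(-1, -1, 2) / sqrt(12) * 2, # mean 2, sample SD sqrt(12)
    tolerance = 1e-6
  )
  expect_equal(scale_per_event(c(0, 0, 6)),
    c(-0.5774, -0.5774, 1.1547),
    tolerance = 1e-4
  )
  expect_error(scale_per_event(1), "at least 2")
})

test_that("interactions are elementwise products, not re-standardized", {
  expect_equal(stat_interaction(c(-1, 0, 1), c(2, 2, 2)), c(-2, 0, 2))
  expect_equal(stat_interaction(rep(0, 3), c(5, 6, 7)), rep(0, 3))
  a <- rnorm(5)
  b <- rnorm(5)
  expect_equal(stat_interaction(a, b), stat_interaction(b, a))
  expect_error(stat_interaction(1:2, 1:3), "length")
})

test_that("design assembly: baseline-only design is all ones with valid indices", {
  fx <- table1_fixture()
  rs <- build_risk_set(fx$actors)
  ev <- split_group_events(fx$events, seed = 1)$events
  d <- build_design(ev, rs, fx$actors, effects(effect_baseline()))
  expect_equal(dim(d$X), c(4 * 10, 1))
  expect_true(all(d$X == 1))
  expect_equal(d$dt, c(1, 60, 60, 30)) # t0 = 0
  expect_true(all(d$obs >= 1 & d$obs <= 10))
})

test_that("design assembly: endogenous columns are zero at the first event and scaled after", {
  fx <- table1_fixture()
  rs <- build_risk_set(fx$actors)
  ev <- split_group_events(fx$events, seed = 1)$events
  specs <- effects(effect_baseline(), effect_inertia(), effect_shared_partners())
  d <- build_design(ev, rs, fx$actors, specs)
  first <- d$X[1:10, ]
  expect_equal(unname(first[, "inertia"]), rep(0, 10))
  expect_equal(unname(first[, "shared.partners"]), rep(0, 10))
  # every later scaled column has mean 0, sample SD 1 (or is all zero)
  for (e in 2:4) {
    col <- d$X[(e - 1) * 10 + 1:10, "inertia"]
    expect_equal(mean(col), 0, tolerance = 1e-12)
    expect_equal(sd(col), 1, tolerance = 1e-12)
  }
  # inertia of (Anne, Ben) at the 4th event: scaled ln(30) over the risk set
  raw <- numeric(10)
  pair <- function(a, b) which(rs$actor1 == min(a, b) & rs$actor2 == max(a, b))
  raw[pair("Anne", "Ben")] <- log(30)
  raw[pair("Anne", "Chris")] <- log(20)
  raw[pair("Dan", "Emma")] <- log(15)
  expected <- (raw - mean(raw)) / sd(raw)
  expect_equal(
    unname(d$X[3 * 10 + pair("Anne", "Ben"), "inertia"]),
    expected[pair("Anne", "Ben")],
    tolerance = 1e-12
  )
})

test_that("statistics are evaluated at the pre-spacing minute, shared within a group", {
  actors <- make_actors(5)
  events <- dplyr::bind_rows(
    raw_event(10, c("a01", "a02"), duration = 30),
    raw_event(20, c("a01", "a02", "a03"), duration = 60)
  )
  ev <- split_group_events(events, seed = 2)$events
  specs <- effects(effect_baseline(), effect_inertia(scale = FALSE))
  d <- build_design(ev, rs <- build_risk_set(actors), actors, specs)
  # the three split rows of the group share identical statistic blocks
  rows <- which(d$events$group_id == 2)
  blocks <- lapply(rows, function(e) d$X[(e - 1) * d$R + seq_len(d$R), ])
  expect_equal(blocks[[1]], blocks[[2]])
  expect_equal(blocks[[2]], blocks[[3]])
  # and none of the group's own constituents fed back into them
  expect_equal(unname(blocks[[1]][1, "inertia"]), log(30)) # only the t=10 event
})

test_that("window_start of zero matches no window and untyped stats replicate across types", {
  actors <- make_actors(5)
  events <- dplyr::bind_rows(
    raw_event(10, c("a01", "a02"), "leisure", 30),
    raw_event(200, c("a02", "a03"), "study", 45),
    raw_event(900, c("a01", "a03"), "leisure", 15)
  )
  ev <- split_group_events(events, seed = 1)$events
  specs <- effects(effect_baseline(), effect_inertia(), effect_shared_partners())
  rs <- build_risk_set(actors)
  d0 <- build_design(ev, rs, actors, specs)
  dw <- build_design(ev, rs, actors, specs, window_start = 0)
  expect_equal(d0$X, dw$X)
  expect_equal(d0$dt, dw$dt)

  rs_t <- build_risk_set(actors, c("leisure", "study"))
  dt_ <- build_design(ev, rs_t, actors, specs)
  # untyped inertia on a typed risk set depends only on the dyad
  for (e in seq_len(dt_$M)) {
    block <- dt_$X[(e - 1) * dt_$R + seq_len(dt_$R), "inertia"]
    expect_equal(
      as.vector(tapply(block, dt_$riskset$dyad, function(x) diff(range(x)))),
      rep(0, 10)
    )
  }
})

test_that("design assembly validates observed events against the risk set", {
  actors <- make_actors(3)
  ev <- dyadic_tbl(5, "a01", "zz")
  expect_error(
    build_design(ev, build_risk_set(actors), actors, effects(effect_baseline())),
    "not present in the risk set"
  )
  evs <- dyadic_tbl(c(5, 10), c("a01", "a01"), c("a02", "a03"))
  expect_error(
    build_design(evs, build_risk_set(actors), actors,
      effects(effect_baseline()),
      t0 = 7
    ),
    "precede"
  )
})
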