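write_tmp <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("actor files parse and age dichotomizes at 24/25", {
  path <- write_tmp(c(
    "id,gender,age,extraversion",
    "a,female,20,4.5",
    "b,male,24,5.5",
    "c,female,25,6.0"
  ))
  actors <- read_actor_table(path)
  expect_identical(actors$age_group, c("young", "young", "older"))
  expect_identical(actors$actor_id, c("a", "b", "c"))
  expect_equal(actors$extraversion, c(4.5, 5.5, 6.0))
})

test_that("actor file validation names the offending rows", {
  dup <- write_tmp(c("id,gender,age", "a,female,20", "a,male,22"))
  expect_error(read_actor_table(dup), "duplicate actor id\\(s\\): a")
  badg <- write_tmp(c("id,gender,age", "a,unknown,20"))
  expect_error(read_actor_table(badg), "gender")
  bada <- write_tmp(c("id,gender,age", "a,female,old"))
  expect_error(read_actor_table(bada), "age")
  # no trait columns is fine
  plain <- write_tmp(c("id,gender,age", "a,female,20", "b,male,22"))
  expect_equal(ncol(read_actor_table(plain)), 4)
})

test_that("trait standardization imputes the mean and z-scores", {
  a <- tibble::tibble(
    actor_id = c("x", "y", "z"), gender = "female", age = 20,
    age_group = "young", extraversion = c(4, 6, NA)
  )
  out <- standardize_traits(a, "extraversion")
  expect_equal(out$extraversion, c(-1, 1, 0)) # imputed 5; sd(4,6,5) = 1
  expect_equal(attr(out, "imputed")[["extraversion"]], 1)

  # idempotent on an already standardized column
  out2 <- standardize_traits(out, "extraversion")
  expect_equal(out2$extraversion, out$extraversion, tolerance = 1e-12)

  a$extraversion <- c(3, 3, 3)
  expect_error(standardize_traits(a, "extraversion"), "zero standard deviation")
  a$extraversion <- NA_real_
  expect_error(standardize_traits(a, "extraversion"), "no observed values")
})

test_that("event lists parse in both dialects, sorted by onset", {
  fx <- table1_fixture()
  dyadic <- write_tmp(c(
    "time,actor1,actor2,setting,duration",
    "61,Anne,Chris,Leisure,20",
    "1,Anne,Ben,Leisure,30",
    "151,Ben,Dan,Study-related,300",
    "121,Dan,Emma,Study-related,15"
  ))
  ev <- read_event_list(dyadic, fx$actors)
  expect_equal(ev$time, c(1, 61, 121, 151))
  expect_equal(ev$duration, c(30, 20, 15, 300))
  expect_identical(ev$participants[[1]], c("Anne", "Ben"))

  group <- write_tmp(c(
    "time,members,setting,duration",
    "10,Anne;Ben;Chris,Leisure,45",
    "5,Dan;Emma,Study,30"
  ))
  ev2 <- read_event_list(group, fx$actors)
  expect_equal(ev2$group_size, c(2L, 3L))
  expect_identical(ev2$participants[[2]], c("Anne", "Ben", "Chris"))
})

test_that("event validation rejects unknown actors, short durations, singletons", {
  fx <- table1_fixture()
  unk <- write_tmp(c("time,actor1,actor2,duration", "1,Anne,Zed,30"))
  expect_error(read_event_list(unk, fx$actors), "Zed")
  short <- write_tmp(c("time,actor1,actor2,duration", "1,Anne,Ben,1"))
  expect_error(read_event_list(short, fx$actors), "duration")
  solo <- write_tmp(c("time,members,duration", "1,Anne,30"))
  expect_error(read_event_list(solo, fx$actors), "fewer than 2")
})

test_that("group splitting spaces events inside the following minute", {
  ev <- raw_event(100, c("a", "b", "c"), duration = 30)
  out <- split_group_events(ev, seed = 7)
  expect_equal(out$events$time, c(100.25, 100.5, 100.75))
  expect_equal(unique(out$events$stat_time), 100)
  expect_equal(unique(out$events$group_size), 3L)
  expect_setequal(
    paste(out$events$actor1, out$events$actor2),
    c("a b", "a c", "b c")
  )
  # dyadic events keep their onset
  two <- split_group_events(raw_event(50, c("a", "b")), seed = 1)
  expect_equal(two$events$time, 50)
})

test_that("splitting yields sum of m(m-1)/2 dyadic events and conserves participation", {
  events <- dplyr::bind_rows(
    raw_event(10, c("a", "b")),
    raw_event(20, c("a", "b", "c")),
    raw_event(30, c("a", "b", "c", "d"))
  )
  out <- split_group_events(events, seed = 3)
  expect_equal(nrow(out$events), 1 + 3 + 6)
  expect_equal(out$report$n_raw_events, 3)
  expect_equal(out$report$n_dyadic_events, 10)
  expect_equal(out$report$expansion_log_factor, log(10 / 3))
  # each member of a group of size m appears in m - 1 of its dyads
  g3 <- out$events[out$events$group_id == 3, ]
  counts <- table(c(g3$actor1, g3$actor2))
  expect_true(all(counts == 3))
  # spaced group times stay strictly inside (t, t + 1), raw order preserved
  grp <- out$events$group_size > 2
  expect_true(all(out$events$time[grp] > out$events$stat_time[grp]))
  expect_true(all(out$events$time < out$events$stat_time + 1))
  expect_true(!is.unsorted(out$events$stat_time))
})

test_that("splitting is seed-reproducible and seed-sensitive", {
  events <- dplyr::bind_rows(
    raw_event(1, c("a", "b", "c", "d")),
    raw_event(5, c("b", "c", "e"))
  )
  s1 <- split_group_events(events, seed = 11)$events
  s2 <- split_group_events(events, seed = 11)$events
  expect_identical(s1, s2)
  s3 <- split_group_events(events, seed = 12)$events
  expect_false(identical(s1, s3))
  # different seeds permute within groups only: same dyads, same times
  expect_setequal(paste(s1$actor1, s1$actor2), paste(s3$actor1, s3$actor2))
  expect_identical(s1$time, s3$time)
  expect_error(split_group_events(events), "seed")
})

test_that("expansion log factor matches the printed event counts", {
  expect_equal(round(expansion_log_factor(2886, 11690), 2), 1.40)
  expect_equal(expansion_log_factor(100, 100), 0)
  expect_equal(expansion_log_factor(10, 30), log(3))
  expect_error(expansion_log_factor(0, 10), "positive")
  expect_error(expansion_log_factor(10, 5), "smaller")
})

test_that("event round trip through the file dialects is lossless", {
  fx <- table1_fixture()
  events <- dplyr::bind_rows(
    raw_event(10, c("Anne", "Ben", "Chris"), "leisure", 45),
    raw_event(20, c("Dan", "Emma"), "study", 30)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_list(events, path, dialect = "group")
  back <- read_event_list(path, fx$actors)
  expect_equal(back$time, events$time)
  expect_identical(back$participants, events$participants)
  expect_equal(back$duration, events$duration)
})
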