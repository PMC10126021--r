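# small in-code fixtures shared across the suite

make_actors <- function(n, traits = NULL, seed = 1) {
  withr::with_seed(seed, {
    a <- tibble::tibble(
      actor_id = sprintf("a%02d", seq_len(n)),
      gender = sample(c("female", "male"), n, TRUE),
      age = sample(18:30, n, TRUE)
    )
    a$age_group <- ifelse(a$age <= 24, "young", "older")
    for (tr in traits) {
      a[[tr]] <- rnorm(n)
      a[[tr]] <- (a[[tr]] - mean(a[[tr]])) / sd(a[[tr]])
    }
    a
  })
}

# the first four observed interactions of the worked example:
# (1, Anne, Ben, leisure, 30), (61, Anne, Chris, leisure, 20),
# (121, Dan, Emma, study, 15), (151, Ben, Dan, study, 300)
table1_fixture <- function() {
  actors <- tibble::tibble(
    actor_id = c("Anne", "Ben", "Chris", "Dan", "Emma"),
    gender = c("female", "male", "male", "male", "female"),
    age = c(20, 21, 22, 26, 20),
    age_group = c("young", "young", "young", "older", "young")
  )
  events <- tibble::tibble(
    time = c(1, 61, 121, 151),
    participants = list(
      c("Anne", "Ben"), c("Anne", "Chris"), c("Dan", "Emma"), c("Ben", "Dan")
    ),
    setting = c("leisure", "leisure", "study", "study"),
    duration = c(30, 20, 15, 300),
    group_size = 2L
  )
  list(actors = actors, events = events)
}

raw_event <- function(time, members, setting = NA_character_, duration = 30) {
  tibble::tibble(
    time = time, participants = list(members), setting = setting,
    duration = duration, group_size = length(members)
  )
}

# dyadic event rows built directly (already-split shape)
dyadic_tbl <- function(time, a1, a2, setting = NA_character_,
                       duration = 30, group_size = 2L,
                       stat_time = time, group_id = seq_along(time)) {
  tibble::tibble(
    group_id = group_id, time = time, stat_time = stat_time,
    actor1 = pmin(a1, a2), actor2 = pmax(a1, a2),
    setting = setting, duration = duration, group_size = group_size
  )
}

# a hand-assembled design object for likelihood-level tests
toy_design <- function(m, r, p, seed = 1, dt = NULL) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(m * r * p), m * r, p,
      dimnames = list(NULL, paste0("x", seq_len(p)))
    )
    structure(
      list(
        X = x,
        obs = sample.int(r, m, replace = TRUE),
        dt = dt %||% runif(m, 0.5, 2),
        active = matrix(TRUE, r, m),
        events = tibble::tibble(group_id = seq_len(m)),
        effects = colnames(x),
        M = m, R = r, P = p
      ),
      class = "rem_design"
    )
  })
}

`%||%` <- rlang::`%||%`

# explicit per-entry enumeration of the conditional choice probabilities;
# deliberately loop-based and independent of the vectorized likelihood code
ordinal_loglik_oracle <- function(beta, design) {
  total <- 0
  for (e in seq_len(design$M)) {
    rows <- (e - 1) * design$R + seq_len(design$R)
    act <- design$active[, e]
    rates <- numeric(design$R)
    for (r in which(act)) {
      rates[r] <- event_rate(beta, design$X[rows[r], ])
    }
    total <- total + log(rates[design$obs[e]] / sum(rates))
  }
  total
}
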