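#' Assemble the design array for a relational event sequence
#'
#' For every observed dyadic event, every statistic in `specs` is evaluated
#' over the full risk set on the history strictly before the event's
#' statistic-evaluation time `stat_time` (the pre-spacing onset minute: all
#' dyadic events split from one group interaction share their statistic
#' values, and none of a group's constituents feeds back into its own
#' group's statistics). Endogenous statistics are standardized per event
#' over the active risk set. Waiting times are computed from the spaced
#' event times, with the clock starting at `t0`.
#'
#' @param events Dyadic events from [split_group_events()] (columns
#'   `group_id`, `time`, `stat_time`, `actor1`, `actor2`, `setting`,
#'   `duration`, `group_size`; `stat_time` and `group_id` are filled in when
#'   missing).
#' @param risk_set A [build_risk_set()] result (typed when `specs` contains
#'   type effects; events are then matched on `(dyad, setting)`).
#' @param actors Actor table (with standardized traits for trait effects and
#'   optional `availability`).
#' @param specs An [effects()] list (or a list coercible to one).
#' @param calendar A [rem_calendar()] (for the weekend statistic).
#' @param window_start Optional minute: events with `stat_time` before it
#'   are dropped and endogenous statistics see only the remaining window
#'   history (moving-window estimation). `NULL` and `0` are equivalent for
#'   non-negative times.
#' @param t0 Origin for the first waiting time; defaults to `window_start`
#'   (or 0).
#'
#' @return A `rem_design` object: list with the flat statistic matrix `X`
#'   (`M * R` rows, one block of `R` risk-set entries per event, `P` effect
#'   columns), observed entry indices `obs`, waiting times `dt`, the active
#'   mask (`R x M`), the events, risk set and effect specs.
#' @export
build_design <- function(events, risk_set, actors, specs,
                         calendar = rem_calendar(),
                         window_start = NULL, t0 = NULL) {
  specs <- as_effect_list(specs)
  events <- prepare_dyadic_events(events)
  if (!is.null(window_start)) {
    drop <- events$stat_time < window_start
    if (any(drop)) {
      warn(paste0(
        sum(drop), " event(s) before window_start dropped from the design"
      ))
      events <- events[!drop, ]
    }
  }
  if (nrow(events) == 0) {
    abort("no events to build a design from")
  }
  t0 <- t0 %||% window_start %||% 0
  events <- events[order(events$time), ]
  if (events$time[1] < t0) {
    abort("event times precede the waiting-time origin t0")
  }

  r_n <- nrow(risk_set)
  m_n <- nrow(events)
  p_n <- length(specs)
  typed <- !is.null(attr(risk_set, "types"))

  obs <- match_observed(events, risk_set, typed)
  active <- active_mask_by_event(events, risk_set, actors)
  bad <- which(!active[cbind(obs, seq_len(m_n))])
  if (length(bad)) {
    abort(paste0(
      "observed dyad not in the active risk set for event(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }

  x <- matrix(0, nrow = m_n * r_n, ncol = p_n,
    dimnames = list(NULL, names(specs))
  )
  static <- static_columns(specs, risk_set, actors)
  for (gid in unique(events$group_id)) {
    rows <- which(events$group_id == gid)
    first <- rows[1]
    cols <- event_stat_columns(
      specs, risk_set, actors, events,
      t = events$stat_time[first],
      group_size = events$group_size[first],
      calendar = calendar, window_start = window_start,
      active = active[, first], static = static
    )
    for (e in rows) {
      x[(e - 1) * r_n + seq_len(r_n), ] <- cols
    }
  }
  dt <- diff(c(t0, events$time))
  if (any(dt < 0)) {
    abort("waiting times must be non-negative; events are mis-ordered")
  }
  structure(
    list(
      X = x, obs = obs, dt = dt, active = active,
      events = events, riskset = risk_set, specs = specs,
      effects = names(specs), M = m_n, R = r_n, P = p_n,
      window_start = window_start, t0 = t0
    ),
    class = "rem_design"
  )
}

#' @export
print.rem_design <- function(x, ...) {
  cat(
    "<rem_design> ", x$M, " events x ", x$R, " risk-set entries x ",
    x$P, " effects (", paste(x$effects, collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

as_effect_list <- function(specs) {
  if (inherits(specs, "rem_effect_list")) {
    return(specs)
  }
  if (inherits(specs, "rem_effect")) {
    return(effects(list(specs)))
  }
  effects(specs)
}

# fill stat_time / group_id defaults and canonicalize the dyad order
prepare_dyadic_events <- function(events) {
  if (!all(c("actor1", "actor2", "time", "duration") %in% names(events))) {
    abort("dyadic events need columns actor1, actor2, time, duration")
  }
  events$actor1 <- as.character(events$actor1)
  events$actor2 <- as.character(events$actor2)
  swap <- events$actor1 > events$actor2
  if (any(swap)) {
    tmp <- events$actor1[swap]
    events$actor1[swap] <- events$actor2[swap]
    events$actor2[swap] <- tmp
  }
  if (any(events$actor1 == events$actor2)) {
    abort("self-pairs are not valid dyadic events")
  }
  if (is.null(events$stat_time)) {
    events$stat_time <- events$time
  }
  if (is.null(events$group_id)) {
    events$group_id <- seq_len(nrow(events))
  }
  if (is.null(events$group_size)) {
    events$group_size <- 2L
  }
  if (is.null(events$setting)) {
    events$setting <- NA_character_
  }
  events
}

match_observed <- function(events, risk_set, typed) {
  if (typed) {
    if (anyNA(events$setting)) {
      abort("typed risk set requires a setting for every event")
    }
    key_rs <- paste(risk_set$actor1, risk_set$actor2, risk_set$type)
    key_ev <- paste(events$actor1, events$actor2, events$setting)
  } else {
    key_rs <- paste(risk_set$actor1, risk_set$actor2)
    key_ev <- paste(events$actor1, events$actor2)
  }
  obs <- match(key_ev, key_rs)
  if (anyNA(obs)) {
    abort(paste0(
      "observed event(s) not present in the risk set: event row(s) ",
      paste(head(which(is.na(obs)), 5), collapse = ", ")
    ))
  }
  obs
}

active_mask_by_event <- function(events, risk_set, actors) {
  if (is.null(actors[["availability"]])) {
    return(matrix(TRUE, nrow(risk_set), nrow(events)))
  }
  vapply(
    events$stat_time,
    function(t) active_entry_mask(risk_set, t, actors),
    logical(nrow(risk_set))
  )
}

# time-constant columns, computed once
static_columns <- function(specs, risk_set, actors) {
  out <- list()
  for (sp in specs) {
    out[[sp$name]] <- switch(sp$kind,
      baseline = stat_baseline(risk_set),
      category_pair = stat_category_pair(
        risk_set, actors, sp$params$attribute, sp$params$mode, sp$params$level
      ),
      trait_min = ,
      trait_max = stat_trait_extreme(
        risk_set, actors, sp$params$trait, sp$params$mode
      ),
      type_dummy = stat_type_dummy(risk_set, sp$params$focal_type),
      NULL
    )
  }
  out
}

# statistic matrix (R x P) for one event context; shared by build_design()
# and the simulator so both always agree on the statistics
event_stat_columns <- function(specs, risk_set, actors, history, t,
                               group_size, calendar, window_start,
                               active, static = NULL) {
  static <- static %||% static_columns(specs, risk_set, actors)
  r_n <- nrow(risk_set)
  cols <- matrix(0, r_n, length(specs), dimnames = list(NULL, names(specs)))
  for (sp in specs) {
    if (sp$kind == "interaction") next
    v <- if (!is.null(static[[sp$name]])) {
      static[[sp$name]]
    } else {
      switch(sp$kind,
        weekend = rep(stat_weekend(t, calendar), r_n),
        group = rep(stat_group(group_size), r_n),
        inertia = stat_inertia(
          history, risk_set, t, window_start, sp$params$weighted
        ),
        shared_partners = stat_shared_partners(
          history, risk_set, t, window_start
        ),
        type_inertia = stat_type_inertia(
          history, risk_set, t, window_start, sp$params$weighted
        ),
        type_shared_partners = stat_type_shared_partners(
          history, risk_set, t, window_start
        ),
        abort(paste0("unknown effect kind: ", sp$kind))
      )
    }
    if (isTRUE(sp$scale)) {
      v[active] <- scale_per_event(v[active])
      v[!active] <- 0
    }
    cols[, sp$name] <- v
  }
  for (sp in specs) {
    if (sp$kind != "interaction") next
    cols[, sp$name] <- stat_interaction(
      cols[, sp$params$a], cols[, sp$params$b]
    )
  }
  cols
}
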