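#' Read a relational event list from a delimited text file
#'
#' Two header dialects are auto-detected:
#' * dyadic: columns `time, actor1, actor2, setting, duration`;
#' * group: columns `time, members, setting, duration`, where `members`
#'   holds all participant ids joined by `";"`.
#'
#' `setting` is optional in both dialects. Events are returned sorted by
#' onset time (stable for ties, preserving file order); participants are
#' validated against the actor table.
#'
#' @param path Path to the file.
#' @param actors Actor table the participants must belong to.
#' @return A tibble of raw events with columns `time` (onset minute),
#'   `participants` (list of actor ids), `setting`, `duration` (minutes) and
#'   `group_size`.
#' @export
read_event_list <- function(path, actors) {
  if (!file.exists(path)) {
    abort(paste0("event file not found: ", path))
  }
  raw <- read_delimited(path)
  if ("members" %in% names(raw)) {
    need <- c("time", "members", "duration")
    parts <- strsplit(as.character(raw$members), ";", fixed = TRUE)
  } else {
    need <- c("time", "actor1", "actor2", "duration")
    parts <- NULL
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("event file misses column(s): ", paste(miss, collapse = ", ")))
  }
  if (is.null(parts)) {
    parts <- Map(c, as.character(raw$actor1), as.character(raw$actor2))
    parts <- lapply(parts, unname)
  }
  time <- suppressWarnings(as.numeric(raw$time))
  duration <- suppressWarnings(as.numeric(raw$duration))
  if (anyNA(time) || anyNA(duration)) {
    abort("non-numeric time or duration in event file")
  }
  setting <- if ("setting" %in% names(raw)) {
    as.character(raw$setting)
  } else {
    rep(NA_character_, nrow(raw))
  }
  events <- tibble::tibble(
    time = time,
    participants = lapply(parts, unique),
    setting = setting,
    duration = duration,
    group_size = lengths(lapply(parts, unique))
  )
  validate_raw_events(events, actors)
  events[order(events$time), ]
}

validate_raw_events <- function(events, actors) {
  small <- which(events$group_size < 2)
  if (length(small)) {
    abort(paste0(
      "event(s) with fewer than 2 participants in row(s): ",
      paste(small, collapse = ", ")
    ))
  }
  short <- which(events$duration <= 1)
  if (length(short)) {
    abort(paste0(
      "duration must exceed 1 minute; offending row(s): ",
      paste(short, collapse = ", ")
    ))
  }
  known <- as.character(actors$actor_id)
  unknown <- setdiff(unique(unlist(events$participants)), known)
  if (length(unknown)) {
    abort(paste0(
      "unknown actor id(s) in event list: ", paste(unknown, collapse = ", ")
    ))
  }
  invisible(events)
}

#' Split group interactions into spaced dyadic events
#'
#' A group interaction among `m > 2` actors is decomposed into its
#' `M = m * (m - 1) / 2` constituent dyadic events, in seeded random order,
#' evenly spaced strictly inside the minute following the onset: the k-th
#' event of the group receives time `t_e + k / (M + 1)`. Statistics are
#' *not* affected by the induced spacing: every dyadic event also carries
#' `stat_time = t_e`, the pre-spacing onset at which history statistics must
#' be evaluated (see [build_design()]). Dyadic raw events keep their onset
#' unchanged.
#'
#' @param events Raw events from [read_event_list()] (or built in code with
#'   the same columns).
#' @param seed Integer seed for the within-group permutation (required, for
#'   reproducibility).
#' @return A list with `events`: tibble of dyadic events (`group_id`,
#'   `time`, `stat_time`, `actor1`, `actor2`, `setting`, `duration`,
#'   `group_size`), and `report`: a one-row tibble with `n_raw_events`,
#'   `n_dyadic_events` and `expansion_log_factor`.
#' @examples
#' ev <- tibble::tibble(
#'   time = 100, participants = list(c("a", "b", "c")),
#'   setting = NA_character_, duration = 30, group_size = 3L
#' )
#' split_group_events(ev, seed = 1)$events$time # 100.25 100.50 100.75
#' @export
split_group_events <- function(events, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required to split group events reproducibly")
  }
  out <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nrow(events)), function(i) {
      t_e <- events$time[i]
      members <- sort(as.character(events$participants[[i]]), method = "radix")
      m <- length(members)
      pairs <- combn(members, 2)
      n_pairs <- ncol(pairs)
      if (m == 2) {
        times <- t_e
        ord <- 1L
      } else {
        ord <- sample.int(n_pairs)
        times <- t_e + seq_len(n_pairs) / (n_pairs + 1)
      }
      tibble::tibble(
        group_id = i,
        time = times,
        stat_time = t_e,
        actor1 = pairs[1, ord],
        actor2 = pairs[2, ord],
        setting = events$setting[i],
        duration = events$duration[i],
        group_size = m
      )
    })
  })
  dyadic <- dplyr::bind_rows(out)
  dyadic <- dyadic[order(dyadic$time), ]
  report <- tibble::tibble(
    n_raw_events = nrow(events),
    n_dyadic_events = nrow(dyadic),
    expansion_log_factor = expansion_log_factor(nrow(events), nrow(dyadic))
  )
  list(events = dyadic, report = report)
}

#' Log expansion factor induced by group splitting
#'
#' Splitting group interactions into dyadic events inflates the event rate
#' by the ratio of post-split to original event counts; on the log-rate
#' scale the inflation is `ln(n_dyadic / n_raw)`. Subtracting it from a
#' fitted group coefficient gives the net group effect
#' (see [net_group_effect()]).
#'
#' @param n_raw Number of raw (pre-split) events, positive.
#' @param n_dyadic Number of dyadic (post-split) events, `>= n_raw`.
#' @return `ln(n_dyadic / n_raw)`.
#' @examples
#' expansion_log_factor(2886, 11690) # about 1.40
#' @export
expansion_log_factor <- function(n_raw, n_dyadic) {
  if (n_raw <= 0 || n_dyadic <= 0) {
    abort("event counts must be positive")
  }
  if (n_dyadic < n_raw) {
    abort("n_dyadic cannot be smaller than n_raw")
  }
  log(n_dyadic / n_raw)
}

#' Write raw events in a dialect read_event_list() can parse back
#'
#' @param events Raw event tibble (see [read_event_list()]).
#' @param path Output file path.
#' @param dialect `"group"` (semicolon-joined `members` column, any group
#'   size) or `"dyadic"` (two actor columns; errors on group events).
#' @return `path`, invisibly.
#' @export
write_event_list <- function(events, path, dialect = c("group", "dyadic")) {
  dialect <- match.arg(dialect)
  if (dialect == "dyadic") {
    if (any(events$group_size > 2)) {
      abort("dyadic dialect cannot represent group events")
    }
    out <- tibble::tibble(
      time = events$time,
      actor1 = vapply(events$participants, `[`, "", 1),
      actor2 = vapply(events$participants, `[`, "", 2),
      setting = events$setting,
      duration = events$duration
    )
  } else {
    out <- tibble::tibble(
      time = events$time,
      members = vapply(
        events$participants, paste, "", collapse = ";"
      ),
      setting = events$setting,
      duration = events$duration
    )
  }
  readr::write_csv(out, path)
  invisible(path)
}
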