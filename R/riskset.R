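#' Build the risk set of candidate relational events
#'
#' The risk set R(t) contains every relational event that could occur: all
#' unordered actor pairs, optionally crossed with a set of event types
#' (settings). With `N` actors and no types the risk set holds
#' `N * (N - 1) / 2` entries; with `K` types, `K` times as many.
#'
#' Entries are in a deterministic canonical order: actors are sorted
#' lexicographically (radix order, locale-independent), dyads enumerated as
#' `(a1, a2)` with `a1 < a2` sorted by `(a1, a2)`, and each dyad is crossed
#' with the sorted event types. The integer columns `i1`, `i2` (positions of
#' the members in the sorted actor vector) and `dyad` (position of the pair
#' in the untyped enumeration) index into this canonical order and are used
#' throughout the package.
#'
#' @param actors An actor table (tibble with column `actor_id`), e.g. from
#'   [read_actor_table()].
#' @param event_types Optional character vector of event type labels
#'   (e.g. `c("leisure", "study")`). `NULL` or empty for an untyped risk set.
#'
#' @return A tibble of class `rem_riskset` with columns `entry`, `actor1`,
#'   `actor2`, `type` (`NA` when untyped), `dyad`, `i1`, `i2`.
#' @examples
#' actors <- tibble::tibble(actor_id = c("a", "b", "c"))
#' build_risk_set(actors)
#' @export
build_risk_set <- function(actors, event_types = NULL) {
  ids <- actors$actor_id
  if (is.null(ids) || length(ids) < 2) {
    abort("at least 2 actors are required to build a risk set")
  }
  if (anyDuplicated(ids)) {
    abort("actor ids must be unique")
  }
  ids <- sort(as.character(ids), method = "radix")
  n <- length(ids)
  i2 <- rep(seq_len(n), times = seq_len(n) - 1L)  # column index of upper tri
  i1 <- sequence(seq_len(n) - 1L)                 # row index, i1 < i2
  # reorder so dyads run (1,2),(1,3),...,(1,n),(2,3),...
  ord <- order(i1, i2)
  i1 <- i1[ord]
  i2 <- i2[ord]
  n_dyads <- length(i1)
  types <- if (length(event_types)) sort(as.character(event_types)) else NULL
  k <- max(1L, length(types))
  rs <- tibble::tibble(
    entry = seq_len(n_dyads * k),
    actor1 = rep(ids[i1], each = k),
    actor2 = rep(ids[i2], each = k),
    type = if (is.null(types)) NA_character_ else rep(types, times = n_dyads),
    dyad = rep(seq_len(n_dyads), each = k),
    i1 = rep(i1, each = k),
    i2 = rep(i2, each = k)
  )
  structure(
    rs,
    actor_ids = ids,
    n_actors = n,
    types = types,
    class = c("rem_riskset", class(tibble::tibble()))
  )
}

#' Restrict a risk set to the dyads available at a time point
#'
#' An actor can carry availability windows (a list-column `availability` in
#' the actor table, each element a data frame with `start`/`end` minutes,
#' interval `[start, end)`). A dyad is at risk at time `t` iff both members
#' are available; actors without availability intervals are always available.
#'
#' @param risk_set A [build_risk_set()] result.
#' @param t Time in minutes, `>= 0`.
#' @param actors The actor table the risk set was built from.
#'
#' @return The subset of `risk_set` rows active at `t` (attributes kept).
#'   When every actor is unavailable the result has zero rows and carries
#'   attribute `degenerate = TRUE`.
#' @export
active_risk_set <- function(risk_set, t, actors) {
  if (t < 0) {
    abort("t must be non-negative")
  }
  keep <- active_entry_mask(risk_set, t, actors)
  out <- risk_set[keep, ]
  attrs <- c("actor_ids", "n_actors", "types")
  for (a in attrs) attr(out, a) <- attr(risk_set, a)
  if (!any(keep)) {
    attr(out, "degenerate") <- TRUE
    warn("no dyads at risk at this time point (degenerate risk set)")
  }
  out
}

# logical mask over risk-set entries: both members available at t
active_entry_mask <- function(risk_set, t, actors) {
  avail <- actors[["availability"]]
  if (is.null(avail)) {
    return(rep(TRUE, nrow(risk_set)))
  }
  ids <- attr(risk_set, "actor_ids")
  actor_ok <- vapply(seq_along(ids), function(i) {
    iv <- avail[[match(ids[i], actors$actor_id)]]
    if (is.null(iv) || nrow(iv) == 0) {
      return(TRUE)
    }
    any(iv$start <= t & t < iv$end)
  }, logical(1))
  actor_ok[risk_set$i1] & actor_ok[risk_set$i2]
}

# lookup matrix: dyad index by actor index pair (both triangles filled)
dyad_lookup <- function(risk_set) {
  n <- attr(risk_set, "n_actors")
  m <- matrix(NA_integer_, n, n)
  un <- !duplicated(risk_set$dyad)
  m[cbind(risk_set$i1[un], risk_set$i2[un])] <- risk_set$dyad[un]
  m[cbind(risk_set$i2[un], risk_set$i1[un])] <- risk_set$dyad[un]
  m
}

n_dyads <- function(risk_set) {
  n <- attr(risk_set, "n_actors")
  n * (n - 1L) / 2L
}
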