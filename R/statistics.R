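#' Statistics over the risk set
#'
#' Each `stat_*()` function evaluates one covariate x_p(s, r[, c], t) for
#' every entry of the risk set at a time point, given the dyadic event
#' history. Endogenous statistics (inertia, shared partners and their
#' setting-restricted variants) use only events with statistic-evaluation
#' time strictly before `t` (and at or after `window_start` when given).
#' These are the building blocks [build_design()] assembles into a design
#' array; they are exported both for inspection and because the simulator
#' reuses them verbatim.
#'
#' @param risk_set A [build_risk_set()] result.
#' @param t Evaluation time in minutes.
#' @param history Tibble of past dyadic events (columns `actor1`, `actor2`,
#'   `stat_time`, `setting`, `duration`, `group_size`), e.g. from
#'   [split_group_events()].
#' @param window_start Optional minute; events before it are ignored by the
#'   endogenous statistics (moving-window restriction).
#' @return A numeric vector with one element per risk-set entry (scalar for
#'   [stat_weekend()] and [stat_group()], which are constant over the risk
#'   set at a given event).
#' @name rem_statistics
NULL

#' @rdname rem_statistics
#' @export
stat_baseline <- function(risk_set) {
  rep(1, nrow(risk_set))
}

#' @rdname rem_statistics
#' @param actors Actor table.
#' @param attribute Categorical actor attribute column name.
#' @param mode `"both_level"` or `"mixed"`.
#' @param level Attribute level (for `"both_level"`).
#' @export
stat_category_pair <- function(risk_set, actors, attribute,
                               mode = c("both_level", "mixed"),
                               level = NULL) {
  mode <- match.arg(mode)
  vals <- actor_column(risk_set, actors, attribute)
  a <- vals[risk_set$i1]
  b <- vals[risk_set$i2]
  if (mode == "both_level") {
    if (is.null(level)) {
      abort("mode 'both_level' requires a level")
    }
    if (!level %in% vals) {
      abort(paste0("level '", level, "' absent from attribute '", attribute, "'"))
    }
    as.numeric(a == level & b == level)
  } else {
    as.numeric(a != b)
  }
}

#' @rdname rem_statistics
#' @param trait Standardized trait column name.
#' @export
stat_trait_extreme <- function(risk_set, actors, trait,
                               mode = c("min", "max")) {
  mode <- match.arg(mode)
  vals <- actor_column(risk_set, actors, trait)
  if (!is.numeric(vals)) {
    abort(paste0("trait '", trait, "' is not numeric"))
  }
  if (anyNA(vals)) {
    abort(paste0("trait '", trait, "' has missing values; standardize first"))
  }
  f <- if (mode == "min") pmin else pmax
  f(vals[risk_set$i1], vals[risk_set$i2])
}

#' @rdname rem_statistics
#' @param calendar A [rem_calendar()].
#' @export
stat_weekend <- function(t, calendar = rem_calendar()) {
  as.numeric(is_weekend(t, calendar))
}

#' @rdname rem_statistics
#' @param group_size Number of participants of the observed event.
#' @export
stat_group <- function(group_size) {
  as.numeric(group_size > 2)
}

#' @rdname rem_statistics
#' @param weighted Weight each past event by `ln(d_e) / (|A_e| - 1)`
#'   (duration and group size); `FALSE` counts events with weight 1.
#' @export
stat_inertia <- function(history, risk_set, t, window_start = NULL,
                         weighted = TRUE) {
  h <- history_window(history, t, window_start)
  per_dyad_sum(h, risk_set, weighted)[risk_set$dyad]
}

#' @rdname rem_statistics
#' @export
stat_shared_partners <- function(history, risk_set, t, window_start = NULL) {
  h <- history_window(history, t, window_start)
  sp_counts(h, risk_set)[cbind(risk_set$i1, risk_set$i2)]
}

#' @rdname rem_statistics
#' @param focal_type Event type whose entries get the value 1.
#' @export
stat_type_dummy <- function(risk_set, focal_type) {
  types <- attr(risk_set, "types")
  if (is.null(types)) {
    abort("type dummy requires a typed risk set")
  }
  if (!focal_type %in% types) {
    abort(paste0("unknown event type: ", focal_type))
  }
  as.numeric(risk_set$type == focal_type)
}

#' @rdname rem_statistics
#' @export
stat_type_inertia <- function(history, risk_set, t, window_start = NULL,
                              weighted = TRUE) {
  per_type_stat(history, risk_set, t, window_start, function(h) {
    per_dyad_sum(h, risk_set, weighted)[risk_set$dyad]
  })
}

#' @rdname rem_statistics
#' @export
stat_type_shared_partners <- function(history, risk_set, t,
                                      window_start = NULL) {
  per_type_stat(history, risk_set, t, window_start, function(h) {
    sp_counts(h, risk_set)[cbind(risk_set$i1, risk_set$i2)]
  })
}

#' Standardize a statistic per time point
#'
#' Endogenous count statistics are standardized at every event over the
#' risk-set entries: `(x - mean(x)) / sd(x)` with the sample SD. A constant
#' vector (SD zero, e.g. before any history has accumulated) maps to all
#' zeros so early events remain usable.
#'
#' @param values Numeric vector over the (active) risk set, length >= 2.
#' @return The standardized vector.
#' @examples
#' scale_per_event(c(1, 2, 3)) # -1 0 1
#' @export
scale_per_event <- function(values) {
  if (length(values) < 2) {
    abort("per-event scaling needs at least 2 risk-set entries")
  }
  s <- sd(values)
  if (s == 0) {
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Interaction of two statistic columns
#'
#' Elementwise product; the product is not re-standardized (components that
#' are endogenous enter already scaled).
#'
#' @param a,b Numeric vectors of equal length.
#' @return `a * b`.
#' @export
stat_interaction <- function(a, b) {
  if (length(a) != length(b)) {
    abort("interaction components differ in length")
  }
  a * b
}

# ---- internal helpers -----------------------------------------------------

actor_column <- function(risk_set, actors, column) {
  if (!column %in% names(actors)) {
    abort(paste0("unknown actor attribute: ", column))
  }
  actors[[column]][match(attr(risk_set, "actor_ids"), actors$actor_id)]
}

history_window <- function(history, t, window_start = NULL) {
  if (is.null(history) || nrow(history) == 0) {
    return(history)
  }
  keep <- history$stat_time < t
  if (!is.null(window_start)) {
    keep <- keep & history$stat_time >= window_start
  }
  history[keep, ]
}

history_indices <- function(h, risk_set) {
  ids <- attr(risk_set, "actor_ids")
  list(i1 = match(h$actor1, ids), i2 = match(h$actor2, ids))
}

# duration/group-size weighted (or unweighted) sum per dyad
per_dyad_sum <- function(h, risk_set, weighted = TRUE) {
  v <- numeric(n_dyads(risk_set))
  if (is.null(h) || nrow(h) == 0) {
    return(v)
  }
  idx <- history_indices(h, risk_set)
  d <- dyad_lookup(risk_set)[cbind(idx$i1, idx$i2)]
  w <- if (weighted) log(h$duration) / (h$group_size - 1) else rep(1, nrow(h))
  agg <- rowsum(w, d)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

# matrix of distinct-shared-partner counts between all actor pairs
sp_counts <- function(h, risk_set) {
  n <- attr(risk_set, "n_actors")
  if (is.null(h) || nrow(h) == 0) {
    return(matrix(0, n, n))
  }
  idx <- history_indices(h, risk_set)
  adj <- matrix(0, n, n)
  adj[cbind(idx$i1, idx$i2)] <- 1
  adj[cbind(idx$i2, idx$i1)] <- 1
  adj %*% adj
}

per_type_stat <- function(history, risk_set, t, window_start, fn) {
  types <- attr(risk_set, "types")
  if (is.null(types)) {
    abort("setting-specific statistics require a typed risk set")
  }
  h <- history_window(history, t, window_start)
  out <- numeric(nrow(risk_set))
  for (ty in types) {
    sel <- risk_set$type == ty
    h_ty <- if (is.null(h) || nrow(h) == 0) h else h[!is.na(h$setting) & h$setting == ty, ]
    out[sel] <- fn(h_ty)[sel]
  }
  out
}
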