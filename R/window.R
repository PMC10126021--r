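#' Construct moving windows over an observation period
#'
#' Windows are `[t_start + k * step, t_start + k * step + length)` for
#' `k = 0, 1, ...` while the window end is at most `t_end`, giving
#' `floor((t_end - t_start - length) / step) + 1` windows. When the window
#' length exceeds the span a single window covering the span is returned
#' with a warning.
#'
#' @param t_start,t_end Span of the observation period in minutes.
#' @param length_minutes Window length in minutes (> 0).
#' @param step_minutes Step between window starts, `0 < step <= length`
#'   (overlap is `length - step`).
#' @return A tibble with `window`, `start`, `end` and `label` (the window
#'   midpoint expressed in days).
#' @examples
#' nrow(make_windows(0, 23 * 1440, 3 * 1440, 1440)) # 21 windows
#' @export
make_windows <- function(t_start, t_end, length_minutes, step_minutes) {
  if (length_minutes <= 0) {
    abort("window length must be positive")
  }
  if (step_minutes <= 0 || step_minutes > length_minutes) {
    abort("step must satisfy 0 < step <= length")
  }
  span <- t_end - t_start
  if (length_minutes > span) {
    warn("window length exceeds the observation span; using a single window")
    starts <- t_start
    length_minutes <- span
  } else {
    k <- floor((span - length_minutes) / step_minutes)
    starts <- t_start + step_minutes * (0:k)
  }
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    end = starts + length_minutes,
    label = (starts + length_minutes / 2) / 1440
  )
}

#' Fit a relational event model in moving windows
#'
#' The five-step moving-window procedure: slide a window over the event
#' sequence, fit the same model to the events inside each window, and
#' collect the coefficient trajectory. Endogenous statistics inside a
#' window use only the window's own history (`window_start` is the window
#' start), and the waiting time of a window's first event is measured from
#' the window start. A weekend effect should be omitted (the windows
#' themselves trace any weekday/weekend rhythm); including one triggers a
#' warning.
#'
#' @param events Dyadic events (from [split_group_events()]).
#' @param risk_set,actors,specs,calendar As in [build_design()].
#' @param windows A [make_windows()] tibble.
#' @param kind Likelihood kind, `"full"` or `"ordinal"`.
#' @param min_events Windows with fewer events are skipped with a warning
#'   (default 100; small windows give unstable estimates).
#' @param gof_share,gof_seed When `gof_seed` is given, the top-share hit
#'   rate is computed per window with the window's own fit.
#' @return A `rem_window_trajectory`: list with `estimates` (long tibble:
#'   window, label, term, estimate, std.error) and `windows` (per-window
#'   label, n_events, logLik, BIC, gof).
#' @export
fit_moving_window <- function(events, risk_set, actors, specs,
                              windows, kind = c("full", "ordinal"),
                              calendar = rem_calendar(),
                              min_events = 100,
                              gof_share = 0.05, gof_seed = NULL) {
  kind <- match.arg(kind)
  specs <- as_effect_list(specs)
  if (any(vapply(specs, `[[`, "", "kind") == "weekend")) {
    warn(paste0(
      "a weekend effect in a moving-window model is redundant: ",
      "the window trajectory picks up weekday/weekend differences itself"
    ))
  }
  events <- prepare_dyadic_events(events)
  est <- list()
  win <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    ev_w <- events[events$stat_time >= w$start & events$stat_time < w$end, ]
    if (nrow(ev_w) < min_events) {
      warn(paste0(
        "window ", w$window, " [", w$start, ", ", w$end, ") holds ",
        nrow(ev_w), " events (< ", min_events, "); skipped"
      ))
      next
    }
    design <- build_design(
      ev_w, risk_set, actors, specs,
      calendar = calendar, window_start = w$start, t0 = w$start
    )
    fit <- fit_rem(design, kind = kind)
    gof <- NA_real_
    if (!is.null(gof_seed)) {
      gof <- top_share_hit_rate(
        fit$coefficients, design,
        share = gof_share, seed = gof_seed
      )$hit_rate
    }
    est[[length(est) + 1]] <- dplyr::mutate(
      tidy(fit)[c("term", "estimate", "std.error")],
      window = w$window, label = w$label, .before = 1
    )
    win[[length(win) + 1]] <- tibble::tibble(
      window = w$window, start = w$start, end = w$end, label = w$label,
      n_events = nrow(ev_w), logLik = fit$loglik, BIC = fit$bic, gof = gof
    )
  }
  if (!length(win)) {
    abort("all windows were skipped; nothing to fit")
  }
  structure(
    list(
      estimates = dplyr::bind_rows(est),
      windows = dplyr::bind_rows(win),
      kind = kind
    ),
    class = "rem_window_trajectory"
  )
}

#' @export
print.rem_window_trajectory <- function(x, ...) {
  cat(
    "<rem_window_trajectory> ", nrow(x$windows), " windows, ",
    length(unique(x$estimates$term)), " effects, ", x$kind,
    " likelihood\n",
    sep = ""
  )
  print(x$windows, ...)
  invisible(x)
}

#' Export a window trajectory as long-format delimited text
#'
#' One row per window and effect with the per-window model summaries
#' attached, suitable for plotting coefficient trajectories.
#'
#' @param trajectory A [fit_moving_window()] result.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  long <- dplyr::left_join(
    trajectory$estimates,
    trajectory$windows[c("window", "n_events", "BIC", "gof")],
    by = "window"
  )
  readr::write_tsv(long, path)
  invisible(path)
}
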