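#' Top-share predictive hit rate
#'
#' Goodness-of-fit metric: the proportion of observed events whose dyad was
#' among the top `share` (default 5%) of risk-set entries ranked by
#' predicted rate. Dyadic events that were split from one group interaction
#' count once: the group scores a hit iff its *best-ranked* constituent
#' dyad is inside the top set (group-event refinement). Ties in the
#' predicted rates are broken by a seeded random permutation, so a
#' rate-constant (baseline-only) model on dyadic data hits at the nominal
#' share in expectation. The top-set size is `k = ceiling(share * |R|)`
#' over the active risk set.
#'
#' @param beta Coefficient vector (fitted or hypothesized).
#' @param design A [build_design()] result (in-sample, or a held-out design
#'   built with the same effects).
#' @param share Top share in (0, 1]; default 0.05.
#' @param seed Integer seed for tie-breaking (required).
#' @return A `rem_gof` object: list with `hit_rate`, per-original-event
#'   `hits` tibble (`group_id`, `hit`, `best_rank`, `k`), `share`, `seed`.
#' @export
top_share_hit_rate <- function(beta, design, share = 0.05, seed) {
  if (share <= 0 || share > 1) {
    abort("share must be in (0, 1]")
  }
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required for rank tie-breaking")
  }
  r_n <- design$R
  eta <- matrix(design$X %*% beta, nrow = r_n) # R x M
  gids <- unique(design$events$group_id)
  res <- withr::with_seed(as.integer(seed), {
    purrr::map(gids, function(gid) {
      rows <- which(design$events$group_id == gid)
      first <- rows[1]
      act <- design$active[, first]
      rates <- eta[act, first]
      k <- ceiling(share * sum(act))
      # rank among active entries, ties broken at random
      tie <- runif(length(rates))
      ranks <- order(order(-rates, tie))
      obs_pos <- match(design$obs[rows], which(act))
      best <- min(ranks[obs_pos])
      tibble::tibble(group_id = gid, hit = best <= k, best_rank = best, k = k)
    })
  })
  hits <- dplyr::bind_rows(res)
  structure(
    list(
      hit_rate = mean(hits$hit),
      hits = hits,
      share = share,
      seed = as.integer(seed)
    ),
    class = "rem_gof"
  )
}

#' @export
print.rem_gof <- function(x, ...) {
  cat(
    "<rem_gof> top-", format(100 * x$share), "% hit rate: ",
    sprintf("%.1f%%", 100 * x$hit_rate), " over ", nrow(x$hits),
    " original events\n",
    sep = ""
  )
  invisible(x)
}
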