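#' Event rate of a candidate event
#'
#' The relational event model is log-linear: the rate of candidate event
#' with statistic vector `x` is `exp(sum(beta * x))`.
#'
#' @param beta Coefficient vector.
#' @param x Statistic vector of the same length.
#' @return A positive scalar rate (events per minute).
#' @export
event_rate <- function(beta, x) {
  if (length(beta) != length(x)) {
    abort("beta and x differ in length")
  }
  if (!all(is.finite(beta)) || !all(is.finite(x))) {
    abort("non-finite inputs to event_rate")
  }
  exp(sum(beta * x))
}

#' Relational event model log-likelihood
#'
#' Under the piecewise-constant hazard assumption the waiting time to the
#' next event is exponential with rate equal to the summed rates over the
#' risk set, and the observed pair is drawn with probability proportional
#' to its rate. The full log-likelihood over the observed sequence is
#' therefore
#' \deqn{\ell(\beta) = \sum_e \big[\beta^\top x_{obs(e)}
#'   - \Delta t_e \sum_{r \in R(t_e)} e^{\beta^\top x_r}\big],}
#' and when only the event order is used the waiting-time factor reduces to
#' the conditional multinomial choice probability, giving the ordinal
#' log-likelihood
#' \deqn{\ell(\beta) = \sum_e \big[\beta^\top x_{obs(e)}
#'   - \ln \sum_{r \in R(t_e)} e^{\beta^\top x_r}\big].}
#'
#' @param beta Coefficient vector (length `design$P`).
#' @param design A [build_design()] result.
#' @param kind `"full"` (uses waiting times) or `"ordinal"` (order only).
#' @return The log-likelihood value.
#' @export
loglik <- function(beta, design, kind = c("full", "ordinal")) {
  kind <- match.arg(kind)
  loglik_parts(beta, design, kind)$value
}

# value, gradient and Hessian in one pass
loglik_parts <- function(beta, design, kind, hessian = FALSE) {
  if (design$M == 0) {
    abort("empty design")
  }
  r_n <- design$R
  m_n <- design$M
  eta <- design$X %*% beta                       # (M*R) x 1
  lam <- matrix(exp(eta), nrow = r_n)            # R x M
  lam[!design$active] <- 0
  obs_lin <- (seq_len(m_n) - 1) * r_n + design$obs
  denom <- colSums(lam)                          # sum of rates per event
  if (any(denom == 0)) {
    abort("total event rate is zero for some event")
  }
  if (kind == "full") {
    w_event <- design$dt                         # weight on the hazard sum
    value <- sum(eta[obs_lin]) - sum(design$dt * denom)
  } else {
    w_event <- 1 / denom
    value <- sum(eta[obs_lin]) - sum(log(denom))
  }
  w <- as.vector(lam) * rep(w_event, each = r_n) # per-entry weight
  grad <- colSums(design$X[obs_lin, , drop = FALSE]) -
    as.vector(crossprod(design$X, w))
  hess <- NULL
  if (hessian) {
    xw <- design$X * sqrt(w)
    hess <- -crossprod(xw)
    if (kind == "ordinal") {
      # + sum_e mu_e mu_e^T with mu_e = sum_r p_er x_r
      mu <- rowsum(design$X * w, rep(seq_len(m_n), each = r_n))
      hess <- hess + crossprod(mu)
    }
  }
  list(value = value, gradient = grad, hessian = hess)
}

#' Fit a relational event model by maximum likelihood
#'
#' Newton-Raphson ascent with analytic gradient and Hessian (the full and
#' ordinal log-likelihoods are globally concave in beta), step-halving when
#' a step does not improve the objective, deterministic start at the zero
#' vector. Standard errors come from the observed information (inverse of
#' the negative Hessian at the maximum).
#'
#' @param design A [build_design()] result.
#' @param kind `"full"` or `"ordinal"` likelihood.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `rem_fit` object; see [tidy.rem_fit()] and [glance.rem_fit()].
#' @export
fit_rem <- function(design, kind = c("full", "ordinal"),
                    tol = 1e-8, max_iter = 200) {
  kind <- match.arg(kind)
  check_collinearity(design)
  beta <- numeric(design$P)
  parts <- loglik_parts(beta, design, kind, hessian = TRUE)
  converged <- FALSE
  iter <- 0
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(parts$gradient)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(
      solve(parts$hessian, -parts$gradient),
      error = function(e) parts$gradient # fall back to steepest ascent
    )
    size <- 1
    repeat {
      cand <- beta + size * step
      cand_parts <- tryCatch(
        loglik_parts(cand, design, kind, hessian = TRUE),
        error = function(e) NULL
      )
      if (!is.null(cand_parts) && is.finite(cand_parts$value) &&
        cand_parts$value >= parts$value - 1e-12) {
        break
      }
      size <- size / 2
      if (size < 1e-12) {
        abort("Newton step failed to improve the log-likelihood")
      }
    }
    beta <- cand
    parts <- cand_parts
    trace <- c(trace, parts$value)
  }
  if (!converged && max(abs(parts$gradient)) < tol) {
    converged <- TRUE
  }
  if (!converged) {
    abort(paste0(
      "fit_rem did not converge in ", max_iter, " iterations; ",
      "last gradient max-norm ", signif(max(abs(parts$gradient)), 3),
      "; log-likelihood trace tail: ",
      paste(signif(utils::tail(trace, 5), 8), collapse = ", ")
    ))
  }
  vcov <- solve(-parts$hessian)
  se <- sqrt(diag(vcov))
  est <- setNames(as.vector(beta), design$effects)
  z <- est / se
  fit <- structure(
    list(
      coefficients = est,
      se = setNames(se, design$effects),
      vcov = vcov,
      loglik = parts$value,
      M = design$M,
      P = design$P,
      kind = kind,
      converged = TRUE,
      iterations = iter,
      gradient_norm = max(abs(parts$gradient)),
      p_values = setNames(2 * pnorm(-abs(z)), design$effects)
    ),
    class = "rem_fit"
  )
  fit$bic <- bic(fit)
  fit
}

check_collinearity <- function(design) {
  qr_x <- qr(design$X)
  if (qr_x$rank < design$P) {
    drop <- design$effects[qr_x$pivot[(qr_x$rank + 1):design$P]]
    abort(paste0(
      "design columns are collinear: ", paste(drop, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2 * loglik + p * ln(M)`, with `M` the number of observed (split)
#' dyadic events the likelihood runs over and `p` the number of
#' coefficients. Lower is better.
#'
#' @param fit A converged [fit_rem()] result.
#' @return The BIC value.
#' @export
bic <- function(fit) {
  if (!isTRUE(fit$converged)) {
    abort("BIC requires a converged fit")
  }
  -2 * fit$loglik + fit$P * log(fit$M)
}

#' @export
print.rem_fit <- function(x, ...) {
  cat(
    "<rem_fit> ", x$kind, " likelihood, ", x$M, " events, logLik ",
    signif(x$loglik, 8), ", BIC ", signif(x$bic, 8), "\n",
    sep = ""
  )
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted relational event model
#'
#' @param x A `rem_fit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` and `rate.multiplier` (`exp(estimate)`).
#' @method tidy rem_fit
#' @export
tidy.rem_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p.value = unname(x$p_values),
    rate.multiplier = exp(unname(x$coefficients))
  )
}

#' Model-level summary of a fitted relational event model
#'
#' @param x A `rem_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `BIC`, `nobs`, `npar`,
#'   `likelihood`, `converged`, `iterations`.
#' @method glance rem_fit
#' @export
glance.rem_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    BIC = x$bic,
    nobs = x$M,
    npar = x$P,
    likelihood = x$kind,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Interpretation helpers
#'
#' `rate_multiplier()` converts a coefficient to the multiplicative change
#' in the event rate per unit of its statistic (`exp(beta)`).
#' `expected_waiting_time()` gives the expected minutes between events for
#' a dyad profile: the inverse of the summed rate
#' `R * exp(beta_baseline + sum(beta * x))` over `R` risk-set entries.
#' `net_group_effect()` corrects a fitted group coefficient for the
#' artificial rate inflation of group splitting
#' (`beta_group - ln(n_dyadic / n_raw)`).
#'
#' @param beta_p A single coefficient.
#' @return `rate_multiplier()`: `exp(beta_p)`.
#' @examples
#' rate_multiplier(0.14) # about 1.15
#' expected_waiting_time(-10.93, 7875) # about 7.09 minutes
#' net_group_effect(2.15, 2886, 11690) # about 0.75
#' @export
rate_multiplier <- function(beta_p) {
  if (!is.finite(beta_p)) {
    abort("beta must be finite")
  }
  exp(beta_p)
}

#' @rdname rate_multiplier
#' @param beta_baseline Baseline (intercept) coefficient.
#' @param riskset_size Number of risk-set entries the profile applies to.
#' @param extra Optional list of `c(beta, x)` pairs added to the linear
#'   predictor.
#' @export
expected_waiting_time <- function(beta_baseline, riskset_size, extra = list()) {
  if (riskset_size < 1) {
    abort("riskset_size must be at least 1")
  }
  shift <- sum(vapply(extra, function(e) e[1] * e[2], numeric(1)))
  1 / (riskset_size * exp(beta_baseline + shift))
}

#' @rdname rate_multiplier
#' @param beta_group Fitted group-context coefficient.
#' @param n_raw,n_dyadic Pre- and post-split event counts.
#' @export
net_group_effect <- function(beta_group, n_raw, n_dyadic) {
  beta_group - expansion_log_factor(n_raw, n_dyadic)
}

#' Export a fit summary as delimited text
#'
#' Writes a coefficient table (effect, estimate, SE, significance flag at
#' 0.05) in tab-separated form.
#'
#' @param fit A `rem_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  tab <- tidy(fit)
  tab$significant <- ifelse(tab$p.value < 0.05, "*", "")
  readr::write_tsv(tab, path)
  invisible(path)
}
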