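# Cox proportional-hazards machinery -------------------------------------
#
# The model is S(t | x) = S0(t)^exp(psi(x)) with psi the log relative
# hazard. The partial likelihood below is also the training loss of the
# neural risk model, so the gradient with respect to the scores is exposed.

check_outcomes <- function(time, event) {
  check_numeric_vector(time, "time")
  if (length(event) != length(time)) stop_input("`time` and `event` lengths differ")
  if (!all(event %in% c(0, 1))) stop_input("`event` must be a 0/1 indicator")
  if (any(time <= 0)) stop_input("`time` must be positive")
  if (sum(event) == 0) stop_input("no events: the partial likelihood is undefined")
  invisible(NULL)
}

# Sorted risk-set structures shared by the routines below. Subjects are
# ordered by decreasing observed time so risk sets are prefixes; tied times
# form groups whose last index bounds the risk set.
cox_risk_structure <- function(time, event) {
  n <- length(time)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  d_s <- event[ord]
  grp <- cumsum(c(TRUE, diff(t_s) != 0))
  lasts <- c(which(diff(t_s) != 0), n)      # last sorted index of each tie group
  dk <- as.vector(rowsum(d_s, grp))         # events per tie group
  ev_grp <- which(dk > 0)
  list(n = n, ord = ord, time = t_s, event = d_s, grp = grp,
       lasts = lasts, dk = dk, ev_grp = ev_grp)
}

#' Cox partial log-likelihood
#'
#' Log partial likelihood of a vector of risk scores (log relative hazards)
#' under the Cox model, with Breslow (default) or Efron handling of tied
#' event times. Invariant to adding a constant to all scores; log-sum-exp
#' terms are shifted by the maximum score for overflow safety.
#'
#' @param scores Numeric vector of risk scores psi, one per subject.
#' @param time Positive observed times (event or censoring).
#' @param event 0/1 event indicator; at least one event is required.
#' @param ties `"breslow"` or `"efron"`.
#' @return The log partial likelihood (a scalar).
#' @export
cox_partial_log_likelihood <- function(scores, time, event,
                                       ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_numeric_vector(scores, "scores")
  check_outcomes(time, event)
  if (length(scores) != length(time)) stop_input("`scores` and `time` lengths differ")
  rs <- cox_risk_structure(time, event)
  s <- scores[rs$ord]
  M <- max(s)
  w <- exp(s - M)
  S0 <- cumsum(w)
  ll <- sum(s[rs$event == 1])
  for (k in rs$ev_grp) {
    e <- rs$lasts[k]
    d <- rs$dk[k]
    if (ties == "breslow" || d == 1) {
      ll <- ll - d * (log(S0[e]) + M)
    } else {
      in_grp <- rs$grp == k & rs$event == 1
      D0 <- sum(w[in_grp])
      l <- seq_len(d) - 1
      ll <- ll - sum(log(S0[e] - (l / d) * D0) + M)
    }
  }
  ll
}

#' Gradient of the Cox partial log-likelihood in the risk scores
#'
#' Analytic gradient of [cox_partial_log_likelihood()] (Breslow ties) with
#' respect to each subject's score. The negative of this gradient drives
#' the neural risk model's training updates.
#'
#' @inheritParams cox_partial_log_likelihood
#' @return Numeric vector, same length as `scores`.
#' @export
cox_pl_gradient <- function(scores, time, event) {
  check_numeric_vector(scores, "scores")
  check_outcomes(time, event)
  rs <- cox_risk_structure(time, event)
  s <- scores[rs$ord]
  M <- max(s)
  w <- exp(s - M)
  S0 <- cumsum(w)
  q <- numeric(rs$n)
  for (k in rs$ev_grp) {
    e <- rs$lasts[k]
    q[e] <- q[e] + rs$dk[k] / S0[e]
  }
  A <- rev(cumsum(rev(q)))          # sum of d_k / S0_k over risk sets containing i
  g_sorted <- rs$event - w * A      # scale factors in w and S0 cancel
  g <- numeric(rs$n)
  g[rs$ord] <- g_sorted
  g
}

# Log-likelihood, score vector and observed information for a linear
# predictor X beta, used by the Newton iterations of fit_linear_cox().
cox_lgh <- function(X, beta, rs, ties) {
  p <- ncol(X)
  Xs <- X[rs$ord, , drop = FALSE]
  s <- drop(Xs %*% beta)
  M <- max(s)
  w <- exp(s - M)
  S0 <- cumsum(w)
  S1 <- apply(Xs * w, 2, cumsum)
  if (!is.matrix(S1)) S1 <- matrix(S1, nrow = 1)
  XX <- Xs[, rep(seq_len(p), each = p), drop = FALSE] *
        Xs[, rep(seq_len(p), times = p), drop = FALSE]
  S2 <- apply(XX * w, 2, cumsum)
  if (!is.matrix(S2)) S2 <- matrix(S2, nrow = 1)

  ll <- sum(s[rs$event == 1])
  grad <- colSums(Xs[rs$event == 1, , drop = FALSE])
  info <- matrix(0, p, p)
  for (k in rs$ev_grp) {
    e <- rs$lasts[k]
    d <- rs$dk[k]
    if (ties == "breslow" || d == 1) {
      r1 <- S1[e, ] / S0[e]
      ll <- ll - d * (log(S0[e]) + M)
      grad <- grad - d * r1
      info <- info + d * (matrix(S2[e, ], p, p) / S0[e] - tcrossprod(r1))
    } else {
      in_grp <- rs$grp == k & rs$event == 1
      D0 <- sum(w[in_grp])
      D1 <- colSums(Xs[in_grp, , drop = FALSE] * w[in_grp])
      D2 <- colSums(XX[in_grp, , drop = FALSE] * w[in_grp])
      for (l in seq_len(d) - 1) {
        f0 <- S0[e] - (l / d) * D0
        f1 <- S1[e, ] - (l / d) * D1
        f2 <- matrix(S2[e, ] - (l / d) * D2, p, p)
        ll <- ll - (log(f0) + M)
        grad <- grad - f1 / f0
        info <- info + f2 / f0 - tcrossprod(f1 / f0)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a linear Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with step-halving
#' line search, Wald standard errors from the inverse observed information,
#' hazard ratios with 95% confidence intervals exp(beta +/- 1.96 SE), and
#' two-sided Wald p-values. The Breslow baseline survival at x = 0 is
#' attached to the fit.
#'
#' @param X Numeric covariate matrix (n x p), n > p, no zero-variance column.
#' @param time,event Survival outcome as in [cox_partial_log_likelihood()].
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient norm; iteration also
#'   stops once the Newton step falls below numerical precision (1e-10),
#'   which on large cohorts is the binding criterion.
#' @return An object of class `icu_coxfit` with elements `coefficients`,
#'   `standard_errors`, `hazard_ratios`, `ci_lower`, `ci_upper`,
#'   `p_values`, `loglik`, `baseline`, and `convergence_info`.
#' @export
fit_linear_cox <- function(X, time, event, ties = c("breslow", "efron"),
                           max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_outcomes(time, event)
  if (nrow(X) != length(time)) stop_input("`X` rows and `time` length differ")
  if (nrow(X) <= ncol(X)) stop_input("need more subjects than covariates")
  if (anyNA(X) || any(!is.finite(X))) stop_input("`X` contains non-finite values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop_input("zero-variance covariate column(s): %s", paste(bad, collapse = ", "))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  rs <- cox_risk_structure(time, event)
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_lgh(X, beta, rs, ties)
  iter <- 0L
  gnorm <- sqrt(sum(cur$grad^2))
  while (gnorm >= tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      cond <- structure(
        class = c("icusurv_no_convergence", "error", "condition"),
        list(message = sprintf(
               "Newton-Raphson did not converge in %d iterations (|grad| = %.3g)",
               max_iter, gnorm),
             call = sys.call(-1), beta = beta, grad_norm = gnorm)
      )
      stop(cond)
    }
    delta <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(delta)) stop_input("observed information is singular (separation or collinearity)")
    if (max(abs(delta)) < 1e-8 * (1 + max(abs(beta)))) break  # beta at precision
    step <- 1
    repeat {
      cand <- beta + step * delta
      new <- cox_lgh(X, cand, rs, ties)
      if (new$ll > cur$ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    cur <- new
    gnorm <- sqrt(sum(cur$grad^2))
    if (any(abs(beta) > 15)) {
      stop_input("coefficients diverging (|beta| > 15): likely separation")
    }
  }

  vcov <- solve(cur$info)
  se <- sqrt(diag(vcov))
  hr <- exp(beta)
  z <- beta / se
  fit <- structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    standard_errors = stats::setNames(se, colnames(X)),
    hazard_ratios = stats::setNames(hr, colnames(X)),
    ci_lower = stats::setNames(exp(beta - 1.96 * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + 1.96 * se), colnames(X)),
    p_values = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    vcov = vcov,
    loglik = cur$ll,
    ties = ties,
    n = nrow(X),
    n_events = sum(event),
    convergence_info = list(iterations = iter, grad_norm = gnorm),
    baseline = breslow_baseline(drop(X %*% beta), time, event)
  ), class = "icu_coxfit")
  fit
}

#' @export
print.icu_coxfit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(
    coef = x$coefficients, HR = x$hazard_ratios,
    `lower95` = x$ci_lower, `upper95` = x$ci_upper,
    se = x$standard_errors, p = signif(x$p_values, 3)
  )
  print(tab, digits = 4)
  invisible(x)
}

#' Serialize a fitted Cox model
#'
#' Writes the fit as JSON (coefficients, hazard ratios, confidence bounds,
#' p-values, convergence info) and/or as a CSV hazard-ratio table with one
#' row per covariate (columns Abnormality, Hazard ratio, CI bounds, P).
#'
#' @param fit An `icu_coxfit`.
#' @param json_path,csv_path Output paths; `NULL` skips that format.
#' @return Invisibly, the hazard-ratio table data.frame.
#' @export
write_coxfit <- function(fit, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(fit, "icu_coxfit"))
  tab <- data.frame(
    covariate = names(fit$coefficients),
    hazard_ratio = round(unname(fit$hazard_ratios), 4),
    ci_lower = round(unname(fit$ci_lower), 4),
    ci_upper = round(unname(fit$ci_upper), 4),
    p_value = signif(unname(fit$p_values), 4),
    stringsAsFactors = FALSE
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      coefficients = as.list(fit$coefficients),
      hazard_ratios = as.list(fit$hazard_ratios),
      ci_lower = as.list(fit$ci_lower),
      ci_upper = as.list(fit$ci_upper),
      p_values = as.list(fit$p_values),
      convergence_info = fit$convergence_info
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(tab)
}

#' Breslow baseline survival function
#'
#' Estimates the cumulative baseline hazard H0(t) = sum over event times
#' t_k <= t of d_k / sum(at risk) exp(psi), and the baseline survival
#' S0(t) = exp(-H0(t)), a right-continuous nonincreasing step function
#' equal to 1 before the first event time.
#'
#' @inheritParams cox_partial_log_likelihood
#' @return An object of class `icu_baseline`: list with `time` (ordered
#'   distinct event times), `hazard` (increments d_k / sum exp(psi)),
#'   `cumhaz`, and `surv`.
#' @export
breslow_baseline <- function(scores, time, event) {
  check_numeric_vector(scores, "scores")
  check_outcomes(time, event)
  rs <- cox_risk_structure(time, event)
  s <- scores[rs$ord]
  M <- max(s)
  w <- exp(s - M)
  S0 <- cumsum(w)
  ev <- rs$ev_grp
  t_ev <- rs$time[rs$lasts[ev]]
  # log-space: robust to extreme score ranges (exp(M) may overflow)
  h0 <- exp(log(rs$dk[ev]) - log(S0[rs$lasts[ev]]) - M)
  o <- order(t_ev)               # ascend in time
  t_ev <- t_ev[o]; h0 <- h0[o]
  H0 <- cumsum(h0)
  structure(list(time = t_ev, hazard = h0, cumhaz = H0, surv = exp(-H0)),
            class = "icu_baseline")
}

#' @export
print.icu_baseline <- function(x, ...) {
  cat(sprintf("Breslow baseline survival: %d event times, S0 range [%.4f, 1]\n",
              length(x$time), min(x$surv)))
  invisible(x)
}

#' Subject-specific survival curve
#'
#' Evaluates S(t | x) = S0(t)^exp(psi) on a grid of times, where S0 is a
#' Breslow baseline and psi the subject's risk score.
#'
#' @param baseline An `icu_baseline` from [breslow_baseline()].
#' @param score Scalar risk score psi.
#' @param times Evaluation times; defaults to the baseline's event times.
#' @return data.frame with columns `time` and `surv` (values in \[0, 1\],
#'   nonincreasing in `time`).
#' @export
survival_function <- function(baseline, score, times = NULL) {
  stopifnot(inherits(baseline, "icu_baseline"))
  check_scalar_number(score, "score")
  times <- times %||% baseline$time
  check_numeric_vector(times, "times")
  s0 <- c(1, baseline$surv)[findInterval(times, baseline$time) + 1L]
  data.frame(time = times, surv = s0^exp(score))
}
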