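# Evaluation: concordance index and bootstrap protocol --------------------

#' Concordance index for censored survival data
#'
#' Over ordered subject pairs where the shorter observed time belongs to a
#' subject with an event, credits 1 when the longer-time subject's risk is
#' strictly lower and 0.5 on risk ties; pairs with tied observed times are
#' not comparable. Higher risk is expected for shorter time-to-event, so a
#' random score gives 0.5 in expectation and a score strictly decreasing
#' in a fully observed event time gives exactly 1.
#'
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @param risk Risk scores (log relative hazards or any monotone
#'   transformation thereof).
#' @return Object of class `c_index_result`: list with `value`,
#'   `concordant_pairs` (tie credit included), `comparable_pairs`.
#' @export
c_index <- function(time, event, risk) {
  check_numeric_vector(time, "time")
  check_numeric_vector(risk, "risk")
  if (length(time) != length(event) || length(time) != length(risk)) {
    stop_input("`time`, `event`, `risk` lengths differ")
  }
  if (!all(event %in% c(0, 1))) stop_input("`event` must be a 0/1 indicator")
  conc <- 0
  comp <- 0
  for (j in which(event == 1)) {
    later <- time > time[j]
    comp <- comp + sum(later)
    conc <- conc + sum(risk[later] < risk[j]) + 0.5 * sum(risk[later] == risk[j])
  }
  if (comp < 1) stop_input("no comparable pair (all subjects censored or tied)")
  structure(list(value = conc / comp, concordant_pairs = conc,
                 comparable_pairs = comp), class = "c_index_result")
}

#' @export
print.c_index_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%.1f / %d comparable pairs)\n",
              x$value, x$concordant_pairs, x$comparable_pairs))
  invisible(x)
}

# 70/10/20 (or as configured) role assignment.
split_roles <- function(n, fractions) {
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  roles <- rep("test", n)
  perm <- sample.int(n)
  roles[perm[seq_len(n_train)]] <- "train"
  roles[perm[n_train + seq_len(n_val)]] <- "val"
  roles
}

# Fit/evaluate one model spec on one bootstrap replicate; returns the test
# C-index. model_spec types:
#   saps_score : the SAPS-II integer score itself as the risk score
#   coxph      : linear Cox fit on the spec's feature blocks
#   deepsurv   : fusion network per the spec's fusion_config
fit_and_score <- function(cohort, idx_train, idx_val, idx_test, model_spec, gcn) {
  test <- cohort_subset(cohort, idx_test)
  if (identical(model_spec$type, "saps_score")) {
    risk <- test$data$saps_score
  } else if (identical(model_spec$type, "coxph")) {
    train <- cohort_subset(cohort, c(idx_train, idx_val))
    Xtr <- do.call(cbind, feature_matrices(train, model_spec$features, gcn = gcn))
    Xte <- do.call(cbind, feature_matrices(test, model_spec$features, gcn = gcn))
    keep <- apply(Xtr, 2, stats::sd) > 0
    ctr <- colMeans(Xtr[, keep, drop = FALSE])
    scl <- apply(Xtr[, keep, drop = FALSE], 2, stats::sd)
    Ztr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, ctr), 2, scl, `/`)
    Zte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, ctr), 2, scl, `/`)
    fit <- fit_linear_cox(Ztr, train$data$time, train$data$event)
    risk <- drop(Zte %*% fit$coefficients)
  } else if (identical(model_spec$type, "deepsurv")) {
    train <- cohort_subset(cohort, idx_train)
    val <- cohort_subset(cohort, idx_val)
    model <- train_risk_model(train, val, model_spec$config, gcn = gcn)
    risk <- risk_forward(model, test, gcn = gcn)
  } else {
    stop_input("unknown model_spec type '%s'", model_spec$type %||% "<missing>")
  }
  c_index(test$data$time, test$data$event, risk)$value
}

#' Bootstrap evaluation of a survival model
#'
#' The study's evaluation protocol: for each replicate, sample n subjects
#' with replacement from the cohort, split the sample into training,
#' validation and test sets (default 70/10/20), train the model (with
#' validation-based early stopping for the neural models), and compute the
#' test-set C-index. The 95% CI is the 2.5/97.5 percentile of the
#' replicate values (normal approximation behind `ci_method = "normal"`).
#' Replicates whose test split has no comparable pair are redrawn (at most
#' 10 attempts each). Fully seeded: the per-replicate seeds are drawn once
#' from the master seed, so two models evaluated with the same master seed
#' see identical resamples and are validly paired.
#'
#' @param cohort An `icu_cohort`.
#' @param model_spec list with `type` (`"saps_score"`, `"coxph"`,
#'   `"deepsurv"`), optional `name`, plus `features` (character vector of
#'   feature blocks) for `coxph` or `config` (a [fusion_config()]) for
#'   `deepsurv`.
#' @param n_replicates Number of bootstrap replicates (default 200).
#' @param seed Master seed.
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param gcn Optional [gcn_params()] shared by all replicates.
#' @return Object of class `bootstrap_result`: `model`, `replicate_values`,
#'   `mean`, `ci95`, `n_replicates`, `split_fractions`, `seeds`.
#' @export
bootstrap_experiment <- function(cohort, model_spec, n_replicates = 200L,
                                 seed = 1L, split_fractions = c(0.7, 0.1, 0.2),
                                 ci_method = c("percentile", "normal"),
                                 gcn = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cohort, "icu_cohort"))
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop_input("`split_fractions` must sum to 1")
  }
  n <- nrow(cohort$data)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  values <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    done <- FALSE
    for (attempt in 0:9) {
      set.seed(derive_seed(rep_seeds[r], attempt))
      idx <- sample.int(n, n, replace = TRUE)
      roles <- split_roles(n, split_fractions)
      spec <- model_spec
      if (identical(spec$type, "deepsurv")) {
        spec$config$seed <- derive_seed(rep_seeds[r], 1000L + attempt)
      }
      v <- tryCatch(
        fit_and_score(cohort, idx[roles == "train"], idx[roles == "val"],
                      idx[roles == "test"], spec, gcn),
        error = function(e) e
      )
      if (!inherits(v, "error")) {
        values[r] <- v
        done <- TRUE
        break
      }
      message(sprintf("replicate %d attempt %d redrawn: %s",
                      r, attempt + 1, conditionMessage(v)))
    }
    if (!done) stop_input("replicate %d failed after 10 attempts", r)
  }
  ci <- if (ci_method == "percentile") {
    unname(stats::quantile(values, c(0.025, 0.975), type = 7))
  } else {
    mean(values) + c(-1.96, 1.96) * stats::sd(values) / sqrt(n_replicates)
  }
  structure(list(
    model = model_spec$name %||% model_spec$type,
    replicate_values = values,
    mean = mean(values),
    ci95 = ci,
    n_replicates = as.integer(n_replicates),
    split_fractions = split_fractions,
    seeds = rep_seeds,
    ci_method = ci_method
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s: mean C-index %.4f (95%% CI %.4f-%.4f, %d replicates)\n",
              x$model, x$mean, x$ci95[1], x$ci95[2], x$n_replicates))
  invisible(x)
}

#' Paired comparison of two bootstrapped models
#'
#' Two-sided paired test on the per-replicate C-index differences
#' (b minus a). Requires both results to come from the same master seed
#' (identical per-replicate resamples). Default test: Wilcoxon signed
#' rank; a paired t-test is available behind `method = "t"`.
#'
#' @param a,b `bootstrap_result` objects with identical replicate seeds.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return list with `mean_difference` (b - a), `p_value`, `direction`,
#'   `method`.
#' @export
compare_models <- function(a, b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  if (!identical(a$seeds, b$seeds)) {
    stop_input("bootstrap results are not paired (different replicate seeds)")
  }
  d <- b$replicate_values - a$replicate_values
  if (all(d == 0)) {
    p <- 1
  } else if (method == "wilcoxon") {
    p <- stats::wilcox.test(d, exact = FALSE)$p.value
  } else {
    p <- stats::t.test(d)$p.value
  }
  list(
    mean_difference = mean(d),
    p_value = p,
    direction = if (mean(d) > 0) sprintf("%s > %s", b$model, a$model)
                else if (mean(d) < 0) sprintf("%s > %s", a$model, b$model)
                else "tied",
    method = method
  )
}

#' Subgroup C-indexes
#'
#' Restricts the C-index to subjects matching each predicate (by default:
#' normal chest X-ray, abnormal, and each of the 13 findings). Subgroups
#' without a comparable pair are flagged as not evaluable rather than
#' raising an error for the whole batch.
#'
#' @param time,event,risk As in [c_index()].
#' @param groups Named list of logical vectors (subject inclusion masks).
#' @return data.frame with columns `group`, `n`, `value`,
#'   `comparable_pairs`, `evaluable`.
#' @export
subgroup_c_index <- function(time, event, risk, groups) {
  if (!length(groups) || is.null(names(groups))) {
    stop_input("`groups` must be a named list of logical masks")
  }
  rows <- lapply(names(groups), function(g) {
    m <- groups[[g]]
    res <- tryCatch(c_index(time[m], event[m], risk[m]), error = function(e) NULL)
    data.frame(
      group = g, n = sum(m),
      value = if (is.null(res)) NA_real_ else res$value,
      comparable_pairs = if (is.null(res)) 0 else res$comparable_pairs,
      evaluable = !is.null(res),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Standard finding subgroups of a cohort
#'
#' @param cohort An `icu_cohort`.
#' @return Named list of logical masks: `normal`, `abnormal`, and one per
#'   disease finding.
#' @export
cohort_subgroups <- function(cohort) {
  L <- cohort_label_matrix(cohort)
  groups <- list(normal = L[, "normal"] == 1, abnormal = L[, "normal"] == 0)
  for (f in setdiff(colnames(L), "normal")) groups[[f]] <- L[, f] == 1
  groups
}
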