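# Experiment orchestration -------------------------------------------------
#
# Configuration-driven reproduction of the study's experiment grid on a
# synthetic (or user-supplied) cohort: several feature settings of the
# fusion model, linear CoxPH counterparts, the bootstrap evaluation with
# shared replicate seeds (so pairwise comparisons are valid), subgroup
# breakdowns, and the multivariate hazard-ratio table over the 13 disease
# findings.

#' Multivariate hazard-ratio table for the disease findings
#'
#' Fits a multivariate linear Cox model on the 13 binary disease
#' indicators (optionally adjusted for the 15 SAPS-II factor columns) and
#' writes/returns the hazard-ratio table (one row per finding: hazard
#' ratio, 95% CI, Wald p-value).
#'
#' @param cohort An `icu_cohort`.
#' @param adjust_saps Also include the 15 SAPS-II factor columns as
#'   adjustment covariates? (default FALSE; both covariate sets are
#'   exposed rather than assuming one).
#' @param csv_path Optional output CSV path.
#' @return list with `fit` (the `icu_coxfit`) and `table` (data.frame
#'   restricted to the finding rows).
#' @export
make_hr_table <- function(cohort, adjust_saps = FALSE, csv_path = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"))
  L <- cohort_label_matrix(cohort)
  X <- L[, setdiff(colnames(L), "normal"), drop = FALSE]
  if (adjust_saps) X <- cbind(X, saps_factor_matrix(cohort))
  fit <- fit_linear_cox(X, cohort$data$time, cohort$data$event)
  findings <- setdiff(colnames(L), "normal")
  tab <- data.frame(
    abnormality = findings,
    hazard_ratio = round(unname(fit$hazard_ratios[findings]), 4),
    ci_lower = round(unname(fit$ci_lower[findings]), 4),
    ci_upper = round(unname(fit$ci_upper[findings]), 4),
    p_value = signif(unname(fit$p_values[findings]), 4),
    stringsAsFactors = FALSE
  )
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  list(fit = fit, table = tab)
}

# Resolve a model entry of an experiment config into a model_spec list.
resolve_model_spec <- function(entry) {
  type <- entry$type %||% stop_input("model entry without a `type`")
  spec <- list(name = entry$name %||% type, type = type)
  if (type == "coxph") {
    spec$features <- unlist(entry$features %||% "saps")
  } else if (type == "deepsurv") {
    fus <- entry$fusion %||% list()
    fus$modalities <- unlist(entry$features %||% fus$modalities %||% "saps")
    spec$config <- do.call(fusion_config, fus)
  } else if (type != "saps_score") {
    stop_input("unknown model type '%s'", type)
  }
  spec
}

#' Run a configured experiment grid
#'
#' Generates (or loads) a cohort, evaluates every configured model with
#' [bootstrap_experiment()] under a shared master seed (so the models are
#' compared on identical resamples), computes the pairwise comparison
#' matrix, per-finding subgroup C-indexes for each model on a held-out
#' test split, and the hazard-ratio table; writes all result tables as CSV
#' plus a JSON provenance block. Deterministic per config.
#'
#' @param config Path to a YAML/JSON experiment file, or an equivalent
#'   nested list with entries:
#'   \describe{
#'     \item{cohort}{arguments for [cohort_config()], or a string path to
#'       a directory written by [write_cohort()].}
#'     \item{models}{list of model entries: `name`, `type`
#'       (`saps_score` / `coxph` / `deepsurv`), `features`, and optional
#'       `fusion` overrides for [fusion_config()].}
#'     \item{evaluation}{`n_replicates`, `seed`, optional
#'       `split_fractions`, `ci_method`.}
#'     \item{outputs}{output directory.}
#'     \item{subgroups}{logical: compute subgroup tables? (default TRUE)}
#'     \item{hr_table}{logical: fit the finding hazard-ratio table?
#'       (default TRUE)}
#'   }
#' @param seed Optional master-seed override.
#' @return Object of class `experiment_report`: per-model
#'   `bootstrap_result`s, the comparison matrix, subgroup and HR tables,
#'   and the output directory. Result files: `results.csv`,
#'   `comparisons.csv`, `subgroups.csv`, `hr_table.csv`,
#'   `provenance.json`.
#' @export
run_experiment <- function(config, seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  out_dir <- config$outputs %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("experiment stage '%s' failed: %s", what, conditionMessage(e))
    })
  }

  cohort <- stage("cohort", {
    if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      generate_cohort(do.call(cohort_config, config$cohort %||% list()))
    }
  })

  eval_cfg <- config$evaluation %||% list()
  master_seed <- as.integer(seed %||% eval_cfg$seed %||% 1L)
  n_rep <- as.integer(eval_cfg$n_replicates %||% 200L)
  split <- unlist(eval_cfg$split_fractions %||% c(0.7, 0.1, 0.2))
  ci_method <- eval_cfg$ci_method %||% "percentile"

  specs <- lapply(config$models %||% stop_input("config has no `models`"),
                  resolve_model_spec)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) stop_input("model names must be unique")
  needs_gcn <- any(vapply(specs, function(s) {
    identical(s$type, "deepsurv") && "gcn" %in% s$config$modalities ||
      identical(s$type, "coxph") && "gcn" %in% (s$features %||% character())
  }, logical(1)))
  gcn <- if (needs_gcn) {
    do.call(gcn_params, c(list(token_dim = cohort$config$token_dim),
                          config$gcn %||% list()))
  }

  results <- lapply(names(specs), function(nm) {
    stage(paste0("bootstrap:", nm),
          bootstrap_experiment(cohort, specs[[nm]], n_replicates = n_rep,
                               seed = master_seed, split_fractions = split,
                               ci_method = ci_method, gcn = gcn))
  })
  names(results) <- names(specs)

  res_tab <- data.frame(
    model = names(results),
    mean_c_index = vapply(results, function(r) round(r$mean, 4), numeric(1)),
    ci_lower = vapply(results, function(r) round(r$ci95[1], 4), numeric(1)),
    ci_upper = vapply(results, function(r) round(r$ci95[2], 4), numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(res_tab, file.path(out_dir, "results.csv"), row.names = FALSE)

  k <- length(results)
  cmp <- matrix(NA_real_, k, k, dimnames = list(names(results), names(results)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) cmp[i, j] <- compare_models(results[[i]], results[[j]])$p_value
  }
  utils::write.csv(data.frame(model = rownames(cmp), cmp, check.names = FALSE),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)

  subgroup_tab <- NULL
  if (isTRUE(config$subgroups %||% TRUE)) {
    subgroup_tab <- stage("subgroups", {
      set.seed(derive_seed(master_seed, 555L))
      roles <- split_roles(nrow(cohort$data), split)
      rows <- lapply(names(specs), function(nm) {
        risk <- fit_and_score_risks(cohort, roles, specs[[nm]], gcn)
        test <- cohort_subset(cohort, which(roles == "test"))
        sg <- subgroup_c_index(test$data$time, test$data$event, risk,
                               cohort_subgroups(test))
        cbind(model = nm, sg)
      })
      do.call(rbind, rows)
    })
    utils::write.csv(subgroup_tab, file.path(out_dir, "subgroups.csv"),
                     row.names = FALSE)
  }

  hr_tab <- NULL
  if (isTRUE(config$hr_table %||% TRUE)) {
    hr_tab <- stage("hr_table", make_hr_table(
      cohort, adjust_saps = isTRUE(config$hr_adjust_saps),
      csv_path = file.path(out_dir, "hr_table.csv"))$table)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("icusurv")),
    master_seed = master_seed,
    n_replicates = n_rep,
    split_fractions = split,
    cohort_config = unclass(cohort$config),
    models = lapply(specs, function(s) {
      list(name = s$name, type = s$type,
           features = s$features %||% s$config$modalities)
    }),
    replicate_seeds = results[[1]]$seeds
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(results = results, results_table = res_tab,
                 comparison_matrix = cmp, subgroup_table = subgroup_tab,
                 hr_table = hr_tab, output_dir = out_dir),
            class = "experiment_report")
}

# Risks on the test part of a fixed split (used by the subgroup analysis:
# train on the training portion of the whole cohort, test on the held-out
# subjects).
fit_and_score_risks <- function(cohort, roles, spec, gcn) {
  test <- cohort_subset(cohort, which(roles == "test"))
  if (identical(spec$type, "saps_score")) return(test$data$saps_score)
  if (identical(spec$type, "coxph")) {
    train <- cohort_subset(cohort, which(roles != "test"))
    Xtr <- do.call(cbind, feature_matrices(train, spec$features, gcn = gcn))
    Xte <- do.call(cbind, feature_matrices(test, spec$features, gcn = gcn))
    keep <- apply(Xtr, 2, stats::sd) > 0
    ctr <- colMeans(Xtr[, keep, drop = FALSE])
    scl <- apply(Xtr[, keep, drop = FALSE], 2, stats::sd)
    fit <- fit_linear_cox(
      sweep(sweep(Xtr[, keep, drop = FALSE], 2, ctr), 2, scl, `/`),
      train$data$time, train$data$event)
    return(drop(sweep(sweep(Xte[, keep, drop = FALSE], 2, ctr), 2, scl, `/`)
                %*% fit$coefficients))
  }
  train <- cohort_subset(cohort, which(roles == "train"))
  val <- cohort_subset(cohort, which(roles == "val"))
  model <- train_risk_model(train, val, spec$config, gcn = gcn)
  risk_forward(model, test, gcn = gcn)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report\n")
  print(x$results_table)
  cat(sprintf("outputs in %s\n", x$output_dir))
  invisible(x)
}

#' Path of the bundled demo experiment configuration
#'
#' A small profile (reduced cohort, few replicates, few epochs) that runs
#' the main model grid in minutes on one CPU.
#' @return File path of the YAML config.
#' @export
demo_experiment_config <- function() {
  icusurv_extdata("demo_experiment.yaml")
}
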