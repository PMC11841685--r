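# Synthetic ICU cohort generator -----------------------------------------
#
# Emulates the statistical structure the multimodal survival analysis
# assumes: 15 SAPS-II risk factors with physiologic ranges, an integer
# SAPS-II score, 14 correlated binary radiograph findings (13 diseases +
# "normal"), token/image embeddings carrying planted label signal, and
# Cox-structured event times (Weibull baseline, log-normal administrative
# censoring calibrated to a target in-ICU mortality fraction). All times
# are hours since ICU admission.

.label_names <- c(
  "atelectasis", "cardiomegaly", "consolidation", "edema",
  "enlarged_cardiomediastinum", "fracture", "lung_lesion", "lung_opacity",
  "pleural_effusion", "pleural_other", "pneumonia", "pneumothorax",
  "support_devices", "normal"
)

#' Names of the 14 radiograph finding labels
#'
#' The 13 thorax-disease findings commonly annotated in radiology reports
#' plus the derived `normal` label (1 iff all 13 disease labels are 0).
#' @return Character vector of length 14.
#' @export
finding_labels <- function() .label_names

# Marginal disease prevalences and severity loadings for label generation.
.label_prevalence <- c(
  atelectasis = 0.25, cardiomegaly = 0.20, consolidation = 0.06,
  edema = 0.18, enlarged_cardiomediastinum = 0.04, fracture = 0.03,
  lung_lesion = 0.04, lung_opacity = 0.30, pleural_effusion = 0.25,
  pleural_other = 0.02, pneumonia = 0.10, pneumothorax = 0.04,
  support_devices = 0.35
)
.label_loading <- 0.9

# Default planted log hazard ratios on generator covariates. "saps" applies
# to the standardized SAPS-II score ((score - 36) / 12.5, fixed reference
# moments matching the factor distributions); finding names apply to the
# binary labels. Signs mirror the direction of association typically
# reported for these findings.
default_true_beta <- function() {
  c(saps = 0.9, lung_opacity = 0.45, consolidation = 0.4, edema = 0.35,
    lung_lesion = 0.35, support_devices = 0.3, pleural_effusion = 0.25,
    atelectasis = -0.2, cardiomegaly = -0.2)
}

.saps_ref <- c(mean = 36, sd = 12.5)
.age_ref <- c(mean = 67, sd = 13)
.hr_ref <- c(mean = 92, sd = 22)

#' Configuration of the synthetic cohort generator
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param target_event_fraction Proportion of subjects dying in the ICU;
#'   the censoring scale is calibrated by bisection to hit it.
#' @param true_beta Named numeric vector of planted log hazard ratios over
#'   generator covariates: `saps` (standardized SAPS-II score) and/or any
#'   of the 13 disease labels. Ignored when `risk_form = "quadratic"`.
#' @param baseline_shape,baseline_scale Weibull baseline parameters of
#'   S(t | psi) = exp(-scale * t^shape * exp(psi)), t in hours.
#' @param embedding_signal_strength Scale (>= 0) of the planted label signal
#'   in the text/image embeddings.
#' @param noise_sd Standard deviation (>= 0) of the embedding noise.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @param token_dim,image_dim Embedding dimensions (defaults 768 and 1024).
#' @param token_range Integer range of tokens per report (inclusive).
#' @param censor_sdlog Log-scale SD of the log-normal censoring time.
#' @param censor_meanlog Log-scale mean of the censoring time; `NULL`
#'   (default) means "calibrate to `target_event_fraction`".
#' @param risk_form `"linear"` (psi = covariates x true_beta) or
#'   `"quadratic"` (psi quadratic in standardized age and heart rate, used
#'   to study nonlinear-risk settings).
#' @param include_embeddings Generate embeddings? Disable for purely
#'   tabular experiments to save time and memory.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1000,
                          target_event_fraction = 0.22,
                          true_beta = default_true_beta(),
                          baseline_shape = 1.1,
                          baseline_scale = 0.002,
                          embedding_signal_strength = 1,
                          noise_sd = 1,
                          seed = 1L,
                          token_dim = 768L,
                          image_dim = 1024L,
                          token_range = c(20L, 200L),
                          censor_sdlog = 0.8,
                          censor_meanlog = NULL,
                          risk_form = c("linear", "quadratic"),
                          include_embeddings = TRUE) {
  risk_form <- match.arg(risk_form)
  check_scalar_number(n_subjects, "n_subjects")
  if (n_subjects < 2) stop_input("`n_subjects` must be >= 2")
  check_scalar_number(target_event_fraction, "target_event_fraction")
  if (target_event_fraction <= 0 || target_event_fraction >= 1) {
    stop_input("`target_event_fraction` must be in (0, 1)")
  }
  check_scalar_number(baseline_shape, "baseline_shape")
  check_scalar_number(baseline_scale, "baseline_scale")
  if (baseline_shape <= 0 || baseline_scale <= 0) {
    stop_input("Weibull baseline parameters must be positive")
  }
  check_scalar_number(embedding_signal_strength, "embedding_signal_strength")
  if (embedding_signal_strength < 0) stop_input("`embedding_signal_strength` must be >= 0")
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  check_scalar_number(seed, "seed")
  if (length(true_beta) && is.null(names(true_beta))) {
    stop_input("`true_beta` must be a named vector")
  }
  known <- c("saps", setdiff(.label_names, "normal"))
  unknown <- setdiff(names(true_beta), known)
  if (length(unknown)) {
    stop_input("unknown `true_beta` covariate(s): %s", paste(unknown, collapse = ", "))
  }
  if (token_range[1] < 1 || token_range[2] < token_range[1]) {
    stop_input("`token_range` must be an increasing positive integer range")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    target_event_fraction = target_event_fraction,
    true_beta = true_beta,
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale,
    embedding_signal_strength = embedding_signal_strength,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    token_dim = as.integer(token_dim),
    image_dim = as.integer(image_dim),
    token_range = as.integer(token_range),
    censor_sdlog = censor_sdlog,
    censor_meanlog = censor_meanlog,
    risk_form = risk_form,
    include_embeddings = isTRUE(include_embeddings)
  ), class = "cohort_config")
}

# Draw n risk-factor vectors from physiologically plausible distributions
# (uses the current RNG stream).
generate_risk_factors <- function(n) {
  data.frame(
    age = clip(18 + 77 * stats::rbeta(n, 4.5, 2.6), 18, 95),
    heart_rate = clip(stats::rnorm(n, 92, 22), 30, 190),
    systolic_bp = clip(stats::rnorm(n, 115, 26), 50, 230),
    temperature = clip(stats::rnorm(n, 37.1, 0.9), 32, 41.5),
    pao2_fio2_ratio = clip(stats::rnorm(n, 260, 110), 45, 600),
    urine_output = clip(stats::rlnorm(n, log(1400), 0.7), 10, 8000),
    bun = clip(stats::rlnorm(n, log(24), 0.6), 2, 250),
    sodium = clip(stats::rnorm(n, 138.5, 5), 110, 170),
    potassium = clip(stats::rnorm(n, 4.1, 0.6), 1.8, 9),
    bicarbonate = clip(stats::rnorm(n, 23, 4.5), 4, 50),
    bilirubin = clip(stats::rlnorm(n, log(0.9), 0.9), 0.1, 60),
    wbc = clip(stats::rlnorm(n, log(10.5), 0.45), 0.3, 150),
    gcs = sample(3:15, n, replace = TRUE,
                 prob = c(0.04, 0.02, 0.02, 0.03, 0.03, 0.04, 0.04,
                          0.05, 0.06, 0.07, 0.08, 0.12, 0.40)),
    chronic_disease = sample(.chronic_levels, n, replace = TRUE,
                             prob = c(0.87, 0.05, 0.045, 0.035)),
    admission_type = sample(.admission_levels, n, replace = TRUE,
                            prob = c(0.15, 0.62, 0.23)),
    ventilated = stats::runif(n) < 0.35,
    stringsAsFactors = FALSE
  )
}

# 13 disease labels from a Bernoulli model with a shared latent severity
# factor so comorbidities co-occur; "normal" is derived, never sampled.
generate_labels <- function(n) {
  u <- stats::rnorm(n)
  L <- matrix(0L, n, 14, dimnames = list(NULL, .label_names))
  for (j in names(.label_prevalence)) {
    eta <- stats::qlogis(.label_prevalence[[j]]) + .label_loading * u
    L[, j] <- as.integer(stats::runif(n) < stats::plogis(eta))
  }
  L[, "normal"] <- as.integer(rowSums(L[, setdiff(.label_names, "normal")]) == 0)
  L
}

# Planted linear predictor psi per subject.
cohort_linear_predictor <- function(factors, saps, labels, config) {
  if (config$risk_form == "quadratic") {
    z_age <- (factors$age - .age_ref[["mean"]]) / .age_ref[["sd"]]
    z_hr <- (factors$heart_rate - .hr_ref[["mean"]]) / .hr_ref[["sd"]]
    return(0.9 * (z_age^2 - 1) + 0.9 * (z_hr^2 - 1))
  }
  beta <- config$true_beta
  psi <- numeric(nrow(factors))
  if ("saps" %in% names(beta)) {
    psi <- psi + beta[["saps"]] * (saps - .saps_ref[["mean"]]) / .saps_ref[["sd"]]
  }
  for (j in intersect(names(beta), colnames(labels))) {
    psi <- psi + beta[[j]] * labels[, j]
  }
  psi
}

#' Simulate Cox-structured survival outcomes
#'
#' Inverts S(t | psi) = exp(-scale * t^shape * exp(psi)): with E ~ Exp(1),
#' the latent event time is T = (E / (scale * exp(psi)))^(1/shape). The
#' latent censoring time C is log-normal (administrative ICU discharge);
#' the observed time is y = min(T, C) with event indicator
#' delta = 1 iff T <= C. Uses the current RNG stream.
#'
#' @param psi Numeric vector of linear predictors (log relative hazards).
#' @param config A [cohort_config()]; supplies the Weibull baseline and
#'   censoring scale.
#' @param censor_meanlog Overrides the config's censoring log-mean (used by
#'   the calibration in [generate_cohort()]).
#' @return data.frame with columns `observed_time`, `event`,
#'   `latent_event_time`, `latent_censor_time`.
#' @export
simulate_survival <- function(psi, config, censor_meanlog = NULL) {
  check_numeric_vector(psi, "psi")
  stopifnot(inherits(config, "cohort_config"))
  meanlog <- censor_meanlog %||% config$censor_meanlog %||% log(400)
  n <- length(psi)
  E <- stats::rexp(n)
  T_lat <- (E / (config$baseline_scale * exp(psi)))^(1 / config$baseline_shape)
  C_lat <- stats::rlnorm(n, meanlog, config$censor_sdlog)
  data.frame(
    observed_time = pmin(T_lat, C_lat),
    event = as.integer(T_lat <= C_lat),
    latent_event_time = T_lat,
    latent_censor_time = C_lat
  )
}

# Calibrate the censoring log-mean by bisection on fixed uniform draws so
# the achieved event fraction hits the target at the sample level.
calibrate_censoring <- function(T_lat, U, target, sdlog) {
  frac <- function(meanlog) mean(T_lat <= stats::qlnorm(U, meanlog, sdlog))
  lo <- log(1e-3); hi <- log(1e6)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic ICU cohort
#'
#' Deterministic given the config (including its seed). Draws risk factors,
#' scores them with [saps2_score()], samples correlated finding labels,
#' plants the configured linear predictor, simulates Weibull/log-normal
#' survival with the censoring scale calibrated by bisection to the target
#' event fraction, and (optionally) generates per-subject token and image
#' embeddings carrying the label signal.
#'
#' @param config A [cohort_config()].
#' @return An object of class `icu_cohort`: list with `data` (one row per
#'   subject: id, 15 risk factors, `ventilated`, `saps_score`, 14 labels,
#'   `psi_true`, `time`, `event`, latent times), `text_pooled` (n x
#'   token_dim matrix of average-pooled token embeddings), `image_emb`
#'   (n x image_dim), `emb_seeds` (per-subject seeds the synthetic
#'   embedding provider uses to regenerate token matrices), `config`, and
#'   the calibrated `censor_meanlog`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  factors <- generate_risk_factors(n)
  saps <- saps2_score(factors)
  labels <- generate_labels(n)
  psi <- cohort_linear_predictor(factors, saps, labels, config)

  E <- stats::rexp(n)
  T_lat <- (E / (config$baseline_scale * exp(psi)))^(1 / config$baseline_shape)
  U <- stats::runif(n)
  meanlog <- config$censor_meanlog %||%
    calibrate_censoring(T_lat, U, config$target_event_fraction, config$censor_sdlog)
  C_lat <- stats::qlnorm(U, meanlog, config$censor_sdlog)

  data <- cbind(
    data.frame(subject_id = sprintf("S%05d", seq_len(n)), stringsAsFactors = FALSE),
    factors,
    data.frame(saps_score = saps),
    as.data.frame(labels),
    data.frame(
      psi_true = psi,
      time = pmin(T_lat, C_lat),
      event = as.integer(T_lat <= C_lat),
      latent_event_time = T_lat,
      latent_censor_time = C_lat
    )
  )

  emb_seeds <- vapply(seq_len(n), function(i) derive_seed(config$seed, i), integer(1))
  text_pooled <- NULL
  image_emb <- NULL
  if (config$include_embeddings) {
    proj <- embedding_projections(config)
    text_pooled <- matrix(0, n, config$token_dim)
    image_emb <- matrix(0, n, config$image_dim)
    for (i in seq_len(n)) {
      emb <- generate_embeddings(labels[i, ], config, emb_seed = emb_seeds[i],
                                 projections = proj)
      text_pooled[i, ] <- colMeans(emb$token_embeddings)
      image_emb[i, ] <- emb$image_embedding
    }
  }

  structure(list(
    data = data,
    text_pooled = text_pooled,
    image_emb = image_emb,
    emb_seeds = emb_seeds,
    config = config,
    censor_meanlog = meanlog
  ), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ICU cohort: %d subjects, %.1f%% events, seed %d%s\n",
    nrow(x$data), 100 * mean(x$data$event), x$config$seed,
    if (is.null(x$text_pooled)) " (no embeddings)" else ""
  ))
  invisible(x)
}

#' Subset (or resample) a cohort
#'
#' Index-based subsetting that keeps the tabular data and embedding rows
#' aligned. Duplicate indices are allowed, which is how bootstrap
#' resampling is implemented.
#'
#' @param cohort An `icu_cohort`.
#' @param idx Integer indices (may repeat).
#' @return An `icu_cohort` restricted to `idx`.
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "icu_cohort"))
  out <- cohort
  out$data <- cohort$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  if (!is.null(cohort$text_pooled)) out$text_pooled <- cohort$text_pooled[idx, , drop = FALSE]
  if (!is.null(cohort$image_emb)) out$image_emb <- cohort$image_emb[idx, , drop = FALSE]
  out$emb_seeds <- cohort$emb_seeds[idx]
  out
}

#' Write a cohort to plain-text files
#'
#' Serializes the tabular data to `cohort.csv`, the pooled text and image
#' embeddings to `text_embeddings.csv` / `image_embeddings.csv` (rows keyed
#' by `subject_id` in the first column), and the generator configuration
#' plus per-subject embedding seeds to `config.json` for provenance.
#'
#' @param cohort An `icu_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$data, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(cohort$text_pooled)) {
    utils::write.csv(
      data.frame(subject_id = cohort$data$subject_id, cohort$text_pooled),
      file.path(dir, "text_embeddings.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(subject_id = cohort$data$subject_id, cohort$image_emb),
      file.path(dir, "image_embeddings.csv"), row.names = FALSE)
  }
  cfg <- unclass(cohort$config)
  cfg$true_beta <- as.list(cfg$true_beta)   # keep the coefficient names
  jsonlite::write_json(
    list(config = cfg, censor_meanlog = cohort$censor_meanlog,
         emb_seeds = cohort$emb_seeds),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv` and `config.json`.
#' @return An `icu_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- cohort_config(
    n_subjects = cfg$n_subjects,
    target_event_fraction = cfg$target_event_fraction,
    true_beta = unlist(cfg$true_beta),
    baseline_shape = cfg$baseline_shape,
    baseline_scale = cfg$baseline_scale,
    embedding_signal_strength = cfg$embedding_signal_strength,
    noise_sd = cfg$noise_sd,
    seed = cfg$seed,
    token_dim = cfg$token_dim,
    image_dim = cfg$image_dim,
    token_range = cfg$token_range,
    censor_sdlog = cfg$censor_sdlog,
    censor_meanlog = cfg$censor_meanlog,
    risk_form = cfg$risk_form,
    include_embeddings = cfg$include_embeddings
  )
  data <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  text_pooled <- NULL
  image_emb <- NULL
  tpath <- file.path(dir, "text_embeddings.csv")
  if (file.exists(tpath)) {
    tp <- utils::read.csv(tpath)
    text_pooled <- unname(as.matrix(tp[, -1, drop = FALSE]))
    ip <- utils::read.csv(file.path(dir, "image_embeddings.csv"))
    image_emb <- unname(as.matrix(ip[, -1, drop = FALSE]))
  }
  structure(list(
    data = data, text_pooled = text_pooled, image_emb = image_emb,
    emb_seeds = as.integer(meta$emb_seeds), config = config,
    censor_meanlog = meta$censor_meanlog
  ), class = "icu_cohort")
}

cohort_label_matrix <- function(cohort) {
  as.matrix(cohort$data[, .label_names, drop = FALSE])
}
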