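# DeepSurv-style multimodal risk model ------------------------------------
#
# Per-modality single-layer MLP heads, elementwise averaging of the
# non-structured hidden features, concatenation with the SAPS head output
# (averaged block first, then the SAPS block -- a fixed, documented order
# so serialized weights are portable), a nonlinear risk head, and training
# by minimizing the batchwise negative Cox partial likelihood with Adam.
# When a single modality is enabled the model reduces to plain DeepSurv.

.modalities <- c("saps", "labels", "text", "gcn", "image")

#' Configuration of the fusion risk model
#'
#' @param modalities Subset of `"saps"`, `"labels"`, `"text"`
#'   (transformer-pooled report embedding), `"gcn"` (graph-encoded text),
#'   `"image"`. All non-`saps` modalities are elementwise-averaged and must
#'   share a head output dimension.
#' @param head_dims Named list modality -> c(input_dim, output_dim).
#'   Defaults: saps 15 -> 15, labels 14 -> 14, text 768 -> 32,
#'   image 1024 -> 32, gcn 56 -> 32. A dimension mismatch among averaged
#'   heads is a configuration error, never a silent projection.
#' @param risk_hidden Width of the risk head's hidden layer; `NULL` uses
#'   the fused dimension; `0` makes the risk head linear.
#' @param dropout Dropout proportion on the risk head's hidden layer,
#'   in \[0, 1) (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Training batch size (default 72); risk sets for the
#'   partial-likelihood loss are formed within each batch.
#' @param max_epochs Maximum training epochs (default 250).
#' @param patience Early-stopping patience: stop after this many epochs
#'   without validation-loss improvement (default 10).
#' @param saps_activation Apply the ReLU after the SAPS head's linear
#'   layer? Default FALSE: the fusion design concatenates the structured
#'   SAPS block as-is, and a rectified 15-unit head measurably degrades
#'   recovery of linear risk signal.
#' @param standardize Standardize inputs (except binary labels) to
#'   training-set mean 0 / SD 1? (default TRUE).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(modalities = "saps",
                          head_dims = NULL,
                          risk_hidden = NULL,
                          dropout = 0.5,
                          learning_rate = 0.001,
                          batch_size = 72L,
                          max_epochs = 250L,
                          patience = 10L,
                          saps_activation = FALSE,
                          standardize = TRUE,
                          seed = 1L) {
  if (!length(modalities) || !all(modalities %in% .modalities)) {
    stop_input("`modalities` must be a non-empty subset of: %s",
               paste(.modalities, collapse = ", "))
  }
  modalities <- .modalities[.modalities %in% modalities]  # canonical order
  defaults <- list(saps = c(15L, 15L), labels = c(14L, 14L),
                   text = c(768L, 32L), gcn = c(56L, 32L),
                   image = c(1024L, 32L))
  hd <- defaults
  for (m in names(head_dims %||% list())) hd[[m]] <- as.integer(head_dims[[m]])
  avg <- setdiff(modalities, "saps")
  if (length(avg) > 1) {
    outs <- vapply(hd[avg], `[`, integer(1), 2L)
    if (length(unique(outs)) != 1) {
      stop_input("averaged modalities must share an output dimension, got: %s",
                 paste(sprintf("%s=%d", avg, outs), collapse = ", "))
    }
  }
  check_scalar_number(dropout, "dropout")
  if (dropout < 0 || dropout >= 1) stop_input("`dropout` must be in [0, 1)")
  if (max_epochs < 0) stop_input("`max_epochs` must be >= 0")
  if (batch_size < 2) stop_input("`batch_size` must be >= 2")
  structure(list(
    modalities = modalities,
    head_dims = hd[modalities],
    risk_hidden = if (!is.null(risk_hidden)) as.integer(risk_hidden),
    dropout = dropout,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    saps_activation = isTRUE(saps_activation),
    standardize = isTRUE(standardize),
    seed = as.integer(seed)
  ), class = "fusion_config")
}

#' Early-average fusion of hidden features
#'
#' Elementwise mean of the per-modality hidden vectors, concatenated with
#' the SAPS block (averaged block first, SAPS block second). With a single
#' non-SAPS modality the "average" is that modality's hidden vector; with
#' none, the fused vector is the SAPS block alone.
#'
#' @param saps Numeric vector (the SAPS block), or `NULL`.
#' @param hidden_by_modality Named list of equal-length hidden vectors to
#'   average (may be empty).
#' @return The fused feature vector.
#' @export
fuse_features <- function(saps, hidden_by_modality = list()) {
  if (length(hidden_by_modality)) {
    lens <- lengths(hidden_by_modality)
    if (length(unique(lens)) != 1) {
      stop_input("averaged hidden vectors have unequal lengths: %s",
                 paste(lens, collapse = ", "))
    }
    avg <- Reduce(`+`, hidden_by_modality) / length(hidden_by_modality)
  } else {
    avg <- numeric(0)
  }
  c(avg, saps %||% numeric(0))
}

# Fused dimension implied by a config.
fused_dim <- function(config) {
  avg <- setdiff(config$modalities, "saps")
  d <- 0L
  if (length(avg)) d <- d + config$head_dims[[avg[1]]][2]
  if ("saps" %in% config$modalities) d <- d + config$head_dims[["saps"]][2]
  d
}

#' Initialize a fusion risk model
#'
#' He-initialized weights for the per-modality heads and risk head, seeded
#' by the config.
#'
#' @param config A [fusion_config()].
#' @return Object of class `icu_risk_model` with untrained parameters and
#'   an empty training history.
#' @export
init_risk_model <- function(config) {
  stopifnot(inherits(config, "fusion_config"))
  set.seed(config$seed)
  p <- list()
  for (m in config$modalities) {
    dims <- config$head_dims[[m]]
    p[[paste0("W_", m)]] <- matrix(stats::rnorm(dims[1] * dims[2], sd = sqrt(2 / dims[1])),
                                   dims[1], dims[2])
    p[[paste0("b_", m)]] <- numeric(dims[2])
  }
  fd <- fused_dim(config)
  h <- config$risk_hidden %||% fd
  if (h > 0) {
    p$W_risk <- matrix(stats::rnorm(fd * h, sd = sqrt(2 / fd)), fd, h)
    p$b_risk <- numeric(h)
    p$w_out <- matrix(stats::rnorm(h, sd = sqrt(2 / h)), h, 1)
  } else {
    p$w_out <- matrix(stats::rnorm(fd, sd = sqrt(2 / fd)), fd, 1)
  }
  p$b_out <- 0
  structure(list(
    parameters = p, config = config, risk_hidden = as.integer(h),
    centers = NULL, scales = NULL,
    training_history = data.frame(epoch = integer(), train_loss = numeric(),
                                  val_loss = numeric()),
    best_epoch = 0L
  ), class = "icu_risk_model")
}

#' @export
print.icu_risk_model <- function(x, ...) {
  cat(sprintf("DeepSurv-style risk model: modalities {%s}, %s\n",
              paste(x$config$modalities, collapse = ", "),
              if (nrow(x$training_history)) {
                sprintf("trained %d epochs (best %d)",
                        nrow(x$training_history), x$best_epoch)
              } else "untrained"))
  invisible(x)
}

# SAPS-II factor design matrix: the 13 continuous measurements plus the
# two categoricals encoded by their SAPS-II point values (an ordinal
# severity encoding keeping the block at exactly 15 columns).
saps_factor_matrix <- function(cohort) {
  d <- cohort$data
  tab <- saps2_point_table()$components
  chronic_pts <- unlist(tab$chronic_disease$points)[d$chronic_disease]
  adm_pts <- unlist(tab$admission_type$points)[d$admission_type]
  cbind(
    age = d$age, heart_rate = d$heart_rate, systolic_bp = d$systolic_bp,
    temperature = d$temperature, pao2_fio2_ratio = d$pao2_fio2_ratio,
    urine_output = d$urine_output, bun = d$bun, sodium = d$sodium,
    potassium = d$potassium, bicarbonate = d$bicarbonate,
    bilirubin = d$bilirubin, wbc = d$wbc, gcs = d$gcs,
    chronic_disease = unname(chronic_pts), admission_type = unname(adm_pts)
  )
}

#' Per-modality feature matrices for a cohort
#'
#' @param cohort An `icu_cohort`.
#' @param modalities Subset of the model modalities.
#' @param gcn A [gcn_params()] for the `gcn` modality (defaults used if
#'   `NULL`).
#' @return Named list of n x input_dim matrices.
#' @export
feature_matrices <- function(cohort, modalities, gcn = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"))
  out <- list()
  for (m in modalities) {
    out[[m]] <- switch(m,
      saps = saps_factor_matrix(cohort),
      labels = cohort_label_matrix(cohort),
      text = {
        if (is.null(cohort$text_pooled)) stop_input("cohort carries no text embeddings")
        cohort$text_pooled
      },
      image = {
        if (is.null(cohort$image_emb)) stop_input("cohort carries no image embeddings")
        cohort$image_emb
      },
      gcn = encode_cohort_text(cohort, "gcn", params = gcn)
    )
  }
  out
}

standardize_features <- function(feats, centers = NULL, scales = NULL) {
  if (is.null(centers)) {
    centers <- lapply(feats, colMeans)
    scales <- lapply(feats, function(X) {
      s <- apply(X, 2, stats::sd)
      s[s < 1e-12] <- 1
      s
    })
  }
  out <- feats
  for (m in names(feats)) {
    if (m == "labels") next  # binary indicators stay on their own scale
    out[[m]] <- sweep(sweep(feats[[m]], 2, centers[[m]]), 2, scales[[m]], `/`)
  }
  list(feats = out, centers = centers, scales = scales)
}

relu <- function(X) pmax(X, 0)

# Forward pass over a batch. feats: named list of n x in matrices.
nn_forward <- function(p, feats, config, risk_hidden, drop_mask = NULL) {
  H <- list(); pre <- list()
  for (m in config$modalities) {
    z <- feats[[m]] %*% p[[paste0("W_", m)]] +
      matrix(p[[paste0("b_", m)]], nrow(feats[[m]]), ncol(p[[paste0("W_", m)]]),
             byrow = TRUE)
    pre[[m]] <- z
    H[[m]] <- if (m == "saps" && !config$saps_activation) z else relu(z)
  }
  avg_mods <- setdiff(config$modalities, "saps")
  blocks <- list()
  if (length(avg_mods)) {
    blocks$avg <- Reduce(`+`, H[avg_mods]) / length(avg_mods)
  }
  if ("saps" %in% config$modalities) blocks$saps <- H[["saps"]]
  F_mat <- do.call(cbind, blocks)
  if (risk_hidden > 0) {
    U_pre <- F_mat %*% p$W_risk + matrix(p$b_risk, nrow(F_mat), risk_hidden, byrow = TRUE)
    U <- relu(U_pre)
    Ud <- if (is.null(drop_mask)) U else U * drop_mask
    psi <- drop(Ud %*% p$w_out) + p$b_out
  } else {
    U_pre <- NULL; U <- NULL; Ud <- NULL
    psi <- drop(F_mat %*% p$w_out) + p$b_out
  }
  list(psi = psi, H = H, pre = pre, F_mat = F_mat,
       U_pre = U_pre, Ud = Ud, n_avg = length(avg_mods))
}

# Backward pass: gradients of the batch loss in all parameters, given
# dpsi = d(loss)/d(psi).
nn_backward <- function(p, feats, config, risk_hidden, fw, dpsi, drop_mask = NULL) {
  g <- list()
  dpsi <- matrix(dpsi, ncol = 1)
  if (risk_hidden > 0) {
    g$w_out <- crossprod(fw$Ud, dpsi)
    g$b_out <- sum(dpsi)
    dUd <- dpsi %*% t(p$w_out)
    dU <- if (is.null(drop_mask)) dUd else dUd * drop_mask
    dUpre <- dU * (fw$U_pre > 0)
    g$W_risk <- crossprod(fw$F_mat, dUpre)
    g$b_risk <- colSums(dUpre)
    dF <- dUpre %*% t(p$W_risk)
  } else {
    g$w_out <- crossprod(fw$F_mat, dpsi)
    g$b_out <- sum(dpsi)
    dF <- dpsi %*% t(p$w_out)
  }
  avg_mods <- setdiff(config$modalities, "saps")
  col <- 0L
  if (length(avg_mods)) {
    da <- ncol(fw$H[[avg_mods[1]]])
    davg <- dF[, seq_len(da), drop = FALSE] / length(avg_mods)
    col <- da
    for (m in avg_mods) {
      dpre <- davg * (fw$pre[[m]] > 0)
      g[[paste0("W_", m)]] <- crossprod(feats[[m]], dpre)
      g[[paste0("b_", m)]] <- colSums(dpre)
    }
  }
  if ("saps" %in% config$modalities) {
    ds <- dF[, (col + 1):ncol(dF), drop = FALSE]
    dpre <- if (config$saps_activation) ds * (fw$pre[["saps"]] > 0) else ds
    g$W_saps <- crossprod(feats[["saps"]], dpre)
    g$b_saps <- colSums(dpre)
  }
  g
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0L)
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# Shuffled batches, each guaranteed at least one event (events are swapped
# in from event-rich batches when needed; batch construction uses the
# current RNG stream).
make_batches <- function(n, batch_size, event) {
  perm <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) perm[s:min(s + batch_size - 1, n)])
  if (length(batches) > 1 && length(batches[[length(batches)]]) < 2) {
    k <- length(batches)
    batches[[k - 1]] <- c(batches[[k - 1]], batches[[k]])
    batches[[k]] <- NULL
  }
  ev_count <- vapply(batches, function(b) sum(event[b]), numeric(1))
  need <- which(ev_count == 0)
  for (b in need) {
    donor <- which.max(ev_count)
    if (ev_count[donor] < 2) next  # cannot fix; caller validates total events
    di <- batches[[donor]][which(event[batches[[donor]]] == 1)[1]]
    ci <- batches[[b]][which(event[batches[[b]]] == 0)[1]]
    batches[[donor]][batches[[donor]] == di] <- ci
    batches[[b]][batches[[b]] == ci] <- di
    ev_count[donor] <- ev_count[donor] - 1
    ev_count[b] <- 1
  }
  batches
}

# Mean negative log partial likelihood per event, evaluation mode.
eval_loss <- function(p, feats, config, risk_hidden, time, event) {
  psi <- nn_forward(p, feats, config, risk_hidden)$psi
  -cox_partial_log_likelihood(psi, time, event) / sum(event)
}

#' Train the fusion risk model
#'
#' Minimizes the batchwise negative Cox partial likelihood (Breslow ties,
#' normalized per event) with Adam, shuffling each epoch with batches that
#' always contain at least one event. After every epoch the full training
#' and validation losses are recorded in evaluation mode (dropout off);
#' training stops early when the validation loss has not improved for
#' `patience` epochs, and the weights from the best validation epoch are
#' restored. Fully deterministic given the config seed.
#'
#' @param cohort_train,cohort_val Disjoint `icu_cohort` splits, each with
#'   at least one event.
#' @param config A [fusion_config()].
#' @param gcn A [gcn_params()] when the `gcn` modality is enabled.
#' @return A trained `icu_risk_model` (parameters, config, standardization
#'   constants, per-epoch history, `best_epoch`).
#' @export
train_risk_model <- function(cohort_train, cohort_val, config, gcn = NULL) {
  stopifnot(inherits(cohort_train, "icu_cohort"), inherits(cohort_val, "icu_cohort"))
  if (sum(cohort_train$data$event) == 0) stop_input("training cohort has no events")
  if (sum(cohort_val$data$event) == 0) stop_input("validation cohort has no events")

  feats_tr <- feature_matrices(cohort_train, config$modalities, gcn = gcn)
  feats_va <- feature_matrices(cohort_val, config$modalities, gcn = gcn)
  if (config$standardize) {
    st <- standardize_features(feats_tr)
    feats_tr <- st$feats
    feats_va <- standardize_features(feats_va, st$centers, st$scales)$feats
  } else {
    st <- list(centers = NULL, scales = NULL)
  }

  model <- init_risk_model(config)        # seeds the RNG stream as well
  p <- model$parameters
  h <- model$risk_hidden
  time_tr <- cohort_train$data$time; event_tr <- cohort_train$data$event
  time_va <- cohort_val$data$time; event_va <- cohort_val$data$event
  n <- nrow(cohort_train$data)

  if (config$max_epochs == 0) {
    model$centers <- st$centers; model$scales <- st$scales
    return(model)
  }

  adam <- adam_init(p)
  best <- list(loss = Inf, p = p, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_batches(n, config$batch_size, event_tr)
    for (b in batches) {
      if (sum(event_tr[b]) == 0) next
      fb <- lapply(feats_tr, function(X) X[b, , drop = FALSE])
      mask <- NULL
      if (h > 0 && config$dropout > 0) {
        mask <- matrix((stats::runif(length(b) * h) >= config$dropout) /
                         (1 - config$dropout), length(b), h)
      }
      fw <- nn_forward(p, fb, config, h, drop_mask = mask)
      dpsi <- -cox_pl_gradient(fw$psi, time_tr[b], event_tr[b]) / sum(event_tr[b])
      g <- nn_backward(p, fb, config, h, fw, dpsi, drop_mask = mask)
      upd <- adam_step(p, g, adam, config$learning_rate)
      p <- upd$p; adam <- upd$state
    }
    tr_loss <- eval_loss(p, feats_tr, config, h, time_tr, event_tr)
    va_loss <- eval_loss(p, feats_va, config, h, time_va, event_va)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss, val_loss = va_loss)
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, p = p, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$parameters <- best$p
  model$best_epoch <- best$epoch
  model$training_history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$centers <- st$centers
  model$scales <- st$scales
  model
}

#' Risk scores from a trained model
#'
#' Deterministic evaluation-mode forward pass (dropout off): returns the
#' log relative hazard psi for each subject of the cohort.
#'
#' @param model An `icu_risk_model`.
#' @param cohort An `icu_cohort` carrying every enabled modality.
#' @param gcn A [gcn_params()] when the `gcn` modality is enabled (must be
#'   the one used in training).
#' @return Numeric vector of risk scores.
#' @export
risk_forward <- function(model, cohort, gcn = NULL) {
  stopifnot(inherits(model, "icu_risk_model"))
  feats <- feature_matrices(cohort, model$config$modalities, gcn = gcn)
  if (model$config$standardize && !is.null(model$centers)) {
    feats <- standardize_features(feats, model$centers, model$scales)$feats
  }
  nn_forward(model$parameters, feats, model$config, model$risk_hidden)$psi
}

#' Predicted survival curves
#'
#' Composes [risk_forward()] with [survival_function()]: subject-specific
#' curves S(t | x) = S0(t)^exp(psi(x)) from a baseline estimated on the
#' training split, enabling patient-vs-patient survival-probability
#' comparisons at a common time.
#'
#' @param model An `icu_risk_model`.
#' @param baseline An `icu_baseline` (from the training data).
#' @param cohort Subjects to predict for.
#' @param times Evaluation times (defaults to the baseline's event times).
#' @param gcn Optional [gcn_params()].
#' @return data.frame with columns `subject_id`, `time`, `surv`.
#' @export
predict_survival <- function(model, baseline, cohort, times = NULL, gcn = NULL) {
  psi <- risk_forward(model, cohort, gcn = gcn)
  ids <- cohort$data$subject_id
  out <- lapply(seq_along(psi), function(i) {
    sf <- survival_function(baseline, psi[i], times = times)
    data.frame(subject_id = ids[i], time = sf$time, surv = sf$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Save / load a trained risk model
#'
#' The checkpoint is a single JSON file holding the flattened weights, the
#' fusion configuration, standardization constants, and the training
#' history.
#'
#' @param model An `icu_risk_model`.
#' @param path Checkpoint path (`.json`).
#' @return `write_risk_model` returns `path` invisibly; `read_risk_model`
#'   returns the model.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "icu_risk_model"))
  payload <- list(
    parameters = lapply(model$parameters, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else list(data = x)
    }),
    config = unclass(model$config),
    risk_hidden = model$risk_hidden,
    centers = model$centers, scales = model$scales,
    training_history = model$training_history,
    best_epoch = model$best_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  config <- fusion_config(
    modalities = cfg$modalities, head_dims = cfg$head_dims,
    risk_hidden = cfg$risk_hidden, dropout = cfg$dropout,
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, patience = cfg$patience,
    saps_activation = cfg$saps_activation, standardize = cfg$standardize,
    seed = cfg$seed
  )
  p <- lapply(x$parameters, function(e) {
    if (!is.null(e$dim)) matrix(e$data, e$dim[1], e$dim[2]) else e$data
  })
  structure(list(
    parameters = p, config = config, risk_hidden = x$risk_hidden,
    centers = x$centers, scales = x$scales,
    training_history = as.data.frame(x$training_history),
    best_epoch = x$best_epoch
  ), class = "icu_risk_model")
}
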