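test_that("early average fusion has its closed forms", {
  saps <- rnorm(15)
  h <- rnorm(32)
  expect_equal(fuse_features(saps, list(text = h, image = h)), c(h, saps))
  expect_equal(fuse_features(saps, list(text = h)), c(h, saps))
  expect_equal(fuse_features(saps, list()), saps)
  # elementwise mean against an explicit loop
  t1 <- rnorm(32); i1 <- rnorm(32)
  fused <- fuse_features(saps, list(text = t1, image = i1))
  want <- numeric(32)
  for (j in 1:32) want[j] <- (t1[j] + i1[j]) / 2
  expect_equal(fused[1:32], want, tolerance = 1e-12)
  expect_length(fused, 47)
  expect_error(fuse_features(saps, list(a = rnorm(3), b = rnorm(4))),
               "unequal lengths")
})

test_that("averaged heads with mismatched output dims are a config error", {
  expect_error(fusion_config(c("saps", "text", "image"),
                             head_dims = list(text = c(768, 32),
                                              image = c(1024, 16))),
               "share an output dimension")
  expect_error(fusion_config("saps", dropout = 1), "dropout")
  expect_error(fusion_config(c("saps", "sound")), "subset")
})

make_tiny_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed,
                                token_dim = 12, image_dim = 10,
                                token_range = c(5, 15), ...))
}

test_that("risk_forward is a deterministic evaluation-mode pass", {
  co <- make_tiny_cohort(seed = 2)
  cfg <- fusion_config(c("saps", "text", "image"),
                       head_dims = list(text = c(12, 8), image = c(10, 8)),
                       max_epochs = 0, seed = 3)
  model <- init_risk_model(cfg)
  model$centers <- NULL                      # untrained: raw features
  model$config$standardize <- FALSE
  r1 <- risk_forward(model, co)
  r2 <- risk_forward(model, co)
  expect_identical(r1, r2)
  expect_true(all(is.finite(r1)))
  # zero network gives psi = 0 for every record
  zero <- model
  zero$parameters <- lapply(zero$parameters, function(x) x * 0)
  expect_equal(risk_forward(zero, co), rep(0, nrow(co$data)))
})

test_that("a linear saps-only head reduces to a dot product", {
  co <- make_tiny_cohort(seed = 4)
  cfg <- fusion_config("saps", risk_hidden = 0, saps_activation = FALSE,
                       standardize = FALSE, max_epochs = 0, seed = 5)
  model <- init_risk_model(cfg)
  w <- rnorm(15)
  model$parameters$W_saps <- diag(15)
  model$parameters$b_saps <- numeric(15)
  model$parameters$w_out <- matrix(w, 15, 1)
  model$parameters$b_out <- 0
  X <- feature_matrices(co, "saps")$saps
  want <- vapply(seq_len(nrow(X)), function(i) sum(w * X[i, ]), numeric(1))
  expect_equal(risk_forward(model, co), want, tolerance = 1e-10)
})

test_that("internal batch fusion equals the exported fuse_features", {
  co <- make_tiny_cohort(seed = 6)
  cfg <- fusion_config(c("saps", "text", "image"),
                       head_dims = list(text = c(12, 8), image = c(10, 8)),
                       max_epochs = 0, seed = 7, standardize = FALSE)
  model <- init_risk_model(cfg)
  feats <- feature_matrices(co, cfg$modalities)
  fw <- icusurv:::nn_forward(model$parameters, feats, cfg, model$risk_hidden)
  i <- 5
  heads <- lapply(c("text", "image"), function(m) fw$H[[m]][i, ])
  names(heads) <- c("text", "image")
  expect_equal(unname(fw$F_mat[i, ]),
               unname(fuse_features(fw$H[["saps"]][i, ], heads)),
               tolerance = 1e-12)
})

test_that("training decreases the loss and restores the best epoch", {
  co <- make_tiny_cohort(n = 200, seed = 8)
  sp <- three_way_split(200, 9)
  cfg <- fusion_config("saps", max_epochs = 25, patience = 25,
                       learning_rate = 0.002, seed = 10)
  m <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val), cfg)
  h <- m$training_history
  expect_gt(nrow(h), 0)
  expect_lt(h$train_loss[m$best_epoch], h$train_loss[1])
  expect_equal(m$best_epoch, h$epoch[which.min(h$val_loss)])
  # max_epochs = 0 returns the freshly initialized model
  m0 <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val),
                         fusion_config("saps", max_epochs = 0, seed = 10))
  expect_identical(nrow(m0$training_history), 0L)
  expect_equal(m0$best_epoch, 0L)
})

test_that("training is reproducible given the config seed", {
  co <- make_tiny_cohort(n = 150, seed = 11)
  sp <- three_way_split(150, 12)
  cfg <- fusion_config("saps", max_epochs = 8, patience = 8, seed = 13)
  m1 <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val), cfg)
  m2 <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val), cfg)
  expect_identical(m1$parameters, m2$parameters)
  expect_identical(m1$training_history, m2$training_history)
})

test_that("cohorts without events are rejected", {
  co <- make_tiny_cohort(n = 60, seed = 14)
  dead <- co
  dead$data$event <- 0L
  cfg <- fusion_config("saps", max_epochs = 2, seed = 15)
  expect_error(train_risk_model(dead, co, cfg), "no events")
  expect_error(train_risk_model(co, dead, cfg), "no events")
})

test_that("saps-only deepsurv approaches the linear Cox fit on linear risk", {
  co <- generate_cohort(cohort_config(n_subjects = 1500, seed = 16,
                                      include_embeddings = FALSE))
  sp <- three_way_split(1500, 17)
  te <- cohort_subset(co, sp$test)
  cfg <- fusion_config("saps", max_epochs = 60, patience = 10,
                       learning_rate = 0.003, seed = 18)
  m <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val), cfg)
  deep_c <- c_index(te$data$time, te$data$event, risk_forward(m, te))$value
  trv <- cohort_subset(co, c(sp$train, sp$val))
  X <- feature_matrices(trv, "saps")$saps
  Xte <- feature_matrices(te, "saps")$saps
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  fit <- fit_linear_cox(sweep(sweep(X, 2, ctr), 2, scl, "/"),
                        trv$data$time, trv$data$event)
  rk <- drop(sweep(sweep(Xte, 2, ctr), 2, scl, "/") %*% fit$coefficients)
  cox_c <- c_index(te$data$time, te$data$event, rk)$value
  expect_gt(deep_c, cox_c - 0.02)
})

test_that("predicted survival composes risk_forward with the baseline", {
  co <- make_tiny_cohort(n = 100, seed = 19)
  cfg <- fusion_config("saps", max_epochs = 0, seed = 20, standardize = FALSE)
  model <- init_risk_model(cfg)
  # keep the untrained scores in a physiological range for this check
  model$parameters <- lapply(model$parameters, function(x) x * 0.01)
  bl <- breslow_baseline(risk_forward(model, co), co$data$time, co$data$event)
  two <- cohort_subset(co, c(3, 9))
  pred <- predict_survival(model, bl, two, times = c(24, 72, 168))
  psi <- risk_forward(model, two)
  manual <- survival_function(bl, psi[1], times = c(24, 72, 168))
  expect_equal(pred$surv[pred$subject_id == two$data$subject_id[1]],
               manual$surv, tolerance = 1e-12)
  # lower risk implies pointwise higher survival
  lo <- which.min(psi); hi <- which.max(psi)
  s_lo <- pred$surv[pred$subject_id == two$data$subject_id[lo]]
  s_hi <- pred$surv[pred$subject_id == two$data$subject_id[hi]]
  expect_true(all(s_lo >= s_hi))
})

test_that("model checkpoints round-trip through JSON", {
  co <- make_tiny_cohort(n = 150, seed = 21)
  sp <- three_way_split(150, 22)
  cfg <- fusion_config("saps", max_epochs = 4, patience = 4, seed = 23)
  m <- train_risk_model(cohort_subset(co, sp$train), cohort_subset(co, sp$val), cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  back <- read_risk_model(path)
  expect_equal(risk_forward(back, co), risk_forward(m, co), tolerance = 1e-12)
  expect_equal(back$best_epoch, m$best_epoch)
})
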