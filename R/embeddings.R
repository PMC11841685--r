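# Synthetic embedding provider --------------------------------------------
#
# Stands in for pretrained text/image feature extractors: a fixed seeded
# Gaussian projection of the 14 finding labels defines the planted signal,
# to which token-level (text) and vector-level (image) Gaussian noise is
# added. Token matrices are regenerable per subject from a stored seed, so
# a cohort only has to keep the pooled text vector in memory.

# Fixed label-to-embedding projections, a pure function of the config seed.
embedding_projections <- function(config) {
  set.seed(derive_seed(config$seed, 424243L))
  list(
    text = matrix(stats::rnorm(config$token_dim * 14), config$token_dim, 14),
    image = matrix(stats::rnorm(config$image_dim * 14), config$image_dim, 14)
  )
}

#' Generate synthetic token and image embeddings for one subject
#'
#' The token matrix has `m` rows (m drawn uniformly from the configured
#' token range), each row equal to `P_text %*% labels * signal_strength`
#' plus independent Gaussian noise, so its column mean is the planted
#' signal plus noise of standard deviation `noise_sd / sqrt(m)`. The image
#' embedding is `P_img %*% labels * signal_strength` plus independent
#' noise. Deterministic given `emb_seed`.
#'
#' @param labels Binary vector of the 14 finding labels.
#' @param config A [cohort_config()].
#' @param emb_seed Integer seed for this subject's draws.
#' @param projections Optional precomputed [embedding_projections()]
#'   (recomputed from the config otherwise).
#' @return list with `token_embeddings` (m x token_dim matrix) and
#'   `image_embedding` (length image_dim vector).
#' @export
generate_embeddings <- function(labels, config, emb_seed = config$seed,
                                projections = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- as.numeric(labels)
  if (length(labels) != 14 || !all(labels %in% c(0, 1))) {
    stop_input("`labels` must be a binary vector of length 14")
  }
  if (config$embedding_signal_strength < 0) {
    stop_input("`embedding_signal_strength` must be >= 0")
  }
  proj <- projections %||% embedding_projections(config)
  s <- config$embedding_signal_strength
  text_signal <- drop(proj$text %*% labels) * s
  image_signal <- drop(proj$image %*% labels) * s
  set.seed(emb_seed)
  m <- if (config$token_range[1] == config$token_range[2]) {
    config$token_range[1]
  } else {
    sample(config$token_range[1]:config$token_range[2], 1L)
  }
  tokens <- matrix(text_signal, m, config$token_dim, byrow = TRUE) +
    matrix(stats::rnorm(m * config$token_dim, sd = config$noise_sd),
           m, config$token_dim)
  image <- image_signal +
    stats::rnorm(config$image_dim, sd = config$noise_sd)
  list(token_embeddings = tokens, image_embedding = image)
}

#' Regenerate one subject's token-embedding matrix
#'
#' Token matrices are not stored with the cohort; the synthetic embedding
#' provider regenerates them exactly from the subject's stored seed.
#'
#' @param cohort An `icu_cohort`.
#' @param i Subject index.
#' @return m x token_dim matrix.
#' @export
token_embeddings <- function(cohort, i) {
  stopifnot(inherits(cohort, "icu_cohort"))
  labels <- as.numeric(cohort$data[i, .label_names])
  generate_embeddings(labels, cohort$config, emb_seed = cohort$emb_seeds[i])$token_embeddings
}

#' Embedding provider interface
#'
#' Returns an object with two functions, `tokens(i)` and `image(i)`, that
#' supply a subject's token-embedding matrix and image-embedding vector.
#' `type = "synthetic"` (default) regenerates token matrices from the
#' cohort's per-subject seeds; `type = "file"` serves the arrays stored
#' with the cohort (pooled text vectors, since token matrices are not
#' serialized). Extraction from real reports/images with pretrained
#' encoders is a third-party plug-in implementing the same two functions.
#'
#' @param cohort An `icu_cohort`.
#' @param type `"synthetic"` or `"file"`.
#' @return list with functions `tokens` and `image`.
#' @export
embedding_provider <- function(cohort, type = c("synthetic", "file")) {
  type <- match.arg(type)
  stopifnot(inherits(cohort, "icu_cohort"))
  if (type == "synthetic") {
    list(
      tokens = function(i) token_embeddings(cohort, i),
      image = function(i) {
        labels <- as.numeric(cohort$data[i, .label_names])
        generate_embeddings(labels, cohort$config,
                            emb_seed = cohort$emb_seeds[i])$image_embedding
      }
    )
  } else {
    if (is.null(cohort$text_pooled)) {
      stop_input("cohort carries no stored embeddings")
    }
    list(
      tokens = function(i) cohort$text_pooled[i, , drop = FALSE],
      image = function(i) cohort$image_emb[i, ]
    )
  }
}
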