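# Independent oracles used across the suite. Each one re-derives the
# quantity it checks by direct enumeration or elementwise loops, never by
# calling the implementation under test.

# Exhaustive O(n^2) pairwise concordance enumeration: comparable pairs are
# those where the shorter observed time belongs to an event subject;
# credit 1 when that subject's risk is strictly higher, 0.5 on ties.
brute_c_index <- function(time, event, risk) {
  conc <- 0
  comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[j] == 1 && time[j] < time[i]) {
        comp <- comp + 1
        if (risk[j] > risk[i]) conc <- conc + 1
        else if (risk[j] == risk[i]) conc <- conc + 0.5
      }
    }
  }
  list(value = conc / comp, concordant = conc, comparable = comp)
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Direct sliding-window 1-D convolution + position mean: one output row
# per channel c, H0[c, ] = mean over positions p of sum_j w[c, j] * X[p + j - 1, ].
conv_oracle <- function(tokens, W, bias = NULL) {
  k <- ncol(W)
  m <- nrow(tokens)
  P <- m - k + 1
  N <- nrow(W)
  H <- matrix(0, N, ncol(tokens))
  for (cch in seq_len(N)) {
    acc <- matrix(0, P, ncol(tokens))
    for (p in seq_len(P)) {
      for (j in seq_len(k)) {
        acc[p, ] <- acc[p, ] + W[cch, j] * tokens[p + j - 1, ]
      }
    }
    H[cch, ] <- colMeans(acc)
    if (!is.null(bias)) H[cch, ] <- H[cch, ] + bias[cch]
  }
  H
}

# A mid-severity risk-factor vector whose SAPS-II total (69) was scored by
# hand against the category point table.
midrange_factors <- function() {
  list(age = 65, heart_rate = 125, systolic_bp = 85, temperature = 39.5,
       pao2_fio2_ratio = 150, urine_output = 700, bun = 30, sodium = 126,
       potassium = 5.2, bicarbonate = 17, bilirubin = 4.5, wbc = 25,
       gcs = 10, chronic_disease = "none", admission_type = "medical",
       ventilated = TRUE)
}

healthy_factors <- function() {
  list(age = 30, heart_rate = 80, systolic_bp = 120, temperature = 37,
       pao2_fio2_ratio = 450, urine_output = 1500, bun = 15, sodium = 140,
       potassium = 4.2, bicarbonate = 24, bilirubin = 0.7, wbc = 8,
       gcs = 15, chronic_disease = "none",
       admission_type = "scheduled_surgical", ventilated = FALSE)
}

# Random censored survival instance for property loops.
random_instance <- function(n, seed, tie_times = TRUE, tie_risks = TRUE) {
  set.seed(seed)
  time <- if (tie_times) sample(1:max(3, n %/% 2), n, replace = TRUE) else
    stats::rexp(n)
  event <- stats::rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1
  risk <- if (tie_risks) sample(seq(-2, 2, by = 0.5), n, replace = TRUE) else
    stats::rnorm(n)
  list(time = as.numeric(time), event = event, risk = risk)
}

# Small standard splits used by model tests.
three_way_split <- function(n, seed, fractions = c(0.7, 0.1, 0.2)) {
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = perm[seq_len(n_tr)],
       val = perm[n_tr + seq_len(n_va)],
       test = perm[(n_tr + n_va + 1):n])
}
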