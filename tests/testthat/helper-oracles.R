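# Independent, deliberately naive reference implementations used to
# cross-check the package. Kept loop-level and separate from the package
# code paths on purpose.

# Fleiss' 1971 kappa, transcribed term by term from the definitional
# formulas: P_i = [sum_j n_ij (n_ij - 1)] / [n (n - 1)], p_j = sum_i n_ij /
# (N n), kappa = (Pbar - Pe) / (1 - Pe).
oracle_fleiss <- function(m) {
  N <- nrow(m)
  n <- sum(m[1, ])
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(ncol(m))) {
      s <- s + m[i, j] * (m[i, j] - 1)
    }
    P_i[i] <- s / (n * (n - 1))
  }
  p_j <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    p_j[j] <- sum(m[, j]) / (N * n)
  }
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

# random two-category rating matrix, guaranteed non-degenerate
random_rating_matrix <- function(max_items = 12, raters = 2:4) {
  repeat {
    N <- sample(1:max_items, 1)
    n <- sample(raters, 1)
    k <- rbinom(N, n, runif(1, 0.2, 0.8))
    m <- cbind(k, n - k)
    if (sum(k) > 0 && sum(k) < N * n) return(m)
  }
}

# precision / recall / F1 recomputed from a raw outcome vector by counting
oracle_metrics <- function(outcomes) {
  tp <- sum(outcomes == "tp"); fp <- sum(outcomes == "fp")
  tn <- sum(outcomes == "tn"); fn <- sum(outcomes == "fn")
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else if (tp == 0 && (fp + fn) > 0) 0 else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = prec, recall = rec, f1 = f1)
}
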