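# Random-sample generators shared across tests. Times are drawn on a coarse
# grid so ties occur routinely; tie-free variants draw continuous times.

random_surv <- function(n, K = 1L, cens_prob = 0.3, tied = TRUE) {
  time <- if (tied) sample(1:8, n, replace = TRUE) else round(rexp(n), 6) + 1e-6
  status <- ifelse(runif(n) < cens_prob, 0L, sample.int(K, n, replace = TRUE))
  # guarantee validity: at least one subject, any status layout is legal
  surv_data(time, status, n_causes = K)
}

random_uncensored <- function(n, K = 1L, tied = TRUE) {
  random_surv(n, K, cens_prob = 0, tied = tied)
}

random_binary <- function(n, p = 0.4) {
  y <- rbinom(n, 1L, p)
  if (all(y == y[1L])) y[1L] <- 1L - y[1L]  # both classes for AUC tests
  binary_data(y)
}

# Brute-force empirical survival P(T > t), the oracle for uncensored KM.
empirical_survival <- function(time, t) {
  vapply(t, function(u) mean(time > u), numeric(1))
}

subset_sample_for_test <- function(d, idx) {
  surv_data(d$time[idx], d$status[idx], n_causes = d$n_causes)
}

subset_sample_pred <- function(d, idx) {
  surv_data(d$time[idx], d$status[idx], n_causes = d$n_causes,
            predictors = d$predictors[idx, , drop = FALSE])
}

# horizon usable at all (metric functions enforce G > 0 themselves)
brier_allows <- function(d, h) h <= max(d$time)

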