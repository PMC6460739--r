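test_that("binary Brier score matches closed forms", {
  expect_equal(brier_binary(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(brier_binary(c(1, 0), c(1, 0)), 0)
  # constant prevalence prediction scores p(1-p)
  expect_equal(brier_binary(c(1, 1, 0, 0, 0), rep(0.4, 5)), 0.24)
  expect_error(brier_binary(c(1, 0), c(0.5, 0.5, 0.5)), "length")
  expect_error(brier_binary(c(1, 0), c(1.2, 0)), "\\[0, 1\\]")
})

test_that("null binary Brier equals p(1-p) at the sample prevalence", {
  set.seed(201)
  for (rep in 1:20) {
    b <- random_binary(sample(5:100, 1), p = runif(1, 0.1, 0.9))
    p <- mean(b$outcome)
    expect_equal(brier_binary(b, null_risk(b)), p * (1 - p),
                 tolerance = 1e-14)
  }
})

test_that("IPCW Brier score matches hand computation under censoring", {
  d <- surv_data(c(1, 3), c(1, 0))
  # subject 1: event before t=2, weight 1/G(1-) = 1, Y = 1, R = 1
  # subject 2: at risk at t=2, weight 1/G(2) = 1, Y = 0, R = 0
  expect_equal(brier_ipcw(d, c(1, 0), horizon = 2), 0)
  # subjects censored before the horizon carry zero weight
  d2 <- surv_data(c(1, 2, 4), c(0, 1, 0))
  G <- reverse_kaplan_meier(d2)
  w1 <- 1 / eval_step(G, 2, "left")   # event subject, G(2-) = G(1) = 2/3
  w2 <- 1 / eval_step(G, 3)           # at-risk subject
  expect_equal(brier_ipcw(d2, c(0, 0.5, 0.5), horizon = 3),
               (w1 * (1 - 0.5)^2 + w2 * (0 - 0.5)^2) / 3)
})

test_that("IPCW Brier rejects horizons beyond the identifiable range", {
  d <- surv_data(c(1, 2), c(0, 0))
  expect_error(brier_ipcw(d, c(0.5, 0.5), horizon = 3), "identifiable")
  # all subjects censored before the horizon: G hits zero
  expect_error(brier_ipcw(d, c(0.5, 0.5), horizon = 2), "identifiable")
  expect_error(brier_ipcw(surv_data(1, 1), 0.5, horizon = -1), "positive")
})

test_that("IPCW Brier equals the binary Brier on uncensored data", {
  set.seed(202)
  for (rep in 1:200) {
    K <- sample(1:2, 1)
    d <- random_uncensored(n = sample(3:40, 1), K = K)
    cause <- sample.int(K, 1)
    risk <- runif(length(d$time))
    horizon <- runif(1, min(d$time) / 2, max(d$time))
    y <- as.numeric(d$time <= horizon & d$status == cause)
    expect_identical(brier_ipcw(d, risk, horizon, cause),
                     brier_binary(y, risk))
  }
})

test_that("Brier is invariant to subject order and non-target relabeling", {
  set.seed(203)
  d <- random_surv(50, K = 3L)
  risk <- runif(50)
  h <- max(d$time[d$status == 0]) * 0.9
  b <- brier_ipcw(d, risk, h, cause = 1)
  perm <- sample(50)
  expect_equal(brier_ipcw(subset_sample_for_test(d, perm), risk[perm], h, 1),
               b, tolerance = 1e-14)
  swapped <- ifelse(d$status == 2L, 3L, ifelse(d$status == 3L, 2L, d$status))
  expect_equal(brier_ipcw(surv_data(d$time, swapped, n_causes = 3), risk, h, 1),
               b, tolerance = 1e-14)
})

test_that("null risks are the prevalence / KM risk / AJ incidence", {
  expect_equal(null_risk(binary_data(c(1, 1, 0, 0, 0))), rep(0.4, 5))
  # survival, no censoring, horizon past all events
  d <- surv_data(c(1, 2, 3), c(1, 1, 1))
  expect_equal(null_risk(d, horizon = 5), rep(1, 3))
  # single-cause competing risks reduces to the survival null
  d2 <- surv_data(d$time, d$status, n_causes = 1)
  expect_equal(null_risk(d2, horizon = 2),
               rep(1 - eval_step(kaplan_meier(d2), 2), 3))
  expect_error(null_risk(d, horizon = NULL), "horizon")
})

test_that("IPA rescales the Brier score against the null model", {
  expect_equal(ipa(0.24, 0.24), 0)
  expect_equal(ipa(0, 0.24), 100)
  expect_equal(ipa(0.204, 0.250), 18.4)
  expect_equal(ipa(0.204, 0.250, percent = FALSE), 0.184)
  expect_error(ipa(0.1, 0), "undefined")
})

test_that("IPA of the null model's own predictions is exactly zero", {
  set.seed(204)
  for (rep in 1:15) {
    b <- random_binary(sample(5:60, 1))
    expect_equal(ipa_report(b, null_risk(b))$ipa, 0, tolerance = 1e-12)
    d <- random_surv(sample(20:60, 1), K = 1L)
    h <- stats::median(d$time)
    if (eval_step(reverse_kaplan_meier(d), h) > 0 &&
        brier_allows(d, h)) {
      expect_equal(ipa_report(d, null_risk(d, h), h)$ipa, 0,
                   tolerance = 1e-12)
    }
    d2 <- random_surv(sample(20:60, 1), K = 2L)
    if (eval_step(reverse_kaplan_meier(d2), h) > 0 && brier_allows(d2, h)) {
      expect_equal(ipa_report(d2, null_risk(d2, h, 2), h, cause = 2)$ipa, 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("perfect predictions reach Brier 0 and IPA 100%", {
  b <- binary_data(c(1, 1, 0, 0, 0))
  rep_b <- ipa_report(b, b$outcome)
  expect_equal(rep_b$model_brier, 0)
  expect_equal(rep_b$ipa, 100)
  # uncensored survival scored through event indicators
  d <- random_uncensored(30)
  h <- stats::median(d$time)
  y <- as.numeric(d$time <= h & d$status == 1L)
  rep_s <- ipa_report(d, y, horizon = h)
  expect_equal(rep_s$model_brier, 0)
  expect_equal(rep_s$ipa, 100)
})

test_that("uncensored survival reports equal binary reports on indicators", {
  set.seed(205)
  for (rep in 1:10) {
    d <- random_uncensored(sample(10:50, 1))
    h <- sample(d$time, 1)
    risk <- runif(length(d$time))
    y <- as.numeric(d$time <= h & d$status == 1L)
    rs <- ipa_report(d, risk, horizon = h)
    rb <- ipa_report(binary_data(y), risk)
    expect_equal(rs$model_brier, rb$model_brier, tolerance = 1e-14)
    expect_equal(rs$null_brier, rb$null_brier, tolerance = 1e-14)
    expect_equal(rs$ipa, rb$ipa, tolerance = 1e-12)
  }
})

test_that("ipa_curve sweeps horizons and drops unidentifiable ones", {
  set.seed(206)
  d <- random_surv(80, K = 1L, cens_prob = 0.2)
  h <- stats::quantile(d$time, 0.5, names = FALSE)
  risk <- runif(80)
  single <- ipa_curve(d, risk, h)
  ref <- ipa_report(d, risk, h)
  expect_equal(nrow(single), 1L)
  expect_equal(single$ipa, ref$ipa)
  # null risks at every horizon give IPA 0
  hs <- stats::quantile(d$time, c(0.25, 0.5, 0.75), names = FALSE)
  nr <- vapply(hs, function(t) null_risk(d, t), numeric(80))
  curve <- ipa_curve(d, nr, hs)
  expect_equal(curve$ipa, rep(0, length(hs)), tolerance = 1e-12)
  # horizons past the data are dropped with a warning, not an error
  expect_warning(curve2 <- ipa_curve(d, risk, c(h, max(d$time) + 5)),
                 "dropped")
  expect_equal(nrow(curve2), 1L)
})

test_that("binary AUC equals the Mann-Whitney pair count", {
  expect_equal(auc_binary(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auc_binary(c(1, 0, 1), c(0.4, 0.4, 0.4)), 0.5)
  expect_equal(auc_binary(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  expect_error(auc_binary(c(1, 1), c(0.2, 0.4)), "both outcome classes")
  set.seed(207)
  for (rep in 1:20) {
    b <- random_binary(sample(4:50, 1))
    risk <- sample(seq(0, 1, 0.1), length(b$outcome), replace = TRUE)
    cases <- risk[b$outcome == 1]
    ctrls <- risk[b$outcome == 0]
    pairs <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_binary(b, risk), mean(pairs), tolerance = 1e-12)
  }
})

test_that("calibration curves recover known calibration structure", {
  # constant risk at the prevalence: a single point (p, p)
  b <- binary_data(rep(c(1, 0, 0, 0, 0), 10))
  cc <- calibration_curve(b, rep(0.2, 50))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$mean_predicted, 0.2)
  expect_equal(cc$observed, 0.2)
  # risks equal to outcomes: points (0,0) and (1,1)
  cc2 <- calibration_curve(b, b$outcome, n_bins = 2)
  expect_equal(cc2$mean_predicted, cc2$observed)
  expect_setequal(cc2$observed, c(0, 1))
  # a large calibrated logistic sample stays within 0.05 per decile
  sim <- simulate_binary(20000, log_or = 1, prevalence = 0.4, seed = 208)
  risk <- attr(sim, "true_risk")
  cc3 <- calibration_curve(sim, risk, n_bins = 10)
  expect_lt(max(abs(cc3$observed - cc3$mean_predicted)), 0.05)
})

test_that("IPCW calibration curve is consistent on censored data", {
  set.seed(209)
  d <- simulate_survival(surv_sim_config(n = 4000, cause_rates = 0.3,
                                         betas = NULL, censor_rate = 0.1,
                                         seed = 209))
  h <- 2
  truth <- 1 - exp(-0.3 * h)
  cc <- calibration_curve(d, rep(truth, 4000), horizon = h)
  expect_equal(nrow(cc), 1L)
  expect_lt(abs(cc$observed - truth), 0.03)
})

test_that("independent noise on calibrated risks degrades expected IPA", {
  set.seed(210)
  diffs <- replicate(50, {
    sim <- simulate_binary(500, log_or = 0.8, prevalence = 0.4)
    risk <- attr(sim, "true_risk")
    noisy <- pmin(pmax(risk + runif(500, -0.1, 0.1), 0), 1)
    nb <- brier_binary(sim, null_risk(sim))
    ipa(brier_binary(sim, noisy), nb) - ipa(brier_binary(sim, risk), nb)
  })
  upper99 <- mean(diffs) + stats::qt(0.99, 49) * stats::sd(diffs) / sqrt(50)
  expect_lt(upper99, 0)
})
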