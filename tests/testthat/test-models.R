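test_that("intercept-only logistic fit recovers the logit prevalence", {
  b <- binary_data(c(1, 1, 0, 0, 0))
  m <- fit_logistic(b, predictor_spec())
  expect_equal(unname(coef(m$fit)), qlogis(0.4), tolerance = 1e-8)
  expect_equal(predict_absolute_risk(m, data.frame(row.names = 1:5)),
               rep(0.4, 5), tolerance = 1e-8)
})

test_that("logistic regression recovers the generating slope", {
  sim <- simulate_binary(1e5, log_or = 1, prevalence = 0.4, seed = 301)
  m <- fit_logistic(sim, predictor_spec("x"))
  expect_lt(abs(coef(m$fit)[["x"]] - 1), 0.03)
})

test_that("perfect separation raises a convergence error", {
  b <- binary_data(c(0, 0, 0, 1, 1, 1),
                   predictors = data.frame(z = c(1, 2, 3, 10, 11, 12)))
  expect_error(fit_logistic(b, predictor_spec("z")), "converge")
})

test_that("Cox regression recovers a null effect", {
  d <- simulate_survival(surv_sim_config(
    n = 10000, cause_rates = 0.2, betas = matrix(0, 1, 1),
    censor_rate = 0.1, seed = 302))
  m <- fit_cox(d, predictor_spec("x1"))
  expect_lt(abs(coef(m$fit)[["x1"]]), 0.05)
})

test_that("Cox estimate maximizes the Breslow partial likelihood", {
  # tie-free toy data, single binary covariate; brute-force grid oracle
  time <- c(1.1, 1.9, 2.7, 3.4, 4.2, 5.0)
  status <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  d <- surv_data(time, status, predictors = data.frame(x = x))
  log_pl <- function(beta) {
    sum(vapply(which(status == 1), function(i) {
      at_risk <- time >= time[i]
      beta * x[i] - log(sum(exp(beta * x[at_risk])))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 1e-3)
  oracle <- grid[which.max(vapply(grid, log_pl, numeric(1)))]
  m <- fit_cox(d, predictor_spec("x"))
  expect_lt(abs(coef(m$fit)[["x"]] - oracle), 1e-3)
})

test_that("covariate-free Cox baseline equals the Nelson-Aalen increments", {
  set.seed(303)
  d <- random_surv(40, K = 1L)
  m <- fit_cox(d, predictor_spec())
  tt <- sort(unique(d$time[d$status == 1L]))
  dk <- vapply(tt, function(t) sum(d$time == t & d$status == 1L), numeric(1))
  n <- vapply(tt, function(t) sum(d$time >= t), numeric(1))
  expect_equal(m$baseline$time, tt)
  expect_equal(m$baseline$increment, dk / n, tolerance = 1e-12)
})

test_that("cause-specific fits reduce to single-cause Cox fits", {
  set.seed(304)
  d <- simulate_survival(surv_sim_config(n = 300, cause_rates = 0.3,
                                         betas = matrix(c(0.5, 0.3), 1, 2),
                                         censor_rate = 0.1, seed = 304))
  csc <- fit_cause_specific(d, predictor_spec("x1", "x2"))
  cox <- fit_cox(d, predictor_spec("x1", "x2"))
  expect_equal(coef(csc$fits[[1]]$fit), coef(cox$fit))
  expect_equal(csc$fits[[1]]$baseline, cox$baseline)
})

test_that("cause-specific Cox recovers two-cause generating effects", {
  d <- simulate_survival(surv_sim_config(
    n = 10000, cause_rates = c(0.15, 0.05),
    betas = rbind(c(0.7, 0.5), c(0.3, 0)), censor_rate = 0.1, seed = 305))
  csc <- fit_cause_specific(d, predictor_spec("x1", "x2"))
  truth <- rbind(c(0.7, 0.5), c(0.3, 0))
  for (k in 1:2) {
    est <- coef(csc$fits[[k]]$fit)
    se <- sqrt(diag(vcov(csc$fits[[k]]$fit)))
    # the rarer cause has wider sampling error; allow 3 SE where that
    # exceeds the nominal 0.05 band
    expect_true(all(abs(est - truth[k, ]) < pmax(0.05, 3 * se)))
  }
})

test_that("null cause-specific absolute risk reproduces Aalen-Johansen", {
  set.seed(306)
  d <- random_surv(120, K = 2L, cens_prob = 0.25)
  m0 <- fit_cause_specific(d, predictor_spec())
  tt <- sort(unique(d$time[d$status != 0L]))
  for (k in 1:2) {
    aj <- eval_step(aalen_johansen(d, k), tt)
    pred <- predict_absolute_risk(m0, data.frame(row.names = 1), tt, cause = k)
    expect_equal(as.numeric(pred), aj, tolerance = 1e-10)
  }
  # K = 1 with a null spec equals 1 - Kaplan-Meier
  d1 <- random_surv(60, K = 1L)
  m1 <- fit_cox(d1, predictor_spec())
  tt1 <- sort(unique(d1$time))
  expect_equal(
    as.numeric(predict_absolute_risk(m1, data.frame(row.names = 1), tt1)),
    1 - eval_step(kaplan_meier(d1), tt1), tolerance = 1e-10)
})

test_that("absolute risks are monotone, conservative and relabel-invariant", {
  d <- simulate_survival(surv_sim_config(n = 400, seed = 307))
  m <- fit_cause_specific(d, list(predictor_spec("x1", "x2"),
                                  predictor_spec("x1")))
  nd <- d$predictors[1:15, ]
  hs <- c(0.5, 1, 2, 4, 8)
  r1 <- predict_absolute_risk(m, nd, hs, cause = 1)
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_true(all(diff(t(r1)) >= -1e-12))  # non-decreasing in the horizon
  # swapping the labels of the two non-target causes leaves the
  # target-cause risk unchanged
  d3 <- simulate_survival(surv_sim_config(
    n = 400, cause_rates = c(0.15, 0.05, 0.08),
    betas = rbind(c(0.7, 0.5), c(0.3, 0), c(0.1, 0.2)),
    censor_rate = 0.1, seed = 311))
  specs3 <- list(predictor_spec("x1", "x2"), predictor_spec("x1"),
                 predictor_spec("x1"))
  swap <- ifelse(d3$status == 2L, 3L, ifelse(d3$status == 3L, 2L, d3$status))
  m3 <- fit_cause_specific(d3, specs3)
  m3s <- fit_cause_specific(
    surv_data(d3$time, swap, n_causes = 3, predictors = d3$predictors),
    specs3)
  nd3 <- d3$predictors[1:10, ]
  expect_equal(predict_absolute_risk(m3s, nd3, hs, cause = 1),
               predict_absolute_risk(m3, nd3, hs, cause = 1),
               tolerance = 1e-12)
  # zeroing all covariate effects collapses predictions to one curve
  m0 <- m
  for (k in 1:2) m0$fits[[k]]$fit$coefficients[] <- 0
  r0 <- predict_absolute_risk(m0, nd, 4, cause = 1)
  expect_equal(max(r0) - min(r0), 0, tolerance = 1e-14)
})

test_that("declared transforms and units rescale reported effects", {
  set.seed(308)
  n <- 2000
  age <- rnorm(n, 65, 8)
  psa <- exp(rnorm(n))
  lp <- -1 + 0.04 * age - 2.6 + 0.5 * log2(psa)
  y <- rbinom(n, 1, plogis(lp))
  b <- binary_data(y, predictors = data.frame(age = age, psa = psa))
  m <- fit_logistic(b, predictor_spec(
    continuous_var("age", scale = 5),
    continuous_var("psa", transform = "log2")))
  # per-5-year age effect is 5x the per-year effect
  expect_equal(coef(m$fit)[["age"]] / 5,
               coef(glm(y ~ age + log2(psa), family = binomial()))[["age"]],
               tolerance = 1e-6)
  expect_lt(abs(coef(m$fit)[["psa"]] - 0.5), 0.15)
  s <- model_summary(m)
  expect_named(s, c("variable", "estimate", "ratio", "lower", "upper",
                    "p_value"))
  expect_equal(s$ratio, exp(s$estimate))
})

test_that("logistic and Cox fits match reference implementations", {
  # logistic: compare against glm on the manually encoded design
  sim <- simulate_binary(2000, log_or = 0.7, prevalence = 0.25, seed = 309)
  m <- fit_logistic(sim, predictor_spec("x"))
  ref <- glm(sim$outcome ~ sim$predictors$x, family = binomial())
  expect_equal(unname(coef(m$fit)), unname(coef(ref)), tolerance = 1e-8)
  # Cox: compare against coxph called directly on the raw data
  d <- simulate_survival(surv_sim_config(n = 1000, cause_rates = 0.2,
                                         betas = matrix(0.5, 1, 1),
                                         censor_rate = 0.15, seed = 310))
  m2 <- fit_cox(d, predictor_spec("x1"))
  ref2 <- survival::coxph(survival::Surv(d$time, d$status) ~ d$predictors$x1,
                          ties = "breslow")
  expect_equal(unname(coef(m2$fit)), unname(coef(ref2)), tolerance = 1e-8)
})
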