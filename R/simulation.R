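#' @title Simulation toolkit
#' @description Generators for the package's study designs: a single
#'   standard-normal predictor with a logistic outcome at a controlled
#'   marginal prevalence (used to study how IPA reacts to discrimination and
#'   miscalibration), and exponential competing-risks data with
#'   proportional-hazards covariate effects (used to exercise the IPCW and
#'   absolute-risk machinery).
#' @name simulation
NULL

# Deterministic substream seeds below 2^31, derived from one master seed.
# Lehmer-style mixing keeps streams for different task indices apart.
substream_seed <- function(master, index) {
  s <- (as.double(master) %% 2147483647) + 1
  for (step in c(index + 1, 2)) {
    s <- (s * 48271 + step * 69621) %% 2147483647
  }
  as.integer(s)
}

#' Intercept achieving a target marginal prevalence
#'
#' For a logistic model `P(Y=1|X) = expit(a + b X)` with `X ~ N(0,1)`,
#' solves for the intercept `a` such that the marginal prevalence
#' `E[expit(a + b X)]` equals the target. The expectation is computed by
#' adaptive quadrature and the root located by bracketing; the achieved
#' prevalence matches the target to better than 1e-6.
#'
#' @param prevalence Target marginal prevalence in (0, 1).
#' @param log_or Log odds ratio `b` of the standard-normal predictor.
#' @return The intercept `a`.
#' @examples
#' solve_intercept(0.4, 0)    # logit(0.4)
#' solve_intercept(0.5, 2.5)  # 0 by symmetry
#' @export
solve_intercept <- function(prevalence, log_or) {
  stopifnot(prevalence > 0, prevalence < 1, is.finite(log_or))
  marginal <- function(a) {
    stats::integrate(function(x) stats::plogis(a + log_or * x) * stats::dnorm(x),
                     -Inf, Inf, rel.tol = 1e-12)$value
  }
  stats::uniroot(function(a) marginal(a) - prevalence,
                 lower = -40, upper = 40, tol = 1e-10)$root
}

#' Simulate binary outcomes from a one-predictor logistic model
#'
#' Draws `X ~ N(0,1)` and `Y ~ Bernoulli(expit(a + b X))` with the intercept
#' `a` chosen by [solve_intercept()] so the marginal prevalence hits the
#' target.
#'
#' @param n Sample size.
#' @param log_or Log odds ratio of the predictor.
#' @param prevalence Target marginal prevalence.
#' @param seed Optional seed; the draw is reproducible when supplied.
#' @return A [binary_data()] sample whose predictors hold the column `x`
#'   and, as attributes, the `true_risk` vector and intercept used.
#' @export
simulate_binary <- function(n, log_or, prevalence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- solve_intercept(prevalence, log_or)
  x <- stats::rnorm(n)
  p <- stats::plogis(a + log_or * x)
  y <- stats::rbinom(n, 1L, p)
  out <- binary_data(y, predictors = data.frame(x = x))
  attr(out, "true_risk") <- p
  attr(out, "intercept") <- a
  out
}

#' Configuration of the discrimination/miscalibration experiment
#'
#' Defaults encode the study design: three learning sets of n = 1000 whose
#' marginal prevalences are 40, 25 and 10%, a fresh validation set of
#' n = 200 at 40% prevalence, a grid of 21 log odds ratios in `[-1, 1]`,
#' and 50 repetitions. The model fitted on the 40% learning set is
#' calibrated for the validation population; the 25% and 10% models are
#' increasingly miscalibrated, with identical discrimination.
#'
#' @param learning_n,validation_n Learning / validation sample sizes.
#' @param validation_prevalence Marginal prevalence of the validation set.
#' @param learning_prevalences Marginal prevalences of the learning sets.
#' @param log_or_grid Grid of log odds ratios.
#' @param repetitions Number of repetitions per grid point.
#' @param seed Master seed spawning one substream per
#'   (grid point, repetition, arm).
#' @return An object of class `"fig2_config"`.
#' @export
fig2_config <- function(learning_n = 1000L, validation_n = 200L,
                        validation_prevalence = 0.40,
                        learning_prevalences = c(0.40, 0.25, 0.10),
                        log_or_grid = seq(-1, 1, length.out = 21L),
                        repetitions = 50L, seed = 1L) {
  stopifnot(all(learning_prevalences > 0 & learning_prevalences < 1),
            validation_prevalence > 0, validation_prevalence < 1,
            all(abs(log_or_grid) <= 1), repetitions >= 1L,
            learning_n >= 2L, validation_n >= 2L)
  structure(list(learning_n = as.integer(learning_n),
                 validation_n = as.integer(validation_n),
                 validation_prevalence = validation_prevalence,
                 learning_prevalences = learning_prevalences,
                 log_or_grid = log_or_grid,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "fig2_config")
}

#' Run the discrimination/miscalibration experiment
#'
#' For every grid point and repetition: simulate the learning sets and a
#' fresh validation set, fit a one-predictor logistic model per learning
#' set, and record IPA (against the validation-prevalence null model) and
#' AUC on the validation set. Degenerate validation draws with a single
#' outcome class are redrawn from the next substream (with a message).
#'
#' @param config A [fig2_config()].
#' @return An object of class `"fig2_result"`: a list with `results` (long
#'   `data.frame`: `log_or`, `rep`, `learning_prevalence`, `ipa`, `auc`) and
#'   `summary` (per grid point and arm: mean IPA and AUC).
#' @export
run_fig2 <- function(config = fig2_config()) {
  stopifnot(inherits(config, "fig2_config"))
  arms <- config$learning_prevalences
  n_arms <- length(arms)
  grid <- config$log_or_grid
  R <- config$repetitions
  stride <- n_arms + 2L  # validation + redraw slack + learning arms
  rows <- vector("list", length(grid) * R * n_arms)
  k <- 0L
  for (g in seq_along(grid)) {
    for (r in seq_len(R)) {
      base_idx <- ((g - 1L) * R + (r - 1L)) * stride
      valid <- simulate_binary(config$validation_n, grid[g],
                               config$validation_prevalence,
                               seed = substream_seed(config$seed, base_idx))
      tries <- 0L
      while (length(unique(valid$outcome)) < 2L && tries < 100L) {
        tries <- tries + 1L
        message(sprintf(
          "degenerate validation draw at log_or=%g rep %d; resampling",
          grid[g], r))
        valid <- simulate_binary(
          config$validation_n, grid[g], config$validation_prevalence,
          seed = substream_seed(config$seed + tries, base_idx))
      }
      nb <- brier_binary(valid, null_risk(valid))
      for (a in seq_len(n_arms)) {
        learn <- simulate_binary(config$learning_n, grid[g], arms[a],
                                 seed = substream_seed(config$seed,
                                                       base_idx + 1L + a))
        fit <- fit_logistic(learn, predictor_spec("x"))
        risk <- predict_absolute_risk(fit, valid$predictors)
        mb <- brier_binary(valid, risk)
        k <- k + 1L
        rows[[k]] <- data.frame(log_or = grid[g], rep = r,
                                learning_prevalence = arms[a],
                                ipa = ipa(mb, nb),
                                auc = auc_binary(valid, risk))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(ipa, auc) ~ log_or + learning_prevalence,
                              data = results, FUN = mean)
  summary <- summary[order(summary$learning_prevalence, summary$log_or), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, config = config),
            class = "fig2_result")
}

#' @export
print.fig2_result <- function(x, ...) {
  cat(sprintf(
    "Discrimination/miscalibration experiment: %d grid points x %d reps x %d arms\n",
    length(x$config$log_or_grid), x$config$repetitions,
    length(x$config$learning_prevalences)))
  at0 <- x$summary[abs(x$summary$log_or) < 1e-12, ]
  if (nrow(at0)) {
    cat("Mean IPA/AUC at log odds ratio 0:\n")
    print(data.frame(learning_prevalence = at0$learning_prevalence,
                     mean_ipa = round(at0$ipa, 2),
                     mean_auc = round(at0$auc, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Configuration of the competing-risks generator
#'
#' Defaults emulate an active-surveillance-style cohort: two competing
#' causes (disease progression and death from other causes) with constant
#' cause-specific baseline hazards, a continuous and a binary risk factor
#' acting proportionally on the cause-specific hazards, and independent
#' exponential censoring.
#'
#' @param n Sample size.
#' @param cause_rates Baseline cause-specific hazard rates, one per cause
#'   (events per time unit).
#' @param betas Matrix of log hazard ratios, causes by covariates; `NULL`
#'   for no covariate effects.
#' @param censor_rate Rate of the independent exponential censoring time
#'   (0 disables censoring).
#' @param seed Optional seed.
#' @return An object of class `"surv_sim_config"`.
#' @export
surv_sim_config <- function(n = 500L,
                            cause_rates = c(0.15, 0.05),
                            betas = rbind(c(0.7, 0.5), c(0.3, 0)),
                            censor_rate = 0.10, seed = NULL) {
  stopifnot(n >= 1L, all(cause_rates > 0), censor_rate >= 0)
  if (!is.null(betas)) {
    betas <- as.matrix(betas)
    stopifnot(nrow(betas) == length(cause_rates))
  }
  structure(list(n = as.integer(n), cause_rates = cause_rates,
                 betas = betas, censor_rate = censor_rate, seed = seed),
            class = "surv_sim_config")
}

#' Simulate right-censored competing-risks data
#'
#' Cause-specific event times are exponential with subject-specific rates
#' `rate_k * exp(x' beta_k)`; the observed time is the minimum of the event
#' times and an independent exponential censoring time, and the status
#' records which cause (or censoring) won. Covariates are a standard-normal
#' column `x1` and a Bernoulli(0.4) column `x2` (as many columns as `betas`
#' has; extra columns repeat this pattern).
#'
#' @param config A [surv_sim_config()].
#' @return A [surv_data()] sample carrying the covariates as predictors.
#' @export
simulate_survival <- function(config = surv_sim_config()) {
  stopifnot(inherits(config, "surv_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  K <- length(config$cause_rates)
  p <- if (is.null(config$betas)) 0L else ncol(config$betas)
  X <- if (p > 0L) {
    cols <- lapply(seq_len(p), function(j) {
      if (j %% 2L == 1L) stats::rnorm(n) else stats::rbinom(n, 1L, 0.4)
    })
    names(cols) <- paste0("x", seq_len(p))
    as.data.frame(cols)
  } else NULL
  lp <- if (p > 0L) {
    as.matrix(X) %*% t(config$betas)  # n x K
  } else matrix(0, n, K)
  rates <- sweep(exp(lp), 2L, config$cause_rates, `*`)
  total <- rowSums(rates)
  event_time <- stats::rexp(n, rate = total)
  cause <- vapply(seq_len(n), function(i) {
    sample.int(K, 1L, prob = rates[i, ])
  }, integer(1))
  if (config$censor_rate > 0) {
    cens_time <- stats::rexp(n, rate = config$censor_rate)
  } else {
    cens_time <- rep(Inf, n)
  }
  time <- pmin(event_time, cens_time)
  status <- ifelse(event_time <= cens_time, cause, 0L)
  surv_data(time, status, n_causes = K, predictors = X)
}
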