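#' Brier score for binary outcomes
#'
#' Mean squared difference between predicted risks and observed 0/1 outcomes.
#'
#' @param x A [binary_data()] sample or a plain 0/1 vector.
#' @param risk Predicted risks in `[0, 1]`, one per subject.
#' @return The Brier score, a number in `[0, 1]`.
#' @examples
#' brier_binary(c(1, 0), c(0.5, 0.5))  # 0.25
#' @export
brier_binary <- function(x, risk) {
  if (!inherits(x, "binary_data")) x <- binary_data(x)
  risk <- check_risks(risk, length(x$outcome))
  mean((x$outcome - risk)^2)
}

#' IPCW Brier score for right-censored outcomes
#'
#' Brier score at a prediction horizon t, estimated with inverse probability
#' of censoring weighting. With Y_i(t) = 1 if subject i fails from the target
#' cause by t, each subject contributes W_i (Y_i(t) - R_i)^2 where
#' W_i = 1/G(T_i-) if the subject failed (from any cause) by t,
#' W_i = 1/G(t) if still event-free at t, and W_i = 0 if censored at or
#' before t; G is the reverse Kaplan-Meier censoring survival.
#'
#' @param x A [surv_data()] sample.
#' @param risk Predicted risks of the target cause by the horizon.
#' @param horizon Positive prediction horizon.
#' @param cause Target cause (default 1).
#' @param G Optional pre-computed censoring [step_function()]; by default the
#'   marginal reverse Kaplan-Meier of `x`.
#' @return The IPCW Brier score.
#' @examples
#' d <- surv_data(c(1, 3), c(1, 0))
#' brier_ipcw(d, risk = c(1, 0), horizon = 2)  # 0
#' @export
brier_ipcw <- function(x, risk, horizon, cause = 1L, G = NULL) {
  stopifnot(inherits(x, "surv_data"))
  risk <- check_risks(risk, length(x$time))
  cause <- as.integer(cause)
  if (cause < 1L || cause > x$n_causes) {
    stop(sprintf("'cause' must be in 1..%d", x$n_causes), call. = FALSE)
  }
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0) {
    stop("'horizon' must be a single positive number", call. = FALSE)
  }
  if (is.null(G)) G <- reverse_kaplan_meier(x)
  if (horizon > max(x$time) || eval_step(G, horizon) <= 0) {
    stop("horizon beyond identifiable range: no censoring-survival mass at t",
         call. = FALSE)
  }
  w <- ipcw_weights(x, horizon, G)
  y <- as.numeric(x$time <= horizon & x$status == cause)
  mean(w * (y - risk)^2)
}

# IPCW weights at horizon t: 1/G(T_i-) for failures by t, 1/G(t) for
# subjects still at risk at t, 0 for subjects censored at or before t
# (including censoring exactly at t, whose status at t is unknown).
ipcw_weights <- function(x, horizon, G = reverse_kaplan_meier(x)) {
  w <- numeric(length(x$time))
  failed <- x$time <= horizon & x$status != 0L
  at_risk <- x$time > horizon
  w[failed] <- 1 / eval_step(G, x$time[failed], side = "left")
  w[at_risk] <- 1 / eval_step(G, horizon)
  w
}

#' Null-model risk predictions
#'
#' Constant risk assigned to every subject by the covariate-free benchmark:
#' the outcome prevalence for binary data, `1 - KM(horizon)` for survival
#' data, and the Aalen-Johansen cumulative incidence `F_cause(horizon)` for
#' competing risks.
#'
#' @param x A [binary_data()] or [surv_data()] sample.
#' @param horizon Prediction horizon (required for censored settings).
#' @param cause Target cause for competing risks (default 1).
#' @return Numeric vector: the constant null risk, one entry per subject.
#' @examples
#' null_risk(binary_data(c(1, 1, 0, 0, 0)))  # 0.4 each
#' @export
null_risk <- function(x, horizon = NULL, cause = 1L) {
  if (inherits(x, "binary_data")) {
    return(rep(mean(x$outcome), length(x$outcome)))
  }
  stopifnot(inherits(x, "surv_data"))
  if (is.null(horizon)) {
    stop("'horizon' is required for censored outcomes", call. = FALSE)
  }
  p <- if (x$n_causes == 1L) {
    1 - eval_step(kaplan_meier(x), horizon)
  } else {
    eval_step(aalen_johansen(x, cause), horizon)
  }
  rep(p, length(x$time))
}

#' Index of prediction accuracy
#'
#' IPA = 1 - model Brier / null Brier. 100% is a perfect model, 0 means the
#' model is no better than the covariate-free benchmark, and negative values
#' mean the model is harmful (worse than ignoring the covariates).
#'
#' @param model_brier Brier score of the model under evaluation.
#' @param null_brier Brier score of the null model; must be positive.
#' @param percent Return percent (default) rather than a fraction.
#' @return IPA, in percent by default.
#' @examples
#' ipa(0.204, 0.250)  # 18.4
#' @export
ipa <- function(model_brier, null_brier, percent = TRUE) {
  if (any(null_brier <= 0)) {
    stop("IPA undefined: null-model Brier score is zero (degenerate sample)",
         call. = FALSE)
  }
  out <- 1 - model_brier / null_brier
  if (percent) 100 * out else out
}

#' IPA report for one model at one horizon
#'
#' Computes the model Brier score, the null-model Brier score and the IPA in
#' a single record. The setting (binary, survival, competing risks) is taken
#' from the class of `x`. By default the null model is estimated on the
#' evaluation sample itself; pass `null_risk.` to score against a benchmark
#' estimated elsewhere (for example an intercept-only model fitted on the
#' learning sample).
#'
#' @param x A [binary_data()] or [surv_data()] sample.
#' @param risk Predicted risks, one per subject.
#' @param horizon Prediction horizon (censored settings only).
#' @param cause Target cause (competing risks only).
#' @param null_risk. Optional externally supplied null risks.
#' @return An object of class `"ipa_report"`: a list with `setting`,
#'   `horizon`, `cause`, `model_brier`, `null_brier` and `ipa` (percent).
#' @examples
#' b <- binary_data(c(1, 1, 0, 0, 0))
#' ipa_report(b, risk = b$outcome)$ipa  # 100
#' @export
ipa_report <- function(x, risk, horizon = NULL, cause = 1L,
                       null_risk. = NULL) {
  if (is.null(null_risk.)) null_risk. <- null_risk(x, horizon, cause)
  n <- n_subjects(x)
  null_risk. <- check_risks(null_risk., n, "null_risk.")
  if (inherits(x, "binary_data")) {
    setting <- "binary"
    mb <- brier_binary(x, risk)
    nb <- brier_binary(x, null_risk.)
    horizon <- NULL
    cause <- NULL
  } else {
    setting <- if (x$n_causes == 1L) "survival" else "competing-risks"
    G <- reverse_kaplan_meier(x)
    mb <- brier_ipcw(x, risk, horizon, cause, G = G)
    nb <- brier_ipcw(x, null_risk., horizon, cause, G = G)
    if (x$n_causes == 1L) cause <- NULL
  }
  structure(
    list(setting = setting, horizon = horizon, cause = cause,
         model_brier = mb, null_brier = nb, ipa = ipa(mb, nb)),
    class = "ipa_report"
  )
}

#' @export
print.ipa_report <- function(x, ...) {
  cat(sprintf("IPA report (%s setting%s%s)\n", x$setting,
              if (!is.null(x$horizon)) sprintf(", horizon %g", x$horizon) else "",
              if (!is.null(x$cause)) sprintf(", cause %d", x$cause) else ""))
  cat(sprintf("  Brier (model): %.2f%%\n", 100 * x$model_brier))
  cat(sprintf("  Brier (null):  %.2f%%\n", 100 * x$null_brier))
  cat(sprintf("  IPA:           %.2f%%\n", x$ipa))
  invisible(x)
}

#' IPA as a function of the prediction horizon
#'
#' Evaluates one IPA report per horizon. Horizons beyond the identifiable
#' range (censoring survival zero, or past the last observed time) are
#' dropped with a warning rather than failing the whole curve.
#'
#' @param x A [surv_data()] sample.
#' @param risk Matrix of predicted risks, subjects by horizons (a single
#'   vector is recycled across horizons).
#' @param horizons Numeric vector of prediction horizons.
#' @param cause Target cause (default 1).
#' @return A `data.frame` with columns `horizon`, `model_brier`,
#'   `null_brier`, `ipa`.
#' @export
ipa_curve <- function(x, risk, horizons, cause = 1L) {
  stopifnot(inherits(x, "surv_data"))
  n <- length(x$time)
  if (is.null(dim(risk))) risk <- matrix(risk, nrow = n, ncol = length(horizons))
  if (nrow(risk) != n || ncol(risk) != length(horizons)) {
    stop("'risk' must be a subjects-by-horizons matrix", call. = FALSE)
  }
  rows <- lapply(seq_along(horizons), function(j) {
    rep <- tryCatch(ipa_report(x, risk[, j], horizons[j], cause),
                    error = function(e) e)
    if (inherits(rep, "error")) {
      warning(sprintf("horizon %g dropped: %s", horizons[j],
                      conditionMessage(rep)), call. = FALSE)
      return(NULL)
    }
    data.frame(horizon = horizons[j], model_brier = rep$model_brier,
               null_brier = rep$null_brier, ipa = rep$ipa)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Area under the ROC curve for binary outcomes
#'
#' Mann-Whitney probability that a randomly chosen event subject receives a
#' higher predicted risk than a randomly chosen non-event subject, with ties
#' counted one half.
#'
#' @param x A [binary_data()] sample or 0/1 vector.
#' @param risk Predicted risks (any monotone score works).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_binary(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
auc_binary <- function(x, risk) {
  if (!inherits(x, "binary_data")) x <- binary_data(x)
  risk <- as.numeric(risk)
  if (length(risk) != length(x$outcome)) {
    stop("'risk' must have one prediction per subject", call. = FALSE)
  }
  n1 <- sum(x$outcome == 1)
  n0 <- sum(x$outcome == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both outcome classes must be present", call. = FALSE)
  }
  r <- rank(risk, ties.method = "average")
  (sum(r[x$outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration curve
#'
#' Groups subjects into equal-frequency bins of predicted risk and compares
#' the mean predicted risk per bin with the observed event frequency. For
#' censored settings the observed frequency is the IPCW-weighted proportion
#' of target-cause events by the horizon.
#'
#' @param x A [binary_data()] or [surv_data()] sample.
#' @param risk Predicted risks, one per subject.
#' @param horizon Prediction horizon (censored settings only).
#' @param cause Target cause (competing risks).
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return A `data.frame` with one row per nonempty bin: `mean_predicted`,
#'   `observed`, `n`.
#' @export
calibration_curve <- function(x, risk, horizon = NULL, cause = 1L,
                              n_bins = 10L) {
  n <- n_subjects(x)
  risk <- check_risks(risk, n)
  if (n_bins < 1L) stop("'n_bins' must be at least 1", call. = FALSE)
  if (inherits(x, "binary_data")) {
    y <- x$outcome
    w <- rep(1, n)
  } else {
    G <- reverse_kaplan_meier(x)
    if (is.null(horizon)) {
      stop("'horizon' is required for censored outcomes", call. = FALSE)
    }
    if (horizon > max(x$time) || eval_step(G, horizon) <= 0) {
      stop("horizon beyond identifiable range: no censoring-survival mass at t",
           call. = FALSE)
    }
    y <- as.numeric(x$time <= horizon & x$status == cause)
    w <- ipcw_weights(x, horizon, G)
  }
  # equal-frequency bins; with few distinct predictions (e.g. 0/1 risks or a
  # constant model) quantile breaks collapse, so bin by exact value instead
  bin <- if (length(unique(risk)) <= n_bins) {
    factor(risk)
  } else {
    br <- unique(stats::quantile(risk,
                                 probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
    if (length(br) > 1L) cut(risk, breaks = br, include.lowest = TRUE)
    else factor(rep(1L, n))
  }
  out <- lapply(levels(bin), function(b) {
    i <- bin == b
    if (!any(i) || sum(w[i]) == 0) return(NULL)
    data.frame(mean_predicted = mean(risk[i]),
               observed = sum(w[i] * y[i]) / sum(w[i]),
               n = sum(i))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
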