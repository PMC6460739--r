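#' Drop-one-variable IPA-gain analysis
#'
#' Quantifies each predictor's contribution to out-of-sample accuracy by
#' refitting the model on the learning data with that variable removed
#' (categorical variables are dropped as whole blocks) and recording the
#' loss in IPA on the validation data: `ipa_gain = IPA(full) - IPA(reduced)`.
#' A negative gain means the reduced model outperforms the full model. Every
#' row is scored against the same validation sample and the same null-model
#' Brier score as the full model, so gains are directly comparable.
#'
#' In the competing-risks setting variables are dropped from the
#' target-cause model only; models for the other causes keep their own
#' specifications.
#'
#' @param learn Learning sample ([binary_data()] or [surv_data()]) carrying
#'   predictors; models are fitted here.
#' @param valid Validation sample of the same class; IPA is computed here.
#' @param spec A [predictor_spec()] for the model under study (the
#'   target-cause model in the competing-risks setting).
#' @param horizon Prediction horizon (censored settings).
#' @param cause Target cause (competing risks).
#' @param other_specs Competing risks only: list of specs for the non-target
#'   causes, in cause order with the target cause's entry ignored; defaults
#'   to empty (covariate-free) models for the other causes.
#' @param null_source `"validation"` (default) estimates the null model on
#'   the validation sample; `"learning"` scores against a covariate-free
#'   model estimated on the learning sample.
#' @return An object of class `"importance_table"`: a list with the full
#'   model's `ipa_report` and a `data.frame` `rows` of per-variable gains
#'   (NA, with a note, where a reduced fit failed).
#' @export
drop_one_ipa <- function(learn, valid, spec, horizon = NULL, cause = 1L,
                         other_specs = NULL,
                         null_source = c("validation", "learning")) {
  null_source <- match.arg(null_source)
  if (!identical(class(learn), class(valid))) {
    stop("'learn' and 'valid' must be samples of the same setting",
         call. = FALSE)
  }
  if (!length(spec$variables)) {
    stop("drop-one analysis needs at least one predictor", call. = FALSE)
  }

  fit_and_score <- function(sp) {
    m <- fit_setting_model(learn, sp, cause, other_specs)
    risk <- predict_setting_risk(m, valid, horizon, cause)
    ipa_report(valid, risk, horizon, cause,
               null_risk. = null_predictions(learn, valid, horizon, cause,
                                             null_source))
    }

  full <- fit_and_score(spec)
  rows <- lapply(spec_names(spec), function(v) {
    red <- tryCatch(fit_and_score(spec_drop(spec, v)),
                    error = function(e) e)
    if (inherits(red, "error")) {
      data.frame(variable = v, ipa_gain = NA_real_,
                 note = conditionMessage(red))
    } else {
      stopifnot(identical(red$null_brier, full$null_brier))
      data.frame(variable = v, ipa_gain = full$ipa - red$ipa, note = "")
    }
  })
  structure(list(full = full, rows = do.call(rbind, rows)),
            class = "importance_table")
}

# Fit the model matching the sample's setting.
fit_setting_model <- function(learn, spec, cause, other_specs) {
  if (inherits(learn, "binary_data")) return(fit_logistic(learn, spec))
  if (learn$n_causes == 1L) return(fit_cox(learn, spec))
  specs <- if (is.null(other_specs)) {
    rep(list(predictor_spec()), learn$n_causes)
  } else other_specs
  specs[[cause]] <- spec
  fit_cause_specific(learn, specs)
}

predict_setting_risk <- function(m, valid, horizon, cause) {
  newdata <- if (inherits(valid, "binary_data")) {
    if (is.null(valid$predictors)) {
      data.frame(row.names = seq_along(valid$outcome))
    } else valid$predictors
  } else {
    if (is.null(valid$predictors)) {
      data.frame(row.names = seq_along(valid$time))
    } else valid$predictors
  }
  predict_absolute_risk(m, newdata, horizon, cause)
}

# Null risks for the validation sample, optionally estimated on the
# learning sample (covariate-free model transported to validation).
null_predictions <- function(learn, valid, horizon, cause, null_source) {
  src <- if (null_source == "learning") learn else valid
  rep(null_risk(src, horizon, cause)[1L], n_subjects(valid))
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Drop-one IPA analysis (%s setting%s)\n", x$full$setting,
              if (!is.null(x$full$horizon))
                sprintf(", horizon %g", x$full$horizon) else ""))
  cat(sprintf("  Brier (full model): %.2f%%; Brier (null model): %.2f%%\n",
              100 * x$full$model_brier, 100 * x$full$null_brier))
  cat(sprintf("  Full model IPA: %.2f%%\n", x$full$ipa))
  cat("  Loss in IPA (%) compared to full model:\n")
  tab <- data.frame(variable = x$rows$variable,
                    ipa_gain = round(x$rows$ipa_gain, 2))
  print(tab, row.names = FALSE)
  bad <- x$rows$note != ""
  if (any(bad)) {
    cat("  unavailable rows:\n")
    for (i in which(bad)) {
      cat(sprintf("    %s: %s\n", x$rows$variable[i], x$rows$note[i]))
    }
  }
  invisible(x)
}

#' Write an importance table as TSV
#'
#' Serializes the drop-one analysis with a provenance header block (setting,
#' horizon, Brier scores, full-model IPA) followed by one row per variable.
#'
#' @param x An `"importance_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# setting\t%s", x$full$setting),
    if (!is.null(x$full$horizon)) sprintf("# horizon\t%.15g", x$full$horizon),
    sprintf("# model_brier\t%.15g", x$full$model_brier),
    sprintf("# null_brier\t%.15g", x$full$null_brier),
    sprintf("# full_model_ipa_percent\t%.15g", x$full$ipa)
  ), con)
  utils::write.table(
    data.frame(variable = x$rows$variable,
               ipa_gain_percent = sprintf("%.15g", x$rows$ipa_gain),
               note = x$rows$note),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
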