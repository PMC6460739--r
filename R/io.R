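#' Read a delimited file into an outcome sample
#'
#' Reads a CSV/TSV file (delimiter auto-detected from the header line unless
#' declared) and maps its columns onto a [binary_data()] or [surv_data()]
#' sample. Rows with missing values in any used column are dropped with a
#' message reporting the count.
#'
#' @param path Path to the delimited file.
#' @param mapping Named list describing the columns: either
#'   `list(outcome = "col")` for binary data or
#'   `list(time = "col", status = "col")` for censored data, plus optional
#'   `predictors` (character vector of column names), `n_causes`, and
#'   `status_codes` (named vector translating file codes to the internal
#'   0 = censored, 1..K = causes convention, e.g.
#'   `c(cens = 0, progression = 1, death = 2)`).
#' @param delimiter `","`, `"\t"`, or `NULL` to auto-detect.
#' @return A [binary_data()] or [surv_data()] sample with predictors
#'   attached when requested.
#' @export
read_sample <- function(path, mapping, delimiter = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(delimiter)) delimiter <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  used <- unique(c(mapping$outcome, mapping$time, mapping$status,
                   mapping$predictors))
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop(sprintf("mapped column(s) not in file: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  complete <- stats::complete.cases(df[, used, drop = FALSE])
  if (any(!complete)) {
    message(sprintf("dropped %d row(s) with missing values in mapped columns",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  predictors <- if (length(mapping$predictors)) {
    df[, mapping$predictors, drop = FALSE]
  } else NULL

  if (!is.null(mapping$outcome)) {
    return(binary_data(df[[mapping$outcome]], predictors = predictors))
  }
  if (is.null(mapping$time) || is.null(mapping$status)) {
    stop("mapping must give either 'outcome' or both 'time' and 'status'",
         call. = FALSE)
  }
  time <- df[[mapping$time]]
  if (!is.numeric(time)) stop("time column must be numeric", call. = FALSE)
  status <- df[[mapping$status]]
  if (!is.null(mapping$status_codes)) {
    codes <- mapping$status_codes
    idx <- match(as.character(status), names(codes))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf("status value '%s' at row %d not in declared codes",
                   status[bad], bad), call. = FALSE)
    }
    status <- unname(codes[idx])
  }
  status <- as.integer(status)
  K <- if (!is.null(mapping$n_causes)) as.integer(mapping$n_causes) else NULL
  if (!is.null(K) && any(status > K)) {
    bad <- which(status > K)[1L]
    stop(sprintf("status code %d at row %d exceeds declared number of causes %d",
                 status[bad], bad, K), call. = FALSE)
  }
  surv_data(time, status, n_causes = K, predictors = predictors)
}

#' Write an IPA report as TSV
#'
#' Machine-readable serialization: a commented provenance header followed by
#' one key/value row per quantity, proportions at full precision and IPA
#' additionally in percent.
#'
#' @param report An `"ipa_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ipa_report <- function(report, path) {
  rows <- data.frame(
    key = c("setting",
            if (!is.null(report$horizon)) "horizon",
            if (!is.null(report$cause)) "cause",
            "model_brier", "null_brier", "ipa_percent"),
    value = c(report$setting,
              if (!is.null(report$horizon)) sprintf("%.15g", report$horizon),
              if (!is.null(report$cause)) sprintf("%d", report$cause),
              sprintf("%.15g", report$model_brier),
              sprintf("%.15g", report$null_brier),
              sprintf("%.15g", report$ipa)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run a configured analysis end to end
#'
#' One-call driver tying the modules together, intended for scripted and
#' command-line use. Reads the input table, scores either a supplied
#' predicted-risk column or a model fitted from a predictor specification,
#' and writes the IPA report (plus the drop-one importance table when a
#' specification is given) into the output directory. The `"simulate"`
#' setting runs the discrimination/miscalibration experiment instead.
#'
#' @param config Named list:
#'   \describe{
#'     \item{setting}{`"binary"`, `"survival"`, `"competing-risks"` or
#'       `"simulate"`.}
#'     \item{input}{Input CSV/TSV path (not used by `"simulate"`).}
#'     \item{mapping}{Column mapping for [read_sample()].}
#'     \item{risk_column}{Column holding externally predicted risks
#'       (mutually exclusive with `spec`).}
#'     \item{spec}{A [predictor_spec()] to fit and validate (mutually
#'       exclusive with `risk_column`); data are split into learning and
#'       validation halves unless `validation_input` is given.}
#'     \item{validation_input, validation_mapping}{Optional separate
#'       validation table.}
#'     \item{horizon}{Prediction horizon (censored settings).}
#'     \item{cause}{Target cause (competing risks; default 1).}
#'     \item{null_source}{`"validation"` (default) or `"learning"`.}
#'     \item{out_dir}{Output directory (created if missing).}
#'     \item{seed}{Seed for the data split / simulation.}
#'     \item{repetitions, log_or_points}{`"simulate"` only; experiment size.}
#'   }
#' @return Invisibly, a list of the objects produced (report, importance
#'   table or simulation result) and the files written.
#' @export
ipa_run <- function(config) {
  setting <- match.arg(config$setting,
                       c("binary", "survival", "competing-risks", "simulate"))
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  written <- character()

  if (setting == "simulate") {
    cfg <- fig2_config(
      repetitions = if (is.null(config$repetitions)) 50L
                    else config$repetitions,
      log_or_grid = seq(-1, 1, length.out =
                          if (is.null(config$log_or_points)) 21L
                          else config$log_or_points),
      seed = seed)
    res <- run_fig2(cfg)
    f1 <- file.path(out_dir, "simulation_results.tsv")
    f2 <- file.path(out_dir, "simulation_summary.tsv")
    utils::write.table(format(res$results, digits = 15, trim = TRUE), f1,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(res$summary, digits = 15, trim = TRUE), f2,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(result = res, files = c(f1, f2))))
  }

  cause <- if (is.null(config$cause)) 1L else as.integer(config$cause)
  horizon <- config$horizon
  sample <- read_sample(config$input, config$mapping)
  if (setting == "binary" && !inherits(sample, "binary_data")) {
    stop("binary setting needs an 'outcome' column mapping", call. = FALSE)
  }
  if (setting != "binary" && !inherits(sample, "surv_data")) {
    stop("censored settings need 'time' and 'status' column mappings",
         call. = FALSE)
  }

  if (!is.null(config$risk_column)) {
    if (!is.null(config$spec)) {
      stop("give either 'risk_column' or 'spec', not both", call. = FALSE)
    }
    df <- utils::read.table(config$input, header = TRUE,
                            sep = detect_sep(config$input),
                            check.names = FALSE)
    risk <- as.numeric(df[[config$risk_column]])
    report <- ipa_report(sample, risk, horizon, cause)
    f <- file.path(out_dir, "ipa_report.tsv")
    write_ipa_report(report, f)
    return(invisible(list(report = report, files = f)))
  }

  if (is.null(config$spec)) {
    stop("give 'risk_column' or a predictor 'spec'", call. = FALSE)
  }
  if (!is.null(config$validation_input)) {
    learn <- sample
    valid <- read_sample(config$validation_input,
                         if (is.null(config$validation_mapping))
                           config$mapping else config$validation_mapping)
  } else {
    set.seed(seed)
    n <- n_subjects(sample)
    idx <- sample.int(n, size = floor(n / 2))
    learn <- subset_sample(sample, idx)
    valid <- subset_sample(sample, setdiff(seq_len(n), idx))
  }
  null_source <- if (is.null(config$null_source)) "validation"
                 else config$null_source
  imp <- drop_one_ipa(learn, valid, config$spec, horizon = horizon,
                      cause = cause, null_source = null_source)
  f1 <- file.path(out_dir, "ipa_report.tsv")
  f2 <- file.path(out_dir, "importance.tsv")
  write_ipa_report(imp$full, f1)
  write_importance(imp, f2)
  m <- fit_setting_model(learn, config$spec, cause, NULL)
  f3 <- file.path(out_dir, "model_summary.tsv")
  ms <- if (m$family == "cause-specific-cox") {
    do.call(rbind, lapply(seq_len(m$n_causes), function(k) {
      cbind(cause = k, model_summary(m$fits[[k]]))
    }))
  } else model_summary(m)
  utils::write.table(format(ms, digits = 15, trim = TRUE), f3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(report = imp$full, importance = imp, model = m,
                 files = c(f1, f2, f3)))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

# Row subset of a sample, keeping predictors aligned.
subset_sample <- function(x, idx) {
  if (inherits(x, "binary_data")) {
    binary_data(x$outcome[idx],
                predictors = if (is.null(x$predictors)) NULL
                             else x$predictors[idx, , drop = FALSE])
  } else {
    surv_data(x$time[idx], x$status[idx], n_causes = x$n_causes,
              predictors = if (is.null(x$predictors)) NULL
                           else x$predictors[idx, , drop = FALSE])
  }
}
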