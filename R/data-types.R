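#' Right-censored outcome data
#'
#' Container for subject-level time-to-event data with right censoring and,
#' optionally, competing causes of failure. Status codes follow the usual
#' convention: `0` marks a censored observation, codes `1..K` mark an event of
#' the corresponding cause.
#'
#' @param time Numeric vector of positive, finite follow-up times.
#' @param status Integer vector of status codes in `{0, ..., n_causes}`.
#' @param n_causes Number of competing causes `K >= 1`. Defaults to the
#'   largest status code observed (at least 1).
#' @param predictors Optional `data.frame` of subject-level covariates with
#'   one row per subject.
#' @return An object of class `"surv_data"`: a list with elements `time`,
#'   `status`, `n_causes` and (possibly `NULL`) `predictors`.
#' @examples
#' d <- surv_data(time = c(1, 2, 3), status = c(1, 0, 2))
#' d$n_causes
#' @seealso [binary_data()], [kaplan_meier()], [aalen_johansen()]
#' @export
surv_data <- function(time, status, n_causes = NULL, predictors = NULL) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) == 0L) {
    stop("empty sample: at least one subject is required", call. = FALSE)
  }
  if (length(time) != length(status)) {
    stop("'time' and 'status' must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(status)) {
    stop("'time' and 'status' must not contain missing values", call. = FALSE)
  }
  if (any(time <= 0) || any(!is.finite(time))) {
    stop("all follow-up times must be positive and finite", call. = FALSE)
  }
  if (is.null(n_causes)) {
    n_causes <- max(1L, max(status))
  }
  n_causes <- as.integer(n_causes)
  if (n_causes < 1L) stop("'n_causes' must be at least 1", call. = FALSE)
  if (any(status < 0L) || any(status > n_causes)) {
    bad <- which(status < 0L | status > n_causes)[1L]
    stop(sprintf("status code %d at row %d outside {0,...,%d}",
                 status[bad], bad, n_causes), call. = FALSE)
  }
  if (!is.null(predictors)) {
    predictors <- as.data.frame(predictors)
    if (nrow(predictors) != length(time)) {
      stop("'predictors' must have one row per subject", call. = FALSE)
    }
  }
  structure(
    list(time = time, status = status, n_causes = n_causes,
         predictors = predictors),
    class = "surv_data"
  )
}

#' Binary outcome data
#'
#' Container for subject-level 0/1 outcomes, optionally with covariates.
#'
#' @param outcome Vector of 0/1 outcomes (logicals are coerced).
#' @param predictors Optional `data.frame` of covariates, one row per subject.
#' @return An object of class `"binary_data"` with elements `outcome` and
#'   `predictors`.
#' @examples
#' b <- binary_data(c(1, 1, 0, 0, 0))
#' mean(b$outcome)
#' @export
binary_data <- function(outcome, predictors = NULL) {
  outcome <- as.numeric(outcome)
  if (length(outcome) == 0L) {
    stop("empty sample: at least one subject is required", call. = FALSE)
  }
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    stop("outcomes must be 0 or 1 with no missing values", call. = FALSE)
  }
  if (!is.null(predictors)) {
    predictors <- as.data.frame(predictors)
    if (nrow(predictors) != length(outcome)) {
      stop("'predictors' must have one row per subject", call. = FALSE)
    }
  }
  structure(list(outcome = outcome, predictors = predictors),
            class = "binary_data")
}

#' @export
print.surv_data <- function(x, ...) {
  n <- length(x$time)
  tab <- table(factor(x$status, levels = 0:x$n_causes))
  cat(sprintf("Right-censored sample: %d subjects, %d cause(s)\n",
              n, x$n_causes))
  cat(sprintf("  censored: %d; events by cause: %s\n", tab[[1L]],
              paste(sprintf("%s=%d", names(tab)[-1L], as.integer(tab[-1L])),
                    collapse = ", ")))
  if (!is.null(x$predictors)) {
    cat(sprintf("  predictors: %s\n",
                paste(names(x$predictors), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.binary_data <- function(x, ...) {
  cat(sprintf("Binary sample: %d subjects, prevalence %.3f\n",
              length(x$outcome), mean(x$outcome)))
  if (!is.null(x$predictors)) {
    cat(sprintf("  predictors: %s\n",
                paste(names(x$predictors), collapse = ", ")))
  }
  invisible(x)
}

# Validate a vector of predicted risks against a sample size.
check_risks <- function(risk, n, what = "risk") {
  risk <- as.numeric(risk)
  if (length(risk) != n) {
    stop(sprintf("'%s' must have length %d (one prediction per subject), got %d",
                 what, n, length(risk)), call. = FALSE)
  }
  if (anyNA(risk) || any(risk < 0) || any(risk > 1)) {
    stop(sprintf("'%s' must lie in [0, 1] with no missing values", what),
         call. = FALSE)
  }
  risk
}

n_subjects <- function(x) {
  if (inherits(x, "binary_data")) length(x$outcome) else length(x$time)
}
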