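#' Declare a continuous predictor
#'
#' @param name Column name in the predictor data.
#' @param transform `"identity"` or `"log2"` (for variables reported on a
#'   per-twofold scale).
#' @param scale Divisor applied after the transform, so effects are reported
#'   per `scale` units (e.g. `scale = 5` for per-5-year age effects).
#' @return A predictor descriptor for [predictor_spec()].
#' @export
continuous_var <- function(name, transform = c("identity", "log2"),
                           scale = 1) {
  transform <- match.arg(transform)
  stopifnot(is.character(name), length(name) == 1L, scale > 0)
  structure(list(name = name, kind = "continuous", transform = transform,
                 scale = scale), class = "predictor_var")
}

#' Declare a categorical predictor
#'
#' @param name Column name in the predictor data.
#' @param reference Reference level; defaults to the first observed level.
#' @return A predictor descriptor for [predictor_spec()].
#' @export
categorical_var <- function(name, reference = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, kind = "categorical", reference = reference),
            class = "predictor_var")
}

#' Predictor specification
#'
#' Declares which covariates enter a model, how continuous variables are
#' transformed and scaled, and which level of each categorical variable is
#' the reference. Categorical variables are treated as indivisible blocks:
#' all their indicator columns are dropped together in the drop-one analysis.
#'
#' @param ... [continuous_var()] / [categorical_var()] descriptors, or bare
#'   character names (treated as untransformed continuous variables).
#' @return An object of class `"predictor_spec"`.
#' @examples
#' spec <- predictor_spec(
#'   continuous_var("age", scale = 5),
#'   continuous_var("psa_density", transform = "log2"),
#'   categorical_var("ct_stage", reference = "cT1")
#' )
#' @export
predictor_spec <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1L]]) &&
      !inherits(vars[[1L]], "predictor_var")) {
    vars <- vars[[1L]]
  }
  vars <- lapply(vars, function(v) {
    if (is.character(v)) continuous_var(v) else v
  })
  if (!all(vapply(vars, inherits, logical(1), "predictor_var"))) {
    stop("predictors must be continuous_var()/categorical_var() or names",
         call. = FALSE)
  }
  nm <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate predictor names", call. = FALSE)
  structure(list(variables = vars), class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("Predictor spec with %d variable(s):\n", length(x$variables)))
  for (v in x$variables) {
    extra <- if (v$kind == "continuous") {
      sprintf(" [%s%s]", v$transform,
              if (v$scale != 1) sprintf(", per %g units", v$scale) else "")
    } else {
      sprintf(" [categorical%s]",
              if (!is.null(v$reference)) paste0(", ref ", v$reference) else "")
    }
    cat(sprintf("  %s (%s)%s\n", v$name, v$kind, extra))
  }
  invisible(x)
}

#' Names of the variables in a predictor specification
#' @param spec A [predictor_spec()].
#' @return Character vector of variable names, in declaration order.
#' @export
spec_names <- function(spec) {
  vapply(spec$variables, `[[`, character(1), "name")
}

# Drop one named variable (whole categorical block) from a spec.
spec_drop <- function(spec, name) {
  keep <- spec$variables[spec_names(spec) != name]
  structure(list(variables = keep), class = "predictor_spec")
}

# Build the transformed model data.frame declared by a spec. Continuous
# variables are transformed and rescaled; categorical variables become
# factors with the declared reference level first.
spec_frame <- function(spec, data) {
  data <- as.data.frame(data)
  out <- list()
  for (v in spec$variables) {
    if (!v$name %in% names(data)) {
      stop(sprintf("predictor '%s' not found in the data", v$name),
           call. = FALSE)
    }
    col <- data[[v$name]]
    if (v$kind == "continuous") {
      col <- as.numeric(col)
      if (v$transform == "log2") {
        if (any(col <= 0)) {
          stop(sprintf("'%s': log2 transform needs positive values", v$name),
               call. = FALSE)
        }
        col <- log2(col)
      }
      col <- col / v$scale
    } else {
      col <- as.factor(col)
      if (!is.null(v$reference)) {
        if (!v$reference %in% levels(col)) {
          stop(sprintf("'%s': reference level '%s' not observed",
                       v$name, v$reference), call. = FALSE)
        }
        col <- stats::relevel(col, ref = v$reference)
      }
      if (nlevels(droplevels(col)) < 2L) {
        stop(sprintf("'%s': categorical variable needs >= 2 observed levels",
                     v$name), call. = FALSE)
      }
    }
    out[[v$name]] <- col
  }
  if (!length(out)) {
    return(as.data.frame(matrix(nrow = nrow(data), ncol = 0)))
  }
  as.data.frame(out, optional = TRUE)
}

spec_formula <- function(spec, lhs = NULL) {
  rhs <- if (length(spec$variables)) {
    paste(sprintf("`%s`", spec_names(spec)), collapse = " + ")
  } else "1"
  stats::as.formula(paste(if (is.null(lhs)) "" else lhs, "~", rhs))
}

#' Fit a logistic regression risk model
#'
#' Maximum-likelihood logistic regression via [stats::glm()] on the design
#' declared by a [predictor_spec()]. Separation or failed convergence raises
#' an error rather than returning a silently unstable fit.
#'
#' @param x A [binary_data()] sample carrying predictors.
#' @param spec A [predictor_spec()]; an empty spec fits the intercept-only
#'   (null) model.
#' @return An object of class `"ipa_model"` with `family = "logistic"`.
#' @export
fit_logistic <- function(x, spec = predictor_spec()) {
  stopifnot(inherits(x, "binary_data"))
  mf <- spec_frame(spec, if (is.null(x$predictors)) {
    data.frame(row.names = seq_along(x$outcome))
  } else x$predictors)
  mf$.y <- x$outcome
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(spec_formula(spec, ".y"), family = stats::binomial(),
               data = mf, control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || sep ||
      any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop(sprintf(
      "logistic fit did not converge (separation suspected after %d iterations; max |coef| = %.2f)",
      fit$iter, max(abs(stats::coef(fit)), na.rm = TRUE)), call. = FALSE)
  }
  structure(list(family = "logistic", spec = spec, fit = fit),
            class = "ipa_model")
}

#' Fit a Cox proportional-hazards risk model
#'
#' Maximum partial-likelihood Cox regression via [survival::coxph()] with
#' Breslow tie handling and Breslow baseline cumulative hazard. With
#' competing causes, a `cause` restriction treats other-cause events as
#' censored; by default all causes are pooled as "event".
#'
#' @param x A [surv_data()] sample carrying predictors.
#' @param spec A [predictor_spec()]; an empty spec gives the Nelson-Aalen
#'   baseline with no covariate effects.
#' @param cause Optional cause restriction.
#' @return An object of class `"ipa_model"` with `family = "cox"`.
#' @export
fit_cox <- function(x, spec = predictor_spec(), cause = NULL) {
  stopifnot(inherits(x, "surv_data"))
  event <- if (is.null(cause)) x$status != 0L else x$status == as.integer(cause)
  if (!any(event)) stop("no events to fit a Cox model on", call. = FALSE)
  mf <- spec_frame(spec, if (is.null(x$predictors)) {
    data.frame(row.names = seq_along(x$time))
  } else x$predictors)
  mf$.time <- x$time
  mf$.event <- as.numeric(event)
  fit <- survival::coxph(spec_formula(spec, "survival::Surv(.time, .event)"),
                         data = mf, ties = "breslow", x = TRUE, y = TRUE,
                         model = TRUE,
                         control = survival::coxph.control(iter.max = 100))
  if (length(stats::coef(fit)) && any(is.na(stats::coef(fit)))) {
    stop("Cox fit produced undefined coefficients (collinear design?)",
         call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  inc <- diff(c(0, bh$hazard))
  keep <- inc > 0
  structure(
    list(family = "cox", spec = spec, fit = fit, cause = cause,
         baseline = list(time = bh$time[keep], increment = inc[keep])),
    class = "ipa_model"
  )
}

#' Fit cause-specific Cox models for competing risks
#'
#' One Cox model per cause, each treating other-cause events as censored.
#' Specifications may differ by cause (for instance a rich model for the
#' cause of interest and an age-only model for the competing cause).
#'
#' @param x A [surv_data()] sample with `n_causes >= 1` and predictors.
#' @param specs A single [predictor_spec()] used for every cause, or a list
#'   of one spec per cause.
#' @return An object of class `"ipa_model"` with `family = "cause-specific-cox"`
#'   and one component fit per cause.
#' @export
fit_cause_specific <- function(x, specs) {
  stopifnot(inherits(x, "surv_data"))
  K <- x$n_causes
  if (inherits(specs, "predictor_spec")) specs <- rep(list(specs), K)
  if (length(specs) != K) {
    stop(sprintf("need one predictor spec per cause (%d)", K), call. = FALSE)
  }
  fits <- lapply(seq_len(K), function(k) {
    if (!any(x$status == k)) {
      stop(sprintf("cause %d has no events", k), call. = FALSE)
    }
    fit_cox(x, specs[[k]], cause = k)
  })
  structure(list(family = "cause-specific-cox", specs = specs, fits = fits,
                 n_causes = K),
            class = "ipa_model")
}

# Linear predictor at covariates x (uncentered, matching the
# centered = FALSE baseline).
model_lp <- function(m, newdata) {
  spec <- if (!is.null(m$spec)) m$spec else NULL
  if (!length(spec$variables)) return(rep(0, nrow(as.data.frame(newdata))))
  mf <- spec_frame(spec, newdata)
  X <- stats::model.matrix(spec_formula(spec), data = mf)
  beta <- stats::coef(m$fit)
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Predict absolute risk at a horizon
#'
#' Horizon-specific predicted risk of the target cause for new subjects.
#' For logistic models this is the fitted probability (the horizon is fixed
#' by the outcome definition). For Cox models the discrete product-limit
#' form is used: `1 - prod(1 - exp(xb) dH0(u))` over event times `u <= t`,
#' so a covariate-free fit reproduces `1 - KM` exactly.
#' For cause-specific Cox models the cause-specific hazards are combined by
#' the Benichou-Gail formula: the risk of cause k by t accumulates
#' `S(u- | x) dLambda_k(u | x)` over event times `u <= t`, where `S(.|x)` is
#' the discrete product-limit over the all-cause hazard increments. With
#' empty specifications this reproduces the Aalen-Johansen estimator
#' exactly. Horizons beyond the baseline support reuse the last value, with
#' a warning.
#'
#' @param m An `"ipa_model"` from [fit_logistic()], [fit_cox()] or
#'   [fit_cause_specific()].
#' @param newdata `data.frame` of covariates for the subjects to predict.
#' @param horizon Numeric vector of prediction horizons (ignored for
#'   logistic models).
#' @param cause Target cause for cause-specific models (default 1).
#' @return A matrix of risks in `[0, 1]`, subjects by horizons; a vector if
#'   a single horizon is given.
#' @export
predict_absolute_risk <- function(m, newdata, horizon = NULL, cause = 1L) {
  stopifnot(inherits(m, "ipa_model"))
  newdata <- as.data.frame(newdata)
  if (m$family == "logistic") {
    mf <- spec_frame(m$spec, newdata)
    return(as.numeric(stats::predict(m$fit, newdata = mf, type = "response")))
  }
  if (is.null(horizon)) {
    stop("'horizon' is required for time-to-event models", call. = FALSE)
  }
  if (m$family == "cox") {
    lp <- model_lp(m, newdata)
    if (any(horizon > max(c(0, m$baseline$time)))) {
      warning("horizon beyond baseline-hazard support; using last value",
              call. = FALSE)
    }
    idx <- findInterval(horizon, m$baseline$time)
    out <- matrix(0, length(lp), length(horizon))
    for (i in seq_along(lp)) {
      dh <- pmin(exp(lp[i]) * m$baseline$increment, 1)
      surv <- cumprod(1 - dh)
      out[i, ] <- 1 - c(1, surv)[idx + 1L]
    }
  } else {
    out <- bg_absolute_risk(m, newdata, horizon, cause)
  }
  out <- pmin(pmax(out, 0), 1)
  if (length(horizon) == 1L) as.numeric(out) else out
}

# Benichou-Gail absolute risk from cause-specific Cox fits, in the discrete
# product-limit form: S(u-|x) = prod_{v<u} (1 - sum_k dLambda_k(v|x)),
# F_k(t|x) = sum_{u<=t} S(u-|x) dLambda_k(u|x).
bg_absolute_risk <- function(m, newdata, horizon, cause) {
  cause <- as.integer(cause)
  if (cause < 1L || cause > m$n_causes) {
    stop(sprintf("'cause' must be in 1..%d", m$n_causes), call. = FALSE)
  }
  times <- sort(unique(unlist(lapply(m$fits, function(f) f$baseline$time))))
  if (any(horizon > max(c(0, times)))) {
    warning("horizon beyond baseline-hazard support; using last value",
            call. = FALSE)
  }
  # per-cause baseline increments aligned on the merged event-time grid
  dH0 <- vapply(m$fits, function(f) {
    inc <- numeric(length(times))
    inc[match(f$baseline$time, times)] <- f$baseline$increment
    inc
  }, numeric(length(times)))
  dH0 <- matrix(dH0, nrow = length(times))
  lp <- vapply(m$fits, function(f) model_lp(f, newdata),
               numeric(nrow(newdata)))
  lp <- matrix(lp, nrow = nrow(newdata))
  n <- nrow(newdata)
  out <- matrix(0, n, length(horizon))
  for (i in seq_len(n)) {
    dH <- sweep(dH0, 2L, exp(lp[i, ]), `*`)      # dLambda_k(u | x_i)
    total <- rowSums(dH)
    s_left <- cumprod(c(1, utils::head(pmax(1 - total, 0), -1L)))
    Fk <- cumsum(s_left * dH[, cause])
    idx <- findInterval(horizon, times)
    out[i, ] <- c(0, Fk)[idx + 1L]
  }
  out
}

#' @export
print.ipa_model <- function(x, ...) {
  cat(sprintf("Fitted %s risk model\n", x$family))
  if (x$family == "cause-specific-cox") {
    for (k in seq_len(x$n_causes)) {
      cat(sprintf("-- cause %d --\n", k))
      print(model_summary(x$fits[[k]]), row.names = FALSE, digits = 3)
    }
  } else {
    print(model_summary(x), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Model coefficient summary
#'
#' Per-coefficient effect estimates on the ratio scale (odds ratios for
#' logistic models, hazard ratios for Cox models) with Wald 95% confidence
#' intervals and p-values.
#'
#' @param m An `"ipa_model"` (for cause-specific fits, summarise each
#'   component fit separately).
#' @return A `data.frame` with columns `variable`, `estimate`, `ratio`,
#'   `lower`, `upper`, `p_value`.
#' @export
model_summary <- function(m) {
  stopifnot(inherits(m, "ipa_model"), m$family != "cause-specific-cox")
  beta <- stats::coef(m$fit)
  if (m$family == "logistic") {
    se <- sqrt(diag(stats::vcov(m$fit)))
  } else {
    se <- sqrt(diag(stats::vcov(m$fit)))
    if (!length(beta)) {
      return(data.frame(variable = character(), estimate = numeric(),
                        ratio = numeric(), lower = numeric(),
                        upper = numeric(), p_value = numeric()))
    }
  }
  z <- beta / se
  data.frame(variable = names(beta), estimate = unname(beta),
             ratio = exp(unname(beta)),
             lower = exp(unname(beta - 1.96 * se)),
             upper = exp(unname(beta + 1.96 * se)),
             p_value = 2 * stats::pnorm(-abs(unname(z))))
}
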