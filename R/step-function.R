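#' Right-continuous step function
#'
#' Piecewise-constant, right-continuous function defined by strictly
#' increasing jump times, the value after each jump, and the value before the
#' first jump. Used throughout the package to carry survival curves S(t),
#' censoring-survival curves G(t) and cumulative-incidence curves F_k(t).
#' Evaluation beyond the last jump returns the last value; validity of a
#' prediction horizon is enforced by the metric functions, not here.
#'
#' @param jump_times Strictly increasing numeric vector (may be empty).
#' @param values Value of the function on `[jump_times[i], jump_times[i+1])`.
#' @param initial_value Value on `[0, jump_times[1])`.
#' @return An object of class `"step_function"`.
#' @examples
#' G <- step_function(c(1, 2), c(0.5, 0.25), initial_value = 1)
#' eval_step(G, 1)            # 0.5 (right-continuous)
#' eval_step(G, 1, "left")    # 1.0 (left limit)
#' @export
step_function <- function(jump_times, values, initial_value) {
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values)) {
    stop("'jump_times' and 'values' must have equal length", call. = FALSE)
  }
  if (length(jump_times) > 1L && any(diff(jump_times) <= 0)) {
    stop("'jump_times' must be strictly increasing", call. = FALSE)
  }
  structure(list(jump_times = jump_times, values = values,
                 initial_value = as.numeric(initial_value)[1L]),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param f A [step_function()].
#' @param t Numeric vector of non-negative evaluation times.
#' @param side `"right"` for the right-continuous value f(t), `"left"` for
#'   the left limit f(t-).
#' @return Numeric vector of values, one per element of `t`.
#' @export
eval_step <- function(f, t, side = c("right", "left")) {
  stopifnot(inherits(f, "step_function"))
  side <- match.arg(side)
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) {
    stop("evaluation times must be non-negative", call. = FALSE)
  }
  idx <- findInterval(t, f$jump_times, left.open = (side == "left"))
  out <- c(f$initial_value, f$values)[idx + 1L]
  out
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("Step function: %d jump(s), initial value %g\n",
              length(x$jump_times), x$initial_value))
  if (length(x$jump_times)) {
    show <- utils::head(data.frame(time = x$jump_times, value = x$values), 8L)
    print(show, row.names = FALSE)
    if (length(x$jump_times) > 8L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.step_function <- function(x, ...) {
  data.frame(time = c(0, x$jump_times),
             value = c(x$initial_value, x$values))
}

#' Write a step function as two-column TSV
#'
#' Serializes the curve as `(time, value)` rows, starting at time 0 with the
#' initial value, suitable for plotting.
#'
#' @param f A [step_function()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_step_function <- function(f, path) {
  utils::write.table(format(as.data.frame(f), digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
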