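#' Softmax probability of choosing one option over another
#'
#' \deqn{p(i \succ j) = \frac{1}{1 + \exp(-\beta (V_i - V_j))}}
#' Because only the value difference enters, adding a constant to both
#' option values leaves every probability unchanged — anticipation carried
#' over from earlier choices adds equally to both options and cancels.
#' Evaluation is saturated, never overflowing, for extreme arguments.
#'
#' @param v_i,v_j signed option values.
#' @param beta non-negative inverse temperature; `beta = 0` gives 0.5.
#' @return probability of choosing option `i`.
#' @export
choice_probability <- function(v_i, v_j, beta) {
  stopifnot(all(beta >= 0))
  plogis(beta * (v_i - v_j))
}

#' Log-likelihood of a choice dataset under a model
#'
#' Sums the log softmax probability of each observed choice. The `choice`
#' column is coded 0 = sooner, 1 = later (the strings `"sooner"`/`"later"`
#' are also accepted). Log-probabilities are computed on the log scale
#' directly (via `plogis(log.p = TRUE)`), so the likelihood is exact even
#' where a probability would underflow.
#'
#' @param data choice dataset: a `choice_pairs` table plus a `choice`
#'   column.
#' @param params parameter vector from [model_params()].
#' @param spec a `dread_model_spec`.
#' @return the summed log-likelihood (finite for finite `beta`).
#' @export
dataset_loglik <- function(data, params, spec) {
  f <- make_loglik_fn(data, spec)
  f(params)
}

choice_sign <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    choice <- as.character(choice)
    stopifnot(all(choice %in% c("sooner", "later")))
    ifelse(choice == "later", 1, -1)
  } else {
    stopifnot(all(choice %in% c(0, 1)))
    ifelse(choice == 1, 1, -1)
  }
}

#' Build a fast log-likelihood closure for repeated evaluation
#'
#' Precomputes the per-record quantities so that optimizers and grid
#' searches can evaluate the likelihood cheaply. The returned function maps
#' a full parameter vector (see [model_params()]) to the summed
#' log-likelihood.
#'
#' @inheritParams dataset_loglik
#' @return `function(params) -> log-likelihood`.
#' @export
make_loglik_fn <- function(data, spec) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("empty choice dataset")
  if (!"choice" %in% names(data)) stop("dataset lacks a 'choice' column")
  sgn <- choice_sign(data$choice)
  pairs <- data
  function(params) {
    dv <- pair_value_diff(pairs, params, spec)
    sum(plogis(params[["beta"]] * dv * sgn, log.p = TRUE))
  }
}

#' Per-record choice probabilities under a model (diagnostic dump)
#'
#' @inheritParams dataset_loglik
#' @param clip probabilities are clipped this far from 0 and 1 for
#'   reporting only; the likelihood itself is never clipped.
#' @return `data` with added columns `value_diff`, `p_later`, `p_choice`.
#' @export
choice_probability_table <- function(data, params, spec, clip = 1e-12) {
  dv <- pair_value_diff(data, params, spec)
  p_later <- clamp(plogis(params[["beta"]] * dv), clip, 1 - clip)
  sgn <- choice_sign(data$choice)
  data$value_diff <- dv
  data$p_later <- p_later
  data$p_choice <- ifelse(sgn > 0, p_later, 1 - p_later)
  data
}
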