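#' Model identifiers for the dread-discounting family
#'
#' The family shares one value equation for a prospective painful option of
#' magnitude `x` delivered after delay `T`:
#' \deqn{V(x, T) = -[\gamma_P^T u(x) + D(x, T)]}
#' where \eqn{u(x)} is the instantaneous disutility of the pain,
#' \eqn{\gamma_P} discounts the pain itself, and \eqn{D(x,T)} is the
#' accumulated dread over the delay. The members differ only in `D`:
#'
#' * `null`: no discounting, no dread (\eqn{V = -u(x)}); free: \eqn{\beta}.
#' * `exp_discount`: exponential discounting only (\eqn{D = 0});
#'   free: \eqn{\beta, \gamma_P}.
#' * `fixed_delay_cost`: exponential discounting plus a fixed anticipation
#'   cost `A` that does not scale with magnitude or delay; free:
#'   \eqn{\beta, \gamma_P, A}.
#' * `constant_dread`: constant instantaneous dread,
#'   \eqn{D = \alpha T u(x)}; free: \eqn{\beta, \gamma_P, \alpha}.
#' * `general_dread`: dread rises exponentially toward the pain at rate
#'   \eqn{\gamma_P} and is itself discounted back to the present at rate
#'   \eqn{\gamma_D}: \eqn{D = \alpha u(x) \sum_{t=0}^{T-1} \gamma_D^t
#'   \gamma_P^{T-t}}; free: \eqn{\beta, \gamma_P, \gamma_D, \alpha}.
#' * `undiscounted_dread`: `general_dread` with \eqn{\gamma_D = 1};
#'   free: \eqn{\beta, \gamma_P, \alpha}.
#' * `restricted_dread`: `general_dread` with \eqn{\gamma_D = \gamma_P},
#'   which collapses to \eqn{D = \alpha T \gamma_P^T u(x)};
#'   free: \eqn{\beta, \gamma_P, \alpha}.
#'
#' @export
DREAD_MODELS <- c("null", "exp_discount", "fixed_delay_cost",
                  "constant_dread", "general_dread",
                  "undiscounted_dread", "restricted_dread")

.default_bounds <- list(
  beta    = c(0, 1000),
  gamma_p = c(0, 1),
  gamma_d = c(0, 1),
  alpha   = c(0, 1),
  A       = c(-50, 0)
)

.free_params <- list(
  null               = "beta",
  exp_discount       = c("beta", "gamma_p"),
  fixed_delay_cost   = c("beta", "gamma_p", "A"),
  constant_dread     = c("beta", "gamma_p", "alpha"),
  undiscounted_dread = c("beta", "gamma_p", "alpha"),
  restricted_dread   = c("beta", "gamma_p", "alpha"),
  general_dread      = c("beta", "gamma_p", "gamma_d", "alpha")
)

#' Construct a model specification
#'
#' @param model_id one of [DREAD_MODELS].
#' @param utility `"linear"` (disutility equals the stated magnitude) or
#'   `"weibull"` (concave disutility fitted from pain ratings, see
#'   [fit_weibull_utility()]).
#' @param wparams a [weibull_utility_params()] object; required when
#'   `utility = "weibull"`.
#' @param delay_cost how the fixed anticipation cost `A` of the
#'   `fixed_delay_cost` model attaches to an option: `"relative"` (default)
#'   adds `A` to the strictly later option of each pair — identifiable even
#'   when both options are delayed, as in the interleaved shock task —
#'   while `"absolute"` adds `A` to any option with positive delay, natural
#'   for designs whose sooner option is "today".
#' @param bounds optional named list overriding the default fitting bounds.
#' @return an object of class `dread_model_spec`.
#' @export
model_spec <- function(model_id,
                       utility = c("linear", "weibull"),
                       wparams = NULL,
                       delay_cost = c("relative", "absolute"),
                       bounds = NULL) {
  model_id <- match.arg(model_id, DREAD_MODELS)
  utility <- match.arg(utility)
  delay_cost <- match.arg(delay_cost)
  if (utility == "weibull" && is.null(wparams))
    stop("`wparams` is required for weibull utility")
  if (!is.null(wparams)) wparams <- validate_wparams(wparams)
  b <- .default_bounds
  if (!is.null(bounds)) {
    stopifnot(all(names(bounds) %in% names(b)))
    for (nm in names(bounds)) {
      stopifnot(length(bounds[[nm]]) == 2L, bounds[[nm]][1] < bounds[[nm]][2])
      b[[nm]] <- as.numeric(bounds[[nm]])
    }
  }
  structure(list(model_id = model_id,
                 utility_kind = utility,
                 wparams = wparams,
                 delay_cost = delay_cost,
                 free = .free_params[[model_id]],
                 bounds = b[.free_params[[model_id]]]),
            class = "dread_model_spec")
}

#' @export
print.dread_model_spec <- function(x, ...) {
  cat("<dread_model_spec>", x$model_id, "\n")
  cat("  utility:", x$utility_kind, "\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  for (nm in x$free)
    cat(sprintf("    %-8s in [%g, %g]\n", nm, x$bounds[[nm]][1], x$bounds[[nm]][2]))
  invisible(x)
}

#' Number of free parameters of a model specification
#' @param spec a `dread_model_spec`.
#' @return integer count.
#' @export
n_free_params <- function(spec) length(spec$free)

#' Construct / validate a parameter set for a model
#'
#' Fills unused parameters with their fixed values (`gamma_p = 1`,
#' `gamma_d = 1`, `alpha = 0`, `A = 0`) so that every model evaluates
#' through the shared value equation.
#'
#' @param spec a `dread_model_spec`.
#' @param ... named parameter values among `beta`, `gamma_p`, `gamma_d`,
#'   `alpha`, `A`.
#' @return named numeric vector of all five parameters.
#' @export
model_params <- function(spec, ...) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.numeric(vals[[1]]) &&
      !is.null(names(vals[[1]])))
    vals <- as.list(vals[[1]])
  unknown <- setdiff(names(vals), names(.default_bounds))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  missing <- setdiff(spec$free, names(vals))
  if (length(missing)) stop("missing free parameters: ", paste(missing, collapse = ", "))
  full <- c(beta = NA_real_, gamma_p = 1, gamma_d = 1, alpha = 0, A = 0)
  for (nm in names(vals)) full[[nm]] <- as.numeric(vals[[nm]])
  for (nm in spec$free) {
    b <- spec$bounds[[nm]]
    if (full[[nm]] < b[1] || full[[nm]] > b[2])
      stop(sprintf("parameter %s = %g outside bounds [%g, %g]", nm, full[[nm]], b[1], b[2]))
  }
  full
}

#' Instantaneous disutility of a pain magnitude
#'
#' Linear utility maps the stated magnitude to itself; Weibull utility is
#' the concave saturating form
#' \eqn{u(x) = r_{max} (1 - \exp(-(x / scale)^{shape}))} estimated from
#' visual-analogue pain ratings.
#'
#' @param magnitude non-negative pain magnitude(s) (expected shocks per
#'   episode, or \% of worst imaginable pain).
#' @param spec a `dread_model_spec` (its `utility_kind` and `wparams` are
#'   used).
#' @return non-negative disutility, same length as `magnitude`.
#' @export
utility <- function(magnitude, spec) {
  stopifnot(all(magnitude >= 0))
  if (spec$utility_kind == "linear") return(as.numeric(magnitude))
  w <- spec$wparams
  w$r_max * (1 - exp(-(magnitude / w$scale)^w$shape))
}

#' Accumulated dread over a delay
#'
#' Dread is summed over the prospective moments `t = 0, ..., T-1` before the
#' pain is consumed at `t = T`; at moment `t` the instantaneous dread is the
#' discounted expectation of the pain, \eqn{\gamma_P^{T-t} u(x)}, itself
#' discounted back to the present by \eqn{\gamma_D^t}. Closed forms are used
#' for the named special cases. `T = 0` gives zero dread for every model.
#'
#' @param magnitude pain magnitude(s).
#' @param delay non-negative integer delay(s) `T`.
#' @param params parameter vector from [model_params()].
#' @param spec a `dread_model_spec`.
#' @return non-negative dread, vectorized over inputs.
#' @export
dread <- function(magnitude, delay, params, spec) {
  stopifnot(all(delay >= 0))
  u <- utility(magnitude, spec)
  T <- as.numeric(delay)
  gp <- params[["gamma_p"]]
  a <- params[["alpha"]]
  switch(spec$model_id,
    null = ,
    exp_discount = ,
    fixed_delay_cost = rep(0, max(length(u), length(T))),
    constant_dread = a * T * u,
    undiscounted_dread = {
      if (gp < 1) a * u * gp * (1 - gp^T) / (1 - gp) else a * u * T
    },
    restricted_dread = a * T * gp^T * u,
    general_dread = {
      gd <- params[["gamma_d"]]
      # sum_{t=0}^{T-1} gd^t gp^(T-t) = gp^T * sum ((gd/gp)^t)
      mapply(function(ui, Ti) {
        if (Ti == 0) return(0)
        t <- 0:(Ti - 1)
        a * ui * sum(gd^t * gp^(Ti - t))
      }, u, T)
    })
}

#' Total aversive value of a prospective painful option
#'
#' Returns the signed (non-positive) value
#' \eqn{V = -[\gamma_P^T u(x) + D(x, T)]} plus, for the `fixed_delay_cost`
#' model, the fixed anticipation cost `A` (non-positive) attached according
#' to the spec's `delay_cost` convention. Under the `null` model
#' \eqn{V = -u(x)} regardless of delay.
#'
#' @param magnitude pain magnitude(s).
#' @param delay delay(s) `T` in task time units.
#' @param params parameter vector from [model_params()].
#' @param spec a `dread_model_spec`.
#' @param is_later logical: is this option the strictly later option of its
#'   pair? Only consulted by the `fixed_delay_cost` model under the
#'   `"relative"` convention.
#' @return signed value(s) `V <= 0`.
#' @export
total_value <- function(magnitude, delay, params, spec, is_later = FALSE) {
  u <- utility(magnitude, spec)
  T <- as.numeric(delay)
  gp <- params[["gamma_p"]]
  v <- switch(spec$model_id,
    null = -u,
    -(gp^T * u + dread(magnitude, delay, params, spec)))
  if (spec$model_id == "fixed_delay_cost") {
    A <- params[["A"]]
    applies <- if (spec$delay_cost == "relative") rep_len(is_later, length(v)) else T > 0
    v <- v + A * as.numeric(applies)
  }
  v
}

#' Value difference (later minus sooner) for each pair of a choice set
#'
#' The workhorse for the likelihood: computes `V(later) - V(sooner)` per row
#' of a choice-pair table (columns `s1_magnitude`, `s2_magnitude`, `d1`,
#' `d2`; option 1 is the sooner option).
#'
#' @param pairs a choice-pair data frame (see [generate_exp1_choice_set()]).
#' @param params parameter vector from [model_params()].
#' @param spec a `dread_model_spec`.
#' @return numeric vector of value differences.
#' @export
pair_value_diff <- function(pairs, params, spec) {
  later <- pairs$d2 > pairs$d1
  v1 <- total_value(pairs$s1_magnitude, pairs$d1, params, spec, is_later = FALSE)
  v2 <- total_value(pairs$s2_magnitude, pairs$d2, params, spec, is_later = later)
  v2 - v1
}

#' Weibull utility parameters
#'
#' @param r_max positive asymptote of the rating curve (rating units).
#' @param scale positive magnitude scale.
#' @param shape positive exponent.
#' @return object of class `weibull_utility_params`.
#' @export
weibull_utility_params <- function(r_max, scale, shape) {
  validate_wparams(list(r_max = r_max, scale = scale, shape = shape))
}

validate_wparams <- function(w) {
  stopifnot(is.list(w), all(c("r_max", "scale", "shape") %in% names(w)))
  w <- w[c("r_max", "scale", "shape")]
  if (!all(vapply(w, function(z) is.finite(z) && z > 0, logical(1))))
    stop("Weibull utility parameters must be finite and positive")
  structure(lapply(w, as.numeric), class = "weibull_utility_params")
}

#' Fit a three-parameter Weibull utility function to pain ratings
#'
#' Least-squares fit of \eqn{r(x) = r_{max}(1 - \exp(-(x/scale)^{shape}))}
#' to visual-analogue ratings over stimulus magnitudes, using a coarse grid
#' of starting values followed by Gauss-Newton refinement (`nls`); the
#' returned fit's residual sum of squares is never worse than the best grid
#' candidate's.
#'
#' @param ratings data frame with columns `magnitude` and `rating`.
#' @return a `weibull_utility_params` object with attributes `rss` and
#'   `flat` (TRUE for the degenerate constant-ratings fallback).
#' @export
fit_weibull_utility <- function(ratings) {
  stopifnot(is.data.frame(ratings), all(c("magnitude", "rating") %in% names(ratings)))
  x <- as.numeric(ratings$magnitude)
  r <- as.numeric(ratings$rating)
  if (length(x) < 4 || length(unique(x)) < 3)
    stop("need at least 4 ratings spanning at least 3 distinct magnitudes")
  if (all(abs(r - r[1]) < .Machine$double.eps^0.5)) {
    warning("all ratings identical: returning flat fit (r_max = mean rating)")
    w <- list(r_max = max(mean(r), 1e-8), scale = 1e-6, shape = 1)
    out <- validate_wparams(w)
    attr(out, "rss") <- 0
    attr(out, "flat") <- TRUE
    return(out)
  }
  rss_of <- function(p) {
    pred <- p[1] * (1 - exp(-(x / p[2])^p[3]))
    sum((r - pred)^2)
  }
  grid <- expand.grid(r_max = max(r) * c(0.8, 1, 1.5, 3),
                      scale = stats::quantile(x, c(0.25, 0.5, 0.75, 1)) * c(1),
                      shape = c(0.5, 1, 1.5, 2.5))
  grid_rss <- apply(grid, 1, rss_of)
  best <- as.numeric(grid[which.min(grid_rss), ])
  # refine from the best grid start, then from a few runners-up
  starts <- grid[order(grid_rss)[seq_len(min(5, nrow(grid)))], , drop = FALSE]
  fit_best <- best
  rss_best <- min(grid_rss)
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    res <- try(suppressWarnings(stats::optim(log(p0), function(lp) rss_of(exp(lp)),
                                             method = "Nelder-Mead",
                                             control = list(reltol = 1e-12, maxit = 2000))),
               silent = TRUE)
    if (!inherits(res, "try-error") && is.finite(res$value) && res$value < rss_best) {
      rss_best <- res$value
      fit_best <- exp(res$par)
    }
  }
  out <- validate_wparams(list(r_max = fit_best[1], scale = fit_best[2], shape = fit_best[3]))
  attr(out, "rss") <- rss_best
  attr(out, "flat") <- FALSE
  out
}
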