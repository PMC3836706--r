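#' Smooth bound-constraint transformation
#'
#' Maps an unbounded simplex search space onto the open parameter box by a
#' per-coordinate logistic: `theta = 0` maps to the midpoint of each bound
#' interval, large `|theta|` approaches the bounds monotonically. The
#' inverse errors on values at or outside the bounds.
#'
#' @param theta unbounded numeric vector (length = number of free
#'   parameters).
#' @param spec a `dread_model_spec` supplying the bounds.
#' @return `bound_transform`: named bounded parameter values;
#'   `bound_transform_inverse`: the unbounded coordinates.
#' @export
bound_transform <- function(theta, spec) {
  stopifnot(length(theta) == length(spec$free), all(is.finite(theta)))
  out <- numeric(length(theta))
  for (i in seq_along(theta)) {
    b <- spec$bounds[[spec$free[i]]]
    out[i] <- b[1] + (b[2] - b[1]) * plogis(theta[i])
  }
  setNames(out, spec$free)
}

#' @rdname bound_transform
#' @param params bounded parameter values (named or in `spec$free` order).
#' @export
bound_transform_inverse <- function(params, spec) {
  if (!is.null(names(params))) params <- params[spec$free]
  stopifnot(length(params) == length(spec$free))
  out <- numeric(length(params))
  for (i in seq_along(params)) {
    b <- spec$bounds[[spec$free[i]]]
    z <- (params[i] - b[1]) / (b[2] - b[1])
    if (!is.finite(z) || z <= 0 || z >= 1)
      stop(sprintf("parameter %s = %g is on or outside its bounds [%g, %g]",
                   spec$free[i], params[i], b[1], b[2]))
    out[i] <- qlogis(z)
  }
  setNames(out, spec$free)
}

#' Fitting configuration
#'
#' Desk-scale defaults: 20 uniform random starts and a single restart of
#' the whole procedure, with simplex tolerances of 1e-6. The full-scale
#' configuration used for definitive fits (100 starts, 1000 restarts) is
#' reachable by argument.
#'
#' @param n_starts random starting points per restart, drawn uniformly
#'   between the parameter bounds.
#' @param n_restarts whole-procedure repeats; the best likelihood across
#'   all restarts is kept.
#' @param reltol relative convergence tolerance passed to the simplex.
#' @param maxit maximum simplex iterations per start.
#' @param bound_tol relative distance from a bound below which an estimate
#'   is flagged as "at bound".
#' @param start_dist `"log"` (default) seeds parameters whose bounds span
#'   more than two orders of magnitude (the inverse temperature)
#'   log-uniformly; `"uniform"` draws every start uniformly between the
#'   bounds, the convention of the full-scale procedure.
#' @param n_scout number of best coarse-grid cells injected as additional
#'   deterministic starts (0 disables the scout pass).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, n_restarts = 1, reltol = 1e-6,
                       maxit = 1000, bound_tol = 1e-4,
                       start_dist = c("log", "uniform"), n_scout = 3) {
  stopifnot(n_starts >= 1, n_restarts >= 1, n_scout >= 0)
  start_dist <- match.arg(start_dist)
  structure(list(n_starts = n_starts, n_restarts = n_restarts,
                 reltol = reltol, maxit = maxit, bound_tol = bound_tol,
                 start_dist = start_dist, n_scout = n_scout),
            class = "fit_config")
}

draw_starts <- function(spec, n, dist = "log") {
  starts <- matrix(NA_real_, n, length(spec$free),
                   dimnames = list(NULL, spec$free))
  for (nm in spec$free) {
    b <- spec$bounds[[nm]]
    wide <- b[1] >= 0 && b[2] / max(b[1], 1e-3) > 100
    if (identical(dist, "log") && wide) {
      # axes spanning orders of magnitude (the inverse temperature) are
      # seeded log-uniformly: uniform draws would put nearly every start in
      # the saturated high-beta region where the likelihood is flat and the
      # simplex stalls
      lo <- max(b[1], 1e-3)
      starts[, nm] <- exp(runif(n, log(lo), log(b[2])))
    } else {
      starts[, nm] <- runif(n, b[1], b[2])
    }
  }
  starts
}

#' Maximum-likelihood fit of one subject's choices under one model
#'
#' Nelder-Mead simplex search on bound-transformed coordinates inside a
#' random multistart overlay: `n_starts` starting points are drawn
#' uniformly between the parameter bounds per restart, and the best
#' log-likelihood across all starts and restarts is returned. Models with a
#' single free parameter (the Null model's `beta`) are optimized by golden
#' section over the bounded interval instead of a 1-D simplex. Estimates
#' landing within `bound_tol` (relative) of a bound are flagged, not
#' silently clamped — e.g. a subject who always chooses the sooner option
#' drives `beta` to its upper bound.
#'
#' @param data choice dataset (pairs plus `choice` column).
#' @param spec a `dread_model_spec`.
#' @param config a [fit_config()].
#' @param seed integer seed; identical `(data, spec, config, seed)` give an
#'   identical fit.
#' @param extra_starts optional matrix of additional bounded starting
#'   points (columns = free parameters).
#' @return object of class `dread_fit`: `params` (full vector), `logLik`,
#'   `n_obs`, `spec`, `converged`, `at_bound` (named logical),
#'   `n_starts_used`, `seed`.
#' @export
fit_subject <- function(data, spec, config = fit_config(), seed = 1,
                        extra_starts = NULL, warm_nested = TRUE) {
  if (nrow(data) == 0) stop("empty choice dataset")
  # every model's optimum can sit at (or approach) the corner where it
  # collapses to a nested, simpler member — e.g. exponential discounting
  # reduces to the null model on its gamma_p = 1 boundary, and the 4-D
  # general dread surface is multimodal with its two 3-parameter special
  # cases as basins. Nested members fit reliably, so their solutions are
  # appended as warm starts (placed just inside the bounds); this also
  # guarantees the fitted likelihood is never materially below a nested
  # model's, which the likelihood-ratio machinery relies on.
  if (isTRUE(warm_nested)) {
    warm <- nested_warm_starts(data, spec, config, seed)
    if (!is.null(warm)) extra_starts <- rbind(extra_starts, warm)
  }
  # scout pass: rank the cells of a coarse log-grid by likelihood and seed
  # the simplex from the best ones — a few hundred vectorized evaluations
  # that keep the multistart out of deceptive corner basins
  if (length(spec$free) >= 2 && (config$n_scout %||% 3) > 0) {
    scout <- scout_starts(data, spec, n_top = config$n_scout %||% 3)
    extra_starts <- rbind(extra_starts, scout)
  }
  ll <- make_loglik_fn(data, spec)
  negll_theta <- function(theta) {
    p <- bound_transform(theta, spec)
    -ll(fill_params(p, spec))
  }
  k <- length(spec$free)
  set.seed(as.integer(seed))

  best_val <- Inf
  best_theta <- NULL
  conv <- FALSE
  n_used <- 0L

  if (k == 1L) {
    b <- spec$bounds[[spec$free]]
    f1 <- function(x) -ll(fill_params(setNames(x, spec$free), spec))
    opt <- optimize(f1, interval = b, tol = config$reltol)
    # golden section can miss a boundary optimum; check the bounds too
    cand_x <- c(opt$minimum, b[1] + 1e-9 * diff(b), b[2] - 1e-9 * diff(b))
    cand_v <- vapply(cand_x, f1, numeric(1))
    j <- which.min(cand_v)
    best_params <- setNames(cand_x[j], spec$free)
    best_val <- cand_v[j]
    conv <- TRUE
    n_used <- 1L
  } else {
    for (r in seq_len(config$n_restarts)) {
      starts <- draw_starts(spec, config$n_starts, config$start_dist %||% "log")
      if (!is.null(extra_starts) && r == 1L)
        starts <- rbind(starts, extra_starts[, spec$free, drop = FALSE])
      for (s in seq_len(nrow(starts))) {
        theta0 <- try(bound_transform_inverse(starts[s, ], spec), silent = TRUE)
        if (inherits(theta0, "try-error")) next
        res <- try(optim(theta0, negll_theta, method = "Nelder-Mead",
                         control = list(reltol = config$reltol,
                                        maxit = config$maxit)),
                   silent = TRUE)
        if (inherits(res, "try-error") || !is.finite(res$value)) next
        n_used <- n_used + 1L
        if (res$value < best_val) {
          best_val <- res$value
          best_theta <- res$par
          conv <- res$convergence == 0
        }
      }
    }
    if (is.null(best_theta))
      stop("all optimization starts failed to evaluate")
    best_params <- bound_transform(best_theta, spec)
  }

  at_bound <- vapply(spec$free, function(nm) {
    b <- spec$bounds[[nm]]
    rel <- (best_params[[nm]] - b[1]) / (b[2] - b[1])
    rel <= config$bound_tol || rel >= 1 - config$bound_tol
  }, logical(1))

  structure(list(params = fill_params(best_params, spec),
                 free_params = best_params,
                 logLik = -best_val,
                 n_obs = nrow(data),
                 spec = spec,
                 converged = conv,
                 at_bound = at_bound,
                 n_starts_used = n_used,
                 seed = as.integer(seed),
                 method = "simplex"),
            class = "dread_fit")
}

# expand a named vector over the free parameters to the full 5-vector
fill_params <- function(p, spec) {
  do.call(model_params, c(list(spec), as.list(p)))
}

# coarse log-grid scout: best few cells of a small exhaustive evaluation,
# used as additional simplex starts
scout_starts <- function(data, spec, n_top = 3, res_other = 8, res_beta = 12) {
  sgn <- choice_sign(data$choice)
  other <- setdiff(spec$free, "beta")
  # unit-interval parameters (discount factors, the dread weight) get
  # logit-spaced points — dense at both ends, where log spacing leaves the
  # near-1 region empty; other axes use the log-scale grid
  axes <- lapply(other, function(nm) {
    b <- spec$bounds[[nm]]
    if (b[1] >= 0 && b[2] <= 1)
      b[1] + (b[2] - b[1]) *
        plogis(seq(qlogis(0.02), qlogis(0.98), length.out = res_other))
    else grid_axis(b, res_other)
  })
  names(axes) <- other
  beta_axis <- grid_axis(spec$bounds[["beta"]], res_beta)
  cells <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  top <- matrix(NA_real_, 0, length(spec$free),
                dimnames = list(NULL, spec$free))
  scores <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    po <- setNames(as.numeric(cells[i, ]), other)
    p <- fill_params(c(beta = 1, po), spec)
    dv <- pair_value_diff(data, p, spec)
    Ls <- colSums(plogis(outer(dv * sgn, beta_axis), log.p = TRUE))
    j <- which.max(Ls)
    top <- rbind(top, c(beta = beta_axis[j], po)[spec$free])
    scores <- c(scores, Ls[j])
  }
  top[order(scores, decreasing = TRUE)[seq_len(min(n_top, nrow(top)))], ,
      drop = FALSE]
}

# warm starting points at the nesting corners, strictly inside the bounds
nested_warm_starts <- function(data, spec, config, seed) {
  eps_g <- 1e-6          # gamma within eps of 1
  eps_a <- 1e-6          # alpha within eps of 0
  fit_nested <- function(model, s) {
    fit_subject(data, model_spec(model), config, seed = s, warm_nested = TRUE)
  }
  ws <- seed_stream(seed, 2)
  rows <- switch(spec$model_id,
    null = NULL,
    exp_discount = {
      f0 <- fit_nested("null", ws[1])
      list(c(beta = f0$free_params[["beta"]], gamma_p = 1 - eps_g))
    },
    fixed_delay_cost = {
      fe <- fit_nested("exp_discount", ws[1])
      list(c(fe$free_params[c("beta", "gamma_p")], A = -1e-4))
    },
    constant_dread = ,
    undiscounted_dread = ,
    restricted_dread = {
      fe <- fit_nested("exp_discount", ws[1])
      list(c(fe$free_params[c("beta", "gamma_p")], alpha = eps_a))
    },
    general_dread = {
      f_u <- fit_nested("undiscounted_dread", ws[1])
      f_r <- fit_nested("restricted_dread", ws[2])
      list(c(f_u$free_params[c("beta", "gamma_p")], gamma_d = 1 - eps_g,
             alpha = f_u$free_params[["alpha"]]),
           c(f_r$free_params[c("beta", "gamma_p")],
             gamma_d = unname(f_r$free_params[["gamma_p"]]),
             alpha = f_r$free_params[["alpha"]]))
    })
  if (is.null(rows)) return(NULL)
  warm <- do.call(rbind, rows)
  colnames(warm) <- spec$free
  # keep strictly interior so the bound transform stays finite
  for (j in seq_len(ncol(warm))) {
    b <- spec$bounds[[spec$free[j]]]
    pad <- 1e-7 * (b[2] - b[1])
    warm[, j] <- pmin(pmax(warm[, j], b[1] + pad), b[2] - pad)
  }
  warm
}

#' @export
print.dread_fit <- function(x, ...) {
  cat("<dread_fit>", x$spec$model_id, sprintf("(%s)\n", x$method))
  cat("  logLik:", format(x$logLik, digits = 8), " n:", x$n_obs, "\n")
  p <- x$free_params
  flags <- ifelse(x$at_bound[names(p)], " [at bound]", "")
  for (nm in names(p))
    cat(sprintf("  %-8s %.6g%s\n", nm, p[[nm]], flags[nm]))
  invisible(x)
}

# log-spaced grid axis between bounds; bounds at zero (or negative lower
# bounds for the cost parameter A) are floored at 1e-3 of the interval's
# magnitude so a log scale is defined.
grid_axis <- function(b, resolution) {
  lo <- b[1]; hi <- b[2]
  if (lo >= 0) {
    floor_ <- max(lo, 1e-3)
    exp(seq(log(floor_), log(hi), length.out = resolution))
  } else {
    # negative interval [lo, 0]: log scale on the magnitude
    -rev(exp(seq(log(1e-3), log(-lo), length.out = resolution)))
  }
}

#' Exhaustive log-scale grid search of the likelihood surface
#'
#' Evaluates the likelihood on a per-parameter log-spaced grid between the
#' bounds, then (optionally) refines at ten times the resolution in a
#' window of one coarse step around the grid optimum — and around a
#' supplied simplex optimum, enabling the standard cross-check that the two
#' search strategies agree. Restricted by default to models with at most
#' three free parameters. `beta` enters the likelihood only as a multiplier
#' of the value difference, so the `beta` axis is evaluated vectorized for
#' each combination of the remaining parameters; memory stays bounded by
#' one `n_choices x resolution` block at a time.
#'
#' @param data choice dataset.
#' @param spec a `dread_model_spec`.
#' @param resolution grid points per parameter (default 100).
#' @param refine perform the 10x local refinement.
#' @param simplex_fit optional `dread_fit` whose neighborhood is also
#'   refined; the result then carries `grid_delta`, the signed difference
#'   `logLik(simplex) - logLik(grid)`.
#' @param allow_high_dim evaluate specs with more than three free
#'   parameters anyway.
#' @return a `dread_fit` (method `"grid"`), with `grid_delta` when
#'   `simplex_fit` was given.
#' @export
grid_search <- function(data, spec, resolution = 100, refine = TRUE,
                        simplex_fit = NULL, allow_high_dim = FALSE) {
  k <- length(spec$free)
  if (k > 3 && !allow_high_dim)
    stop("grid search is restricted to models with <= 3 free parameters; ",
         "set allow_high_dim = TRUE to override")
  ll <- make_loglik_fn(data, spec)
  sgn <- choice_sign(data$choice)

  axes <- lapply(spec$free, function(nm) grid_axis(spec$bounds[[nm]], resolution))
  names(axes) <- spec$free

  eval_axes <- function(axes) {
    beta_axis <- axes[["beta"]]
    other <- setdiff(names(axes), "beta")
    best <- list(L = -Inf, params = NULL)
    if (length(other) == 0L) {
      for (bta in beta_axis) {
        p <- fill_params(c(beta = bta), spec)
        L <- ll(p)
        if (L > best$L) best <- list(L = L, params = c(beta = bta))
      }
      return(best)
    }
    others_grid <- do.call(expand.grid, c(axes[other], KEEP.OUT.ATTRS = FALSE))
    for (i in seq_len(nrow(others_grid))) {
      po <- setNames(as.numeric(others_grid[i, ]), other)
      p <- fill_params(c(beta = 1, po), spec)
      dv <- pair_value_diff(data, p, spec)
      # log-lik for all betas at once: columns are beta values
      m <- plogis(outer(dv * sgn, beta_axis), log.p = TRUE)
      Ls <- colSums(m)
      j <- which.max(Ls)
      if (Ls[j] > best$L)
        best <- list(L = Ls[j], params = c(beta = beta_axis[j], po))
    }
    best
  }

  best <- eval_axes(axes)

  refine_around <- function(center, best) {
    local_axes <- lapply(spec$free, function(nm) {
      ax <- axes[[nm]]
      x0 <- center[[nm]]
      j <- which.min(abs(ax - x0))
      lo <- ax[max(1L, j - 1L)]
      hi <- ax[min(length(ax), j + 1L)]
      if (lo == hi) return(lo)
      if (lo > 0) exp(seq(log(lo), log(hi), length.out = resolution))
      else if (hi < 0) -rev(exp(seq(log(-hi), log(-lo), length.out = resolution)))
      else seq(lo, hi, length.out = resolution)
    })
    names(local_axes) <- spec$free
    cand <- eval_axes(local_axes)
    if (cand$L > best$L) cand else best
  }

  if (refine) {
    best <- refine_around(best$params, best)
    if (!is.null(simplex_fit))
      best <- refine_around(simplex_fit$free_params, best)
  }

  out <- structure(list(params = fill_params(best$params, spec),
                        free_params = setNames(as.numeric(best$params[spec$free]),
                                               spec$free),
                        logLik = best$L,
                        n_obs = nrow(data),
                        spec = spec,
                        converged = TRUE,
                        at_bound = setNames(rep(FALSE, k), spec$free),
                        n_starts_used = NA_integer_,
                        seed = NA_integer_,
                        method = "grid"),
                   class = "dread_fit")
  if (!is.null(simplex_fit)) out$grid_delta <- simplex_fit$logLik - best$L
  out
}

#' Curvature check at a candidate maximum-likelihood estimate
#'
#' Central-difference second partial derivatives of the negative
#' log-likelihood with respect to each free parameter. At a proper local
#' maximum of the likelihood all diagonal curvatures are positive; a
#' non-positive curvature flags a saddle or ridge. Parameters sitting on a
#' bound are reported as not applicable.
#'
#' @param data choice dataset.
#' @param spec a `dread_model_spec`.
#' @param params full parameter vector at the candidate optimum.
#' @param h relative step size.
#' @return data frame with columns `param`, `curvature`, `positive`,
#'   `applicable`.
#' @export
verify_curvature <- function(data, spec, params, h = 1e-4) {
  ll <- make_loglik_fn(data, spec)
  f <- function(p) -ll(p)
  f0 <- f(params)
  rows <- lapply(spec$free, function(nm) {
    b <- spec$bounds[[nm]]
    x <- params[[nm]]
    step <- h * max(abs(x), diff(b) * 1e-2)
    if (x - step <= b[1] || x + step >= b[2])
      return(data.frame(param = nm, curvature = NA_real_,
                        positive = NA, applicable = FALSE))
    pp <- pm <- params
    pp[[nm]] <- x + step
    pm[[nm]] <- x - step
    curv <- (f(pp) - 2 * f0 + f(pm)) / step^2
    data.frame(param = nm, curvature = curv, positive = curv > 0,
               applicable = TRUE)
  })
  do.call(rbind, rows)
}
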