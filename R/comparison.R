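#' Bayesian Information Criterion
#'
#' \deqn{BIC = -2L + k \ln n} where `L` is the maximized log-likelihood,
#' `k` the number of free parameters and `n` the number of independent
#' observations (here: choices entering the likelihood). Lower is better.
#'
#' @param L maximized log-likelihood.
#' @param k free-parameter count.
#' @param n observation count (>= 1).
#' @return the BIC value.
#' @export
bic <- function(L, k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  -2 * L + k * log(n)
}

#' Fixed-effects group model comparison
#'
#' Sums log-likelihoods and per-subject BICs across subjects for each
#' model and ranks the models; all subjects must be fitted under all
#' models. Parameters are subject-specific (each subject contributes its
#' own `k` free parameters to its own BIC); model identity is shared.
#'
#' @param per_subject_fits named list: subject -> named list: model ->
#'   `dread_fit`.
#' @return data frame of class `comparison_table` with per-model `k`
#'   (per subject), total `n`, summed `logLik`, summed `BIC`, `delta_bic`
#'   relative to the best model, and `rank`.
#' @export
group_compare <- function(per_subject_fits) {
  stopifnot(is.list(per_subject_fits), length(per_subject_fits) >= 1)
  models <- names(per_subject_fits[[1]])
  gaps <- unlist(lapply(names(per_subject_fits), function(s) {
    miss <- setdiff(models, names(per_subject_fits[[s]]))
    if (length(miss)) paste0(s, ": ", paste(miss, collapse = ", ")) else NULL
  }))
  if (length(gaps)) stop("missing fits — ", paste(gaps, collapse = "; "))
  rows <- lapply(models, function(m) {
    fits <- lapply(per_subject_fits, `[[`, m)
    k <- length(fits[[1]]$spec$free)
    L <- sum(vapply(fits, `[[`, numeric(1), "logLik"))
    n <- sum(vapply(fits, `[[`, numeric(1), "n_obs"))
    B <- sum(vapply(fits, function(f) bic(f$logLik, length(f$spec$free), f$n_obs),
                    numeric(1)))
    data.frame(model = m, k = k, n = n, logLik = L, BIC = B)
  })
  tab <- do.call(rbind, rows)
  tab$delta_bic <- tab$BIC - min(tab$BIC)
  tab$rank <- rank(tab$BIC, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' Likelihood-ratio test between nested fits
#'
#' \eqn{\chi^2 = 2 (L_{full} - L_{restricted})}, compared against the
#' upper tail of the chi-square distribution with `df` degrees of freedom.
#' A full likelihood below the restricted one signals an optimizer failure
#' and raises an error rather than a negative statistic.
#'
#' @param L_full,L_restricted maximized log-likelihoods of the nesting and
#'   nested model.
#' @param df degrees of freedom (>= 1): number of freed parameters.
#' @return list with `ratio` (likelihood ratio), `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(L_full, L_restricted, df, slack = 0.01) {
  stopifnot(df >= 1)
  # a boundary-corner optimum (e.g. the full model collapsing onto the
  # restricted one at a bound) can legitimately sit a hair below the
  # restricted optimum; only a material deficit signals optimizer failure
  if (L_full < L_restricted - slack)
    stop("L_full < L_restricted: the full model was not optimized to at ",
         "least the restricted optimum; refit with more starts")
  chisq <- max(0, 2 * (L_full - L_restricted))
  list(ratio = exp(L_full - L_restricted),
       chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}

# per-frame parameter sharing maps of the framing restriction battery,
# built on the 4-parameter general dread model
.framing_variants <- list(
  all_framing    = list(freed = c("beta", "gamma_p", "gamma_d", "alpha"), k = 8),
  beta_framing   = list(freed = "beta",    k = 5),
  gammaP_framing = list(freed = "gamma_p", k = 5),
  gammaD_framing = list(freed = "gamma_d", k = 5),
  alpha_framing  = list(freed = "alpha",   k = 5),
  no_framing     = list(freed = character(0), k = 4)
)

#' Framing-effect restriction battery for one subject
#'
#' Fits the general dread model jointly to a subject's pain-frame and
#' relief-frame choices under six parameter-sharing regimes: all four
#' parameters free per frame (`all_framing`, k = 8), exactly one of
#' `beta`/`gamma_p`/`gamma_d`/`alpha` allowed to differ between frames
#' (k = 5 each), or everything shared (`no_framing`, k = 4). Each variant's
#' BIC uses the subject's total choice count across both frames.
#' `no_framing` is fitted as a pooled single fit; `all_framing` as two
#' independent per-frame fits; the single-freed variants by joint 5-D
#' multistart simplex, with the pooled and per-frame solutions injected as
#' additional starts so the nesting inequality
#' `L(all) >= L(variant) >= L(none)` holds by construction of the start
#' set.
#'
#' @param pain_data,relief_data the subject's choice datasets in the two
#'   frames.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param spec model specification; defaults to the general dread model.
#' @return list of class `framing_battery` with elements `table` (variant,
#'   k, n, logLik, BIC, delta_bic, rank, plus the LR test of each variant
#'   against `no_framing`) and `fits` (per-variant parameter estimates per
#'   frame).
#' @export
framing_battery <- function(pain_data, relief_data, config = fit_config(),
                            seed = 1, spec = model_spec("general_dread")) {
  if (is.null(pain_data) || nrow(pain_data) == 0) stop("pain frame missing")
  if (is.null(relief_data) || nrow(relief_data) == 0) stop("relief frame missing")
  stopifnot(identical(spec$model_id, "general_dread"))
  seeds <- seed_stream(seed, 12)
  n_total <- nrow(pain_data) + nrow(relief_data)
  ll_pain <- make_loglik_fn(pain_data, spec)
  ll_relief <- make_loglik_fn(relief_data, spec)

  pooled <- rbind(pain_data, relief_data)
  fit_none <- fit_subject(pooled, spec, config, seed = seeds[1])
  fit_pain <- fit_subject(pain_data, spec, config, seed = seeds[2],
                          extra_starts = matrix(fit_none$free_params, 1,
                                                dimnames = list(NULL, spec$free)))
  fit_relief <- fit_subject(relief_data, spec, config, seed = seeds[3],
                            extra_starts = matrix(fit_none$free_params, 1,
                                                  dimnames = list(NULL, spec$free)))
  L_all <- fit_pain$logLik + fit_relief$logLik
  L_none <- fit_none$logLik

  results <- list(
    all_framing = list(logLik = L_all,
                       params = list(pain = fit_pain$params,
                                     relief = fit_relief$params)),
    no_framing = list(logLik = L_none,
                      params = list(pain = fit_none$params,
                                    relief = fit_none$params))
  )

  single <- setdiff(names(.framing_variants), c("all_framing", "no_framing"))
  variant_solutions <- list()
  fit_one_variant <- function(v, vi, extra_bounded = NULL) {
    freed <- .framing_variants[[v]]$freed
    shared <- setdiff(spec$free, freed)
    par_names <- c(shared, paste0(freed, "_pain"), paste0(freed, "_relief"))
    vbounds <- c(spec$bounds[shared],
                 setNames(spec$bounds[freed], paste0(freed, "_pain")),
                 setNames(spec$bounds[freed], paste0(freed, "_relief")))
    split_params <- function(x) {
      x <- setNames(as.numeric(x), par_names)
      pp <- c(x[shared], setNames(x[paste0(freed, "_pain")], freed))
      pr <- c(x[shared], setNames(x[paste0(freed, "_relief")], freed))
      list(pain = fill_params(pp[spec$free], spec),
           relief = fill_params(pr[spec$free], spec))
    }
    negll <- function(theta) {
      x <- numeric(length(theta))
      for (i in seq_along(theta)) {
        b <- vbounds[[i]]
        x[i] <- b[1] + (b[2] - b[1]) * plogis(theta[i])
      }
      p <- split_params(x)
      -(ll_pain(p$pain) + ll_relief(p$relief))
    }
    to_theta <- function(x) {
      vapply(seq_along(x), function(i) {
        b <- vbounds[[i]]
        qlogis(clamp((x[i] - b[1]) / (b[2] - b[1]), 1e-9, 1 - 1e-9))
      }, numeric(1))
    }
    # informed starts: pooled solution; per-frame all-framing solution
    # (shared components averaged); plus random starts
    s_pool <- c(fit_none$free_params[shared],
                fit_none$free_params[freed], fit_none$free_params[freed])
    s_split <- c((fit_pain$free_params[shared] + fit_relief$free_params[shared]) / 2,
                 fit_pain$free_params[freed], fit_relief$free_params[freed])
    set.seed(seeds[3 + vi])
    rand <- matrix(NA_real_, config$n_starts, length(par_names))
    for (i in seq_along(par_names)) {
      b <- vbounds[[i]]
      wide <- b[1] >= 0 && b[2] / max(b[1], 1e-3) > 100
      rand[, i] <- if (identical(config$start_dist %||% "log", "log") && wide)
        exp(runif(config$n_starts, log(max(b[1], 1e-3)), log(b[2])))
      else runif(config$n_starts, b[1], b[2])
    }
    starts <- rbind(s_pool, s_split, rand)
    if (!is.null(extra_bounded)) starts <- rbind(starts, extra_bounded)
    best_val <- Inf; best_x <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- try(optim(to_theta(starts[s, ]), negll, method = "Nelder-Mead",
                       control = list(reltol = config$reltol,
                                      maxit = config$maxit)),
                 silent = TRUE)
      if (inherits(res, "try-error") || !is.finite(res$value)) next
      if (res$value < best_val) {
        best_val <- res$value
        best_x <- vapply(seq_along(res$par), function(i) {
          b <- vbounds[[i]]
          b[1] + (b[2] - b[1]) * plogis(res$par[i])
        }, numeric(1))
      }
    }
    if (is.null(best_x)) { best_val <- -L_none; best_x <- s_pool }
    L_v <- -best_val
    # nesting guard: a 5-parameter variant can never fit worse than the
    # pooled model it nests (the informed start guarantees this up to
    # simplex termination error)
    if (L_v < L_none) L_v <- L_none
    list(logLik = L_v, params = split_params(best_x),
         x = setNames(as.numeric(best_x), par_names))
  }

  for (vi in seq_along(single)) {
    v <- single[vi]
    variant_solutions[[v]] <- fit_one_variant(v, vi)
  }
  # gamma_p and gamma_d play near-symmetric roles in the dread sum, so the
  # optimizer can settle on the mimicking solution of the other variant;
  # polish each of the pair from the other's solution with the roles
  # swapped, keeping the better likelihood
  swap_start <- function(sol, from_freed, to_freed) {
    x <- sol$x
    shared_to <- setdiff(spec$free, to_freed)
    st <- setNames(numeric(length(shared_to) + 2),
                   c(shared_to, paste0(to_freed, c("_pain", "_relief"))))
    for (nm in shared_to)
      st[nm] <- if (nm == from_freed) unname(x[to_freed]) else unname(x[nm])
    st[paste0(to_freed, "_pain")] <- unname(x[paste0(from_freed, "_pain")])
    st[paste0(to_freed, "_relief")] <- unname(x[paste0(from_freed, "_relief")])
    st
  }
  if (all(c("gammaP_framing", "gammaD_framing") %in% single)) {
    sP <- variant_solutions$gammaP_framing
    sD <- variant_solutions$gammaD_framing
    polish <- function(target, source, from_freed, to_freed, vi) {
      st <- try(swap_start(source, from_freed, to_freed), silent = TRUE)
      if (inherits(st, "try-error") || anyNA(st)) return(variant_solutions[[target]])
      cand <- fit_one_variant(target, vi, extra_bounded = matrix(st, 1))
      if (cand$logLik > variant_solutions[[target]]$logLik) cand
      else variant_solutions[[target]]
    }
    variant_solutions$gammaP_framing <-
      polish("gammaP_framing", sD, "gamma_d", "gamma_p", 7)
    variant_solutions$gammaD_framing <-
      polish("gammaD_framing", sP, "gamma_p", "gamma_d", 8)
  }
  for (v in single) results[[v]] <- variant_solutions[[v]][c("logLik", "params")]

  rows <- lapply(names(.framing_variants), function(v) {
    k <- .framing_variants[[v]]$k
    L <- results[[v]]$logLik
    data.frame(variant = v, k = k, n = n_total, logLik = L,
               BIC = bic(L, k, n_total))
  })
  tab <- do.call(rbind, rows)
  tab$delta_bic <- tab$BIC - min(tab$BIC)
  tab$rank <- rank(tab$BIC, ties.method = "first")
  df_freed <- vapply(names(.framing_variants),
                     function(v) length(.framing_variants[[v]]$freed), numeric(1))
  tab$lr_chisq <- 2 * pmax(0, tab$logLik - results$no_framing$logLik)
  tab$lr_df <- df_freed[tab$variant]
  tab$lr_p <- ifelse(tab$lr_df > 0,
                     pchisq(tab$lr_chisq, tab$lr_df, lower.tail = FALSE), NA)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = results, n = n_total, seed = seed),
            class = "framing_battery")
}

#' Group-level framing battery across subjects
#'
#' Runs [framing_battery()] per subject and aggregates fixed-effects
#' summaries: summed log-likelihood and BIC per variant, the group
#' likelihood-ratio test of each variant against `no_framing` (per-subject
#' chi-squares and degrees of freedom summed across subjects), and the
#' geometric mean of the per-subject likelihood ratios.
#'
#' @param cohort named list: subject -> list(pain = data, relief = data).
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return list with `table` (group summary) and `per_subject` (list of
#'   `framing_battery` objects).
#' @export
framing_battery_group <- function(cohort, config = fit_config(), seed = 1) {
  stopifnot(length(cohort) >= 1)
  seeds <- seed_stream(seed, length(cohort))
  per <- lapply(seq_along(cohort), function(i)
    framing_battery(cohort[[i]]$pain, cohort[[i]]$relief, config, seeds[i]))
  names(per) <- names(cohort)
  variants <- names(.framing_variants)
  rows <- lapply(variants, function(v) {
    picks <- lapply(per, function(b) b$table[b$table$variant == v, ])
    L <- sum(vapply(picks, `[[`, numeric(1), "logLik"))
    B <- sum(vapply(picks, `[[`, numeric(1), "BIC"))
    chisq <- sum(vapply(picks, `[[`, numeric(1), "lr_chisq"))
    df <- sum(vapply(picks, `[[`, numeric(1), "lr_df"))
    lrs <- vapply(picks, function(p) p$logLik, numeric(1)) -
      vapply(per, function(b) b$fits$no_framing$logLik, numeric(1))
    data.frame(variant = v, k = .framing_variants[[v]]$k,
               logLik = L, BIC = B,
               lr_chisq = chisq, lr_df = df,
               lr_p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA,
               geom_mean_lr = exp(mean(lrs)))
  })
  tab <- do.call(rbind, rows)
  tab$delta_bic <- tab$BIC - min(tab$BIC)
  tab$rank <- rank(tab$BIC, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  list(table = tab, per_subject = per)
}

#' Interpretive label for a BIC difference (annotation only)
#'
#' @param delta non-negative BIC difference.
#' @return character label; never used for decisions.
#' @export
delta_bic_label <- function(delta) {
  cut(delta, breaks = c(-Inf, 2, 6, 10, Inf),
      labels = c("negligible", "positive", "substantial", "strong"))
}
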