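#' Specify a synthetic agent
#'
#' An agent is a generating model plus parameters (within the fitting
#' bounds), an optional phenotype tag, and optional per-frame parameter
#' overrides used to build framing effects into simulated data.
#'
#' @param model_id one of [DREAD_MODELS].
#' @param params named parameter values for the model's free parameters.
#' @param phenotype optional tag (`"zero"`, `"positive"`, `"negative"`,
#'   `"reversing"`, ...).
#' @param frame_overrides optional named list: frame -> named parameter
#'   overrides (e.g. `list(pain = c(gamma_p = 0.85))`).
#' @param utility,wparams utility kind and Weibull parameters, passed to
#'   [model_spec()].
#' @return list of class `agent_spec`.
#' @export
agent_spec <- function(model_id, params, phenotype = NA_character_,
                       frame_overrides = NULL,
                       utility = "linear", wparams = NULL) {
  spec <- model_spec(model_id, utility = utility, wparams = wparams)
  full <- do.call(model_params, c(list(spec), as.list(params)))
  if (!is.null(frame_overrides)) {
    stopifnot(is.list(frame_overrides))
    for (f in names(frame_overrides)) {
      ov <- frame_overrides[[f]]
      stopifnot(all(names(ov) %in% names(.default_bounds)))
    }
  }
  structure(list(spec = spec, params = full, phenotype = phenotype,
                 frame_overrides = frame_overrides),
            class = "agent_spec")
}

agent_frame_params <- function(agent, frame) {
  p <- agent$params
  ov <- agent$frame_overrides[[frame]]
  if (!is.null(ov)) for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  p
}

#' Simulate an agent's choices over a choice set
#'
#' Each record's choice is drawn from the agent's softmax probability of
#' choosing the later option given its generating model and parameters.
#'
#' @param pairs a `choice_pairs` table.
#' @param agent an [agent_spec()].
#' @param seed integer seed (reproducible).
#' @param frame frame label stamped on the dataset; if the agent carries an
#'   override for this frame it is applied to the generating parameters.
#' @return the pairs table with columns `frame`, `choice` (0 = sooner,
#'   1 = later) and `p_later_true` added.
#' @export
simulate_agent <- function(pairs, agent, seed = 1, frame = "unframed") {
  stopifnot(inherits(agent, "agent_spec"))
  params <- agent_frame_params(agent, frame)
  dv <- pair_value_diff(pairs, params, agent$spec)
  p_later <- plogis(params[["beta"]] * dv)
  set.seed(as.integer(seed))
  out <- pairs
  out$frame <- frame
  out$choice <- rbinom(nrow(pairs), 1, p_later)
  out$p_later_true <- p_later
  out
}

#' Realize Poisson shock counts for delivered episodes
#'
#' The number of shocks in a delivered 5-s train is Poisson with the
#' episode's stated mean; agents choose on the stated mean, so this
#' realization is dataset realism only and never enters the likelihood.
#'
#' @param means expected shock counts.
#' @param seed integer seed.
#' @return integer shock counts.
#' @export
realize_shock_counts <- function(means, seed = 1) {
  set.seed(as.integer(seed))
  stats::rpois(length(means), means)
}

#' Simulate staircase pain ratings from a Weibull curve
#'
#' Emulates the rating phase: shock rate stepped up from the lowest to the
#' highest magnitude and then back down symmetrically, each step rated on
#' the 0-10 visual-analogue scale as the Weibull curve value plus Gaussian
#' noise, clamped to the scale.
#'
#' @param wparams a [weibull_utility_params()].
#' @param noise_sd non-negative rating noise SD.
#' @param magnitudes ascending magnitudes of the staircase (default the
#'   2-14 shocks/5 s ladder in steps of 2).
#' @param seed integer seed.
#' @return data frame: `order`, `direction` (`up`/`down`), `magnitude`,
#'   `rating`.
#' @export
simulate_ratings <- function(wparams, noise_sd = 0.5,
                             magnitudes = seq(2, 14, by = 2), seed = 1) {
  stopifnot(noise_sd >= 0)
  wparams <- validate_wparams(wparams)
  mags <- c(magnitudes, rev(magnitudes))
  true <- wparams$r_max * (1 - exp(-(mags / wparams$scale)^wparams$shape))
  set.seed(as.integer(seed))
  rating <- clamp(true + rnorm(length(mags), 0, noise_sd), 0, 10)
  data.frame(order = seq_along(mags),
             direction = rep(c("up", "down"), each = length(magnitudes)),
             magnitude = mags, rating = rating)
}

#' Specify a synthetic cohort
#'
#' @param agents list of [agent_spec()] objects (one subject each; repeat
#'   an element for multiplicity).
#' @param experiment 1 (two framed blocks sharing one choice set per
#'   subject) or 2 (a single unframed dental choice set).
#' @param design a [design_config()].
#' @param frames frames to simulate for experiment 1.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(agents, experiment = 1, design = design_config(),
                        frames = c("pain", "relief")) {
  stopifnot(length(agents) >= 1,
            all(vapply(agents, inherits, logical(1), "agent_spec")),
            experiment %in% c(1, 2))
  structure(list(agents = agents, experiment = experiment,
                 design = design, frames = frames),
            class = "cohort_spec")
}

#' Simulate a full study with known ground truth
#'
#' For each agent of the cohort: generates a fresh choice set (Experiment 1:
#' one set presented in both frames, as in the task's otherwise-identical
#' framed blocks; Experiment 2: the fixed dental grid), simulates choices
#' per frame, and records the generating parameters in a manifest for
#' recovery scoring.
#'
#' @param cohort a [cohort_spec()].
#' @param seed integer seed; the whole bundle is deterministic given
#'   `(cohort, seed)`.
#' @return list of class `study_bundle`: `data` (one long data frame:
#'   `subject_id`, `frame`, pair columns, `choice`), `manifest` (one row
#'   per subject: phenotype, model, generating parameters incl. per-frame
#'   overrides), `experiment`.
#' @export
simulate_study <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- length(cohort$agents)
  seeds <- seed_stream(seed, 3 * n)
  frames <- if (cohort$experiment == 1) cohort$frames else "unframed"
  data_rows <- list()
  manifest_rows <- list()
  for (i in seq_len(n)) {
    agent <- cohort$agents[[i]]
    sid <- sprintf("s%02d", i)
    pairs <- if (cohort$experiment == 1)
      generate_exp1_choice_set(cohort$design, seed = seeds[3 * i - 2])
    else generate_exp2_choice_set(cohort$design)
    fseeds <- seed_stream(seeds[3 * i - 1], length(frames))
    for (j in seq_along(frames)) {
      d <- simulate_agent(pairs, agent, seed = fseeds[j], frame = frames[j])
      d$subject_id <- sid
      data_rows[[length(data_rows) + 1L]] <- d
    }
    mrow <- data.frame(subject_id = sid,
                       phenotype = agent$phenotype,
                       model_id = agent$spec$model_id,
                       t(agent$params))
    for (f in names(agent$frame_overrides %||% list())) {
      ov <- agent$frame_overrides[[f]]
      for (nm in names(ov)) mrow[[paste(f, nm, sep = "_")]] <- ov[[nm]]
    }
    manifest_rows[[i]] <- mrow
  }
  data <- do.call(rbind, data_rows)
  rownames(data) <- NULL
  all_cols <- unique(unlist(lapply(manifest_rows, names)))
  manifest_rows <- lapply(manifest_rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  })
  manifest <- do.call(rbind, c(manifest_rows, list(make.row.names = FALSE)))
  structure(list(data = data, manifest = manifest,
                 experiment = cohort$experiment, seed = as.integer(seed)),
            class = "study_bundle")
}

#' Agent presets for the four observed time-preference phenotypes
#'
#' Default generating parameters chosen from the model family's geometry:
#' `zero` agents value only magnitude (Null model); `positive` agents
#' discount exponentially; `negative` agents carry saturating undiscounted
#' dread; `reversing` agents carry self-discounted dread whose aversiveness
#' peaks at the intermediate delay \eqn{T^* = -1/\ln\gamma_P - 1/\alpha}
#' (about 18 trials at the defaults) together with a concave (Weibull)
#' subjective pain utility — saturating pain sensitivity compresses
#' magnitude differences, letting the interior maximum of dread dominate
#' choice, which is what makes the dip-then-rise pattern expressible. The
#' default mix (7 zero, 4 positive, 12 negative, 2 reversing of 25) mirrors
#' the observed cohort composition.
#'
#' @param n named counts per phenotype.
#' @param beta softmax inverse temperature shared by all preset agents;
#'   the default is high so choices are near-deterministic.
#' @return list of [agent_spec()]s, length `sum(n)`.
#' @export
phenotype_cohort_preset <- function(n = c(zero = 7, positive = 4,
                                          negative = 12, reversing = 2),
                                    beta = 20) {
  mk <- list(
    zero = function() agent_spec("null", c(beta = beta), "zero"),
    positive = function() agent_spec("exp_discount",
                                     c(beta = beta, gamma_p = 0.9), "positive"),
    negative = function() agent_spec("undiscounted_dread",
                                     c(beta = beta, gamma_p = 0.95, alpha = 0.5),
                                     "negative"),
    reversing = function() agent_spec("restricted_dread",
                                      c(beta = beta, gamma_p = 0.95, alpha = 0.9),
                                      "reversing",
                                      utility = "weibull",
                                      wparams = weibull_utility_params(10, 2, 0.8)))
  agents <- list()
  for (ph in names(n))
    for (i in seq_len(n[[ph]]))
      agents[[length(agents) + 1L]] <- mk[[ph]]()
  agents
}

#' Parameter-recovery experiment: simulate, fit, score
#'
#' For each row of the parameter grid and each of `n_agents` seeded agents:
#' simulates an Experiment-1-style dataset under the model at the row's
#' parameters, fits the same model by [fit_subject()], and scores the
#' estimates against truth.
#'
#' @param model_id generating (and fitted) model.
#' @param param_grid data frame, one row per generating parameter cell
#'   (columns = free parameter names).
#' @param n_agents replicate agents per cell.
#' @param design a [design_config()]; each agent's 95-pair set is presented
#'   in two frames, giving 190 choices by default.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return list: `estimates` (long data frame: cell, agent, parameter,
#'   true, est, error), `summary` (per cell x parameter: bias, RMSE,
#'   median absolute error).
#' @export
recovery_experiment <- function(model_id, param_grid, n_agents = 20,
                                design = design_config(),
                                config = fit_config(), seed = 1) {
  stopifnot(nrow(param_grid) >= 1)
  spec <- model_spec(model_id)
  stopifnot(all(spec$free %in% names(param_grid)))
  seeds <- seed_stream(seed, nrow(param_grid) * n_agents * 3)
  est_rows <- list()
  si <- 0L
  for (cell in seq_len(nrow(param_grid))) {
    pvals <- setNames(as.numeric(param_grid[cell, spec$free]), spec$free)
    agent <- agent_spec(model_id, pvals)
    for (a in seq_len(n_agents)) {
      pairs <- generate_exp1_choice_set(design, seed = seeds[si + 1L])
      d1 <- simulate_agent(pairs, agent, seed = seeds[si + 2L], frame = "pain")
      d2 <- simulate_agent(pairs, agent, seed = seeds[si + 3L], frame = "relief")
      dat <- rbind(d1, d2)
      fit <- fit_subject(dat, spec, config, seed = seeds[si + 3L])
      for (nm in spec$free)
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          cell = cell, agent = a, parameter = nm,
          true = pvals[[nm]], est = fit$free_params[[nm]],
          error = fit$free_params[[nm]] - pvals[[nm]])
      si <- si + 3L
    }
  }
  est <- do.call(rbind, est_rows)
  rownames(est) <- NULL
  agg <- do.call(rbind, lapply(split(est, list(est$cell, est$parameter)), function(g)
    data.frame(cell = g$cell[1], parameter = g$parameter[1],
               true = g$true[1],
               bias = mean(g$error), rmse = sqrt(mean(g$error^2)),
               median_abs_error = stats::median(abs(g$error)))))
  rownames(agg) <- NULL
  list(estimates = est, summary = agg)
}
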