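test_that("the bound transform is a smooth bijection onto the box", {
  spec <- model_spec("undiscounted_dread")
  mid <- bound_transform(c(0, 0, 0), spec)
  expect_equal(unname(mid), c(500, 0.5, 0.5))
  # round trip
  p <- c(beta = 0.25, gamma_p = 0.9, alpha = 0.37)
  expect_equal(bound_transform(bound_transform_inverse(p, spec), spec), p,
               tolerance = 1e-10)
  # monotone approach to the upper bound
  gp <- vapply(seq(0, 30, by = 3),
               function(th) bound_transform(c(0, th, 0), spec)[["gamma_p"]],
               numeric(1))
  expect_true(all(diff(gp) > 0))
  expect_lt(max(gp), 1)
  # inverse of a boundary value errors
  expect_error(bound_transform_inverse(c(beta = 0.2, gamma_p = 1, alpha = 0.5),
                                       spec), "bounds")
})

test_that("subject fits beat a grid oracle and are seed-deterministic", {
  agent <- agent_spec("null", c(beta = 0.4))
  dat <- fix_dataset(agent, seed = 9)
  spec <- model_spec("null")
  fit <- fit_subject(dat, spec, fit_config(), seed = 2)
  # grid oracle: the simplex/golden-section optimum beats every grid point
  betas <- exp(seq(log(1e-3), log(1000), length.out = 400))
  grid_L <- vapply(betas, function(b)
    dataset_loglik(dat, model_params(spec, beta = b), spec), numeric(1))
  expect_gte(fit$logLik, max(grid_L) - 1e-8)
  expect_lt(abs(fit$free_params[["beta"]] - 0.4), 0.15)

  fit2 <- fit_subject(dat, spec, fit_config(), seed = 2)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$logLik, fit2$logLik)
})

test_that("deterministic sooner-choosers drive beta to the flagged bound", {
  cs <- generate_exp1_choice_set(fix_design(24), seed = 5)
  # remove indifferent pairs so sooner is strictly better throughout
  cs <- cs[cs$s1_magnitude != cs$s2_magnitude | cs$d1 != cs$d2, ]
  dat <- cs
  dat$choice <- 0
  spec <- model_spec("undiscounted_dread")
  fit <- fit_subject(dat, spec, fit_config(n_starts = 10), seed = 3)
  expect_true(any(fit$at_bound))
})

test_that("more starts never worsen the best likelihood", {
  agent <- agent_spec("undiscounted_dread",
                      c(beta = 0.25, gamma_p = 0.9, alpha = 0.5))
  dat <- fix_dataset(agent, seed = 13, config = fix_design(40))
  spec <- model_spec("undiscounted_dread")
  L <- vapply(c(2, 6, 14), function(ns)
    fit_subject(dat, spec, fit_config(n_starts = ns), seed = 21)$logLik,
    numeric(1))
  expect_true(all(diff(L) >= -1e-9))
})

test_that("grid search agrees with the simplex on 3-parameter fixtures", {
  for (m in c("constant_dread", "undiscounted_dread", "restricted_dread")) {
    agent <- agent_spec(m, c(beta = 0.25, gamma_p = 0.9, alpha = 0.5))
    dat <- fix_dataset(agent, seed = 31, config = fix_design(28))
    spec <- model_spec(m)
    fit <- fit_subject(dat, spec, fit_config(n_starts = 10), seed = 7)
    g <- grid_search(dat, spec, resolution = 40, refine = TRUE, simplex_fit = fit)
    expect_lt(abs(g$grid_delta), 0.1)
  }
})

test_that("1-D grids hit the analytic optimum and high dims are refused", {
  agent <- agent_spec("null", c(beta = 0.4))
  dat <- fix_dataset(agent, seed = 17)
  spec <- model_spec("null")
  g <- grid_search(dat, spec, resolution = 200, refine = TRUE)
  opt <- optimize(function(b)
    dataset_loglik(dat, model_params(spec, beta = b), spec),
    c(0, 1000), maximum = TRUE, tol = 1e-10)
  expect_equal(g$logLik, opt$objective, tolerance = 1e-4)
  expect_error(grid_search(dat, model_spec("general_dread"), resolution = 5),
               "3 free")
})

test_that("curvature diagnostics separate maxima from flat directions", {
  agent <- agent_spec("undiscounted_dread",
                      c(beta = 0.25, gamma_p = 0.9, alpha = 0.5))
  dat <- fix_dataset(agent, seed = 23)
  spec <- model_spec("undiscounted_dread")
  fit <- fit_subject(dat, spec, fit_config(n_starts = 12), seed = 5)
  curv <- verify_curvature(dat, spec, fit$params)
  expect_true(all(curv$positive[curv$applicable]))

  # away from the optimum the likelihood need not be locally concave:
  # beta far into the saturated regime has vanishing curvature
  p_flat <- fit$params
  p_flat[["beta"]] <- 900
  curv_flat <- verify_curvature(dat, spec, p_flat)
  expect_false(isTRUE(curv_flat$positive[curv_flat$param == "beta"] &&
                      curv_flat$curvature[curv_flat$param == "beta"] > 1e-4))

  # parameters on a bound are not applicable
  p_bound <- fit$params
  p_bound[["alpha"]] <- 1
  curv_b <- verify_curvature(dat, spec, p_bound)
  expect_false(curv_b$applicable[curv_b$param == "alpha"])
})

test_that("parameter recovery over seeded agents brackets the truth", {
  grid <- data.frame(beta = 0.25, gamma_p = 0.9, alpha = 0.5)
  rec <- recovery_experiment("undiscounted_dread", grid, n_agents = 5,
                             config = fit_config(n_starts = 8), seed = 11)
  gp <- rec$estimates[rec$estimates$parameter == "gamma_p", ]
  expect_lte(median(abs(gp$est - gp$true)), 0.1)
  expect_equal(rec$summary$parameter[order(rec$summary$parameter)],
               sort(c("beta", "gamma_p", "alpha")))
})
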