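test_that("utility maps magnitudes as specified for both kinds", {
  lin <- model_spec("null")
  expect_equal(utility(10, lin), 10)
  expect_equal(utility(0, lin), 0)

  w <- model_spec("null", utility = "weibull",
                  wparams = weibull_utility_params(10, 5, 1))
  expect_equal(utility(0, w), 0)
  expect_equal(utility(5, w), 10 * (1 - exp(-1)), tolerance = 1e-12)
  # non-decreasing for both kinds
  xs <- seq(0, 20, by = 0.5)
  expect_true(all(diff(utility(xs, lin)) >= 0))
  expect_true(all(diff(utility(xs, w)) >= 0))
  expect_error(model_spec("null", utility = "weibull"), "wparams")
})

test_that("dread matches the brute-force summation oracle", {
  # frozen derived values, cross-checked by term-by-term summation
  spec_u <- model_spec("undiscounted_dread")
  p_u <- model_params(spec_u, beta = 0.25, gamma_p = 0.9, alpha = 0.5)
  expect_equal(dread(10, 5, p_u, spec_u),
               oracle_dread_sum(10, 5, 0.9, 1, 0.5), tolerance = 1e-12)
  expect_equal(dread(10, 5, p_u, spec_u), 18.42795, tolerance = 1e-5)

  spec_r <- model_spec("restricted_dread")
  p_r <- model_params(spec_r, beta = 0.25, gamma_p = 0.9, alpha = 0.5)
  expect_equal(dread(10, 5, p_r, spec_r),
               oracle_dread_sum(10, 5, 0.9, 0.9, 0.5), tolerance = 1e-12)
  expect_equal(dread(10, 5, p_r, spec_r), 0.5 * 5 * 0.9^5 * 10, tolerance = 1e-12)

  # all models: zero delay means zero dread
  for (m in DREAD_MODELS) {
    s <- model_spec(m)
    args <- list(beta = 0.3, gamma_p = 0.7, gamma_d = 0.7, alpha = 0.7,
                 A = -5)[c("beta", s$free[-1])]
    p <- do.call(model_params, c(list(s), args))
    expect_equal(dread(7, 0, p, s), 0, info = m)
  }
})

test_that("closed forms equal the general dread sum across a full grid", {
  spec_g <- model_spec("general_dread")
  spec_r <- model_spec("restricted_dread")
  spec_u <- model_spec("undiscounted_dread")
  for (gam in c(0.05, 0.3, 0.7, 0.9, 0.99)) {
    for (a in c(0.1, 0.5, 1)) {
      p_g_r <- model_params(spec_g, beta = 1, gamma_p = gam, gamma_d = gam, alpha = a)
      p_g_u <- model_params(spec_g, beta = 1, gamma_p = gam, gamma_d = 1, alpha = a)
      p_r <- model_params(spec_r, beta = 1, gamma_p = gam, alpha = a)
      p_u <- model_params(spec_u, beta = 1, gamma_p = gam, alpha = a)
      for (T in c(0, 1, 7, 30, 60)) {
        x <- 1:14
        expect_equal(dread(x, T, p_r, spec_r), dread(x, T, p_g_r, spec_g),
                     tolerance = 1e-12)
        expect_equal(dread(x, T, p_u, spec_u), dread(x, T, p_g_u, spec_g),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("total value matches the frozen derived examples", {
  n <- model_spec("null")
  expect_equal(total_value(10, 0, model_params(n, beta = 1), n), -10)
  expect_equal(total_value(10, 40, model_params(n, beta = 1), n), -10)

  e <- model_spec("exp_discount")
  pe <- model_params(e, beta = 1, gamma_p = 0.9)
  expect_equal(total_value(10, 5, pe, e), -5.9049, tolerance = 1e-10)

  u <- model_spec("undiscounted_dread")
  pu <- model_params(u, beta = 0.25, gamma_p = 0.9, alpha = 0.5)
  expect_equal(total_value(10, 5, pu, u), -(5.9049 + 18.42795), tolerance = 1e-5)

  expect_error(model_spec("not_a_model"))
})

test_that("fixed delay cost conventions attach A as documented", {
  pairs <- data.frame(s1_magnitude = c(5, 5), s2_magnitude = c(5, 5),
                      d1 = c(0, 3), d2 = c(4, 3))
  rel <- model_spec("fixed_delay_cost", delay_cost = "relative")
  abs_ <- model_spec("fixed_delay_cost", delay_cost = "absolute")
  p <- model_params(rel, beta = 1, gamma_p = 1, A = -2)
  # relative: A only on the strictly later option
  expect_equal(pair_value_diff(pairs, p, rel), c(-2, 0))
  # absolute: A on any delayed option; cancels when both delayed
  expect_equal(pair_value_diff(pairs[1, ], p, abs_), -2)  # sooner is "today"
  expect_equal(pair_value_diff(pairs[2, ], p, abs_), 0)   # both delayed
})

test_that("undiscounted dread aversiveness saturates monotonically", {
  spec <- model_spec("undiscounted_dread")
  for (gam in c(0.7, 0.9, 0.95)) for (a in c(0.2, 0.8)) {
    p <- model_params(spec, beta = 1, gamma_p = gam, alpha = a)
    v <- abs(total_value(10, 0:200, p, spec))
    # per-step change has the constant sign of (alpha*gamma - (1 - gamma)):
    # dread accumulation vs decay of the discounted pain itself
    drift <- sign(a * gam - (1 - gam))
    expect_true(all(drift * diff(v) >= -1e-12))
    bound <- 10 * (1 + a * gam / (1 - gam))
    expect_true(all(v <= bound + 1e-9))
    # saturation limit: the discounted pain term vanishes, dread remains
    expect_equal(v[201], 10 * a * gam / (1 - gam), tolerance = 1e-2)
  }
})

test_that("restricted dread has an interior maximum near the stationary point", {
  spec <- model_spec("restricted_dread")
  for (gam in c(0.85, 0.9, 0.95)) for (a in c(0.3, 0.6, 1)) {
    p <- model_params(spec, beta = 1, gamma_p = gam, alpha = a)
    t_star <- -1 / log(gam) - 1 / a
    if (t_star <= 0) next
    v <- abs(total_value(10, 0:300, p, spec))  # brute-force scan oracle
    expect_lte(abs((which.max(v) - 1) - t_star), 1)
  }
})

test_that("the family nests as documented at boundary parameters", {
  e <- model_spec("exp_discount")
  n <- model_spec("null")
  pe <- model_params(e, beta = 1, gamma_p = 0.85)
  x <- c(3, 8, 12); T <- c(0, 5, 33)
  for (m in c("constant_dread", "undiscounted_dread", "restricted_dread")) {
    s <- model_spec(m)
    p0 <- model_params(s, beta = 1, gamma_p = 0.85, alpha = 0)
    expect_equal(total_value(x, T, p0, s), total_value(x, T, pe, e),
                 tolerance = 1e-12, info = m)
    p1 <- model_params(s, beta = 1, gamma_p = 1, alpha = 0)
    expect_equal(total_value(x, T, p1, s),
                 total_value(x, T, model_params(n, beta = 1), n),
                 tolerance = 1e-12, info = m)
  }
})

test_that("weibull utility fitting recovers noiseless parameters", {
  truth <- weibull_utility_params(9, 8, 1.2)
  mags <- 2:14
  ratings <- data.frame(magnitude = mags,
                        rating = truth$r_max * (1 - exp(-(mags / truth$scale)^truth$shape)))
  fit <- fit_weibull_utility(ratings)
  expect_equal(fit$r_max, 9, tolerance = 1e-3)
  expect_equal(fit$scale, 8, tolerance = 1e-3)
  expect_equal(fit$shape, 1.2, tolerance = 1e-3)
})

test_that("weibull fitting handles degenerate and linear ratings", {
  flat <- data.frame(magnitude = 2:10, rating = 0)
  expect_warning(f0 <- fit_weibull_utility(flat), "flat")
  expect_lt(f0$r_max, 1e-6)
  expect_true(attr(f0, "flat"))

  lin <- data.frame(magnitude = 2:14, rating = 2:14)
  fit <- fit_weibull_utility(lin)
  # at least as good as every candidate on an independent coarse grid
  rss_fit <- attr(fit, "rss")
  grid <- expand.grid(r_max = c(10, 14, 20, 40), scale = c(4, 8, 16, 32),
                      shape = c(0.5, 1, 1.5, 2.5))
  rss_grid <- apply(grid, 1, function(p) {
    pred <- p[1] * (1 - exp(-(lin$magnitude / p[2])^p[3]))
    sum((lin$rating - pred)^2)
  })
  expect_lte(rss_fit, min(rss_grid) + 1e-8)

  expect_error(fit_weibull_utility(data.frame(magnitude = c(1, 2), rating = c(1, 2))))
})
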