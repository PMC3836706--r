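test_that("choice curves summarize proportions per delay bin", {
  cs <- generate_exp1_choice_set(seed = 2)
  all_later <- cs
  all_later$choice <- 1
  cv <- choice_curve(all_later, 1)
  expect_true(all(cv$p_later[cv$populated] == 1))
  expect_equal(sum(cv$n_total), 95)

  # beta = 0: pure coin flips, every bin within 3 binomial SDs of 0.5
  agent <- agent_spec("null", c(beta = 0))
  big <- do.call(rbind, lapply(1:53, function(i)
    simulate_agent(generate_exp1_choice_set(seed = i), agent, seed = 1000 + i)))
  cv0 <- choice_curve(big, 1)
  expect_true(all(abs(cv0$p_later - 0.5) <= 3 * sqrt(0.25 / cv0$n_total)))

  # a strong saturating-dread agent: proportions fall then level off
  neg <- agent_spec("undiscounted_dread", c(beta = 20, gamma_p = 0.95, alpha = 0.5))
  dneg <- do.call(rbind, lapply(1:10, function(i)
    simulate_agent(generate_exp1_choice_set(seed = i), neg, seed = 2000 + i)))
  cvn <- choice_curve(dneg, 1)
  expect_true(all(diff(cvn$p_later) < 0))
  expect_lt(cvn$p_later[4], 0.25)
})

test_that("frame-averaged curves differ from pooled counts when frames differ", {
  cs <- generate_exp1_choice_set(fix_design(40), seed = 3)
  a <- simulate_agent(cs, agent_spec("null", c(beta = 0)), 1, "pain")
  b <- simulate_agent(cs, agent_spec("null", c(beta = 0)), 2, "relief")
  both <- rbind(a, b)
  cv_avg <- choice_curve(both, 1, pool_frames = "average")
  per <- (choice_curve(a, 1)$p_later + choice_curve(b, 1)$p_later) / 2
  expect_equal(cv_avg$p_later, per)
})

test_that("phenotype classification follows the exact-test rules", {
  n <- rep(50, 4)
  # flat at 0.5: zero
  expect_equal(classify_time_preference(curve_from_counts(rep(25, 4), n))$label,
               "zero")
  # monotone fall 0.5 -> 0.1: negative (oracle: adjacent Fisher tests)
  falling <- curve_from_counts(c(25, 18, 10, 5), n)
  expect_equal(classify_time_preference(falling)$label, "negative")
  # fall then rise 0.5 -> 0.1 -> 0.9: reversing
  reversing <- curve_from_counts(c(25, 15, 5, 45), n)
  expect_equal(classify_time_preference(reversing)$label, "reversing")
  # monotone rise: positive
  rising <- curve_from_counts(c(25, 33, 41, 46), n)
  expect_equal(classify_time_preference(rising)$label, "positive")
  # cross-check one Fisher decision against the oracle test directly
  p_or <- fisher.test(matrix(c(15, 35, 5, 45), 2, byrow = TRUE))$p.value
  expect_lt(p_or, 0.05)
  # fewer than two populated bins: unclassifiable
  sparse <- curve_from_counts(c(25, 0, 0, 0), c(50, 0, 0, 0))
  expect_equal(classify_time_preference(sparse)$label, "unclassifiable")
})

test_that("classification depends only on per-bin counts and is exhaustive", {
  cs <- generate_exp1_choice_set(seed = 6)
  agent <- agent_spec("undiscounted_dread", c(beta = 20, gamma_p = 0.95, alpha = 0.5))
  d <- simulate_agent(cs, agent, seed = 4)
  l1 <- classify_time_preference(choice_curve(d, 1))$label
  perm <- d[sample.int(nrow(d)), ]
  l2 <- classify_time_preference(choice_curve(perm, 1))$label
  expect_identical(l1, l2)

  # property: random count tables always get exactly one of the four labels
  set.seed(31)
  labels <- replicate(120, {
    n <- sample(20:60, 4, replace = TRUE)
    k <- rbinom(4, n, runif(4))
    classify_time_preference(curve_from_counts(k, n))$label
  })
  expect_true(all(labels %in% c("zero", "positive", "negative", "reversing")))
})

test_that("framing effect exact test reports direction and p-value", {
  cs <- generate_exp1_choice_set(fix_design(40), seed = 9)
  same <- simulate_agent(cs, agent_spec("null", c(beta = 5)), 3, "pain")
  relief <- same
  relief$frame <- "relief"
  ident <- framing_effect_test(same, relief)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$direction, 0)

  # constructed 95-choice frames at sooner frequencies 0.74 vs 0.67
  mk <- function(n_sooner, n, frame) {
    d <- cs[rep(1, n), ]
    d$choice <- c(rep(0, n_sooner), rep(1, n - n_sooner))
    d$frame <- frame
    d
  }
  res <- framing_effect_test(mk(70, 95, "pain"), mk(64, 95, "relief"))
  oracle <- fisher.test(matrix(c(70, 25, 64, 31), 2, byrow = TRUE))$p.value
  expect_equal(res$p_value, oracle)
  expect_equal(res$direction, 1)
  # reversed direction flags negative
  rev <- framing_effect_test(mk(40, 95, "pain"), mk(80, 95, "relief"))
  expect_equal(rev$direction, -1)
  expect_lt(rev$p_value, 0.05)
})

test_that("exclusion rules remove adapters and maximum dreaders", {
  cs <- generate_exp1_choice_set(fix_design(24), seed = 10)
  frames <- function(choices_pain, choices_relief) {
    p <- cs; p$frame <- "pain"; p$choice <- choices_pain
    r <- cs; r$frame <- "relief"; r$choice <- choices_relief
    rbind(p, r)
  }
  n <- nrow(cs)
  mostly_sooner <- c(rep(0, n - 1), 1)
  cohort <- list(
    ok = list(data = frames(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5)),
              max_rate_rating = 7),
    dreader = list(data = frames(rep(0, n), rbinom(n, 1, 0.4)),
                   max_rate_rating = 8),
    adapted = list(data = frames(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5)),
                   max_rate_rating = 3),
    borderline = list(data = frames(mostly_sooner, mostly_sooner),
                      max_rate_rating = 6))
  out <- apply_exclusions(cohort)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$reason, c("", "max_dreader", "adaptation", ""))
})
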