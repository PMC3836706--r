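test_that("the default shock-task choice set is counterbalanced and binned", {
  cs <- generate_exp1_choice_set(seed = 3)
  expect_s3_class(cs, "choice_pairs")
  expect_equal(nrow(cs), 95)
  n_sooner_larger <- sum(cs$s1_magnitude > cs$s2_magnitude)
  n_later_larger <- sum(cs$s2_magnitude > cs$s1_magnitude)
  expect_lte(abs(n_sooner_larger - n_later_larger), 1)
  expect_setequal(unique(cs$bin), c("zero", "short", "medium", "long"))
  expect_true(all(cs$s1_magnitude >= 3 & cs$s1_magnitude <= 12))
  expect_true(all(cs$s2_magnitude >= 3 & cs$s2_magnitude <= 12))
  expect_true(all(cs$d1 >= 4 & cs$d2 <= 51 & cs$d1 <= cs$d2))
  expect_equal(sum(cs$side_of_sooner == "left"), 48)
  # counterbalance holds within every delay bin, not just overall
  for (b in unique(cs$bin)) {
    sub <- cs[cs$bin == b, ]
    expect_lte(abs(sum(sub$s1_magnitude > sub$s2_magnitude) -
                   sum(sub$s2_magnitude > sub$s1_magnitude)), 1)
  }
})

test_that("tiny and repeated generations behave as specified", {
  cfg2 <- design_config(n_choice_trials = 2,
                        bin_counts = c(zero = 0, short = 2, medium = 0, long = 0))
  cs2 <- generate_exp1_choice_set(cfg2, seed = 1)
  expect_equal(nrow(cs2), 2)
  expect_equal(sum(cs2$s1_magnitude > cs2$s2_magnitude), 1)
  expect_equal(sum(cs2$s2_magnitude > cs2$s1_magnitude), 1)

  # same marginals across seeds, different pairings; identical under one seed
  a <- generate_exp1_choice_set(seed = 11)
  b <- generate_exp1_choice_set(seed = 12)
  expect_equal(sum(a$s1_magnitude > a$s2_magnitude),
               sum(b$s1_magnitude > b$s2_magnitude))
  expect_equal(table(a$bin), table(b$bin))
  expect_false(identical(a[order(a$s1_magnitude, a$s2_magnitude, a$d1, a$d2), -1],
                         b[order(b$s1_magnitude, b$s2_magnitude, b$d1, b$d2), -1]))
  expect_identical(generate_exp1_choice_set(seed = 11), a)
})

test_that("infeasible design configurations raise design errors", {
  bad_delay <- design_config(delay_range = c(4, 10),
                             bin_counts = c(zero = 1, short = 1, medium = 1,
                                            long = 1), n_choice_trials = 4)
  expect_error(generate_exp1_choice_set(bad_delay, seed = 1),
               class = "design_infeasible")
  tight <- design_config(n_choice_trials = 4,
                         bin_counts = c(zero = 0, short = 4, medium = 0, long = 0),
                         magnitude_range = c(5, 5))
  expect_error(generate_exp1_choice_set(tight, seed = 1),
               class = "design_infeasible")
})

test_that("the interleaved schedule satisfies its structural constraints", {
  cs <- generate_exp1_choice_set(seed = 3)
  sch <- generate_exp1_schedule(cs, seed = 5)
  expect_equal(sum(sch$kind == "choice"), 95)
  ch <- sch[sch$kind == "choice", ]
  refs <- unlist(Map(function(a, b) unique(c(a, b)),
                     ch$outcome_slot_1, ch$outcome_slot_2))
  expect_equal(anyDuplicated(refs), 0)        # injective outcome map
  expect_true(max(refs) <= nrow(sch))         # exhaustive bound scan
  # offsets equal the pair delays
  m <- match(ch$pair_id, cs$pair_id)
  expect_equal(ch$outcome_slot_1 - ch$trial_index, cs$d1[m])
  expect_equal(ch$outcome_slot_2 - ch$trial_index, cs$d2[m])
  # no-choice trials thicken toward the end of the run
  first_half <- sch$kind[seq_len(nrow(sch) %/% 2)]
  second_half <- sch$kind[-seq_len(nrow(sch) %/% 2)]
  expect_gt(mean(second_half == "no_choice"), mean(first_half == "no_choice"))
  # determinism
  expect_identical(generate_exp1_schedule(cs, seed = 5), sch)
})

test_that("a single pair schedules its two outcome slots at its delays", {
  cfg <- design_config(n_choice_trials = 1,
                       bin_counts = c(zero = 0, short = 1, medium = 0, long = 0),
                       horizon = 60)
  pair <- generate_exp1_choice_set(cfg, seed = 2)
  pair$d1 <- 4; pair$d2 <- 5
  sch <- generate_exp1_schedule(pair, cfg, seed = 1)
  ch <- sch[sch$kind == "choice", ]
  expect_equal(ch$outcome_slot_1, ch$trial_index + 4)
  expect_equal(ch$outcome_slot_2, ch$trial_index + 5)
  # horizon too small for the pair's later delay
  cfg_small <- design_config(n_choice_trials = 1, horizon = 5,
                             bin_counts = c(zero = 0, short = 1, medium = 0,
                                            long = 0))
  expect_error(generate_exp1_schedule(pair, cfg_small, seed = 1),
               class = "design_infeasible")
})

test_that("the dental choice set implements the stated grid", {
  e2 <- generate_exp2_choice_set()
  expect_equal(nrow(e2), 66)
  expect_true(all(e2$d1 == 0))
  expect_equal(max(e2$d2), 237)
  expect_setequal(unique(c(e2$s1_magnitude, e2$s2_magnitude)),
                  c(60, 55, 51, 46, 37, 16))
  expect_setequal(unique(e2$d2), c(1, 5, 13, 32, 89, 237))
  expect_equal(sum(e2$s1_magnitude > e2$s2_magnitude),
               sum(e2$s2_magnitude > e2$s1_magnitude))
  # every non-60 magnitude faces 60 at every delay in both orders
  for (m in c(55, 51, 46, 37, 16)) for (dd in c(1, 5, 13, 32, 89, 237)) {
    expect_equal(sum(e2$s1_magnitude == 60 & e2$s2_magnitude == m & e2$d2 == dd), 1)
    expect_equal(sum(e2$s1_magnitude == m & e2$s2_magnitude == 60 & e2$d2 == dd), 1)
  }
  no_eq <- generate_exp2_choice_set(design_config(exp2_include_equal = FALSE))
  expect_equal(nrow(no_eq), 60)
})

test_that("delay differences bin deterministically for both experiments", {
  expect_equal(as.character(bin_delay_difference(0, 1)), "zero")
  expect_equal(as.character(bin_delay_difference(c(1, 10), 1)),
               c("short", "short"))
  expect_equal(as.character(bin_delay_difference(15, 1)), "medium")
  expect_equal(as.character(bin_delay_difference(c(20, 21, 47), 1)),
               c("medium", "long", "long"))
  expect_equal(as.character(bin_delay_difference(c(0, 5, 13, 32, 89, 237), 2)),
               c("zero", "short", "medium", "medium", "long", "long"))
  expect_error(bin_delay_difference(-1, 1), "non-negative")
})

test_that("frame display values derive from the objective magnitude", {
  cfg <- design_config()
  expect_equal(frame_display_value(9, "pain", cfg), 7)
  expect_equal(frame_display_value(9, "relief", cfg), 5)
})

test_that("choice tables round-trip through the CSV interchange", {
  cs <- generate_exp1_choice_set(seed = 8)
  path <- tempfile(fileext = ".csv")
  write_choice_csv(cs, path, meta = c(experiment = "1"))
  back <- read_choice_csv(path)
  expect_equal(attr(back, "seed"), 8L)
  expect_equal(back$s1_magnitude, cs$s1_magnitude)
  expect_equal(back$d2, cs$d2)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("choice,x", "maybe,1"), bad)
  expect_error(read_choice_csv(bad), "malformed")
})
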