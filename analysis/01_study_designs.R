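#!/usr/bin/env Rscript
# Construct the two study designs and verify their structural properties:
# the 95-pair interleaved shock-choice set (counterbalanced magnitudes,
# delay-difference bins, outcome schedule) and the dental-appointment grid.
# Writes: results/exp1_choice_set.csv, results/exp1_schedule.csv,
#         results/exp2_choice_set.csv

library(dreadr)
dir.create("results", showWarnings = FALSE)
seed <- 1

cfg <- design_config()
cs <- generate_exp1_choice_set(cfg, seed = seed)
cat(sprintf("Experiment 1: %d choice pairs; sooner-larger %d vs later-larger %d (equal %d)\n",
            nrow(cs), sum(cs$s1_magnitude > cs$s2_magnitude),
            sum(cs$s2_magnitude > cs$s1_magnitude),
            sum(cs$s1_magnitude == cs$s2_magnitude)))
print(table(cs$bin))
write_choice_csv(cs, "results/exp1_choice_set.csv", seed = seed,
                 meta = c(experiment = "1"))

sch <- generate_exp1_schedule(cs, cfg, seed = seed)
ch <- sch[sch$kind == "choice", ]
refs <- unlist(Map(function(a, b) unique(c(a, b)),
                   ch$outcome_slot_1, ch$outcome_slot_2))
cat(sprintf("Schedule: %d trials (%d choice, %d no-choice); outcome slots unique: %s; max slot %d <= %d\n",
            nrow(sch), sum(sch$kind == "choice"), sum(sch$kind == "no_choice"),
            anyDuplicated(refs) == 0, max(refs), nrow(sch)))
thirds <- split(sch$kind == "no_choice", cut(sch$trial_index, 3, labels = c("early", "mid", "late")))
cat("No-choice frequency by run third:",
    paste(sprintf("%s %.2f", names(thirds), vapply(thirds, mean, numeric(1))), collapse = ", "), "\n")
write_choice_csv(sch, "results/exp1_schedule.csv", seed = seed)

e2 <- generate_exp2_choice_set(cfg)
cat(sprintf("Experiment 2: %d pairs, sooner always today, later delays {%s} days, magnitudes {%s}%%\n",
            nrow(e2), paste(sort(unique(e2$d2)), collapse = ", "),
            paste(sort(unique(c(e2$s1_magnitude, e2$s2_magnitude))), collapse = ", ")))
write_choice_csv(e2, "results/exp2_choice_set.csv", seed = seed,
                 meta = c(experiment = "2"))
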