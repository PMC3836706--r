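#' Design configuration for the two choice experiments
#'
#' Experiment 1 is an interleaved shock-choice task: on each of ~190 trials a
#' 5-s shock train is delivered; 95 choice trials each offer two prospective
#' "severe episodes" (3-12 expected shocks, 4-51 trials in the future) and
#' every trial not claimed by a chosen outcome delivers the baseline episode
#' (2 shocks/5 s). Experiment 2 offers hypothetical dental appointments: the
#' sooner appointment is always "today", the later at 1-237 days, magnitudes
#' 16-60 \% of worst imaginable dental pain.
#'
#' @param n_choice_trials number of choice pairs per run (default 95).
#' @param magnitude_range inclusive range of Exp-1 expected shock counts.
#' @param delay_range inclusive range of Exp-1 delays, in trials.
#' @param bin_counts named allocation of the choice pairs across the four
#'   delay-difference bins (`zero`, `short`, `medium`, `long`); must sum to
#'   `n_choice_trials`. Defaults to a near-even split.
#' @param sooner_delay_cap upper cap on the sooner option's delay (trials):
#'   the sooner outcome is near-term (`d1 ~ U[4, min(cap, 51 - diff)]`), so
#'   the delay-difference axis tracks the later outcome's delay — the same
#'   convention as the dental task, whose sooner option is always "today".
#'   The default of 10 keeps short-difference pairs inside the rising limb
#'   of an interior-maximum dread curve, which is what lets a reversing
#'   agent express its dip-then-rise pattern on this design.
#' @param baseline_rate baseline shocks per 5-s episode (display anchor for
#'   the pain frame).
#' @param max_rate maximum shocks per 5-s episode (display anchor for the
#'   relief frame).
#' @param horizon total trials per Exp-1 run (choice + no-choice); default
#'   `2 * n_choice_trials + 15`.
#' @param schedule_retry_cap retry budget for the constrained schedule
#'   sampler.
#' @param exp2_magnitudes,exp2_delays Exp-2 pain magnitudes (\%) and later
#'   delays (days).
#' @param exp2_include_equal include one 60-vs-60 pair per delay.
#' @return a list of class `design_config`.
#' @export
design_config <- function(n_choice_trials = 95,
                          magnitude_range = c(3, 12),
                          delay_range = c(4, 51),
                          bin_counts = NULL,
                          sooner_delay_cap = 10,
                          baseline_rate = 2,
                          max_rate = 14,
                          horizon = NULL,
                          schedule_retry_cap = 10000,
                          exp2_magnitudes = c(60, 55, 51, 46, 37, 16),
                          exp2_delays = c(1, 5, 13, 32, 89, 237),
                          exp2_include_equal = TRUE) {
  stopifnot(n_choice_trials >= 1,
            length(magnitude_range) == 2, magnitude_range[1] <= magnitude_range[2],
            length(delay_range) == 2, delay_range[1] <= delay_range[2])
  if (is.null(bin_counts)) {
    base <- n_choice_trials %/% 4
    extra <- n_choice_trials %% 4
    bin_counts <- c(zero = base, short = base, medium = base, long = base) +
      c(0, as.numeric(seq_len(3) <= extra))
  }
  stopifnot(all(c("zero", "short", "medium", "long") %in% names(bin_counts)),
            sum(bin_counts) == n_choice_trials, all(bin_counts >= 0))
  if (is.null(horizon)) horizon <- 2 * n_choice_trials + 15
  structure(list(n_choice_trials = n_choice_trials,
                 magnitude_range = magnitude_range,
                 delay_range = delay_range,
                 bin_counts = bin_counts[c("zero", "short", "medium", "long")],
                 sooner_delay_cap = sooner_delay_cap,
                 baseline_rate = baseline_rate,
                 max_rate = max_rate,
                 horizon = horizon,
                 schedule_retry_cap = schedule_retry_cap,
                 exp2_magnitudes = exp2_magnitudes,
                 exp2_delays = exp2_delays,
                 exp2_include_equal = exp2_include_equal),
            class = "design_config")
}

# delay-difference windows for the Exp-1 bins, in trials
.exp1_bin_windows <- list(zero = c(0, 0), short = c(1, 10),
                          medium = c(11, 20), long = c(21, Inf))

#' Bin a delay difference into zero/short/medium/long
#'
#' Experiment 1 bins differences in trials (zero; 1-10 short; 11-20 medium;
#' >20 long); Experiment 2 bins differences in days (zero; 1-5 short; 6-32
#' medium; >32 long, covering the designed delays 1, 5 / 13, 32 / 89, 237).
#'
#' @param delay_difference non-negative integer difference(s) `d2 - d1`.
#' @param experiment 1 or 2.
#' @return ordered factor with levels `zero < short < medium < long`.
#' @export
bin_delay_difference <- function(delay_difference, experiment = 1) {
  if (any(delay_difference < 0)) stop("delay_difference must be non-negative")
  stopifnot(experiment %in% c(1, 2))
  breaks <- if (experiment == 1) c(-0.5, 0.5, 10.5, 20.5, Inf)
            else c(-0.5, 0.5, 5.5, 32.5, Inf)
  cut(delay_difference, breaks = breaks,
      labels = c("zero", "short", "medium", "long"), ordered_result = TRUE)
}

#' Generate the counterbalanced Experiment-1 choice set
#'
#' Pairs are built as mirrored twins within each delay-difference bin: each
#' base pair (magnitudes `a` vs `b`, delays `d1`, `d2`) is accompanied by
#' its mirror (`b` vs `a`, same delays), so that the number of pairs whose
#' sooner magnitude exceeds the later magnitude is balanced to within one in
#' every bin; an odd bin count contributes one equal-magnitude pair. Sides
#' of the sooner option are counterbalanced across trials.
#'
#' @param config a [design_config()].
#' @param seed integer seed; the generated set is deterministic given
#'   `(config, seed)`.
#' @return data frame of class `choice_pairs` with columns `pair_id`,
#'   `s1_magnitude`, `s2_magnitude` (sooner / later expected magnitudes),
#'   `d1`, `d2` (delays), `delay_diff`, `bin`, `side_of_sooner`, `frame`.
#' @export
generate_exp1_choice_set <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  mr <- config$magnitude_range
  dr <- config$delay_range
  mags <- seq(mr[1], mr[2])
  if (length(mags) < 2 && any(config$bin_counts > 1))
    stop_design_infeasible("magnitude range too narrow to counterbalance orderings")
  set.seed(as.integer(seed))
  rows <- list()
  for (bin in names(config$bin_counts)) {
    n_b <- config$bin_counts[[bin]]
    if (n_b == 0) next
    win <- .exp1_bin_windows[[bin]]
    lo <- win[1]; hi <- min(win[2], dr[2] - dr[1])
    if (lo > hi)
      stop_design_infeasible(sprintf(
        "delay range [%d, %d] cannot host any '%s'-bin delay difference",
        dr[1], dr[2], bin))
    diffs_avail <- seq(lo, hi)
    n_base <- n_b %/% 2
    d1_cap <- config$sooner_delay_cap %||% dr[2]
    make_pair <- function(m1, m2) {
      dd <- if (length(diffs_avail) == 1) diffs_avail else sample(diffs_avail, 1)
      d1_hi <- min(d1_cap, dr[2] - dd)
      d1 <- if (d1_hi <= dr[1]) dr[1] else sample(seq(dr[1], d1_hi), 1)
      data.frame(s1_magnitude = m1, s2_magnitude = m2,
                 d1 = d1, d2 = d1 + dd, delay_diff = dd, bin = bin)
    }
    for (i in seq_len(n_base)) {
      mm <- sample(mags, 2, replace = FALSE)
      base <- make_pair(mm[1], mm[2])
      mirror <- base
      mirror$s1_magnitude <- base$s2_magnitude
      mirror$s2_magnitude <- base$s1_magnitude
      rows[[length(rows) + 1L]] <- base
      rows[[length(rows) + 1L]] <- mirror
    }
    if (n_b %% 2 == 1) {
      m <- sample(mags, 1)
      rows[[length(rows) + 1L]] <- make_pair(m, m)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  n <- nrow(pairs)
  side <- rep(c("left", "right"), length.out = n)
  pairs$side_of_sooner <- sample(side)
  pairs$frame <- "unframed"
  pairs$pair_id <- seq_len(n)
  rownames(pairs) <- NULL
  pairs <- pairs[, c("pair_id", "s1_magnitude", "s2_magnitude", "d1", "d2",
                     "delay_diff", "bin", "side_of_sooner", "frame")]
  class(pairs) <- c("choice_pairs", "data.frame")
  attr(pairs, "seed") <- as.integer(seed)
  attr(pairs, "experiment") <- 1L
  pairs
}

#' Frame-specific display magnitudes for Experiment-1 options
#'
#' Outcomes are objectively identical across frames; only the on-screen
#' description differs. In the pain frame a magnitude `x` is shown as the
#' extra shocks above the baseline rate (`x - baseline`); in the relief
#' frame as the shocks relieved from the maximum rate (`max - x`). Models
#' always consume the objective magnitude.
#'
#' @param magnitude objective expected shocks per episode.
#' @param frame `"pain"` or `"relief"`.
#' @param config a [design_config()] supplying the anchors.
#' @return displayed numbers.
#' @export
frame_display_value <- function(magnitude, frame, config = design_config()) {
  frame <- match.arg(frame, c("pain", "relief"))
  if (frame == "pain") magnitude - config$baseline_rate
  else config$max_rate - magnitude
}

#' Build an interleaved Experiment-1 schedule for a choice set
#'
#' Places the choice trials among `horizon` total trials so that the two
#' candidate outcome slots of every choice trial (at offsets `d1` and `d2`
#' from it) are globally unique — no two choice trials refer to an outcome
#' on the same trial — and no slot exceeds the final trial. Placement uses
#' constrained rejection sampling over random orders with a bounded retry
#' budget; because late trials cannot host a choice whose outcome would
#' overrun the horizon, no-choice trials necessarily thicken toward the end
#' of the run.
#'
#' @param pairs a `choice_pairs` table from [generate_exp1_choice_set()].
#' @param config a [design_config()]; `config$horizon` sets the run length.
#' @param seed integer seed.
#' @return data frame of class `dread_schedule` with one row per trial:
#'   `trial_index`, `kind` (`choice`/`no_choice`), `pair_id`,
#'   `outcome_slot_1`, `outcome_slot_2` (NA on no-choice trials).
#' @export
generate_exp1_schedule <- function(pairs, config = design_config(), seed = 1) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  N <- config$horizon
  if (max(pairs$d2) >= N)
    stop_design_infeasible("a pair's later delay exceeds the schedule horizon")
  n <- nrow(pairs)
  set.seed(as.integer(seed))
  for (attempt in seq_len(config$schedule_retry_cap)) {
    used <- logical(N)        # outcome slots already referred to
    is_choice <- integer(N)   # 0 = no choice, else row index into pairs
    order_idx <- sample.int(n)
    ok <- TRUE
    for (i in order_idx) {
      d1 <- pairs$d1[i]; d2 <- pairs$d2[i]
      latest <- N - d2
      cand <- which(is_choice[seq_len(latest)] == 0L)
      if (!length(cand)) { ok <- FALSE; break }
      cand <- sample(cand)
      placed <- FALSE
      for (t in head(cand, 80L)) {
        slots <- unique(c(t + d1, t + d2))
        if (!any(used[slots])) {
          used[slots] <- TRUE
          is_choice[t] <- i
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      pair_at <- rep(NA_integer_, N)
      pair_at[is_choice > 0L] <- is_choice[is_choice > 0L]
      sched <- data.frame(
        trial_index = seq_len(N),
        kind = ifelse(is_choice > 0L, "choice", "no_choice"),
        pair_id = pairs$pair_id[pair_at],
        outcome_slot_1 = seq_len(N) + pairs$d1[pair_at],
        outcome_slot_2 = seq_len(N) + pairs$d2[pair_at])
      class(sched) <- c("dread_schedule", "data.frame")
      attr(sched, "seed") <- as.integer(seed)
      attr(sched, "attempts") <- attempt
      return(sched)
    }
  }
  stop_design_infeasible(sprintf(
    "could not place %d choice trials in %d trials after %d attempts", n, N,
    config$schedule_retry_cap))
}

#' Generate the Experiment-2 dental-appointment choice set
#'
#' The sooner appointment is always "today" (delay 0). At each later delay,
#' each non-60 magnitude is paired against 60 \% dental pain in both
#' orderings (larger pain sooner, and larger pain later), giving an exactly
#' counterbalanced set; optionally one 60-vs-60 pair per delay is added.
#'
#' @param config a [design_config()].
#' @return a `choice_pairs` data frame (sooner option columns
#'   `s1_magnitude`, `d1 = 0`).
#' @export
generate_exp2_choice_set <- function(config = design_config()) {
  mags <- config$exp2_magnitudes
  ref <- max(mags)
  others <- setdiff(mags, ref)
  rows <- list()
  for (dd in config$exp2_delays) {
    for (m in others) {
      rows[[length(rows) + 1L]] <- data.frame(s1_magnitude = ref, s2_magnitude = m,
                                              d1 = 0, d2 = dd)
      rows[[length(rows) + 1L]] <- data.frame(s1_magnitude = m, s2_magnitude = ref,
                                              d1 = 0, d2 = dd)
    }
    if (isTRUE(config$exp2_include_equal))
      rows[[length(rows) + 1L]] <- data.frame(s1_magnitude = ref, s2_magnitude = ref,
                                              d1 = 0, d2 = dd)
  }
  pairs <- do.call(rbind, rows)
  pairs$delay_diff <- pairs$d2 - pairs$d1
  pairs$bin <- as.character(bin_delay_difference(pairs$delay_diff, experiment = 2))
  pairs$side_of_sooner <- rep(c("left", "right"), length.out = nrow(pairs))
  pairs$frame <- "unframed"
  pairs$pair_id <- seq_len(nrow(pairs))
  pairs <- pairs[, c("pair_id", "s1_magnitude", "s2_magnitude", "d1", "d2",
                     "delay_diff", "bin", "side_of_sooner", "frame")]
  class(pairs) <- c("choice_pairs", "data.frame")
  attr(pairs, "experiment") <- 2L
  pairs
}
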