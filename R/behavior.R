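#' Choice-proportion curve over delay-difference bins
#'
#' Model-free summary of a choice dataset: per delay-difference bin (zero,
#' short, medium, long — see [bin_delay_difference()]), the number of
#' choices of the later option, the total, and the proportion
#' `p(Choose later)`. With counterbalanced magnitude orderings, a
#' proportion below 0.5 indicates negative time preference (pain preferred
#' sooner). Empty bins carry `NA` proportions and are flagged.
#'
#' @param data choice dataset (pairs plus `choice` column); may contain
#'   several frames.
#' @param experiment 1 or 2 (selects the binning).
#' @param pool_frames `"combine"` pools counts across frames; `"average"`
#'   computes per-frame proportions and averages them (counts are then the
#'   combined counts, proportions the frame average).
#' @return data frame of class `choice_curve`: `bin`, `n_later`, `n_total`,
#'   `p_later`, `populated`.
#' @export
choice_curve <- function(data, experiment = 1,
                         pool_frames = c("combine", "average")) {
  stopifnot(nrow(data) > 0)
  pool_frames <- match.arg(pool_frames)
  data$bin <- bin_delay_difference(data$d2 - data$d1, experiment)
  later <- choice_sign(data$choice) > 0
  lvls <- c("zero", "short", "medium", "long")
  count_curve <- function(d, lt) {
    n_later <- vapply(lvls, function(b) sum(lt[d$bin == b]), numeric(1))
    n_total <- vapply(lvls, function(b) sum(d$bin == b), numeric(1))
    data.frame(bin = factor(lvls, levels = lvls, ordered = TRUE),
               n_later = n_later, n_total = n_total,
               p_later = ifelse(n_total > 0, n_later / n_total, NA_real_))
  }
  curve <- count_curve(data, later)
  if (pool_frames == "average" && length(unique(data$frame)) > 1) {
    per <- lapply(split(seq_len(nrow(data)), data$frame), function(ix)
      count_curve(data[ix, ], later[ix])$p_later)
    curve$p_later <- rowMeans(do.call(cbind, per), na.rm = TRUE)
  }
  curve$populated <- curve$n_total > 0
  rownames(curve) <- NULL
  class(curve) <- c("choice_curve", "data.frame")
  curve
}

#' Classify a subject's time-preference phenotype from a choice curve
#'
#' Four mutually exclusive categories:
#' * `zero` — no bin's later-choice proportion deflects significantly from
#'   0.5 (two-sided exact binomial test);
#' * `positive` — significant increases in `p(Choose later)` across bins
#'   but no significant decreases (two-sided exact test on the 2x2 counts
#'   of adjacent populated bins);
#' * `negative` — significant decreases but no increases;
#' * `reversing` — both, the signature of pain that is maximally aversive
#'   at intermediate delay.
#'
#' When some bin deflects from 0.5 but no between-bin change reaches
#' significance, the direction of the strongest deflection decides between
#' `positive` and `negative`, keeping the labels exhaustive.
#'
#' @param curve a [choice_curve()] (raw counts are used, so classification
#'   depends only on per-bin totals, not on record order).
#' @param alpha_level test level (default 0.05).
#' @param comparisons `"adjacent"` (default) tests consecutive populated
#'   bins; `"all_pairs"` tests every populated pair.
#' @return list of class `phenotype_label`: `label`, `binomial_p` (per
#'   bin), `pair_tests` (per comparison: bins, p, direction).
#' @export
classify_time_preference <- function(curve, alpha_level = 0.05,
                                     comparisons = c("adjacent", "all_pairs")) {
  comparisons <- match.arg(comparisons)
  pop <- which(curve$populated)
  if (length(pop) < 2)
    return(structure(list(label = "unclassifiable", binomial_p = NULL,
                          pair_tests = NULL), class = "phenotype_label"))
  binom_p <- rep(NA_real_, nrow(curve))
  for (i in pop)
    binom_p[i] <- binom.test(curve$n_later[i], curve$n_total[i], 0.5)$p.value

  idx_pairs <- if (comparisons == "adjacent") {
    Map(c, pop[-length(pop)], pop[-1])
  } else {
    unlist(lapply(seq_along(pop)[-length(pop)], function(a)
      lapply(pop[seq_along(pop) > a], function(b) c(pop[a], b))), recursive = FALSE)
  }
  pair_tests <- do.call(rbind, lapply(idx_pairs, function(ij) {
    i <- ij[1]; j <- ij[2]
    tab <- matrix(c(curve$n_later[i], curve$n_total[i] - curve$n_later[i],
                    curve$n_later[j], curve$n_total[j] - curve$n_later[j]),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab)$p.value
    data.frame(from = as.character(curve$bin[i]), to = as.character(curve$bin[j]),
               p = p,
               direction = sign(curve$p_later[j] - curve$p_later[i]))
  }))

  sig_binom <- any(binom_p[pop] < alpha_level)
  sig <- pair_tests$p < alpha_level
  has_incr <- any(sig & pair_tests$direction > 0)
  has_decr <- any(sig & pair_tests$direction < 0)

  label <- if (!sig_binom) "zero"
  else if (has_incr && has_decr) "reversing"
  else if (has_incr) "positive"
  else if (has_decr) "negative"
  else {
    i_star <- pop[which.min(binom_p[pop])]
    if (curve$p_later[i_star] > 0.5) "positive" else "negative"
  }
  structure(list(label = label, binomial_p = binom_p, pair_tests = pair_tests),
            class = "phenotype_label")
}

#' @export
print.phenotype_label <- function(x, ...) {
  cat("<phenotype_label>", x$label, "\n")
  invisible(x)
}

#' Exact test for a framing effect on sooner-choice frequency
#'
#' Two-sided exact test (Fisher) on the 2x2 table of sooner- vs
#' later-choice counts by frame. The direction flag is positive when the
#' sooner-choice frequency is higher in the pain frame — the expected
#' direction if framing pain as an increase amplifies dread.
#'
#' @param pain_data,relief_data the subject's choice datasets per frame.
#' @return list: `p_sooner_pain`, `p_sooner_relief`, `p_value`,
#'   `direction` (+1 expected direction, -1 reversed, 0 none).
#' @export
framing_effect_test <- function(pain_data, relief_data) {
  stopifnot(nrow(pain_data) > 0, nrow(relief_data) > 0)
  sooner_pain <- sum(choice_sign(pain_data$choice) < 0)
  sooner_relief <- sum(choice_sign(relief_data$choice) < 0)
  tab <- matrix(c(sooner_pain, nrow(pain_data) - sooner_pain,
                  sooner_relief, nrow(relief_data) - sooner_relief),
                nrow = 2, byrow = TRUE)
  p1 <- sooner_pain / nrow(pain_data)
  p2 <- sooner_relief / nrow(relief_data)
  list(p_sooner_pain = p1, p_sooner_relief = p2,
       p_value = fisher.test(tab)$p.value,
       direction = sign(p1 - p2))
}

#' Apply the study's participant exclusion rules
#'
#' Excludes (a) subjects whose end-of-session rating of the maximum shock
#' rate falls below 4/10, indicating adaptation over the session, and (b)
#' "maximum dreaders" who chose the sooner outcome on 100\% of choices in
#' at least one frame, whose indifference points are unobservable within
#' the offered choice set.
#'
#' @param cohort named list: subject -> list with elements `data` (choice
#'   dataset with a `frame` column) and `max_rate_rating` (0-10; may be
#'   `NA` to skip the rating rule).
#' @param rating_threshold exclusion threshold on the rating (default 4).
#' @return data frame: `subject`, `included`, `reason` (`""`,
#'   `"adaptation"`, or `"max_dreader"`).
#' @export
apply_exclusions <- function(cohort, rating_threshold = 4) {
  rows <- lapply(names(cohort), function(s) {
    entry <- cohort[[s]]
    rating <- entry$max_rate_rating %||% NA_real_
    reason <- ""
    if (!is.na(rating) && rating < rating_threshold) {
      reason <- "adaptation"
    } else {
      frames <- split(entry$data, entry$data$frame)
      all_sooner <- vapply(frames, function(d)
        nrow(d) > 0 && all(choice_sign(d$choice) < 0), logical(1))
      if (any(all_sooner)) reason <- "max_dreader"
    }
    data.frame(subject = s, included = reason == "", reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
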