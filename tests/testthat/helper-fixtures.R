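# shared fixtures: small designs, agents and datasets built in code

fix_design <- function(n = 20) {
  base <- n %/% 4
  design_config(n_choice_trials = n,
                bin_counts = c(zero = n - 3 * base, short = base,
                               medium = base, long = base))
}

# one subject's two-frame dataset simulated from a given agent
fix_dataset <- function(agent, seed = 1, config = design_config()) {
  ss <- seed_stream(seed, 3)
  cs <- generate_exp1_choice_set(config, seed = ss[1])
  rbind(simulate_agent(cs, agent, ss[2], "pain"),
        simulate_agent(cs, agent, ss[3], "relief"))
}

# independent brute-force oracle for the dread sum: term-by-term summation
# of discounted instantaneous dread, never the closed forms
oracle_dread_sum <- function(u, T, gamma_p, gamma_d, alpha) {
  if (T == 0) return(0)
  t <- 0:(T - 1)
  alpha * u * sum(gamma_d^t * gamma_p^(T - t))
}

# independent per-record log-probability oracle (naive logistic form)
oracle_record_logp <- function(dv, beta, chose_later) {
  p_later <- 1 / (1 + exp(-beta * dv))
  log(ifelse(chose_later, p_later, 1 - p_later))
}

# hand-built choice curve from per-bin counts
curve_from_counts <- function(n_later, n_total) {
  lvls <- c("zero", "short", "medium", "long")
  out <- data.frame(bin = factor(lvls, levels = lvls, ordered = TRUE),
                    n_later = n_later, n_total = n_total,
                    p_later = ifelse(n_total > 0, n_later / n_total, NA),
                    populated = n_total > 0)
  class(out) <- c("choice_curve", "data.frame")
  out
}
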