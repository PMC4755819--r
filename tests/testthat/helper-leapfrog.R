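# Shared fixtures, all built in code.

# A hand-built single-participant trial table.
tiny_trials <- function(choice, reward, participant_id = "p1",
                        group = "younger", condition = "independent",
                        rt_ms = NA_real_) {
  stopifnot(length(choice) == length(reward))
  data.frame(participant_id = participant_id, group = group,
             condition = condition, trial = seq_along(choice),
             choice = choice, reward = reward, rt_ms = rt_ms)
}

# Pool n simulated agents of one kind into a labelled trial table.
pool_agents <- function(kind, n, seed, epsilon = 0.17, env = env_config(),
                        ...) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    a <- if (kind == "reflexive") agent_config(kind, epsilon = epsilon, ...)
         else agent_config(kind, ...)
    run_agent(env, a, participant_id = sprintf("%s_%03d", kind, i))
  }))
}

# Closed-form inter-jump interval pmf for the ramping hazard (independent
# oracle for the dependent-condition simulator).
ramp_pmf <- function(h0 = 0.01, dh = 0.01) {
  s_max <- ceiling((1 - h0) / dh) + 1
  h <- pmin(h0 + dh * (seq_len(s_max) - 1), 1)
  h * cumprod(c(1, 1 - h[-s_max]))
}

# Brute-force P(odd number of jumps) over all 2^k jump sequences with
# per-step hazards h (independent oracle for parity_update).
odd_parity_brute <- function(h) {
  k <- length(h)
  total <- 0
  for (m in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(k)]
    if (sum(bits) %% 2 == 1)
      total <- total + prod(ifelse(bits == 1, h, 1 - h))
  }
  total
}
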