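# Shared fixtures, built in code.

base_params <- function(...) default_parameters(...)

# All spreads forced to zero: probabilistic draws must equal the
# deterministic values exactly.
zero_spread_params <- function() {
  p <- default_parameters()
  p$state_econ$utility_se <- rep(0, 4)
  p$state_econ$cost_cv <- rep(0, 4)
  p$interventions$gain_se <- rep(0, 5)
  p$interventions$cost_cv <- rep(0, 5)
  p
}

# A parameter set where every reward is zero (costs and utilities).
zero_reward_params <- function() {
  p <- default_parameters()
  p$state_econ$utility <- rep(0, 4)
  p$state_econ$utility_se <- rep(0, 4)
  p$state_econ$cost_direct_medical <- rep(0, 4)
  p$state_econ$cost_direct_nonmedical <- rep(0, 4)
  p$state_econ$cost_indirect_nonmedical <- rep(0, 4)
  p$interventions$annual_cost <- rep(0, 5)
  p$interventions$utility_gain <- rep(0, 5)
  p$interventions$gain_se <- rep(0, 5)
  p
}

# Independent step-by-step projection oracle: explicit scalar sums, no
# matrix multiplication.
project_oracle <- function(initial, P, horizon) {
  k <- length(initial)
  traj <- matrix(0, horizon + 1, k)
  traj[1, ] <- initial
  for (t in seq_len(horizon)) {
    for (j in seq_len(k)) {
      acc <- 0
      for (i in seq_len(k)) acc <- acc + traj[t, i] * P[i, j]
      traj[t + 1, j] <- acc
    }
  }
  traj
}

# Random small row-stochastic matrix (with a final absorbing state).
random_stochastic_matrix <- function(k) {
  P <- matrix(stats::rexp(k * k), k, k)
  P <- P / rowSums(P)
  P[k, ] <- c(rep(0, k - 1), 1)
  P
}
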