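# Shared fixtures: small hand-built datasets, quick simulator calls, and a
# constructor for draws objects with known contents.

tiny_df <- function() {
  data.frame(
    id = c("p1", "p2", "p3", "p4"),
    arm = c(1, 1, 2, 2),
    age = c(70, 80, 75, 68),
    sex = c(1, 0, 1, 1),
    hardman = c(2, NA, 1, 3),
    qol_1 = c(0.70, 0.55, NA, 0.80),
    qol_2 = c(0.75, 0.60, 0.65, 0.85),
    cost = c(12000, NA, 15000, 9000),
    t_1 = 0.5, t_2 = 0.375,
    stringsAsFactors = FALSE)
}

tiny_data <- function() as_trial_data(tiny_df())

# complete two-arm dataset without any missing values
complete_data <- function(n_per_arm = 30, seed = 101) {
  cfg <- sim_config(
    seed = seed, n = rep(n_per_arm, 2),
    qol_missing = list(type = "MCAR", rates = matrix(0, 2, 2)),
    cost_missing = list(type = "MCAR", rates = c(0, 0)),
    hardman_missing = list(type = "MCAR", rates = c(0, 0)))
  suppressWarnings(generate_trial(cfg))
}

sim_trial <- function(...) suppressWarnings(generate_trial(sim_config(...)))

# a draws container with prescribed per-parameter vectors, split over two
# chains, for exercising the decision-output operations in isolation
fake_draws <- function(values) {
  n <- length(values[[1]])
  half <- n %/% 2
  mk <- function(idx) {
    m <- vapply(values, function(v) v[idx], numeric(length(idx)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(idx),
                                     dimnames = list(NULL, names(values)))
    m
  }
  structure(list(chains = list(mk(seq_len(half)), mk((half + 1):n)),
                 monitors = names(values),
                 settings = mcmc_settings(n_iter = n, warmup = 0)),
            class = "cea_draws")
}

quick_settings <- function(n_iter = 3000, warmup = 400, seed = 1)
  mcmc_settings(n_chains = 2, n_iter = n_iter, warmup = warmup, seed = seed)

# two-component pooled prior used across model tests
toy_pool <- function() {
  pool_experts(list(
    expert_prior("a", c(-0.15, -0.10), c(0.08, 0.08), 0.4),
    expert_prior("b", c(-0.25, -0.20), c(0.06, 0.06), 0.2)))
}
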