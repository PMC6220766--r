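test_that("QALY mean and sd follow the duration-weighted forms", {
  expect_equal(qaly_mean(c(0, 0)), 0)
  expect_equal(qaly_mean(c(0.8, 0.6)), 0.625)   # 0.8/2 + 3*0.6/8
  expect_equal(qaly_mean(c(0.7, 0.9), weights = c(1, 0)), 0.7)
  expect_error(qaly_mean(c(1, 2, 3), weights = c(0.5, 0.375)), "length")

  expect_equal(qaly_sd(0, 0, 0), 0)
  expect_equal(qaly_sd(0.2, 0.4, 0), sqrt(0.01 + 0.0225))
  # perfect correlation collapses to the weighted sum of sds
  expect_equal(qaly_sd(0.3, 0.3, 1), 0.875 * 0.3)
  # default weights reproduce the 1/4, 3/8, 9/64 coefficients
  s1 <- 0.23; s2 <- 0.31; r <- -0.4
  expect_equal(qaly_sd(s1, s2, r),
               sqrt(s1^2 / 4 + 3 * r * s1 * s2 / 8 + 9 * s2^2 / 64))
})

test_that("qaly_sd^2 matches the Monte-Carlo variance of weighted QoL draws", {
  S <- matrix(c(0.25^2, 0.6 * 0.25 * 0.3, 0.6 * 0.25 * 0.3, 0.3^2), 2, 2)
  set.seed(42)
  y <- mvtnorm::rmvnorm(1e5, mean = c(0.7, 0.72), sigma = S)
  q <- y %*% c(1 / 2, 3 / 8)
  v <- qaly_sd(0.25, 0.3, 0.6)^2
  se <- v * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(drop(q)) - v), 4 * se)
})

test_that("linear predictor matches a by-hand recomputation", {
  cfg <- model_config(qol_missingness = "MNAR")
  state <- list(
    eta = matrix(c(0.6, 0.65, 0.62, 0.70, 12, 11), 3, 2, byrow = TRUE),
    beta = matrix(seq(-0.01, 0.1, length.out = 18), 3, 6,
                  dimnames = list(NULL, c("age", "sex", "h2", "h3", "h4", "h5"))),
    delta = matrix(c(-0.1, -0.2, -0.1, -0.2), 2, 2, byrow = TRUE),
    gamma = 0.5)
  rec <- list(arm = 2, age = 74, sex = 1, hardman = 3, r_1 = 0, r_2 = 1, s = 1)
  by_hand <- unname(state$eta[1, 2] + state$beta[1, "age"] * 74 +
    state$beta[1, "sex"] * 1 + state$beta[1, "h3"] + state$delta[1, 2])
  expect_equal(linear_predictor(rec, "qol1", state, cfg), by_hand)

  # observed timepoint: the pattern-mixture offset is not applied
  rec2 <- rec; rec2$r_1 <- 1
  expect_equal(linear_predictor(rec2, "qol1", state, cfg),
               by_hand - state$delta[1, 2])

  # all coefficients zero reduces to the arm intercept
  state0 <- state
  state0$beta[] <- 0; state0$delta[] <- 0
  expect_equal(linear_predictor(rec, "qol2", state0, cfg), state$eta[2, 2])

  # unimputed missing covariate is an error, not a silent zero
  rec3 <- rec; rec3$hardman <- NA
  expect_error(linear_predictor(rec3, "cost", state, cfg), "impute")
})

test_that("log_joint matches an independent trivariate-normal oracle", {
  tr <- complete_data(n_per_arm = 2, seed = 77)
  cfg <- model_config(covariates = character(0))
  m <- build_model(cfg, tr$data)
  set.seed(8)
  state <- init_state(m, init = "fixed")
  state$b <- -2.5; state$sigma_c <- 4
  state$Sigma <- list(matrix(c(0.05, 0.02, 0.02, 0.07), 2, 2),
                      matrix(c(0.06, 0.01, 0.01, 0.05), 2, 2))
  w <- c(1 / 2, 3 / 8)
  oracle <- 0
  for (i in seq_len(m$n)) {
    k <- m$arm[i]
    S <- state$Sigma[[k]]
    mu3 <- c(state$eta[1, k], state$eta[2, k],
             state$eta[3, k])      # cost mean = nu_c + b(E QALY - nu_q) = nu_c
    Swq <- drop(S %*% w)
    V <- rbind(cbind(S, state$b * Swq),
               c(state$b * Swq,
                 state$sigma_c^2 + state$b^2 * drop(t(w) %*% S %*% w)))
    x <- c(m$y[i, ], m$cost[i])
    d <- x - mu3
    oracle <- oracle - 0.5 * (3 * log(2 * pi) +
                                determinant(V)$modulus +
                                drop(t(d) %*% solve(V) %*% d))
  }
  expect_equal(log_joint(m, state, include_prior = FALSE), as.numeric(oracle),
               tolerance = 1e-10)
})

test_that("log_joint honours the rejection and equivalence contracts", {
  tr <- sim_trial(seed = 14, n = c(20, 20))
  cfg_mar <- model_config()
  cfg_mnar <- model_config(qol_missingness = "MNAR")
  m_mar <- build_model(cfg_mar, tr$data)
  m_0 <- build_model(cfg_mnar, tr$data, sensitivity_prior(qol = c(0, 0)))
  set.seed(2)
  for (rep in 1:5) {
    st <- init_state(m_0)
    expect_equal(log_joint(m_0, st), log_joint(m_mar, st))
  }

  # non-positive-definite covariance is rejected with -Inf
  st <- init_state(m_mar)
  st$Sigma[[1]] <- matrix(c(0.04, 0.09, 0.09, 0.04), 2, 2)
  expect_identical(log_joint(m_mar, st), -Inf)

  # with no missing data, MAR and any MNAR point mass agree for all states
  comp <- complete_data(n_per_arm = 15, seed = 21)
  mc_mar <- build_model(cfg_mar, comp$data)
  mc_mnar <- build_model(cfg_mnar, comp$data,
                         sensitivity_prior(qol = c(-0.3, 0.2)))
  set.seed(3)
  for (rep in 1:5) {
    st <- init_state(mc_mnar)
    st$delta <- mc_mnar$sensitivity$qol
    expect_equal(log_joint(mc_mnar, st, include_prior = FALSE),
                 log_joint(mc_mar, st, include_prior = FALSE))
  }
})

test_that("log_joint is invariant to patient ordering", {
  tr <- complete_data(n_per_arm = 12, seed = 31)
  cfg <- model_config()
  m <- build_model(cfg, tr$data)
  set.seed(5)
  st <- init_state(m)
  perm <- sample(nrow(tr$data$df))
  df2 <- tr$data$df[perm, ]
  m2 <- build_model(cfg, as_trial_data(df2))
  expect_equal(log_joint(m2, st), log_joint(m, st))
})

test_that("elicited levels convert to offsets by subtracting observed means", {
  pp <- pool_experts(list(expert_prior("a", c(0.55, 0.62), c(0.1, 0.1), 0.3),
                          expert_prior("b", c(0.70, 0.75), c(0.08, 0.12), 0.1)))
  obs <- c(0.75, 0.70)
  sp <- elicited_levels_to_offsets(pp, obs)
  expect_s3_class(sp, "sensitivity_prior")
  expect_equal(sp$kind, "mixture")
  expect_equal(sp$qol$means[[1]], c(0.55, 0.62) - obs)
  expect_equal(sp$qol$means[[2]], c(0.70, 0.75) - obs)
  # elicited mean 0.55 against observed 0.75 gives a -0.20 offset
  expect_equal(sp$qol$means[[1]][1], -0.20)
  # covariances are preserved componentwise (pure location shift)
  expect_equal(sp$qol$covs, pp$covs)
  # level equal to the observed mean centres the offset at zero
  sp0 <- elicited_levels_to_offsets(
    pool_experts(list(expert_prior("c", obs, c(0.1, 0.1), 0))), obs)
  expect_equal(sp0$qol$means[[1]], c(0, 0))

  expect_error(elicited_levels_to_offsets(pp, c(0.7, NA)), "no observed")

  # observed arm means come from complete cases only
  td <- tiny_data()
  om <- observed_qol_means(td, timepoint = 1)
  expect_equal(om, c(mean(c(0.70, 0.55)), 0.80))
})

test_that("build_model checks structure and counts parameters", {
  tr <- sim_trial(seed = 44, n = c(20, 20))
  cfg <- model_config()
  m <- build_model(cfg, tr$data)
  # hand count: 3 eta per arm (6) + 3 equations x 6 coefficients (18)
  # + 3 free Sigma elements per arm (6) + slope + residual sd (2)
  # + 4 free category probabilities per arm (8)
  expect_equal(n_parameters(m), 40)

  cfg0 <- model_config(covariates = character(0))
  comp <- complete_data(n_per_arm = 10)
  m0 <- build_model(cfg0, comp$data)
  expect_equal(n_parameters(m0), 6 + 6 + 2)

  expect_error(build_model(model_config(qol_missingness = "MNAR"), tr$data),
               "sensitivity")
  mnar <- build_model(model_config(qol_missingness = "MNAR"), tr$data,
                      sensitivity_prior(qol = toy_pool()))
  expect_equal(n_parameters(mnar), 42)  # two time-invariant offsets
})
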