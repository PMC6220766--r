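test_that("zero missingness probabilities give a complete dataset", {
  tr <- complete_data(n_per_arm = 40, seed = 1)
  df <- tr$data$df
  expect_true(all(df$r_1 == 1L) && all(df$r_2 == 1L) && all(df$s == 1L))
  expect_false(anyNA(df$hardman))
})

test_that("generation is seed-reproducible and moments match the truth", {
  a <- sim_trial(seed = 500, n = c(2500, 2500))
  b <- sim_trial(seed = 500, n = c(2500, 2500))
  expect_identical(a$data$df, b$data$df)

  cfg <- a$truth$config
  y1 <- a$truth$y_full[a$data$df$arm == 1, ]
  # marginal QoL means and covariance recover the generating values (4 SE)
  n1 <- nrow(y1)
  for (j in 1:2) {
    se <- sqrt(cfg$Sigma[[1]][j, j] / n1)
    expect_lt(abs(mean(y1[, j]) - cfg$qol_levels[j, 1]), 4 * se)
  }
  # total QoL variance = residual covariance + centred covariate spread
  eff_h <- cfg$beta_qol$hardman -
    sum(cfg$covariates$hardman_probs * cfg$beta_qol$hardman)
  v_eff <- cfg$beta_qol$age^2 * cfg$covariates$age_sd^2 +
    cfg$beta_qol$sex^2 * cfg$covariates$sex_p * (1 - cfg$covariates$sex_p) +
    sum(cfg$covariates$hardman_probs * eff_h^2)
  v_tot <- cfg$Sigma[[1]][2, 2] + v_eff
  expect_lt(abs(var(y1[, 2]) - v_tot), 4 * v_tot * sqrt(2 / (n1 - 1)))
  # cost mean per arm
  c2 <- a$truth$cost_full[a$data$df$arm == 2]
  expect_lt(abs(mean(c2) - cfg$cost_levels[2]),
            4 * sd(c2) / sqrt(length(c2)))
})

test_that("MCAR rates and MNAR pattern offsets are realised", {
  # MCAR: missing fraction within the binomial bound
  tr <- sim_trial(seed = 321, n = c(2500, 2500),
                  qol_missing = list(type = "MCAR",
                                     rates = rbind(c(0.2, 0.2), c(0.2, 0.2))))
  miss_frac <- mean(tr$data$df$r_1 == 0)
  expect_lt(abs(miss_frac - 0.2), 4 * sqrt(0.2 * 0.8 / 5000))

  # MNAR: the missing-minus-observed pattern mean difference equals Delta
  d_true <- -0.2
  trm <- sim_trial(seed = 322, n = c(2500, 2500),
                   qol_missing = list(type = "MNAR",
                                      rates = rbind(c(0.3, 0.3), c(0.3, 0.3))),
                   delta = matrix(c(0, 0, d_true, d_true), 2, 2))
  df <- trm$data$df
  y_full <- trm$truth$y_full
  in2 <- df$arm == 2
  gap <- mean(y_full[in2 & df$r_1 == 0, 1]) - mean(y_full[in2 & df$r_1 == 1, 1])
  n_m <- sum(in2 & df$r_1 == 0); n_o <- sum(in2 & df$r_1 == 1)
  se <- sqrt(0.24^2 / n_m + 0.24^2 / n_o) + 0.01   # covariate spread inflates
  expect_lt(abs(gap - d_true), 4 * se)
  # reference arm (offset zero) shows no such gap
  in1 <- df$arm == 1
  gap1 <- mean(y_full[in1 & df$r_1 == 0, 1]) - mean(y_full[in1 & df$r_1 == 1, 1])
  expect_lt(abs(gap1), 4 * se)
})

test_that("post-hoc masking handles MCAR/MAR and refuses MNAR", {
  comp <- complete_data(n_per_arm = 3000, seed = 9)$data
  expect_error(
    apply_missingness(comp, list(qol = list(type = "MNAR",
                                            rates = matrix(0.2, 2, 2)))),
    "generate_trial")

  # zero probability is the identity
  same <- apply_missingness(comp, list(qol = list(type = "MCAR",
                                                  rates = matrix(0, 2, 2))),
                            seed = 2)
  expect_identical(same$df$qol_1, comp$df$qol_1)

  # identical seed, identical mask
  m1 <- apply_missingness(comp, list(qol = list(type = "MCAR",
                                                rates = matrix(0.3, 2, 2))),
                          seed = 5)
  m2 <- apply_missingness(comp, list(qol = list(type = "MCAR",
                                                rates = matrix(0.3, 2, 2))),
                          seed = 5)
  expect_identical(is.na(m1$df$qol_1), is.na(m2$df$qol_1))

  # MAR with positive age coefficient: missingness rises across age tertiles
  mar <- apply_missingness(
    comp, list(qol = list(type = "MAR", rates = matrix(0.25, 2, 2),
                          age_coef = 1)), seed = 6)
  ter <- cut(mar$df$age, quantile(mar$df$age, c(0, 1 / 3, 2 / 3, 1)),
             include.lowest = TRUE)
  rates <- tapply(is.na(mar$df$qol_1), ter, mean)
  expect_true(rates[1] < rates[2] && rates[2] < rates[3])
  # original values retained in the truth channel
  expect_false(anyNA(attr(mar, "truth_values")$qol_1))
})

test_that("synthetic expert panels support pooling and extremes", {
  one <- generate_expert_panel(1, seed = 3)
  pp <- pool_experts(one)
  pt <- c(0.6, 0.6)
  expect_equal(pooled_density(pp, pt),
               mvtnorm::dmvnorm(pt, one[[1]]$mean, expert_cov(one[[1]])))

  same <- rep(generate_expert_panel(1, seed = 4), 5)
  pp5 <- pool_experts(same)
  expect_equal(pooled_density(pp5, pt), pooled_density(pool_experts(same[1]), pt))

  # constructed extremes are recovered from a wider panel
  panel <- generate_expert_panel(10, seed = 5)
  # extremes constructed beyond the panel's attainable mean differences
  panel <- c(panel, list(
    expert_prior("SCEP", c(0.95, 0.45), c(0.1, 0.1), 0),
    expert_prior("ENTH", c(0.40, 0.95), c(0.1, 0.1), 0)))
  expect_equal(select_extreme_expert(panel, "sceptical")$expert_id, "SCEP")
  expect_equal(select_extreme_expert(panel, "enthusiastic")$expert_id, "ENTH")
  # roles and modes allow subgroup pools
  roles <- vapply(panel[1:10], `[[`, character(1), "role")
  expect_setequal(unique(roles), c("doctor", "nurse"))
})
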