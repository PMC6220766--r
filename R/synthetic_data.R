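#' Configuration for the synthetic trial generator
#'
#' Generates two-arm trials with exactly the statistical structure the
#' joint model assumes: arm-specific bivariate-normal QoL with covariate
#' effects, cost drawn conditionally on the realised QALY, and
#' MCAR/MAR/MNAR missingness.  MNAR follows the pattern-mixture
#' factorisation — the missingness pattern is drawn first and unobserved
#' QoL values are then drawn from the pattern-specific mean (mean plus the
#' offset `Delta_jk`) — so the generating offsets are exactly the
#' estimands of the sensitivity analysis.
#'
#' The defaults emulate a 301-patient emergency-surgery trial: arm sizes
#' 140 (arm 1, reference) and 161 (arm 2, intervention); utility-scale QoL
#' means around 0.66-0.75 with incremental QoL 0.063 and 0.046 at the two
#' timepoints; QoL missingness of 24%/17% (timepoint 1) and 27%/21%
#' (timepoint 2) by arm under a MAR mechanism driven by age; cost
#' missingness of 49%/45% (MCAR) with an incremental cost of -704 GBP; and
#' morbidity-index missingness of 14%/10%.
#'
#' @param n length-2 vector of per-arm sample sizes (arm 1 = reference).
#' @param qol_levels `J x K` matrix of marginal QoL means by timepoint and
#'   arm (covariate effects are centred so these are population means).
#' @param beta_qol list with `age` (per year), `sex`, and `hardman`
#'   (length-5 effects by category) applied to both QoL timepoints.
#' @param Sigma list of K 2x2 QoL covariance matrices.
#' @param cost_levels length-K marginal mean costs (GBP).
#' @param beta_cost list as `beta_qol`, on the GBP scale.
#' @param cost_slope regression slope of cost on QALY (GBP per QALY).
#' @param cost_sd conditional residual sd of cost (GBP).
#' @param covariates list with `age_mean`, `age_sd`, `sex_p`,
#'   `hardman_probs` (length 5).
#' @param qol_missing list with `type` (`"MCAR"`, `"MAR"` or `"MNAR"`),
#'   `rates` (`J x K` matrix of missingness probabilities), and for MAR an
#'   `age_coef` (log-odds per sd of age).
#' @param cost_missing list with `type` (`"MCAR"` or `"MAR"`), `rates`
#'   (length K), optional `age_coef`.
#' @param hardman_missing list with `type` `"MCAR"` and `rates` (length K).
#' @param delta `J x K` matrix (or length-2 per-arm vector) of true
#'   pattern-mixture QoL offsets; nonzero values require
#'   `qol_missing$type == "MNAR"`.
#' @param gamma true cost offset (GBP) for missing costs (0 = costs MAR).
#' @param durations length-J follow-up durations (fractions of a year).
#' @param qaly_weights duration weights used for the conditional cost draw.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(
    n = c(140L, 161L),
    qol_levels = rbind(c(0.66, 0.723), c(0.70, 0.746)),
    beta_qol = list(age = -0.004, sex = 0.03,
                    hardman = c(0, -0.03, -0.06, -0.10, -0.15)),
    Sigma = list(matrix(c(0.26^2, 0.55 * 0.26 * 0.28,
                          0.55 * 0.26 * 0.28, 0.28^2), 2, 2),
                 matrix(c(0.24^2, 0.60 * 0.24 * 0.26,
                          0.60 * 0.24 * 0.26, 0.26^2), 2, 2)),
    cost_levels = c(15500, 14796),
    beta_cost = list(age = 50, sex = 300,
                     hardman = c(0, 400, 900, 1600, 2500)),
    cost_slope = -4000, cost_sd = 5500,
    covariates = list(age_mean = 75, age_sd = 7, sex_p = 0.8,
                      hardman_probs = c(0.35, 0.30, 0.20, 0.10, 0.05)),
    qol_missing = list(type = "MAR", rates = rbind(c(0.24, 0.17), c(0.27, 0.21)),
                       age_coef = 0.5),
    cost_missing = list(type = "MCAR", rates = c(0.49, 0.45)),
    hardman_missing = list(type = "MCAR", rates = c(0.14, 0.10)),
    delta = matrix(0, 2, 2), gamma = 0,
    durations = c(0.5, 0.375), qaly_weights = c(1 / 2, 3 / 8),
    seed = 1L) {
  if (!is.matrix(delta)) delta <- matrix(delta, 2, 2, byrow = TRUE)
  stopifnot(length(n) == 2L, all(n >= 2), nrow(qol_levels) == 2L,
            all(vapply(Sigma, is_pd2, logical(1))),
            all(unlist(qol_missing$rates) >= 0),
            all(unlist(qol_missing$rates) <= 1),
            all(cost_missing$rates >= 0 & cost_missing$rates <= 1),
            all(hardman_missing$rates >= 0 & hardman_missing$rates <= 1))
  if (any(delta != 0) && qol_missing$type != "MNAR")
    stopf("nonzero QoL offsets require qol_missing$type == 'MNAR'")
  structure(as.list(environment()), class = "sim_config")
}

# centred covariate contribution to an equation's mean
centred_effect <- function(cfg, age, sex, hardman, beta) {
  eff_h <- beta$hardman - sum(cfg$covariates$hardman_probs * beta$hardman)
  beta$age * (age - cfg$covariates$age_mean) +
    beta$sex * (sex - cfg$covariates$sex_p) + eff_h[hardman]
}

miss_prob <- function(type, rate, age_std, age_coef) {
  switch(type,
         MCAR = rep(rate, length(age_std)),
         MAR = stats::plogis(stats::qlogis(rate) + age_coef * age_std),
         MNAR = rep(rate, length(age_std)),
         stopf("unknown missingness type '%s'", type))
}

#' Generate a synthetic trial
#'
#' Draws covariates, then the missingness pattern, then outcomes given the
#' pattern (QoL from the pattern-specific bivariate normal, cost
#' conditionally on the realised QALY), then masks the values flagged
#' missing.  The generating parameter values, the complete (pre-masking)
#' outcomes, and the realised marginal increments — the quantities the
#' fitted model monitors — are returned alongside as the truth channel.
#'
#' @param config a [sim_config()].
#' @return list with `data` (a `trial_data`, missing values masked) and
#'   `truth` (a `sim_truth`: the config, full outcomes, and realised
#'   estimands `eta_diff`, `inc_qol`, `inc_qaly`, `inc_cost`, `delta`,
#'   `gamma`).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  n <- sum(cfg$n)
  arm <- rep(1:2, cfg$n)
  cv <- cfg$covariates
  age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  sex <- stats::rbinom(n, 1, cv$sex_p)
  hardman <- sample.int(5, n, replace = TRUE, prob = cv$hardman_probs)
  age_std <- (age - cv$age_mean) / cv$age_sd

  # missingness pattern first (pattern-mixture factorisation)
  Rm <- matrix(1L, n, 2)
  for (j in 1:2) for (k in 1:2) {
    idx <- which(arm == k)
    p <- miss_prob(cfg$qol_missing$type, cfg$qol_missing$rates[j, k],
                   age_std[idx], cfg$qol_missing$age_coef %||% 0)
    Rm[idx, j] <- 1L - stats::rbinom(length(idx), 1, p)
  }
  s <- integer(n)
  for (k in 1:2) {
    idx <- which(arm == k)
    p <- miss_prob(cfg$cost_missing$type, cfg$cost_missing$rates[k],
                   age_std[idx], cfg$cost_missing$age_coef %||% 0)
    s[idx] <- 1L - stats::rbinom(length(idx), 1, p)
  }
  h_obs <- integer(n)
  for (k in 1:2) {
    idx <- which(arm == k)
    h_obs[idx] <- 1L - stats::rbinom(length(idx), 1, cfg$hardman_missing$rates[k])
  }

  # outcomes given pattern
  mu <- matrix(NA_real_, n, 2)
  for (j in 1:2)
    mu[, j] <- cfg$qol_levels[j, arm] +
      centred_effect(cfg, age, sex, hardman, cfg$beta_qol) +
      (1 - Rm[, j]) * cfg$delta[j, arm]
  y <- mu
  for (k in 1:2) {
    idx <- which(arm == k)
    y[idx, ] <- mu[idx, , drop = FALSE] +
      mvtnorm::rmvnorm(length(idx), sigma = cfg$Sigma[[k]])
  }
  w <- cfg$qaly_weights
  qaly <- drop(y %*% w)
  nu_q <- drop(mu %*% w)
  nu_c <- cfg$cost_levels[arm] +
    centred_effect(cfg, age, sex, hardman, cfg$beta_cost) +
    (1 - s) * cfg$gamma
  cost <- stats::rnorm(n, nu_c + cfg$cost_slope * (qaly - nu_q), cfg$cost_sd)

  df <- data.frame(id = sprintf("P%04d", seq_len(n)), arm = arm,
                   age = age, sex = sex,
                   hardman = ifelse(h_obs == 1L, hardman, NA_integer_),
                   qol_1 = ifelse(Rm[, 1] == 1L, y[, 1], NA_real_),
                   qol_2 = ifelse(Rm[, 2] == 1L, y[, 2], NA_real_),
                   cost = ifelse(s == 1L, cost, NA_real_),
                   t_1 = cfg$durations[1], t_2 = cfg$durations[2])
  data <- as_trial_data(df, J = 2L, K = 2L,
                        covariates = c("age", "sex", "hardman"))

  inc_qol <- vapply(1:2, function(j)
    mean(mu[arm == 2, j]) - mean(mu[arm == 1, j]), numeric(1))
  truth <- structure(list(
    config = cfg,
    y_full = y, cost_full = cost, hardman_full = hardman,
    eta_diff = cfg$qol_levels[, 2] - cfg$qol_levels[, 1],
    eta_cost_diff = cfg$cost_levels[2] - cfg$cost_levels[1],
    inc_qol = inc_qol, inc_qaly = sum(w * inc_qol),
    inc_cost = mean(nu_c[arm == 2]) - mean(nu_c[arm == 1]),
    delta = cfg$delta, gamma = cfg$gamma), class = "sim_truth")
  list(data = data, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> inc QoL (%.3f, %.3f), inc QALY %.4f, inc cost %.0f GBP\n",
    x$inc_qol[1], x$inc_qol[2], x$inc_qaly, x$inc_cost))
  invisible(x)
}

#' Mask values of a complete dataset under MCAR or MAR
#'
#' Applies a missingness mechanism to a fully observed dataset.  MAR
#' masking probabilities may depend only on the fully observed fields (age,
#' sex).  Pattern-mixture MNAR cannot be applied as a post-hoc mask — the
#' unobserved values must be drawn from shifted means — so MNAR requests
#' are directed to [generate_trial()].  Original values are retained in
#' the `"truth_values"` attribute for evaluation.
#'
#' @param complete a `trial_data` without missing values in the targeted
#'   fields.
#' @param mechanism list with optional entries `qol`, `cost`, `hardman`;
#'   each a list with `type` (`"MCAR"` or `"MAR"`), `rates` (a `J x K`
#'   matrix for QoL, length-K vector otherwise), and optional `age_coef`.
#' @param seed integer seed.
#' @return a `trial_data` with values masked; identical mask for identical
#'   seeds.
#' @export
apply_missingness <- function(complete, mechanism, seed = 1L) {
  stopifnot(inherits(complete, "trial_data"))
  types <- vapply(mechanism, function(m) m$type, character(1))
  if (any(types == "MNAR"))
    stopf(paste("pattern-mixture MNAR cannot be applied as a post-hoc mask;",
                "use generate_trial() so unobserved values are drawn from",
                "their pattern-specific means"))
  set.seed(seed)
  df <- complete$df
  arm <- df$arm
  age_std <- if ("age" %in% complete$covariates)
    (df$age - mean(df$age)) / stats::sd(df$age) else rep(0, nrow(df))
  truth <- df
  if (!is.null(mechanism$qol)) {
    m <- mechanism$qol
    for (j in seq_len(complete$J)) for (k in seq_len(complete$K)) {
      idx <- which(arm == k)
      p <- miss_prob(m$type, m$rates[j, k], age_std[idx], m$age_coef %||% 0)
      drop_i <- idx[stats::rbinom(length(idx), 1, p) == 1L]
      df[[paste0("qol_", j)]][drop_i] <- NA_real_
    }
  }
  if (!is.null(mechanism$cost)) {
    m <- mechanism$cost
    for (k in seq_len(complete$K)) {
      idx <- which(arm == k)
      p <- miss_prob(m$type, m$rates[k], age_std[idx], m$age_coef %||% 0)
      df$cost[idx[stats::rbinom(length(idx), 1, p) == 1L]] <- NA_real_
    }
  }
  if (!is.null(mechanism$hardman) && "hardman" %in% complete$covariates) {
    m <- mechanism$hardman
    for (k in seq_len(complete$K)) {
      idx <- which(arm == k)
      p <- miss_prob(m$type, m$rates[k], age_std[idx], m$age_coef %||% 0)
      df$hardman[idx[stats::rbinom(length(idx), 1, p) == 1L]] <- NA_integer_
    }
  }
  # masking cannot introduce new violations, so the rebuild skips re-warning
  out <- suppressWarnings(as_trial_data(df, J = complete$J, K = complete$K,
                                        covariates = complete$covariates))
  attr(out, "truth_values") <- truth
  out
}

#' Generate a synthetic expert panel
#'
#' Random experts with locations, spreads and cross-arm correlations drawn
#' uniformly within stated ranges, tagged alternately with role and mode
#' labels so subgroup pooling can be exercised.
#'
#' @param n_experts panel size, at least 1.
#' @param mean_range range for the elicited locations (utility scale).
#' @param sd_range range for the elicited spreads.
#' @param rho_range range for the cross-arm correlations.
#' @param seed optional integer seed.
#' @return list of `expert_prior` objects.
#' @export
generate_expert_panel <- function(n_experts, mean_range = c(0.4, 0.8),
                                  sd_range = c(0.05, 0.2),
                                  rho_range = c(0, 0.6), seed = NULL) {
  stopifnot(n_experts >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_experts), function(i) {
    expert_prior(
      expert_id = sprintf("E%02d", i),
      mean = stats::runif(2, mean_range[1], mean_range[2]),
      sd = stats::runif(2, sd_range[1], sd_range[2]),
      rho = stats::runif(1, rho_range[1], rho_range[2]),
      role = if (i %% 2L) "doctor" else "nurse",
      mode = if (i %% 3L) "face-to-face" else "online")
  })
}
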