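#' QALY mean from quality-of-life means
#'
#' The quality-adjusted life year over the follow-up is a duration-weighted
#' sum of the QoL scores, `QALY = sum_j w_j * QoL_j`.  With two assessments
#' (3 and 12 months) the default weights are (1/2, 3/8), so the mean QALY
#' implied by QoL means `mu` is `mu[1]/2 + 3*mu[2]/8`.
#'
#' @param mu vector of QoL means, one per follow-up assessment.
#' @param weights duration weights, same length as `mu`.
#' @return scalar mean QALY.
#' @examples
#' qaly_mean(c(0.8, 0.6))  # 0.625
#' @export
qaly_mean <- function(mu, weights = c(1 / 2, 3 / 8)) {
  if (length(mu) != length(weights))
    stopf("mu and weights must have equal length")
  sum(weights * mu)
}

#' QALY standard deviation from the QoL covariance
#'
#' For a bivariate QoL vector with standard deviations `sigma1`, `sigma2`
#' and correlation `varrho`, the weighted sum `w1*QoL1 + w2*QoL2` has
#' standard deviation
#' `sqrt(w1^2 s1^2 + 2 w1 w2 varrho s1 s2 + w2^2 s2^2)`; with the default
#' weights this is `sqrt(s1^2/4 + 3*varrho*s1*s2/8 + 9*s2^2/64)`.
#'
#' @param sigma1,sigma2 nonnegative QoL standard deviations.
#' @param varrho QoL correlation in `[-1, 1]`.
#' @param weights duration weights (length 2).
#' @return scalar standard deviation of the QALY.
#' @examples
#' qaly_sd(0.2, 0.4, 0)  # sqrt(0.01 + 0.0225)
#' @export
qaly_sd <- function(sigma1, sigma2, varrho, weights = c(1 / 2, 3 / 8)) {
  stopifnot(sigma1 >= 0, sigma2 >= 0, abs(varrho) <= 1, length(weights) == 2L)
  v <- weights[1]^2 * sigma1^2 +
    2 * weights[1] * weights[2] * varrho * sigma1 * sigma2 +
    weights[2]^2 * sigma2^2
  stopifnot(v >= -1e-12)
  sqrt(max(v, 0))
}

#' Model configuration for the joint pattern-mixture model
#'
#' Describes the joint Bayesian model: an arm-specific bivariate-normal
#' imputation model for the repeated QoL scores with covariate adjustment,
#' linked to a conditional cost model (cost given QALY) that together imply
#' the bivariate QALY/cost substantive model, plus the missingness
#' assumption for each endpoint.  Under MNAR, pattern-mixture offsets are
#' added to the mean of unobserved values: `Delta_jk` for QoL (arm- and,
#' optionally, timepoint-specific) and `Gamma` for cost.
#'
#' @param J number of QoL assessments (currently 2).
#' @param K number of arms (currently 2; arm 1 = reference).
#' @param covariates baseline covariates to adjust for: any of `"age"`,
#'   `"sex"`, `"hardman"` (the 5-level morbidity index, which may itself be
#'   missing and then receives a categorical imputation submodel).
#' @param qaly_weights duration weights combining QoL scores into QALYs.
#' @param qol_missingness `"MAR"` or `"MNAR"`; MNAR requires a sensitivity
#'   prior (or point mass) for `Delta` in [build_model()].
#' @param cost_missingness `"MAR"` or `"MNAR"` (for `Gamma`).
#' @param delta_time_invariant share one `Delta` per arm across timepoints
#'   (default); otherwise independent copies of the prior per timepoint.
#' @param priors list of hyperparameters: `coef_sd` (normal prior sd for
#'   intercepts and coefficients, default 100 — effectively vague on the
#'   utility and thousand-GBP scales), `wishart_df` (degrees of freedom for
#'   the Wishart prior on the QoL precision, default `J`, the minimum),
#'   `wishart_scale` (rate matrix `wishart_scale * I`, default 0.01, weakly
#'   informative on the utility scale), `sigma_c_max` (upper bound of the
#'   uniform prior on the conditional cost residual sd, standardised scale).
#' @param cost_scale costs are divided by this internally (default 1000,
#'   i.e. sampling in thousand-GBP units) and rescaled on output.
#' @return An object of class `model_config`.
#' @export
model_config <- function(J = 2L, K = 2L,
                         covariates = c("age", "sex", "hardman"),
                         qaly_weights = c(1 / 2, 3 / 8),
                         qol_missingness = c("MAR", "MNAR"),
                         cost_missingness = c("MAR", "MNAR"),
                         delta_time_invariant = TRUE,
                         priors = list(), cost_scale = 1000) {
  J <- as.integer(J); K <- as.integer(K)
  stopifnot(J == 2L, K >= 2L, length(qaly_weights) == J)
  p <- list(coef_sd = 100, wishart_df = J, wishart_scale = 0.01,
            sigma_c_max = 100)
  p[names(priors)] <- priors
  if (p$wishart_df < J) stopf("Wishart degrees of freedom must be >= J")
  structure(list(J = J, K = K, covariates = covariates,
                 qaly_weights = qaly_weights,
                 qol_missingness = match.arg(qol_missingness),
                 cost_missingness = match.arg(cost_missingness),
                 delta_time_invariant = isTRUE(delta_time_invariant),
                 priors = p, cost_scale = cost_scale),
            class = "model_config")
}

#' Sensitivity prior on the pattern-mixture offsets
#'
#' Wraps either a point mass (the classic "delta method", used for
#' tipping-point scans) or a mixture-of-bivariate-normals prior (a pooled
#' expert prior, or a single expert) on the QoL offsets
#' `(Delta_arm1, Delta_arm2)`, plus an optional treatment of the cost
#' offset `Gamma`.
#'
#' @param qol either a numeric length-2 vector (point mass per arm, shared
#'   across timepoints), a `J x K` matrix of fixed offsets, a
#'   `pooled_prior`, or a single `expert_prior`.
#' @param gamma `NULL` (costs MAR / `Gamma = 0`), a single number (fixed
#'   offset in GBP), or a list `list(mean=, sd=)` for a normal prior (GBP).
#' @return An object of class `sensitivity_prior` with elements `kind`
#'   (`"point"` or `"mixture"`), `qol`, `gamma`.
#' @export
sensitivity_prior <- function(qol, gamma = NULL) {
  if (inherits(qol, "expert_prior")) qol <- pool_experts(list(qol))
  if (inherits(qol, "pooled_prior")) {
    kind <- "mixture"
  } else if (is.numeric(qol)) {
    kind <- "point"
    if (!is.matrix(qol)) {
      stopifnot(length(qol) == 2L)
      qol <- matrix(qol, nrow = 1)[rep(1, 2), , drop = FALSE] # J x K, J = 2
    }
  } else stopf("qol must be numeric, an expert_prior or a pooled_prior")
  if (!is.null(gamma) && !is.numeric(gamma) &&
      !(is.list(gamma) && all(c("mean", "sd") %in% names(gamma))))
    stopf("gamma must be NULL, a fixed number, or list(mean=, sd=)")
  structure(list(kind = kind, qol = qol, gamma = gamma),
            class = "sensitivity_prior")
}

#' Convert an elicited prior on QoL levels to an offset prior
#'
#' Experts are asked about the QoL level of typical patients with missing
#' data, but the pattern-mixture model needs offsets: the difference
#' between the mean of missing and observed values.  This shifts every
#' mixture component mean by minus the observed-data arm mean at the
#' elicited timepoint, leaving covariances untouched.
#'
#' @param prior_on_levels a `pooled_prior` or `expert_prior` on QoL levels.
#' @param observed_arm_means length-2 vector of complete-case QoL means
#'   (arm 1, arm 2) at the elicited timepoint; see [observed_qol_means()].
#' @return A `sensitivity_prior` of kind `"mixture"` governing `Delta`.
#' @export
elicited_levels_to_offsets <- function(prior_on_levels, observed_arm_means) {
  if (inherits(prior_on_levels, "expert_prior"))
    prior_on_levels <- pool_experts(list(prior_on_levels))
  stopifnot(inherits(prior_on_levels, "pooled_prior"),
            length(observed_arm_means) == 2L)
  if (anyNA(observed_arm_means))
    stopf("no observed QoL values in at least one arm")
  shifted <- new_pooled_prior(
    prior_on_levels$weights,
    lapply(prior_on_levels$means, function(m) m - observed_arm_means),
    prior_on_levels$covs, prior_on_levels$ids)
  out <- sensitivity_prior(qol = shifted)
  out$observed_arm_means <- as.numeric(observed_arm_means)
  out
}

#' Complete-case QoL means per arm
#' @param data a `trial_data`.
#' @param timepoint QoL assessment index (default 1, the elicited one).
#' @return length-K vector of observed-data means.
#' @export
observed_qol_means <- function(data, timepoint = 1L) {
  q <- data$df[[paste0("qol_", timepoint)]]
  out <- vapply(seq_len(data$K), function(k) {
    x <- q[data$df$arm == k & !is.na(q)]
    if (!length(x)) NA_real_ else mean(x)
  }, numeric(1))
  if (anyNA(out)) stopf("no observed QoL values in at least one arm")
  out
}

# Covariate design matrix (age, sex, hardman dummies for levels 2..5)
# given a completed hardman vector.  Columns match rows of state$beta.
covariate_design <- function(model, hardman) {
  n <- model$n
  cols <- list()
  if ("age" %in% model$config$covariates) cols$age <- model$age
  if ("sex" %in% model$config$covariates) cols$sex <- model$sex
  if ("hardman" %in% model$config$covariates) {
    for (h in 2:5) cols[[paste0("h", h)]] <- as.numeric(hardman == h)
  }
  if (!length(cols)) return(matrix(0, n, 0))
  do.call(cbind, cols)
}

#' Build the joint Bayesian pattern-mixture model
#'
#' Assembles the model specification: validated data, configuration and
#' (for MNAR) the sensitivity prior.  The base-case MAR model is obtained
#' by omitting the sensitivity prior and leaving both missingness
#' assumptions at `"MAR"`.
#'
#' @param config a [model_config()].
#' @param data a `trial_data` with `J` and `K` matching the config.
#' @param sensitivity a [sensitivity_prior()], required when either
#'   endpoint is declared MNAR.
#' @return An object of class `cea_model` with a callable log-density
#'   ([log_joint()]) and sampler ([run_mcmc()]).
#' @export
build_model <- function(config, data, sensitivity = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(data, "trial_data"))
  if (data$J != config$J) stopf("data has %d QoL timepoints, config %d",
                                data$J, config$J)
  if (data$K != config$K) stopf("data has %d arms, config %d", data$K, config$K)
  missing_cov <- setdiff(config$covariates, data$covariates)
  if (length(missing_cov))
    stopf("covariate(s) not in dataset: %s", paste(missing_cov, collapse = ", "))
  if (config$qol_missingness == "MNAR" && is.null(sensitivity))
    stopf("MNAR QoL model requested without a sensitivity prior or fixed offset")
  if (config$cost_missingness == "MNAR" &&
      (is.null(sensitivity) || is.null(sensitivity$gamma)))
    stopf("MNAR cost model requested without a prior or fixed value for Gamma")
  df <- data$df
  n <- nrow(df)
  hardman <- if ("hardman" %in% config$covariates) df$hardman else NULL
  if (!is.null(hardman) && any(!is.na(hardman) & !(hardman %in% 1:5)))
    stopf("morbidity index values outside 1..5")
  m <- structure(list(
    config = config, data = data, sensitivity = sensitivity,
    n = n, arm = df$arm,
    y = as.matrix(df[, paste0("qol_", seq_len(config$J))]),
    R = as.matrix(df[, paste0("r_", seq_len(config$J))]),
    cost = df$cost / config$cost_scale, s = df$s,
    age = if ("age" %in% config$covariates) df$age else NULL,
    sex = if ("sex" %in% config$covariates) df$sex else NULL,
    hardman = hardman,
    w = config$qaly_weights), class = "cea_model")
  m$p <- ncol(covariate_design(m, rep(1L, n)))
  m$coef_names <- colnames(covariate_design(m, rep(1L, n)))
  m
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> n = %d, %d arms, %d QoL timepoints\n",
              x$n, x$config$K, x$config$J))
  cat(sprintf("  QoL missingness: %s; cost missingness: %s\n",
              x$config$qol_missingness, x$config$cost_missingness))
  if (!is.null(x$sensitivity))
    cat(sprintf("  sensitivity prior: %s\n", x$sensitivity$kind))
  cat(sprintf("  covariates: %s; %d sampled parameters\n",
              paste(x$config$covariates, collapse = ", "), n_parameters(x)))
  invisible(x)
}

#' Number of sampled parameters in a model
#'
#' Counts the free parameters the sampler updates: arm intercepts for the
#' three equations, covariate coefficients, the per-arm QoL covariances
#' (3 free elements each), the cost slope and residual sd, the morbidity
#' category probabilities (4 free per arm), and any non-fixed sensitivity
#' parameters.
#'
#' @param model a `cea_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  cfg <- model$config
  count <- 3L * cfg$K + 3L * model$p + 3L * cfg$K + 2L
  if ("hardman" %in% cfg$covariates) count <- count + 4L * cfg$K
  if (cfg$qol_missingness == "MNAR" && model$sensitivity$kind == "mixture")
    count <- count + (if (cfg$delta_time_invariant) cfg$K else cfg$J * cfg$K)
  if (cfg$cost_missingness == "MNAR" && is.list(model$sensitivity$gamma))
    count <- count + 1L
  count
}

# Pattern-mixture offset matrix o (n x J) implied by a state.
offset_matrix <- function(model, state) {
  cfg <- model$config
  o <- matrix(0, model$n, cfg$J)
  if (cfg$qol_missingness == "MNAR") {
    for (j in seq_len(cfg$J))
      o[, j] <- (1 - model$R[, j]) * state$delta[j, model$arm]
  }
  o
}

# Mean matrix mu (n x J) for the QoL equations given completed hardman.
mu_matrix <- function(model, state, X) {
  mu <- matrix(0, model$n, model$config$J)
  for (j in seq_len(model$config$J)) {
    mu[, j] <- state$eta[j, model$arm] +
      if (model$p) drop(X %*% state$beta[j, ]) else 0
  }
  mu + offset_matrix(model, state)
}

# Cost linear predictor nu_c (n vector, standardised scale, incl. Gamma).
nu_cost <- function(model, state, X) {
  nu <- state$eta[3, model$arm] + if (model$p) drop(X %*% state$beta[3, ]) else 0
  if (model$config$cost_missingness == "MNAR")
    nu <- nu + (1 - model$s) * state$gamma
  nu
}

#' Linear predictor for one patient record
#'
#' Evaluates `eta_jk + beta_a*age + beta_s*sex + beta_h[category]` for the
#' requested equation, adding the pattern-mixture offset
#' (`(1 - R_ij) * Delta_jk` for QoL, `(1 - S_i) * Gamma` for cost) when the
#' model is MNAR for that endpoint.  The cost equation is on the
#' standardised cost scale.
#'
#' @param record a one-row data frame (or named list) with `arm`, the
#'   configured covariates, and indicators `r_1 ... r_J`, `s`.
#' @param equation `"qol1"`, `"qol2"` or `"cost"`.
#' @param state a parameter state as produced by the sampler.
#' @param config the [model_config()].
#' @return scalar linear predictor.
#' @export
linear_predictor <- function(record, equation = c("qol1", "qol2", "cost"),
                             state, config) {
  equation <- match.arg(equation)
  j <- switch(equation, qol1 = 1L, qol2 = 2L, cost = 3L)
  k <- as.integer(record$arm)
  out <- state$eta[j, k]
  if ("age" %in% config$covariates) out <- out + state$beta[j, "age"] * record$age
  if ("sex" %in% config$covariates) out <- out + state$beta[j, "sex"] * record$sex
  if ("hardman" %in% config$covariates) {
    h <- record$hardman
    if (is.na(h)) stopf("missing covariate not imputed; impute before evaluation")
    if (h >= 2) out <- out + state$beta[j, paste0("h", h)]
  }
  if (equation != "cost" && config$qol_missingness == "MNAR")
    out <- out + (1 - record[[paste0("r_", j)]]) * state$delta[j, k]
  if (equation == "cost" && config$cost_missingness == "MNAR")
    out <- out + (1 - record$s) * state$gamma
  unname(out)
}

# log density of a Wishart(df, V) evaluated at precision P, with the
# conjugate "rate" parameterisation: prior ∝ |P|^((df-d-1)/2) exp(-tr(R0 P)/2),
# R0 = rate matrix = V^{-1}.
log_dwishart <- function(P, df, R0) {
  d <- nrow(P)
  ldetP <- determinant(P, logarithm = TRUE)$modulus
  ldetR0 <- determinant(R0, logarithm = TRUE)$modulus
  lmvgamma <- (d * (d - 1) / 4) * log(pi) +
    sum(lgamma(df / 2 + (1 - seq_len(d)) / 2))
  as.numeric((df - d - 1) / 2 * ldetP - sum(diag(R0 %*% P)) / 2 -
    df * d / 2 * log(2) + df / 2 * ldetR0 - lmvgamma)
}

#' Joint log density of the pattern-mixture model
#'
#' Evaluates the complete-data-augmented log joint: the arm-specific
#' bivariate-normal QoL log-likelihood with pattern-mixture means, the
#' conditional cost log-likelihood
#' `Cost_i | QALY_i ~ N(nu_ic + b (QALY_i - nu_iq), sigma_c^2)` where
#' `QALY_i` is the duration-weighted combination of the (possibly imputed)
#' QoL scores, the categorical covariate-submodel log-likelihood, and (if
#' `include_prior`) all log priors including the sensitivity prior.
#' Missing values must be filled in via `state$imp`.  Returns `-Inf` when
#' any `Sigma_k` is not positive definite.
#'
#' @param model a `cea_model`.
#' @param state a parameter state (see [init_state()]).
#' @param include_prior include the log-prior terms (default `TRUE`).
#' @return scalar log density (finite for interior states).
#' @export
log_joint <- function(model, state, include_prior = TRUE) {
  cfg <- model$config
  for (k in seq_len(cfg$K)) if (!is_pd2(state$Sigma[[k]])) return(-Inf)
  if (state$sigma_c <= 0) return(-Inf)
  comp <- completed_data(model, state)
  X <- covariate_design(model, comp$hardman)
  mu <- mu_matrix(model, state, X)
  ll <- 0
  for (k in seq_len(cfg$K)) {
    idx <- model$arm == k
    ll <- ll + sum(mvtnorm::dmvnorm(comp$y[idx, , drop = FALSE] -
                                      mu[idx, , drop = FALSE],
                                    sigma = state$Sigma[[k]], log = TRUE))
  }
  qaly <- drop(comp$y %*% model$w)
  nu_q <- drop(mu %*% model$w)
  cmean <- nu_cost(model, state, X) + state$b * (qaly - nu_q)
  ll <- ll + sum(stats::dnorm(comp$cost, cmean, state$sigma_c, log = TRUE))
  if ("hardman" %in% cfg$covariates)
    ll <- ll + sum(log(state$pi[cbind(model$arm, comp$hardman)]))
  if (!include_prior) return(ll)
  pr <- sum(stats::dnorm(c(state$eta, state$beta, state$b), 0,
                         cfg$priors$coef_sd, log = TRUE))
  if (state$sigma_c > cfg$priors$sigma_c_max) return(-Inf)
  pr <- pr - log(cfg$priors$sigma_c_max)
  R0 <- diag(cfg$priors$wishart_scale, cfg$J)
  for (k in seq_len(cfg$K))
    pr <- pr + log_dwishart(solve(state$Sigma[[k]]), cfg$priors$wishart_df, R0)
  if (cfg$qol_missingness == "MNAR" && model$sensitivity$kind == "mixture") {
    if (cfg$delta_time_invariant) {
      pr <- pr + log(pooled_density(model$sensitivity$qol, state$delta[1, ]))
    } else {
      for (j in seq_len(cfg$J))
        pr <- pr + log(pooled_density(model$sensitivity$qol, state$delta[j, ]))
    }
  }
  if (cfg$cost_missingness == "MNAR" && is.list(model$sensitivity$gamma)) {
    g <- model$sensitivity$gamma
    pr <- pr + stats::dnorm(state$gamma, g$mean / cfg$cost_scale,
                            g$sd / cfg$cost_scale, log = TRUE)
  }
  ll + pr
}

# Observed data with current imputations substituted.
completed_data <- function(model, state) {
  y <- model$y
  if (length(state$imp$qol)) y[is.na(model$y)] <- state$imp$qol
  cost <- model$cost
  if (length(state$imp$cost)) cost[is.na(model$cost)] <- state$imp$cost
  hardman <- model$hardman
  if (!is.null(hardman) && length(state$imp$hardman))
    hardman[is.na(model$hardman)] <- state$imp$hardman
  if (is.null(hardman)) hardman <- rep(1L, model$n)
  list(y = y, cost = cost, hardman = hardman)
}
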