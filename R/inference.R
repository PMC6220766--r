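#' MCMC settings
#'
#' @param n_chains number of chains (at least 2 so convergence diagnostics
#'   are available; default 2).
#' @param n_iter total post-warmup draws across all chains (default 50000,
#'   i.e. 25000 per chain with two chains).
#' @param warmup warmup (burn-in) iterations per chain, discarded.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param init `"diffuse"` (default) or `"fixed"` (data-based starting
#'   values without dispersion; chains then differ only through their
#'   random-number streams).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2L, n_iter = 50000L, warmup = 5000L,
                          thin = 1L, seed = 1L,
                          init = c("diffuse", "fixed")) {
  stopifnot(n_chains >= 2L, n_iter >= n_chains, warmup >= 0L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed), init = match.arg(init)),
            class = "mcmc_settings")
}

#' Initial parameter state
#'
#' Diffuse initialisation: intercepts drawn from a normal centred at the
#' observed endpoint mean with four times the observed sd, coefficients at
#' zero, per-arm QoL covariances at the complete-case sample covariance,
#' the cost slope from a standard normal, and sensitivity parameters drawn
#' from their prior (or fixed at their point mass).  Missing values are
#' initialised near observed arm means.
#'
#' @param model a `cea_model`.
#' @param init `"diffuse"` or `"fixed"`.
#' @return An object of class `cea_state`.
#' @export
init_state <- function(model, init = "diffuse") {
  cfg <- model$config
  J <- cfg$J; K <- cfg$K
  diff_mult <- if (init == "diffuse") 4 else 0
  eta <- matrix(0, 3, K)
  for (j in seq_len(J)) {
    obs <- model$y[, j][model$R[, j] == 1]
    eta[j, ] <- stats::rnorm(K, mean(obs), diff_mult * stats::sd(obs))
  }
  cobs <- model$cost[model$s == 1]
  eta[3, ] <- stats::rnorm(K, mean(cobs), diff_mult * stats::sd(cobs))
  beta <- matrix(0, 3, model$p, dimnames = list(NULL, model$coef_names))
  Sigma <- vector("list", K)
  for (k in seq_len(K)) {
    yk <- model$y[model$arm == k, , drop = FALSE]
    S <- stats::cov(yk, use = "pairwise.complete.obs")
    if (anyNA(S) || !is_pd2(S)) S <- diag(0.04, J)
    Sigma[[k]] <- S
  }
  b <- stats::rnorm(1, 0, if (init == "diffuse") 1 else 0)
  sigma_c <- stats::sd(cobs) * (if (init == "diffuse") stats::runif(1, 0.7, 1.5) else 1)
  delta <- matrix(0, J, K)
  z <- 1L
  if (cfg$qol_missingness == "MNAR") {
    sp <- model$sensitivity
    if (sp$kind == "point") {
      delta <- sp$qol
    } else {
      d <- sample_prior(sp$qol, if (cfg$delta_time_invariant) 1L else J)
      delta <- if (cfg$delta_time_invariant) matrix(d[1, ], J, K, byrow = TRUE)
               else d
      z <- sample.int(length(sp$qol$weights), 1, prob = sp$qol$weights)
    }
  }
  gamma <- 0
  if (cfg$cost_missingness == "MNAR") {
    g <- model$sensitivity$gamma
    gamma <- if (is.list(g)) stats::rnorm(1, g$mean, g$sd) / cfg$cost_scale
             else g / cfg$cost_scale
  }
  pi <- matrix(0.2, K, 5)
  if ("hardman" %in% cfg$covariates) {
    for (k in seq_len(K)) {
      h <- model$hardman[model$arm == k]
      pi[k, ] <- (tabulate(h[!is.na(h)], 5) + 1) / (sum(!is.na(h)) + 5)
    }
  }
  imp <- list(qol = numeric(0), cost = numeric(0), hardman = integer(0))
  ymiss <- which(is.na(model$y))
  if (length(ymiss)) {
    jj <- (ymiss - 1) %/% model$n + 1
    imp$qol <- eta[cbind(jj, model$arm[(ymiss - 1) %% model$n + 1])] +
      stats::rnorm(length(ymiss), 0, 0.1)
  }
  if (any(model$s == 0))
    imp$cost <- stats::rnorm(sum(model$s == 0), mean(cobs), stats::sd(cobs))
  if (!is.null(model$hardman) && anyNA(model$hardman)) {
    hobs <- model$hardman[!is.na(model$hardman)]
    imp$hardman <- sample(hobs, sum(is.na(model$hardman)), replace = TRUE)
  }
  structure(list(eta = eta, beta = beta, Sigma = Sigma, b = b,
                 sigma_c = sigma_c, delta = delta, gamma = gamma, z = z,
                 pi = pi, imp = imp),
            class = "cea_state")
}

# Monitor names for a model.
monitor_names <- function(model) {
  cfg <- model$config
  nm <- c("inc_qol1", "inc_qol2", "inc_qaly", "inc_cost",
          "eta_qol1_diff", "eta_qol2_diff", "eta_cost_diff",
          paste0("mean_qol1_arm", seq_len(cfg$K)),
          paste0("mean_qol2_arm", seq_len(cfg$K)),
          paste0("mean_cost_arm", seq_len(cfg$K)),
          paste0("qaly_mean_arm", seq_len(cfg$K)),
          "b_slope", "sigma_c",
          as.vector(t(outer(seq_len(cfg$K), c("sigma1", "sigma2", "rho"),
                            function(k, s) paste0(s, "_arm", k)))))
  if (cfg$qol_missingness == "MNAR") {
    nm <- c(nm, if (cfg$delta_time_invariant)
      paste0("delta_arm", seq_len(cfg$K))
      else as.vector(outer(seq_len(cfg$J), seq_len(cfg$K),
                           function(j, k) paste0("delta_qol", j, "_arm", k))))
  }
  if (cfg$cost_missingness == "MNAR") nm <- c(nm, "gamma_cost")
  nm
}

#' Run the Gibbs sampler
#'
#' Samples the joint pattern-mixture model by Gibbs sampling with data
#' augmentation: missing QoL scores, costs and morbidity categories are
#' drawn from their full conditionals each sweep; regression coefficients,
#' the cost slope and the sensitivity offsets have conjugate normal
#' updates (the mixture prior on `Delta` is handled through a component
#' indicator); the QoL precisions are Wishart updates and the morbidity
#' category probabilities Dirichlet updates.  Chains are initialised with
#' diffuse starting values and are reproducible given the seed.
#'
#' @param model a `cea_model` from [build_model()].
#' @param settings an [mcmc_settings()].
#' @return An object of class `cea_draws`: per-chain matrices of monitored
#'   scalars (arm-level marginal means, treatment increments, sensitivity
#'   and covariance parameters) plus metadata.
#' @export
run_mcmc <- function(model, settings = mcmc_settings()) {
  stopifnot(inherits(model, "cea_model"), inherits(settings, "mcmc_settings"))
  n_save <- ceiling(settings$n_iter / settings$n_chains)
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    chains[[ch]] <- run_chain(model, n_save, settings$warmup, settings$thin,
                              settings$init)
  }
  structure(list(chains = chains, settings = settings,
                 monitors = colnames(chains[[1]]),
                 model_info = list(n = model$n,
                                   qol_missingness = model$config$qol_missingness,
                                   cost_missingness = model$config$cost_missingness)),
            class = "cea_draws")
}

#' @export
print.cea_draws <- function(x, ...) {
  cat(sprintf("<cea_draws> %d chains x %d draws; %d monitored quantities\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$monitors)))
  invisible(x)
}

#' Extract the pooled draws of one monitored quantity
#' @param draws a `cea_draws`.
#' @param parameter monitored name, e.g. `"inc_qaly"`.
#' @return numeric vector (chains concatenated).
#' @export
get_draws <- function(draws, parameter) {
  stopifnot(inherits(draws, "cea_draws"))
  if (!parameter %in% draws$monitors)
    stopf("'%s' is not a monitored quantity (available: %s)", parameter,
          paste(draws$monitors, collapse = ", "))
  unlist(lapply(draws$chains, function(m) m[, parameter]), use.names = FALSE)
}

#' Monte Carlo standard error of a posterior mean
#'
#' Batch-means MCSE computed per chain and combined across chains.
#'
#' @param draws a `cea_draws`.
#' @param parameter monitored name.
#' @return scalar MCSE.
#' @export
posterior_mcse <- function(draws, parameter) {
  if (!parameter %in% draws$monitors)
    stopf("'%s' is not a monitored quantity", parameter)
  per <- vapply(draws$chains, function(m) mcse_batch(m[, parameter]), numeric(1))
  sqrt(sum(per^2)) / length(per)
}

# ---- internal sampler -----------------------------------------------------

run_chain <- function(model, n_save, warmup, thin, init) {
  cfg <- model$config
  J <- cfg$J; K <- cfg$K; n <- model$n; w <- model$w
  arm <- model$arm
  idx_arm <- lapply(seq_len(K), function(k) which(arm == k))
  n_k <- lengths(idx_arm)
  D <- matrix(0, n, K); D[cbind(seq_len(n), arm)] <- 1
  R <- model$R
  miss1 <- which(R[, 1] == 0 & R[, 2] == 1)
  miss2 <- which(R[, 1] == 1 & R[, 2] == 0)
  missb <- which(R[, 1] == 0 & R[, 2] == 0)
  miss_c <- which(model$s == 0)
  miss_h <- if (is.null(model$hardman)) integer(0) else which(is.na(model$hardman))
  miss_any_y <- which(is.na(model$y))
  qol_mnar <- cfg$qol_missingness == "MNAR"
  cost_mnar <- cfg$cost_missingness == "MNAR"
  sp <- model$sensitivity
  delta_free <- qol_mnar && sp$kind == "mixture"
  gamma_free <- cost_mnar && is.list(sp$gamma)
  gamma_prior <- if (gamma_free)
    list(mean = sp$gamma$mean / cfg$cost_scale, sd = sp$gamma$sd / cfg$cost_scale)
  coef_prec <- 1 / cfg$priors$coef_sd^2
  R0 <- diag(cfg$priors$wishart_scale, J)
  df0 <- cfg$priors$wishart_df

  # precomputed pieces of the mixture prior on Delta, and a collapsed
  # sampler: the component indicator is drawn with Delta integrated out
  # (the Gaussian likelihood times each normal component has a closed-form
  # marginal), then Delta is drawn from the selected component's
  # conditional -- this avoids the slow mixing of alternating z | Delta
  # and Delta | z when the panel has many separated components
  if (delta_free) {
    n_comp <- length(sp$qol$weights)
    pr_P <- lapply(sp$qol$covs, solve)
    pr_Pm <- Map(function(P, m) drop(P %*% m), pr_P, sp$qol$means)
    pr_lw0 <- log(sp$qol$weights) -
      0.5 * vapply(sp$qol$covs, function(S)
        log(S[1, 1] * S[2, 2] - S[1, 2]^2), numeric(1)) -
      0.5 * vapply(seq_len(n_comp), function(e)
        sum(sp$qol$means[[e]] * pr_Pm[[e]]), numeric(1))
    collapsed_draw <- function(Q, l) {
      lw <- numeric(n_comp); mus <- matrix(0, 2, n_comp)
      As <- vector("list", n_comp)
      for (e in seq_len(n_comp)) {
        Ae <- Q + pr_P[[e]]
        detA <- Ae[1, 1] * Ae[2, 2] - Ae[1, 2] * Ae[2, 1]
        be <- l + pr_Pm[[e]]
        mue <- c(Ae[2, 2] * be[1] - Ae[1, 2] * be[2],
                 -Ae[2, 1] * be[1] + Ae[1, 1] * be[2]) / detA
        lw[e] <- pr_lw0[e] - 0.5 * log(detA) + 0.5 * sum(be * mue)
        mus[, e] <- mue; As[[e]] <- Ae
      }
      znew <- sample.int(n_comp, 1, prob = exp(lw - max(lw)))
      R <- chol(As[[znew]])
      list(z = znew, d = mus[, znew] + backsolve(R, stats::rnorm(2)))
    }
  }

  # initial state, with a retry cap on non-finite log densities
  state <- NULL
  for (try in 1:20) {
    cand <- init_state(model, init)
    if (is.finite(log_joint(model, cand))) { state <- cand; break }
  }
  if (is.null(state)) stopf("could not find a finite starting state")

  ycur <- model$y
  if (length(miss_any_y)) ycur[miss_any_y] <- state$imp$qol
  ccur <- model$cost
  if (length(miss_c)) ccur[miss_c] <- state$imp$cost
  hcur <- model$hardman
  if (length(miss_h)) hcur[miss_h] <- state$imp$hardman
  if (is.null(hcur)) hcur <- rep(1L, n)

  eta <- state$eta; beta <- state$beta; Sigma <- state$Sigma
  b <- state$b; sigma_c <- state$sigma_c
  delta <- state$delta; gamma <- state$gamma; z <- state$z; pii <- state$pi
  has_h <- "hardman" %in% cfg$covariates
  X <- covariate_design(model, hcur)
  p <- model$p; q <- K + p

  off <- matrix(0, n, J)                      # pattern-mixture offsets
  upd_off <- function() {
    if (qol_mnar) for (j in seq_len(J)) off[, j] <<- (1 - R[, j]) * delta[j, arm]
  }
  upd_off()
  mu_fixed <- function() {                    # n x J, excluding offsets
    m <- matrix(0, n, J)
    for (j in seq_len(J))
      m[, j] <- eta[j, arm] + if (p) drop(X %*% beta[j, ]) else 0
    m
  }
  nu_c_fn <- function() {
    v <- eta[3, arm] + if (p) drop(X %*% beta[3, ]) else 0
    if (cost_mnar) v + (1 - model$s) * gamma else v
  }

  out <- matrix(NA_real_, n_save, length(monitor_names(model)),
                dimnames = list(NULL, monitor_names(model)))
  saved <- 0L
  total <- warmup + n_save * thin

  for (iter in seq_len(total)) {
    mu0 <- mu_fixed()                         # before offsets
    mu <- mu0 + off
    nu_c <- nu_c_fn()
    qaly <- drop(ycur %*% w)
    nu_q <- drop(mu %*% w)

    ## --- impute morbidity category -------------------------------------
    if (length(miss_h)) {
      logw <- matrix(0, length(miss_h), 5)
      karm <- arm[miss_h]
      base1 <- mu[miss_h, 1] - ifelse(hcur[miss_h] >= 2,
                                      beta[1, paste0("h", pmax(hcur[miss_h], 2))], 0)
      base2 <- mu[miss_h, 2] - ifelse(hcur[miss_h] >= 2,
                                      beta[2, paste0("h", pmax(hcur[miss_h], 2))], 0)
      base3 <- nu_c[miss_h] - ifelse(hcur[miss_h] >= 2,
                                     beta[3, paste0("h", pmax(hcur[miss_h], 2))], 0)
      for (cat_h in 1:5) {
        b1 <- if (cat_h >= 2) beta[1, paste0("h", cat_h)] else 0
        b2 <- if (cat_h >= 2) beta[2, paste0("h", cat_h)] else 0
        b3 <- if (cat_h >= 2) beta[3, paste0("h", cat_h)] else 0
        m1 <- base1 + b1; m2 <- base2 + b2
        ll <- numeric(length(miss_h))
        for (k in seq_len(K)) {
          kk <- karm == k
          if (!any(kk)) next
          ll[kk] <- dbvn_log(ycur[miss_h[kk], 1] - m1[kk],
                             ycur[miss_h[kk], 2] - m2[kk], Sigma[[k]])
        }
        cm <- base3 + b3 + b * (qaly[miss_h] - (w[1] * m1 + w[2] * m2))
        ll <- ll + stats::dnorm(ccur[miss_h], cm, sigma_c, log = TRUE) +
          log(pii[cbind(karm, cat_h)])
        logw[, cat_h] <- ll
      }
      logw <- logw - apply(logw, 1, max)
      pw <- exp(logw); pw <- pw / rowSums(pw)
      u <- stats::runif(length(miss_h))
      cs <- t(apply(pw, 1, cumsum))
      hcur[miss_h] <- as.integer(1L + rowSums(cs < u))
      X <- covariate_design(model, hcur)
      mu0 <- mu_fixed(); mu <- mu0 + off; nu_c <- nu_c_fn()
      nu_q <- drop(mu %*% w)
    }

    ## --- impute missing QoL --------------------------------------------
    # cost feedback: Cost ~ N(nu_c + b*(w'y - nu_q), sigma_c^2)
    r_c <- ccur - nu_c + b * nu_q             # = b*w'y + resid at y = 0
    S11 <- vapply(Sigma, function(S) S[1, 1], numeric(1))
    S22 <- vapply(Sigma, function(S) S[2, 2], numeric(1))
    S12 <- vapply(Sigma, function(S) S[1, 2], numeric(1))
    if (length(miss1)) {
      k1 <- arm[miss1]
      s11 <- S11[k1]; s22 <- S22[k1]; s12 <- S12[k1]
      pm <- mu[miss1, 1] + s12 / s22 * (ycur[miss1, 2] - mu[miss1, 2])
      pv <- s11 - s12^2 / s22
      prec <- 1 / pv + (b * w[1])^2 / sigma_c^2
      lin <- pm / pv + (b * w[1]) / sigma_c^2 *
        (r_c[miss1] - b * w[2] * ycur[miss1, 2])
      ycur[miss1, 1] <- stats::rnorm(length(miss1), lin / prec, sqrt(1 / prec))
    }
    if (length(miss2)) {
      k2 <- arm[miss2]
      s11 <- S11[k2]; s22 <- S22[k2]; s12 <- S12[k2]
      pm <- mu[miss2, 2] + s12 / s11 * (ycur[miss2, 1] - mu[miss2, 1])
      pv <- s22 - s12^2 / s11
      prec <- 1 / pv + (b * w[2])^2 / sigma_c^2
      lin <- pm / pv + (b * w[2]) / sigma_c^2 *
        (r_c[miss2] - b * w[1] * ycur[miss2, 1])
      ycur[miss2, 2] <- stats::rnorm(length(miss2), lin / prec, sqrt(1 / prec))
    }
    if (length(missb)) {
      for (k in seq_len(K)) {
        ib <- missb[arm[missb] == k]
        if (!length(ib)) next
        P <- solve(Sigma[[k]]) + (b^2 / sigma_c^2) * tcrossprod(w)
        V <- solve(P)
        lin <- t(solve(Sigma[[k]], t(mu[ib, , drop = FALSE]))) +
          (b / sigma_c^2) * outer(r_c[ib], w)
        mn <- lin %*% V
        ycur[ib, ] <- mn + mvtnorm::rmvnorm(length(ib), sigma = V)
      }
    }
    qaly <- drop(ycur %*% w)

    ## --- impute missing cost --------------------------------------------
    if (length(miss_c)) {
      cm <- nu_c[miss_c] + b * (qaly[miss_c] - nu_q[miss_c])
      ccur[miss_c] <- stats::rnorm(length(miss_c), cm, sigma_c)
    }

    ## --- QoL regression block (eta_1., eta_2., beta_1., beta_2.) --------
    Z <- cbind(D, X)
    A <- matrix(0, 2 * q, 2 * q)
    mvec <- numeric(2 * q)
    for (k in seq_len(K)) {
      ik <- idx_arm[[k]]
      P <- solve(Sigma[[k]])
      Zk <- Z[ik, , drop = FALSE]
      ZtZ <- crossprod(Zk)
      yt <- cbind(ycur[ik, 1] - off[ik, 1], ycur[ik, 2] - off[ik, 2])
      for (j1 in 1:2) for (j2 in 1:2) {
        A[((j1 - 1) * q + 1):(j1 * q), ((j2 - 1) * q + 1):(j2 * q)] <-
          A[((j1 - 1) * q + 1):(j1 * q), ((j2 - 1) * q + 1):(j2 * q)] +
          P[j1, j2] * ZtZ
      }
      for (j1 in 1:2) {
        mvec[((j1 - 1) * q + 1):(j1 * q)] <-
          mvec[((j1 - 1) * q + 1):(j1 * q)] +
          crossprod(Zk, P[j1, 1] * yt[, 1] + P[j1, 2] * yt[, 2])
      }
    }
    # cost feedback through -b * nu_q
    a_i <- nu_c
    u <- ccur - a_i - b * qaly + b * drop(off %*% w)
    H <- cbind(-b * w[1] * Z, -b * w[2] * Z)
    A <- A + crossprod(H) / sigma_c^2
    mvec <- mvec + crossprod(H, u) / sigma_c^2
    diag(A) <- diag(A) + coef_prec
    th <- draw_mvn_canonical(A, mvec)
    eta[1, ] <- th[1:K]
    if (p) beta[1, ] <- th[(K + 1):q]
    eta[2, ] <- th[q + (1:K)]
    if (p) beta[2, ] <- th[(q + K + 1):(2 * q)]
    mu0 <- mu_fixed(); mu <- mu0 + off
    nu_q <- drop(mu %*% w)

    ## --- cost regression block (eta_3., beta_3., b [, gamma]) -----------
    Wd <- cbind(Z, qaly - nu_q)
    prior_mean <- rep(0, ncol(Wd))
    prior_prec <- rep(coef_prec, ncol(Wd))
    resp <- ccur
    if (cost_mnar) {
      if (gamma_free) {
        Wd <- cbind(Wd, 1 - model$s)
        prior_mean <- c(prior_mean, gamma_prior$mean)
        prior_prec <- c(prior_prec, 1 / gamma_prior$sd^2)
      } else resp <- resp - (1 - model$s) * gamma
    }
    A3 <- crossprod(Wd) / sigma_c^2
    diag(A3) <- diag(A3) + prior_prec
    m3 <- crossprod(Wd, resp) / sigma_c^2 + prior_prec * prior_mean
    th3 <- draw_mvn_canonical(A3, m3)
    eta[3, ] <- th3[1:K]
    if (p) beta[3, ] <- th3[(K + 1):q]
    b <- th3[q + 1]
    if (gamma_free) gamma <- th3[q + 2]
    nu_c <- nu_c_fn()

    ## --- conditional cost residual sd -----------------------------------
    resid <- ccur - nu_c - b * (qaly - nu_q)
    SS <- sum(resid^2)
    for (try in 1:100) {
      tau <- (SS / 2) / stats::rgamma(1, (n - 1) / 2)
      if (sqrt(tau) < cfg$priors$sigma_c_max) break
    }
    sigma_c <- sqrt(tau)

    ## --- QoL covariances -------------------------------------------------
    for (k in seq_len(K)) {
      ik <- idx_arm[[k]]
      E <- ycur[ik, , drop = FALSE] - mu[ik, , drop = FALSE]
      Sk <- R0 + crossprod(E)
      Prec <- stats::rWishart(1, df0 + n_k[k], solve(Sk))[, , 1]
      Sigma[[k]] <- solve(Prec)
    }

    ## --- sensitivity offsets Delta (mixture prior) ----------------------
    if (delta_free) {
      if (cfg$delta_time_invariant) {
        qk <- numeric(K); lk <- numeric(K)
        for (k in seq_len(K)) {
          ik <- idx_arm[[k]]
          mi <- cbind(1 - R[ik, 1], 1 - R[ik, 2])
          any_m <- rowSums(mi) > 0
          if (!any(any_m)) next
          ikm <- ik[any_m]; mim <- mi[any_m, , drop = FALSE]
          P <- solve(Sigma[[k]])
          e0 <- cbind(ycur[ikm, 1] - mu0[ikm, 1], ycur[ikm, 2] - mu0[ikm, 2])
          qk[k] <- sum((mim %*% P) * mim)
          lk[k] <- sum((e0 %*% P) * mim)
          cw <- b * drop(mim %*% w)
          r0 <- ccur[ikm] - nu_c[ikm] - b * (qaly[ikm] - drop(mu0[ikm, , drop = FALSE] %*% w))
          qk[k] <- qk[k] + sum(cw^2) / sigma_c^2
          lk[k] <- lk[k] - sum(cw * r0) / sigma_c^2
        }
        res <- collapsed_draw(diag(qk, 2), lk)
        z <- res$z
        delta <- matrix(res$d, J, K, byrow = TRUE)
      } else {
        # free (j, k) offsets: likelihood couples timepoints within an arm,
        # the prior couples arms within a timepoint
        Ad <- matrix(0, J * K, J * K)   # order (j=1,k=1),(j=2,k=1),(j=1,k=2),...
        md <- numeric(J * K)
        for (k in seq_len(K)) {
          ik <- idx_arm[[k]]
          mi <- cbind(1 - R[ik, 1], 1 - R[ik, 2])
          any_m <- rowSums(mi) > 0
          pos <- (k - 1) * J + (1:J)
          if (any(any_m)) {
            ikm <- ik[any_m]; mim <- mi[any_m, , drop = FALSE]
            P <- solve(Sigma[[k]])
            e0 <- cbind(ycur[ikm, 1] - mu0[ikm, 1], ycur[ikm, 2] - mu0[ikm, 2])
            for (i in seq_along(ikm)) {
              Mi <- diag(mim[i, ], J)
              Ad[pos, pos] <- Ad[pos, pos] + Mi %*% P %*% Mi
              md[pos] <- md[pos] + drop(Mi %*% P %*% e0[i, ])
            }
            cw <- b * (mim * matrix(w, nrow(mim), J, byrow = TRUE))
            r0 <- ccur[ikm] - nu_c[ikm] -
              b * (qaly[ikm] - drop(mu0[ikm, , drop = FALSE] %*% w))
            Ad[pos, pos] <- Ad[pos, pos] + crossprod(cw) / sigma_c^2
            md[pos] <- md[pos] - crossprod(cw, r0) / sigma_c^2
          }
        }
        # per-timepoint collapsed updates, conditioning on the other
        # timepoint's offsets through the likelihood cross-blocks
        zs <- if (length(z) == J) z else rep(z[1], J)
        dvec <- as.vector(delta)        # order (j=1,k=1),(j=2,k=1),(j=1,k=2),...
        for (j in seq_len(J)) {
          pos_j <- (seq_len(K) - 1) * J + j
          pos_o <- setdiff(seq_len(J * K), pos_j)
          lj <- md[pos_j] - drop(Ad[pos_j, pos_o, drop = FALSE] %*% dvec[pos_o])
          res <- collapsed_draw(Ad[pos_j, pos_j], lj)
          zs[j] <- res$z
          dvec[pos_j] <- res$d
        }
        z <- zs
        delta <- matrix(dvec, J, K)
      }
      upd_off()
      mu <- mu0 + off
      nu_q <- drop(mu %*% w)
    }

    ## --- morbidity category probabilities --------------------------------
    if (has_h) {
      for (k in seq_len(K)) {
        g <- stats::rgamma(5, 1 + tabulate(hcur[idx_arm[[k]]], 5))
        pii[k, ] <- g / sum(g)
      }
    }

    ## --- record -----------------------------------------------------------
    if (iter > warmup && (iter - warmup) %% thin == 0L) {
      saved <- saved + 1L
      mean_q <- vapply(seq_len(K), function(k)
        colMeans(mu[idx_arm[[k]], , drop = FALSE]), numeric(J))   # J x K
      mean_c <- vapply(seq_len(K), function(k) mean(nu_c[idx_arm[[k]]]),
                       numeric(1)) * cfg$cost_scale
      inc_q <- mean_q[, 2] - mean_q[, 1]
      rec <- c(inc_q[1], inc_q[2], sum(w * inc_q), mean_c[2] - mean_c[1],
               eta[1, 2] - eta[1, 1], eta[2, 2] - eta[2, 1],
               (eta[3, 2] - eta[3, 1]) * cfg$cost_scale,
               mean_q[1, ], mean_q[2, ], mean_c,
               drop(w %*% mean_q),
               b * cfg$cost_scale, sigma_c * cfg$cost_scale,
               as.vector(vapply(seq_len(K), function(k)
                 c(sqrt(Sigma[[k]][1, 1]), sqrt(Sigma[[k]][2, 2]),
                   Sigma[[k]][1, 2] / sqrt(Sigma[[k]][1, 1] * Sigma[[k]][2, 2])),
                 numeric(3))))
      if (qol_mnar)
        rec <- c(rec, if (cfg$delta_time_invariant) delta[1, ] else as.vector(delta))
      if (cost_mnar) rec <- c(rec, gamma * cfg$cost_scale)
      out[saved, ] <- rec
    }
  }
  out
}

# ---- diagnostics ----------------------------------------------------------

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (rank-free) PSRF from between- and within-chain variances:
#' with m chains of length n, `What` the mean within-chain variance and `B`
#' n times the variance of the chain means,
#' `Rhat = sqrt(((n-1)/n * What + (1 + 1/m) * B/n) / What)`.
#'
#' @param draws a `cea_draws` (at least 2 chains of at least 10 draws).
#' @param parameter monitored name.
#' @return scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(draws, parameter) {
  stopifnot(inherits(draws, "cea_draws"))
  if (length(draws$chains) < 2L)
    stopf("Gelman-Rubin diagnostic requires at least two chains")
  x <- lapply(draws$chains, function(m) m[, parameter])
  n <- length(x[[1]])
  if (n < 10L) stopf("need at least 10 draws per chain")
  m <- length(x)
  means <- vapply(x, mean, numeric(1))
  vars <- vapply(x, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + (1 + 1 / m) * B / n) / W)
}

#' Assess MCMC convergence
#'
#' Computes the Gelman-Rubin statistic and a batch-means effective sample
#' size for each monitored parameter and flags the run as passed when every
#' Rhat is below the threshold (1.05 by convention here).
#'
#' @param draws a `cea_draws`.
#' @param threshold Rhat pass threshold (default 1.05).
#' @param parameters monitored names to check (default: all).
#' @return An object of class `convergence_report`: data frame `table` with
#'   `parameter`, `rhat`, `ess`, plus `pass` and `threshold`.
#' @export
assess_convergence <- function(draws, threshold = 1.05, parameters = NULL) {
  stopifnot(inherits(draws, "cea_draws"))
  parameters <- parameters %||% draws$monitors
  if (!length(parameters)) stopf("empty monitor list")
  tab <- data.frame(parameter = parameters,
                    rhat = vapply(parameters, function(p) gelman_rubin(draws, p),
                                  numeric(1)),
                    ess = vapply(parameters, function(p) {
                      x <- get_draws(draws, p)
                      se <- posterior_mcse(draws, p)
                      if (se == 0) length(x) else min((stats::sd(x) / se)^2,
                                                      length(x))
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 pass = all(is.finite(tab$rhat)) && all(tab$rhat < threshold)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s (threshold Rhat < %.3f)\n",
              if (x$pass) "PASS" else "FAIL", x$threshold))
  worst <- x$table[order(-x$table$rhat), ][1:min(5, nrow(x$table)), ]
  print(worst, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Trace data for plotting
#'
#' Long-format draws (chain, iteration, parameter, value) for any plotting
#' layer; the package deliberately exports data, not figures.
#'
#' @param draws a `cea_draws`.
#' @param parameters monitored names (default: all).
#' @return data frame.
#' @export
trace_data <- function(draws, parameters = NULL) {
  parameters <- parameters %||% draws$monitors
  do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    do.call(rbind, lapply(parameters, function(p)
      data.frame(chain = ch, iter = seq_len(nrow(m)), parameter = p,
                 value = m[, p], stringsAsFactors = FALSE)))
  }))
}
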