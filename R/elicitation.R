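#' Expert beliefs as bivariate normal priors
#'
#' Each expert's belief about the quality-of-life of "typical" patients with
#' missing QoL data is represented as a bivariate normal distribution over
#' the two arms: a location and spread per arm plus a cross-arm correlation.
#' Arm 1 is the reference/control arm, arm 2 the intervention arm.  The
#' elicited spread is interpreted as a standard deviation.
#'
#' @param expert_id identifier string.
#' @param mean length-2 vector of elicited locations (arm 1, arm 2), on the
#'   scale the question was asked (here the utility scale).
#' @param sd length-2 vector of elicited standard deviations, strictly
#'   positive.
#' @param rho cross-arm correlation in (-1, 1).
#' @param role optional tag, e.g. `"doctor"` or `"nurse"`.
#' @param mode optional tag, e.g. `"face-to-face"` or `"online"`.
#' @return An object of class `expert_prior`.
#' @export
expert_prior <- function(expert_id, mean, sd, rho = 0, role = NA_character_,
                         mode = NA_character_) {
  stopifnot(length(mean) == 2L, length(sd) == 2L, length(rho) == 1L)
  if (any(sd <= 0)) stopf("elicited spreads must be strictly positive")
  if (abs(rho) >= 1) stopf("cross-arm correlation must lie in (-1, 1)")
  structure(list(expert_id = as.character(expert_id), role = role, mode = mode,
                 mean = as.numeric(mean), sd = as.numeric(sd),
                 rho = as.numeric(rho)),
            class = "expert_prior")
}

#' @export
print.expert_prior <- function(x, ...) {
  cat(sprintf(
    "<expert_prior> %s: mean (%.3f, %.3f), sd (%.3f, %.3f), rho %.3f\n",
    x$expert_id, x$mean[1], x$mean[2], x$sd[1], x$sd[2], x$rho))
  invisible(x)
}

#' Covariance matrix implied by an expert prior
#' @param expert an `expert_prior`.
#' @return 2x2 covariance matrix.
#' @export
expert_cov <- function(expert) {
  s <- expert$sd
  matrix(c(s[1]^2, expert$rho * s[1] * s[2],
           expert$rho * s[1] * s[2], s[2]^2), 2, 2)
}

#' Assemble an expert's joint prior from a conditional answer
#'
#' Experts state a location and spread per arm, then answer one conditional
#' question: their expected arm-2 value given that the arm-1 value equals
#' `x0`.  Under the bivariate normal representation
#' `E[Y2 | Y1 = x0] = m2 + rho * (s2/s1) * (x0 - m1)`, which is inverted for
#' the cross-arm correlation.  Implied correlations outside (-0.999, 0.999)
#' are clipped with a warning.
#'
#' @param m1,s1 location and spread for arm 1 (reference).
#' @param m2,s2 location and spread for arm 2 (intervention).
#' @param x0 conditioning value for arm 1; must differ from `m1`.
#' @param cond_mean elicited arm-2 location given arm 1 equals `x0`.
#' @inheritParams expert_prior
#' @return An `expert_prior` with the implied correlation.
#' @examples
#' e <- expert_prior_from_conditional(0.6, 0.1, 0.7, 0.1, x0 = 0.7,
#'                                    cond_mean = 0.75)
#' e$rho  # 0.5
#' @export
expert_prior_from_conditional <- function(m1, s1, m2, s2, x0, cond_mean,
                                          expert_id = "expert",
                                          role = NA_character_,
                                          mode = NA_character_) {
  if (s1 <= 0 || s2 <= 0) stopf("elicited spreads must be strictly positive")
  if (x0 == m1)
    stopf(paste("undefined correlation: the conditioning value equals the",
                "arm-1 location; re-elicit with a different conditioning value"))
  rho <- (cond_mean - m2) * s1 / (s2 * (x0 - m1))
  if (abs(rho) >= 1) {
    warnf("implied correlation %.3f outside (-1, 1); clipped to %s0.999",
          rho, if (rho > 0) "" else "-")
    rho <- sign(rho) * 0.999
  }
  expert_prior(expert_id, c(m1, m2), c(s1, s2), rho, role = role, mode = mode)
}

#' Conditional mean read back from an expert prior
#' @param expert an `expert_prior`.
#' @param x0 conditioning arm-1 value.
#' @return `E[Y2 | Y1 = x0]` under the expert's joint normal.
#' @export
expert_conditional_mean <- function(expert, x0) {
  expert$mean[2] + expert$rho * (expert$sd[2] / expert$sd[1]) *
    (x0 - expert$mean[1])
}

#' Pool expert priors by linear opinion pooling
#'
#' Aggregates individual bivariate normal priors as a weighted arithmetic
#' mean of densities, i.e. a finite mixture of bivariate normals.  The
#' default is equal weights.  Although every component is normal, the pooled
#' prior generally is not.
#'
#' @param experts nonempty list of `expert_prior` objects (a single
#'   `expert_prior` is accepted).
#' @param weights optional nonnegative weights, one per expert, not all
#'   zero; normalised internally.
#' @return An object of class `pooled_prior`: list with `weights`
#'   (normalised), `means` (list of 2-vectors), `covs` (list of 2x2
#'   matrices) and the component `ids`.
#' @export
pool_experts <- function(experts, weights = NULL) {
  if (inherits(experts, "expert_prior")) experts <- list(experts)
  if (!length(experts)) stopf("cannot pool an empty expert list")
  stopifnot(all(vapply(experts, inherits, logical(1), "expert_prior")))
  if (is.null(weights)) weights <- rep(1, length(experts))
  if (length(weights) != length(experts))
    stopf("weights must match the number of experts")
  if (any(weights < 0) || sum(weights) == 0)
    stopf("weights must be nonnegative and not all zero")
  new_pooled_prior(weights / sum(weights),
                   lapply(experts, `[[`, "mean"),
                   lapply(experts, expert_cov),
                   vapply(experts, `[[`, character(1), "expert_id"))
}

new_pooled_prior <- function(weights, means, covs, ids = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-12)
  for (S in covs) if (!is_pd2(S)) stopf("component covariance not positive definite")
  structure(list(weights = as.numeric(weights), means = means, covs = covs,
                 ids = ids %||% paste0("component", seq_along(weights))),
            class = "pooled_prior")
}

#' @export
print.pooled_prior <- function(x, ...) {
  m <- pooled_mean(x)
  cat(sprintf("<pooled_prior> %d component(s); mixture mean (%.3f, %.3f)\n",
              length(x$weights), m[1], m[2]))
  invisible(x)
}

#' Mixture mean of a pooled prior
#' @param prior a `pooled_prior`.
#' @return length-2 vector.
#' @export
pooled_mean <- function(prior) {
  drop(Reduce(`+`, Map(function(w, m) w * m, prior$weights, prior$means)))
}

#' Mixture covariance of a pooled prior
#' @param prior a `pooled_prior`.
#' @return 2x2 matrix (law of total variance over components).
#' @export
pooled_cov <- function(prior) {
  mbar <- pooled_mean(prior)
  Reduce(`+`, Map(function(w, m, S) {
    d <- m - mbar
    w * (S + tcrossprod(d))
  }, prior$weights, prior$means, prior$covs))
}

#' Density of a pooled prior
#'
#' Evaluates the linear pool `sum_e w_e * N(point; m_e, S_e)`.
#'
#' @param prior a `pooled_prior`.
#' @param point length-2 vector, or an n x 2 matrix of points.
#' @return density value(s), nonnegative.
#' @export
pooled_density <- function(prior, point) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  out <- numeric(nrow(pts))
  for (e in seq_along(prior$weights)) {
    out <- out + prior$weights[e] *
      mvtnorm::dmvnorm(pts, mean = prior$means[[e]], sigma = prior$covs[[e]])
  }
  if (is.matrix(point)) out else out[1]
}

#' Sample from a pooled prior
#'
#' Draws by component selection followed by component sampling; a variance
#' floor of 1e-12 keeps near-degenerate components drawable.
#'
#' @param prior a `pooled_prior`.
#' @param n number of draws, at least 1.
#' @param seed optional integer seed for reproducibility.
#' @return n x 2 matrix of draws.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(prior$weights), n, replace = TRUE,
                     prob = prior$weights)
  out <- matrix(NA_real_, n, 2)
  for (e in unique(comp)) {
    idx <- which(comp == e)
    S <- prior$covs[[e]] + diag(1e-12, 2)
    out[idx, ] <- mvtnorm::rmvnorm(length(idx), mean = prior$means[[e]],
                                   sigma = S)
  }
  colnames(out) <- c("arm1", "arm2")
  out
}

#' Select an extreme expert from a panel
#'
#' Scepticism/enthusiasm are judged on the arm mean difference (sceptical =
#' largest arm1 - arm2 difference, i.e. favouring the control arm;
#' enthusiastic = largest arm2 - arm1); certainty on the generalised
#' variance (determinant of the expert covariance), smallest = most certain.
#' Ties are broken by list order.
#'
#' @param experts nonempty list of `expert_prior` objects.
#' @param criterion one of `"sceptical"`, `"enthusiastic"`,
#'   `"most_certain"`, `"least_certain"`.
#' @return The selected `expert_prior`.
#' @export
select_extreme_expert <- function(experts,
                                  criterion = c("sceptical", "enthusiastic",
                                                "most_certain",
                                                "least_certain")) {
  if (inherits(experts, "expert_prior")) experts <- list(experts)
  if (!length(experts)) stopf("cannot select from an empty expert list")
  criterion <- match.arg(criterion)
  score <- switch(criterion,
    sceptical = vapply(experts, function(e) e$mean[1] - e$mean[2], numeric(1)),
    enthusiastic = vapply(experts, function(e) e$mean[2] - e$mean[1], numeric(1)),
    most_certain = vapply(experts, function(e) -det(expert_cov(e)), numeric(1)),
    least_certain = vapply(experts, function(e) det(expert_cov(e)), numeric(1)))
  experts[[which.max(score)]]
}

#' Read expert elicitation records
#'
#' Accepts a CSV file (columns `expert_id`, `role`, `mode`, `m1`, `s1`,
#' `m2`, `s2`, `x0`, `cond_mean`) or a JSON array of records with the same
#' fields, and converts each conditional answer into a joint prior.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return list of `expert_prior` objects.
#' @export
read_expert_records <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("expert_id", "m1", "s1", "m2", "s2", "x0", "cond_mean")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stopf("schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    expert_prior_from_conditional(
      tab$m1[i], tab$s1[i], tab$m2[i], tab$s2[i], tab$x0[i], tab$cond_mean[i],
      expert_id = tab$expert_id[i],
      role = if ("role" %in% names(tab)) tab$role[i] else NA_character_,
      mode = if ("mode" %in% names(tab)) tab$mode[i] else NA_character_)
  })
}

#' Subset an expert panel by tag
#' @param experts list of `expert_prior` objects.
#' @param role,mode optional tag values to keep.
#' @return filtered list.
#' @export
filter_experts <- function(experts, role = NULL, mode = NULL) {
  keep <- rep(TRUE, length(experts))
  if (!is.null(role))
    keep <- keep & vapply(experts, function(e) identical(e$role, role), logical(1))
  if (!is.null(mode))
    keep <- keep & vapply(experts, function(e) identical(e$mode, mode), logical(1))
  experts[keep]
}

#' Serialise a pooled prior to JSON
#' @param prior a `pooled_prior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pooled_prior <- function(prior, path) {
  jsonlite::write_json(
    list(weights = prior$weights, ids = prior$ids,
         means = lapply(prior$means, as.numeric),
         covs = lapply(prior$covs, function(S) as.numeric(S))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a pooled prior from JSON
#' @param path path written by [write_pooled_prior()].
#' @return a `pooled_prior`.
#' @export
read_pooled_prior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  E <- length(x$weights)
  means <- if (is.matrix(x$means)) lapply(seq_len(E), function(e) x$means[e, ])
           else lapply(seq_len(E), function(e) unlist(x$means[[e]]))
  covs <- if (is.matrix(x$covs)) lapply(seq_len(E), function(e) matrix(x$covs[e, ], 2, 2))
          else lapply(seq_len(E), function(e) matrix(unlist(x$covs[[e]]), 2, 2))
  new_pooled_prior(x$weights, means, covs, x$ids)
}
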