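# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer rounding where .5 rounds up, matching how trial reports present
#' percentages (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}

# 2x2 positive-definiteness check without eigen() overhead; the tolerance
# is relative so near-degenerate but valid covariances (tiny elicited
# spreads) pass while indefinite matrices fail.
is_pd2 <- function(S, tol = 1e-12) {
  if (!is.matrix(S) || !all(dim(S) == 2L)) return(FALSE)
  if (!(S[1, 1] > 0 && S[2, 2] > 0)) return(FALSE)
  if (abs(S[1, 2] - S[2, 1]) > 1e-8 * max(1, abs(S[1, 2]))) return(FALSE)
  (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]) > tol * S[1, 1] * S[2, 2]
}

# Draw one multivariate normal vector given precision matrix A and linear
# term m (posterior is N(A^-1 m, A^-1)).  Used by the conjugate Gibbs blocks.
draw_mvn_canonical <- function(A, m) {
  R <- chol(A)
  mu <- backsolve(R, backsolve(R, m, transpose = TRUE))
  mu + backsolve(R, stats::rnorm(length(m)))
}

# Bivariate normal log density of residual pairs (e1, e2) under a 2x2
# covariance, vectorised; avoids per-call input checking in the sampler's
# inner loops.
dbvn_log <- function(e1, e2, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  q <- (S[2, 2] * e1^2 - 2 * S[1, 2] * e1 * e2 + S[1, 1] * e2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# Batch-means Monte Carlo standard error of the mean of a single chain.
mcse_batch <- function(x) {
  n <- length(x)
  if (n < 10) return(stats::sd(x) / sqrt(n))
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
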