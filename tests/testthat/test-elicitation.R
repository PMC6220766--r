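test_that("conditional answers invert to the implied correlation", {
  # E[Y2 | Y1 = x0] = m2 + rho (s2/s1)(x0 - m1), inverted for rho
  e <- expert_prior_from_conditional(0.6, 0.1, 0.7, 0.1, x0 = 0.7,
                                     cond_mean = 0.75)
  expect_equal(e$rho, 0.5)

  # conditional equal to the marginal means independence
  e0 <- expert_prior_from_conditional(0.6, 0.1, 0.7, 0.1, x0 = 0.8,
                                      cond_mean = 0.7)
  expect_equal(e0$rho, 0)

  # round-trip: reading the conditional mean back recovers the answer
  for (cm in c(0.62, 0.71, 0.78)) {
    e2 <- expert_prior_from_conditional(0.55, 0.12, 0.68, 0.09, x0 = 0.7,
                                        cond_mean = cm)
    expect_equal(expert_conditional_mean(e2, 0.7), cm, tolerance = 1e-10)
  }

  # inadmissible implied correlation is clipped with a warning
  expect_warning(
    ec <- expert_prior_from_conditional(0.6, 0.1, 0.7, 0.1, x0 = 0.7,
                                        cond_mean = 0.82),
    "clipped")
  expect_equal(ec$rho, 0.999)

  # conditioning at the arm-1 location leaves rho undefined
  expect_error(expert_prior_from_conditional(0.6, 0.1, 0.7, 0.1, x0 = 0.6,
                                             cond_mean = 0.7),
               "re-elicit")
})

test_that("linear pooling forms the weighted mixture with the right moments", {
  e1 <- expert_prior("a", c(0.1, 0.1), c(0.05, 0.05), 0)
  e2 <- expert_prior("b", c(-0.1, -0.1), c(0.05, 0.05), 0)
  pp <- pool_experts(list(e1, e2))
  expect_equal(pp$weights, c(0.5, 0.5))
  expect_equal(pooled_mean(pp), c(0, 0))
  # mixture variance = within + between: 0.05^2 + 0.1^2
  expect_equal(diag(pooled_cov(pp)), c(0.0125, 0.0125))

  # identical experts pool to the common density
  same <- pool_experts(list(e1, e1))
  pts <- as.matrix(expand.grid(seq(-0.2, 0.3, length.out = 5),
                               seq(-0.2, 0.3, length.out = 5)))
  expect_equal(pooled_density(same, pts),
               mvtnorm::dmvnorm(pts, e1$mean, expert_cov(e1)))

  # degenerate weights select one expert; rescaling weights is a no-op
  w20 <- pool_experts(list(e1, e2), weights = c(2, 0))
  expect_equal(pooled_density(w20, pts),
               mvtnorm::dmvnorm(pts, e1$mean, expert_cov(e1)))
  pa <- pool_experts(list(e1, e2), weights = c(1, 3))
  pb <- pool_experts(list(e1, e2), weights = c(0.25, 0.75))
  expect_equal(pooled_density(pa, pts), pooled_density(pb, pts),
               tolerance = 1e-14)

  expect_error(pool_experts(list()), "empty")
  expect_error(pool_experts(list(e1, e2), weights = c(0, 0)), "not all zero")
})

test_that("pooled density is the exact linear pool and integrates to one", {
  set.seed(33)
  panel <- generate_expert_panel(6, seed = 33)
  pp <- pool_experts(panel)
  pts <- cbind(runif(100, 0, 1.2), runif(100, 0, 1.2))
  manual <- rowSums(vapply(seq_along(panel), function(e)
    pp$weights[e] * mvtnorm::dmvnorm(pts, panel[[e]]$mean,
                                     expert_cov(panel[[e]])),
    numeric(100)))
  expect_equal(pooled_density(pp, pts), manual, tolerance = 1e-12)

  # quadrature over a wide box captures the full mass
  g <- seq(-1, 2.2, length.out = 321)
  h <- g[2] - g[1]
  grid <- as.matrix(expand.grid(g, g))
  mass <- sum(pooled_density(pp, grid)) * h^2
  expect_equal(mass, 1, tolerance = 1e-3)

  # single standard bivariate component at the origin
  std <- ceamiss:::new_pooled_prior(1, list(c(0, 0)), list(diag(2)))
  expect_equal(pooled_density(std, c(0, 0)), 1 / (2 * pi), tolerance = 1e-12)
})

test_that("prior sampling is reproducible and matches mixture moments", {
  pp <- pool_experts(list(expert_prior("a", c(0.1, 0.2), c(0.05, 0.08), 0.3)))
  x <- sample_prior(pp, 1e5, seed = 7)
  se <- sqrt(diag(pooled_cov(pp)) / 1e5)
  expect_lt(abs(mean(x[, 1]) - 0.1), 4 * se[1])
  expect_lt(abs(mean(x[, 2]) - 0.2), 4 * se[2])
  expect_identical(sample_prior(pp, 50, seed = 9), sample_prior(pp, 50, seed = 9))

  mix <- toy_pool()
  xm <- sample_prior(mix, 2e5, seed = 11)
  mm <- pooled_mean(mix); vv <- pooled_cov(mix)
  expect_lt(abs(mean(xm[, 1]) - mm[1]), 4 * sqrt(vv[1, 1] / 2e5))
  expect_lt(abs(var(xm[, 2]) - vv[2, 2]), 4 * vv[2, 2] * sqrt(2 / 2e5))

  tiny <- pool_experts(list(expert_prior("t", c(0.3, 0.3), c(1e-9, 1e-9), 0)))
  xd <- sample_prior(tiny, 10, seed = 3)
  expect_equal(unname(colMeans(xd)), c(0.3, 0.3), tolerance = 1e-6)
})

test_that("extreme-expert selection follows the stated criteria and ties", {
  panel <- list(
    expert_prior("sceptic", c(0.75, 0.55), c(0.10, 0.10), 0),  # control +0.20
    expert_prior("enthus", c(0.51, 0.80), c(0.10, 0.10), 0),   # interv +0.29
    expert_prior("narrow", c(0.65, 0.70), c(0.02, 0.02), 0),
    expert_prior("wide", c(0.65, 0.70), c(0.30, 0.30), 0))
  expect_equal(select_extreme_expert(panel, "sceptical")$expert_id, "sceptic")
  expect_equal(select_extreme_expert(panel, "enthusiastic")$expert_id, "enthus")
  expect_equal(select_extreme_expert(panel, "most_certain")$expert_id, "narrow")
  expect_equal(select_extreme_expert(panel, "least_certain")$expert_id, "wide")

  single <- panel[1]
  for (cr in c("sceptical", "enthusiastic", "most_certain", "least_certain"))
    expect_equal(select_extreme_expert(single, cr)$expert_id, "sceptic")

  tie <- list(expert_prior("first", c(0, 0), c(0.1, 0.1), 0),
              expert_prior("second", c(0.2, 0.2), c(0.1, 0.1), 0))
  expect_equal(select_extreme_expert(tie, "most_certain")$expert_id, "first")
  expect_error(select_extreme_expert(list(), "sceptical"), "empty")
})

test_that("expert records and pooled priors survive file round-trips", {
  tab <- data.frame(expert_id = c("e1", "e2"), role = c("doctor", "nurse"),
                    mode = c("online", "face-to-face"),
                    m1 = c(0.6, 0.5), s1 = c(0.1, 0.15),
                    m2 = c(0.7, 0.55), s2 = c(0.1, 0.12),
                    x0 = c(0.7, 0.65), cond_mean = c(0.75, 0.57))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  experts <- read_expert_records(path)
  expect_length(experts, 2)
  expect_equal(experts[[1]]$rho, 0.5)
  expect_length(filter_experts(experts, role = "nurse"), 1)

  pp <- pool_experts(experts)
  jp <- withr::local_tempfile(fileext = ".json")
  write_pooled_prior(pp, jp)
  pp2 <- read_pooled_prior(jp)
  pts <- cbind(c(0.5, 0.62), c(0.6, 0.7))
  expect_equal(pooled_density(pp2, pts), pooled_density(pp, pts),
               tolerance = 1e-12)
})
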