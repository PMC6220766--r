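#' CEA configuration
#'
#' @param wtp willingness-to-pay per QALY in GBP (default 30000).
#' @param wtp_grid ascending grid of willingness-to-pay values for the
#'   cost-effectiveness acceptability curve.
#' @param level credible level for equal-tailed intervals (default 0.95).
#' @return An object of class `cea_config`.
#' @export
cea_config <- function(wtp = 30000, wtp_grid = seq(0, 50000, by = 2500),
                       level = 0.95) {
  stopifnot(wtp >= 0, level > 0, level < 1)
  if (is.unsorted(wtp_grid)) stopf("wtp_grid must be sorted ascending")
  structure(list(wtp = wtp, wtp_grid = wtp_grid, level = level),
            class = "cea_config")
}

summ_vec <- function(x, level) {
  a <- (1 - level) / 2
  qs <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  c(mean = mean(x), lower = qs[1], upper = qs[2])
}

#' Posterior summaries of the treatment increments
#'
#' Summarises the monitored incremental quantities — QoL at each timepoint,
#' QALY and cost (all intervention minus reference) — by posterior mean and
#' equal-tailed credible interval.
#'
#' @param draws a `cea_draws`.
#' @param level credible level (default 0.95).
#' @return An object of class `cea_result`: a data frame with columns
#'   `quantity`, `mean`, `lower`, `upper` and attribute `level`.
#' @export
incremental_summaries <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "cea_draws"))
  wanted <- c("inc_qol1", "inc_qol2", "inc_qaly", "inc_cost")
  missing_m <- setdiff(wanted, draws$monitors)
  if (length(missing_m))
    stopf("monitored quantity missing: %s", paste(missing_m, collapse = ", "))
  rows <- t(vapply(wanted, function(p) summ_vec(get_draws(draws, p), level),
                   numeric(3)))
  out <- data.frame(quantity = wanted, mean = rows[, 1], lower = rows[, 2],
                    upper = rows[, 3], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, level = level, class = c("cea_result", "data.frame"))
}

#' Incremental net benefit
#'
#' Per posterior draw, `INB = wtp * inc_QALY - inc_cost`, summarised by the
#' posterior mean and equal-tailed credible interval.
#'
#' @param draws a `cea_draws`.
#' @param config a [cea_config()] (or a single willingness-to-pay value).
#' @param level credible level.
#' @return list with `wtp`, `mean`, `lower`, `upper` and the per-draw INB
#'   vector `draws` (GBP).
#' @export
inb <- function(draws, config = cea_config(), level = 0.95) {
  wtp <- if (inherits(config, "cea_config")) config$wtp else config
  if (wtp < 0) stopf("willingness-to-pay must be nonnegative")
  if (inherits(config, "cea_config")) level <- config$level
  x <- wtp * get_draws(draws, "inc_qaly") - get_draws(draws, "inc_cost")
  s <- summ_vec(x, level)
  list(wtp = wtp, mean = s[["mean"]], lower = s[["lower"]],
       upper = s[["upper"]], draws = x)
}

#' Probability that the intervention is cost-effective
#'
#' The fraction of posterior draws with strictly positive incremental net
#' benefit; draws with INB exactly zero count as not cost-effective.
#'
#' @inheritParams inb
#' @return probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(draws, config = cea_config()) {
  x <- inb(draws, config)$draws
  if (!length(x)) stopf("no posterior draws")
  mean(x > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' `P(INB > 0)` across a grid of willingness-to-pay values.  At
#' `wtp = 0` the curve equals `P(inc_cost < 0)`.
#'
#' @param draws a `cea_draws`.
#' @param grid ascending willingness-to-pay grid (defaults to the
#'   [cea_config()] grid).
#' @return data frame with columns `wtp` and `prob`.
#' @export
ceac <- function(draws, grid = cea_config()$wtp_grid) {
  if (!length(grid)) stopf("empty willingness-to-pay grid")
  if (is.unsorted(grid)) stopf("willingness-to-pay grid must be sorted ascending")
  dq <- get_draws(draws, "inc_qaly")
  dc <- get_draws(draws, "inc_cost")
  prob <- vapply(grid, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(wtp = grid, prob = prob)
}

#' Density strip of a posterior quantity
#'
#' Kernel density on a grid, normalised so the maximum is exactly 1, for
#' rendering as a shaded strip (darkness proportional to density).  The
#' posterior mean and equal-tailed interval are attached as attributes, so
#' any plotting layer can add the markers.
#'
#' @param x numeric vector of at least 100 posterior draws.
#' @param n grid resolution (default 512).
#' @param level credible level for the interval markers.
#' @return data frame with columns `value` and `density` (max 1), with
#'   attributes `mean`, `lower`, `upper`.
#' @export
density_strip <- function(x, n = 512, level = 0.95) {
  if (length(x) < 100) stopf("density strip requires at least 100 draws")
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
  # degenerate draws: bw.nrd0's scale fallback would smear a point mass
  # over a wide window, so apply a tight bandwidth floor instead
  if (!is.finite(bw) || bw <= 0 || stats::sd(x) == 0)
    bw <- max(1e-8, abs(mean(x)) * 1e-6)
  d <- stats::density(x, bw = bw, n = n)
  s <- summ_vec(x, level)
  structure(data.frame(value = d$x, density = d$y / max(d$y)),
            mean = s[["mean"]], lower = s[["lower"]], upper = s[["upper"]])
}

#' Tipping-point scan over fixed sensitivity offsets
#'
#' Refits the model at each fixed offset `Delta` of the grid (the classic
#' "delta method": a point-mass sensitivity prior, typically applied to one
#' arm), records the posterior mean incremental net benefit, and reports
#' the first grid crossing of zero, linearly interpolated between the
#' bracketing grid values.  `Delta_tip` is `NA` when the INB does not
#' change sign over the grid.
#'
#' @param spec_builder function taking a single offset value and returning
#'   a `cea_model` (it decides which arm(s) the offset applies to).
#' @param delta_grid ascending grid of offset values (utility scale).
#' @param settings [mcmc_settings()] used for each fit.
#' @param config a [cea_config()].
#' @return list with `table` (data frame `delta`, `inb_mean`) and
#'   `delta_tip`.
#' @export
tipping_point_scan <- function(spec_builder, delta_grid,
                               settings = mcmc_settings(n_iter = 4000L,
                                                        warmup = 500L),
                               config = cea_config()) {
  if (!length(delta_grid)) stopf("empty offset grid")
  if (is.unsorted(delta_grid)) stopf("offset grid must be sorted ascending")
  inb_mean <- vapply(delta_grid, function(d) {
    fit <- run_mcmc(spec_builder(d), settings)
    inb(fit, config)$mean
  }, numeric(1))
  tab <- data.frame(delta = delta_grid, inb_mean = inb_mean)
  delta_tip <- NA_real_
  sgn <- sign(inb_mean)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (any(inb_mean == 0)) {
    delta_tip <- delta_grid[which(inb_mean == 0)[1]]
  } else if (length(cross)) {
    i <- cross[1]
    delta_tip <- delta_grid[i] + (0 - inb_mean[i]) *
      (delta_grid[i + 1] - delta_grid[i]) / (inb_mean[i + 1] - inb_mean[i])
  }
  list(table = tab, delta_tip = delta_tip)
}

#' Batch scenario report of CEA results
#'
#' Fits a list of models (e.g. MAR base case, pooled-prior MNAR, subgroup
#' pools, extreme single experts) with shared settings and assembles one
#' table of incremental summaries, INB and probability cost-effective per
#' scenario.
#'
#' @param models named list of `cea_model` objects.
#' @param settings [mcmc_settings()].
#' @param config [cea_config()].
#' @return data frame with one row per scenario and columns for each
#'   increment's posterior mean and interval, the INB and P(cost-effective).
#' @export
scenario_report <- function(models, settings = mcmc_settings(),
                            config = cea_config()) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  rows <- lapply(names(models), function(nm) {
    fit <- run_mcmc(models[[nm]], settings)
    s <- incremental_summaries(fit, config$level)
    i <- inb(fit, config)
    out <- data.frame(scenario = nm, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(s))) {
      out[[paste0(s$quantity[r], "_mean")]] <- s$mean[r]
      out[[paste0(s$quantity[r], "_lower")]] <- s$lower[r]
      out[[paste0(s$quantity[r], "_upper")]] <- s$upper[r]
    }
    out$inb_mean <- i$mean
    out$inb_lower <- i$lower
    out$inb_upper <- i$upper
    out$prob_ce <- prob_cost_effective(fit, config)
    out
  })
  do.call(rbind, rows)
}
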