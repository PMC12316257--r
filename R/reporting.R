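#' Per-cohort quantiles of observed carbon stocks
#'
#' Empirical 5/50/95% quantiles of the per-hectare stocks, one row per
#' cohort, using the linear-interpolation quantile definition (R type 7).
#' Cohorts with no observations yield a row of `NA`s with a warning.
#'
#' @param stocks a `stock_obs` data.frame.
#' @param probs quantile probabilities (default 0.05, 0.50, 0.95).
#' @return data.frame of class `quantile_table`: `cohort`, `n` and one
#'   column per requested quantile (`q5`, `q50`, `q95`).
#' @export
stock_quantiles <- function(stocks, probs = c(0.05, 0.5, 0.95)) {
  rows <- lapply(COHORTS, function(coh) {
    v <- stocks$carbon_stock[stocks$cohort == coh]
    if (!length(v)) {
      warning("no stock observations for cohort ", coh, call. = FALSE)
      q <- rep(NA_real_, length(probs))
    } else q <- quantile(v, probs, type = 7, names = FALSE)
    cbind(data.frame(cohort = coh, n = length(v)),
          as.data.frame(as.list(setNames(q, paste0("q", 100 * probs)))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quantile_table", "data.frame")
  out
}

#' Posterior quantiles of window-mean annual gains
#'
#' 5/50/95% quantiles over posterior draws of the window-mean gain of a
#' population-average tree ([gain_draws()]), per growth cohort and age
#' window. The default windows split young (`[1, 7]` years) from older
#' (`[7, 40]`) trees.
#'
#' @param fit a growth `carbon_fit`.
#' @param windows named list of `c(a, b)` age windows (years).
#' @param probs quantile probabilities.
#' @return data.frame of class `quantile_table`: `cohort`, `window`,
#'   `mean`, `sd` and quantile columns.
#' @export
gain_quantiles <- function(fit, windows = list("1-7" = c(1, 7),
                                               "7-40" = c(7, 40)),
                           probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(fit, "carbon_fit"), fit$model == "growth")
  cohorts <- GROWTH_COHORTS[paste0("theta_", GROWTH_COHORTS) %in%
                              colnames(fit$draws)]
  rows <- list()
  for (coh in cohorts) for (w in names(windows)) {
    g <- gain_draws(fit, coh, windows[[w]])
    rows[[paste(coh, w)]] <- cbind(
      data.frame(cohort = coh, window = w, mean = mean(g), sd = sd(g)),
      as.data.frame(as.list(setNames(
        quantile(g, probs, type = 7, names = FALSE),
        paste0("q", 100 * probs)))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quantile_table", "data.frame")
  out
}

#' Standardized covariate effects, largest first
#'
#' One row per covariate with its thematic group (Social / Field / Soil /
#' Climate), posterior mean, sd and 95% interval, sorted by decreasing
#' absolute posterior mean — because the covariates are standardized,
#' this ranking compares their influence directly.
#'
#' @param fit a `carbon_fit` (stock or growth).
#' @return data.frame of class `effect_table` with 8 rows.
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "carbon_fit"))
  wanted <- paste0("theta_", covariate_names())
  s <- posterior_summary(fit, wanted)
  out <- data.frame(covariate = covariate_names(),
                    group = covariate_groups()$group,
                    mean = s$mean, sd = s$sd, q2.5 = s$q2.5,
                    q97.5 = s$q97.5, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$mean)), ]
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Posterior carbon and gain trajectories over age
#'
#' Per cohort and age: the posterior median and 95% credible band of the
#' carbon of a population-average tree, and of its one-year gain
#' (`C(t) - C(t-1)` per draw, `C(0) = 0`). Each band is computed by
#' pushing every posterior draw through the trajectory, so the median
#' curve is the pointwise posterior median, not the trajectory of the
#' posterior-median parameters (the two coincide only for a degenerate
#' posterior). Suitable for log-scale plotting.
#'
#' @param fit a growth `carbon_fit`.
#' @param ages increasing integer grid (default 1:40).
#' @return data.frame: `cohort`, `age`, `carbon_q50`, `carbon_lo`,
#'   `carbon_hi`, `gain_q50`, `gain_lo`, `gain_hi`.
#' @export
trajectory_export <- function(fit, ages = 1:40) {
  stopifnot(inherits(fit, "carbon_fit"), fit$model == "growth")
  if (!length(ages) || any(diff(ages) <= 0) || any(ages < 1))
    abort_validation("`ages` must be an increasing grid of ages >= 1")
  cohorts <- GROWTH_COHORTS[paste0("theta_", GROWTH_COHORTS) %in%
                              colnames(fit$draws)]
  out <- list()
  for (coh in cohorts) {
    d <- posterior_draws(fit, c(paste0("theta_", coh),
                                paste0("beta_", coh)))
    carbon <- outer(seq_len(nrow(d)), ages,
                    function(i, a) d[i, 1] * a^d[i, 2])
    prev <- outer(seq_len(nrow(d)), ages,
                  function(i, a) ifelse(a > 1, d[i, 1] * (a - 1)^d[i, 2], 0))
    gain <- carbon - prev
    qs <- function(m, p) apply(m, 2, quantile, p, type = 7)
    out[[coh]] <- data.frame(
      cohort = coh, age = ages,
      carbon_q50 = qs(carbon, 0.5), carbon_lo = qs(carbon, 0.025),
      carbon_hi = qs(carbon, 0.975),
      gain_q50 = qs(gain, 0.5), gain_lo = qs(gain, 0.025),
      gain_hi = qs(gain, 0.975), row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Combined per-cohort summary of stocks and gains
#'
#' The descriptive-statistics table of a study: per cohort, 5/50/95%
#' quantiles of observed stocks (Mg/ha) and — when a growth fit is
#' supplied — posterior quantiles of the window-mean annual gains
#' (kg/tree/year) for young and older trees. Remnant trees have no ages,
#' so their gain cells stay empty.
#'
#' @param stocks a `stock_obs` data.frame.
#' @param growth_fit optional growth `carbon_fit`.
#' @param windows named list of age windows passed to [gain_quantiles()].
#' @return data.frame of class `quantile_table`.
#' @export
summary_table <- function(stocks, growth_fit = NULL,
                          windows = list("1-7" = c(1, 7),
                                         "7-40" = c(7, 40))) {
  st <- stock_quantiles(stocks)
  names(st)[-(1:2)] <- paste0("stock_", names(st)[-(1:2)])
  if (is.null(growth_fit)) return(st)
  gq <- gain_quantiles(growth_fit, windows)
  for (w in names(windows)) {
    sub <- gq[gq$window == w, ]
    qcols <- grep("^q", names(sub), value = TRUE)
    add <- sub[match(st$cohort, sub$cohort), qcols]
    names(add) <- paste0("gain_", w, "_", qcols)
    st <- cbind(st, add)
  }
  rownames(st) <- NULL
  class(st) <- c("quantile_table", "data.frame")
  st
}
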