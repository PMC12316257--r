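#' Median carbon stock under the plot-level model
#'
#' The stock model is lognormal, so its location parameter
#' `theta_coh * exp(sum(theta_cov * x))` is the *median* stock of cohort
#' `coh` in a plot with standardized covariates `x`; at `x = 0` (a plot in
#' average conditions) the median is `theta_coh` itself.
#'
#' @param params a [stock_params()].
#' @param cohort character vector of cohorts.
#' @param x standardized covariate vector (length 8), or a matrix with one
#'   row per element of `cohort`.
#' @return Median stock(s) in Mg/ha.
#' @export
stock_median <- function(params, cohort, x) {
  stopifnot(inherits(params, "stock_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(params$theta_cov))
    abort_validation("`x` must have ", length(params$theta_cov),
                     " covariate columns")
  if (any(!cohort %in% COHORTS))
    abort_validation("unknown cohort: ",
                     paste(setdiff(cohort, COHORTS), collapse = ", "))
  if (nrow(x) == 1 && length(cohort) > 1)
    x <- x[rep(1, length(cohort)), , drop = FALSE]
  unname(params$theta_cohort[cohort] *
           exp(as.vector(x %*% params$theta_cov)))
}

#' Log-likelihood of observed stocks
#'
#' Sum over observations of the lognormal log-density with location
#' `log(stock_median)` and scale `sigma`. Observations must be strictly
#' positive; empty (plot, cohort) cells are never part of the likelihood.
#'
#' @param params a [stock_params()].
#' @param obs a `stock_obs` data.frame ([aggregate_stocks()] /
#'   [stock_observations()]).
#' @param X a `covariate_matrix` ([standardize_covariates()]) covering
#'   every observed plot.
#' @return The scalar log-likelihood.
#' @export
stock_loglik <- function(params, obs, X) {
  stopifnot(inherits(params, "stock_params"))
  if (any(obs$carbon_stock <= 0))
    abort_validation("stock observations must be strictly positive")
  miss <- setdiff(obs$plot_id, rownames(X$values))
  if (length(miss))
    abort_validation("plots missing from the covariate matrix: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  med <- stock_median(params, obs$cohort,
                      X$values[obs$plot_id, , drop = FALSE])
  sum(dlnorm(obs$carbon_stock, meanlog = log(med), sdlog = params$sigma,
             log = TRUE))
}

#' Simulate stock observations from known parameters
#'
#' Draws one lognormal stock per (plot, cohort) cell of the presence
#' plan, with the model's location and scale. The presence plan encodes
#' which cohorts actually occur in which plots; absent cells yield no
#' observation at all (matching how real inventories are aggregated).
#'
#' @param params a [stock_params()].
#' @param X a `covariate_matrix`.
#' @param presence data.frame with `plot_id` and `cohort`, one row per
#'   cell to simulate; defaults to all cohorts in all plots.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A `stock_obs` data.frame.
#' @export
simulate_stocks <- function(params, X, presence = NULL, seed = 1) {
  stopifnot(inherits(params, "stock_params"))
  if (is.null(presence))
    presence <- expand.grid(plot_id = rownames(X$values), cohort = COHORTS,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(presence$plot_id, rownames(X$values))
  if (length(miss))
    abort_validation("presence plan references unknown plot(s): ",
                     paste(utils::head(miss, 5), collapse = ", "))
  med <- stock_median(params, presence$cohort,
                      X$values[presence$plot_id, , drop = FALSE])
  set.seed(seed)
  stock_observations(data.frame(
    plot_id = presence$plot_id, cohort = presence$cohort,
    carbon_stock = rlnorm(nrow(presence), log(med), params$sigma),
    stringsAsFactors = FALSE))
}

#' Fit the plot-level stock model by MCMC
#'
#' Posterior inference for the cohort median stocks `theta_coh` (Mg/ha),
#' the eight standardized covariate effects and the lognormal scale
#' `sigma`, using JAGS. The model is sampled on the log scale (where it
#' is a normal linear model, enabling block updates of all coefficients)
#' and reported on the natural scale. Convergence is gated on split-R-hat
#' and effective sample size; a failed gate raises a structured error
#' carrying the full diagnostics rather than returning silently.
#'
#' @param obs a `stock_obs` data.frame (>= 10 observations).
#' @param X a `covariate_matrix` covering every observed plot.
#' @param priors a [stock_priors()].
#' @param sampler a [sampler_options()].
#' @return A `carbon_fit`; parameters are named `theta_<cohort>`,
#'   `theta_<covariate>`, `sigma` and `sigma2`.
#' @export
fit_stocks <- function(obs, X, priors = stock_priors(),
                       sampler = sampler_options()) {
  if (nrow(obs) < 10)
    abort_validation("need at least 10 stock observations to fit")
  miss <- setdiff(obs$plot_id, rownames(X$values))
  if (length(miss))
    abort_validation("plots missing from the covariate matrix: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  cohorts <- COHORTS[COHORTS %in% unique(obs$cohort)]
  model <- "model {
    for (i in 1:N) {
      ly[i] ~ dnorm(ltheta[coh[i]] + inprod(X[i, ], thetaX), tau)
    }
    for (c in 1:C) { ltheta[c] ~ dnorm(theta_meanlog, 1 / theta_sdlog^2) }
    for (k in 1:K) { thetaX[k] ~ dnorm(0, 1 / cov_sd^2) }
    sigma ~ dnorm(0, 1 / sigma_sd^2) T(0, )
    tau <- 1 / (sigma * sigma)
  }"
  data <- list(
    N = nrow(obs), C = length(cohorts), K = ncol(X$values),
    ly = log(obs$carbon_stock), coh = match(obs$cohort, cohorts),
    X = X$values[obs$plot_id, , drop = FALSE],
    theta_meanlog = priors$theta_meanlog, theta_sdlog = priors$theta_sdlog,
    cov_sd = priors$cov_sd, sigma_sd = priors$sigma_sd
  )
  samples <- run_jags(model, data, c("ltheta", "thetaX", "sigma"), sampler)
  chain_list <- lapply(samples, function(ch) {
    ch <- as.matrix(ch)
    out <- cbind(exp(ch[, sprintf("ltheta[%d]", seq_along(cohorts)),
                        drop = FALSE]),
                 ch[, sprintf("thetaX[%d]", seq_len(ncol(X$values))),
                    drop = FALSE],
                 ch[, "sigma"], ch[, "sigma"]^2)
    colnames(out) <- c(paste0("theta_", cohorts),
                       paste0("theta_", covariate_names()),
                       "sigma", "sigma2")
    out
  })
  new_carbon_fit("stock", chain_list, sampler, priors,
                 sprintf("%d stock observations, %d plots, %d cohorts",
                         nrow(obs), length(unique(obs$plot_id)),
                         length(cohorts)))
}
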