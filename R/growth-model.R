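#' Median tree carbon at a given age under the growth model
#'
#' The growth model puts tree carbon on a lognormal power law of age:
#' the median carbon of a tree of cohort `coh` and species `sp` at age
#' `t` in a plot with standardized covariates `x` is
#' `theta_coh * theta_sp * t^beta_coh * exp(sum(theta_cov * x))` (kg).
#' Remnant trees have no known age and are outside the model's domain.
#' An unknown species takes `theta_sp = 1`, the centre of the lognormal
#' species-effect distribution, i.e. a population-average tree.
#'
#' @param params a [growth_params()].
#' @param cohort `"planted"` or `"spontaneous"` (vectorized).
#' @param age age(s) in years, >= 1.
#' @param species optional species name(s); matched against
#'   `params$species_effects` when realized effects are present.
#' @param x standardized covariate vector (length 8) or matrix with one
#'   row per tree; `NULL` means average conditions (`x = 0`).
#' @return Median carbon in kg.
#' @export
expected_carbon <- function(params, cohort, age, species = NULL, x = NULL) {
  stopifnot(inherits(params, "growth_params"))
  bad <- setdiff(unique(cohort), GROWTH_COHORTS)
  if (length(bad))
    abort_validation("the growth model applies only to planted and ",
                     "spontaneous trees, not: ", paste(bad, collapse = ", "))
  if (any(!is.finite(age) | age < 1))
    abort_validation("`age` must be >= 1 year")
  n <- max(length(cohort), length(age))
  cohort <- rep_len(cohort, n)
  age <- rep_len(age, n)
  th_sp <- rep_len(1, n)
  if (!is.null(species) && !is.null(params$species_effects)) {
    hit <- match(rep_len(species, n), names(params$species_effects))
    th_sp[!is.na(hit)] <- params$species_effects[hit[!is.na(hit)]]
  }
  cov_term <- if (is.null(x)) rep_len(1, n) else {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != length(params$theta_cov))
      abort_validation("`x` must have ", length(params$theta_cov),
                       " covariate columns")
    if (nrow(x) == 1) x <- x[rep(1, n), , drop = FALSE]
    exp(as.vector(x %*% params$theta_cov))
  }
  unname(params$theta_cohort[cohort] * th_sp *
           age^params$beta_cohort[cohort] * cov_term)
}

#' Annual carbon gain along the median growth trajectory
#'
#' The annual gain at age `t` is the one-year finite difference of the
#' median trajectory of a population-average tree in average conditions:
#' `C(t) - C(t - 1)` with `theta_sp = 1`, `x = 0` (with `C(0) = 0`, so
#' the gain at age 1 is the first-year carbon). The instantaneous
#' derivative `theta * beta * t^(beta - 1)` is available as an
#' alternative. With `beta > 1` gains increase with age; with `beta < 1`
#' they decrease; at `beta = 1` they are the constant `theta_coh`.
#'
#' @param params a [growth_params()].
#' @param cohort `"planted"` or `"spontaneous"`.
#' @param ages increasing grid of ages (years, >= 1).
#' @param method `"difference"` (default) or `"derivative"`.
#' @return data.frame with `age` and `gain` (kg/year).
#' @export
annual_gain_curve <- function(params, cohort, ages,
                              method = c("difference", "derivative")) {
  method <- match.arg(method)
  if (!length(ages)) abort_validation("`ages` must be a non-empty grid")
  if (any(diff(ages) <= 0)) abort_validation("`ages` must be increasing")
  if (any(ages < 1)) abort_validation("`ages` must be >= 1")
  gain <- if (method == "difference") {
    now <- expected_carbon(params, cohort, ages)
    before <- ifelse(ages > 1,
                     expected_carbon(params, cohort, pmax(ages - 1, 1)), 0)
    before[ages == 1] <- 0
    now - before
  } else {
    th <- params$theta_cohort[[cohort]]
    be <- params$beta_cohort[[cohort]]
    th * be * ages^(be - 1)
  }
  data.frame(age = ages, gain = unname(gain))
}

#' Mean annual gain over an age window
#'
#' Because one-year gains telescope, the mean finite-difference gain over
#' the window `[a, b]` is exactly `(C(b) - C(a)) / (b - a)` on the median
#' trajectory — the estimator behind the reported per-year carbon
#' accumulations of young (`[1, 7]`) and older (`(7, 40]`) trees.
#'
#' @param params a [growth_params()].
#' @param cohort `"planted"` or `"spontaneous"`.
#' @param window numeric `c(a, b)` with `b > a >= 1`, years.
#' @return Mean annual gain in kg/year.
#' @export
window_gain <- function(params, cohort, window) {
  if (length(window) != 2 || window[2] <= window[1] || window[1] < 1)
    abort_validation("`window` must be c(a, b) with b > a >= 1")
  diff(expected_carbon(params, cohort, window)) / diff(window)
}

#' Log-likelihood of tree carbon under the growth model
#'
#' The data term sums lognormal log-densities of each tree's carbon at
#' the model's location; the hierarchy contributes, for every realized
#' species effect, the log-density of `theta_sp` under its lognormal
#' distribution centred at 1. All trees must be planted or spontaneous
#' with age and carbon present, and every species in the data must have a
#' realized effect in `params$species_effects`.
#'
#' @param params a [growth_params()] with `species_effects` realized.
#' @param trees a `tree_inventory` restricted to aged growth-cohort trees
#'   with `carbon` filled.
#' @param X a `covariate_matrix` covering the trees' plots.
#' @return Scalar log joint density (likelihood + species-effect term).
#' @export
growth_loglik <- function(params, trees, X) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!trees$cohort %in% GROWTH_COHORTS))
    abort_validation("growth likelihood applies only to planted and ",
                     "spontaneous trees")
  if (any(is.na(trees$age)))
    abort_validation("all trees must have an age")
  if (any(is.na(trees$carbon) | trees$carbon <= 0))
    abort_validation("all trees must have positive carbon")
  if (is.null(params$species_effects))
    abort_validation("`params$species_effects` must hold realized effects")
  miss <- setdiff(unique(trees$species), names(params$species_effects))
  if (length(miss))
    abort_validation("species without a realized effect: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  med <- expected_carbon(params, trees$cohort, trees$age, trees$species,
                         X$values[trees$plot_id, , drop = FALSE])
  data_term <- sum(dlnorm(trees$carbon, log(med), params$sigma, log = TRUE))
  sp_term <- sum(dlnorm(params$species_effects, meanlog = log(1),
                        sdlog = params$sigma_sp, log = TRUE))
  data_term + sp_term
}

#' Simulate tree carbon from the growth model
#'
#' Draws carbon for each tree of a design (cohort, species, age, plot)
#' from the lognormal power law. Species effects are taken from
#' `params$species_effects` when realized, otherwise drawn from their
#' lognormal distribution; the realized values are returned so recovery
#' scoring can compare against them.
#'
#' @param params a [growth_params()].
#' @param trees a `tree_inventory` (planted/spontaneous, ages present).
#' @param X a `covariate_matrix` covering the trees' plots.
#' @param seed integer RNG seed.
#' @return A list: `trees` (the inventory with `carbon` filled, kg) and
#'   `params` (the input with `species_effects` realized).
#' @export
simulate_growth <- function(params, trees, X, seed = 1) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!trees$cohort %in% GROWTH_COHORTS) || any(is.na(trees$age)))
    abort_validation("design trees must be planted/spontaneous with ages")
  set.seed(seed)
  species <- sort(unique(trees$species))
  if (is.null(params$species_effects)) {
    params$species_effects <- setNames(
      rlnorm(length(species), meanlog = log(1), sdlog = params$sigma_sp),
      species)
  } else {
    miss <- setdiff(species, names(params$species_effects))
    if (length(miss))
      abort_validation("species without a realized effect: ",
                       paste(utils::head(miss, 5), collapse = ", "))
  }
  med <- expected_carbon(params, trees$cohort, trees$age, trees$species,
                         X$values[trees$plot_id, , drop = FALSE])
  trees$carbon <- rlnorm(nrow(trees), log(med), params$sigma)
  list(trees = trees, params = params)
}

#' Fit the tree-level growth model by MCMC
#'
#' Posterior inference for the cohort baselines `theta_coh` (kg at age 1),
#' the power-law exponents `beta_coh`, the species-effect scale
#' `sigma_sp` and realized species effects, the eight standardized
#' covariate effects and the residual scale `sigma`. As in
#' [fit_stocks()], sampling happens on the log scale with block updates
#' and the convergence gate raises a structured error on failure.
#'
#' @param trees a `tree_inventory` of aged planted/spontaneous trees with
#'   `carbon` filled (>= 50 trees, >= 2 species).
#' @param X a `covariate_matrix` covering the trees' plots.
#' @param priors a [growth_priors()].
#' @param sampler a [sampler_options()].
#' @return A `carbon_fit`; parameters `theta_planted`,
#'   `theta_spontaneous`, `beta_planted`, `beta_spontaneous`, `sigma_sp`,
#'   `theta_<covariate>`, `sigma`, `sigma2` and one `theta_sp[<species>]`
#'   per species.
#' @export
fit_growth <- function(trees, X, priors = growth_priors(),
                       sampler = sampler_options()) {
  if (any(!trees$cohort %in% GROWTH_COHORTS))
    abort_validation("growth model fits only planted and spontaneous trees; ",
                     "filter the inventory first (see validate_inventory)")
  if (any(is.na(trees$age)))
    abort_validation("all trees must have an age; ageless growth-cohort ",
                     "trees are excluded upstream")
  if (any(is.na(trees$carbon) | trees$carbon <= 0))
    abort_validation("all trees must have positive carbon")
  if (nrow(trees) < 50)
    abort_validation("need at least 50 trees to fit the growth model")
  species <- sort(unique(trees$species))
  if (length(species) < 2)
    warning("single-species data: sigma_sp is prior-dominated",
            call. = FALSE)
  cohorts <- GROWTH_COHORTS[GROWTH_COHORTS %in% unique(trees$cohort)]
  if (length(cohorts) < 2)
    warning("only one growth cohort present; cohort contrasts unavailable",
            call. = FALSE)
  miss <- setdiff(unique(trees$plot_id), rownames(X$values))
  if (length(miss))
    abort_validation("plots missing from the covariate matrix: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  model <- "model {
    for (i in 1:N) {
      ly[i] ~ dnorm(ltheta[coh[i]] + lsp[sp[i]] + beta[coh[i]] * lage[i] +
                    inprod(X[i, ], thetaX), tau)
    }
    for (c in 1:C) {
      ltheta[c] ~ dnorm(theta_meanlog, 1 / theta_sdlog^2)
      beta[c] ~ dnorm(beta_mean, 1 / beta_sd^2)
    }
    for (s in 1:S) { lsp[s] ~ dnorm(0, tau_sp) }
    for (k in 1:K) { thetaX[k] ~ dnorm(0, 1 / cov_sd^2) }
    sigma_sp ~ dnorm(0, 1 / sigma_sp_sd^2) T(0, )
    tau_sp <- 1 / (sigma_sp * sigma_sp)
    sigma ~ dnorm(0, 1 / sigma_sd^2) T(0, )
    tau <- 1 / (sigma * sigma)
  }"
  data <- list(
    N = nrow(trees), C = length(cohorts), S = length(species),
    K = ncol(X$values),
    ly = log(trees$carbon), coh = match(trees$cohort, cohorts),
    sp = match(trees$species, species), lage = log(trees$age),
    X = X$values[trees$plot_id, , drop = FALSE],
    theta_meanlog = priors$theta_meanlog, theta_sdlog = priors$theta_sdlog,
    beta_mean = priors$beta_mean, beta_sd = priors$beta_sd,
    sigma_sp_sd = priors$sigma_sp_sd, cov_sd = priors$cov_sd,
    sigma_sd = priors$sigma_sd
  )
  samples <- run_jags(model, data,
                      c("ltheta", "beta", "lsp", "sigma_sp", "thetaX",
                        "sigma"), sampler)
  chain_list <- lapply(samples, function(ch) {
    ch <- as.matrix(ch)
    out <- cbind(
      exp(ch[, sprintf("ltheta[%d]", seq_along(cohorts)), drop = FALSE]),
      ch[, sprintf("beta[%d]", seq_along(cohorts)), drop = FALSE],
      ch[, "sigma_sp"],
      ch[, sprintf("thetaX[%d]", seq_len(ncol(X$values))), drop = FALSE],
      ch[, "sigma"], ch[, "sigma"]^2,
      exp(ch[, sprintf("lsp[%d]", seq_along(species)), drop = FALSE]))
    colnames(out) <- c(paste0("theta_", cohorts), paste0("beta_", cohorts),
                       "sigma_sp", paste0("theta_", covariate_names()),
                       "sigma", "sigma2",
                       sprintf("theta_sp[%s]", species))
    out
  })
  new_carbon_fit("growth", chain_list, sampler, priors,
                 sprintf("%d trees, %d species, %d plots", nrow(trees),
                         length(species), length(unique(trees$plot_id))))
}

#' Posterior predicted carbon of an average tree at given ages
#'
#' Pushes every posterior draw through the median trajectory
#' (`theta_sp = 1`) of the requested cohort at the requested ages and
#' summarizes the resulting distribution. Ages outside the 1-60 year
#' range the model was built for trigger an extrapolation warning.
#'
#' @param fit a growth `carbon_fit`.
#' @param cohort `"planted"` or `"spontaneous"`.
#' @param age vector of ages (years).
#' @param x standardized covariate vector; `NULL` for average conditions.
#' @return data.frame with `age`, `mean`, `sd`, `q2.5`, `q50`, `q97.5`
#'   of predicted carbon (kg).
#' @export
predict_age_carbon <- function(fit, cohort, age, x = NULL) {
  stopifnot(inherits(fit, "carbon_fit"), fit$model == "growth")
  cohort <- match.arg(cohort, GROWTH_COHORTS)
  if (any(age < 1 | age > 60))
    warning("age outside [1, 60] years: extrapolating beyond the data",
            call. = FALSE)
  d <- posterior_draws(fit, c(paste0("theta_", cohort),
                              paste0("beta_", cohort),
                              paste0("theta_", covariate_names())))
  cov_term <- if (is.null(x)) 1 else
    exp(as.vector(d[, paste0("theta_", covariate_names()), drop = FALSE] %*%
                    x))
  out <- lapply(age, function(a) {
    draws <- d[, 1] * a^d[, 2] * cov_term
    data.frame(age = a, mean = mean(draws), sd = sd(draws),
               q2.5 = quantile(draws, 0.025), q50 = quantile(draws, 0.5),
               q97.5 = quantile(draws, 0.975), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Posterior draws of the window-mean annual gain
#'
#' For each posterior draw, the mean annual gain of a population-average
#' tree over `[a, b]` is `(C(b) - C(a)) / (b - a)` on that draw's median
#' trajectory — the telescoped mean of its one-year gains.
#'
#' @param fit a growth `carbon_fit`.
#' @param cohort `"planted"` or `"spontaneous"`.
#' @param window numeric `c(a, b)`, years, `b > a >= 1`.
#' @return Numeric vector of posterior draws (kg/year).
#' @export
gain_draws <- function(fit, cohort, window) {
  stopifnot(inherits(fit, "carbon_fit"), fit$model == "growth")
  cohort <- match.arg(cohort, GROWTH_COHORTS)
  if (length(window) != 2 || window[2] <= window[1] || window[1] < 1)
    abort_validation("`window` must be c(a, b) with b > a >= 1")
  d <- posterior_draws(fit, c(paste0("theta_", cohort),
                              paste0("beta_", cohort)))
  (d[, 1] * window[2]^d[, 2] - d[, 1] * window[1]^d[, 2]) / diff(window)
}
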