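#' Generative parameters of the plot-level stock model
#'
#' The stock model describes the carbon stock `Cs[coh, p]` of cohort `coh`
#' in plot `p` as lognormal around a multiplicative median,
#' `Cs ~ LN(log(theta_coh * exp(sum(theta_cov * x))), sigma^2)`,
#' where `x` are the plot's standardized covariates. `theta_coh` is the
#' cohort's median stock (Mg/ha) in average conditions (all covariates at
#' their mean, i.e. `x = 0`) and `sigma` is the lognormal scale.
#'
#' @param theta_cohort named positive numeric, one median stock (Mg/ha)
#'   per cohort `remnant`, `spontaneous`, `planted`.
#' @param theta_cov numeric length 8, standardized covariate effects on
#'   the log scale; names must match [covariate_names()] (unnamed vectors
#'   are taken in that order).
#' @param sigma positive lognormal scale of the observation distribution.
#' @return An object of class `stock_params`.
#' @examples
#' stock_params(theta_cohort = c(remnant = 6.33, spontaneous = 2.06,
#'                               planted = 1.53),
#'              theta_cov = rep(0, 8), sigma = 1.1)
#' @export
stock_params <- function(theta_cohort, theta_cov, sigma) {
  theta_cohort <- check_cohort_vector(theta_cohort, COHORTS, "theta_cohort")
  theta_cov <- check_covariate_vector(theta_cov)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  structure(
    list(theta_cohort = theta_cohort, theta_cov = theta_cov, sigma = sigma),
    class = "stock_params"
  )
}

#' Generative parameters of the tree-level growth model
#'
#' Tree carbon over age follows a lognormal power law,
#' `Cf ~ LN(log(theta_coh * theta_sp * age^beta_coh *
#' exp(sum(theta_cov * x))), sigma^2)`, with multiplicative species
#' effects `theta_sp ~ LN(log(1), sigma_sp^2)`. Only planted and
#' spontaneous trees carry ages, so `theta_cohort` and `beta_cohort` have
#' exactly those two entries. `beta > 1` means accelerating annual gains,
#' `beta < 1` decelerating.
#'
#' @param theta_cohort named positive numeric with entries `planted` and
#'   `spontaneous`: baseline carbon at age 1 (kg), interpretable as the
#'   first-year gain.
#' @param beta_cohort named positive numeric, power-law exponents for the
#'   same two cohorts.
#' @param sigma_sp positive; scale of the lognormal species random effect.
#' @param theta_cov standardized covariate effects, as in [stock_params()].
#' @param sigma positive lognormal residual scale.
#' @param species_effects optional named positive numeric of realized
#'   species effects `theta_sp`; `NULL` means unrealized (drawn when
#'   simulating, taken as 1 when predicting a population-level tree).
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(theta_cohort = c(planted = 18, spontaneous = 3.2),
#'               beta_cohort = c(planted = 0.75, spontaneous = 1.35),
#'               sigma_sp = 0.3, theta_cov = rep(0, 8), sigma = 0.5)
#' @export
growth_params <- function(theta_cohort, beta_cohort, sigma_sp, theta_cov,
                          sigma, species_effects = NULL) {
  theta_cohort <- check_cohort_vector(theta_cohort, GROWTH_COHORTS,
                                      "theta_cohort")
  beta_cohort <- check_cohort_vector(beta_cohort, GROWTH_COHORTS,
                                     "beta_cohort")
  check_number(sigma_sp, "sigma_sp", lower = 0, strict_lower = TRUE)
  theta_cov <- check_covariate_vector(theta_cov)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (!is.null(species_effects)) {
    if (is.null(names(species_effects)) || any(!is.finite(species_effects)) ||
        any(species_effects <= 0))
      abort_validation("`species_effects` must be a named positive vector")
  }
  structure(
    list(theta_cohort = theta_cohort, beta_cohort = beta_cohort,
         sigma_sp = sigma_sp, theta_cov = theta_cov, sigma = sigma,
         species_effects = species_effects),
    class = "growth_params"
  )
}

check_cohort_vector <- function(x, cohorts, name) {
  if (is.null(names(x))) {
    if (length(x) != length(cohorts))
      abort_validation(sprintf("`%s` must have %d entries (%s)", name,
                               length(cohorts),
                               paste(cohorts, collapse = ", ")))
    names(x) <- cohorts
  }
  if (!setequal(names(x), cohorts))
    abort_validation(sprintf("`%s` must be named with: %s", name,
                             paste(cohorts, collapse = ", ")))
  x <- x[cohorts]
  if (any(!is.finite(x)) || any(x <= 0))
    abort_validation(sprintf("`%s` must be strictly positive and finite", name))
  x
}

check_covariate_vector <- function(theta_cov) {
  nm <- covariate_names()
  if (length(theta_cov) != length(nm))
    abort_validation(sprintf("`theta_cov` must have length %d", length(nm)))
  if (is.null(names(theta_cov))) names(theta_cov) <- nm
  if (!setequal(names(theta_cov), nm))
    abort_validation("`theta_cov` names must match covariate_names()")
  theta_cov <- theta_cov[nm]
  if (any(!is.finite(theta_cov)))
    abort_validation("`theta_cov` must be finite")
  theta_cov
}

#' @export
print.stock_params <- function(x, ...) {
  cat("Stock-model parameters (lognormal, exponential covariate link)\n")
  cat("  median stock in average conditions (Mg/ha):\n")
  print(round(x$theta_cohort, 3))
  nz <- x$theta_cov[x$theta_cov != 0]
  cat("  non-zero covariate effects:",
      if (length(nz)) paste(names(nz), round(nz, 3), collapse = ", ")
      else "none", "\n")
  cat("  sigma:", format(x$sigma), "\n")
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth-model parameters (lognormal power law over age)\n")
  cat("  baseline carbon at age 1 (kg):",
      paste(names(x$theta_cohort), round(x$theta_cohort, 3), collapse = ", "),
      "\n")
  cat("  power-law exponents:",
      paste(names(x$beta_cohort), round(x$beta_cohort, 3), collapse = ", "),
      "\n")
  cat("  sigma_sp:", format(x$sigma_sp), " sigma:", format(x$sigma), "\n")
  if (!is.null(x$species_effects))
    cat("  realized species effects:", length(x$species_effects), "species\n")
  invisible(x)
}

#' Prior and sampler settings for the Bayesian fits
#'
#' Priors are weakly informative on the observed scale and shared between
#' the two models where the parameter exists: lognormal(log 5, 1.5) on the
#' cohort baselines, normal(0, 1) on standardized covariate effects,
#' half-normal(0, 1) on lognormal scales, and normal(1, 0.5) on power-law
#' exponents (left untruncated so the conjugate block sampler applies;
#' with trees of age >= 1 the data leave no practical posterior mass at
#' negative exponents). All are overridable.
#'
#' @param theta_meanlog,theta_sdlog lognormal prior on cohort baselines.
#' @param cov_sd sd of the normal prior on covariate effects.
#' @param sigma_sd scale of the half-normal prior on `sigma`.
#' @return A list of class `model_priors`.
#' @export
stock_priors <- function(theta_meanlog = log(5), theta_sdlog = 1.5,
                         cov_sd = 1, sigma_sd = 1) {
  structure(list(theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
                 cov_sd = cov_sd, sigma_sd = sigma_sd),
            class = "model_priors")
}

#' @rdname stock_priors
#' @param beta_mean,beta_sd normal prior on the power-law exponents.
#' @param sigma_sp_sd scale of the half-normal prior on `sigma_sp`.
#' @export
growth_priors <- function(theta_meanlog = log(5), theta_sdlog = 1.5,
                          beta_mean = 1, beta_sd = 0.5, sigma_sp_sd = 1,
                          cov_sd = 1, sigma_sd = 1) {
  structure(list(theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma_sp_sd = sigma_sp_sd, cov_sd = cov_sd,
                 sigma_sd = sigma_sd),
            class = "model_priors")
}

#' @rdname stock_priors
#' @param chains number of MCMC chains (>= 2, so split-R-hat is defined).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param draws retained sampling iterations per chain.
#' @param seed integer; chain RNGs are seeded deterministically from it.
#' @param rhat_max convergence gate: the fit aborts with a structured
#'   convergence error if any split-R-hat exceeds this.
#' @param min_ess convergence gate on the smallest effective sample size.
#' @export
sampler_options <- function(chains = 4, warmup = 1000, draws = 1000,
                            seed = 1, rhat_max = 1.01, min_ess = 100) {
  if (chains < 2) abort_validation("`chains` must be >= 2")
  check_number(warmup, "warmup", lower = 10)
  check_number(draws, "draws", lower = 10)
  check_number(seed, "seed", lower = 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_max = rhat_max, min_ess = min_ess),
            class = "sampler_options")
}
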