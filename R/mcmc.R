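# Shared MCMC plumbing for the two hierarchical models. Both likelihoods
# are lognormal, which on the log scale is a normal linear model; JAGS is
# therefore run on log(carbon) with its `glm` module loaded so the whole
# linear structure is block-sampled (the Jacobian of the log transform is
# constant in the parameters, so the posterior is identical to the
# lognormal formulation used by stock_loglik()/growth_loglik()).

run_jags <- function(model_string, data, monitor, sampler) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("rjags (and a JAGS installation) is required for model fitting")
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(sampler$chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed * 1000L + i))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = sampler$chains,
                             n.adapt = max(100L, sampler$warmup %/% 2L),
                             quiet = TRUE)
  update(model, max(100L, sampler$warmup - sampler$warmup %/% 2L),
         progress.bar = "none")
  rjags::coda.samples(model, variable.names = monitor,
                      n.iter = sampler$draws, progress.bar = "none")
}

# Split-R-hat: each chain is halved and the classic potential scale
# reduction factor computed over the 2 * chains segments, which also
# flags within-chain drift that whole-chain R-hat misses.
split_rhat <- function(mat) {
  # mat: iterations x chains for one parameter
  n <- nrow(mat)
  half <- n %/% 2L
  segs <- cbind(mat[seq_len(half), , drop = FALSE],
                mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

summarize_chains <- function(chain_list, sampler) {
  # chain_list: list (per chain) of iterations x parameter matrices on
  # the *reporting* scale
  pars <- colnames(chain_list[[1]])
  draws <- do.call(rbind, chain_list)
  ess <- tryCatch(
    as.numeric(coda::effectiveSize(coda::as.mcmc.list(
      lapply(chain_list, coda::mcmc)))),
    error = function(e) rep(NA_real_, length(pars)))
  summ <- data.frame(
    parameter = pars,
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = apply(draws, 2, quantile, 0.025),
    q50 = apply(draws, 2, quantile, 0.5),
    q97.5 = apply(draws, 2, quantile, 0.975),
    rhat = vapply(pars, function(p)
      split_rhat(vapply(chain_list, function(ch) ch[, p],
                        numeric(nrow(chain_list[[1]])))), 1),
    ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(draws = draws, summary = summ)
}

new_carbon_fit <- function(model, chain_list, sampler, priors, data_info) {
  s <- summarize_chains(chain_list, sampler)
  fit <- structure(
    list(model = model, draws = s$draws, chains = chain_list,
         summary = s$summary, sampler = sampler, priors = priors,
         data_info = data_info),
    class = "carbon_fit"
  )
  bad_rhat <- s$summary$parameter[s$summary$rhat > sampler$rhat_max]
  low_ess <- s$summary$parameter[!is.na(s$summary$ess) &
                                   s$summary$ess < sampler$min_ess]
  if (length(bad_rhat) || length(low_ess))
    abort_convergence(
      sprintf(paste0("MCMC did not converge: %d parameter(s) with split-",
                     "R-hat > %.3f (%s), %d with ESS < %g (%s). Increase ",
                     "warmup/draws or revisit the data."),
              length(bad_rhat), sampler$rhat_max,
              paste(utils::head(bad_rhat, 4), collapse = ", "),
              length(low_ess), sampler$min_ess,
              paste(utils::head(low_ess, 4), collapse = ", ")),
      diagnostics = fit)
  fit
}

#' Posterior summaries and draws of a fitted model
#'
#' @param fit a `carbon_fit` from [fit_stocks()] or [fit_growth()].
#' @param pars optional character vector restricting to some parameters
#'   (regular expressions are not interpreted; names are matched exactly).
#' @return `posterior_summary()`: data.frame with one row per parameter
#'   (`mean`, `sd`, `q2.5`, `q50`, `q97.5`, split `rhat`, `ess`).
#'   `posterior_draws()`: matrix of pooled posterior draws, one column per
#'   parameter, on the reporting (natural) scale.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "carbon_fit"))
  s <- fit$summary
  if (!is.null(pars)) {
    miss <- setdiff(pars, s$parameter)
    if (length(miss))
      abort_validation("unknown parameter(s): ", paste(miss, collapse = ", "))
    s <- s[match(pars, s$parameter), ]
    rownames(s) <- NULL
  }
  s
}

#' @rdname posterior_summary
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "carbon_fit"))
  d <- fit$draws
  if (!is.null(pars)) {
    miss <- setdiff(pars, colnames(d))
    if (length(miss))
      abort_validation("unknown parameter(s): ", paste(miss, collapse = ", "))
    d <- d[, pars, drop = FALSE]
  }
  d
}

#' @export
print.carbon_fit <- function(x, max_rows = 16L, ...) {
  cat(sprintf("Bayesian %s model fit (%d chains x %d draws, JAGS)\n",
              x$model, x$sampler$chains, x$sampler$draws))
  cat(sprintf("  data: %s\n", x$data_info))
  s <- x$summary
  main <- s[!grepl("^theta_sp\\[", s$parameter), ]
  show <- utils::head(main, max_rows)
  show[-1] <- lapply(show[-1], function(v) round(v, 3))
  print(show, row.names = FALSE)
  if (nrow(main) > max_rows)
    cat("  ...", nrow(main) - max_rows, "more rows\n")
  n_sp <- sum(grepl("^theta_sp\\[", s$parameter))
  if (n_sp) cat("  (+", n_sp, "species effects; see posterior_summary())\n")
  cat(sprintf("  max split-R-hat %.3f, min ESS %.0f\n",
              max(s$rhat), min(s$ess, na.rm = TRUE)))
  invisible(x)
}

#' Write posterior artifacts to CSV
#'
#' `write_posterior()` writes the summary table (one row per parameter);
#' `write_draws()` writes the pooled draws, one column per parameter.
#'
#' @param fit a `carbon_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  write.csv(posterior_summary(fit), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
write_draws <- function(fit, path) {
  write.csv(as.data.frame(posterior_draws(fit)), path, row.names = FALSE)
  invisible(path)
}
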