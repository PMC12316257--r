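# Small in-code fixtures shared across test files.

fixture_trees <- function() {
  tree_inventory(data.frame(
    tree_id = c("t1", "t2", "t3", "t4", "t5"),
    plot_id = c("p1", "p1", "p1", "p2", "p2"),
    species = c("Milicia excelsa", "Alstonia boonei", "Milicia excelsa",
                "Ceiba pentandra", "Cola nitida"),
    cohort = c("remnant", "spontaneous", "planted", "remnant",
               "spontaneous"),
    dbh = c(65, 24, 15, 80, 30),
    height = c(32, 18, 11, 38, 20),
    age = c(NA, 12, 6, NA, 20),
    stringsAsFactors = FALSE))
}

fixture_fields <- function(n = 6) {
  set.seed(99)
  field_table(data.frame(
    plot_id = paste0("p", seq_len(n)),
    site_id = rep(c("s1", "s2"), length.out = n),
    area = seq(0.5, 2.5, length.out = n),
    ownership = rep(c(0, 1), length.out = n),
    knowledge = seq(10, 90, length.out = n),
    prev_forest = rep(c(1, 0), length.out = n),
    cocoa_density = seq(600, 1600, length.out = n),
    bulk_density = seq(1.2, 1.6, length.out = n),
    soc = seq(8, 25, length.out = n),
    temperature = seq(22.8, 26.0, length.out = n),
    precipitation = seq(1150, 1850, length.out = n),
    stringsAsFactors = FALSE))
}

fixture_wood_density <- function() {
  wood_density_table(data.frame(
    taxon = c("Milicia excelsa", "Ceiba pentandra", "Alstonia boonei",
              "Cola", "Milicia"),
    level = c("species", "species", "species", "genus", "genus"),
    density_g_cm3 = c(0.62, 0.28, 0.33, 0.55, 0.60),
    stringsAsFactors = FALSE))
}

# a degenerate (point-mass) growth fit for reporting tests, bypassing MCMC
fake_growth_fit <- function(theta_p = 6, beta_p = 1.3, theta_s = 3,
                            beta_s = 1.1, theta_cov = rep(0, 8),
                            sigma = 0.5, jitter = 0, n = 200) {
  set.seed(42)
  pars <- c(theta_planted = theta_p, theta_spontaneous = theta_s,
            beta_planted = beta_p, beta_spontaneous = beta_s,
            sigma_sp = 0.3,
            setNames(theta_cov, paste0("theta_", covariate_names())),
            sigma = sigma, sigma2 = sigma^2)
  draws <- matrix(rep(pars, each = n), nrow = n,
                  dimnames = list(NULL, names(pars)))
  if (jitter > 0)
    draws <- draws * exp(matrix(rnorm(length(draws), 0, jitter),
                                nrow = n))
  summ <- data.frame(parameter = colnames(draws),
                     mean = colMeans(draws),
                     sd = apply(draws, 2, sd),
                     q2.5 = apply(draws, 2, quantile, 0.025),
                     q50 = apply(draws, 2, quantile, 0.5),
                     q97.5 = apply(draws, 2, quantile, 0.975),
                     rhat = 1, ess = n, row.names = NULL)
  structure(list(model = "growth", draws = draws, summary = summ,
                 sampler = sampler_options(chains = 2, warmup = 10,
                                           draws = n / 2),
                 data_info = "fixture"),
            class = "carbon_fit")
}

quick_sampler <- function(seed = 1, chains = 2, warmup = 400, draws = 500,
                          rhat_max = 1.05) {
  sampler_options(chains = chains, warmup = warmup, draws = draws,
                  seed = seed, rhat_max = rhat_max)
}
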