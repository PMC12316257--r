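#' Design of a synthetic multi-site cocoa inventory
#'
#' Describes the study layout the generators emulate: 15 sites of 10
#' fields each, plot areas 0.3-5 ha, three tree cohorts with
#' size-structured diameters, farmer-reported ages of 1-40 years for
#' planted and spontaneous trees, and eight plot covariates spanning the
#' climatic gradients of the cocoa belt (22.6-26.2 degrees C, 1,100-1,900
#' mm). Cohort shares default to the observed relative abundances
#' (spontaneous most numerous, then planted, then remnant); diameter
#' distributions are truncated lognormals calibrated so the share of
#' trees above 50 cm dbh is about 25% (remnant), 15% (spontaneous) and 4%
#' (planted).
#'
#' @param n_sites number of sites.
#' @param fields_per_site plots per site.
#' @param area_range ha, `c(min, max)` of the uniform plot-area draw.
#' @param cohort_shares named shares (`remnant`, `spontaneous`,
#'   `planted`); normalized to sum to 1.
#' @param trees_per_ha `c(min, max)` of the uniform per-plot tree
#'   density draw.
#' @param n_species size of the species pool (geometric abundance skew).
#' @param n_genera number of genera the pool is spread over.
#' @param abundance_decay geometric decay of species abundances.
#' @param age_range years, planted/spontaneous age draw.
#' @param cohort_presence named per-cohort probability that a plot hosts
#'   the cohort at all (empty cells produce no stock observation).
#' @param dbh_meanlog,dbh_sdlog named per-cohort lognormal dbh parameters
#'   (cm), truncated at the 10 cm inventory threshold.
#' @param seed default integer seed carried by the design.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_sites = 15, fields_per_site = 10,
                         area_range = c(0.3, 5),
                         cohort_shares = c(remnant = 3304,
                                           spontaneous = 4734,
                                           planted = 3520),
                         trees_per_ha = c(20, 80),
                         n_species = 60, n_genera = 25,
                         abundance_decay = 0.93,
                         age_range = c(1, 40),
                         cohort_presence = c(remnant = 0.8,
                                             spontaneous = 0.95,
                                             planted = 0.9),
                         dbh_meanlog = c(remnant = 3.3042,
                                         spontaneous = 2.7875,
                                         planted = 2.7994),
                         dbh_sdlog = c(remnant = 0.8, spontaneous = 0.9,
                                       planted = 0.6),
                         seed = 1) {
  check_number(n_sites, "n_sites", lower = 1)
  check_number(fields_per_site, "fields_per_site", lower = 1)
  if (length(area_range) != 2 || area_range[1] <= 0 ||
      area_range[2] < area_range[1])
    abort_validation("`area_range` must be a valid positive range")
  if (trees_per_ha[2] < trees_per_ha[1] || trees_per_ha[1] <= 0)
    abort_validation("`trees_per_ha` must be a valid positive range")
  cohort_shares <- check_cohort_vector(cohort_shares, COHORTS,
                                       "cohort_shares")
  cohort_shares <- cohort_shares / sum(cohort_shares)
  cohort_presence <- check_cohort_vector(cohort_presence, COHORTS,
                                         "cohort_presence")
  if (any(cohort_presence > 1))
    abort_validation("`cohort_presence` entries are probabilities")
  if (age_range[1] < 1 || age_range[2] < age_range[1] || age_range[2] > 60)
    abort_validation("`age_range` must lie within [1, 60]")
  structure(
    list(n_sites = as.integer(n_sites),
         fields_per_site = as.integer(fields_per_site),
         area_range = area_range, cohort_shares = cohort_shares,
         trees_per_ha = trees_per_ha, n_species = as.integer(n_species),
         n_genera = as.integer(n_genera),
         abundance_decay = abundance_decay, age_range = age_range,
         cohort_presence = cohort_presence,
         dbh_meanlog = check_cohort_vector(dbh_meanlog, COHORTS,
                                           "dbh_meanlog"),
         dbh_sdlog = check_cohort_vector(dbh_sdlog, COHORTS, "dbh_sdlog"),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Synthetic study design: %d sites x %d fields, %.1f-%.1f ha\n",
              x$n_sites, x$fields_per_site, x$area_range[1],
              x$area_range[2]))
  cat("  cohort shares:",
      paste(names(x$cohort_shares), round(x$cohort_shares, 3),
            collapse = ", "), "\n")
  cat(sprintf("  species pool %d over %d genera, seed %d\n", x$n_species,
              x$n_genera, x$seed))
  invisible(x)
}

species_pool <- function(design) {
  g <- rep(seq_len(design$n_genera), length.out = design$n_species)
  genus <- sprintf("Genus%02d", g)
  sp_idx <- stats::ave(g, g, FUN = seq_along)
  data.frame(species = sprintf("%s synthspec%02d", genus, sp_idx),
             genus = genus,
             weight = design$abundance_decay^seq_len(design$n_species),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic field table
#'
#' One plot per (site, field) cell with areas, site-level climate drawn
#' across the design's gradients (shared within a site up to small local
#' jitter, as real climate rasters would be) and the remaining covariates
#' from plausible independent distributions: Bernoulli(0.5) ownership and
#' previous-forest flags, Beta(2, 2)-scaled knowledge percentages, and
#' lognormal cocoa density, soil bulk density and soil organic carbon
#' around field-realistic centres (1,100 ind/ha; 1.4 kg/dm3; 15 g/kg).
#'
#' @param design a [study_design()].
#' @param seed integer seed; defaults to the design's.
#' @return A `field_table` with `n_sites * fields_per_site` plots.
#' @export
generate_fields <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n <- design$n_sites * design$fields_per_site
  site <- rep(sprintf("S%02d", seq_len(design$n_sites)),
              each = design$fields_per_site)
  plot_id <- paste0(site, sprintf("-P%02d",
                                  rep(seq_len(design$fields_per_site),
                                      design$n_sites)))
  site_temp <- runif(design$n_sites, 22.6, 26.2)
  site_prec <- runif(design$n_sites, 1100, 1900)
  idx <- rep(seq_len(design$n_sites), each = design$fields_per_site)
  field_table(data.frame(
    plot_id = plot_id, site_id = site,
    area = runif(n, design$area_range[1], design$area_range[2]),
    ownership = rbinom(n, 1, 0.5),
    knowledge = 100 * stats::rbeta(n, 2, 2),
    prev_forest = rbinom(n, 1, 0.5),
    cocoa_density = rlnorm(n, log(1100), 0.35),
    bulk_density = rlnorm(n, log(1.4), 0.08),
    soc = rlnorm(n, log(15), 0.35),
    temperature = pmin(pmax(site_temp[idx] + rnorm(n, 0, 0.1), 22.6), 26.2),
    precipitation = pmin(pmax(site_prec[idx] + rnorm(n, 0, 20), 1100), 1900),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic tree inventory
#'
#' Draws per-plot tree lists matching the design: cohorts by their target
#' shares, diameters from cohort-specific lognormals truncated at the
#' 10 cm threshold (so remnants carry the largest share of > 50 cm
#' trees), heights from the monotone curve `1.5 * dbh^0.7` with lognormal
#' noise, species from the geometrically skewed pool, and integer ages
#' for planted and spontaneous trees only.
#'
#' @param design a [study_design()].
#' @param fields a `field_table`, usually from [generate_fields()].
#' @param seed integer seed.
#' @return A `tree_inventory`.
#' @export
generate_inventory <- function(design, fields, seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed + 1L)
  pool <- species_pool(design)
  n_per <- pmax(1L, round(fields$area *
                            runif(nrow(fields), design$trees_per_ha[1],
                                  design$trees_per_ha[2])))
  n <- sum(n_per)
  plot_id <- rep(fields$plot_id, n_per)
  cohort <- sample(COHORTS, n, replace = TRUE, prob = design$cohort_shares)
  sp_i <- sample(seq_len(nrow(pool)), n, replace = TRUE, prob = pool$weight)
  # inverse-cdf draw from the lognormal truncated at the 10 cm threshold
  p10 <- stats::plnorm(10, design$dbh_meanlog[cohort],
                       design$dbh_sdlog[cohort])
  dbh <- stats::qlnorm(p10 + runif(n) * (1 - p10),
                       design$dbh_meanlog[cohort], design$dbh_sdlog[cohort])
  height <- pmin(pmax(1.5 * dbh^0.7 * rlnorm(n, 0, 0.15), 2), 60)
  age <- ifelse(cohort == "remnant", NA_real_,
                sample(seq(design$age_range[1], design$age_range[2]), n,
                       replace = TRUE))
  tree_inventory(data.frame(
    tree_id = sprintf("T%06d", seq_len(n)), plot_id = plot_id,
    species = pool$species[sp_i], genus = pool$genus[sp_i],
    cohort = cohort, dbh = dbh, height = height, age = age,
    stringsAsFactors = FALSE))
}

#' Generate a synthetic wood-density reference table
#'
#' One density per species of the design's pool, drawn from a normal
#' centred at 0.55 g/cm3 (sd 0.08) truncated to (0.2, 0.9), matching the
#' near-identical cohort medians of field wood-density data.
#'
#' @param design a [study_design()].
#' @param seed integer seed.
#' @return A [wood_density_table()].
#' @export
generate_wood_density <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed + 2L)
  pool <- species_pool(design)
  d <- rnorm(nrow(pool), 0.55, 0.08)
  while (any(bad <- d <= 0.2 | d >= 0.9))
    d[bad] <- rnorm(sum(bad), 0.55, 0.08)
  wood_density_table(data.frame(taxon = pool$species, level = "species",
                                density_g_cm3 = d, stringsAsFactors = FALSE))
}

#' Default generative parameters for recovery studies
#'
#' `default_stock_params()` sets the cohort median stocks to the observed
#' field medians (6.33 / 2.06 / 1.53 Mg/ha for remnant / spontaneous /
#' planted), covariate effects to the three reported plot-level effects
#' (ownership -0.39, previous forest +0.41, cocoa density -0.34, others
#' zero) and a lognormal scale of 1.1, consistent with the spread of
#' observed per-cohort stock quantiles.
#'
#' `default_growth_params()` is a constructed divergence scenario:
#' exponents 0.75 (planted) vs 1.35 (spontaneous) with baselines 18 and
#' 3.2 kg place the crossing of the two cohorts' annual-gain curves
#' around year 7, after which spontaneous trees pull away — the
#' qualitative pattern seen in the field. Species-effect scale 0.3,
#' tree-level covariate effects ownership +0.19, previous forest +0.13,
#' cocoa density -0.13, temperature -0.08, residual scale 0.5.
#'
#' @return A [stock_params()] or [growth_params()].
#' @export
default_stock_params <- function() {
  stock_params(
    theta_cohort = c(remnant = 6.33, spontaneous = 2.06, planted = 1.53),
    theta_cov = c(ownership = -0.39, knowledge = 0, prev_forest = 0.41,
                  cocoa_density = -0.34, bulk_density = 0, soc = 0,
                  temperature = 0, precipitation = 0),
    sigma = 1.1)
}

#' @rdname default_stock_params
#' @export
default_growth_params <- function() {
  growth_params(
    theta_cohort = c(planted = 18, spontaneous = 3.2),
    beta_cohort = c(planted = 0.75, spontaneous = 1.35),
    sigma_sp = 0.3,
    theta_cov = c(ownership = 0.19, knowledge = 0, prev_forest = 0.13,
                  cocoa_density = -0.13, bulk_density = 0, soc = 0,
                  temperature = -0.08, precipitation = 0),
    sigma = 0.5)
}

#' Generate a complete synthetic stock study
#'
#' Fields, standardized covariates, a per-cohort presence plan and
#' lognormal stock observations drawn from known parameters, bundled with
#' the ground truth for recovery scoring.
#'
#' @param design a [study_design()].
#' @param truth a [stock_params()]; the generative truth.
#' @param seed integer seed.
#' @return A list of class `stock_study`: `fields`, `X`, `stocks`,
#'   `truth` (a `synthetic_truth`).
#' @export
generate_stock_study <- function(design = study_design(),
                                 truth = default_stock_params(),
                                 seed = design$seed) {
  fields <- generate_fields(design, seed)
  X <- standardize_covariates(fields)
  set.seed(seed + 3L)
  keep <- rbinom(nrow(fields) * 3, 1,
                 rep(design$cohort_presence[COHORTS],
                     each = nrow(fields))) == 1
  presence <- expand.grid(plot_id = fields$plot_id, cohort = COHORTS,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)[keep, ]
  stocks <- simulate_stocks(truth, X, presence, seed = seed + 4L)
  structure(list(fields = fields, X = X, stocks = stocks,
                 truth = synthetic_truth("stock", truth, design, seed)),
            class = "stock_study")
}

#' Generate a complete synthetic growth study
#'
#' Fields, standardized covariates, an aged planted/spontaneous tree
#' design and carbon drawn from the power-law growth model with realized
#' species effects, bundled with the ground truth.
#'
#' @param design a [study_design()].
#' @param truth a [growth_params()].
#' @param seed integer seed.
#' @return A list of class `growth_study`: `fields`, `X`, `trees` (with
#'   `carbon` filled), `truth`.
#' @export
generate_growth_study <- function(design = study_design(),
                                  truth = default_growth_params(),
                                  seed = design$seed) {
  fields <- generate_fields(design, seed)
  X <- standardize_covariates(fields)
  trees <- generate_inventory(design, fields, seed)
  trees <- trees[trees$cohort %in% GROWTH_COHORTS, ]
  class(trees) <- c("tree_inventory", "data.frame")
  sim <- simulate_growth(truth, trees, X, seed = seed + 5L)
  structure(list(fields = fields, X = X, trees = sim$trees,
                 truth = synthetic_truth("growth", sim$params, design,
                                         seed)),
            class = "growth_study")
}

synthetic_truth <- function(kind, params, design, seed) {
  structure(list(kind = kind, params = params, design = design,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic %s-study truth (seed %d)\n", x$kind, x$seed))
  print(x$params)
  invisible(x)
}

#' Serialize a synthetic truth to JSON and back
#'
#' A flat, human-readable record of the generative parameters (including
#' realized species effects), the design and the seed; `read_truth()`
#' reconstructs an identical object, so truths can accompany exported
#' synthetic studies on disk.
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(kind = truth$kind, seed = truth$seed,
         params = lapply(unclass(truth$params), function(v)
           if (is.null(v)) NULL else as.list(v)),
         design = lapply(unclass(truth$design), function(v) as.list(v))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unlist2 <- function(v) if (is.list(v)) unlist(v) else v
  p <- lapply(j$params, unlist2)
  params <- if (j$kind == "stock")
    stock_params(p$theta_cohort, p$theta_cov, p$sigma)
  else
    growth_params(p$theta_cohort, p$beta_cohort, p$sigma_sp, p$theta_cov,
                  p$sigma, species_effects = p$species_effects)
  d <- lapply(j$design, unlist2)
  design <- study_design(d$n_sites, d$fields_per_site, d$area_range,
                         d$cohort_shares, d$trees_per_ha, d$n_species,
                         d$n_genera, d$abundance_decay, d$age_range,
                         d$cohort_presence, d$dbh_meanlog, d$dbh_sdlog,
                         d$seed)
  synthetic_truth(j$kind, params, design, j$seed)
}

#' Score posterior recovery of a known truth
#'
#' Lines every generative parameter up against its posterior summary and
#' reports the posterior mean, the 95% credible interval, whether it
#' covers the truth, and the z-score `(mean - truth) / sd`. Species
#' effects are scored when the fit carries them.
#'
#' @param truth a `synthetic_truth` (from the study generators).
#' @param fit the matching `carbon_fit`, or a posterior-summary
#'   data.frame with columns `parameter`, `mean`, `sd`, `q2.5`, `q97.5`
#'   (e.g. a re-read `posterior_*.csv`).
#' @return A data.frame of class `recovery_report` with one row per
#'   parameter and attribute `coverage` (fraction of parameters whose 95%
#'   interval covers the truth).
#' @export
score_recovery <- function(truth, fit) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (inherits(fit, "carbon_fit")) fit <- list(summary = fit$summary)
  else if (is.data.frame(fit)) {
    need <- c("parameter", "mean", "sd", "q2.5", "q97.5")
    if (!all(need %in% names(fit)))
      abort_validation("posterior summary must have columns: ",
                       paste(need, collapse = ", "))
    fit <- list(summary = fit)
  } else abort_validation("`fit` must be a carbon_fit or summary data.frame")
  p <- truth$params
  tv <- if (truth$kind == "stock") {
    c(setNames(p$theta_cohort, paste0("theta_", names(p$theta_cohort))),
      setNames(p$theta_cov, paste0("theta_", names(p$theta_cov))),
      sigma = p$sigma)
  } else {
    c(setNames(p$theta_cohort, paste0("theta_", names(p$theta_cohort))),
      setNames(p$beta_cohort, paste0("beta_", names(p$beta_cohort))),
      sigma_sp = p$sigma_sp,
      setNames(p$theta_cov, paste0("theta_", names(p$theta_cov))),
      sigma = p$sigma,
      if (!is.null(p$species_effects))
        setNames(p$species_effects,
                 sprintf("theta_sp[%s]", names(p$species_effects))))
  }
  s <- fit$summary
  miss <- setdiff(names(tv), s$parameter)
  if (length(miss))
    abort_validation("truth parameter(s) absent from the fit: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  s <- s[match(names(tv), s$parameter), ]
  out <- data.frame(parameter = names(tv), truth = unname(tv),
                    mean = s$mean, q2.5 = s$q2.5, q97.5 = s$q97.5,
                    covered = tv >= s$q2.5 & tv <= s$q97.5,
                    z = (s$mean - unname(tv)) / s$sd,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "coverage") <- mean(out$covered)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d parameters, 95%%-CI coverage %.0f%%\n",
              nrow(x), 100 * attr(x, "coverage")))
  main <- x[!grepl("^theta_sp\\[", x$parameter), ]
  main[c("truth", "mean", "q2.5", "q97.5", "z")] <-
    lapply(main[c("truth", "mean", "q2.5", "q97.5", "z")], round, 3)
  print(as.data.frame(main), row.names = FALSE)
  n_sp <- nrow(x) - nrow(main)
  if (n_sp)
    cat(sprintf("  (+ %d species effects, %.0f%% covered)\n", n_sp,
                100 * mean(x$covered[grepl("^theta_sp\\[", x$parameter)])))
  invisible(x)
}
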