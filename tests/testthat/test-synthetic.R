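test_that("field generation matches the design and its gradients", {
  d <- study_design(seed = 2)
  f <- generate_fields(d)
  expect_s3_class(f, "field_table")
  expect_equal(nrow(f), 150L)                      # 15 sites x 10 fields
  expect_equal(length(unique(f$site_id)), 15L)
  expect_true(all(f$temperature >= 22.6 & f$temperature <= 26.2))
  expect_true(all(f$precipitation >= 1100 & f$precipitation <= 1900))
  expect_true(all(f$area >= 0.3 & f$area <= 5))
  expect_true(all(f$ownership %in% 0:1 & f$prev_forest %in% 0:1))
  expect_identical(f, generate_fields(d))          # seed determinism
  expect_false(identical(f, generate_fields(d, seed = 3)))
})

test_that("inventories carry the study's size and age structure", {
  d <- study_design(seed = 2)
  f <- generate_fields(d)
  tr <- generate_inventory(d, f)
  expect_s3_class(tr, "tree_inventory")
  expect_true(all(tr$dbh >= 10))
  expect_true(all(is.na(tr$age[tr$cohort == "remnant"])))
  expect_true(all(!is.na(tr$age[tr$cohort != "remnant"])))
  expect_true(all(tr$age >= 1 & tr$age <= 40, na.rm = TRUE))
  # cohort size structure: share of > 50 cm trees orders
  # remnant > spontaneous > planted
  big <- tapply(tr$dbh > 50, tr$cohort, mean)
  expect_gt(big["remnant"], big["spontaneous"])
  expect_gt(big["spontaneous"], big["planted"])
  # spontaneous is the most numerous cohort
  expect_equal(names(which.max(table(tr$cohort))), "spontaneous")
  expect_lte(length(unique(tr$species)), d$n_species)
  expect_identical(tr, generate_inventory(d, f))
})

test_that("generated wood densities are plausible and reproducible", {
  d <- study_design(seed = 2)
  wd <- generate_wood_density(d)
  expect_true(all(wd$species > 0.2 & wd$species < 0.9))
  expect_equal(median(wd$species), 0.55, tolerance = 0.05)
  expect_identical(wd, generate_wood_density(d))
})

test_that("a stock study with flat effects centres on its cohort medians", {
  truth <- stock_params(c(remnant = 6.33, spontaneous = 2.06,
                          planted = 1.53), rep(0, 8), sigma = 1.1)
  study <- generate_stock_study(study_design(seed = 1), truth)
  expect_s3_class(study$stocks, "stock_obs")
  meds <- tapply(study$stocks$carbon_stock, study$stocks$cohort, median)
  for (coh in COHORTS)
    expect_equal(unname(meds[coh]), unname(truth$theta_cohort[coh]),
                 tolerance = 0.35)
  # per-cohort geometric means are a tighter check of the same location
  gm <- tapply(log(study$stocks$carbon_stock), study$stocks$cohort, mean)
  for (coh in COHORTS)
    expect_equal(unname(gm[coh]), log(unname(truth$theta_cohort[coh])),
                 tolerance = 0.25)
  # different seed: different draws, same truth
  s2 <- generate_stock_study(study_design(seed = 1), truth, seed = 9)
  expect_false(identical(study$stocks, s2$stocks))
  expect_identical(study$truth$params, s2$truth$params)
})

test_that("a growth study realizes the constructed cohort divergence", {
  study <- generate_growth_study(study_design(seed = 1))
  tr <- study$trees
  expect_true(all(tr$cohort %in% c("planted", "spontaneous")))
  expect_true(all(!is.na(tr$carbon) & tr$carbon > 0))
  expect_gt(sum(tr$cohort == "planted"), 1000)
  expect_gt(sum(tr$cohort == "spontaneous"), 1000)
  # at age ~40 spontaneous trees out-carbon planted ones
  old <- tr[tr$age >= 35, ]
  expect_gt(median(old$carbon[old$cohort == "spontaneous"]),
            median(old$carbon[old$cohort == "planted"]))
  # realized species effects are bundled with the truth
  expect_true(!is.null(study$truth$params$species_effects))
  expect_true(all(unique(tr$species) %in%
                    names(study$truth$params$species_effects)))
})

test_that("synthetic truths serialize to JSON and back unchanged", {
  study <- generate_stock_study(study_design(n_sites = 3, seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(study$truth, path)
  back <- read_truth(path)
  expect_equal(back$params, study$truth$params, tolerance = 1e-12)
  expect_equal(back$design, study$truth$design, tolerance = 1e-12)
  expect_identical(back$kind, "stock")

  g <- generate_growth_study(study_design(n_sites = 2, seed = 6))
  write_truth(g$truth, path)
  gback <- read_truth(path)
  expect_equal(gback$params$species_effects,
               g$truth$params$species_effects, tolerance = 1e-12)
})

test_that("recovery scoring flags coverage correctly", {
  truth <- shadecarbon:::synthetic_truth("stock", default_stock_params(),
                                         study_design(), 1L)
  p <- truth$params
  vals <- c(p$theta_cohort, p$theta_cov, p$sigma)
  nm <- c(paste0("theta_", COHORTS), paste0("theta_", covariate_names()),
          "sigma")
  point <- data.frame(parameter = nm, mean = vals, sd = 1e-12,
                      q2.5 = vals, q97.5 = vals)
  rep <- score_recovery(truth, point)
  expect_equal(attr(rep, "coverage"), 1)
  expect_true(all(abs(rep$z) < 1e-6))

  missed <- point
  missed$q2.5 <- vals + 1
  missed$q97.5 <- vals + 2
  rep2 <- score_recovery(truth, missed)
  expect_equal(attr(rep2, "coverage"), 0)
  expect_false(any(rep2$covered))

  bad <- point[-1, ]
  expect_error(score_recovery(truth, bad), "absent from the fit")
})
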