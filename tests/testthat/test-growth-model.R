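test_that("median carbon follows the power law and its special cases", {
  p <- growth_params(c(planted = 6, spontaneous = 6),
                     c(planted = 1.3, spontaneous = 1),
                     sigma_sp = 0.3, theta_cov = rep(0, 8), sigma = 0.5)
  expect_equal(expected_carbon(p, "planted", 1), 6)     # theta at age 1
  expect_equal(expected_carbon(p, "planted", 40), 6 * 40^1.3)
  expect_equal(expected_carbon(p, "planted", 40), 725.8, tolerance = 1e-3)
  # beta = 1: linear in age
  expect_equal(expected_carbon(p, "spontaneous", 1:10), 6 * (1:10))
  expect_error(expected_carbon(p, "remnant", 5),
               class = "shadecarbon_validation_error")
  expect_error(expected_carbon(p, "planted", 0.5),
               class = "shadecarbon_validation_error")

  # realized species effects multiply; unknown species fall back to 1
  p_sp <- growth_params(p$theta_cohort, p$beta_cohort, p$sigma_sp,
                        p$theta_cov, p$sigma,
                        species_effects = c("Cola nitida" = 1.5))
  expect_equal(expected_carbon(p_sp, "planted", 2, species = "Cola nitida"),
               1.5 * expected_carbon(p_sp, "planted", 2))
  expect_equal(expected_carbon(p_sp, "planted", 2, species = "Unknown sp"),
               expected_carbon(p_sp, "planted", 2))
})

test_that("annual gains are monotone in age according to beta", {
  up <- growth_params(c(planted = 6, spontaneous = 6),
                      c(planted = 1.35, spontaneous = 0.75),
                      0.3, rep(0, 8), 0.5)
  g_up <- annual_gain_curve(up, "planted", 1:60)$gain
  g_dn <- annual_gain_curve(up, "spontaneous", 1:60)$gain
  expect_true(all(diff(g_up) > 0))   # beta > 1: accelerating
  expect_true(all(diff(g_dn) < 0))   # beta < 1: decelerating

  lin <- growth_params(c(planted = 6, spontaneous = 6),
                       c(planted = 1, spontaneous = 1), 0.3, rep(0, 8), 0.5)
  expect_equal(annual_gain_curve(lin, "planted", 1:40)$gain, rep(6, 40))

  der <- annual_gain_curve(up, "planted", 2:10, method = "derivative")
  expect_equal(der$gain, 6 * 1.35 * (2:10)^0.35)
  expect_error(annual_gain_curve(up, "planted", numeric(0)),
               class = "shadecarbon_validation_error")
})

test_that("window-mean gains telescope to the endpoint difference", {
  p <- growth_params(c(planted = 6, spontaneous = 3.2),
                     c(planted = 1.3, spontaneous = 1.35),
                     0.3, rep(0, 8), 0.5)
  expect_equal(window_gain(p, "planted", c(1, 7)),
               (expected_carbon(p, "planted", 7) -
                  expected_carbon(p, "planted", 1)) / 6, tolerance = 1e-15)
  expect_equal(window_gain(p, "planted", c(1, 7)), 11.5, tolerance = 1e-2)
  # identity holds for arbitrary windows and both cohorts
  for (w in list(c(1, 7), c(7, 40), c(3, 29))) {
    for (coh in c("planted", "spontaneous")) {
      ages <- seq(w[1], w[2])
      fd <- diff(expected_carbon(p, coh, ages))
      expect_equal(mean(fd), window_gain(p, coh, w), tolerance = 1e-12)
    }
  }
  expect_error(window_gain(p, "planted", c(7, 7)),
               class = "shadecarbon_validation_error")
})

test_that("the growth log joint matches its closed form", {
  p <- growth_params(c(planted = 6, spontaneous = 3),
                     c(planted = 1, spontaneous = 1),
                     sigma_sp = 0.4, theta_cov = rep(0, 8), sigma = 1,
                     species_effects = c("Milicia excelsa" = 1,
                                         "Cola nitida" = 1))
  f <- fixture_fields(4)
  X <- standardize_covariates(f)
  one <- tree_inventory(data.frame(
    tree_id = "t", plot_id = "p1", species = "Milicia excelsa",
    cohort = "planted", dbh = 20, height = 12, age = 3,
    carbon = 18))  # its median: 6 * 3^1 * 1
  # data term at the median with sigma 1: -log(sqrt(2 pi)) - log(carbon);
  # species term: two effects at the mode of LN(log 1, sigma_sp^2)
  sp_term <- 2 * (-log(sqrt(2 * pi) * 0.4))
  expect_equal(growth_loglik(p, one, X),
               -log(sqrt(2 * pi)) - log(18) + sp_term, tolerance = 1e-12)

  two <- rbind(as.data.frame(one),
               within(as.data.frame(one), tree_id <- "t2"))
  two <- tree_inventory(two)
  expect_equal(growth_loglik(p, two, X) - sp_term,
               2 * (growth_loglik(p, one, X) - sp_term), tolerance = 1e-12)

  rem <- as.data.frame(one); rem$cohort <- "remnant"; rem$age <- NA
  expect_error(growth_loglik(p, tree_inventory(rem), X),
               class = "shadecarbon_validation_error")
  noeff <- as.data.frame(one); noeff$species <- "Ceiba pentandra"
  expect_error(growth_loglik(p, tree_inventory(noeff), X),
               "without a realized effect")
})

test_that("growth simulation is deterministic and median-centred", {
  d <- study_design(n_sites = 4, seed = 8)
  f <- generate_fields(d)
  X <- standardize_covariates(f)
  trees <- generate_inventory(d, f)
  trees <- trees[trees$cohort != "remnant", ]
  class(trees) <- c("tree_inventory", "data.frame")
  p <- default_growth_params()
  a <- simulate_growth(p, trees, X, seed = 3)
  b <- simulate_growth(p, trees, X, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$trees$carbon,
                         simulate_growth(p, trees, X, seed = 4)$trees$carbon))

  # the ratio carbon / median has median ~1 (lognormal median property)
  med <- expected_carbon(a$params, a$trees$cohort, a$trees$age,
                         a$trees$species,
                         X$values[a$trees$plot_id, ])
  expect_equal(median(a$trees$carbon / med), 1, tolerance = 0.05)

  # degenerate scales collapse onto the deterministic power law
  p0 <- growth_params(p$theta_cohort, p$beta_cohort, sigma_sp = 1e-8,
                      theta_cov = p$theta_cov, sigma = 1e-8)
  s0 <- simulate_growth(p0, trees, X, seed = 5)
  med0 <- expected_carbon(s0$params, trees$cohort, trees$age,
                          trees$species, X$values[trees$plot_id, ])
  expect_equal(s0$trees$carbon, med0, tolerance = 1e-5)
})

test_that("posterior age predictions are monotone and interval-ordered", {
  fit <- fake_growth_fit(jitter = 0.05)
  pr <- predict_age_carbon(fit, "spontaneous", c(7, 40))
  expect_gt(pr$q50[2], pr$q50[1])
  expect_true(all(pr$q2.5 <= pr$q50 & pr$q50 <= pr$q97.5))
  expect_warning(predict_age_carbon(fit, "planted", 80), "extrapolating")

  # degenerate posterior: prediction is a point mass at the median curve
  pt <- fake_growth_fit(theta_s = 3, beta_s = 1.1)
  pr0 <- predict_age_carbon(pt, "spontaneous", 10)
  expect_equal(pr0$mean, 3 * 10^1.1)
  expect_equal(pr0$sd, 0)
  expect_equal(pr0$q2.5, pr0$q97.5)
})

test_that("fit_growth rejects inventories outside its domain", {
  f <- fixture_fields(4)
  X <- standardize_covariates(f)
  tr <- fixture_trees()
  tr$carbon <- 10
  expect_error(fit_growth(tr, X), "planted and spontaneous")
  tr2 <- tr[tr$cohort != "remnant", ]
  class(tr2) <- c("tree_inventory", "data.frame")
  tr2$age[1] <- NA
  expect_error(fit_growth(tr2, X), "age")
})
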