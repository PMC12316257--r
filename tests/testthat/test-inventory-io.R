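test_that("tree inventories parse, normalize cohort case and derive genus", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tree_id,plot_id,species,cohort,dbh_cm,height_m,age_yr,wood_density",
    "t1,p1,Milicia excelsa,Remnant,65,32,,",
    "t2,p1,Alstonia boonei,SPONTANEOUS,24,18,12,0.33",
    "t3,p2,Cola nitida,planted,15.5,11,6,"), path)
  trees <- read_tree_inventory(path)
  expect_s3_class(trees, "tree_inventory")
  expect_equal(nrow(trees), 3L)
  expect_equal(trees$cohort, c("remnant", "spontaneous", "planted"))
  expect_equal(trees$genus, c("Milicia", "Alstonia", "Cola"))
  expect_equal(trees$age, c(NA, 12, 6))
  expect_equal(trees$wood_density, c(NA, 0.33, NA))
})

test_that("sub-threshold diameters and bad numerics fail with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tree_id,plot_id,species,cohort,dbh_cm,height_m,age_yr,wood_density",
    "t1,p1,Milicia excelsa,remnant,9.5,30,,",
    "t2,p1,Cola nitida,planted,15,11,4,"), path)
  expect_error(read_tree_inventory(path),
               class = "shadecarbon_validation_error")
  expect_error(read_tree_inventory(path), "10 cm.*row.*1")

  writeLines(c(
    "tree_id,plot_id,species,cohort,dbh_cm,height_m,age_yr,wood_density",
    "t1,p1,Milicia excelsa,remnant,abc,30,,"), path)
  expect_error(read_tree_inventory(path), "dbh.*unparseable.*1")
})

test_that("missing required columns are named, and col_map adapts headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tree_id,plot_id,species,cohort,DBH,H_tot",
               "t1,p1,Milicia excelsa,remnant,65,32"), path)
  expect_error(read_tree_inventory(path), "dbh_cm")
  trees <- read_tree_inventory(path, col_map = c(dbh = "DBH",
                                                 height = "H_tot"))
  expect_equal(trees$dbh, 65)
})

test_that("field tables coerce binaries, reject duplicates and name gaps", {
  f <- fixture_fields()
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_table(f, path)
  back <- read_field_table(path)
  expect_equal(as.data.frame(back), as.data.frame(f), tolerance = 1e-12)

  raw <- read.csv(path, check.names = FALSE)
  raw$ownership <- ifelse(raw$ownership == 1, "Owner", "non-owner")
  write.csv(raw, path, row.names = FALSE)
  expect_equal(read_field_table(path)$ownership, f$ownership)

  raw2 <- raw
  raw2$plot_id[2] <- raw2$plot_id[1]
  write.csv(raw2, path, row.names = FALSE)
  expect_error(read_field_table(path), "duplicate plot_id")

  raw3 <- raw
  raw3$soc[3] <- NA
  write.csv(raw3, path, row.names = FALSE, na = "")
  expect_error(read_field_table(path), "soc.*p3|missing value")
})

test_that("raw knowledge scores convert to percent of the 46-point maximum", {
  expect_equal(knowledge_percent(46), 100)
  expect_equal(knowledge_percent(23), 50)
  expect_equal(knowledge_percent(0), 0)
  expect_error(knowledge_percent(50), class = "shadecarbon_validation_error")
  path <- withr::local_tempfile(fileext = ".csv")
  f <- fixture_fields(2)
  f$knowledge <- c(46, 23)
  write_field_table(f, path)
  back <- read_field_table(path, knowledge_max = 46)
  expect_equal(back$knowledge, c(100, 50))
})

test_that("inventory round-trips through write-then-read", {
  trees <- fixture_trees()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree_inventory(trees, path)
  back <- read_tree_inventory(path)
  expect_identical(back$tree_id, trees$tree_id)
  expect_identical(back$species, trees$species)
  expect_identical(back$cohort, trees$cohort)
  expect_equal(back$dbh, trees$dbh, tolerance = 1e-12)
  expect_equal(back$height, trees$height, tolerance = 1e-12)
  expect_equal(back$age, trees$age)
})

test_that("cross-validation flags orphans, remnant ages and ageless trees", {
  trees <- fixture_trees()
  trees$age[1] <- 12          # remnant carrying an age
  trees$age[5] <- NA          # spontaneous without age
  trees$plot_id[4] <- "p99"   # orphan plot
  fields <- fixture_fields(2)
  expect_warning(rep <- validate_inventory(trees, fields),
                 "remnant.*dropped")
  expect_false(rep$ok)
  expect_equal(rep$remnant_with_age, "t1")
  expect_true(is.na(rep$trees$age[1]))
  expect_equal(rep$growth_excluded, "t5")
  expect_equal(rep$unmatched_plots, "t4")
  expect_error(suppressWarnings(validate_inventory(trees, fields,
                                                   strict = TRUE)),
               class = "shadecarbon_validation_error")
})

test_that("ages above the 40-year recall horizon warn; above 60 fail", {
  df <- as.data.frame(fixture_trees())
  df$age[2] <- 45
  expect_warning(tree_inventory(df), "older than 40")
  df$age[2] <- 61
  expect_error(tree_inventory(df), "60")
})

test_that("standardization centres, scales by sample sd and is idempotent", {
  f <- fixture_fields(3)
  f$soc <- c(1, 2, 3)
  X <- standardize_covariates(f)
  expect_equal(unname(X$values[, "soc"]), c(-1, 0, 1))

  f4 <- fixture_fields(4)
  f4$ownership <- c(0, 0, 1, 1)
  X4 <- standardize_covariates(f4)
  expect_equal(unname(X4$values[, "ownership"]),
               c(-0.8660254, -0.8660254, 0.8660254, 0.8660254),
               tolerance = 1e-6)

  expect_true(all(abs(colMeans(X4$values)) < 1e-10))
  expect_equal(unname(apply(X4$values, 2, sd)), rep(1, 8))

  # idempotence: re-standardizing already standardized values changes
  # nothing, with centres ~0 and scales ~1
  X5v <- scale(X4$values)
  expect_equal(unname(X5v[, ]), unname(X4$values), tolerance = 1e-10)
  expect_true(all(abs(attr(X5v, "scaled:center")) < 1e-10))
  expect_equal(unname(attr(X5v, "scaled:scale")), rep(1, 8),
               tolerance = 1e-10)

  f4$temperature <- rep(25, 4)
  expect_error(standardize_covariates(f4), "temperature")
})

test_that("aggregation converts kg to Mg/ha and omits empty cells", {
  trees <- tree_inventory(data.frame(
    tree_id = c("a", "b", "c"), plot_id = c("p1", "p1", "p2"),
    species = "Milicia excelsa", cohort = c("remnant", "remnant",
                                            "spontaneous"),
    dbh = 30, height = 20, carbon = c(500, 250, 470)))
  fields <- fixture_fields(2)
  fields$area <- c(0.5, 1)
  st <- aggregate_stocks(trees, fields)
  expect_equal(st$carbon_stock[st$plot_id == "p1"], 1.5)   # 0.75 Mg / 0.5 ha
  expect_equal(st$carbon_stock[st$plot_id == "p2"], 0.47)  # 470 kg / 1 ha
  expect_false(any(st$cohort == "planted"))                # no planted trees
  expect_equal(nrow(st), 2L)

  # conservation: stocks * area * 1000 returns the plot's total kg
  back <- st$carbon_stock * fields$area[match(st$plot_id, fields$plot_id)] *
    1000
  expect_equal(sum(back), sum(trees$carbon), tolerance = 1e-10)
})

test_that("stock observations must be positive and unique per cell", {
  expect_error(stock_observations(data.frame(
    plot_id = "p1", cohort = "remnant", carbon_stock = 0)),
    "strictly positive")
  expect_error(stock_observations(data.frame(
    plot_id = c("p1", "p1"), cohort = "remnant",
    carbon_stock = c(1, 2))), "duplicate")
})

test_that("key-value configs parse sections, numbers and booleans", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# mapping", "trees.dbh = DBH", "strict = true",
               "knowledge_max = 46"), path)
  cfg <- read_config(path)
  expect_equal(cfg$trees$dbh, "DBH")
  expect_true(cfg$strict)
  expect_equal(cfg$knowledge_max, 46)
})
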