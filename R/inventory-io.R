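#' Read a tree inventory table
#'
#' Reads a comma-separated inventory (UTF-8, header row, `.` decimal mark)
#' with one row per tree and returns a validated `tree_inventory`. The
#' canonical columns are `tree_id, plot_id, species, cohort, dbh_cm,
#' height_m, age_yr, wood_density`; files with other headers are adapted
#' through `col_map` without touching the file.
#'
#' Cohort labels are case-normalized to `remnant`, `spontaneous`,
#' `planted`. The genus is derived as the first token of the species
#' binomial. Trees below the 10 cm dbh inventory threshold are a
#' validation failure: the field protocol only records trees from that
#' diameter up, so smaller rows indicate a data problem rather than a
#' small tree.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping canonical names
#'   (e.g. `dbh`) to the file's column names; see
#'   `shadecarbon:::TREE_COLUMN_DEFAULTS` for the defaults.
#' @return A data.frame of class `tree_inventory` with columns `tree_id`,
#'   `plot_id`, `species`, `genus`, `cohort`, `dbh` (cm), `height` (m),
#'   `age` (years, `NA` when unknown), `wood_density` (g/cm3, `NA` when
#'   not measured) and `carbon` (kg, `NA` until filled by allometry).
#' @seealso [read_field_table()], [validate_inventory()],
#'   [estimate_tree_carbon()]
#' @export
read_tree_inventory <- function(path, col_map = NULL) {
  raw <- read_csv_checked(path)
  cols <- resolve_columns(raw, TREE_COLUMN_DEFAULTS, col_map,
                          required = c("tree_id", "plot_id", "species",
                                       "cohort", "dbh", "height"),
                          what = "tree inventory")
  df <- data.frame(
    tree_id = as.character(raw[[cols["tree_id"]]]),
    plot_id = as.character(raw[[cols["plot_id"]]]),
    species = trimws(as.character(raw[[cols["species"]]])),
    cohort = tolower(trimws(as.character(raw[[cols["cohort"]]]))),
    dbh = parse_numeric(raw[[cols["dbh"]]], "dbh"),
    height = parse_numeric(raw[[cols["height"]]], "height"),
    stringsAsFactors = FALSE
  )
  df$age <- if (!is.na(cols["age"]))
    parse_numeric(raw[[cols["age"]]], "age", allow_na = TRUE) else NA_real_
  df$wood_density <- if (!is.na(cols["wood_density"]))
    parse_numeric(raw[[cols["wood_density"]]], "wood_density",
                  allow_na = TRUE) else NA_real_
  tree_inventory(df)
}

#' Construct a tree inventory from a data.frame
#'
#' Validates and classes an in-memory inventory; [read_tree_inventory()]
#' and the synthetic generator both end up here, so every `tree_inventory`
#' satisfies the same invariants: dbh >= 10 cm, positive heights, cohorts
#' in the three-level set, ages (where present) positive and at most 60
#' years, with a warning above 40 where farmer recall becomes unreliable.
#'
#' @param df data.frame with at least `tree_id`, `plot_id`, `species`,
#'   `cohort`, `dbh`, `height`; optional `age`, `wood_density`, `carbon`.
#' @return The classed and completed data.frame.
#' @export
tree_inventory <- function(df) {
  need <- c("tree_id", "plot_id", "species", "cohort", "dbh", "height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("tree inventory is missing column(s): ",
                     paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$cohort <- tolower(trimws(as.character(df$cohort)))
  bad_coh <- which(!df$cohort %in% COHORTS)
  if (length(bad_coh))
    abort_validation("unknown cohort label(s) in row(s) ",
                     paste(utils::head(bad_coh, 5), collapse = ", "),
                     ": ", paste(unique(df$cohort[bad_coh]), collapse = ", "))
  if (anyDuplicated(df$tree_id))
    abort_validation("duplicate tree_id: ",
                     paste(unique(df$tree_id[duplicated(df$tree_id)]),
                           collapse = ", "))
  bad_dbh <- which(is.na(df$dbh) | df$dbh < 10)
  if (length(bad_dbh))
    abort_validation("dbh below the 10 cm inventory threshold (or missing) ",
                     "in row(s): ", paste(bad_dbh, collapse = ", "),
                     data = list(rows = bad_dbh))
  bad_h <- which(is.na(df$height) | df$height <= 0)
  if (length(bad_h))
    abort_validation("non-positive or missing height in row(s): ",
                     paste(bad_h, collapse = ", "))
  if (is.null(df$age)) df$age <- NA_real_
  if (is.null(df$wood_density)) df$wood_density <- NA_real_
  if (is.null(df$carbon)) df$carbon <- NA_real_
  has_age <- !is.na(df$age)
  if (any(has_age & (df$age <= 0 | df$age != round(df$age))))
    abort_validation("ages must be positive integers; bad row(s): ",
                     paste(which(has_age &
                                 (df$age <= 0 | df$age != round(df$age))),
                           collapse = ", "))
  if (any(has_age & df$age > 60))
    abort_validation("age above 60 years in row(s): ",
                     paste(which(has_age & df$age > 60), collapse = ", "),
                     " - beyond the credible range for farmer-reported ages")
  n_old <- sum(has_age & df$age > 40)
  if (n_old)
    warning(sprintf(paste0("%d tree(s) older than 40 years; farmer-reported",
                           " ages this high are kept but uncertain"), n_old),
            call. = FALSE)
  if (is.null(df$genus) || all(is.na(df$genus)))
    df$genus <- vapply(strsplit(df$species, "\\s+"), `[`, "", 1L)
  df <- df[c("tree_id", "plot_id", "species", "genus", "cohort", "dbh",
             "height", "age", "wood_density", "carbon")]
  rownames(df) <- NULL
  class(df) <- c("tree_inventory", "data.frame")
  df
}

#' Read a plot-level field table
#'
#' One row per plot: identifiers, area (ha) and the eight
#' socio-environmental covariates of [covariate_groups()]. Binary
#' covariates accept `owner`/`non-owner`, `forest`/`non-forest`,
#' `yes`/`no`, `true`/`false` or 0/1 and are coerced to 0/1. Farmer tree
#' knowledge is stored as percent of the maximum recognition score; if the
#' file carries raw scores, pass `knowledge_max` (46 for the standard
#' 23-species test scored 0/1/2) to convert.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector, as in
#'   [read_tree_inventory()]; defaults in
#'   `shadecarbon:::FIELD_COLUMN_DEFAULTS`.
#' @param knowledge_max optional maximum raw knowledge score; when given,
#'   `knowledge` is converted to `score / knowledge_max * 100`.
#' @return A data.frame of class `field_table` with `plot_id`, `site_id`,
#'   `area` (ha) and the eight covariates under their canonical names.
#' @export
read_field_table <- function(path, col_map = NULL, knowledge_max = NULL) {
  raw <- read_csv_checked(path)
  cols <- resolve_columns(raw, FIELD_COLUMN_DEFAULTS, col_map,
                          required = names(FIELD_COLUMN_DEFAULTS),
                          what = "field table")
  df <- data.frame(plot_id = as.character(raw[[cols["plot_id"]]]),
                   site_id = as.character(raw[[cols["site_id"]]]),
                   area = parse_numeric(raw[[cols["area"]]], "area_ha"),
                   stringsAsFactors = FALSE)
  for (cv in covariate_names()) {
    x <- raw[[cols[cv]]]
    df[[cv]] <- if (cv %in% c("ownership", "prev_forest"))
      coerce_binary(x, cv) else parse_numeric(x, cv)
  }
  if (!is.null(knowledge_max))
    df$knowledge <- knowledge_percent(df$knowledge, knowledge_max)
  field_table(df)
}

#' @rdname read_field_table
#' @param df data.frame already holding the canonical columns.
#' @export
field_table <- function(df) {
  need <- c("plot_id", "site_id", "area", covariate_names())
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("field table is missing column(s): ",
                     paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  if (anyDuplicated(df$plot_id))
    abort_validation("duplicate plot_id: ",
                     paste(unique(df$plot_id[duplicated(df$plot_id)]),
                           collapse = ", "))
  for (cv in covariate_names()) {
    bad <- which(is.na(df[[cv]]))
    if (length(bad))
      abort_validation(sprintf("missing covariate `%s` for plot(s): %s", cv,
                               paste(df$plot_id[bad], collapse = ", ")))
  }
  if (any(is.na(df$area) | df$area <= 0 | df$area > 10))
    abort_validation("plot areas must lie in (0, 10] ha")
  if (any(df$knowledge < 0 | df$knowledge > 100))
    abort_validation("`knowledge` must be a percentage in [0, 100]")
  if (any(df$cocoa_density < 0) || any(df$bulk_density <= 0) ||
      any(df$soc <= 0) || any(df$precipitation <= 0))
    abort_validation("non-positive value in a strictly positive covariate")
  rownames(df) <- NULL
  class(df) <- c("field_table", "data.frame")
  df
}

#' Convert a raw recognition score to the knowledge percentage
#'
#' The farmer-knowledge covariate is an image-based recognition test of
#' the 23 most common agroforestry species, scored 0 (not recognized),
#' 1 (recognized) or 2 (recognized and named), hence a maximum of 46.
#'
#' @param score numeric raw score(s).
#' @param max_score maximum attainable score (default 46).
#' @return Percent of maximum, in `[0, 100]`.
#' @examples
#' knowledge_percent(46)  # 100
#' knowledge_percent(23)  # 50
#' @export
knowledge_percent <- function(score, max_score = 46) {
  if (any(score < 0 | score > max_score, na.rm = TRUE))
    abort_validation("raw knowledge scores must lie in [0, max_score]")
  score / max_score * 100
}

#' Cross-validate a tree inventory against its field table
#'
#' Report-only consistency checks at the study level: trees whose plot has
#' no field record, remnant trees carrying an age (the age of a remnant
#' tree is unknowable, so it is dropped with a warning), planted or
#' spontaneous trees without an age (kept for stocks, excluded from growth
#' modelling), and non-positive sizes (unreachable through the
#' constructors, but checked again for inventories assembled by hand).
#'
#' @param trees a `tree_inventory`.
#' @param fields a `field_table`.
#' @param strict if `TRUE`, any finding escalates to a validation error.
#' @return A list of class `inventory_validation`: `trees` (the inventory
#'   with remnant ages dropped), `unmatched_plots`, `remnant_with_age`,
#'   `growth_excluded`, `nonpositive_size` (tree_id vectors) and `ok`.
#' @export
validate_inventory <- function(trees, fields, strict = FALSE) {
  unmatched <- trees$tree_id[!trees$plot_id %in% fields$plot_id]
  remnant_age <- trees$tree_id[trees$cohort == "remnant" & !is.na(trees$age)]
  growth_excl <- trees$tree_id[trees$cohort %in% GROWTH_COHORTS &
                                 is.na(trees$age)]
  nonpos <- trees$tree_id[trees$dbh <= 0 | trees$height <= 0]
  if (length(remnant_age)) {
    warning(sprintf(paste0("%d remnant tree(s) carried an age; remnant ages",
                           " are unknowable and were dropped"),
                    length(remnant_age)), call. = FALSE)
    trees$age[trees$tree_id %in% remnant_age] <- NA_real_
  }
  rep <- structure(
    list(trees = trees, unmatched_plots = unmatched,
         remnant_with_age = remnant_age, growth_excluded = growth_excl,
         nonpositive_size = nonpos,
         ok = !length(unmatched) && !length(remnant_age) &&
           !length(growth_excl) && !length(nonpos)),
    class = "inventory_validation"
  )
  if (strict && !rep$ok)
    abort_validation("inventory validation failed in strict mode; findings: ",
                     paste(c(
                       if (length(unmatched)) "unmatched plots",
                       if (length(remnant_age)) "remnant ages",
                       if (length(growth_excl)) "ageless growth-cohort trees",
                       if (length(nonpos)) "non-positive sizes"),
                       collapse = ", "),
                     data = rep)
  rep
}

#' @export
print.inventory_validation <- function(x, ...) {
  cat("Inventory validation:", if (x$ok) "clean\n" else "findings\n")
  cat("  trees with no matching field record:", length(x$unmatched_plots), "\n")
  cat("  remnant trees with (dropped) age:   ", length(x$remnant_with_age), "\n")
  cat("  growth-model exclusions (no age):   ", length(x$growth_excluded), "\n")
  cat("  non-positive sizes:                 ", length(x$nonpositive_size), "\n")
  invisible(x)
}

#' Standardize the plot covariates
#'
#' Centres each of the eight covariates and scales it by its sample
#' (n - 1) standard deviation, so effects estimated on the result are
#' directly comparable across covariates. Binary covariates are
#' standardized like continuous ones. The centres and scales are retained
#' so new plots can be projected onto the same scale and effects mapped
#' back to natural units.
#'
#' @param fields a `field_table` with at least 2 plots.
#' @return A list of class `covariate_matrix`: `plot_id`, `values` (plots
#'   x 8 matrix, rownames = plot_id), `centers`, `scales`.
#' @export
standardize_covariates <- function(fields) {
  if (nrow(fields) < 2)
    abort_validation("need at least 2 plots to standardize covariates")
  raw <- as.matrix(fields[covariate_names()])
  centers <- colMeans(raw)
  scales <- apply(raw, 2, sd)
  flat <- names(scales)[scales == 0]
  if (length(flat))
    abort_validation("covariate(s) with zero variance cannot be ",
                     "standardized: ", paste(flat, collapse = ", "))
  values <- sweep(sweep(raw, 2, centers), 2, scales, `/`)
  rownames(values) <- fields$plot_id
  structure(list(plot_id = fields$plot_id, values = values,
                 centers = centers, scales = scales),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat("Standardized covariate matrix:", nrow(x$values), "plots x",
      ncol(x$values), "covariates\n")
  print(round(rbind(center = x$centers, scale = x$scales), 3))
  invisible(x)
}

#' Aggregate tree carbon to per-hectare plot stocks by cohort
#'
#' Sums per-tree carbon (kg) within each (plot, cohort) cell, converts to
#' Mg and divides by the plot area, giving the carbon stock in Mg/ha.
#' Cells with no trees are omitted, not emitted as zeros: the stock model
#' is lognormal with strictly positive support, so absence of a cohort is
#' a presence/absence fact, not a zero observation.
#'
#' @param trees a `tree_inventory` whose `carbon` column is filled (kg),
#'   e.g. via [add_tree_carbon()].
#' @param fields the matching `field_table` (areas in ha).
#' @return A data.frame of class `stock_obs` with `plot_id`, `cohort`,
#'   `carbon_stock` (Mg/ha).
#' @export
aggregate_stocks <- function(trees, fields) {
  if (any(is.na(trees$carbon)))
    abort_validation("all trees must have carbon filled before aggregation; ",
                     sum(is.na(trees$carbon)), " missing")
  if (any(fields$area <= 0)) abort_validation("plot areas must be positive")
  miss <- setdiff(unique(trees$plot_id), fields$plot_id)
  if (length(miss))
    abort_validation("trees reference plot(s) with no field record: ",
                     paste(miss, collapse = ", "))
  agg <- aggregate(carbon ~ plot_id + cohort, data = trees, FUN = sum)
  area <- setNames(fields$area, fields$plot_id)
  agg$carbon_stock <- agg$carbon / 1000 / area[agg$plot_id]
  agg <- agg[order(agg$plot_id, match(agg$cohort, COHORTS)),
             c("plot_id", "cohort", "carbon_stock")]
  stock_observations(agg)
}

#' @rdname aggregate_stocks
#' @param df data.frame with `plot_id`, `cohort`, `carbon_stock` already
#'   computed (e.g. simulated); validated and classed.
#' @export
stock_observations <- function(df) {
  need <- c("plot_id", "cohort", "carbon_stock")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("stock observations missing column(s): ",
                     paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  df$cohort <- tolower(as.character(df$cohort))
  if (any(!df$cohort %in% COHORTS))
    abort_validation("unknown cohort in stock observations")
  if (any(!is.finite(df$carbon_stock) | df$carbon_stock <= 0))
    abort_validation("carbon stocks must be strictly positive ",
                     "(empty cells are omitted, not zero)")
  if (anyDuplicated(df[c("plot_id", "cohort")]))
    abort_validation("duplicate (plot_id, cohort) stock observation")
  rownames(df) <- NULL
  class(df) <- c("stock_obs", "data.frame")
  df
}

#' Write inventory objects back to their CSV schemas
#'
#' Inverses of the readers: `write_tree_inventory()` emits the canonical
#' `trees.csv` columns, `write_field_table()` the `fields.csv` columns and
#' `write_stock_table()` a `stocks.csv` with `plot_id, cohort,
#' carbon_mg_ha`. Round-tripping through write-then-read reproduces the
#' object.
#'
#' @param x the object to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_inventory <- function(x, path) {
  out <- data.frame(tree_id = x$tree_id, plot_id = x$plot_id,
                    species = x$species, cohort = x$cohort, dbh_cm = x$dbh,
                    height_m = x$height, age_yr = x$age,
                    wood_density = x$wood_density)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tree_inventory
#' @export
write_field_table <- function(x, path) {
  out <- x
  class(out) <- "data.frame"
  names(out) <- names(FIELD_COLUMN_DEFAULTS)[
    match(names(out), names(FIELD_COLUMN_DEFAULTS))]
  names(out) <- FIELD_COLUMN_DEFAULTS[names(out)]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tree_inventory
#' @export
write_stock_table <- function(x, path) {
  write.csv(data.frame(plot_id = x$plot_id, cohort = x$cohort,
                       carbon_mg_ha = x$carbon_stock),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_inventory
#' @export
read_stock_table <- function(path) {
  raw <- read_csv_checked(path)
  need <- c("plot_id", "cohort", "carbon_mg_ha")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_validation("stocks file is missing column(s): ",
                     paste(miss, collapse = ", "))
  stock_observations(data.frame(plot_id = as.character(raw$plot_id),
                                cohort = raw$cohort,
                                carbon_stock = parse_numeric(raw$carbon_mg_ha,
                                                             "carbon_mg_ha")))
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Dotted keys
#' (`trees.dbh = DBH`) become nested sections, which is how column
#' mappings for foreign CSV headers and validation strictness are supplied
#' to the command-line interface.
#'
#' @param path config file path.
#' @return A named list; dotted keys grouped into sub-lists.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      abort_validation("config line is not `key = value`: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (tolower(val) %in% c("true", "false"))
      val <- tolower(val) == "true"
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) out[[parts[1]]][[parts[2]]] <- val
    else out[[key]] <- val
  }
  out
}

# ---- internal CSV helpers ---------------------------------------------

read_csv_checked <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
           fileEncoding = "UTF-8")
}

resolve_columns <- function(raw, defaults, col_map, required, what) {
  cols <- defaults
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), names(defaults))
    if (length(unknown))
      abort_validation("unknown canonical column(s) in col_map: ",
                       paste(unknown, collapse = ", "))
    cols[names(col_map)] <- unlist(col_map)
  }
  present <- cols %in% names(raw)
  miss <- intersect(names(cols)[!present], required)
  if (length(miss))
    abort_validation(sprintf("%s is missing required column(s): %s", what,
                             paste(cols[miss], collapse = ", ")))
  ifelse(present, cols, NA_character_) |> setNames(names(cols))
}

parse_numeric <- function(x, name, allow_na = FALSE) {
  chr <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(out) & nzchar(chr) & !is.na(x))
  if (length(bad))
    abort_validation(sprintf(
      "column `%s`: unparseable numeric value(s) at data row(s) %s", name,
      paste(utils::head(bad, 5), collapse = ", ")))
  if (!allow_na && any(is.na(out)))
    abort_validation(sprintf("column `%s`: missing value(s) at data row(s) %s",
                             name,
                             paste(utils::head(which(is.na(out)), 5),
                                   collapse = ", ")))
  out
}

coerce_binary <- function(x, name) {
  chr <- tolower(trimws(as.character(x)))
  ones <- c("1", "owner", "forest", "yes", "true")
  zeros <- c("0", "non-owner", "nonowner", "not owner", "non-forest",
             "nonforest", "not forest", "no", "false")
  out <- ifelse(chr %in% ones, 1, ifelse(chr %in% zeros, 0, NA_real_))
  bad <- which(is.na(out) & nzchar(chr))
  if (length(bad))
    abort_validation(sprintf(
      "column `%s`: values not interpretable as binary at row(s) %s", name,
      paste(utils::head(bad, 5), collapse = ", ")))
  out
}
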