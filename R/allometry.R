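#' Aboveground biomass from the pantropical allometric power law
#'
#' `AGB = 0.0673 * (rho * D^2 * H)^0.976`, with wood density `rho` in
#' g/cm3, diameter at breast height `D` in cm and total height `H` in m,
#' returning dry biomass in kg. This is the height-inclusive pantropical
#' model for destructive-harvest calibration data across the tropics; it
#' is the standard allometry when tree heights have been measured, as
#' they are in a dendrometer-based inventory.
#'
#' @param dbh diameter at breast height, cm (> 0); vectorized.
#' @param height total height, m (> 0).
#' @param density wood density, g/cm3 (> 0).
#' @return Aboveground biomass in kg, same length as the inputs.
#' @examples
#' compute_agb(dbh = 30, height = 25, density = 0.55)  # ~664 kg
#' @export
compute_agb <- function(dbh, height, density) {
  if (any(!is.finite(dbh) | dbh <= 0))
    abort_validation("`dbh` must be positive and finite")
  if (any(!is.finite(height) | height <= 0))
    abort_validation("`height` must be positive and finite")
  if (any(!is.finite(density) | density <= 0))
    abort_validation("`density` must be positive and finite")
  0.0673 * (density * dbh^2 * height)^0.976
}

#' Convert aboveground biomass to carbon
#'
#' Applies the 0.47 carbon fraction of dry biomass recommended for
#' tropical angiosperms.
#'
#' @param agb aboveground biomass, kg (>= 0).
#' @return Carbon mass in kg, exactly `0.47 * agb`.
#' @export
agb_to_carbon <- function(agb) {
  if (any(!is.finite(agb) | agb < 0))
    abort_validation("`agb` must be non-negative and finite")
  0.47 * agb
}

#' Build a wood-density reference table
#'
#' Holds oven-dry-over-green wood densities keyed by taxon at species and
#' genus level, plus a dataset-mean fallback so no tree is ever dropped
#' for lack of a density. Lookups resolve species first, then the mean of
#' the genus entries, then the fallback.
#'
#' @param df data.frame with columns `taxon`, `level` (`species` or
#'   `genus`) and `density_g_cm3`.
#' @param fallback_default density used when neither species nor genus
#'   matches; defaults to the mean of all entries.
#' @return A list of class `wood_density_table`.
#' @export
wood_density_table <- function(df, fallback_default = NULL) {
  need <- c("taxon", "level", "density_g_cm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("wood-density table missing column(s): ",
                     paste(miss, collapse = ", "))
  df$level <- tolower(df$level)
  if (any(!df$level %in% c("species", "genus")))
    abort_validation("wood-density `level` must be `species` or `genus`")
  d <- df$density_g_cm3
  if (any(!is.finite(d) | d <= 0.05 | d >= 1.5))
    abort_validation("wood densities must lie in (0.05, 1.5) g/cm3")
  sp <- df[df$level == "species", ]
  tokens <- lengths(strsplit(trimws(sp$taxon), "\\s+"))
  if (any(tokens != 2))
    abort_validation("species-level taxa must be two-token binomials: ",
                     paste(sp$taxon[tokens != 2], collapse = ", "))
  gn <- df[df$level == "genus", ]
  if (any(lengths(strsplit(trimws(gn$taxon), "\\s+")) != 1))
    abort_validation("genus-level taxa must be single tokens")
  if (is.null(fallback_default)) fallback_default <- mean(d)
  check_number(fallback_default, "fallback_default", lower = 0.05,
               upper = 1.5, strict_lower = TRUE)
  # genus tier also aggregates the species entries of each genus
  sp_genus <- vapply(strsplit(sp$taxon, "\\s+"), `[`, "", 1L)
  genus_pool <- rbind(data.frame(genus = gn$taxon, density = gn$density_g_cm3),
                      data.frame(genus = sp_genus, density = sp$density_g_cm3))
  genus_mean <- tapply(genus_pool$density, genus_pool$genus, mean)
  structure(
    list(species = setNames(sp$density_g_cm3, sp$taxon),
         genus = setNames(as.numeric(genus_mean), names(genus_mean)),
         fallback_default = fallback_default),
    class = "wood_density_table"
  )
}

#' @rdname wood_density_table
#' @param path CSV with columns `taxon, level, density_g_cm3`.
#' @export
read_wood_density <- function(path, fallback_default = NULL) {
  raw <- read_csv_checked(path)
  wood_density_table(raw, fallback_default = fallback_default)
}

#' @export
print.wood_density_table <- function(x, ...) {
  cat("Wood-density table:", length(x$species), "species,",
      length(x$genus), "genera; fallback", round(x$fallback_default, 3),
      "g/cm3\n")
  invisible(x)
}

#' Resolve a wood density by species, then genus, then fallback
#'
#' @param species character vector of binomials.
#' @param genus character vector of genera (derived from the species name
#'   when missing).
#' @param table a [wood_density_table()].
#' @return data.frame with `density` (g/cm3) and `match_level`
#'   (`species`, `genus` or `default`) per input taxon.
#' @export
lookup_wood_density <- function(species, genus = NULL, table) {
  if (!inherits(table, "wood_density_table"))
    abort_validation("`table` must be a wood_density_table")
  if (is.null(genus))
    genus <- vapply(strsplit(as.character(species), "\\s+"), `[`, "", 1L)
  density <- unname(table$species[species])
  level <- ifelse(is.na(density), NA_character_, "species")
  g <- is.na(density)
  density[g] <- unname(table$genus[genus[g]])
  level[g & !is.na(density)] <- "genus"
  d <- is.na(density)
  density[d] <- table$fallback_default
  level[d] <- "default"
  data.frame(density = density, match_level = level,
             stringsAsFactors = FALSE)
}

#' Estimate carbon for every tree of an inventory
#'
#' Resolves a wood density for each tree (a per-record `wood_density`
#' measurement overrides the reference table, recorded as match level
#' `record`), evaluates the allometric power law and applies the 0.47
#' carbon fraction. Purely deterministic given its inputs.
#'
#' @param trees a `tree_inventory`.
#' @param table a [wood_density_table()].
#' @return data.frame of class `carbon_estimates`: `tree_id`, `agb` (kg),
#'   `carbon` (kg), `density_used` (g/cm3), `match_level`, in input order.
#' @export
estimate_tree_carbon <- function(trees, table) {
  looked <- lookup_wood_density(trees$species, trees$genus, table)
  has_rec <- !is.na(trees$wood_density)
  looked$density[has_rec] <- trees$wood_density[has_rec]
  looked$match_level[has_rec] <- "record"
  n_def <- sum(looked$match_level == "default")
  if (n_def)
    warning(sprintf(paste0("%d tree(s) matched neither species nor genus;",
                           " dataset-mean wood density used"), n_def),
            call. = FALSE)
  agb <- tryCatch(
    compute_agb(trees$dbh, trees$height, looked$density),
    shadecarbon_validation_error = function(e)
      abort_validation("allometry failed: ", conditionMessage(e)))
  out <- data.frame(tree_id = trees$tree_id, agb = agb,
                    carbon = agb_to_carbon(agb),
                    density_used = looked$density,
                    match_level = looked$match_level,
                    stringsAsFactors = FALSE)
  class(out) <- c("carbon_estimates", "data.frame")
  out
}

#' @rdname estimate_tree_carbon
#' @param estimates result of `estimate_tree_carbon()`; merged back into
#'   the inventory's `carbon` column (kg) by `tree_id`.
#' @export
add_tree_carbon <- function(trees, estimates) {
  idx <- match(trees$tree_id, estimates$tree_id)
  if (any(is.na(idx)))
    abort_validation("estimates missing for tree(s): ",
                     paste(utils::head(trees$tree_id[is.na(idx)], 5),
                           collapse = ", "))
  trees$carbon <- estimates$carbon[idx]
  trees
}
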