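#' The eight socio-environmental covariates
#'
#' Every plot carries eight covariates describing the farmer, the field,
#' the soil and the climate. They enter both models as standardized
#' (centred, unit-variance) effects through an exponential link, so their
#' coefficients are directly comparable.
#'
#' @return `covariate_names()` returns the eight canonical column names in
#'   fixed order; `covariate_groups()` returns a data.frame with columns
#'   `covariate`, `group` (Social / Field / Soil / Climate), `label` and
#'   `unit`.
#' @examples
#' covariate_names()
#' covariate_groups()
#' @export
covariate_names <- function() COVARIATE_META$covariate

#' @rdname covariate_names
#' @export
covariate_groups <- function() COVARIATE_META

COVARIATE_META <- data.frame(
  covariate = c("ownership", "knowledge", "prev_forest", "cocoa_density",
                "bulk_density", "soc", "temperature", "precipitation"),
  group = c("Social", "Social", "Field", "Field",
            "Soil", "Soil", "Climate", "Climate"),
  label = c("Farmer ownership", "Farmer's tree knowledge",
            "Previous land use (forest)", "Cocoa tree density",
            "Soil bulk density (30-60 cm)", "Soil organic carbon",
            "Mean annual temperature", "Annual precipitation"),
  unit = c("binary (owner = 1)", "% of maximum score",
           "binary (forest = 1)", "ind/ha", "kg/dm3", "g/kg",
           "deg C", "mm"),
  stringsAsFactors = FALSE
)

# default fields.csv header -> canonical covariate name
FIELD_COLUMN_DEFAULTS <- c(
  plot_id = "plot_id", site_id = "site_id", area = "area_ha",
  ownership = "ownership", knowledge = "knowledge_pct",
  prev_forest = "prev_forest", cocoa_density = "cocoa_density",
  bulk_density = "bulk_density", soc = "soc",
  temperature = "temperature_c", precipitation = "precipitation_mm"
)

TREE_COLUMN_DEFAULTS <- c(
  tree_id = "tree_id", plot_id = "plot_id", species = "species",
  cohort = "cohort", dbh = "dbh_cm", height = "height_m",
  age = "age_yr", wood_density = "wood_density"
)
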