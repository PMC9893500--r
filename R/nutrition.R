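#' Metabolizable energy of a diet from its TDN content
#'
#' Converts total digestible nutrients (TDN, % of dry matter) to dietary
#' metabolizable energy (ME, MJ per kg DM) through digestible energy:
#' ME = (TDN/100) x `mcal_per_kg_tdn` Mcal DE/kg x 4.184 MJ/Mcal x
#' `me_de_ratio`. The default DE density of TDN is 4.409 Mcal/kg and the
#' default ME:DE ratio 0.82, the values used in beef NRC energy systems.
#'
#' @param tdn_pct TDN content, percent of DM, in (0, 100].
#' @param mcal_per_kg_tdn Digestible energy per kg of TDN, Mcal/kg.
#' @param me_de_ratio Fraction of DE captured as ME.
#' @param digits Decimal places for the returned value; `NULL` for no rounding.
#' @return ME in MJ per kg DM.
#' @examples
#' me_from_tdn(57.27) # 8.66
#' me_from_tdn(59.38) # 8.98
#' @export
me_from_tdn <- function(tdn_pct, mcal_per_kg_tdn = 4.409, me_de_ratio = 0.82,
                        digits = 2) {
  if (!is.numeric(tdn_pct) || any(!is.finite(tdn_pct))) {
    stop("`tdn_pct` must be finite numeric")
  }
  if (any(tdn_pct <= 0 | tdn_pct > 100)) {
    stop("`tdn_pct` must lie in (0, 100]")
  }
  me <- (tdn_pct / 100) * mcal_per_kg_tdn * 4.184 * me_de_ratio
  if (!is.null(digits)) me <- round(me, digits)
  me
}

#' Non-fiber (non-structural) carbohydrate content of a diet
#'
#' NFC, % = 100 - (CP + fat + ash + NDF + NDICP), all in percent of DM,
#' where NDICP is the neutral-detergent-insoluble crude protein counted in
#' both CP and NDF. Negative results are returned as-is with a warning
#' (they indicate inconsistent assay inputs, not a computation error).
#'
#' @param cp,fat,ash,ndf,ndicp Component contents, percent of DM, each in
#'   \[0, 100\].
#' @return NFC, percent of DM.
#' @examples
#' nfc(cp = 11.35, fat = 1.27, ash = 6.67, ndf = 60.83, ndicp = 3.56)
#' @export
nfc <- function(cp, fat, ash, ndf, ndicp) {
  comps <- cbind(cp, fat, ash, ndf, ndicp)
  if (any(!is.finite(comps)) || any(comps < 0 | comps > 100)) {
    stop("all components must lie in [0, 100]")
  }
  out <- 100 - (cp + fat + ash + ndf + ndicp)
  if (any(out < 0)) {
    warning("negative NFC: component percentages sum to more than 100")
  }
  out
}

#' Temperature-humidity index from dry-bulb temperature and relative humidity
#'
#' THI = (1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26), the NRC-style
#' dry-bulb/relative-humidity index widely used for livestock heat and cold
#' load. At T = 14.44 C (where 1.8 T = 26) the humidity term vanishes and
#' THI equals the Fahrenheit dry-bulb; the same happens at RH = 100.
#'
#' @param dry_bulb_c Dry-bulb air temperature, degrees C.
#' @param rh_pct Relative humidity, percent, in \[0, 100\].
#' @return THI (dimensionless index).
#' @examples
#' thi(30, 50) # 78.3
#' @export
thi <- function(dry_bulb_c, rh_pct) {
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0 | rh_pct > 100)) {
    stop("`rh_pct` must lie in [0, 100]")
  }
  tf <- 1.8 * dry_bulb_c + 32
  tf - (0.55 - 0.0055 * rh_pct) * (1.8 * dry_bulb_c - 26)
}

#' Read a diet composition table
#'
#' Reads a CSV with one row per nutrient item and one column per regime
#' (as shipped in `inst/extdata/diet_composition.csv`, which mirrors the
#' nutrient panel of a two-regime backgrounding trial). Values are means;
#' a `_sd` suffix column may carry dispersions.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `item`, one column per regime.
#' @export
read_diet_table <- function(path) {
  if (!file.exists(path)) stop("diet table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"item" %in% names(tab)) stop("diet table must have an `item` column")
  tab
}

#' Look up one nutrient value from a diet table
#'
#' @param diet Data.frame from [read_diet_table()].
#' @param item Item name (exact match on the `item` column).
#' @param regime Column name of the regime to read.
#' @return Numeric scalar.
#' @export
diet_value <- function(diet, item, regime) {
  i <- match(item, diet$item)
  if (is.na(i)) stop("item not found in diet table: ", item)
  if (!regime %in% names(diet)) stop("regime column not found: ", regime)
  as.numeric(diet[[regime]][i])
}
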