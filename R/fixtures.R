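#' Load a packaged study table
#'
#' Three study tables ship with the package as plain CSV and are used both as
#' inputs (the material-input inventory and herd performance statistics that
#' parameterise the synthetic generators) and as arithmetic references (the
#' per-source emissions-intensity breakdown):
#' \describe{
#'   \item{`table1_inventory`}{material inputs per farmlet (fertiliser N/P/K,
#'     lime, farmyard manure, pesticides, seeds, diesel, soybean, straw,
#'     transport tonne-km) plus mean pasture and silage quality (DE %, CP %).}
#'   \item{`table2_performance`}{herd performance per farmlet: entry and
#'     finishing weight, total growth, days on the platform and average daily
#'     gain, as mean (SD).}
#'   \item{`table3_contributions`}{per-source emissions intensity
#'     (kg CO2-eq/kg LWG) per farmlet as mean with min–max range across the
#'     30 animals; 14 source rows plus a total.}
#' }
#'
#' @param name one of `"table1_inventory"`, `"table2_performance"`,
#'   `"table3_contributions"`.
#' @return A data.frame mirroring the packaged CSV cell-for-cell.
#' @export
#' @examples
#' t3 <- load_fixture("table3_contributions")
#' t3[t3$source == "Enteric fermentation (CH4)", "pp_mean"]  # 7.09
load_fixture <- function(name) {
  valid <- c("table1_inventory", "table2_performance", "table3_contributions")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown fixture name; expected one of: ",
         paste(valid, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "herdlca",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = NA)
}

#' Per-source summary of the packaged breakdown table
#'
#' Convenience accessor over [load_fixture()]`("table3_contributions")`:
#' returns the mean and (min, max) range of one source row for one system.
#'
#' @param system `"PP"`, `"WC"` or `"HS"`.
#' @param source a row label of the breakdown table, e.g.
#'   `"Enteric fermentation (CH4)"` or `"Total"`.
#' @return A list with elements `mean`, `min`, `max` (NA for sources absent
#'   from a system, e.g. crop residues on permanent pasture).
#' @export
fixture_contribution <- function(system, source) {
  system <- match.arg(system, c("PP", "WC", "HS"))
  t3 <- load_fixture("table3_contributions")
  row <- t3[t3$source == source, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown breakdown source: ", source)
  pre <- tolower(system)
  list(mean = row[[paste0(pre, "_mean")]],
       min = row[[paste0(pre, "_min")]],
       max = row[[paste0(pre, "_max")]])
}

#' Build a farmlet input inventory from the packaged inventory table
#'
#' Maps the inventory fixture's rows for one farmlet into a
#' [farmlet_inventory()] object.  Pasture/silage quality rows are attached as
#' attributes for use by the representative-animal and demo configurations.
#'
#' @param farmlet `"PP"`, `"WC"` or `"HS"`.
#' @param table1 optionally a pre-loaded `table1_inventory` data.frame.
#' @param ... passed on to [farmlet_inventory()] (e.g. `sheep_excreta_n_kg`).
#' @return A `farmlet_inventory` object.
#' @export
inventory_from_table1 <- function(farmlet, table1 = NULL, ...) {
  farmlet <- match.arg(farmlet, c("PP", "WC", "HS"))
  if (is.null(table1)) table1 <- load_fixture("table1_inventory")
  val <- function(key) {
    v <- table1[table1$variable == key, farmlet]
    if (length(v) != 1L) stop("inventory fixture is missing row: ", key)
    as.numeric(v)
  }
  qty_keys <- c("fertiliser_n", "fertiliser_p", "fertiliser_k", "lime",
                "fym", "glyphosate", "fluroxypyr", "seed_grass",
                "seed_clover", "diesel", "soybean", "straw",
                "tkm_soybean_sea", "tkm_soybean_road", "tkm_straw_road",
                "tkm_fertiliser_road")
  quantities <- vapply(qty_keys, val, numeric(1))
  inv <- farmlet_inventory(
    farmlet_id = farmlet,
    area_ha = val("area"),
    quantities = quantities,
    reseeded = farmlet %in% c("WC", "HS"),
    ...
  )
  attr(inv, "pasture_quality") <- c(de = val("pasture_de"),
                                    cp = val("pasture_cp"))
  attr(inv, "silage_quality") <- c(de = val("silage_de"),
                                   cp = val("silage_cp"))
  inv
}
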