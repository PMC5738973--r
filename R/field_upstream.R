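#' Construct a farmlet input inventory
#'
#' Annual material inputs to one farmlet, keyed exactly as the packaged
#' inventory table.  Streams not simulated mechanistically enter as
#' configured quantities: sheep excreta N deposited while the flock grazes
#' the same platform, and crop-residue N returned on reseeded systems.
#'
#' @param farmlet_id label.
#' @param area_ha farmlet area.
#' @param quantities named non-negative numeric vector; allowed keys:
#'   `fertiliser_n`, `fertiliser_p`, `fertiliser_k` (kg), `lime` (kg),
#'   `fym` (t), `glyphosate`, `fluroxypyr`, `seed_grass`, `seed_clover`,
#'   `soybean`, `straw` (kg), `diesel` (l), `tkm_soybean_sea`,
#'   `tkm_soybean_road`, `tkm_straw_road`, `tkm_fertiliser_road` (tkm).
#' @param reseeded whether the farmlet's swards were renewed (drives
#'   crop-residue N2O and reseeding operations; the permanent pasture is
#'   never reseeded).
#' @param sheep_excreta_n_kg kg N per year deposited by the sheep flock
#'   (default sized for a lowland flock of ~75 ewes at ~18 kg N/head/yr).
#' @param crop_residue_n_kg kg N per year in residues of reseeded swards
#'   (zero for unreseeded systems; default is an annualised ploughed-in
#'   sward residue over a ~21 ha farmlet).
#' @return An object of class `farmlet_inventory`.
#' @export
farmlet_inventory <- function(farmlet_id, area_ha, quantities,
                              reseeded = FALSE,
                              sheep_excreta_n_kg = 1350,
                              crop_residue_n_kg = if (reseeded) 700 else 0) {
  allowed <- c("fertiliser_n", "fertiliser_p", "fertiliser_k", "lime",
               "fym", "glyphosate", "fluroxypyr", "seed_grass",
               "seed_clover", "diesel", "soybean", "straw",
               "tkm_soybean_sea", "tkm_soybean_road", "tkm_straw_road",
               "tkm_fertiliser_road")
  bad <- setdiff(names(quantities), allowed)
  if (length(bad))
    stop("inventory keys outside the registry: ", paste(bad, collapse = ", "))
  if (any(quantities < 0) || sheep_excreta_n_kg < 0 || crop_residue_n_kg < 0)
    stop("inventory quantities must be non-negative")
  if (area_ha <= 0) stop("area_ha must be positive")
  q <- stats::setNames(numeric(length(allowed)), allowed)
  q[names(quantities)] <- quantities
  structure(list(farmlet_id = farmlet_id, area_ha = area_ha,
                 quantities = q, reseeded = reseeded,
                 sheep_excreta_n_kg = sheep_excreta_n_kg,
                 crop_residue_n_kg = crop_residue_n_kg),
            class = "farmlet_inventory")
}

#' Soil nitrous oxide and lime carbon dioxide from field inputs
#'
#' Direct N2O from each nitrogen stream applied to or deposited on the
#' farmlet's soils — inorganic fertiliser N and field-applied farmyard
#' manure N (EF1), crop-residue N on reseeded systems (EF1), and sheep
#' excreta (pasture EF3 for sheep) — plus indirect N2O from the leached
#' fraction of all those streams (FracLeach x EF5).  N2O-N is converted to
#' N2O by 44/28.  Unreseeded systems emit no crop-residue record at all.
#' Lime CO2 is released by carbonate stoichiometry (0.12 kg C per kg lime)
#' and pooled under `"Others"`.
#'
#' @param inv a [farmlet_inventory()].
#' @param params a [tier2_params()] set.
#' @return A farmlet-pool emission ledger.
#' @export
soil_n2o <- function(inv, params = default_params()) {
  q <- inv$quantities
  conv <- 44 / 28
  fym_n <- q[["fym"]] * params$fym_n_per_t
  streams <- c(
    "Fertiliser application (N2O)" = q[["fertiliser_n"]],
    "Farmyard manure application (N2O)" = fym_n,
    "Crop residues (N2O)" = inv$crop_residue_n_kg,
    "Urine and dung from ewes on pasture (N2O)" = inv$sheep_excreta_n_kg
  )
  ef <- c(params$ef1_fertiliser, params$ef1_fertiliser,
          params$ef1_fertiliser, params$ef3_prp_sheep)
  keep <- streams > 0 | names(streams) != "Crop residues (N2O)"
  if (!inv$reseeded) keep[3] <- FALSE  # no residue record: unaltered sward
  direct <- emission_record(
    scope = "farmlet_pool", owner_id = inv$farmlet_id,
    source = names(streams)[keep], gas = "N2O",
    mass_kg = (streams * ef * conv)[keep]
  )
  n_total <- sum(streams[keep])
  leach <- emission_record(
    scope = "farmlet_pool", owner_id = inv$farmlet_id,
    source = "Indirect emissions from leaching (N2O)", gas = "N2O",
    mass_kg = n_total * params$frac_leach * params$ef5_leaching * conv
  )
  lime <- if (q[["lime"]] > 0) {
    emission_record(scope = "farmlet_pool", owner_id = inv$farmlet_id,
                    source = "Others", gas = "CO2",
                    mass_kg = q[["lime"]] * 0.12 * 44 / 12)
  }
  rbind_ledgers(direct, leach, lime)
}

#' Default upstream emission-factor table
#'
#' Cradle-to-farm-gate burdens of purchased inputs, kg CO2-eq per inventory
#' unit, plus transport factors per tonne-km.  Proprietary database values
#' cannot be redistributed, so every entry here is an assumed, editable
#' placeholder in the usual range for the input class; swap in licensed
#' factors via the same structure for real assessments.  Each entry maps to
#' the breakdown row it reports under (`source`), with minor inputs pooled
#' under `"Others"`.
#'
#' @return A named list of entries `list(ef, unit, source, provenance)`,
#'   class `upstream_ef_table`.
#' @export
default_upstream_efs <- function() {
  e <- function(ef, unit, source) {
    list(ef = ef, unit = unit, source = source, provenance = "assumed")
  }
  structure(list(
    fertiliser_n = e(3.6, "kg CO2-eq/kg N", "Ammonium nitrate production"),
    fertiliser_p = e(1.0, "kg CO2-eq/kg P", "Single superphosphate production"),
    fertiliser_k = e(0.55, "kg CO2-eq/kg K", "Others"),
    lime = e(0.06, "kg CO2-eq/kg", "Others"),
    fym = e(0, "kg CO2-eq/t", "Others"),  # on-farm co-product, no upstream
    glyphosate = e(10, "kg CO2-eq/kg", "Others"),
    fluroxypyr = e(10, "kg CO2-eq/kg", "Others"),
    seed_grass = e(1.5, "kg CO2-eq/kg", "Others"),
    seed_clover = e(1.5, "kg CO2-eq/kg", "Others"),
    diesel = e(3.2, "kg CO2-eq/l", "Others"),
    soybean = e(0.7, "kg CO2-eq/kg", "Others"),
    straw = e(0.12, "kg CO2-eq/kg", "Barley production"),
    tkm_soybean_sea = e(0.011, "kg CO2-eq/tkm", "Others"),
    tkm_soybean_road = e(0.11, "kg CO2-eq/tkm", "Others"),
    tkm_straw_road = e(0.11, "kg CO2-eq/tkm", "Others"),
    tkm_fertiliser_road = e(0.11, "kg CO2-eq/tkm", "Others")
  ), class = "upstream_ef_table")
}

#' Upstream (embedded) burdens of purchased inputs
#'
#' Multiplies every inventory quantity by its upstream emission factor and
#' ledgers the result under the factor's breakdown row (CO2-eq carried as
#' gas `CO2`).  Fails listing any inventory key with positive quantity that
#' the factor table cannot resolve.
#'
#' @param inv a [farmlet_inventory()].
#' @param efs an upstream factor table as from [default_upstream_efs()].
#' @return A farmlet-pool emission ledger.
#' @export
upstream_burdens <- function(inv, efs = default_upstream_efs()) {
  q <- inv$quantities
  active <- names(q)[q > 0]
  missing <- setdiff(active, names(efs))
  if (length(missing))
    stop("no upstream emission factor for inventory key(s): ",
         paste(missing, collapse = ", "))
  if (!length(active)) return(empty_ledger())
  mass <- vapply(active, function(k) q[[k]] * efs[[k]]$ef, numeric(1))
  src <- vapply(active, function(k) efs[[k]]$source, character(1))
  led <- emission_record(scope = "farmlet_pool", owner_id = inv$farmlet_id,
                         source = src, gas = "CO2", mass_kg = mass)
  led[led$mass_kg > 0, , drop = FALSE]
}

#' Reseeding schedule
#'
#' Sward renewal every `sowing_interval_years` on reseeded systems; the
#' per-event field operations (ploughing, rolling, harrowing, spraying,
#' drilling) are summarised as diesel use per hectare plus an optional
#' extra burden, and annualised by the interval.
#'
#' @param sowing_interval_years years between renewals (>= 1), default 5.
#' @param per_event_diesel_l_per_ha diesel for the renewal operations.
#' @param extra_co2e_kg additional per-event burden, kg CO2-eq.
#' @return An object of class `reseeding_schedule`.
#' @export
reseeding_schedule <- function(sowing_interval_years = 5,
                               per_event_diesel_l_per_ha = 45,
                               extra_co2e_kg = 0) {
  if (sowing_interval_years < 1) stop("sowing interval must be >= 1 year")
  structure(list(sowing_interval_years = sowing_interval_years,
                 per_event_diesel_l_per_ha = per_event_diesel_l_per_ha,
                 extra_co2e_kg = extra_co2e_kg),
            class = "reseeding_schedule")
}

#' Annualised reseeding burdens
#'
#' Per-event burden divided by the sowing interval, pooled under
#' `"Others"`.  Unreseeded farmlets receive none.
#'
#' @param schedule a [reseeding_schedule()].
#' @param inv a [farmlet_inventory()].
#' @param efs upstream factor table (for the diesel factor).
#' @return A farmlet-pool emission ledger (possibly empty).
#' @export
reseeding_burdens <- function(schedule, inv, efs = default_upstream_efs()) {
  if (!inv$reseeded) return(empty_ledger())
  per_event <- schedule$per_event_diesel_l_per_ha * inv$area_ha *
    efs[["diesel"]]$ef + schedule$extra_co2e_kg
  emission_record(scope = "farmlet_pool", owner_id = inv$farmlet_id,
                  source = "Others", gas = "CO2",
                  mass_kg = per_event / schedule$sowing_interval_years)
}

#' All farmlet-pool emissions
#'
#' Concatenates soil N2O (+ lime CO2), upstream input burdens and annualised
#' reseeding burdens into one farmlet-pool ledger.
#'
#' @inheritParams upstream_burdens
#' @param params a [tier2_params()] set.
#' @param schedule a [reseeding_schedule()].
#' @return A farmlet-pool emission ledger.
#' @export
farmlet_pool_emissions <- function(inv, efs = default_upstream_efs(),
                                   params = default_params(),
                                   schedule = reseeding_schedule()) {
  rbind_ledgers(soil_n2o(inv, params),
                upstream_burdens(inv, efs),
                reseeding_burdens(schedule, inv, efs))
}
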