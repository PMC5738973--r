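#' Co-product allocation basis
#'
#' Pasture-originating burdens are shared between the cattle and sheep
#' enterprises that graze the platform in rotation.  Under economic
#' allocation the weights are the enterprises' product values at the system
#' boundary; under mass allocation they are estimated dry-matter intakes.
#'
#' @param method `"economic"` or `"mass"`.
#' @param cattle_value,sheep_value positive weights (currency for economic,
#'   kg DMI for mass).
#' @return An object of class `allocation_basis`.
#' @export
allocation_basis <- function(method = c("economic", "mass"),
                             cattle_value, sheep_value) {
  method <- match.arg(method)
  if (cattle_value <= 0 || sheep_value <= 0)
    stop("allocation values must be positive")
  structure(list(method = method, cattle_value = cattle_value,
                 sheep_value = sheep_value), class = "allocation_basis")
}

#' Enterprise shares from an allocation basis
#'
#' @param basis an [allocation_basis()].
#' @return Named vector `c(cattle, sheep)`; shares sum to 1 and are
#'   invariant under rescaling of both values.
#' @export
#' @examples
#' enterprise_shares(allocation_basis("economic", 78, 22))  # 0.78 / 0.22
enterprise_shares <- function(basis) {
  tot <- basis$cattle_value + basis$sheep_value
  c(cattle = basis$cattle_value / tot, sheep = basis$sheep_value / tot)
}

#' Distribute farmlet burdens across individual animals
#'
#' Implements the two distribution rules: (a) the cattle share of every
#' farmlet-pool burden (field inputs, upstream production, sheep manure) is
#' split evenly across the `n_animals` cattle; (b) animal-scope records stay
#' with their animal, except that burdens from cattle excreta deposited on
#' the shared pasture (urine/dung N2O and its leaching) first surrender the
#' sheep-allocated fraction, since that manure also feeds the sheep
#' enterprise.  Enteric and manure-management records are cattle-body
#' processes and are never reallocated.  The grand total is conserved:
#' cattle rows plus sheep rows reproduce the input ledgers exactly.
#'
#' @param pool a farmlet-pool ledger ([farmlet_pool_emissions()]).
#' @param animal_ledger an animal-scope ledger ([animal_emissions()]).
#' @param share cattle share in (0, 1], e.g.
#'   `enterprise_shares(basis)["cattle"]`.
#' @param n_animals number of cattle sharing the pool.
#' @return A list with ledgers `cattle` (per-animal, pool rows re-owned by
#'   each animal) and `sheep` (the deducted shares).
#' @export
distribute_to_animals <- function(pool, animal_ledger, share, n_animals) {
  stopifnot(n_animals >= 1, share > 0, share <= 1)
  ids <- unique(animal_ledger$owner_id)
  if (length(ids) && length(ids) != n_animals)
    stop("animal ledger has ", length(ids), " animals but n_animals = ",
         n_animals)
  sheep_parts <- list()
  # rule (a): pool evenly across animals after the sheep deduction
  if (nrow(pool)) {
    per_animal <- pool$mass_kg * share / n_animals
    cattle_pool <- do.call(rbind_ledgers, lapply(ids, function(id) {
      p <- pool
      p$scope <- "animal"; p$owner_id <- id; p$mass_kg <- per_animal
      p
    }))
    sp <- pool
    sp$mass_kg <- pool$mass_kg * (1 - share)
    sheep_parts <- c(sheep_parts, list(sp))
  } else cattle_pool <- empty_ledger()
  # rule (b): pasture-deposition rows surrender the sheep fraction
  al <- animal_ledger
  dep <- al$source %in% pasture_deposition_sources()
  if (any(dep)) {
    sp <- al[dep, , drop = FALSE]
    sp$mass_kg <- sp$mass_kg * (1 - share)
    sp$scope <- "farmlet_pool"
    sheep_parts <- c(sheep_parts, list(sp))
    al$mass_kg[dep] <- al$mass_kg[dep] * share
  }
  list(cattle = rbind_ledgers(al, cattle_pool),
       sheep = do.call(rbind_ledgers, sheep_parts))
}

#' Characterize a ledger to CO2 equivalents
#'
#' Multiplies every mass by its gas's GWP100 factor.  Linear: swapping the
#' factor set only reweights gases.
#'
#' @param ledger an emission ledger.
#' @param factors a [gwp_factors()] set.
#' @return The ledger with an added `co2e_kg` column; total in attribute
#'   `"total_co2e"`, per-source breakdown in attribute `"by_source"`.
#' @export
#' @examples
#' led <- emission_record("animal", "a", "Enteric fermentation (CH4)",
#'                        "CH4", 1)
#' attr(characterize(led, gwp_factors("AR5")), "total_co2e")  # 28
characterize <- function(ledger, factors = gwp_factors("AR5")) {
  unknown <- setdiff(unique(ledger$gas), names(factors))
  if (length(unknown))
    stop("no characterization factor for gas: ",
         paste(unknown, collapse = ", "))
  ledger$co2e_kg <- ledger$mass_kg * unname(factors[ledger$gas])
  by_source <- if (nrow(ledger)) {
    stats::aggregate(co2e_kg ~ source, data = ledger, FUN = sum)
  } else data.frame(source = character(), co2e_kg = numeric())
  structure(ledger, total_co2e = sum(ledger$co2e_kg),
            by_source = by_source)
}

#' Emissions intensity
#'
#' The functional-unit quotient: kg CO2-eq per kg liveweight gained.
#' Animals with non-positive gain have undefined intensity; they are flagged
#' with a warning and returned as `NA` so callers can exclude them from
#' distributions while keeping their absolute emissions in system totals.
#'
#' @param total_co2e kg CO2-eq (vectorised).
#' @param lwg kg liveweight gain.
#' @return kg CO2-eq / kg LWG.
#' @export
emissions_intensity <- function(total_co2e, lwg) {
  out <- total_co2e / lwg
  bad <- lwg <= 0
  if (any(bad)) {
    warning(sum(bad), " non-finishing animal(s) with lwg <= 0: ",
            "emissions intensity undefined, returned NA")
    out[bad] <- NA_real_
  }
  out
}

#' Per-animal emissions-intensity results
#'
#' Aggregates a characterized per-animal ledger into one row per animal:
#' liveweight gain, total CO2-eq, emissions intensity and a per-source
#' breakdown (one column per registry source, kg CO2-eq).
#'
#' @param cattle_ledger per-animal ledger after [distribute_to_animals()].
#' @param herd the herd records (for LWG, sex, farmlet, days on platform).
#' @param factors a [gwp_factors()] set.
#' @return A data.frame with columns `animal_id`, `farmlet`, `sex`,
#'   `days`, `adg`, `lwg_kg`, `total_co2e_kg`, `ei`, then one column per
#'   source.  Breakdown columns sum to the total on every row.
#' @export
ei_results <- function(cattle_ledger, herd, factors = gwp_factors("AR5")) {
  chr <- characterize(cattle_ledger, factors)
  lwg <- animal_lwg(herd)
  herd <- herd[order(herd$animal_id, herd$date), , drop = FALSE]
  meta <- do.call(rbind, lapply(split(herd, herd$animal_id), function(a) {
    data.frame(animal_id = a$animal_id[1], farmlet = a$farmlet[1],
               sex = a$sex[1],
               days = as.numeric(a$date[nrow(a)] - a$date[1]),
               stringsAsFactors = FALSE)
  }))
  tot <- stats::aggregate(co2e_kg ~ owner_id, data = chr, FUN = sum)
  wide <- stats::reshape(
    stats::aggregate(co2e_kg ~ owner_id + source, data = chr, FUN = sum),
    idvar = "owner_id", timevar = "source", direction = "wide")
  names(wide) <- sub("^co2e_kg\\.", "", names(wide))
  res <- merge(meta, tot, by.x = "animal_id", by.y = "owner_id")
  res <- merge(res, wide, by.x = "animal_id", by.y = "owner_id")
  res$lwg_kg <- unname(lwg[res$animal_id])
  res$adg <- res$lwg_kg / res$days
  names(res)[names(res) == "co2e_kg"] <- "total_co2e_kg"
  res$ei <- suppressWarnings(
    emissions_intensity(res$total_co2e_kg, res$lwg_kg))
  n_bad <- sum(res$lwg_kg <= 0)
  if (n_bad)
    warning(n_bad, " animal(s) excluded from intensity distributions ",
            "(lwg <= 0); absolute emissions retained")
  src_cols <- source_registry()$source
  for (s in src_cols) {       # absent sources appear as all-zero columns
    if (!s %in% names(res)) res[[s]] <- 0
    res[[s]][is.na(res[[s]])] <- 0
  }
  front <- c("animal_id", "farmlet", "sex", "days", "adg", "lwg_kg",
             "total_co2e_kg", "ei")
  res <- res[c(front, src_cols)]
  class(res) <- c("ei_results", "data.frame")
  res
}
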