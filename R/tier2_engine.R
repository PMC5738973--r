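#' Build animal-periods from weighing records
#'
#' Splits each animal's weighing record into half-open periods
#' `[start, end)` between consecutive weighings and attaches the feed
#' quality in force: pasture samples while grazing, silage samples while
#' housed, time-weighted over the period via [quality_at()].  The period's
#' location is that of its opening weighing.
#'
#' @param herd a `herd_records` data.frame (one or more animals), columns
#'   `animal_id`, `farmlet`, `sex`, `date`, `weight_kg`, `location`.
#' @param feed a feed-series data.frame covering the herd's farmlets and
#'   both feed types.
#' @return A data.frame with one row per period: `animal_id`, `farmlet`,
#'   `sex`, `start`, `end`, `days`, `start_weight`, `end_weight`,
#'   `mean_weight`, `period_adg`, `location`, `de_pct`, `cp_pct`.
#' @export
periods_from_record <- function(herd, feed) {
  stopifnot(is.data.frame(herd), nrow(herd) >= 2)
  herd <- herd[order(herd$animal_id, herd$date), , drop = FALSE]
  out <- lapply(split(herd, herd$animal_id), function(a) {
    if (nrow(a) < 2)
      stop("animal ", a$animal_id[1], " has fewer than 2 weighings")
    if (anyDuplicated(a$date))
      stop("duplicate weighing dates for animal ", a$animal_id[1])
    if (any(a$weight_kg <= 0))
      stop("non-positive weight recorded for animal ", a$animal_id[1])
    n <- nrow(a)
    i <- seq_len(n - 1L)
    days <- as.numeric(a$date[i + 1L] - a$date[i])
    p <- data.frame(
      animal_id = a$animal_id[i], farmlet = a$farmlet[i], sex = a$sex[i],
      start = a$date[i], end = a$date[i + 1L], days = days,
      start_weight = a$weight_kg[i], end_weight = a$weight_kg[i + 1L],
      mean_weight = (a$weight_kg[i] + a$weight_kg[i + 1L]) / 2,
      period_adg = (a$weight_kg[i + 1L] - a$weight_kg[i]) / days,
      location = a$location[i],
      stringsAsFactors = FALSE
    )
    q <- t(vapply(seq_len(nrow(p)), function(j) {
      ft <- if (p$location[j] == "housing") "silage" else "pasture"
      quality_at(feed, p$farmlet[j], ft, p$start[j], p$end[j])
    }, numeric(2)))
    p$de_pct <- q[, 1]
    p$cp_pct <- q[, 2]
    p
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# IPCC (2006) ratios of net energy available to digestible energy consumed
rem_of_de <- function(de) 1.123 - 0.004092 * de + 1.126e-5 * de^2 - 25.4 / de
reg_of_de <- function(de) 1.164 - 0.005160 * de + 1.308e-5 * de^2 - 37.4 / de

# net energy for growth, MJ/d; zero for weight-loss or zero-gain periods
ne_growth <- function(mean_weight, adg, sex, params) {
  c_sex <- params$c_growth[sex]
  mw <- params$mature_weight[sex]
  ifelse(adg > 0,
         22.02 * (mean_weight / (c_sex * mw))^0.75 * pmax(adg, 0)^1.097,
         0)
}

#' Gross energy intake for an animal-period
#'
#' The Tier 2 energy chain: net energy for maintenance
#' `NEm = cfi x W^0.75`, activity allowance `NEa = Ca(location) x NEm`,
#' growth energy `NEg` from the Tier 2 growth equation (floored at zero for
#' zero or negative gain), combined through the REM/REG availability ratios
#' (polynomials in DE) and scaled by dietary digestibility:
#' `GE = ((NEm + NEa)/REM + NEg/REG) / (DE/100)`.
#'
#' @param period one or more animal-periods as built by
#'   [periods_from_record()] (uses `mean_weight`, `period_adg`, `location`,
#'   `de_pct`, `sex`).
#' @param params a [tier2_params()] set.
#' @param sex optional override of `period$sex`.
#' @return GE in MJ/d, one value per period row.
#' @export
gross_energy_intake <- function(period, params, sex = period$sex) {
  de <- period$de_pct
  if (any(de <= 0 | de >= 100))
    stop("digestible energy must lie in (0, 100) %")
  ne_m <- params$cfi_maintenance * period$mean_weight^0.75
  ne_a <- params$ca_activity[period$location] * ne_m
  ne_g <- ne_growth(period$mean_weight, period$period_adg, sex, params)
  unname(((ne_m + ne_a) / rem_of_de(de) + ne_g / reg_of_de(de)) / (de / 100))
}

#' Enteric methane from gross energy intake
#'
#' `CH4 = GE x days x (Ym/100) / 55.65`, with 55.65 MJ/kg the energy
#' content of methane.
#'
#' @param ge gross energy intake, MJ/d.
#' @param ym methane conversion factor, % of GE.
#' @param days length of the period.
#' @param energy_per_kg_ch4 MJ per kg CH4.
#' @return kg CH4 over the period.
#' @export
#' @examples
#' enteric_ch4(250, 6.5, 10)  # 2.920 kg
enteric_ch4 <- function(ge, ym, days, energy_per_kg_ch4 = 55.65) {
  stopifnot(all(ge >= 0), all(days >= 1))
  ge * days * (ym / 100) / energy_per_kg_ch4
}

#' Volatile solids excreted per day
#'
#' `VS = (GE x (1 - DE/100) + UE x GE) x (1 - ash) / 18.45` kg/d, with
#' 18.45 MJ/kg DM the dietary gross-energy density.
#'
#' @inheritParams enteric_ch4
#' @param de_pct digestible energy, %.
#' @param params a [tier2_params()] set.
#' @return kg volatile solids per day.
#' @export
volatile_solids <- function(ge, de_pct, params) {
  (ge * (1 - de_pct / 100) + params$urinary_energy_frac * ge) *
    (1 - params$ash_frac) / 18.45
}

#' Manure-management methane for an animal-period
#'
#' `CH4 = VS_total x B0 x 0.67 x MCF/100`, with the methane conversion
#' factor switched by location: the deep-bedding MCF while housed (midden
#' storage is represented by the deep-bedding system), the pasture MCF for
#' excreta deposited while grazing.
#'
#' @inheritParams volatile_solids
#' @param days period length.
#' @param location `"pasture"` or `"housing"` per period.
#' @return kg CH4 over the period.
#' @export
manure_ch4 <- function(ge, de_pct, days, params, location) {
  stopifnot(all(ge >= 0), all(days >= 1))
  vs <- volatile_solids(ge, de_pct, params) * days
  mcf <- ifelse(location == "housing",
                params$mcf_deep_bedding, params$mcf_pasture)
  vs * params$b0 * params$ch4_density * mcf / 100
}

#' Nitrogen excreted over an animal-period
#'
#' N intake per day is `GE/18.45 x (CP/100)/6.25`; N retained follows the
#' Tier 2 retention equation driven by the period's gain (zero for zero or
#' negative gain, so a non-growing animal excretes its full intake);
#' excretion is intake minus retention, floored at zero.
#'
#' @inheritParams gross_energy_intake
#' @param ge gross energy intake, MJ/d (as from [gross_energy_intake()]).
#' @param cp_pct crude protein, % of DM (defaults to `period$cp_pct`).
#' @return kg N excreted over the period, one value per period row.
#' @export
n_excretion <- function(ge, cp_pct = period$cp_pct, period, params) {
  stopifnot(all(cp_pct >= 0))
  n_intake <- (ge / 18.45) * (cp_pct / 100) / 6.25      # kg N/d
  adg <- period$period_adg
  ne_g <- ne_growth(period$mean_weight, adg, period$sex, params)
  n_ret <- ifelse(adg > 0,
                  adg * (268 - 7.03 * ne_g / pmax(adg, 1e-12)) / 1000 / 6.25,
                  0)
  n_ret <- pmax(n_ret, 0)
  unname(pmax(n_intake - n_ret, 0) * period$days)
}

#' Nitrous oxide pathways from excreted nitrogen
#'
#' Housed excreta produce direct N2O (deep-bedding EF3) and indirect N2O via
#' the volatilised fraction (FracGasMS x EF4); excreta deposited at pasture
#' produce direct N2O (pasture/range/paddock EF3 for cattle) and indirect
#' N2O via leaching (FracLeach x EF5).  All N2O-N is converted to N2O by
#' 44/28.
#'
#' @param n_ex kg N excreted (vectorised over periods).
#' @param location `"pasture"` or `"housing"` per element.
#' @param params a [tier2_params()] set.
#' @return A data.frame with columns `index` (element of `n_ex`), `source`,
#'   `gas`, `mass_kg`; two rows per element.
#' @export
manure_n2o <- function(n_ex, location, params) {
  stopifnot(all(n_ex >= 0), length(location) %in% c(1L, length(n_ex)))
  location <- rep(location, length.out = length(n_ex))
  housed <- location == "housing"
  n2on_to_n2o <- 44 / 28
  direct <- ifelse(housed,
                   n_ex * params$ef3_deep_bedding,
                   n_ex * params$ef3_prp_cattle) * n2on_to_n2o
  indirect <- ifelse(housed,
                     n_ex * params$frac_gas_ms * params$ef4_volatilisation,
                     n_ex * params$frac_leach * params$ef5_leaching) *
    n2on_to_n2o
  data.frame(
    index = rep(seq_along(n_ex), 2L),
    source = c(ifelse(housed, "Manure management (direct N2O)",
                      "Urine and dung from cattle on pasture (N2O)"),
               ifelse(housed,
                      "Manure management (indirect volatilisation N2O)",
                      "Indirect emissions from leaching (N2O)")),
    gas = "N2O",
    mass_kg = c(direct, indirect),
    stringsAsFactors = FALSE
  )
}

# per-period emissions in wide form; the fast path shared by the ledger
# builder and the Monte Carlo engine
period_emissions <- function(periods, params) {
  ge <- gross_energy_intake(periods, params)
  ym <- params$ym[ifelse(periods$location == "housing",
                         "housing", "pasture")]
  n_ex <- n_excretion(ge, periods$cp_pct, periods, params)
  n2o <- manure_n2o(n_ex, periods$location, params)
  housed <- periods$location == "housing"
  out <- data.frame(
    periods[c("animal_id", "farmlet", "sex", "start", "end", "days",
              "location")],
    ge_mj_d = ge,
    enteric_ch4_kg = enteric_ch4(ge, ym, periods$days,
                                 params$energy_per_kg_ch4),
    manure_ch4_kg = manure_ch4(ge, periods$de_pct, periods$days, params,
                               periods$location),
    n_ex_kg = n_ex,
    stringsAsFactors = FALSE
  )
  # unpack the two pathway rows per period back into wide columns
  first <- n2o[seq_along(ge), ]
  second <- n2o[length(ge) + seq_along(ge), ]
  out$n2o_direct_kg <- ifelse(housed, first$mass_kg, 0)
  out$n2o_volat_kg <- ifelse(housed, second$mass_kg, 0)
  out$n2o_prp_kg <- ifelse(housed, 0, first$mass_kg)
  out$n2o_leach_kg <- ifelse(housed, 0, second$mass_kg)
  out
}

#' Per-animal emission ledger from weighing records
#'
#' Runs the full Tier 2 chain for every animal and every period between
#' consecutive weighings, switching parameters by location and diet, and
#' returns the concatenated emission ledger.  Total liveweight gain per
#' animal (final minus entry weight) is attached as the `"lwg"` attribute.
#'
#' @inheritParams periods_from_record
#' @param params a [tier2_params()] set.
#' @param periods optionally a precomputed [periods_from_record()] table
#'   (skips rebuilding; `herd` is still used for liveweight gains).
#' @return An emission ledger (see [emission_record()]) with one row per
#'   animal-period-source, scope `"animal"`.
#' @export
animal_emissions <- function(herd, feed, params = default_params(),
                             periods = NULL) {
  if (is.null(periods)) periods <- periods_from_record(herd, feed)
  pe <- period_emissions(periods, params)
  src_cols <- c("Enteric fermentation (CH4)" = "enteric_ch4_kg",
                "Manure management (CH4)" = "manure_ch4_kg",
                "Manure management (direct N2O)" = "n2o_direct_kg",
                "Manure management (indirect volatilisation N2O)" =
                  "n2o_volat_kg",
                "Urine and dung from cattle on pasture (N2O)" = "n2o_prp_kg",
                "Indirect emissions from leaching (N2O)" = "n2o_leach_kg")
  gases <- c("CH4", "CH4", "N2O", "N2O", "N2O", "N2O")
  parts <- lapply(seq_along(src_cols), function(k) {
    emission_record(scope = "animal", owner_id = pe$animal_id,
                    source = names(src_cols)[k], gas = gases[k],
                    mass_kg = pe[[src_cols[k]]],
                    period_start = pe$start, period_end = pe$end)
  })
  ledger <- do.call(rbind_ledgers, parts)
  ledger <- ledger[ledger$mass_kg > 0 | ledger$source ==
                     "Enteric fermentation (CH4)", , drop = FALSE]
  attr(ledger, "lwg") <- animal_lwg(herd)
  validate_ledger(ledger)
  ledger
}

#' Total liveweight gain per animal
#'
#' @param herd a `herd_records` data.frame.
#' @return Named numeric vector: final minus entry weight, kg, per animal.
#' @export
animal_lwg <- function(herd) {
  herd <- herd[order(herd$animal_id, herd$date), , drop = FALSE]
  vapply(split(herd, herd$animal_id),
         function(a) a$weight_kg[nrow(a)] - a$weight_kg[1L], numeric(1))
}
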