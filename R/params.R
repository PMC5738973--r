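#' Construct a Tier 2 parameter set
#'
#' Bundles every coefficient and emission factor the livestock engine and the
#' field-emission calculations need.  Each value must carry a provenance
#' string (`"IPCC 2006 default"`, `"paper"` or `"assumed"`) so that swapped
#' or recalibrated parameter sets remain auditable; construction fails if a
#' provenance entry is missing.
#'
#' Units and meaning:
#' \describe{
#'   \item{cfi_maintenance}{net energy for maintenance, MJ/d per kg
#'     metabolic weight (kg^0.75).}
#'   \item{ca_activity}{activity multiplier on NEm by location
#'     (named: pasture, housing).}
#'   \item{c_growth}{growth-equation coefficient by sex (heifer 0.8,
#'     steer 1.0).}
#'   \item{mature_weight}{kg, by sex; scales the growth energy equation.}
#'   \item{ym}{methane conversion factor, % of gross energy, by diet class
#'     (named: pasture, housing).}
#'   \item{energy_per_kg_ch4}{55.65 MJ/kg CH4 (fixed).}
#'   \item{urinary_energy_frac, ash_frac}{fractions of GE and of faecal dry
#'     matter in the volatile-solids equation.}
#'   \item{b0, ch4_density}{maximum methane-producing capacity
#'     (m3 CH4/kg VS) and CH4 density (kg/m3).}
#'   \item{mcf_deep_bedding, mcf_pasture}{manure-management methane
#'     conversion factors, %, for housed deep bedding and for excreta
#'     deposited at pasture.}
#'   \item{annual_temp}{deg C; the climate under which the deep-bedding MCF
#'     was chosen (informational).}
#'   \item{ef1_fertiliser, ef3_deep_bedding, ef3_prp_cattle, ef3_prp_sheep,
#'     ef4_volatilisation, ef5_leaching}{N2O-N emission factors per kg N.}
#'   \item{frac_gas_ms, frac_leach}{fractions of managed/applied N
#'     volatilised and leached.}
#'   \item{storage_months}{months housed excreta spend in the midden before
#'     field application.}
#'   \item{fym_n_per_t}{kg N per tonne of farmyard manure applied.}
#' }
#'
#' @param values named list of parameter values (see [default_params()] for
#'   the full set).
#' @param provenance named character vector, one entry per parameter.
#' @return An object of class `tier2_params`.
#' @seealso [default_params()], [params_from_yaml()]
#' @export
tier2_params <- function(values, provenance) {
  stopifnot(is.list(values), length(values) > 0)
  miss <- setdiff(names(values), names(provenance))
  if (length(miss))
    stop("parameters without provenance: ", paste(miss, collapse = ", "))
  p <- values
  frac_names <- c("urinary_energy_frac", "ash_frac", "ef1_fertiliser",
                  "ef3_deep_bedding", "ef3_prp_cattle", "ef3_prp_sheep",
                  "ef4_volatilisation", "ef5_leaching", "frac_gas_ms",
                  "frac_leach")
  for (nm in intersect(frac_names, names(p)))
    if (any(p[[nm]] < 0 | p[[nm]] > 1))
      stop("parameter '", nm, "' must lie in [0, 1]")
  if (any(p$ym <= 0 | p$ym >= 15))
    stop("ym must lie in (0, 15) % of gross energy")
  if (!isTRUE(all.equal(p$energy_per_kg_ch4, 55.65)))
    stop("energy_per_kg_ch4 is the physical constant 55.65 MJ/kg")
  if (p$cfi_maintenance <= 0 || any(p$mature_weight <= 0))
    stop("maintenance coefficient and mature weights must be positive")
  structure(p, provenance = provenance, class = "tier2_params")
}

#' Default Tier 2 parameter set
#'
#' IPCC (2006) defaults for non-lactating, growing cattle on forage diets,
#' with the deep-bedding methane conversion factor set to 20 % for a 12 deg C
#' mean annual temperature and a six-month midden storage represented by the
#' deep-bedding factors.  Mature weights and the farmyard-manure N content
#' are flagged `"assumed"`.
#'
#' @return A `tier2_params` object.
#' @export
#' @examples
#' p <- default_params()
#' p$ym
default_params <- function() {
  tier2_params(
    values = list(
      cfi_maintenance   = 0.322,
      ca_activity       = c(pasture = 0.17, housing = 0),
      c_growth          = c(steer = 1.0, heifer = 0.8),
      mature_weight     = c(steer = 680, heifer = 580),
      ym                = c(pasture = 6.5, housing = 6.5),
      energy_per_kg_ch4 = 55.65,
      urinary_energy_frac = 0.04,
      ash_frac          = 0.08,
      b0                = 0.17,
      ch4_density       = 0.67,
      mcf_deep_bedding  = 20,
      mcf_pasture       = 1,
      annual_temp       = 12,
      ef1_fertiliser    = 0.01,
      ef3_deep_bedding  = 0.01,
      ef3_prp_cattle    = 0.02,
      ef3_prp_sheep     = 0.01,
      ef4_volatilisation = 0.01,
      ef5_leaching      = 0.0075,
      frac_gas_ms       = 0.30,
      frac_leach        = 0.30,
      storage_months    = 6,
      fym_n_per_t       = 6.0
    ),
    provenance = c(
      cfi_maintenance = "IPCC 2006 default",
      ca_activity = "IPCC 2006 default",
      c_growth = "IPCC 2006 default",
      mature_weight = "assumed",
      ym = "IPCC 2006 default (assumed; not printed)",
      energy_per_kg_ch4 = "IPCC 2006 default",
      urinary_energy_frac = "IPCC 2006 default",
      ash_frac = "IPCC 2006 default",
      b0 = "IPCC 2006 default",
      ch4_density = "IPCC 2006 default",
      mcf_deep_bedding = "paper",
      mcf_pasture = "IPCC 2006 default",
      annual_temp = "paper",
      ef1_fertiliser = "IPCC 2006 default",
      ef3_deep_bedding = "IPCC 2006 default",
      ef3_prp_cattle = "IPCC 2006 default",
      ef3_prp_sheep = "IPCC 2006 default",
      ef4_volatilisation = "IPCC 2006 default",
      ef5_leaching = "IPCC 2006 default",
      frac_gas_ms = "IPCC 2006 default",
      frac_leach = "IPCC 2006 default",
      storage_months = "paper",
      fym_n_per_t = "assumed"
    )
  )
}

#' @export
print.tier2_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Tier 2 parameter set (", length(x), " parameters)\n", sep = "")
  for (nm in names(x)) {
    v <- x[[nm]]
    vs <- if (is.null(names(v))) paste(v, collapse = ", ")
          else paste(names(v), v, sep = "=", collapse = ", ")
    cat(sprintf("  %-20s %-28s [%s]\n", nm, vs, prov[[nm]]))
  }
  invisible(x)
}

#' Read / write parameter sets as YAML
#'
#' The YAML layout is one block per parameter with explicit `value` and
#' `provenance` keys; loading fails if any parameter lacks provenance.
#' Named vectors (e.g. `ym` by diet class) round-trip as named maps.
#'
#' @param path file path.
#' @return `params_from_yaml()` returns a `tier2_params` object;
#'   `params_to_yaml()` invisibly returns `path`.
#' @export
params_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  values <- list(); prov <- character()
  for (nm in names(raw)) {
    entry <- raw[[nm]]
    if (!is.list(entry) || is.null(entry$value) || is.null(entry$provenance))
      stop("parameter '", nm, "' must provide both value and provenance")
    v <- entry$value
    if (is.list(v)) v <- unlist(v)
    values[[nm]] <- v
    prov[nm] <- entry$provenance
  }
  tier2_params(values, prov)
}

#' @rdname params_from_yaml
#' @param params a `tier2_params` object.
#' @export
params_to_yaml <- function(params, path) {
  prov <- attr(params, "provenance")
  out <- lapply(names(params), function(nm) {
    v <- params[[nm]]
    list(value = if (is.null(names(v))) v else as.list(v),
         provenance = unname(prov[[nm]]))
  })
  names(out) <- names(params)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' GWP100 characterization factor sets
#'
#' 100-year global warming potentials used to express CH4 and N2O masses as
#' kg CO2-eq: the AR5 set (CH4 28, N2O 265) and the superseded AR4 set
#' (CH4 25, N2O 298).  CO2 is 1 by definition in both.
#'
#' @param name `"AR5"` or `"AR4"` (case-insensitive; `"ar5_gwp100"` style
#'   names also accepted).
#' @return A named numeric vector with elements `CH4`, `N2O`, `CO2` and a
#'   `"set"` attribute.
#' @export
#' @examples
#' gwp_factors("AR5")["CH4"]  # 28
gwp_factors <- function(name = "AR5") {
  key <- toupper(sub("_GWP100$", "", toupper(name)))
  f <- switch(key,
    AR5 = c(CH4 = 28, N2O = 265, CO2 = 1),
    AR4 = c(CH4 = 25, N2O = 298, CO2 = 1),
    stop("unknown GWP factor set: ", name)
  )
  structure(f, set = paste0(key, "_GWP100"))
}
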