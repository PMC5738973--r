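#' Feed conversion coefficients
#'
#' Coefficients mapping laboratory feed measurements to the quantities the
#' Tier 2 engine consumes: modified acid detergent fibre (MADF, g/kg DM) to
#' metabolisable energy (ME, MJ/kg DM) by an affine calibration per feed
#' type, ME to digestible energy (DE, % of gross energy, via the
#' ME = k x DOMD relation with DOMD reported as DE), and total nitrogen to
#' crude protein by the standard 6.25 multiplier.
#'
#' The affine MADF calibrations for UK pastures and silages are not in the
#' public domain; the defaults below are assumed, editable placeholders with
#' negative slope (more fibre, less energy) chosen so that typical MADF
#' values map into the usual UK forage ME band (pasture ~11-12.5, silage
#' ~10-11 MJ/kg DM).  Every numeric expectation tested against them is a
#' hand evaluation of the same affine form, not a published value.
#'
#' @param me_from_madf named list, per feed type, of `c(intercept, slope)`
#'   in MJ/kg DM and MJ/kg DM per g/kg MADF; slope must be <= 0.
#' @param de_from_me scalar k in `ME = k x DOMD` (MJ/kg DM per DOMD point);
#'   DE% = ME / k.
#' @param cp_from_n nitrogen-to-crude-protein multiplier (default 6.25).
#' @return An object of class `conversion_coefficients`.
#' @export
conversion_coefficients <- function(
    me_from_madf = list(pasture = c(intercept = 15.8, slope = -0.0185),
                        silage = c(intercept = 15.0, slope = -0.0180)),
    de_from_me = 0.16,
    cp_from_n = 6.25) {
  for (ft in names(me_from_madf)) {
    co <- me_from_madf[[ft]]
    if (length(co) != 2L)
      stop("me_from_madf$", ft, " must be c(intercept, slope)")
    if (co[[2]] > 0)
      stop("ME~MADF slope must be <= 0 (more fibre, less energy)")
  }
  if (de_from_me <= 0) stop("de_from_me must be positive")
  if (cp_from_n <= 0) stop("cp_from_n must be positive")
  structure(list(me_from_madf = me_from_madf, de_from_me = de_from_me,
                 cp_from_n = cp_from_n),
            class = "conversion_coefficients")
}

#' Convert MADF to metabolisable energy
#'
#' `ME = intercept + slope x MADF` with feed-type-specific coefficients.
#'
#' @param madf fibre content, g/kg DM (vectorised).
#' @param feed_type `"pasture"` or `"silage"`.
#' @param coeffs a [conversion_coefficients()] object.
#' @param sample_id optional label(s) used in out-of-calibration errors.
#' @return ME in MJ/kg DM.
#' @export
madf_to_me <- function(madf, feed_type, coeffs = conversion_coefficients(),
                       sample_id = NULL) {
  if (any(madf < 0)) stop("MADF must be non-negative")
  co <- coeffs$me_from_madf[[feed_type]]
  if (is.null(co)) stop("no ME calibration for feed type: ", feed_type)
  me <- co[[1]] + co[[2]] * madf
  if (any(me <= 0)) {
    bad <- which(me <= 0)
    lab <- if (is.null(sample_id)) paste("index", paste(bad, collapse = ","))
           else paste(sample_id[bad], collapse = ", ")
    stop("MADF out of calibration range (non-positive ME) for sample(s): ",
         lab)
  }
  me
}

#' Convert metabolisable energy to digestible energy
#'
#' Inverts the `ME = k x DOMD` relation; DOMD is reported as digestible
#' energy (% of gross energy).  Strictly increasing in ME and constrained to
#' (0, 100).
#'
#' @param me MJ/kg DM (vectorised), must be positive.
#' @inheritParams madf_to_me
#' @return DE as % of gross energy.
#' @export
me_to_de <- function(me, coeffs = conversion_coefficients()) {
  if (any(me <= 0)) stop("ME must be positive")
  de <- me / coeffs$de_from_me
  if (any(de >= 100))
    stop("calibration error: DE outside (0, 100) for ME = ",
         paste(me[de >= 100], collapse = ", "))
  de
}

#' Convert total nitrogen to crude protein
#'
#' `CP = coefficient x N`, coefficient 6.25 by default.
#'
#' @param total_n nitrogen, % of DM (vectorised), non-negative.
#' @inheritParams madf_to_me
#' @return CP as % of DM.
#' @export
#' @examples
#' n_to_cp(1.0)     # 6.25
#' n_to_cp(3.3152)  # 20.72
n_to_cp <- function(total_n, coeffs = conversion_coefficients()) {
  if (any(total_n < 0)) stop("total N must be non-negative")
  coeffs$cp_from_n * total_n
}

#' Resolve raw feed samples to DE/CP
#'
#' Applies the conversion chain to a feed-sample table that may carry raw
#' measurements (`madf_g_per_kg`, `n_pct`), converted values (`de_pct`,
#' `cp_pct`) or both.  Where both are present the converted (measured)
#' value wins and a warning is issued.
#'
#' @param samples data.frame with `farmlet`, `feed_type`, `date` and at least
#'   one of (`madf_g_per_kg`, `de_pct`) and one of (`n_pct`, `cp_pct`).
#' @inheritParams madf_to_me
#' @return The table with complete `de_pct` and `cp_pct` columns.
#' @export
resolve_feed_samples <- function(samples,
                                 coeffs = conversion_coefficients()) {
  has <- function(col) col %in% names(samples) && any(!is.na(samples[[col]]))
  if (!has("de_pct") && !has("madf_g_per_kg"))
    stop("feed samples need de_pct or madf_g_per_kg")
  if (!has("cp_pct") && !has("n_pct"))
    stop("feed samples need cp_pct or n_pct")
  if (!"de_pct" %in% names(samples)) samples$de_pct <- NA_real_
  if (!"cp_pct" %in% names(samples)) samples$cp_pct <- NA_real_
  if (has("madf_g_per_kg")) {
    both <- !is.na(samples$de_pct) & !is.na(samples$madf_g_per_kg)
    if (any(both))
      warning("both MADF and DE present for ", sum(both),
              " sample(s); keeping measured DE")
    need <- is.na(samples$de_pct) & !is.na(samples$madf_g_per_kg)
    for (ft in unique(samples$feed_type[need])) {
      idx <- need & samples$feed_type == ft
      me <- madf_to_me(samples$madf_g_per_kg[idx], ft, coeffs,
                       sample_id = paste(samples$farmlet[idx],
                                         samples$date[idx]))
      samples$de_pct[idx] <- me_to_de(me, coeffs)
    }
  }
  if (has("n_pct")) {
    both <- !is.na(samples$cp_pct) & !is.na(samples$n_pct)
    if (any(both))
      warning("both total N and CP present for ", sum(both),
              " sample(s); keeping measured CP")
    need <- is.na(samples$cp_pct) & !is.na(samples$n_pct)
    samples$cp_pct[need] <- n_to_cp(samples$n_pct[need], coeffs)
  }
  samples
}

#' Time-weighted feed quality over a period
#'
#' Feed samples represent the roughage on offer from their sampling date
#' until the next sample (a step function, last observation carried
#' forward); dates before the first sample take the first sample's value.
#' The value returned is the day-weighted mean of that step function over
#' the half-open period `[start, end)`.
#'
#' @param series a feed-series data.frame (`farmlet`, `feed_type`, `date`,
#'   `de_pct`, `cp_pct`).
#' @param farmlet,feed_type which sub-series to use.
#' @param start,end period bounds (`end` exclusive).
#' @return Named vector `c(de, cp)`.
#' @export
quality_at <- function(series, farmlet, feed_type, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop("period must have start < end")
  sub <- series[series$farmlet == farmlet & series$feed_type == feed_type, ,
                drop = FALSE]
  if (!nrow(sub))
    stop("no feed samples for farmlet ", farmlet, ", type ", feed_type)
  sub <- sub[order(sub$date), , drop = FALSE]
  # step boundaries clipped to the period
  cuts <- sort(unique(c(start, end, sub$date[sub$date > start &
                                               sub$date < end])))
  days <- as.numeric(diff(cuts))
  idx <- findInterval(as.numeric(cuts[-length(cuts)]),
                      as.numeric(sub$date))
  idx[idx == 0L] <- 1L  # before first sample: carry first value back
  c(de = sum(sub$de_pct[idx] * days) / sum(days),
    cp = sum(sub$cp_pct[idx] * days) / sum(days))
}
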