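#' Herd-level yearly summary statistics
#'
#' The pre-averaged performance variables a practitioner without
#' individual-animal data would work from: herd means of entry weight,
#' finishing weight, total growth, days on the platform and ADG, plus the
#' herd's housed-time fraction and the yearly-mean feed quality per feed
#' type.  Note that mean ADG times mean days does not equal mean growth
#' (ratio of means vs mean of ratios); the representative animal is built
#' from mean ADG and mean days, as averaged performance variables.
#'
#' @param herd `herd_records` for one farmlet.
#' @param feed feed series covering the farmlet.
#' @param housing_windows housing windows used to rebuild the
#'   representative animal's calendar; default annual 1 Oct – 30 Apr from
#'   the herd's first date.
#' @return An object of class `herd_summary`.
#' @export
herd_summary <- function(herd, feed,
                         housing_windows = default_housing_windows(
                           min(herd$date))) {
  farmlet <- unique(herd$farmlet)
  if (length(farmlet) != 1L)
    stop("herd_summary expects a single farmlet")
  by_a <- split(herd[order(herd$animal_id, herd$date), ], herd$animal_id)
  entry <- vapply(by_a, function(a) a$weight_kg[1], numeric(1))
  final <- vapply(by_a, function(a) a$weight_kg[nrow(a)], numeric(1))
  days <- vapply(by_a, function(a)
    as.numeric(a$date[nrow(a)] - a$date[1]), numeric(1))
  adg <- (final - entry) / days
  housed <- vapply(by_a, function(a) {
    d <- as.numeric(diff(a$date))
    sum(d[a$location[-nrow(a)] == "housing"])
  }, numeric(1))
  fmean <- function(ft, col) {
    v <- feed[feed$farmlet == farmlet & feed$feed_type == ft, col]
    if (!length(v)) stop("no ", ft, " samples for farmlet ", farmlet)
    mean(v)
  }
  structure(list(
    farmlet = farmlet, n_animals = length(by_a),
    entry_weight = mean(entry), finishing_weight = mean(final),
    total_growth = mean(final - entry), days = mean(days),
    adg = mean(adg), housed_frac = sum(housed) / sum(days),
    pasture_quality = c(de = fmean("pasture", "de_pct"),
                        cp = fmean("pasture", "cp_pct")),
    silage_quality = c(de = fmean("silage", "de_pct"),
                       cp = fmean("silage", "cp_pct")),
    entry_date = min(herd$date), sex = names(which.max(table(herd$sex))),
    housing_windows = housing_windows
  ), class = "herd_summary")
}

#' Weighing record of the pre-averaged representative animal
#'
#' One synthetic animal growing linearly at the herd-mean ADG from the
#' herd-mean entry weight for the herd-mean number of days, weighed on a
#' fixed cadence and housed by the same calendar windows as the herd.
#'
#' @param summary a [herd_summary()].
#' @param cadence days between the representative animal's weighings.
#' @return A `herd_records` data.frame for animal `"REP"`.
#' @export
representative_record <- function(summary, cadence = 21) {
  days <- round(summary$days)
  times <- unique(c(seq(0, days, by = cadence), days))
  dates <- summary$entry_date + times
  data.frame(
    animal_id = paste0(summary$farmlet, "_REP"), farmlet = summary$farmlet,
    sex = summary$sex, date = dates,
    weight_kg = summary$entry_weight + summary$adg * times,
    location = ifelse(in_housing(dates, summary$housing_windows),
                      "housing", "pasture"),
    stringsAsFactors = FALSE
  )
}

#' Emissions intensity of the representative animal
#'
#' Rebuilds the system around a single pre-averaged animal: the
#' representative record is run through the full Tier 2 engine under
#' yearly-mean feed quality (one constant value per feed type), its
#' pasture-deposition burdens are allocated exactly as for real animals,
#' and it carries the same per-head share of the farmlet pool.  The
#' resulting intensity is the "single value" a representative-animal
#' assessment would report.
#'
#' @param summary a [herd_summary()].
#' @param pool_co2e_per_animal cattle-share farmlet-pool burden per head,
#'   kg CO2-eq (e.g. characterized pool total x cattle share / n animals).
#' @param share cattle enterprise share in (0, 1].
#' @param params a [tier2_params()] set.
#' @param factors a [gwp_factors()] set.
#' @param cadence weighing cadence of the synthetic record, days.
#' @return A list with elements `ei`, `total_co2e_kg`, `lwg_kg`, `record`
#'   and `ledger`.
#' @export
representative_ei <- function(summary, pool_co2e_per_animal = 0,
                              share = 1, params = default_params(),
                              factors = gwp_factors("AR5"), cadence = 21) {
  rec <- representative_record(summary, cadence)
  feed <- rbind(
    data.frame(farmlet = summary$farmlet, feed_type = "pasture",
               date = summary$entry_date,
               de_pct = summary$pasture_quality[["de"]],
               cp_pct = summary$pasture_quality[["cp"]]),
    data.frame(farmlet = summary$farmlet, feed_type = "silage",
               date = summary$entry_date,
               de_pct = summary$silage_quality[["de"]],
               cp_pct = summary$silage_quality[["cp"]])
  )
  ledger <- animal_emissions(rec, feed, params)
  dep <- ledger$source %in% pasture_deposition_sources()
  ledger$mass_kg[dep] <- ledger$mass_kg[dep] * share
  chr <- characterize(ledger, factors)
  lwg <- rec$weight_kg[nrow(rec)] - rec$weight_kg[1]
  total <- attr(chr, "total_co2e") + pool_co2e_per_animal
  list(ei = total / lwg, total_co2e_kg = total, lwg_kg = lwg,
       record = rec, ledger = ledger)
}

#' Aggregation bias of the representative-animal approach
#'
#' Mean individual-animal emissions intensity minus the representative
#' animal's intensity.  For herds whose burden does not vary across animals
#' this is a Jensen gap and is non-negative, vanishing only when all
#' animals gain equally: intensity is convex in liveweight gain, so
#' averaging performance before computing intensity understates the mean.
#'
#' @param individual_eis per-animal intensities (NAs from non-finishing
#'   animals are dropped).
#' @param representative_ei the single pre-averaged value.
#' @return Bias in kg CO2-eq/kg LWG (positive = representative approach
#'   underestimates).
#' @export
aggregation_bias <- function(individual_eis, representative_ei) {
  eis <- individual_eis[!is.na(individual_eis)]
  if (!length(eis)) stop("no individual intensities supplied")
  mean(eis) - representative_ei
}

#' Monte Carlo specification
#'
#' Parameter uncertainty distributions for [monte_carlo()].  Multiplicative
#' lognormal perturbations (median 1, geometric SD `gsd`) suit emission
#' factors; additive truncated-normal perturbations (SD in percentage
#' points) suit feed quality.  Recognised targets: `ym`, `b0`, `mcf`,
#' `ef_n2o` (all N2O emission/partition factors together), `de_pct`,
#' `cp_pct`, `upstream` (all upstream factors together).
#'
#' @param n_iterations number of iterations (default 1000).
#' @param rng_seed integer seed.
#' @param distributions named list; each entry
#'   `list(type = "lognormal", gsd = )` or `list(type = "normal", sd = )`.
#' @return An object of class `mc_spec`.
#' @export
mc_spec <- function(n_iterations = 1000, rng_seed = 1L,
                    distributions = default_mc_distributions()) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  known <- c("ym", "b0", "mcf", "ef_n2o", "de_pct", "cp_pct", "upstream")
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    if (!nm %in% known)
      stop("unknown Monte Carlo parameter: ", nm)
    if (!d$type %in% c("lognormal", "normal"))
      stop("unknown distribution type for ", nm, ": ", d$type)
    if (d$type == "lognormal" && (is.null(d$gsd) || d$gsd < 1))
      stop("lognormal entry for ", nm, " needs gsd >= 1")
    if (d$type == "normal" && (is.null(d$sd) || d$sd < 0))
      stop("normal entry for ", nm, " needs sd >= 0")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 rng_seed = as.integer(rng_seed),
                 distributions = distributions), class = "mc_spec")
}

#' Default Monte Carlo distributions
#'
#' Assumed spreads (the study's own parameter distributions are not in the
#' public record): modest lognormal uncertainty on the methane conversion
#' factor and manure parameters, wider on N2O emission factors (whose
#' published ranges span factors of ~3), additive points on feed quality.
#'
#' @return Named list of distribution entries.
#' @export
default_mc_distributions <- function() {
  list(
    ym = list(type = "lognormal", gsd = 1.10),
    b0 = list(type = "lognormal", gsd = 1.15),
    mcf = list(type = "lognormal", gsd = 1.20),
    ef_n2o = list(type = "lognormal", gsd = 1.30),
    de_pct = list(type = "normal", sd = 2.0),
    cp_pct = list(type = "normal", sd = 1.5),
    upstream = list(type = "lognormal", gsd = 1.20)
  )
}

draw_mc_perturbation <- function(distributions) {
  out <- list()
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    out[[nm]] <- if (d$type == "lognormal") {
      if (d$gsd == 1) 1 else stats::rlnorm(1, 0, log(d$gsd))
    } else {
      if (d$sd == 0) 0 else stats::rnorm(1, 0, d$sd)
    }
  }
  out
}

apply_mc_perturbation <- function(pert, params, periods, efs) {
  p <- unclass(params)
  m <- function(nm) if (is.null(pert[[nm]]))
    if (nm %in% c("de_pct", "cp_pct")) 0 else 1 else pert[[nm]]
  p$ym <- pmin(p$ym * m("ym"), 14.99)
  p$b0 <- p$b0 * m("b0")
  p$mcf_deep_bedding <- min(p$mcf_deep_bedding * m("mcf"), 100)
  p$mcf_pasture <- min(p$mcf_pasture * m("mcf"), 100)
  for (nm in c("ef1_fertiliser", "ef3_deep_bedding", "ef3_prp_cattle",
               "ef3_prp_sheep", "ef4_volatilisation", "ef5_leaching"))
    p[[nm]] <- min(p[[nm]] * m("ef_n2o"), 1)
  params2 <- structure(p, provenance = attr(params, "provenance"),
                       class = "tier2_params")
  periods$de_pct <- pmin(pmax(periods$de_pct + m("de_pct"), 1), 99)
  periods$cp_pct <- pmin(pmax(periods$cp_pct + m("cp_pct"), 0.1), 99)
  efs2 <- efs
  for (k in names(efs2)) efs2[[k]]$ef <- efs2[[k]]$ef * m("upstream")
  list(params = params2, periods = periods, efs = efs2)
}

# mean individual EI (and optionally named animals' EIs) for one system
# under given parameters; lean path shared with run_pipeline
system_mean_ei <- function(periods, lwg, inv, params, efs, share, factors,
                           schedule, track = NULL) {
  pe <- period_emissions(periods, params)
  f <- factors
  dep_n2o <- (pe$n2o_prp_kg + pe$n2o_leach_kg) * share
  co2e <- (pe$enteric_ch4_kg + pe$manure_ch4_kg) * f[["CH4"]] +
    (pe$n2o_direct_kg + pe$n2o_volat_kg + dep_n2o) * f[["N2O"]]
  by_animal <- rowsum(co2e, pe$animal_id)
  pool <- characterize(farmlet_pool_emissions(inv, efs, params, schedule),
                       f)
  pool_per_head <- attr(pool, "total_co2e") * share / length(lwg)
  total <- by_animal[, 1] + pool_per_head
  ei <- total / lwg[rownames(by_animal)]
  ei <- ei[is.finite(ei) & lwg[names(ei)] > 0]
  out <- list(mean_ei = mean(ei))
  if (!is.null(track)) out$tracked <- ei[track]
  out
}

#' Monte Carlo uncertainty propagation
#'
#' Re-runs the full deterministic assessment under `n_iterations` joint
#' draws of the parameter perturbations in the spec, holding the herd and
#' weighing data fixed (livestock heterogeneity enters through the
#' per-animal engine, not the parameter draws).  Perturbations are shared
#' across systems within an iteration, as in paired LCA comparisons, so
#' pairwise exceedance fractions reflect parameter correlation correctly.
#'
#' @param config an [lca_config()]; data are generated/loaded once.
#' @param spec an [mc_spec()].
#' @param track_animals optional character vector of animal ids whose
#'   individual intensities are recorded each iteration.
#' @return An object of class `herd_mc`: `iterates` (data.frame, one column
#'   per system), `intervals` (2.5/50/97.5 percentiles per system),
#'   `pairwise` (fraction of iterations A > B and the two-sided exceedance
#'   p-value), optionally `animal_iterates`.
#' @export
monte_carlo <- function(config, spec = mc_spec(),
                        track_animals = NULL) {
  prep <- prepare_systems(config)
  share <- enterprise_shares(config$allocation)[["cattle"]]
  factors <- gwp_factors(config$gwp)
  set.seed(spec$rng_seed)
  systems <- names(prep)
  iter <- matrix(NA_real_, spec$n_iterations, length(systems),
                 dimnames = list(NULL, systems))
  animal_iter <- if (!is.null(track_animals))
    matrix(NA_real_, spec$n_iterations, length(track_animals),
           dimnames = list(NULL, track_animals))
  for (it in seq_len(spec$n_iterations)) {
    pert <- draw_mc_perturbation(spec$distributions)
    for (s in systems) {
      sy <- prep[[s]]
      ap <- apply_mc_perturbation(pert, config$params, sy$periods,
                                  config$upstream_efs)
      track <- if (!is.null(track_animals))
        intersect(track_animals, names(sy$lwg))
      res <- system_mean_ei(ap$periods, sy$lwg, sy$inventory, ap$params,
                            ap$efs, share, factors, config$reseeding,
                            track = track)
      iter[it, s] <- res$mean_ei
      if (!is.null(track) && length(track))
        animal_iter[it, track] <- res$tracked
    }
  }
  qs <- apply(iter, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 7)
  intervals <- data.frame(system = systems, lo = qs[1, ], median = qs[2, ],
                          hi = qs[3, ], row.names = NULL)
  pairwise <- if (length(systems) < 2) {
    data.frame(a = character(), b = character(), frac_a_gt_b = numeric(),
               p_two_sided = numeric())
  } else do.call(rbind, lapply(utils::combn(systems, 2, simplify = FALSE),
                               function(pr) {
    fr <- mean(iter[, pr[1]] > iter[, pr[2]])
    data.frame(a = pr[1], b = pr[2], frac_a_gt_b = fr,
               p_two_sided = min(1, 2 * min(fr, 1 - fr)),
               stringsAsFactors = FALSE)
  }))
  structure(list(iterates = as.data.frame(iter),
                 animal_iterates = if (!is.null(track_animals))
                   as.data.frame(animal_iter),
                 intervals = intervals, pairwise = pairwise, spec = spec),
            class = "herd_mc")
}

#' Statistical interpretation of per-animal results
#'
#' One-way ANOVA across systems on intensity and on ADG, pairwise Welch
#' t-tests on intensity, Pearson correlation of intensity with ADG within
#' each system, and steer-vs-heifer contrasts on intensity, total gain and
#' days on platform.  Degenerate groups (fewer than two animals or zero
#' variance) skip the affected test with a warning.
#'
#' @param results an [ei_results()] table (any number of systems).
#' @param var_equal use the exact Student variant instead of Welch for the
#'   pairwise tests.
#' @return An object of class `comparison_report` with elements
#'   `anova_ei`, `anova_adg`, `pairwise_ei`, `correlations`,
#'   `sex_contrasts`, `spread`.
#' @export
interpret <- function(results, var_equal = FALSE) {
  res <- results[!is.na(results$ei), , drop = FALSE]
  systems <- sort(unique(res$farmlet))
  grp_ok <- vapply(systems, function(s) {
    x <- res$ei[res$farmlet == s]
    length(x) >= 2 && stats::var(x) > 0
  }, logical(1))
  one_way <- function(col) {
    if (sum(grp_ok) < 2) {
      warning("ANOVA skipped: fewer than two non-degenerate groups")
      return(data.frame(F = NA_real_, p = NA_real_))
    }
    fit <- stats::aov(res[[col]] ~ factor(res$farmlet))
    s <- summary(fit)[[1]]
    data.frame(F = s$`F value`[1], p = s$`Pr(>F)`[1])
  }
  pairwise <- if (length(systems) < 2) {
    data.frame(a = character(), b = character(), diff = numeric(),
               t = numeric(), p = numeric())
  } else do.call(rbind, lapply(
    utils::combn(systems, 2, simplify = FALSE), function(pr) {
      x <- res$ei[res$farmlet == pr[1]]
      y <- res$ei[res$farmlet == pr[2]]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::var(x) == 0 && stats::var(y) == 0)) {
        warning("t-test skipped for ", pr[1], " vs ", pr[2])
        return(data.frame(a = pr[1], b = pr[2], diff = NA_real_,
                          t = NA_real_, p = NA_real_))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(a = pr[1], b = pr[2], diff = mean(x) - mean(y),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  correlations <- do.call(rbind, lapply(systems, function(s) {
    d <- res[res$farmlet == s, ]
    if (nrow(d) < 3 || stats::var(d$ei) == 0 || stats::var(d$adg) == 0) {
      warning("correlation skipped for system ", s)
      return(data.frame(system = s, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(d$ei, d$adg)
    data.frame(system = s, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  sex_vars <- c(ei = "ei", lwg = "lwg_kg", days = "days")
  sex_contrasts <- do.call(rbind, lapply(systems, function(s) {
    d <- res[res$farmlet == s, ]
    do.call(rbind, lapply(names(sex_vars), function(v) {
      col <- sex_vars[[v]]
      x <- d[[col]][d$sex == "steer"]
      y <- d[[col]][d$sex == "heifer"]
      if (length(x) < 2 || length(y) < 2 ||
          (stats::var(x) == 0 && stats::var(y) == 0))
        return(data.frame(system = s, variable = v, diff = NA_real_,
                          t = NA_real_, p = NA_real_))
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(system = s, variable = v, diff = mean(x) - mean(y),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  spread <- do.call(rbind, lapply(systems, function(s) {
    e <- res$ei[res$farmlet == s]
    data.frame(system = s, best = min(e), worst = max(e),
               spread_pct = (max(e) - min(e)) / min(e) * 100,
               stringsAsFactors = FALSE)
  }))
  structure(list(anova_ei = one_way("ei"), anova_adg = one_way("adg"),
                 pairwise_ei = pairwise, correlations = correlations,
                 sex_contrasts = sex_contrasts, spread = spread),
            class = "comparison_report")
}
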