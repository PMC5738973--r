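# Worksheet-style oracle for the Tier 2 chain: straight-line scalar
# arithmetic with literal constants, written independently of the package
# internals.  Takes one period's conditions and returns every source mass.
oracle_period <- function(mean_w, adg, days, de, cp, location, sex,
                          p = oracle_params()) {
  nem <- p$cfi * mean_w^0.75
  nea <- if (location == "pasture") p$ca_pasture * nem else 0
  cg <- if (sex == "steer") p$c_steer else p$c_heifer
  mw <- if (sex == "steer") p$mw_steer else p$mw_heifer
  neg <- if (adg > 0) 22.02 * (mean_w / (cg * mw))^0.75 * adg^1.097 else 0
  rem <- 1.123 - 0.004092 * de + 0.00001126 * de^2 - 25.4 / de
  reg <- 1.164 - 0.005160 * de + 0.00001308 * de^2 - 37.4 / de
  ge <- ((nem + nea) / rem + neg / reg) / (de / 100)
  ym <- if (location == "pasture") p$ym_pasture else p$ym_housing
  ch4_enteric <- ge * days * (ym / 100) / 55.65
  vs_day <- (ge * (1 - de / 100) + p$urinary * ge) * (1 - p$ash) / 18.45
  mcf <- if (location == "housing") p$mcf_housing else p$mcf_pasture
  ch4_manure <- vs_day * days * p$b0 * 0.67 * mcf / 100
  n_in <- (ge / 18.45) * (cp / 100) / 6.25
  n_ret <- if (adg > 0) adg * (268 - 7.03 * neg / adg) / 1000 / 6.25 else 0
  if (n_ret < 0) n_ret <- 0
  n_ex <- max(n_in - n_ret, 0) * days
  to_n2o <- 44 / 28
  if (location == "housing") {
    n2o_direct <- n_ex * p$ef3_housing * to_n2o
    n2o_volat <- n_ex * p$frac_gas * p$ef4 * to_n2o
    n2o_prp <- 0; n2o_leach <- 0
  } else {
    n2o_prp <- n_ex * p$ef3_prp * to_n2o
    n2o_leach <- n_ex * p$frac_leach * p$ef5 * to_n2o
    n2o_direct <- 0; n2o_volat <- 0
  }
  c(ge = ge, enteric_ch4 = ch4_enteric, manure_ch4 = ch4_manure,
    n_ex = n_ex, n2o_direct = n2o_direct, n2o_volat = n2o_volat,
    n2o_prp = n2o_prp, n2o_leach = n2o_leach)
}

# literal constants matching the shipped defaults, restated by hand
oracle_params <- function() {
  list(cfi = 0.322, ca_pasture = 0.17, c_steer = 1.0, c_heifer = 0.8,
       mw_steer = 680, mw_heifer = 580, ym_pasture = 6.5, ym_housing = 6.5,
       urinary = 0.04, ash = 0.08, b0 = 0.17, mcf_housing = 20,
       mcf_pasture = 1, ef3_housing = 0.01, ef3_prp = 0.02, ef4 = 0.01,
       ef5 = 0.0075, frac_gas = 0.30, frac_leach = 0.30)
}

# whole-herd oracle totals per animal and source for the toy herd above,
# under constant feed quality (pasture 72/18, silage 65/12)
oracle_toy_totals <- function(herd, pasture = c(72, 18),
                              silage = c(65, 12)) {
  herd <- herd[order(herd$animal_id, herd$date), ]
  out <- list()
  for (id in unique(herd$animal_id)) {
    a <- herd[herd$animal_id == id, ]
    tot <- c(enteric_ch4 = 0, manure_ch4 = 0, n2o_direct = 0,
             n2o_volat = 0, n2o_prp = 0, n2o_leach = 0)
    for (i in seq_len(nrow(a) - 1)) {
      days <- as.numeric(a$date[i + 1] - a$date[i])
      q <- if (a$location[i] == "housing") silage else pasture
      res <- oracle_period(
        mean_w = (a$weight_kg[i] + a$weight_kg[i + 1]) / 2,
        adg = (a$weight_kg[i + 1] - a$weight_kg[i]) / days,
        days = days, de = q[1], cp = q[2],
        location = a$location[i], sex = a$sex[i]
      )
      tot <- tot + res[names(tot)]
    }
    out[[id]] <- tot
  }
  out
}
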