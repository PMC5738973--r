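p0 <- default_params()

mk_period <- function(mean_weight = 400, period_adg = 0.8, days = 10,
                      de_pct = 70, cp_pct = 20, sex = "steer",
                      location = "housing") {
  data.frame(mean_weight = mean_weight, period_adg = period_adg,
             days = days, de_pct = de_pct, cp_pct = cp_pct, sex = sex,
             location = location, stringsAsFactors = FALSE)
}

test_that("weighing records split into clean half-open periods", {
  herd <- toy_herd()
  feed <- constant_feed()
  per <- periods_from_record(herd, feed)
  a1 <- per[per$animal_id == "A1", ]
  expect_equal(nrow(a1), 2)
  expect_equal(a1$days, c(21, 21))
  expect_equal(a1$period_adg[1], 1.0)
  expect_equal(a1$mean_weight[1], 310.5)
  # 4 events -> 3 periods, contiguous partition
  a3 <- per[per$animal_id == "A3", ]
  expect_equal(nrow(a3), 3)
  expect_equal(a3$start[-1], a3$end[-nrow(a3)])
  # zero-gain period is retained with adg = 0
  a2 <- per[per$animal_id == "A2", ]
  expect_equal(a2$period_adg[1], 0)
  # feed quality attached by location: housed periods get silage values
  expect_true(all(per$de_pct[per$location == "housing"] == 65))
  expect_true(all(per$de_pct[per$location == "pasture"] == 72))

  dup <- herd
  dup$date[2] <- dup$date[1]
  expect_error(periods_from_record(dup, feed), "duplicate.*A1")
  expect_error(periods_from_record(herd[1, ], feed))
})

test_that("gross energy follows the Tier 2 energy chain", {
  # maintenance-only limit: zero gain, housed (no activity allowance)
  per <- mk_period(period_adg = 0, location = "housing")
  nem <- 0.322 * 400^0.75
  rem <- 1.123 - 0.004092 * 70 + 0.00001126 * 70^2 - 25.4 / 70
  expect_equal(gross_energy_intake(per, p0), nem / rem / 0.70)
  expect_equal(nem, 28.80, tolerance = 1e-4)

  # weight-loss periods also collapse to maintenance (NEg floored at 0)
  expect_equal(gross_energy_intake(mk_period(period_adg = -0.3), p0),
               gross_energy_intake(mk_period(period_adg = 0), p0))

  # full chain equals the worksheet oracle, grazing steer
  per2 <- mk_period(location = "pasture")
  ora <- oracle_period(400, 0.8, 10, 70, 20, "pasture", "steer")
  expect_equal(gross_energy_intake(per2, p0), ora[["ge"]],
               tolerance = 1e-12)

  expect_error(gross_energy_intake(mk_period(de_pct = 0), p0), "\\(0, 100\\)")
  expect_error(gross_energy_intake(mk_period(de_pct = 100), p0))
})

test_that("enteric methane is the GE-Ym-energy identity", {
  expect_equal(enteric_ch4(100, 0, 10), 0)
  expect_equal(enteric_ch4(55.65, 100, 1), 1.0)
  expect_equal(enteric_ch4(250, 6.5, 10), 250 * 10 * 0.065 / 55.65)
  expect_equal(enteric_ch4(250, 6.5, 10), 2.920, tolerance = 1e-4)
  # strictly increasing in GE
  ge <- seq(100, 300, by = 25)
  expect_true(all(diff(enteric_ch4(ge, 6.5, 10)) > 0))
})

test_that("manure methane follows the volatile-solids chain", {
  p <- p0
  p$urinary_energy_frac <- 0
  p$ash_frac <- 0
  # fully digestible feed and no urinary energy: no volatile solids
  expect_equal(manure_ch4(200, 100, 10, p, "housing"), 0)
  # unit definition: GE 18.45 MJ/d at DE 0 gives 1 kg VS/day
  expect_equal(volatile_solids(18.45, 0, p), 1)
  p$b0 <- 0.18
  expect_equal(manure_ch4(18.45, 0, 1, p, "housing"),
               1 * 0.18 * 0.67 * 20 / 100)  # 0.02412
  # grazing excreta use the (much smaller) pasture MCF
  expect_equal(manure_ch4(18.45, 0, 1, p, "pasture"),
               1 * 0.18 * 0.67 * 1 / 100)
  # decreasing in DE at fixed GE
  de <- seq(50, 80, by = 5)
  ch4 <- manure_ch4(rep(250, length(de)), de, 10, p0, "housing")
  expect_true(all(diff(ch4) < 0))
})

test_that("nitrogen excretion floors retention for non-growing animals", {
  per <- mk_period()
  expect_equal(n_excretion(250, 0, per, p0), 0)
  # no retention when losing weight: excretion = intake
  per_loss <- mk_period(period_adg = -0.1)
  intake_day <- (250 / 18.45) * (20 / 100) / 6.25
  expect_equal(n_excretion(250, 20, per_loss, p0), intake_day * 10)
  # growing animal matches the worksheet oracle
  ora <- oracle_period(400, 0.8, 10, 70, 20, "housing", "steer")
  ge <- gross_energy_intake(per, p0)
  expect_equal(n_excretion(ge, 20, per, p0), ora[["n_ex"]],
               tolerance = 1e-12)
  expect_lt(n_excretion(ge, 20, per, p0), intake_day * 10)
})

test_that("excreted N routes into the four N2O pathways", {
  z <- manure_n2o(0, "housing", p0)
  expect_equal(z$mass_kg, c(0, 0))
  p_zero <- p0
  for (nm in c("ef3_deep_bedding", "ef3_prp_cattle", "ef4_volatilisation",
               "ef5_leaching"))
    p_zero[[nm]] <- 0
  expect_equal(manure_n2o(c(10, 20), c("housing", "pasture"),
                          p_zero)$mass_kg, rep(0, 4))
  # hand calculation: 100 kg housed N at EF3 = 0.01
  h <- manure_n2o(100, "housing", p0)
  expect_equal(h$mass_kg[h$source == "Manure management (direct N2O)"],
               100 * 0.01 * 44 / 28)
  expect_equal(h$mass_kg[h$source == "Manure management (direct N2O)"],
               1.571, tolerance = 1e-3)
  g <- manure_n2o(100, "pasture", p0)
  expect_setequal(g$source,
                  c("Urine and dung from cattle on pasture (N2O)",
                    "Indirect emissions from leaching (N2O)"))
  expect_equal(g$mass_kg[2], 100 * 0.30 * 0.0075 * 44 / 28)
})

test_that("emissions are additive over a re-partition of time", {
  d <- as.Date("2014-11-01")
  feed <- constant_feed()
  whole <- data.frame(animal_id = "B", farmlet = "PP", sex = "steer",
                      date = d + c(0, 28), weight_kg = c(400, 400),
                      location = "housing", stringsAsFactors = FALSE)
  split2 <- data.frame(animal_id = "B", farmlet = "PP", sex = "steer",
                       date = d + c(0, 14, 28), weight_kg = c(400, 400, 400),
                       location = "housing", stringsAsFactors = FALSE)
  tot <- function(h) {
    led <- animal_emissions(h, feed, p0)
    tapply(led$mass_kg, led$source, sum)
  }
  expect_equal(tot(whole), tot(split2), tolerance = 1e-12)
})

test_that("engine output matches the worksheet oracle to 6 significant figures", {
  herd <- toy_herd()
  led <- animal_emissions(herd, constant_feed(), p0)
  ora <- oracle_toy_totals(herd)
  src_map <- c(enteric_ch4 = "Enteric fermentation (CH4)",
               manure_ch4 = "Manure management (CH4)",
               n2o_direct = "Manure management (direct N2O)",
               n2o_volat = "Manure management (indirect volatilisation N2O)",
               n2o_prp = "Urine and dung from cattle on pasture (N2O)",
               n2o_leach = "Indirect emissions from leaching (N2O)")
  for (id in names(ora)) {
    for (k in names(src_map)) {
      got <- sum(led$mass_kg[led$owner_id == id &
                               led$source == src_map[[k]]])
      expect_equal(got, unname(ora[[id]][k]), tolerance = 5e-7,
                   label = paste(id, k))
    }
  }
  # every emitted label belongs to the registry with a matching gas
  reg <- source_registry()
  expect_true(all(paste(led$source, led$gas) %in%
                    paste(reg$source, reg$gas)))
  # liveweight gains recorded alongside
  expect_equal(attr(led, "lwg")[["A1"]], 39)
})

test_that("near-zero gain drives intensity up without blowing up emissions", {
  feed <- constant_feed()
  d <- as.Date("2014-11-01")
  mk <- function(gain) {
    data.frame(animal_id = "Z", farmlet = "PP", sex = "steer",
               date = d + c(0, 28), weight_kg = c(400, 400 + gain),
               location = "housing", stringsAsFactors = FALSE)
  }
  eis <- vapply(c(28, 2.8, 0.28), function(g) {
    led <- characterize(animal_emissions(mk(g), feed, p0))
    attr(led, "total_co2e") / g
  }, numeric(1))
  tot <- vapply(c(28, 2.8, 0.28), function(g) {
    attr(characterize(animal_emissions(mk(g), feed, p0)), "total_co2e")
  }, numeric(1))
  expect_true(all(is.finite(tot)))
  expect_lt(diff(tot)[1] / tot[1], 0.2)  # emissions barely move
  expect_gt(eis[2] / eis[1], 5)          # intensity explodes hyperbolically
  expect_gt(eis[3] / eis[2], 5)
})
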