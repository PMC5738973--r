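single_system_config <- function(n = 8, seed = 1L, adg_sd = 0.10,
                                 mc = NULL, representative = TRUE) {
  lca_config(
    herd_specs = list(PP = herd_spec("PP", n_animals = n,
                                     entry_weight_mean = 279,
                                     entry_weight_sd = 32.08,
                                     adg_mean = 0.76, adg_sd = adg_sd,
                                     rng_seed = seed)),
    feed_specs = list(PP = feed_specs_from_table1("PP", rng_seed = seed)),
    inventories = list(PP = toy_inventory()),
    mc = mc, representative = representative, seed = seed
  )
}

test_that("a homogeneous herd shows no aggregation bias", {
  s <- herd_spec("PP", n_animals = 4, entry_weight_sd = 0, adg_mean = 0.8,
                 adg_sd = 0, days_sd = 0, sex_ratio = 0,
                 weighing_interval = 21,
                 growth_shape = c(dip = 1, peak = 1, peak_at = 0.5, end = 1),
                 rng_seed = 2L)
  herd <- generate_herd(s)
  feed <- constant_feed()
  al <- animal_emissions(herd, feed)
  chr <- characterize(al)
  ind_ei <- tapply(chr$co2e_kg, chr$owner_id, sum) / animal_lwg(herd)
  expect_lt(diff(range(ind_ei)), 1e-9)

  summ <- herd_summary(herd, feed)
  rep <- representative_ei(summ, pool_co2e_per_animal = 0, share = 1)
  expect_equal(rep$ei, unname(ind_ei[1]), tolerance = 1e-9)
  expect_equal(aggregation_bias(ind_ei, rep$ei), 0, tolerance = 1e-9)
})

test_that("the two-animal toy shows the hand-computed Jensen gap", {
  # constant burden 100, gains 100 and 300 kg
  ind <- emissions_intensity(c(100, 100), c(100, 300))
  expect_equal(mean(ind), 2 / 3)
  rep_ei <- 100 / mean(c(100, 300))
  expect_equal(rep_ei, 0.5)
  expect_equal(aggregation_bias(ind, rep_ei), 1 / 6)
  expect_error(aggregation_bias(numeric(0), 1), "no individual")
})

test_that("constant-burden herds obey Jensen's inequality", {
  set.seed(7)
  for (k in 1:50) {
    n <- sample(3:30, 1)
    lwg <- runif(n, 50, 400)
    burden <- runif(1, 1000, 9000)
    bias <- aggregation_bias(emissions_intensity(rep(burden, n), lwg),
                             burden / mean(lwg))
    expect_gte(bias, 0)
  }
})

test_that("representative recalculation under-states the individual mean on a heterogeneous herd", {
  run <- run_pipeline(single_system_config(n = 20, seed = 31L))
  rep <- run$representative
  expect_equal(rep$mean_individual_ei,
               mean(run$results$ei, na.rm = TRUE))
  expect_gt(rep$bias, 0)
  expect_equal(rep$bias, rep$mean_individual_ei - rep$representative_ei)
})

test_that("Monte Carlo with zero spreads reproduces the deterministic run", {
  cfg <- single_system_config(n = 6, seed = 4L, representative = FALSE)
  det <- mean(run_pipeline(cfg)$results$ei, na.rm = TRUE)
  flat <- mc_spec(n_iterations = 10, rng_seed = 1L,
                  distributions = list(
                    ym = list(type = "lognormal", gsd = 1),
                    de_pct = list(type = "normal", sd = 0)))
  mc <- monte_carlo(cfg, flat)
  expect_equal(unique(round(mc$iterates$PP, 12)), round(det, 12))
})

test_that("Monte Carlo is seed-reproducible and distribution-validated", {
  cfg <- single_system_config(n = 6, seed = 4L, representative = FALSE)
  spec <- mc_spec(n_iterations = 25, rng_seed = 9L)
  expect_identical(monte_carlo(cfg, spec)$iterates,
                   monte_carlo(cfg, spec)$iterates)
  expect_error(mc_spec(distributions = list(
    foo = list(type = "lognormal", gsd = 1.1))), "unknown Monte Carlo")
  expect_error(mc_spec(distributions = list(
    ym = list(type = "cauchy", scale = 1))), "unknown distribution type")
  expect_error(mc_spec(distributions = list(
    ym = list(type = "lognormal", gsd = 0.5))), "gsd")
  expect_error(mc_spec(n_iterations = 0), "n_iterations")
})

test_that("lognormal Ym uncertainty keeps the median at the deterministic run", {
  cfg <- single_system_config(n = 6, seed = 4L, representative = FALSE)
  det <- mean(run_pipeline(cfg)$results$ei, na.rm = TRUE)
  mc <- monte_carlo(cfg, mc_spec(n_iterations = 200, rng_seed = 5L,
                                 distributions = list(
                                   ym = list(type = "lognormal",
                                             gsd = 1.1))))
  x <- mc$iterates$PP
  se_median <- 1.2533 * sd(x) / sqrt(length(x))
  expect_lt(abs(median(x) - det), 3 * se_median)
})

test_that("Monte Carlo intervals widen with the parameter spread", {
  cfg <- single_system_config(n = 6, seed = 4L, representative = FALSE)
  width <- function(gsd) {
    mc <- monte_carlo(cfg, mc_spec(n_iterations = 120, rng_seed = 11L,
                                   distributions = list(
                                     ym = list(type = "lognormal",
                                               gsd = gsd))))
    with(mc$intervals, hi - lo)
  }
  expect_gt(width(1.2), width(1.05))
})

test_that("the worst performer carries wider Monte Carlo uncertainty than the best", {
  cfg <- single_system_config(n = 20, seed = 31L, representative = FALSE)
  run <- run_pipeline(cfg)
  res <- run$results[!is.na(run$results$ei), ]
  best <- res$animal_id[which.min(res$ei)]
  worst <- res$animal_id[which.max(res$ei)]
  mc <- monte_carlo(cfg, mc_spec(n_iterations = 120, rng_seed = 13L),
                    track_animals = c(best, worst))
  iq <- apply(mc$animal_iterates, 2, function(x)
    diff(quantile(x, c(0.025, 0.975))))
  expect_gt(iq[[worst]], iq[[best]])
})

test_that("identical groups give a null F statistic", {
  base <- data.frame(animal_id = sprintf("a%d", 1:5), sex = "steer",
                     days = 400, adg = c(0.5, 0.6, 0.7, 0.8, 0.9),
                     lwg_kg = 300, total_co2e_kg = 4000,
                     ei = c(10, 12, 14, 16, 18), stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(c("A", "B", "C"), function(f)
    transform(base, farmlet = f)))
  rep <- interpret(res)
  expect_equal(rep$anova_ei$F, 0)
  expect_equal(rep$anova_ei$p, 1)
  expect_equal(rep$pairwise_ei$diff, rep(0, 3))
})

test_that("intensity built as c/ADG correlates strongly negatively with ADG", {
  set.seed(3)
  adg <- runif(30, 0.5, 0.9)
  res <- data.frame(animal_id = sprintf("a%d", 1:30), farmlet = "A",
                    sex = "steer", days = 400, adg = adg, lwg_kg = 300,
                    total_co2e_kg = 1, ei = 10 / adg,
                    stringsAsFactors = FALSE)
  rep <- suppressWarnings(interpret(res))
  expect_lt(rep$correlations$r, -0.9)
  expect_lt(rep$correlations$p, 0.001)
})

test_that("Pearson r matches the textbook hand computation", {
  res <- data.frame(animal_id = sprintf("a%d", 1:5), farmlet = "A",
                    sex = "steer", days = 400, adg = c(1, 2, 3, 4, 5),
                    lwg_kg = 300, total_co2e_kg = 1, ei = c(2, 4, 5, 4, 5),
                    stringsAsFactors = FALSE)
  # r = 6 / sqrt(10 * 6) computed by hand from the deviations
  expect_equal(suppressWarnings(interpret(res))$correlations$r,
               6 / sqrt(60),
               tolerance = 1e-12)
})

test_that("degenerate groups are skipped with a warning", {
  res <- data.frame(animal_id = c("a1", "a2", "b1"),
                    farmlet = c("A", "A", "B"), sex = "steer", days = 400,
                    adg = c(0.7, 0.8, 0.75), lwg_kg = 300,
                    total_co2e_kg = 1, ei = c(10, 12, 11),
                    stringsAsFactors = FALSE)
  w <- capture_warnings(rep <- interpret(res))
  expect_true(any(grepl("skipped", w)))
  expect_true(is.na(rep$pairwise_ei$p[1]))
})

test_that("sex contrasts are reported per system", {
  set.seed(8)
  res <- data.frame(animal_id = sprintf("a%d", 1:20), farmlet = "A",
                    sex = rep(c("steer", "heifer"), each = 10), days = 400,
                    adg = 0.7, lwg_kg = rep(c(340, 280), each = 10) +
                      rnorm(20, 0, 5),
                    total_co2e_kg = 1, stringsAsFactors = FALSE)
  res$ei <- 5000 / res$lwg_kg
  rep <- suppressWarnings(interpret(res))
  lwg_row <- rep$sex_contrasts[rep$sex_contrasts$variable == "lwg", ]
  expect_gt(lwg_row$diff, 0)    # steers gain more
  expect_lt(lwg_row$p, 0.001)
  ei_row <- rep$sex_contrasts[rep$sex_contrasts$variable == "ei", ]
  expect_lt(ei_row$diff, 0)     # and so run a lower intensity
})
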