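test_that("seeded herd generation is bit-reproducible", {
  s <- herd_spec("PP", n_animals = 10, rng_seed = 1L)
  expect_identical(generate_herd(s), generate_herd(s))
  s2 <- herd_spec("PP", n_animals = 10, rng_seed = 2L)
  expect_false(identical(generate_herd(s), generate_herd(s2)))
})

test_that("degenerate spec yields identical animals with exact ADG", {
  s <- herd_spec("PP", n_animals = 5, entry_weight_sd = 0, adg_mean = 0.8,
                 adg_sd = 0, days_sd = 0, sex_ratio = 1,
                 weighing_interval = 21,
                 growth_shape = c(dip = 1, peak = 1, peak_at = 0.5, end = 1),
                 rng_seed = 3L)
  herd <- generate_herd(s)
  by_a <- split(herd, herd$animal_id)
  trajs <- lapply(by_a, function(a) a[c("date", "weight_kg")])
  for (tr in trajs[-1]) expect_equal(tr, trajs[[1]],
                                     ignore_attr = "row.names")
  a1 <- by_a[[1]]
  adg <- (a1$weight_kg[nrow(a1)] - a1$weight_kg[1]) /
    as.numeric(a1$date[nrow(a1)] - a1$date[1])
  expect_equal(adg, 0.8, tolerance = 1e-12)
})

test_that("weighing records are well-formed and finish heaviest", {
  herd <- generate_herd(herd_spec("HS", n_animals = 20, rng_seed = 11L))
  for (a in split(herd, herd$animal_id)) {
    expect_true(all(diff(as.numeric(a$date)) >= 1))
    expect_true(all(diff(as.numeric(a$date)) <= 28))
    expect_true(all(a$weight_kg > 0))
    # the sale weighing is the first at/above the animal's own threshold,
    # which the mean trajectory reaches on its final day
    expect_equal(which.max(a$weight_kg), nrow(a))
  }
  expect_true(all(herd$location %in% c("pasture", "housing")))
  # October entry weighings fall in the housing window
  expect_true(all(herd$location[herd$date == min(herd$date)] == "housing"))
})

test_that("periods can lose weight when adg_sd > 0", {
  herd <- generate_herd(herd_spec("PP", n_animals = 30, adg_sd = 0.15,
                                  rng_seed = 5L))
  gains <- unlist(lapply(split(herd, herd$animal_id),
                         function(a) diff(a$weight_kg)))
  expect_true(any(gains < 0))
})

test_that("finishing weights spread around the sex targets", {
  herd <- generate_herd(herd_spec("PP", n_animals = 200, rng_seed = 17L))
  final <- vapply(split(herd, herd$animal_id),
                  function(a) a$weight_kg[nrow(a)], numeric(1))
  sex <- vapply(split(herd, herd$animal_id),
                function(a) a$sex[1], character(1))
  fs <- final[sex == "steer"]
  expect_lt(abs(mean(fs) - 620), 3 * 60 / sqrt(length(fs)) + 5)
  expect_gt(sd(fs), 30)   # sale-weight heterogeneity present
  expect_lt(sd(fs), 90)

  # time-to-finish is spread but uncorrelated with growth rate
  days <- vapply(split(herd, herd$animal_id), function(a)
    as.numeric(a$date[nrow(a)] - a$date[1]), numeric(1))
  adg <- (final - vapply(split(herd, herd$animal_id),
                         function(a) a$weight_kg[1], numeric(1))) / days
  expect_gt(sd(days), 20)
  expect_lt(abs(cor(days, adg)), 0.3)
})

test_that("herd statistics converge to spec values at large n", {
  n <- 3000
  s <- herd_spec("PP", n_animals = n, entry_weight_mean = 279,
                 entry_weight_sd = 32.08, adg_mean = 0.76, adg_sd = 0.10,
                 rng_seed = 99L)
  herd <- generate_herd(s)
  by_a <- split(herd, herd$animal_id)
  adg <- vapply(by_a, function(a)
    (a$weight_kg[nrow(a)] - a$weight_kg[1]) /
      as.numeric(a$date[nrow(a)] - a$date[1]), numeric(1))
  entry <- vapply(by_a, function(a) a$weight_kg[1], numeric(1))
  expect_lt(abs(mean(adg) - 0.76), 3 * 0.10 / sqrt(n))
  expect_lt(abs(sd(adg) - 0.10), 3 * 0.10 / sqrt(2 * n))
  expect_lt(abs(mean(entry) - 279), 3 * 32.08 / sqrt(n))
})

test_that("a herd from the printed performance statistics recovers ADG", {
  herd <- generate_herd(herd_spec_from_table2("PP", rng_seed = 21L))
  by_a <- split(herd, herd$animal_id)
  adg <- vapply(by_a, function(a)
    (a$weight_kg[nrow(a)] - a$weight_kg[1]) /
      as.numeric(a$date[nrow(a)] - a$date[1]), numeric(1))
  expect_equal(length(adg), 30)
  expect_lt(abs(mean(adg) - 0.76), 3 * 0.10 / sqrt(30))
})

test_that("invalid herd specs are rejected", {
  expect_error(herd_spec("PP", adg_mean = 0), "adg_mean")
  expect_error(herd_spec("PP", adg_mean = -0.5), "adg_mean")
  expect_error(herd_spec("PP", weighing_interval = c(7, 21)),
               "weighing_interval")
  expect_error(herd_spec("PP", n_animals = 0))
  expect_error(herd_spec("PP", adg_sd = -1))
})

test_that("feed series: degenerate, printed-mean and seeded behaviour", {
  flat <- feed_spec("PP", "pasture", de_mean = 70, de_sd = 0, cp_mean = 18,
                    cp_sd = 0, seasonal_amplitude = 0)
  fs <- generate_feed_series(flat, "2014-10-01", "2015-10-01")
  expect_true(all(fs$de_pct == 70))
  expect_true(all(fs$cp_pct == 18))

  # sd -> 0 with a full-year span: seasonal sinusoid averages out
  t1 <- feed_spec("PP", "pasture", de_mean = 77.55, de_sd = 0,
                  cp_mean = 20.72, cp_sd = 0, seasonal_amplitude = 3)
  fy <- generate_feed_series(t1, "2014-10-01", "2015-09-30")
  expect_equal(mean(fy$de_pct), 77.55, tolerance = 0.01)
  expect_equal(mean(fy$cp_pct), 20.72, tolerance = 0.01)

  noisy <- feed_spec("PP", "pasture", de_mean = 70, cp_mean = 18,
                     rng_seed = 1L)
  noisy2 <- feed_spec("PP", "pasture", de_mean = 70, cp_mean = 18,
                      rng_seed = 2L)
  a <- generate_feed_series(noisy, "2014-10-01", "2015-10-01")
  b <- generate_feed_series(noisy2, "2014-10-01", "2015-10-01")
  expect_false(identical(a$de_pct, b$de_pct))
  expect_identical(a, generate_feed_series(noisy, "2014-10-01",
                                           "2015-10-01"))

  # interval >= span: single sample at start
  one <- generate_feed_series(flat, "2014-10-01", "2014-10-10")
  expect_equal(nrow(one), 1)
  expect_equal(one$date, as.Date("2014-10-01"))
})

test_that("herd and feed CSV round-trips preserve the data", {
  herd <- generate_herd(herd_spec("PP", n_animals = 3, rng_seed = 1L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_herd_csv(herd, tmp)
  back <- read_herd_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(herd), tolerance = 1e-12)

  fs <- generate_feed_series(feed_spec("PP", "silage", de_mean = 65,
                                       cp_mean = 12, rng_seed = 2L),
                             "2014-10-01", "2015-04-01")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_feed_csv(fs, tmp2)
  expect_equal(as.data.frame(read_feed_csv(tmp2)), as.data.frame(fs),
               tolerance = 1e-12)
})
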