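# small in-code fixtures shared across test files

# constant-quality feed series: one sample per feed type, LOCF makes it flat
constant_feed <- function(farmlet = "PP", date = as.Date("2014-10-01"),
                          pasture_de = 72, pasture_cp = 18,
                          silage_de = 65, silage_cp = 12) {
  rbind(
    data.frame(farmlet = farmlet, feed_type = "pasture", date = date,
               de_pct = pasture_de, cp_pct = pasture_cp,
               stringsAsFactors = FALSE),
    data.frame(farmlet = farmlet, feed_type = "silage", date = date,
               de_pct = silage_de, cp_pct = silage_cp,
               stringsAsFactors = FALSE)
  )
}

# hand-laid-out three-animal herd: mixed sexes, housed and grazing periods,
# one zero-gain period and one weight-loss period
toy_herd <- function(farmlet = "PP") {
  d <- function(x) as.Date(x)
  rbind(
    data.frame(animal_id = "A1", farmlet = farmlet, sex = "steer",
               date = d(c("2014-11-01", "2014-11-22", "2014-12-13")),
               weight_kg = c(300, 321, 339),
               location = c("housing", "housing", "housing"),
               stringsAsFactors = FALSE),
    data.frame(animal_id = "A2", farmlet = farmlet, sex = "heifer",
               date = d(c("2015-05-01", "2015-05-15", "2015-06-05")),
               weight_kg = c(350, 350, 364),   # zero-gain first period
               location = c("pasture", "pasture", "pasture"),
               stringsAsFactors = FALSE),
    data.frame(animal_id = "A3", farmlet = farmlet, sex = "steer",
               date = d(c("2015-03-01", "2015-03-22", "2015-04-12",
                          "2015-05-03")),
               weight_kg = c(420, 415, 436, 457),  # one weight-loss period
               location = c("housing", "housing", "housing", "pasture"),
               stringsAsFactors = FALSE)
  )
}

# a minimal inventory with a handful of streams
toy_inventory <- function(farmlet = "PP", reseeded = FALSE, ...) {
  farmlet_inventory(
    farmlet_id = farmlet, area_ha = 21,
    quantities = c(fertiliser_n = 1000, fertiliser_p = 100, lime = 2000,
                   fym = 100, straw = 10000, diesel = 500,
                   tkm_straw_road = 1000),
    reseeded = reseeded, ...
  )
}
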