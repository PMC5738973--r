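#' Specify a synthetic finishing herd
#'
#' Captures the husbandry of a pasture-based finishing farmlet: a cohort of
#' weaned calves entering in autumn, housed each winter, weighed every two to
#' four weeks, and sold at the first weighing at or above a sex-specific
#' target weight (ca. 555 kg for heifers, 620 kg for steers by default).
#'
#' Each animal draws a lifetime average daily gain (ADG) from
#' `N(adg_mean, adg_sd)`; its within-life trajectory follows a three-phase
#' piecewise-linear ADG shape (post-weaning dip, mid-season peak, finishing
#' slowdown) scaled so the lifetime mean ADG equals the drawn value exactly.
#' Period-level variation is added as a mean-preserving perturbation, so
#' individual periods can show weight loss when `adg_sd > 0` while herd-level
#' statistics converge to the specified values.
#'
#' @param farmlet_id label, e.g. `"PP"`.
#' @param n_animals animals entering the farmlet (default 30).
#' @param entry_weight_mean,entry_weight_sd kg at entry.
#' @param adg_mean,adg_sd lifetime average daily gain, kg/d.
#' @param target_weight_heifer,target_weight_steer mean sale weights, kg.
#' @param days_sd d; per-animal spread of time-to-finish around the sex
#'   mean.  Sale in practice also hinges on carcass conformation and
#'   fat-class criteria that are not modelled explicitly; empirically,
#'   finishing time varies across animals roughly independently of growth
#'   rate, so each animal's sale threshold is drawn as
#'   `entry + ADG x N(duration, days_sd)`.  This keeps the exit rule a pure
#'   per-animal weight threshold while reproducing the observed spreads of
#'   finishing weight, total growth and days on the platform.
#' @param sex_ratio fraction of steers (default 0.5).
#' @param heifer_adg_ratio heifer-to-steer ratio of expected ADG (default
#'   0.95): steers grow somewhat faster than heifers at equal feeding, which
#'   is what gives them their larger total gain.  Multipliers are normalised
#'   by the sex ratio so the herd-level mean ADG stays `adg_mean`.
#' @param entry_date entry (weaning) date, `Date` or ISO string.
#' @param housing_windows list of `c(start, end)` date pairs during which
#'   animals are housed; `NULL` (default) builds annual 1 Oct – 30 Apr
#'   windows covering three years from entry.  A second within-year window
#'   for unfinished animals can be appended explicitly.
#' @param weighing_interval days between weighings: a single value for a
#'   fixed schedule or a `c(min, max)` range (within 14–28) sampled
#'   per animal-period.
#' @param growth_shape named vector `c(dip, peak, peak_at, end)`: relative
#'   ADG at entry, at the peak (located at fraction `peak_at` of the
#'   trajectory) and at finishing.  `c(1, 1, 0.5, 1)` gives a flat profile.
#' @param rng_seed integer seed.
#' @return An object of class `herd_spec`.
#' @export
herd_spec <- function(farmlet_id, n_animals = 30,
                      entry_weight_mean = 280, entry_weight_sd = 32,
                      adg_mean = 0.72, adg_sd = 0.10,
                      target_weight_heifer = 555, target_weight_steer = 620,
                      days_sd = 35, heifer_adg_ratio = 0.95,
                      sex_ratio = 0.5, entry_date = "2014-10-01",
                      housing_windows = NULL,
                      weighing_interval = c(14, 28),
                      growth_shape = c(dip = 0.2, peak = 2.4,
                                       peak_at = 0.55, end = 0.3),
                      rng_seed = 1L) {
  entry_date <- as.Date(entry_date)
  stopifnot(n_animals >= 1, entry_weight_sd >= 0, adg_sd >= 0,
            days_sd >= 0, heifer_adg_ratio > 0, heifer_adg_ratio <= 1,
            sex_ratio >= 0, sex_ratio <= 1,
            target_weight_heifer > entry_weight_mean,
            target_weight_steer > entry_weight_mean)
  if (adg_mean <= 0) stop("adg_mean must be positive")
  wi <- round(weighing_interval)
  if (any(wi < 14) || any(wi > 28))
    stop("weighing_interval must lie within [14, 28] days")
  if (length(wi) == 1L) wi <- c(wi, wi)
  if (is.null(housing_windows))
    housing_windows <- default_housing_windows(entry_date)
  for (w in housing_windows)
    if (as.Date(w[1]) >= as.Date(w[2]))
      stop("housing windows must have start < end")
  structure(list(
    farmlet_id = farmlet_id, n_animals = as.integer(n_animals),
    entry_weight_mean = entry_weight_mean, entry_weight_sd = entry_weight_sd,
    adg_mean = adg_mean, adg_sd = adg_sd,
    target_weight_heifer = target_weight_heifer,
    target_weight_steer = target_weight_steer,
    days_sd = days_sd, heifer_adg_ratio = heifer_adg_ratio,
    sex_ratio = sex_ratio, entry_date = entry_date,
    housing_windows = housing_windows,
    weighing_interval = wi, growth_shape = growth_shape,
    rng_seed = as.integer(rng_seed)
  ), class = "herd_spec")
}

#' Annual winter housing windows
#'
#' Cattle are housed from 1 October to 30 April to protect soil structure in
#' the wet season.
#'
#' @param entry_date date of herd entry; windows cover this and the following
#'   `n_years` winters.
#' @param n_years number of winters.
#' @return A list of `c(start, end)` `Date` pairs.
#' @export
default_housing_windows <- function(entry_date, n_years = 3) {
  entry_date <- as.Date(entry_date)
  y0 <- as.integer(format(entry_date, "%Y"))
  lapply(seq_len(n_years) - 1L, function(k) {
    c(as.Date(sprintf("%d-10-01", y0 + k)),
      as.Date(sprintf("%d-04-30", y0 + k + 1L)))
  })
}

in_housing <- function(dates, windows) {
  out <- rep(FALSE, length(dates))
  for (w in windows)
    out <- out | (dates >= as.Date(w[1]) & dates <= as.Date(w[2]))
  out
}

# cumulative integral of the piecewise-linear ADG shape, normalised so the
# lifetime mean is exactly 1: S(0)=0, S(1)=1, S'(u) proportional to the shape
growth_shape_cumulative <- function(u, shape) {
  dip <- shape[["dip"]]; peak <- shape[["peak"]]
  at <- shape[["peak_at"]]; end <- shape[["end"]]
  area <- at * (dip + peak) / 2 + (1 - at) * (peak + end) / 2
  s_int <- function(x) {
    # integral of the un-normalised shape from 0 to x
    ifelse(x <= at,
           dip * x + (peak - dip) * x^2 / (2 * at),
           at * (dip + peak) / 2 +
             peak * (x - at) - (peak - end) * (x - at)^2 / (2 * (1 - at)))
  }
  ifelse(u <= 1, s_int(pmin(pmax(u, 0), 1)) / area,
         (s_int(1) + end * (u - 1)) / area)  # finishing-rate extrapolation
}

#' Generate a synthetic herd of weighing records
#'
#' @param spec a [herd_spec()].
#' @return A `herd_records` data.frame with columns `animal_id`, `farmlet`,
#'   `sex`, `date`, `weight_kg`, `location` (`"pasture"`/`"housing"`), one
#'   row per weighing event, entry included; animals exit at the first
#'   weighing at or above their sex's target weight.  Bit-reproducible under
#'   `spec$rng_seed`.
#' @export
#' @examples
#' herd <- generate_herd(herd_spec("PP", n_animals = 3, rng_seed = 42))
#' head(herd)
generate_herd <- function(spec) {
  stopifnot(inherits(spec, "herd_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_animals
  n_steer <- round(n * spec$sex_ratio)
  sexes <- sample(c(rep("steer", n_steer), rep("heifer", n - n_steer)))
  # sex ADG multipliers, normalised so the herd mean ADG is adg_mean
  sr <- n_steer / n
  mult_steer <- 1 / (sr + (1 - sr) * spec$heifer_adg_ratio)
  mult_heifer <- spec$heifer_adg_ratio * mult_steer
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- sexes[i]
    target_mean <- if (sex == "steer") spec$target_weight_steer
                   else spec$target_weight_heifer
    repeat {
      w0 <- stats::rnorm(1, spec$entry_weight_mean, spec$entry_weight_sd)
      if (w0 > 50 && w0 < target_mean) break
    }
    # per-animal sale threshold: entry + ADG x (sex-mean duration + noise),
    # so time-to-finish is independent of growth rate
    dur_sex <- (target_mean - spec$entry_weight_mean) / spec$adg_mean
    adg_mult <- if (sex == "steer") mult_steer else mult_heifer
    repeat {
      adg <- stats::rnorm(1, spec$adg_mean, spec$adg_sd) * adg_mult
      dur <- stats::rnorm(1, dur_sex, spec$days_sd)
      target <- w0 + adg * dur
      if (adg > 0.05 && dur > 60 && target > w0 + 50) break
    }
    # final weighing lands on the day the mean trajectory reaches target, so
    # the lifetime mean ADG equals the drawn value (the last interval may be
    # shorter than the weighing cadence, as for a sale-day weighing)
    dur_i <- max(ceiling(dur), 1)
    t <- 0
    times <- 0
    while (t < dur_i) {
      gap <- if (spec$weighing_interval[1] == spec$weighing_interval[2])
        spec$weighing_interval[1]
      else sample(spec$weighing_interval[1]:spec$weighing_interval[2], 1)
      t <- min(t + gap, dur_i)
      times <- c(times, t)
    }
    k <- length(times) - 1L  # periods
    mean_w <- w0 + adg * dur * growth_shape_cumulative(times / dur,
                                                       spec$growth_shape)
    if (k >= 2L && spec$adg_sd > 0) {
      d <- diff(times)
      for (try in 1:100) {
        e <- stats::rnorm(k, 0, spec$adg_sd)
        e <- e - sum(e * d) / sum(d)     # mean-preserving: endpoints pinned
        w <- mean_w + c(0, cumsum(e * d))
        if (all(w > 0)) break
        if (try == 100) w <- mean_w      # pathological spec: fall back
      }
    } else {
      w <- mean_w
    }
    exit <- which(w >= target)[1]
    if (is.na(exit)) exit <- length(w)
    w <- w[seq_len(exit)]
    dates <- spec$entry_date + times[seq_len(exit)]
    rows[[i]] <- data.frame(
      animal_id = sprintf("%s_%02d", spec$farmlet_id, i),
      farmlet = spec$farmlet_id, sex = sex, date = dates,
      weight_kg = w,
      location = ifelse(in_housing(dates, spec$housing_windows),
                        "housing", "pasture"),
      stringsAsFactors = FALSE
    )
  }
  herd <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(herd) <- c("herd_records", "data.frame")
  herd
}

#' Herd spec parameterised from the packaged performance table
#'
#' @param farmlet `"PP"`, `"WC"` or `"HS"`; entry-weight and ADG statistics
#'   are taken from the corresponding columns of the performance fixture.
#' @param rng_seed integer seed.
#' @param ... overrides passed to [herd_spec()].
#' @return A `herd_spec`.
#' @export
herd_spec_from_table2 <- function(farmlet, rng_seed = 1L, ...) {
  farmlet <- match.arg(farmlet, c("PP", "WC", "HS"))
  t2 <- load_fixture("table2_performance")
  g <- function(param, stat) {
    as.numeric(t2[t2$parameter == param, paste0(tolower(farmlet), "_", stat)])
  }
  herd_spec(farmlet_id = farmlet,
            entry_weight_mean = g("entry_weight", "mean"),
            entry_weight_sd = g("entry_weight", "sd"),
            adg_mean = g("adg", "mean"), adg_sd = g("adg", "sd"),
            rng_seed = rng_seed, ...)
}

#' Specify a synthetic feed-quality series
#'
#' @param farmlet_id farmlet label.
#' @param feed_type `"pasture"` or `"silage"`.
#' @param de_mean,de_sd digestible energy, % of gross energy.
#' @param cp_mean,cp_sd crude protein, % of dry matter.
#' @param seasonal_amplitude percentage points of sinusoidal seasonal swing
#'   applied to both DE and CP (spring peak).
#' @param sampling_interval days between samples (sward snips are cut in the
#'   same weeks animals are weighed).
#' @param rng_seed integer seed.
#' @return An object of class `feed_spec`.
#' @export
feed_spec <- function(farmlet_id, feed_type = c("pasture", "silage"),
                      de_mean, de_sd = 1.5, cp_mean, cp_sd = 1.0,
                      seasonal_amplitude = 2, sampling_interval = 14,
                      rng_seed = 1L) {
  feed_type <- match.arg(feed_type)
  stopifnot(de_mean > 0, de_mean < 100, cp_mean > 0, cp_mean < 100,
            de_sd >= 0, cp_sd >= 0, seasonal_amplitude >= 0,
            sampling_interval >= 1)
  structure(list(farmlet_id = farmlet_id, feed_type = feed_type,
                 de_mean = de_mean, de_sd = de_sd,
                 cp_mean = cp_mean, cp_sd = cp_sd,
                 seasonal_amplitude = seasonal_amplitude,
                 sampling_interval = as.integer(sampling_interval),
                 rng_seed = as.integer(rng_seed)),
            class = "feed_spec")
}

#' Generate a dated feed-quality series
#'
#' Samples at `sampling_interval` days between `start` and `end`; each value
#' is the spec mean plus a spring-peaking sinusoid of the given amplitude
#' plus Gaussian noise, clipped to (0, 100).  If the interval exceeds the
#' span a single sample at `start` is returned.
#'
#' @param spec a [feed_spec()].
#' @param start,end date range covered.
#' @return A `feed_series` data.frame with columns `farmlet`, `feed_type`,
#'   `date`, `de_pct`, `cp_pct`.
#' @export
generate_feed_series <- function(spec, start, end) {
  stopifnot(inherits(spec, "feed_spec"))
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop("start must precede end")
  set.seed(spec$rng_seed)
  dates <- if (spec$sampling_interval >= as.numeric(end - start)) start
           else seq(start, end, by = spec$sampling_interval)
  doy <- as.numeric(format(dates, "%j"))
  season <- spec$seasonal_amplitude * cos(2 * pi * (doy - 135) / 365)
  clip <- function(x) pmin(pmax(x, 0.5), 99.5)
  out <- data.frame(
    farmlet = spec$farmlet_id, feed_type = spec$feed_type, date = dates,
    de_pct = clip(spec$de_mean + season +
                    stats::rnorm(length(dates), 0, spec$de_sd)),
    cp_pct = clip(spec$cp_mean + season +
                    stats::rnorm(length(dates), 0, spec$cp_sd)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("feed_series", "data.frame")
  out
}

#' Feed specs parameterised from the packaged inventory table
#'
#' Builds a pasture and a silage [feed_spec()] around the mean DE/CP printed
#' for the chosen farmlet.  Spread and seasonal defaults: pasture varies more
#' than silage (clamp-stored forage buffers seasonality).
#'
#' @inheritParams herd_spec_from_table2
#' @return A list with elements `pasture` and `silage`.
#' @export
feed_specs_from_table1 <- function(farmlet, rng_seed = 1L) {
  farmlet <- match.arg(farmlet, c("PP", "WC", "HS"))
  t1 <- load_fixture("table1_inventory")
  v <- function(key) as.numeric(t1[t1$variable == key, farmlet])
  list(
    pasture = feed_spec(farmlet, "pasture",
                        de_mean = v("pasture_de"), de_sd = 2,
                        cp_mean = v("pasture_cp"), cp_sd = 1.5,
                        seasonal_amplitude = 3, rng_seed = rng_seed),
    silage = feed_spec(farmlet, "silage",
                       de_mean = v("silage_de"), de_sd = 1.5,
                       cp_mean = v("silage_cp"), cp_sd = 1,
                       seasonal_amplitude = 1, rng_seed = rng_seed + 1L)
  )
}

#' Read and write herd and feed CSV files
#'
#' Plain-CSV dialects used throughout: herd records carry
#' `animal_id, farmlet, sex, date, weight_kg, location` and feed series carry
#' `farmlet, feed_type, date, de_pct, cp_pct` (optionally
#' `madf_g_per_kg, n_pct`), dates ISO-8601.
#'
#' @param path file path.
#' @return The data.frame read, with `date` parsed as `Date`.
#' @export
read_herd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "farmlet", "sex", "date", "weight_kg", "location")
  if (!all(req %in% names(df)))
    stop("herd CSV must have columns: ", paste(req, collapse = ", "))
  df$date <- as.Date(df$date)
  class(df) <- c("herd_records", "data.frame")
  df
}

#' @rdname read_herd_csv
#' @param herd,feed data.frames to write.
#' @export
write_herd_csv <- function(herd, path) {
  utils::write.csv(herd, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_herd_csv
#' @export
read_feed_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("farmlet", "feed_type", "date")
  if (!all(req %in% names(df)))
    stop("feed CSV must have columns: ", paste(req, collapse = ", "))
  df$date <- as.Date(df$date)
  class(df) <- c("feed_series", "data.frame")
  df
}

#' @rdname read_herd_csv
#' @export
write_feed_csv <- function(feed, path) {
  utils::write.csv(feed, path, row.names = FALSE)
  invisible(path)
}
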