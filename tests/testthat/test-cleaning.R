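hourly_frame <- function(site, values, start = "2016-01-01 00:00:00",
                         measurement = "no2") {
  out <- data.frame(
    site_id = site,
    timestamp = seq(as.POSIXct(start, tz = "UTC"), by = "hour",
                    length.out = length(values)),
    stringsAsFactors = FALSE)
  out[[measurement]] <- values
  out
}

test_that("nonpositive pollutant values become missing, with counts reported", {
  d <- hourly_frame("s1", c(5.0, 0.0, -1.2, 3.3))
  res <- clean_pollutants(d)
  expect_equal(res$data$no2, c(5.0, NA, NA, 3.3))
  expect_equal(sum(res$report$n_removed), 2)

  ok <- hourly_frame("s1", runif(50, 1, 10))
  expect_equal(clean_pollutants(ok)$data, ok)

  # planted-defect oracle: removal count equals the number planted
  set.seed(4)
  v <- runif(500, 1, 30)
  plant <- sample(500, 37)
  v[plant] <- -runif(37)
  res2 <- clean_pollutants(hourly_frame("s2", v))
  expect_equal(sum(res2$report$n_removed), 37)
  expect_true(all(is.na(res2$data$no2[plant])))
})

test_that("cleaning rules are idempotent and never invent values", {
  set.seed(8)
  v <- rnorm(300, 5, 6)
  d <- hourly_frame("s1", v)
  once <- clean_pollutants(d)$data
  twice <- clean_pollutants(once)$data
  expect_identical(once, twice)
  expect_true(all(which(!is.na(once$no2)) %in% which(!is.na(d$no2))))

  d$temperature <- rnorm(300, -18, 5)
  f_once <- apply_filters(d)
  expect_identical(f_once, apply_filters(f_once))
})

test_that("duplicate readings resolve by pressure, then file order", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  r <- data.frame(
    site_id = c("a", "a", "b", "b", "c", "c", "c"),
    timestamp = rep(t0, 7),
    temperature = 1:7,
    pressure = c(NA, 1013, NA, NA, NA, 990, 991),
    stringsAsFactors = FALSE)
  out <- dedupe_met_readings(r)
  expect_equal(out$temperature[out$site_id == "a"], 2)  # pressure-bearing kept
  expect_equal(out$temperature[out$site_id == "b"], 3)  # neither: first kept
  expect_equal(out$temperature[out$site_id == "c"], 6)  # first pressure-bearing of 3
  expect_equal(anyDuplicated(paste(out$site_id, out$timestamp)), 0)

  # planted duplicates leave unique keys
  set.seed(2)
  big <- data.frame(site_id = sample(letters[1:5], 80, TRUE),
                    timestamp = t0 + 3600 * sample(0:9, 80, TRUE),
                    temperature = rnorm(80), pressure = NA_real_)
  dd <- dedupe_met_readings(big)
  expect_equal(anyDuplicated(paste(dd$site_id, dd$timestamp)), 0)
})

test_that("spot-reading sites are dropped only when every day is a spot day", {
  t0 <- as.POSIXct("2016-01-01 12:00:00", tz = "UTC")
  spot <- data.frame(site_id = "spot", timestamp = t0 + 86400 * (0:99),
                     temperature = rnorm(100))
  full_day <- hourly_frame("full", rnorm(24), measurement = "temperature")
  mixed <- rbind(spot, full_day)
  mixed$site_id[mixed$site_id == "spot"][1:50] <- "mix"
  mixed <- rbind(mixed, hourly_frame("mix", rnorm(24), "2016-07-01 00:00:00",
                                     "temperature"))
  res <- drop_spot_sites(mixed)
  expect_equal(res$dropped, "spot")
  expect_setequal(unique(res$data$site_id), c("mix", "full"))
})

test_that("blacklist and temperature floor filters apply exactly", {
  d <- hourly_frame("s18920", c(-25, -20, -19.9, 4), measurement = "temperature")
  d$pressure <- c(1000, 1001, 1002, 1003)
  d <- rbind(d, within(hourly_frame("s117", rep(10, 4), measurement = "temperature"),
                       pressure <- 999))
  out <- apply_filters(d, blacklist = "s117")
  expect_false(any(out$site_id == "s117"))
  expect_equal(out$temperature, c(NA, -20, -19.9, 4))  # strictly below -20 only
  expect_equal(out$pressure, c(NA, 1001, 1002, 1003))  # whole reading blanked
})

test_that("coverage selection matches a per-day brute-force count", {
  mk <- function(site, n_days, per_day = 2) {
    ts <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC") +
      rep(86400 * (0:(n_days - 1)), each = per_day) + 3600 * (0:(per_day - 1))
    data.frame(site_id = site, timestamp = ts, temperature = rnorm(length(ts)))
  }
  crit <- coverage_criteria(retain_days = 730, reference_days = 1278)
  d <- rbind(mk("short", 729), mk("ok", 730), mk("ref", 1278))
  sel <- select_sites(d, "temperature", crit)
  expect_setequal(sel$retained$temperature, c("ok", "ref"))
  expect_equal(sel$reference, "ref")

  # random gaps: day counts match an independent scan
  set.seed(6)
  g <- mk("gappy", 900)
  g$temperature[sample(nrow(g), 500)] <- NA
  sel2 <- select_sites(g, "temperature", crit)
  oracle_days <- length(unique(as.Date(g$timestamp[!is.na(g$temperature)], tz = "UTC")))
  expect_equal(sel2$coverage$days, oracle_days)
  expect_error(coverage_criteria(retain_days = 0), "retain_days")
  expect_error(coverage_criteria(retain_days = 100, reference_days = 50))
})
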