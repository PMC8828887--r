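two_shell_fixture <- function(sensor_regions, values) {
  map <- make_two_shell_map()
  sites <- centroid_sites(map, sensor_regions)
  data <- data.frame(site_id = sites$site_id,
                     time_stamp = "2016-06-01",
                     pm25 = values, stringsAsFactors = FALSE)
  list(map = map, sites = sites, data = data)
}

test_that("two-shell worked example: first-ring sensors give rings = 1", {
  fx <- two_shell_fixture(c("B", "C"), c(10, 20))
  est <- estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "pm25")
  expect_equal(est$value, 15)
  expect_equal(est$rings, 1L)
})

test_that("two-shell worked example: second-shell sensors give rings = 2", {
  fx <- two_shell_fixture(c("G", "I", "M"), c(10, 20, 30))
  est <- estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "pm25")
  expect_equal(est$rings, 2L)
  expect_equal(est$value, 20)
})

test_that("an in-region valued sensor gives rings = 0 and its own value", {
  fx <- two_shell_fixture(c("A", "B"), c(7.5, 99))
  est <- estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "pm25")
  expect_equal(est$value, 7.5)
  expect_equal(est$rings, 0L)
})

test_that("rings expand past sensors whose value is missing at the timestamp", {
  fx <- two_shell_fixture(c("B", "G"), c(NA, 42))
  est <- estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "pm25")
  expect_equal(est$value, 42)
  expect_equal(est$rings, 2L)
})

test_that("estimate errors on unknown region or measurement", {
  fx <- two_shell_fixture("B", 1)
  expect_error(estimate_region(fx$map, fx$sites, fx$data, "ZZ", "2016-06-01", "pm25"),
               "unknown region")
  expect_error(estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "o3"),
               "unknown measurement")
})

test_that("site assignment matches a brute-force point-in-polygon scan", {
  map <- grid_map(4, 4)
  set.seed(11)
  n <- 100
  sites <- data.frame(site_id = sprintf("p%03d", 1:n),
                      longitude = runif(n, -0.5, 4.5),
                      latitude = runif(n, -0.5, 4.5),
                      stringsAsFactors = FALSE)
  got <- suppressWarnings(assign_sites_to_regions(sites, map))
  for (i in seq_len(n)) {
    hits <- Filter(function(r) point_in_multipolygon(sites$longitude[i],
                                                     sites$latitude[i],
                                                     map$geometry[[r]]),
                   map$region_id)
    if (length(hits)) expect_true(got$region_id[i] %in% hits)
    else expect_true(is.na(got$region_id[i]))
  }
  # a site in the ocean warns and is excluded
  ocean <- data.frame(site_id = "boat", longitude = 50, latitude = 50)
  expect_warning(assign_sites_to_regions(ocean, map), "outside all regions")
})

test_that("estimate_all covers the cross product and matches the group-mean oracle", {
  map <- grid_map(2, 2)
  sites <- centroid_sites(map)
  dates <- c("2016-01-01", "2016-01-02")
  data <- expand.grid(site_id = sites$site_id, time_stamp = dates,
                      stringsAsFactors = FALSE)
  set.seed(3)
  data$no2 <- runif(nrow(data), 5, 50)
  est <- estimate_all(map, sites, data)
  expect_equal(nrow(est), 4 * 2)  # regions x dates
  expect_true(all(est$rings_no2 == 0))  # every region holds a valued sensor
  for (i in seq_len(nrow(est))) {
    sel <- data$time_stamp == est$time_stamp[i] &
      sites$region_id[match(data$site_id, sites$site_id)] == est$region_id[i]
    expect_equal(est$no2[i], mean(data$no2[sel]))
  }
  # a fully missing date yields missing values and missing rings
  data$no2[data$time_stamp == "2016-01-02"] <- NA
  est2 <- estimate_all(map, sites, data)
  gone <- est2[est2$time_stamp == "2016-01-02", ]
  expect_true(all(is.na(gone$no2)) && all(is.na(gone$rings_no2)))
})

test_that("estimates match the filter-and-mean oracle on random maps", {
  set.seed(23)
  for (trial in 1:8) {
    map <- grid_map(sample(2:5, 1), sample(2:5, 1))
    occupied <- sample(map$region_id, max(2, length(map$region_id) %/% 3))
    sites <- centroid_sites(map, occupied)
    data <- data.frame(site_id = sites$site_id, time_stamp = "2016-01-01",
                       v = rnorm(nrow(sites), 20, 5), stringsAsFactors = FALSE)
    data$v[sample(nrow(data), nrow(data) %/% 4)] <- NA
    vals <- split(data$v[!is.na(data$v)],
                  sites$region_id[match(data$site_id[!is.na(data$v)], sites$site_id)])
    est <- estimate_all(map, sites, data)
    for (i in seq_len(nrow(est))) {
      oracle <- oracle_estimate(map$neighbours, est$region_id[i], vals)
      expect_equal(est$v[i], oracle$value)
      expect_equal(est$rings_v[i], oracle$rings)
    }
  }
})

test_that("estimates are bounded by contributing values and permutation-invariant", {
  fx <- two_shell_fixture(c("B", "C", "D"), c(3, 9, 6))
  est <- estimate_region(fx$map, fx$sites, fx$data, "A", "2016-06-01", "pm25")
  expect_gte(est$value, 3)
  expect_lte(est$value, 9)
  shuffled <- fx$data[c(3, 1, 2), ]
  est2 <- estimate_region(fx$map, fx$sites, shuffled, "A", "2016-06-01", "pm25")
  expect_equal(est2, est)
  # adding an in-region sensor can only decrease the ring count
  fx0 <- two_shell_fixture(c("A", "B", "C", "D"), c(5, 3, 9, 6))
  est0 <- estimate_region(fx0$map, fx0$sites, fx0$data, "A", "2016-06-01", "pm25")
  expect_lte(est0$rings, est$rings)
})

test_that("stratified estimation equals plain estimation on the filtered sites", {
  map <- grid_map(3, 3)
  sites <- centroid_sites(map, map$region_id,
                          types = c("urban traffic", "rural background"))
  set.seed(5)
  data <- data.frame(site_id = sites$site_id, time_stamp = "2016-01-01",
                     no2_mean = runif(9, 10, 60), stringsAsFactors = FALSE)
  strat <- estimate_stratified(map, sites, data, "urban traffic")
  expect_true(all(c("no2_UT_mean", "rings_no2_UT_mean") %in% names(strat)))
  plain <- estimate_all(map, sites[sites$environment_type == "urban traffic", ], data)
  expect_equal(strat$no2_UT_mean, plain$no2_mean)
  expect_equal(strat$rings_no2_UT_mean, plain$rings_no2_mean)
  # only the UT sensor in a mixed region is used
  one <- estimate_region(map, sites[sites$environment_type == "urban traffic", ],
                         data, "g0101", "2016-01-01", "no2_mean")
  expect_equal(one$rings, if (sites$environment_type[1] == "urban traffic") 0L else 1L)
  # a stratum with no sensors map-wide is all missing
  empty <- estimate_stratified(map, sites, data, "industrial")
  expect_true(all(is.na(empty$no2_Ind_mean)))
  expect_error(estimate_stratified(map, sites, data, "beach"), "unknown site type")
})

test_that("shortest-distance estimates match an exhaustive scan", {
  map <- grid_map(4, 4)
  set.seed(9)
  n <- 20
  sites <- data.frame(site_id = sprintf("d%02d", 1:n),
                      longitude = runif(n, 0, 4), latitude = runif(n, 0, 4),
                      stringsAsFactors = FALSE)
  sites <- assign_sites_to_regions(sites, map)
  data <- data.frame(site_id = sites$site_id, time_stamp = "2016-01-01",
                     v = rnorm(n, 15, 4), stringsAsFactors = FALSE)
  data$v[sample(n, 5)] <- NA
  for (r in sample(map$region_id, 5)) {
    est <- estimate_distance(map, sites, data, r, "2016-01-01", "v")
    cen <- mp_centroid(map$geometry[[r]])
    ok <- !is.na(data$v)
    d <- haversine_km(cen[1], cen[2], sites$longitude[ok], sites$latitude[ok])
    expect_equal(est$value, data$v[ok][which.min(d)])
    expect_true(is.na(est$rings))
  }
  # via estimate_all the rings columns stay missing for the distance method
  all_d <- estimate_all(map, sites, data, method = "distance")
  expect_true(all(is.na(all_d$rings_v)))
  expect_true(all(!is.na(all_d$v)))
})
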