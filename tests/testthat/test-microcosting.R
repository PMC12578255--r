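test_that("per-sample materials cost divides the batch total by the plate size", {
  # 134.10 USD over a 90-sample molecular plate is the printed PCR cost
  tab <- cost_item_table(
    "pcr_species",
    data.frame(item = c("a", "b"), unit_price = c(100, 34.10),
               quantity_per_batch = c(1, 1)),
    samples_per_batch = 90
  )
  expect_equal(per_sample_material_cost(tab), 1.49)

  # MALDI plate: preparation (11.75) + cleaning (16.45) over 47 samples
  maldi <- cost_item_table(
    "maldi",
    data.frame(item = c("prep", "cleaning"), unit_price = c(11.75, 16.45),
               quantity_per_batch = c(1, 1)),
    samples_per_batch = 47
  )
  expect_equal(per_sample_material_cost(maldi), 0.25 + 0.35)

  empty <- cost_item_table("nothing", samples_per_batch = 47)
  expect_equal(per_sample_material_cost(empty), 0)
})

test_that("materials cost is linear in quantities and rejects invalid batches", {
  items <- data.frame(item = letters[1:3], unit_price = c(2, 5, 0.4),
                      quantity_per_batch = c(3, 0.5, 10))
  base <- per_sample_material_cost(cost_item_table("x", items, 90))
  doubled <- items
  doubled$quantity_per_batch <- doubled$quantity_per_batch * 2
  expect_equal(per_sample_material_cost(cost_item_table("x", doubled, 90)), 2 * base)

  expect_error(cost_item_table("x", items, 0), class = "entocost_invalid_batch_error")
  bad <- items; bad$unit_price[1] <- -1
  expect_error(cost_item_table("x", bad, 90), class = "entocost_validation_error")
})

test_that("cost tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  items <- data.frame(item = c("kit", "tips"), unit_price = c(58.5, 7.9),
                      quantity_per_batch = c(1, 2.5))
  write.csv(items, path, row.names = FALSE)
  tab <- read_cost_items(path, "pcr_species", 90)
  expect_equal(per_sample_material_cost(tab), (58.5 + 7.9 * 2.5) / 90)

  bundled <- system.file("extdata", "cost-items-example.csv", package = "entocost")
  expect_gt(per_sample_material_cost(read_cost_items(bundled, "pcr", 90)), 0)
})

test_that("adjusted time drops only incubations strictly longer than 60 min", {
  s <- timed_steps(c("setup", "incubate", "read"), c(30, 90, 12),
                   c(FALSE, TRUE, FALSE))
  expect_equal(adjusted_time(s), 42)

  # a 60-min incubation is not "above 60 minutes": retained
  s60 <- timed_steps(c("setup", "incubate"), c(30, 60), c(FALSE, TRUE))
  expect_equal(adjusted_time(s60), 90)

  # a long hands-on step is never dropped
  s_hands <- timed_steps(c("long_prep"), 90, FALSE)
  expect_equal(adjusted_time(s_hands), 90)

  expect_error(timed_steps("x", -5, FALSE), class = "entocost_validation_error")
})

test_that("adjusted time is bounded by raw time, with equality iff nothing excluded", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    s <- timed_steps(paste0("s", 1:n), runif(n, 0, 120), runif(n) < 0.4)
    raw <- sum(s$duration)
    adj <- adjusted_time(s)
    expect_lte(adj, raw)
    if (!any(s$is_incubation & s$duration > 60)) expect_equal(adj, raw)
  }
})

test_that("per-plate CSP-ELISA timings reduce to the printed per-sample values", {
  # raw plate total 382.05 min of which 239.94 min are long incubations
  raw <- per_sample_time(382.05, 90)
  adj <- per_sample_time(382.05 - 239.94, 90)
  expect_equal(raw, 4.245)
  expect_equal(adj, 1.579)

  expect_equal(per_sample_time(94.47, 47), 2.01)
  expect_equal(per_sample_time(235.8, 90), 2.62)
  expect_equal(per_sample_time(0, 90), 0)
  expect_error(per_sample_time(10, 0), class = "entocost_invalid_batch_error")
})

test_that("labour rate derives from salary arithmetic and prices adjusted time", {
  rate <- labour_rate(6289.82, hours_per_week = 40, weeks_per_year = 52)
  expect_equal(rate$rate_per_minute, 0.0503991987179487, tolerance = 1e-12)

  expect_equal(labour_cost(0, rate), 0)
  expect_equal(labour_cost(2.01, labour_rate(0, rate_per_minute = 0.0547)),
               0.109947)

  # explicit override wins over the derivation
  expect_equal(labour_rate(1e6, rate_per_minute = 0.25)$rate_per_minute, 0.25)

  # monotone in both arguments
  expect_gte(labour_cost(3, rate), labour_cost(2, rate))
  expect_gte(labour_cost(2, labour_rate(7000)), labour_cost(2, rate))
})

test_that("direct cost is exactly materials plus labour", {
  expect_identical(direct_cost(4.37, 0.48), 4.37 + 0.48)
  expect_identical(direct_cost(3.09, 0.20), 3.29)
  expect_identical(direct_cost(0, 0), 0)
})

test_that("profiles validate their invariants and assemble from components", {
  expect_error(assay_profile("x", 1, 2, 0, 0), class = "entocost_validation_error")
  expect_error(assay_profile("x", 1, 1, -1, 0), class = "entocost_validation_error")

  steps <- timed_steps(c("prep", "incubate", "read"), c(150, 120, 85.8),
                       c(FALSE, TRUE, FALSE))
  tab <- cost_item_table(
    "pcr_species",
    data.frame(item = "batch", unit_price = 134.10, quantity_per_batch = 1), 90
  )
  prof <- profile_from_components(tab, steps, labour_rate(6289.82))
  expect_equal(prof$time_per_sample, 355.8 / 90)
  expect_equal(prof$adjusted_time_per_sample, 235.8 / 90)
  expect_equal(prof$materials_cost_per_sample, 1.49)
  expect_equal(prof$labour_cost_per_sample, (235.8 / 90) * 6289.82 / 124800)
})
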