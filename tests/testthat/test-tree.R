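test_that("validate_tree reports probability violations as diagnostics", {
  ok <- split_tree(0.2)
  expect_length(validate_tree(ok), 0)

  bad_sum <- chance_node(branches = list(
    branch("a", 0.2, terminal_node()),
    branch("b", 0.7, terminal_node())
  ))
  diags <- validate_tree(bad_sum)
  expect_length(diags, 1)
  expect_match(diags, "sum to 0.9")

  out_of_range <- chance_node(branches = list(
    branch("a", 1.2, terminal_node()),
    branch("b", -0.2, terminal_node())
  ))
  expect_length(validate_tree(out_of_range), 2)
  expect_match(validate_tree(out_of_range)[1], "outside \\[0, 1\\]")
})

test_that("enumerate_paths multiplies probabilities and conserves mass", {
  single <- terminal_node(list("unit"))
  paths <- enumerate_paths(single)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$probability, 1)

  two <- enumerate_paths(split_tree(0.2))
  expect_equal(vapply(two, `[[`, numeric(1), "probability"), c(0.2, 0.8))

  # invalid trees are rejected at enumeration
  expect_error(
    enumerate_paths(chance_node(branches = list(branch("a", 0.5, terminal_node())))),
    class = "entocost_validation_error"
  )
})

test_that("the current workflow carries the expected assay load per sample", {
  paths <- enumerate_paths(build_current_workflow())
  expected_assays <- function(paths) {
    out <- numeric()
    for (p in paths) {
      for (a in p$assays) {
        out[a$id] <- sum(out[a$id], p$probability, na.rm = TRUE)
      }
    }
    out
  }
  load <- expected_assays(paths)
  expect_equal(load[["pcr_species"]], 1.0)
  expect_equal(load[["csp_elisa"]], 1.0)
  expect_equal(load[["sanger_sequencing"]], 0.10)
  expect_equal(load[["csp_elisa_repeat"]], 0.05)
  expect_equal(load[["bloodmeal_elisa"]], 0.20)
  expect_equal(sum(vapply(paths, `[[`, numeric(1), "probability")), 1, tolerance = 1e-12)
})

test_that("cohort evaluation conserves counts and scales linearly in n", {
  profiles <- unit_profiles()
  tree <- split_tree(0.3)
  ev <- evaluate_cohort(tree, 1000, profiles)
  expect_equal(sum(ev$paths$expected_count), 1000)
  expect_equal(ev$totals[["direct"]],
               ev$totals[["materials"]] + ev$totals[["labour"]])

  ev1 <- evaluate_cohort(tree, 1, profiles)
  expect_equal(ev$totals, 1000 * ev1$totals)
  expect_equal(per_sample_average(ev), ev1$totals)

  # single assay of unit time on every sample: total time = n
  flat <- terminal_node(list("unit"))
  expect_equal(evaluate_cohort(flat, 15000, profiles)$totals[["time"]], 15000)

  expect_equal(unname(evaluate_cohort(tree, 0, profiles)$totals),
               rep(0, 4))
  expect_error(per_sample_average(evaluate_cohort(tree, 0, profiles)),
               class = "entocost_division_error")
})

test_that("fractional expected counts are kept, never rounded", {
  ev <- evaluate_cohort(split_tree(1 / 3), 10, unit_profiles())
  expect_equal(sort(ev$paths$expected_count), sort(c(10 / 3, 20 / 3)))
  expect_equal(ev$totals[["time"]], 10 / 3)
})

test_that("evaluation fails clearly on a missing assay profile", {
  expect_error(
    evaluate_cohort(split_tree(0.5, assay = "mystery"), 10, unit_profiles()),
    class = "entocost_unknown_assay_error"
  )
})

test_that("dimension masks gate payoff contributions per dimension", {
  masked <- terminal_node(list(assay_use("unit", dims = c("materials", "labour"))))
  ev <- evaluate_cohort(masked, 100, unit_profiles())
  expect_equal(ev$totals[["time"]], 0)
  expect_equal(ev$totals[["materials"]], 100)
  expect_equal(ev$totals[["labour"]], 100)
  expect_equal(ev$totals[["direct"]], 200)
})

test_that("interchanging independent chance-node nesting leaves totals unchanged", {
  profiles <- rbind(unit_profiles(), assay_profile("bm", 3.9, 1.2, 1.21, 0.06))
  # factor A (p = 0.2) adds assay "bm"; factor B (p = 0.1) adds assay "two"
  a_then_b <- chance_node(branches = list(
    branch("a_yes", 0.2, chance_node(
      assays = list("bm"),
      branches = list(branch("b_yes", 0.1, terminal_node(list("two"))),
                      branch("b_no", 0.9, terminal_node()))
    )),
    branch("a_no", 0.8, chance_node(branches = list(
      branch("b_yes", 0.1, terminal_node(list("two"))),
      branch("b_no", 0.9, terminal_node())
    )))
  ))
  b_then_a <- chance_node(branches = list(
    branch("b_yes", 0.1, chance_node(
      assays = list("two"),
      branches = list(branch("a_yes", 0.2, terminal_node(list("bm"))),
                      branch("a_no", 0.8, terminal_node()))
    )),
    branch("b_no", 0.9, chance_node(branches = list(
      branch("a_yes", 0.2, terminal_node(list("bm"))),
      branch("a_no", 0.8, terminal_node())
    )))
  ))
  ev1 <- evaluate_cohort(a_then_b, 15000, profiles)
  ev2 <- evaluate_cohort(b_then_a, 15000, profiles)
  expect_equal(ev1$totals, ev2$totals)
})
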