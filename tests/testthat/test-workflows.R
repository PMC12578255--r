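test_that("all bundled workflow builders produce valid trees across parameter space", {
  set.seed(7)
  for (i in 1:25) {
    params <- workflow_params(
      p_bloodfed = runif(1), p_unsat = runif(1), p_positive = runif(1),
      cohort_size = sample(0:20000, 1),
      include_parity_dissection = runif(1) < 0.5
    )
    for (build in list(build_current_workflow, build_proposed_workflow,
                       build_ideal_workflow)) {
      expect_length(validate_tree(build(params)), 0)
    }
  }
  expect_error(workflow_params(p_unsat = 1.2), class = "entocost_validation_error")
})

test_that("the current workflow reproduces the published cohort totals", {
  ev <- evaluate_workflow("current")
  expect_equal(ev$totals[["time"]], 141795.75)
  expect_equal(ev$totals[["materials"]], 65550.00)
  expect_equal(ev$totals[["labour"]], 7335.00)
  expect_equal(ev$totals[["direct"]], 72885.00)
  # full precision is 9.45305 min/sample; the published 9.4531 is its display
  expect_equal(per_sample_average(ev)[["time"]], 9.45305, tolerance = 1e-12)
  expect_equal(per_sample_average(ev)[["materials"]], 4.37, tolerance = 1e-12)
})

test_that("the proposed workflow reproduces the published totals under the time mask", {
  ev <- evaluate_workflow("proposed")
  expect_equal(ev$totals[["time"]], 67654.50)
  expect_equal(ev$totals[["labour"]], 2952.00)
  # full-precision materials: printed value is the 2-dp display of 46,300.50
  expect_equal(ev$totals[["materials"]], 46300.50)
  expect_equal(per_sample_average(ev)[["time"]], 4.5103, tolerance = 1e-12)

  # the confirmatory repeat ELISA occurrence carries a materials+labour mask
  paths <- enumerate_paths(build_proposed_workflow())
  repeat_uses <- unlist(lapply(paths, function(p) {
    Filter(function(a) a$id == "csp_elisa_repeat", p$assays)
  }), recursive = FALSE)
  expect_gt(length(repeat_uses), 0)
  for (a in repeat_uses) expect_setequal(a$dims, c("materials", "labour"))
})

test_that("the ideal scenario is MALDI-only and reproduces its published totals", {
  ev <- evaluate_workflow("ideal")
  expect_equal(ev$totals[["time"]], 36180.0)
  expect_equal(ev$totals[["materials"]], 10620.0)
  expect_equal(ev$totals[["labour"]], 1980.0)
  expect_equal(ev$totals[["direct"]], 12600.0)

  # switching off the QA branches reduces the proposed tree to the ideal one
  no_qa <- workflow_params(p_unsat = 0)
  prop <- evaluate_workflow("proposed", params = no_qa)
  ideal <- evaluate_workflow("ideal", params = no_qa)
  expect_equal(prop$totals, ideal$totals)

  zero <- workflow_params(cohort_size = 0)
  expect_equal(unname(evaluate_workflow("ideal", params = zero)$totals), rep(0, 4))
})

test_that("proposed totals dominate ideal totals dimension-wise at shared params", {
  set.seed(21)
  for (i in 1:10) {
    params <- workflow_params(p_bloodfed = runif(1), p_unsat = runif(1),
                              p_positive = runif(1), cohort_size = 5000)
    prop <- evaluate_workflow("proposed", params = params)
    ideal <- evaluate_workflow("ideal", params = params)
    expect_true(all(prop$totals >= ideal$totals - 1e-9))
  }
})

test_that("disabling every optional branch leaves only the universal assays", {
  params <- workflow_params(p_bloodfed = 0, p_unsat = 0, p_positive = 0,
                            cohort_size = 1234)
  ev <- evaluate_workflow("current", params = params)
  expect_equal(ev$totals[["time"]], 1234 * (2.620 + 4.245))
  expect_equal(ev$totals[["materials"]], 1234 * (1.49 + 0.30))
  expect_equal(ev$totals[["labour"]], 1234 * (0.30 + 0.12))
})

test_that("totals are linear in each branch probability", {
  at_p <- function(p) {
    evaluate_workflow("current", params = workflow_params(p_bloodfed = p))$totals
  }
  t0 <- at_p(0)
  t1 <- at_p(1)
  # p = 1 adds exactly n * blood-meal payoff relative to p = 0
  expect_equal(t1[["materials"]] - t0[["materials"]], 15000 * 1.21)
  expect_equal(t1[["labour"]] - t0[["labour"]], 15000 * 0.06)
  # midpoint falls exactly halfway (affine in p)
  expect_equal(at_p(0.5), (t0 + t1) / 2)
})

test_that("parity dissection reconciles the all-endpoints baseline costs", {
  # back-computed payoffs: (65,730 - 65,550)/15,000 and (8,895 - 7,335)/15,000
  params <- workflow_params(include_parity_dissection = TRUE)
  expect_equal(params$parity_materials_per_sample, (65730 - 65550) / 15000)
  expect_equal(params$parity_labour_per_sample, (8895 - 7335) / 15000)
  ev <- evaluate_workflow("current", params = params)
  expect_equal(ev$totals[["materials"]], 65730.0)
  expect_equal(ev$totals[["labour"]], 8895.0)
  expect_equal(ev$totals[["direct"]], 74625.0)
  # parity adds no bench time in the bundled reconciliation
  expect_equal(ev$totals[["time"]], 141795.75)
})

test_that("the optional QA PCR stage adds exactly its payoff on the QA subset", {
  with_pcr <- evaluate_workflow("proposed",
                                params = workflow_params(qa_include_pcr = TRUE))
  without <- evaluate_workflow("proposed")
  expect_equal(with_pcr$totals[["time"]] - without$totals[["time"]],
               15000 * 0.10 * 2.620)
  expect_equal(with_pcr$totals[["materials"]] - without$totals[["materials"]],
               15000 * 0.10 * 1.49)
})
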