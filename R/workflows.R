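# The three bundled surveillance workflows of the Kenyan NMCP case study:
# "current" (PCR + ELISA), "proposed" (MALDI-TOF MS with molecular quality
# assurance) and "ideal" (MALDI-TOF MS with 100% reportable results).

#' Parameters of the bundled surveillance workflows
#'
#' Branch probabilities and cohort size of the case-study decision trees.
#' Defaults reflect the Kenyan national malaria control programme scenario:
#' 20% of collected mosquitoes are blood-fed, 10% of samples give
#' unsatisfactory species/blood-meal results prompting follow-up assays, 5%
#' of samples screened for Plasmodium are positive and receive a
#' confirmatory repeat CSP-ELISA on heated lysate, and 15,000 samples are
#' processed per year.
#'
#' @param p_bloodfed Proportion of blood-fed mosquitoes.
#' @param p_unsat Proportion of unsatisfactory primary results.
#' @param p_positive Proportion Plasmodium-positive on CSP-ELISA.
#' @param cohort_size Annual number of mosquito samples.
#' @param include_parity_dissection If `TRUE`, every sample in the current
#'   workflow additionally incurs a parity-dissection payoff (used when the
#'   comparison baseline includes field age-grading by ovary dissection).
#' @param parity_materials_per_sample,parity_labour_per_sample,parity_time_per_sample
#'   Parity-dissection per-sample payoffs. Defaults are reconciled from the
#'   difference between the case study's all-endpoints baseline and its
#'   three-endpoint baseline over 15,000 samples (0.012 USD materials,
#'   0.104 USD labour, 0 min); supply measured values if you have them.
#' @param qa_include_pcr If `TRUE`, the proposed workflow's quality-assurance
#'   path charges a separate species-ID PCR before Sanger sequencing. The
#'   default treats the sequencing payoff as inclusive of amplification,
#'   which is the costing the bundled profiles reproduce.
#' @return A list of class `workflow_params`.
#' @export
workflow_params <- function(p_bloodfed = 0.20, p_unsat = 0.10, p_positive = 0.05,
                            cohort_size = 15000,
                            include_parity_dissection = FALSE,
                            parity_materials_per_sample = 0.012,
                            parity_labour_per_sample = 0.104,
                            parity_time_per_sample = 0,
                            qa_include_pcr = FALSE) {
  check_probability(p_bloodfed, "p_bloodfed")
  check_probability(p_unsat, "p_unsat")
  check_probability(p_positive, "p_positive")
  check_number(cohort_size, "cohort_size", min = 0)
  check_number(parity_materials_per_sample, "parity_materials_per_sample", min = 0)
  check_number(parity_labour_per_sample, "parity_labour_per_sample", min = 0)
  check_number(parity_time_per_sample, "parity_time_per_sample", min = 0)
  structure(
    list(
      p_bloodfed = p_bloodfed, p_unsat = p_unsat, p_positive = p_positive,
      cohort_size = cohort_size,
      include_parity_dissection = isTRUE(include_parity_dissection),
      parity_materials_per_sample = parity_materials_per_sample,
      parity_labour_per_sample = parity_labour_per_sample,
      parity_time_per_sample = parity_time_per_sample,
      qa_include_pcr = isTRUE(qa_include_pcr)
    ),
    class = "workflow_params"
  )
}

#' Bundled per-assay cost profiles of the case study
#'
#' Per-sample time, hands-on time, materials and labour payoffs for every
#' assay in the Kenyan NMCP surveillance workflows, as measured in the
#' KEMRI-Wellcome laboratory (2022–2023 prices, USD). MALDI-TOF MS head/
#' thorax and blood-meal analyses share one payoff (2.01 min, 0.59 USD
#' materials, 0.11 USD labour). These printed per-sample values are the
#' canonical inputs of the bundled trees; [profile_from_components()]
#' recomputes profiles for user-supplied item-level data.
#'
#' @param params Optional [workflow_params()]; its parity payoffs populate
#'   the `parity_dissection` row.
#' @return A data.frame of [assay_profile()] rows.
#' @export
#' @examples
#' reference_profiles()
reference_profiles <- function(params = workflow_params()) {
  rows <- list(
    assay_profile("maldi_head_thorax", 2.010, 2.010, 0.59, 0.11),
    assay_profile("maldi_bloodmeal",   2.010, 2.010, 0.59, 0.11),
    assay_profile("pcr_species",       2.620, 0.620, 1.49, 0.30),
    assay_profile("sanger_sequencing", 15.958, 12.624, 23.23, 0.51),
    assay_profile("csp_elisa",         4.245, 1.579, 0.30, 0.12),
    assay_profile("csp_elisa_repeat",  4.245, 4.245, 0.30, 0.12),
    assay_profile("bloodmeal_elisa",   3.900, 1.234, 1.21, 0.06),
    assay_profile("parity_dissection",
                  params$parity_time_per_sample,
                  params$parity_time_per_sample,
                  params$parity_materials_per_sample,
                  params$parity_labour_per_sample)
  )
  do.call(rbind, rows)
}

# blood-meal stage shared by the current workflow: blood-fed samples get a
# blood-meal ELISA; undetected sources are not analysed further (no-op).
current_bloodmeal_stage <- function(params, assays = list()) {
  chance_node(
    assays = assays,
    branches = list(
      branch("blood_fed", params$p_bloodfed, chance_node(
        assays = list("bloodmeal_elisa"),
        branches = list(
          branch("bm_detected", 1 - params$p_unsat, terminal_node()),
          branch("bm_undetected", params$p_unsat, terminal_node())
        )
      )),
      branch("unfed", 1 - params$p_bloodfed, terminal_node())
    )
  )
}

current_plasmodium_stage <- function(params, assays = list()) {
  chance_node(
    assays = assays,
    branches = list(
      branch("csp_positive", params$p_positive,
             current_bloodmeal_stage(params, assays = list("csp_elisa_repeat"))),
      branch("csp_negative", 1 - params$p_positive,
             current_bloodmeal_stage(params))
    )
  )
}

#' Build the current (PCR/ELISA) surveillance workflow tree
#'
#' Every sample incurs species-identification PCR and Plasmodium CSP-ELISA;
#' a fraction `p_unsat` of species identifications is unsatisfactory and
#' goes on to Sanger sequencing; a fraction `p_positive` is
#' Plasmodium-positive and is confirmed by a repeat CSP-ELISA on heated
#' lysate; the blood-fed fraction `p_bloodfed` incurs a blood-meal ELISA,
#' after which undetected blood-meal sources are not analysed further.
#' With `include_parity_dissection`, every sample also incurs the
#' parity-dissection payoff.
#'
#' @param params A [workflow_params()].
#' @return A `workflow_node` tree.
#' @export
#' @examples
#' ev <- evaluate_cohort(build_current_workflow(), 15000, reference_profiles())
#' round(ev$totals, 2)
build_current_workflow <- function(params = workflow_params()) {
  stopifnot(inherits(params, "workflow_params"))
  base <- list("pcr_species", "csp_elisa")
  if (params$include_parity_dissection) base <- c(base, list("parity_dissection"))
  chance_node(
    assays = base,
    branches = list(
      branch("species_unsatisfactory", params$p_unsat,
             current_plasmodium_stage(params, assays = list("sanger_sequencing"))),
      branch("species_satisfactory", 1 - params$p_unsat,
             current_plasmodium_stage(params))
    )
  )
}

proposed_bloodmeal_stage <- function(params, assays = list()) {
  chance_node(
    assays = assays,
    branches = list(
      branch("blood_fed", params$p_bloodfed, chance_node(
        assays = list("maldi_bloodmeal"),
        branches = list(
          branch("bm_satisfactory", 1 - params$p_unsat, terminal_node()),
          branch("bm_unsatisfactory", params$p_unsat,
                 terminal_node(list("bloodmeal_elisa")))
        )
      )),
      branch("unfed", 1 - params$p_bloodfed, terminal_node())
    )
  )
}

#' Build the proposed (MALDI-TOF MS) surveillance workflow tree
#'
#' Every sample incurs one MALDI-TOF MS head/thorax analysis yielding
#' species, Plasmodium-infection and parity endpoints simultaneously. The
#' unsatisfactory fraction `p_unsat` is re-analysed for quality assurance
#' by Sanger sequencing plus a CSP-ELISA; within that QA subset, the
#' Plasmodium-positive fraction `p_positive` receives the confirmatory
#' repeat heated CSP-ELISA, which contributes to materials and labour but
#' not to the time total (it runs on the already-prepared lysate alongside
#' the QA plate). Blood-fed samples incur a MALDI blood-meal analysis, and
#' the unsatisfactory fraction of those a blood-meal ELISA.
#'
#' @inheritParams build_current_workflow
#' @return A `workflow_node` tree.
#' @export
build_proposed_workflow <- function(params = workflow_params()) {
  stopifnot(inherits(params, "workflow_params"))
  qa_assays <- list("sanger_sequencing", "csp_elisa")
  if (params$qa_include_pcr) qa_assays <- c(list("pcr_species"), qa_assays)
  qa_node <- chance_node(
    assays = qa_assays,
    branches = list(
      branch("csp_positive", params$p_positive,
             proposed_bloodmeal_stage(
               params,
               assays = list(assay_use("csp_elisa_repeat", dims = c("materials", "labour")))
             )),
      branch("csp_negative", 1 - params$p_positive,
             proposed_bloodmeal_stage(params))
    )
  )
  chance_node(
    assays = list("maldi_head_thorax"),
    branches = list(
      branch("maldi_unsatisfactory", params$p_unsat, qa_node),
      branch("maldi_satisfactory", 1 - params$p_unsat,
             proposed_bloodmeal_stage(params))
    )
  )
}

#' Build the ideal (MALDI-only) scenario tree
#'
#' The counterfactual in which a complete reference database and good
#' sample storage make 100% of MALDI-TOF MS results reportable: every
#' sample incurs one head/thorax analysis, blood-fed samples one blood-meal
#' analysis, and no supplementary assays exist.
#'
#' @inheritParams build_current_workflow
#' @return A `workflow_node` tree.
#' @export
build_ideal_workflow <- function(params = workflow_params()) {
  stopifnot(inherits(params, "workflow_params"))
  chance_node(
    assays = list("maldi_head_thorax"),
    branches = list(
      branch("blood_fed", params$p_bloodfed, terminal_node(list("maldi_bloodmeal"))),
      branch("unfed", 1 - params$p_bloodfed, terminal_node())
    )
  )
}

workflow_builders <- function() {
  list(
    current = build_current_workflow,
    proposed = build_proposed_workflow,
    ideal = build_ideal_workflow
  )
}

#' Evaluate a bundled workflow by name
#'
#' @param workflow One of `"current"`, `"proposed"`, `"ideal"`.
#' @param params A [workflow_params()]; its `cohort_size` is used.
#' @param profiles Assay profiles; defaults to [reference_profiles()].
#' @return A [evaluate_cohort()] result.
#' @export
#' @examples
#' evaluate_workflow("ideal")$totals
evaluate_workflow <- function(workflow = c("current", "proposed", "ideal"),
                              params = workflow_params(),
                              profiles = reference_profiles(params)) {
  workflow <- match.arg(workflow)
  tree <- workflow_builders()[[workflow]](params)
  evaluate_cohort(tree, params$cohort_size, profiles)
}
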