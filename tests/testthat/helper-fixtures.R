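# Shared fixtures built in code.

# two-assay profile table with unit payoffs, handy for linearity checks
unit_profiles <- function() {
  rbind(
    assay_profile("unit", 1, 1, 1, 1),
    assay_profile("two", 2, 2, 2, 2)
  )
}

# minimal one-split tree: p goes to assay "unit", 1-p to nothing
split_tree <- function(p = 0.2, assay = "unit") {
  chance_node(branches = list(
    branch("yes", p, terminal_node(list(assay))),
    branch("no", 1 - p, terminal_node())
  ))
}

nmcp_config_path <- function() {
  system.file("extdata", "nmcp.yaml", package = "entocost")
}

expected_table1 <- function() {
  # printed per-sample payoffs of the case study (time, materials, labour)
  list(
    maldi = c(2.010, 0.59, 0.11),
    pcr = c(2.620, 1.49, 0.30),
    sanger = c(15.958, 23.23, 0.51),
    csp = c(4.245, 0.30, 0.12),
    csp_repeat = c(4.245, 0.30, 0.12),
    bloodmeal = c(3.900, 1.21, 0.06)
  )
}
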