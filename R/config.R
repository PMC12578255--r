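# YAML model configs: assay profiles, labour rate, cohort size and workflow
# trees serialized as nested nodes (so probability grouping stays local).
# USD amounts are stored as decimal strings in the bundled fixtures and
# parsed with as.numeric, keeping the text files free of binary-float drift.

config_error <- function(key, why) {
  stop_entocost(sprintf("config error at `%s`: %s", key, why), "entocost_config_error")
}

parse_num <- function(x, key, min = 0) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) config_error(key, "must be a number")
  if (v < min) config_error(key, sprintf("must be >= %g", min))
  v
}

parse_config_node <- function(x, key) {
  if (!is.list(x)) config_error(key, "node must be a mapping")
  allowed <- c("assays", "branches")
  extra <- setdiff(names(x), allowed)
  if (length(extra)) config_error(paste0(key, ".", extra[1]), "unknown key")
  assays <- lapply(seq_along(x$assays %||% list()), function(i) {
    a <- x$assays[[i]]
    akey <- sprintf("%s.assays[%d]", key, i)
    if (is.character(a) && length(a) == 1L) return(assay_use(a))
    if (is.list(a) && !is.null(a$id)) {
      return(assay_use(a$id, dims = unlist(a$dims) %||% PAYOFF_DIMENSIONS))
    }
    config_error(akey, "must be an assay id string or {id, dims}")
  })
  if (is.null(x$branches)) return(terminal_node(assays))
  branches <- lapply(seq_along(x$branches), function(i) {
    b <- x$branches[[i]]
    bkey <- sprintf("%s.branches[%d]", key, i)
    if (!is.list(b)) config_error(bkey, "branch must be a mapping")
    if (is.null(b$label)) config_error(paste0(bkey, ".label"), "missing")
    if (is.null(b$probability)) config_error(paste0(bkey, ".probability"), "missing")
    prob <- parse_num(b$probability, paste0(bkey, ".probability"), min = -Inf)
    branch(as.character(b$label), prob,
           parse_config_node(b$node %||% list(), paste0(bkey, ".node")))
  })
  chance_node(branches, assays = assays)
}

tree_assay_ids <- function(tree) {
  ids <- vapply(tree$assays, function(a) a$id, character(1))
  for (b in tree$branches %||% list()) ids <- c(ids, tree_assay_ids(b$child))
  unique(ids)
}

#' Load and validate a model configuration
#'
#' Reads a YAML config with keys `cohort_size`, `profiles` (a list of assay
#' profile records), optional `labour_rate`, and `workflows` (a named map
#' of nested tree nodes; each node has optional `assays` — assay id strings
#' or `{id, dims}` records for dimension-masked occurrences — and optional
#' `branches` of `{label, probability, node}`). The config is
#' schema-checked (violations name the offending key), every workflow tree
#' must pass [validate_tree()] — probabilities are never silently
#' renormalized — and every referenced assay id must have a profile.
#'
#' @param path Path to a YAML config file; see
#'   `system.file("extdata", "nmcp.yaml", package = "entocost")` for the
#'   bundled case-study config.
#' @return A list of class `model_config` with elements `cohort_size`,
#'   `profiles` (data.frame), `labour_rate` (or `NULL`) and `workflows`
#'   (named list of `workflow_node` trees).
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "nmcp.yaml", package = "entocost"))
#' names(cfg$workflows)
#' evaluate_cohort(cfg$workflows$ideal, cfg$cohort_size, cfg$profiles)$totals
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_entocost(sprintf("config file not found: %s", path), "entocost_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) config_error("(root)", "must be a mapping")
  for (k in c("cohort_size", "profiles", "workflows")) {
    if (is.null(raw[[k]])) config_error(k, "missing required key")
  }
  cohort_size <- parse_num(raw$cohort_size, "cohort_size")
  profiles <- do.call(rbind, lapply(seq_along(raw$profiles), function(i) {
    p <- raw$profiles[[i]]
    key <- sprintf("profiles[%d]", i)
    for (k in c("assay_id", "time_per_sample", "adjusted_time_per_sample",
                "materials_cost_per_sample", "labour_cost_per_sample")) {
      if (is.null(p[[k]])) config_error(paste0(key, ".", k), "missing required key")
    }
    assay_profile(
      as.character(p$assay_id),
      parse_num(p$time_per_sample, paste0(key, ".time_per_sample")),
      parse_num(p$adjusted_time_per_sample, paste0(key, ".adjusted_time_per_sample")),
      parse_num(p$materials_cost_per_sample, paste0(key, ".materials_cost_per_sample")),
      parse_num(p$labour_cost_per_sample, paste0(key, ".labour_cost_per_sample"))
    )
  }))
  rate <- NULL
  if (!is.null(raw$labour_rate)) {
    lr <- raw$labour_rate
    rate <- labour_rate(
      parse_num(lr$annual_salary %||% 0, "labour_rate.annual_salary"),
      parse_num(lr$hours_per_week %||% 40, "labour_rate.hours_per_week"),
      parse_num(lr$weeks_per_year %||% 52, "labour_rate.weeks_per_year"),
      if (!is.null(lr$rate_per_minute)) parse_num(lr$rate_per_minute, "labour_rate.rate_per_minute")
    )
  }
  if (!is.list(raw$workflows) || is.null(names(raw$workflows))) {
    config_error("workflows", "must be a named mapping of trees")
  }
  workflows <- lapply(names(raw$workflows), function(nm) {
    tree <- parse_config_node(raw$workflows[[nm]], paste0("workflows.", nm))
    diags <- validate_tree(tree)
    if (length(diags)) {
      config_error(paste0("workflows.", nm), paste(diags, collapse = "; "))
    }
    unknown <- setdiff(tree_assay_ids(tree), profiles$assay_id)
    if (length(unknown)) {
      stop_entocost(
        sprintf("config error at `workflows.%s`: unknown assay id(s): %s",
                nm, paste(unknown, collapse = ", ")),
        c("entocost_reference_error", "entocost_config_error")
      )
    }
    tree
  })
  names(workflows) <- names(raw$workflows)
  structure(
    list(cohort_size = cohort_size, profiles = profiles,
         labour_rate = rate, workflows = workflows),
    class = "model_config"
  )
}

node_to_config <- function(node) {
  out <- list()
  if (length(node$assays)) {
    out$assays <- lapply(node$assays, function(a) {
      if (identical(a$dims, PAYOFF_DIMENSIONS)) a$id else list(id = a$id, dims = as.list(a$dims))
    })
  }
  if (!is.null(node$branches)) {
    out$branches <- lapply(node$branches, function(b) {
      list(label = b$label, probability = b$probability,
           node = node_to_config(b$child))
    })
  }
  out
}

#' Serialize workflows and profiles to a YAML config
#'
#' Inverse of [load_config()]: writing then re-loading yields equivalent
#' trees and profiles. Currency and time values are written as decimal
#' strings.
#'
#' @param workflows Named list of `workflow_node` trees.
#' @param profiles Assay profile data.frame.
#' @param cohort_size Cohort size recorded in the config.
#' @param path Output file path.
#' @param labour_rate Optional [labour_rate()] block.
#' @return `path`, invisibly.
#' @export
write_config <- function(workflows, profiles, cohort_size, path,
                         labour_rate = NULL) {
  profiles <- as_profile_frame(profiles)
  num_str <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  cfg <- list(
    cohort_size = cohort_size,
    profiles = lapply(seq_len(nrow(profiles)), function(i) {
      list(
        assay_id = profiles$assay_id[i],
        time_per_sample = num_str(profiles$time_per_sample[i]),
        adjusted_time_per_sample = num_str(profiles$adjusted_time_per_sample[i]),
        materials_cost_per_sample = num_str(profiles$materials_cost_per_sample[i]),
        labour_cost_per_sample = num_str(profiles$labour_cost_per_sample[i])
      )
    }),
    workflows = lapply(workflows, node_to_config)
  )
  if (!is.null(labour_rate)) {
    cfg$labour_rate <- list(
      annual_salary = num_str(labour_rate$annual_salary),
      hours_per_week = labour_rate$hours_per_week,
      weeks_per_year = labour_rate$weeks_per_year
    )
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
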