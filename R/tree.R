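# Decision-tree representation and deterministic cohort evaluation.
#
# A workflow tree is a rooted tree of chance nodes. Every node may carry
# assays applied to all samples reaching it; chance nodes additionally split
# the flow over probability-labelled branches. Terminal paths therefore
# accumulate the assay payoffs of every node along the way, and a
# deterministic cohort evaluation rolls an expected (fractional) sample
# count down every path.

PAYOFF_DIMENSIONS <- c("time", "materials", "labour")

#' Assay applied at a tree node
#'
#' @param id Assay identifier; must match an [assay_profile()] at evaluation.
#' @param dims Payoff dimensions this assay occurrence contributes to.
#'   Defaults to all of time, materials and labour. A restricted mask lets a
#'   repeated confirmatory assay add cost without adding calendar time, for
#'   example when it runs alongside the primary plate.
#' @return An object of class `assay_use`.
#' @export
assay_use <- function(id, dims = PAYOFF_DIMENSIONS) {
  stopifnot(is.character(id), length(id) == 1L)
  dims <- match.arg(dims, PAYOFF_DIMENSIONS, several.ok = TRUE)
  structure(list(id = id, dims = dims), class = "assay_use")
}

as_assay_use <- function(x) {
  if (inherits(x, "assay_use")) return(x)
  if (is.character(x) && length(x) == 1L) return(assay_use(x))
  stop_entocost("assays must be assay_use objects or single assay id strings",
                "entocost_validation_error")
}

#' Tree node constructors
#'
#' `terminal_node()` ends a path; `chance_node()` splits it over
#' probability-labelled branches created with `branch()`. Both node kinds
#' may carry `assays` applied to every sample passing through them.
#'
#' @param assays List of [assay_use()] objects (or bare assay id strings).
#' @param branches List of `branch()` objects; probabilities at a chance
#'   node must sum to 1 (checked by [validate_tree()] to 1e-9; silent
#'   renormalization is refused).
#' @return An object of class `workflow_node`.
#' @export
#' @examples
#' tree <- chance_node(
#'   assays = list("pcr_species", "csp_elisa"),
#'   branches = list(
#'     branch("blood_fed", 0.2, terminal_node(list("bloodmeal_elisa"))),
#'     branch("unfed", 0.8, terminal_node())
#'   )
#' )
#' validate_tree(tree)
chance_node <- function(branches, assays = list()) {
  stopifnot(is.list(branches), length(branches) >= 1L)
  lapply(branches, function(b) {
    if (!inherits(b, "workflow_branch")) {
      stop_entocost("chance_node branches must be created with branch()",
                    "entocost_validation_error")
    }
  })
  structure(
    list(assays = lapply(assays, as_assay_use), branches = branches),
    class = "workflow_node"
  )
}

#' @rdname chance_node
#' @export
terminal_node <- function(assays = list()) {
  structure(
    list(assays = lapply(assays, as_assay_use), branches = NULL),
    class = "workflow_node"
  )
}

#' @rdname chance_node
#' @param label Branch label used in path names and diagnostics.
#' @param probability Branch probability in `[0, 1]`.
#' @param node Child `workflow_node`.
#' @export
branch <- function(label, probability, node) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!inherits(node, "workflow_node")) {
    stop_entocost("branch child must be a workflow_node", "entocost_validation_error")
  }
  structure(
    list(label = label, probability = as.numeric(probability), child = node),
    class = "workflow_branch"
  )
}

#' @export
print.workflow_node <- function(x, ...) {
  print_node <- function(node, prefix, lbl, p) {
    ids <- vapply(node$assays, function(a) a$id, character(1))
    head <- if (is.null(lbl)) "root" else sprintf("%s (p=%g)", lbl, p)
    cat(prefix, head,
        if (length(ids)) paste0(" [", paste(ids, collapse = ", "), "]") else "",
        "\n", sep = "")
    for (b in node$branches %||% list()) {
      print_node(b$child, paste0(prefix, "  "), b$label, b$probability)
    }
  }
  print_node(x, "", NULL, NULL)
  invisible(x)
}

#' Validate a workflow tree
#'
#' Checks every chance node: each branch probability lies in `[0, 1]` and
#' the probabilities sum to 1 within 1e-9. Violations are returned as
#' diagnostics (one per violation, locating the node by its branch-label
#' path), never thrown, and never silently renormalized.
#'
#' @param tree A `workflow_node`.
#' @param max_depth Guard against runaway recursion in hand-built structures.
#' @return Character vector of diagnostics; empty if the tree is valid.
#' @export
validate_tree <- function(tree, max_depth = 64L) {
  diags <- character()
  walk <- function(node, path, depth) {
    if (depth > max_depth) {
      diags <<- c(diags, sprintf("node '%s': depth exceeds %d (cycle or runaway tree?)",
                                 path, max_depth))
      return()
    }
    if (!inherits(node, "workflow_node")) {
      diags <<- c(diags, sprintf("node '%s': not a workflow_node", path))
      return()
    }
    if (!is.null(node$branches)) {
      probs <- vapply(node$branches, function(b) b$probability, numeric(1))
      for (i in seq_along(probs)) {
        if (is.na(probs[i]) || probs[i] < 0 || probs[i] > 1) {
          diags <<- c(diags, sprintf(
            "node '%s': branch '%s' probability %s outside [0, 1]",
            path, node$branches[[i]]$label, format(probs[i])
          ))
        }
      }
      if (!anyNA(probs) && abs(sum(probs) - 1) > 1e-9) {
        diags <<- c(diags, sprintf(
          "node '%s': probabilities sum to %.12g, expected 1", path, sum(probs)
        ))
      }
      for (b in node$branches) {
        walk(b$child, paste(path, b$label, sep = "/"), depth + 1L)
      }
    }
  }
  walk(tree, "", 1L)
  diags
}

#' Enumerate terminal paths of a workflow tree
#'
#' Closed-form equivalent of decision-tree rollback: each terminal path is
#' returned with its label sequence, its probability (the product of branch
#' probabilities along it) and the multiset of assay occurrences collected
#' from every node on the path (with their dimension masks).
#'
#' @param tree A valid `workflow_node` (see [validate_tree()]).
#' @return A list of paths, each a list with elements `labels`,
#'   `probability` and `assays`.
#' @export
enumerate_paths <- function(tree) {
  diags <- validate_tree(tree)
  if (length(diags)) {
    stop_entocost(paste0("invalid tree:\n", paste(diags, collapse = "\n")),
                  "entocost_validation_error")
  }
  paths <- list()
  walk <- function(node, labels, prob, assays) {
    assays <- c(assays, node$assays)
    if (is.null(node$branches)) {
      paths[[length(paths) + 1L]] <<- list(
        labels = labels, probability = prob, assays = assays
      )
      return()
    }
    for (b in node$branches) {
      walk(b$child, c(labels, b$label), prob * b$probability, assays)
    }
  }
  walk(tree, character(), 1, list())
  paths
}

# per-path per-sample payoff in each dimension, honouring dimension masks
path_payoff <- function(assays, profiles) {
  out <- c(time = 0, materials = 0, labour = 0)
  for (a in assays) {
    row <- profiles[profiles$assay_id == a$id, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop_entocost(sprintf("no assay profile for '%s'", a$id), "entocost_unknown_assay_error")
    }
    vals <- c(
      time = row$time_per_sample[1],
      materials = row$materials_cost_per_sample[1],
      labour = row$labour_cost_per_sample[1]
    )
    out[a$dims] <- out[a$dims] + vals[a$dims]
  }
  out
}

as_profile_frame <- function(profiles) {
  if (inherits(profiles, "data.frame")) return(profiles)
  if (is.list(profiles)) return(do.call(rbind, profiles))
  stop_entocost("`profiles` must be a data.frame of assay profiles", "entocost_validation_error")
}

#' Deterministic cohort evaluation of a workflow tree
#'
#' Rolls an expected (fractional) count of samples down every terminal path:
#' `cohort_size * path probability` samples incur the summed per-sample
#' payoffs of the assays on that path. Totals are accumulated for time,
#' materials and labour; direct cost is materials plus labour.
#'
#' @param tree A valid `workflow_node`.
#' @param cohort_size Number of samples (non-negative; fractional expected
#'   counts are kept, never rounded).
#' @param profiles A data.frame of [assay_profile()] rows (or a list of
#'   them) covering every assay id referenced by the tree.
#' @return An object of class `cohort_evaluation` with elements
#'   `cohort_size`, `paths` (a data.frame with one row per terminal path:
#'   labels, probability, expected count, per-sample payoffs), `totals` and
#'   `per_sample` (named vectors over time/materials/labour/direct).
#' @export
#' @examples
#' profiles <- reference_profiles()
#' ev <- evaluate_cohort(build_current_workflow(), 15000, profiles)
#' ev$totals["time"] # 141795.75 minutes
evaluate_cohort <- function(tree, cohort_size, profiles) {
  check_number(cohort_size, "cohort_size", min = 0)
  profiles <- as_profile_frame(profiles)
  paths <- enumerate_paths(tree)
  payoff <- t(vapply(paths, function(p) path_payoff(p$assays, profiles), numeric(3)))
  probs <- vapply(paths, `[[`, numeric(1), "probability")
  counts <- cohort_size * probs
  totals <- as.numeric(counts %*% payoff)
  names(totals) <- PAYOFF_DIMENSIONS
  totals <- c(totals, direct = unname(totals["materials"] + totals["labour"]))
  per_sample <- if (cohort_size > 0) totals / cohort_size else totals * NA_real_
  path_frame <- data.frame(
    path = vapply(paths, function(p) {
      if (length(p$labels)) paste(p$labels, collapse = "/") else "(root)"
    }, character(1)),
    probability = probs,
    expected_count = counts,
    time = payoff[, "time"],
    materials = payoff[, "materials"],
    labour = payoff[, "labour"],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      cohort_size = cohort_size,
      paths = path_frame,
      totals = totals,
      per_sample = per_sample
    ),
    class = "cohort_evaluation"
  )
}

#' Per-sample averages of a cohort evaluation
#'
#' @param evaluation A [evaluate_cohort()] result with positive cohort size.
#' @return Named vector of per-sample time (min), materials, labour and
#'   direct cost (USD).
#' @export
per_sample_average <- function(evaluation) {
  stopifnot(inherits(evaluation, "cohort_evaluation"))
  if (evaluation$cohort_size <= 0) {
    stop_entocost("per-sample average requires a positive cohort size",
                  "entocost_division_error")
  }
  evaluation$totals / evaluation$cohort_size
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> n = %s samples, %d terminal path(s)\n",
              format(x$cohort_size, big.mark = ","), nrow(x$paths)))
  cat(sprintf("  time      %s min\n", format(round(x$totals["time"], 2), big.mark = ",")))
  cat(sprintf("  materials %s USD\n", fmt_usd(x$totals["materials"])))
  cat(sprintf("  labour    %s USD\n", fmt_usd(x$totals["labour"])))
  cat(sprintf("  direct    %s USD\n", fmt_usd(x$totals["direct"])))
  invisible(x)
}
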