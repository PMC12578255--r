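# One-way and probabilistic sensitivity analysis over the deterministic
# model. The underlying study is deterministic; this module propagates
# parameter uncertainty through it, in the usual decision-modelling way:
# beta distributions on branch probabilities, gamma on costs and times.

#' Sensitivity-analysis targets
#'
#' A target names the quantity a [param_spec()] varies: either a
#' [workflow_params()] field (`target_param`) or one payoff field of an
#' assay profile (`target_payoff`).
#'
#' @param name A `workflow_params` field name, e.g. `"p_unsat"`.
#' @return An object of class `sa_target`.
#' @export
target_param <- function(name) {
  valid <- c("p_bloodfed", "p_unsat", "p_positive", "cohort_size",
             "parity_materials_per_sample", "parity_labour_per_sample",
             "parity_time_per_sample")
  if (!name %in% valid) {
    stop_entocost(sprintf("unknown workflow parameter '%s'", name),
                  "entocost_validation_error")
  }
  structure(
    list(kind = "param", name = name,
         is_probability = name %in% c("p_bloodfed", "p_unsat", "p_positive"),
         label = name),
    class = "sa_target"
  )
}

#' @rdname target_param
#' @param assay_id Assay whose profile is varied.
#' @param field One of `"time_per_sample"`, `"adjusted_time_per_sample"`,
#'   `"materials_cost_per_sample"`, `"labour_cost_per_sample"`.
#' @export
target_payoff <- function(assay_id,
                          field = c("materials_cost_per_sample",
                                    "labour_cost_per_sample",
                                    "time_per_sample",
                                    "adjusted_time_per_sample")) {
  field <- match.arg(field)
  structure(
    list(kind = "payoff", assay_id = assay_id, field = field,
         is_probability = FALSE,
         label = paste(assay_id, field, sep = ".")),
    class = "sa_target"
  )
}

#' Parameter specification for sensitivity analysis
#'
#' @param target A [target_param()] or [target_payoff()].
#' @param kind `"fixed"` (point mass), `"grid"` (one-way sweep values) or
#'   `"distribution"`.
#' @param value Point value when `kind = "fixed"`.
#' @param grid Numeric vector of sweep values when `kind = "grid"`.
#' @param distribution For `kind = "distribution"`: a list with `family`
#'   (`"beta"`, legal only for probability targets, with `shape1`/`shape2`;
#'   or `"gamma"`, for cost/time targets, with `shape` and `scale`).
#' @return An object of class `param_spec`.
#' @export
#' @examples
#' param_spec(target_param("p_bloodfed"), "distribution",
#'            distribution = list(family = "beta", shape1 = 20, shape2 = 80))
param_spec <- function(target, kind = c("fixed", "grid", "distribution"),
                       value = NULL, grid = NULL, distribution = NULL) {
  stopifnot(inherits(target, "sa_target"))
  kind <- match.arg(kind)
  if (kind == "fixed") {
    check_number(value, "value", min = 0)
    if (target$is_probability) check_probability(value, "value")
  } else if (kind == "grid") {
    if (is.null(grid) || !length(grid)) {
      stop_entocost("grid must be a non-empty numeric vector", "entocost_validation_error")
    }
    for (g in grid) {
      if (target$is_probability) check_probability(g, "grid value") else check_number(g, "grid value", min = 0)
    }
  } else {
    fam <- distribution$family %||% ""
    if (fam == "beta") {
      if (!target$is_probability) {
        stop_entocost("beta distributions are restricted to probability-valued targets",
                      "entocost_validation_error")
      }
      check_number(distribution$shape1, "shape1", min = 0)
      check_number(distribution$shape2, "shape2", min = 0)
      if (distribution$shape1 <= 0 || distribution$shape2 <= 0) {
        stop_entocost("beta shapes must be > 0", "entocost_validation_error")
      }
    } else if (fam == "gamma") {
      if (target$is_probability) {
        stop_entocost("gamma distributions apply to cost/time targets, not probabilities",
                      "entocost_validation_error")
      }
      check_number(distribution$shape, "shape", min = 0)
      check_number(distribution$scale, "scale", min = 0)
      if (distribution$shape <= 0 || distribution$scale <= 0) {
        stop_entocost("gamma shape and scale must be > 0", "entocost_validation_error")
      }
    } else {
      stop_entocost(sprintf("unknown distribution family '%s' (use beta or gamma)", fam),
                    "entocost_validation_error")
    }
  }
  structure(
    list(target = target, kind = kind, value = value, grid = grid,
         distribution = distribution),
    class = "param_spec"
  )
}

apply_target <- function(params, profiles, target, value) {
  if (target$kind == "param") {
    params[[target$name]] <- value
    # parity payoffs are mirrored in the profile table
    parity_cols <- c(parity_materials_per_sample = "materials_cost_per_sample",
                     parity_labour_per_sample = "labour_cost_per_sample",
                     parity_time_per_sample = "time_per_sample")
    if (target$name %in% names(parity_cols)) {
      i <- which(profiles$assay_id == "parity_dissection")
      if (length(i)) profiles[i, parity_cols[[target$name]]] <- value
    }
  } else {
    i <- which(profiles$assay_id == target$assay_id)
    if (!length(i)) {
      stop_entocost(sprintf("no assay profile for '%s'", target$assay_id),
                    "entocost_unknown_assay_error")
    }
    profiles[i, target$field] <- value
  }
  list(params = params, profiles = profiles)
}

evaluate_scenario_pair <- function(params, profiles, scenarios) {
  builders <- workflow_builders()
  base_ev <- evaluate_cohort(builders[[scenarios[1]]](params), params$cohort_size, profiles)
  alt_ev <- evaluate_cohort(builders[[scenarios[2]]](params), params$cohort_size, profiles)
  compare_workflows(base_ev, alt_ev, scenarios[1], scenarios[2])
}

saving_row <- function(report) {
  s <- stats::setNames(report$totals$saving, paste0("saving_", report$totals$dimension))
  p <- stats::setNames(report$totals$pct_saving, paste0("pct_", report$totals$dimension))
  c(s, p)
}

summarise_records <- function(records) {
  dims <- c("time", "materials", "labour", "direct")
  do.call(rbind, lapply(dims, function(d) {
    x <- records[[paste0("saving_", d)]]
    data.frame(
      dimension = d,
      mean = mean(x), sd = stats::sd(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975)),
      p_saving_positive = mean(x > 0),
      stringsAsFactors = FALSE
    )
  }))
}

new_sensitivity_result <- function(records, summary, scenarios, kind) {
  structure(
    list(records = records, summary = summary,
         scenarios = scenarios, kind = kind),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s, %s vs %s, %d record(s)\n",
              x$kind, x$scenarios[1], x$scenarios[2], nrow(x$records)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' One-way (deterministic) sensitivity sweep
#'
#' Re-evaluates the scenario comparison at each grid value of a single
#' parameter, holding all other inputs at their base values. Record order
#' matches grid order.
#'
#' @param base_params Base [workflow_params()].
#' @param spec A [param_spec()] with `kind = "grid"`.
#' @param scenarios Length-2 character vector: baseline and alternative
#'   workflow names (see [evaluate_workflow()]).
#' @param profiles Base assay profiles.
#' @return A `sensitivity_result`: `records` has one row per grid value
#'   with the parameter value and the absolute/percent saving per
#'   dimension; `summary` gives mean, sd, 2.5/97.5 percentiles and the
#'   fraction of records with positive saving.
#' @export
#' @examples
#' sw <- one_way_sweep(
#'   workflow_params(),
#'   param_spec(target_param("p_unsat"), "grid", grid = c(0, 0.1, 0.2))
#' )
#' sw$records[, c("value", "saving_direct")]
one_way_sweep <- function(base_params, spec,
                          scenarios = c("current", "proposed"),
                          profiles = reference_profiles(base_params)) {
  stopifnot(inherits(spec, "param_spec"))
  if (spec$kind != "grid") {
    stop_entocost("one_way_sweep requires a grid param_spec", "entocost_validation_error")
  }
  records <- do.call(rbind, lapply(spec$grid, function(v) {
    st <- apply_target(base_params, profiles, spec$target, v)
    rep_ <- evaluate_scenario_pair(st$params, st$profiles, scenarios)
    as.data.frame(as.list(c(value = v, saving_row(rep_))))
  }))
  records$target <- spec$target$label
  new_sensitivity_result(records, summarise_records(records), scenarios, "one-way sweep")
}

draw_spec <- function(spec, n) {
  switch(spec$kind,
    fixed = rep(spec$value, n),
    distribution = {
      d <- spec$distribution
      if (d$family == "beta") stats::rbeta(n, d$shape1, d$shape2)
      else stats::rgamma(n, shape = d$shape, scale = d$scale)
    },
    stop_entocost("probabilistic_sa accepts fixed or distribution specs",
                  "entocost_validation_error")
  )
}

#' Probabilistic sensitivity analysis (PSA)
#'
#' Draws `n_draws` independent joint parameter sets from the given
#' distributions (beta for probabilities, gamma for costs/times, point
#' masses for fixed parameters), evaluates the deterministic model at each
#' draw, and summarises the resulting saving distributions. Fully
#' reproducible for a given seed; the caller's RNG state is untouched.
#'
#' @param base_params Base [workflow_params()].
#' @param specs A list of [param_spec()] objects (kinds `fixed` or
#'   `distribution`).
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed.
#' @inheritParams one_way_sweep
#' @return A `sensitivity_result`; `records` has one row per draw with the
#'   drawn parameter values (columns named by target) and savings.
#' @export
#' @examples
#' psa <- probabilistic_sa(
#'   workflow_params(),
#'   list(param_spec(target_param("p_bloodfed"), "distribution",
#'                   distribution = list(family = "beta", shape1 = 20, shape2 = 80))),
#'   n_draws = 200, seed = 42
#' )
#' psa$summary
probabilistic_sa <- function(base_params, specs, n_draws, seed,
                             scenarios = c("current", "proposed"),
                             profiles = reference_profiles(base_params)) {
  check_number(n_draws, "n_draws", min = 1)
  check_number(seed, "seed")
  specs <- if (inherits(specs, "param_spec")) list(specs) else specs
  draws <- with_local_seed(seed, {
    m <- lapply(specs, draw_spec, n = n_draws)
    names(m) <- vapply(specs, function(s) s$target$label, character(1))
    m
  })
  records <- do.call(rbind, lapply(seq_len(n_draws), function(i) {
    params <- base_params
    profs <- profiles
    for (j in seq_along(specs)) {
      st <- apply_target(params, profs, specs[[j]]$target, draws[[j]][i])
      params <- st$params
      profs <- st$profiles
    }
    rep_ <- evaluate_scenario_pair(params, profs, scenarios)
    vals <- vapply(seq_along(specs), function(j) draws[[j]][i], numeric(1))
    names(vals) <- names(draws)
    as.data.frame(as.list(c(vals, saving_row(rep_))))
  }))
  new_sensitivity_result(records, summarise_records(records), scenarios, "probabilistic SA")
}
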