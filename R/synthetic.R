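# Random valid model inputs and a stochastic cohort simulator.
#
# The generators exist so that every stage of the engine is testable on
# inputs it has never seen; the simulator routes individual samples through
# the tree by random draws and is the independent stochastic check on the
# deterministic expected-value evaluation (law of large numbers).

#' Configuration for the random-input generators
#'
#' @param seed Integer seed; every generator call is reproducible from it
#'   and leaves the global RNG state untouched.
#' @param n_assays Number of assays to generate ids/profiles for.
#' @param max_depth Maximum tree depth (root = depth 1; `max_depth = 1`
#'   yields a single terminal node).
#' @param max_branching Maximum branches per chance node (>= 2).
#' @param price_range Uniform range for item unit prices (USD).
#' @param quantity_range Uniform range for item quantities per batch.
#' @param time_range Uniform range for per-sample assay times (minutes).
#' @param cost_range Uniform range for per-sample assay costs (USD).
#' @param max_items Maximum items per cost table.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed, n_assays = 5L, max_depth = 3L,
                             max_branching = 3L,
                             price_range = c(0, 50),
                             quantity_range = c(0, 10),
                             time_range = c(0.5, 20),
                             cost_range = c(0.05, 25),
                             max_items = 8L) {
  check_number(seed, "seed")
  check_number(n_assays, "n_assays", min = 1)
  check_number(max_depth, "max_depth", min = 1)
  check_number(max_branching, "max_branching", min = 2)
  for (r in list(price_range, quantity_range, time_range, cost_range)) {
    if (length(r) != 2L || any(r < 0) || r[1] > r[2]) {
      stop_entocost("ranges must be ordered non-negative pairs", "entocost_validation_error")
    }
  }
  structure(
    list(seed = as.integer(seed), n_assays = as.integer(n_assays),
         max_depth = as.integer(max_depth),
         max_branching = as.integer(max_branching),
         price_range = price_range, quantity_range = quantity_range,
         time_range = time_range, cost_range = cost_range,
         max_items = as.integer(max_items)),
    class = "generator_config"
  )
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a random item-level cost table
#'
#' Item prices and quantities are uniform within the configured ranges;
#' `samples_per_batch` is drawn from \{90, 47\} (molecular vs MALDI plate).
#'
#' @param config A [generator_config()].
#' @return A [cost_item_table()].
#' @export
random_cost_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- sample.int(config$max_items, 1L)
    cost_item_table(
      assay_id = sprintf("assay_%d", sample.int(config$n_assays, 1L)),
      items = data.frame(
        item = sprintf("item_%d", seq_len(n)),
        unit_price = runif_range(n, config$price_range),
        quantity_per_batch = runif_range(n, config$quantity_range),
        stringsAsFactors = FALSE
      ),
      samples_per_batch = sample(c(90L, 47L), 1L)
    )
  })
}

#' Generate random assay profiles
#'
#' One profile per assay id `assay_1 ... assay_n`; adjusted time is a
#' uniform fraction of raw time, costs uniform within the cost range.
#'
#' @param config A [generator_config()].
#' @return A data.frame of [assay_profile()] rows.
#' @export
random_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed + 1L, {
    do.call(rbind, lapply(seq_len(config$n_assays), function(i) {
      raw <- runif_range(1, config$time_range)
      assay_profile(
        sprintf("assay_%d", i),
        time_per_sample = raw,
        adjusted_time_per_sample = raw * stats::runif(1),
        materials_cost_per_sample = runif_range(1, config$cost_range),
        labour_cost_per_sample = runif_range(1, config$cost_range)
      )
    }))
  })
}

#' Generate a random valid workflow tree
#'
#' Chance-node probabilities are normalized uniform draws (summing to 1 by
#' construction); node assays are sampled from the config's assay ids; the
#' tree never exceeds `max_depth`. Every generated tree passes
#' [validate_tree()].
#'
#' @param config A [generator_config()].
#' @return A `workflow_node`.
#' @export
random_tree <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed + 2L, {
    rand_assays <- function() {
      k <- sample.int(3L, 1L) - 1L # 0..2 assays per node
      lapply(sample.int(config$n_assays, k, replace = TRUE),
             function(i) assay_use(sprintf("assay_%d", i)))
    }
    build <- function(depth) {
      if (depth >= config$max_depth ||
          (depth > 1L && stats::runif(1) < 0.3)) {
        return(terminal_node(rand_assays()))
      }
      k <- sample(2:config$max_branching, 1L)
      w <- stats::runif(k)
      probs <- w / sum(w)
      # force exact unit sum despite float normalization
      probs[k] <- 1 - sum(probs[-k])
      chance_node(
        assays = rand_assays(),
        branches = lapply(seq_len(k), function(i) {
          branch(sprintf("b%d_%d", depth, i), probs[i], build(depth + 1L))
        })
      )
    }
    build(1L)
  })
}

#' Stochastic cohort simulation
#'
#' Routes `cohort_size` individual samples through the tree by independent
#' categorical draws at every chance node (implemented by equivalent
#' multinomial splitting of the count arriving at the node) and sums the
#' realized per-sample payoffs. Over replicates its mean converges to
#' [evaluate_cohort()]'s expected totals, which is the package's
#' independent check on the deterministic engine.
#'
#' @param tree A valid `workflow_node`.
#' @param cohort_size Non-negative integer number of samples.
#' @param profiles Assay profiles covering the tree's assay ids.
#' @param seed Integer seed; identical seeds give identical realizations.
#' @return Named numeric vector of realized totals
#'   (time/materials/labour/direct).
#' @export
#' @examples
#' profiles <- reference_profiles()
#' tree <- build_current_workflow()
#' simulate_cohort(tree, 1000, profiles, seed = 1)
simulate_cohort <- function(tree, cohort_size, profiles, seed) {
  check_number(cohort_size, "cohort_size", min = 0)
  check_number(seed, "seed")
  diags <- validate_tree(tree)
  if (length(diags)) {
    stop_entocost(paste0("invalid tree:\n", paste(diags, collapse = "\n")),
                  "entocost_validation_error")
  }
  profiles <- as_profile_frame(profiles)
  totals <- c(time = 0, materials = 0, labour = 0)
  with_local_seed(seed, {
    walk <- function(node, count) {
      if (count > 0 && length(node$assays)) {
        totals <<- totals + count * path_payoff(node$assays, profiles)
      }
      if (!is.null(node$branches)) {
        probs <- vapply(node$branches, function(b) b$probability, numeric(1))
        split <- if (count > 0) {
          as.integer(stats::rmultinom(1, size = count, prob = probs))
        } else {
          integer(length(probs))
        }
        for (i in seq_along(node$branches)) {
          walk(node$branches[[i]]$child, split[i])
        }
      }
    }
    walk(tree, as.integer(round(cohort_size)))
  })
  c(totals, direct = unname(totals["materials"] + totals["labour"]))
}
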