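# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_entocost <- function(msg, class) {
  stop(structure(
    class = c(class, "entocost_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_entocost(sprintf("`%s` must be a single number", name), "entocost_validation_error")
  }
  if (x < min) {
    stop_entocost(sprintf("`%s` must be >= %g (got %g)", name, min, x), "entocost_validation_error")
  }
  invisible(as.numeric(x))
}

check_probability <- function(x, name) {
  check_number(x, name, min = 0)
  if (x > 1) {
    stop_entocost(sprintf("`%s` must lie in [0, 1] (got %g)", name, x), "entocost_validation_error")
  }
  invisible(as.numeric(x))
}

# Evaluate `expr` under a local RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

fmt_usd <- function(x, digits = 2) {
  formatC(round(x, digits), format = "f", digits = digits, big.mark = ",")
}
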