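#' Item-level cost table for one assay
#'
#' A micro-costing table lists every reagent and consumable consumed to
#' process one full batch (plate) of an assay, together with the number of
#' samples that batch accommodates. Per-sample materials cost is the batch
#' total divided by the batch size: molecular assays (PCR, ELISA, Sanger
#' sequencing) are costed at 90 samples per plate, MALDI-TOF MS at 47
#' samples per target plate.
#'
#' @param assay_id Character scalar naming the assay.
#' @param items A data.frame with columns `item` (character), `unit_price`
#'   (USD, non-negative) and `quantity_per_batch` (non-negative amount of
#'   the item consumed per batch). May have zero rows.
#' @param samples_per_batch Positive integer; number of samples per plate.
#'   Defaults to 90 (molecular); use 47 for MALDI plates.
#'
#' @return An object of class `cost_item_table`.
#' @seealso [per_sample_material_cost()], [read_cost_items()]
#' @export
#' @examples
#' tab <- cost_item_table(
#'   "pcr_species",
#'   data.frame(
#'     item = c("taq_mix", "primers"),
#'     unit_price = c(100, 34.10),
#'     quantity_per_batch = c(1, 1)
#'   ),
#'   samples_per_batch = 90
#' )
#' per_sample_material_cost(tab)
cost_item_table <- function(assay_id, items = NULL, samples_per_batch = 90L) {
  stopifnot(is.character(assay_id), length(assay_id) == 1L)
  if (is.null(items)) {
    items <- data.frame(
      item = character(), unit_price = numeric(),
      quantity_per_batch = numeric(), stringsAsFactors = FALSE
    )
  }
  required <- c("item", "unit_price", "quantity_per_batch")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop_entocost(
      sprintf("cost item table is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "entocost_validation_error"
    )
  }
  if (any(items$unit_price < 0, na.rm = FALSE) || anyNA(items$unit_price)) {
    stop_entocost("`unit_price` must be non-negative and non-missing", "entocost_validation_error")
  }
  if (any(items$quantity_per_batch < 0) || anyNA(items$quantity_per_batch)) {
    stop_entocost("`quantity_per_batch` must be non-negative and non-missing", "entocost_validation_error")
  }
  samples_per_batch <- check_number(samples_per_batch, "samples_per_batch", min = 0)
  if (samples_per_batch < 1) {
    stop_entocost("`samples_per_batch` must be a positive integer", "entocost_invalid_batch_error")
  }
  structure(
    list(
      assay_id = assay_id,
      items = items[required],
      samples_per_batch = as.integer(samples_per_batch)
    ),
    class = "cost_item_table"
  )
}

#' @export
print.cost_item_table <- function(x, ...) {
  cat(sprintf(
    "<cost_item_table> %s: %d item(s), %d samples/batch, %s USD/sample\n",
    x$assay_id, nrow(x$items), x$samples_per_batch,
    fmt_usd(per_sample_material_cost(x))
  ))
  invisible(x)
}

#' Per-sample materials cost from an item-level table
#'
#' Sums `unit_price * quantity_per_batch` over all items and divides by the
#' batch size. Full floating-point precision is kept; rounding to cents is a
#' display concern only.
#'
#' @param table A [cost_item_table()].
#' @return Materials cost per sample in USD.
#' @export
per_sample_material_cost <- function(table) {
  stopifnot(inherits(table, "cost_item_table"))
  if (table$samples_per_batch == 0) {
    stop_entocost("samples_per_batch must be positive", "entocost_invalid_batch_error")
  }
  sum(table$items$unit_price * table$items$quantity_per_batch) / table$samples_per_batch
}

#' Read cost items from CSV
#'
#' Reads an item-level price list with header `item,unit_price,quantity_per_batch`.
#'
#' @param path Path to a CSV file.
#' @param assay_id Assay name for the resulting table.
#' @param samples_per_batch Samples per plate (90 molecular, 47 MALDI).
#' @return A [cost_item_table()].
#' @export
read_cost_items <- function(path, assay_id, samples_per_batch = 90L) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  cost_item_table(assay_id, items, samples_per_batch)
}

#' Timed protocol steps
#'
#' @param label Character vector of step labels.
#' @param duration Numeric vector of durations in minutes (non-negative).
#' @param is_incubation Logical vector flagging hands-off incubation steps.
#' @return A data.frame of class `timed_steps`.
#' @export
timed_steps <- function(label, duration, is_incubation = FALSE) {
  n <- length(duration)
  label <- rep_len(as.character(label), n)
  is_incubation <- rep_len(as.logical(is_incubation), n)
  if (anyNA(duration) || any(duration < 0)) {
    stop_entocost("step durations must be non-negative", "entocost_validation_error")
  }
  structure(
    data.frame(
      label = label, duration = as.numeric(duration),
      is_incubation = is_incubation, stringsAsFactors = FALSE
    ),
    class = c("timed_steps", "data.frame")
  )
}

#' Hands-on ("adjusted") time of a protocol
#'
#' Labour is costed on adjusted time: the sum of all step durations
#' excluding incubation periods strictly longer than 60 minutes, during
#' which staff are assumed to work on other activities. An incubation of
#' exactly 60 minutes is retained.
#'
#' @param steps A [timed_steps()] data.frame.
#' @return Adjusted time in minutes.
#' @export
#' @examples
#' s <- timed_steps(
#'   c("setup", "incubate", "read"),
#'   c(30, 90, 12),
#'   c(FALSE, TRUE, FALSE)
#' )
#' adjusted_time(s) # 42: the 90-min incubation is excluded
adjusted_time <- function(steps) {
  if (!inherits(steps, "timed_steps")) steps <- timed_steps(steps$label, steps$duration, steps$is_incubation)
  excluded <- steps$is_incubation & steps$duration > 60
  sum(steps$duration[!excluded])
}

#' Per-sample time from a per-plate total
#'
#' @param total_assay_time Total assay time for one full plate, minutes.
#' @param samples_per_batch Samples per plate.
#' @return Time per sample in minutes.
#' @export
per_sample_time <- function(total_assay_time, samples_per_batch) {
  check_number(total_assay_time, "total_assay_time", min = 0)
  check_number(samples_per_batch, "samples_per_batch", min = 0)
  if (samples_per_batch < 1) {
    stop_entocost("`samples_per_batch` must be >= 1", "entocost_invalid_batch_error")
  }
  total_assay_time / samples_per_batch
}

#' Laboratory labour rate
#'
#' Derives a per-minute labour rate from an annual salary and working
#' pattern: `annual_salary / (weeks_per_year * hours_per_week * 60)`.
#' An explicit `rate_per_minute` overrides the derivation.
#'
#' @param annual_salary Annual salary in USD.
#' @param hours_per_week Contracted hours per week (default 40).
#' @param weeks_per_year Working weeks per year (default 52).
#' @param rate_per_minute Optional explicit rate overriding the derivation.
#' @return An object of class `labour_rate`.
#' @export
#' @examples
#' labour_rate(6289.82) # Kenyan lab-technician base salary, 0.0504 USD/min
labour_rate <- function(annual_salary, hours_per_week = 40, weeks_per_year = 52,
                        rate_per_minute = NULL) {
  check_number(annual_salary, "annual_salary", min = 0)
  check_number(hours_per_week, "hours_per_week", min = 0)
  check_number(weeks_per_year, "weeks_per_year", min = 0)
  if (is.null(rate_per_minute)) {
    rate_per_minute <- annual_salary / (weeks_per_year * hours_per_week * 60)
  } else {
    check_number(rate_per_minute, "rate_per_minute", min = 0)
  }
  structure(
    list(
      annual_salary = annual_salary, hours_per_week = hours_per_week,
      weeks_per_year = weeks_per_year, rate_per_minute = rate_per_minute
    ),
    class = "labour_rate"
  )
}

#' @export
print.labour_rate <- function(x, ...) {
  cat(sprintf(
    "<labour_rate> %s USD/yr at %g h/wk x %g wk/yr = %.6f USD/min\n",
    fmt_usd(x$annual_salary), x$hours_per_week, x$weeks_per_year, x$rate_per_minute
  ))
  invisible(x)
}

#' Labour cost of a sample
#'
#' @param adjusted_time Hands-on minutes per sample (see [adjusted_time()]).
#' @param rate A [labour_rate()].
#' @return Labour cost per sample in USD at full precision.
#' @export
labour_cost <- function(adjusted_time, rate) {
  check_number(adjusted_time, "adjusted_time", min = 0)
  stopifnot(inherits(rate, "labour_rate"))
  rate$rate_per_minute * adjusted_time
}

#' Direct cost per sample
#'
#' Direct cost is materials plus labour; capital, start-up and maintenance
#' costs are outside the model.
#'
#' @param materials Materials cost per sample, USD.
#' @param labour Labour cost per sample, USD.
#' @return Direct cost per sample, USD.
#' @export
direct_cost <- function(materials, labour) {
  check_number(materials, "materials", min = 0)
  check_number(labour, "labour", min = 0)
  materials + labour
}

#' Per-sample assay cost profile
#'
#' The per-sample payoff vector of one assay: raw time-to-results, adjusted
#' (hands-on) time, materials cost and labour cost. These are the quantities
#' the decision tree accumulates over a cohort.
#'
#' @param assay_id Character assay name.
#' @param time_per_sample Raw time-to-results per sample, minutes.
#' @param adjusted_time_per_sample Hands-on minutes per sample; must not
#'   exceed `time_per_sample`.
#' @param materials_cost_per_sample Materials USD per sample.
#' @param labour_cost_per_sample Labour USD per sample.
#' @return A one-row data.frame of class `assay_profile`.
#' @export
assay_profile <- function(assay_id, time_per_sample, adjusted_time_per_sample,
                          materials_cost_per_sample, labour_cost_per_sample) {
  check_number(time_per_sample, "time_per_sample", min = 0)
  check_number(adjusted_time_per_sample, "adjusted_time_per_sample", min = 0)
  check_number(materials_cost_per_sample, "materials_cost_per_sample", min = 0)
  check_number(labour_cost_per_sample, "labour_cost_per_sample", min = 0)
  if (adjusted_time_per_sample > time_per_sample + 1e-12) {
    stop_entocost("adjusted time cannot exceed raw time per sample", "entocost_validation_error")
  }
  structure(
    data.frame(
      assay_id = assay_id,
      time_per_sample = time_per_sample,
      adjusted_time_per_sample = adjusted_time_per_sample,
      materials_cost_per_sample = materials_cost_per_sample,
      labour_cost_per_sample = labour_cost_per_sample,
      stringsAsFactors = FALSE
    ),
    class = c("assay_profile", "data.frame")
  )
}

#' Build an assay profile from raw inputs
#'
#' Convenience wrapper tying the micro-costing primitives together: per-plate
#' timed steps and an item-level cost table become a per-sample profile.
#'
#' @param table A [cost_item_table()] (its `samples_per_batch` is the divisor).
#' @param steps Per-plate [timed_steps()].
#' @param rate A [labour_rate()].
#' @return An [assay_profile()].
#' @export
profile_from_components <- function(table, steps, rate) {
  spb <- table$samples_per_batch
  raw <- per_sample_time(sum(steps$duration), spb)
  adj <- per_sample_time(adjusted_time(steps), spb)
  mat <- per_sample_material_cost(table)
  assay_profile(table$assay_id, raw, adj, mat, labour_cost(adj, rate))
}
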