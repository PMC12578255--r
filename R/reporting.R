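# Pairwise comparison of cohort evaluations and table rendering.

#' Compare two cohort evaluations
#'
#' Computes, for each payoff dimension (time, materials, labour, direct),
#' the baseline and alternative totals, the absolute saving
#' `baseline - alternative`, and the percentage saving
#' `saving / baseline * 100`. All values are kept at full floating
#' precision; rounding happens only at rendering.
#'
#' @param baseline,alternative [evaluate_cohort()] results with equal
#'   cohort sizes.
#' @param baseline_label,alternative_label Labels used in rendered tables.
#' @return An object of class `comparison_report` with elements `totals`
#'   (a data.frame over the four dimensions), `per_sample` (same layout on
#'   per-sample scale), `cohort_size`, labels, and `time_display` (hour and
#'   day conversions of the time row, see [minutes_to_display()]).
#' @export
#' @examples
#' cur <- evaluate_workflow("current")
#' prop <- evaluate_workflow("proposed")
#' compare_workflows(cur, prop, "current", "proposed")
compare_workflows <- function(baseline, alternative,
                              baseline_label = "baseline",
                              alternative_label = "alternative") {
  stopifnot(inherits(baseline, "cohort_evaluation"),
            inherits(alternative, "cohort_evaluation"))
  if (baseline$cohort_size != alternative$cohort_size) {
    stop_entocost(
      sprintf("cohort sizes differ (%g vs %g); compare equal cohorts",
              baseline$cohort_size, alternative$cohort_size),
      "entocost_comparison_error"
    )
  }
  dims <- names(baseline$totals)
  saving <- baseline$totals - alternative$totals
  pct <- ifelse(baseline$totals != 0, saving / baseline$totals * 100, 0)
  totals <- data.frame(
    dimension = dims,
    baseline = as.numeric(baseline$totals),
    alternative = as.numeric(alternative$totals),
    saving = as.numeric(saving),
    pct_saving = as.numeric(pct),
    stringsAsFactors = FALSE
  )
  n <- baseline$cohort_size
  per_sample <- totals
  if (n > 0) {
    per_sample[c("baseline", "alternative", "saving")] <-
      per_sample[c("baseline", "alternative", "saving")] / n
  }
  time_row <- totals[totals$dimension == "time", ]
  time_display <- lapply(
    stats::setNames(
      c(time_row$baseline, time_row$alternative, max(time_row$saving, 0)),
      c("baseline", "alternative", "saving")
    ),
    minutes_to_display
  )
  structure(
    list(
      baseline_label = baseline_label,
      alternative_label = alternative_label,
      cohort_size = n,
      totals = totals,
      per_sample = per_sample,
      time_display = time_display
    ),
    class = "comparison_report"
  )
}

#' Convert minutes to display hours and calendar days
#'
#' Hours are exact (`minutes / 60`); days are calendar days rounded up
#' (`ceiling(minutes / 1440)`), the convention under which 141,795.75 min
#' reads as ~99 days and 36,180 min as 26 days.
#'
#' @param minutes Non-negative minutes.
#' @return A list with elements `hours` and `days`.
#' @export
#' @examples
#' minutes_to_display(141795.75) # 2363.2625 hours, 99 days
minutes_to_display <- function(minutes) {
  check_number(minutes, "minutes", min = 0)
  list(hours = minutes / 60, days = as.integer(ceiling(minutes / 1440)))
}

report_frame <- function(report, precision = 2) {
  dims <- report$totals$dimension
  label <- c(
    time = "Time (min)", materials = "Materials (USD)",
    labour = "Labour (USD)", direct = "Direct (USD)"
  )[dims]
  # per-sample minutes at 4 dp, currency at `precision`; % at 2 dp
  ps_digits <- ifelse(dims == "time", 4, precision)
  data.frame(
    dimension = unname(label),
    per_sample_baseline = round(report$per_sample$baseline, ps_digits),
    per_sample_alternative = round(report$per_sample$alternative, ps_digits),
    baseline = round(report$totals$baseline, precision),
    alternative = round(report$totals$alternative, precision),
    saving = round(report$totals$saving, precision),
    pct_saving = round(report$totals$pct_saving, 2),
    stringsAsFactors = FALSE
  )
}

#' Render a comparison report
#'
#' Emits the comparison as machine-readable CSV, an aligned plain-text
#' table, or a markdown table. Values are rounded half-even at the stated
#' precision at rendering time only; percentages always at 2 decimals and
#' per-sample minutes at 4. The CSV variant is bit-identical across runs.
#'
#' @param report A [compare_workflows()] result.
#' @param precision Decimal places for currency/total columns.
#' @param format One of `"csv"`, `"text"`, `"markdown"`.
#' @return The rendered table as a single character string.
#' @export
render_tables <- function(report, precision = 2,
                          format = c("text", "csv", "markdown")) {
  stopifnot(inherits(report, "comparison_report"))
  format <- match.arg(format)
  df <- report_frame(report, precision)
  header <- c(
    "dimension",
    paste0("per_sample_", report$baseline_label),
    paste0("per_sample_", report$alternative_label),
    report$baseline_label, report$alternative_label,
    "saving", "pct_saving"
  )
  if (format == "csv") {
    names(df) <- header
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  cells <- df
  for (j in 2:7) {
    digits <- c(NA, 4, 4, precision, precision, precision, 2)[j]
    if (j %in% 2:3) {
      digits <- ifelse(report$totals$dimension == "time", 4, precision)
      cells[[j]] <- mapply(function(v, d) formatC(v, format = "f", digits = d, big.mark = ","),
                           df[[j]], digits)
    } else {
      cells[[j]] <- formatC(df[[j]], format = "f", digits = digits, big.mark = ",")
    }
  }
  names(cells) <- header
  widths <- pmax(nchar(header), apply(cells, 2, function(x) max(nchar(x))))
  pad <- function(x, w) formatC(x, width = w)
  if (format == "markdown") {
    lines <- c(
      paste0("| ", paste(mapply(pad, header, widths), collapse = " | "), " |"),
      paste0("|", paste(vapply(widths, function(w) strrep("-", w + 2), character(1)),
                        collapse = "|"), "|"),
      apply(cells, 1, function(r) {
        paste0("| ", paste(mapply(pad, r, widths), collapse = " | "), " |")
      })
    )
  } else {
    lines <- c(
      paste(mapply(pad, header, widths), collapse = "  "),
      apply(cells, 1, function(r) paste(mapply(pad, r, widths), collapse = "  "))
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s, n = %s\n",
              x$baseline_label, x$alternative_label,
              format(x$cohort_size, big.mark = ",")))
  cat(render_tables(x, format = "text"))
  td <- x$time_display
  cat(sprintf(
    "time: %s %.4f h (~%d d) | %s %.4f h (~%d d) | saved %.4f h (~%d d)\n",
    x$baseline_label, td$baseline$hours, td$baseline$days,
    x$alternative_label, td$alternative$hours, td$alternative$days,
    td$saving$hours, td$saving$days
  ))
  invisible(x)
}
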