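# Single-patient classification against a normative control cohort.
#
# With one or two patient lines per condition, per-well rank tests lack
# power, so each patient value is instead compared against the control
# cohort's box-and-whisker limits ("inter-ocular trauma test"): a well is of
# interest when the patient falls outside the outer limits of the control
# box plot.

#' Control box-and-whisker limits for one well
#'
#' Quartiles use linear interpolation between order statistics at position
#' `(n - 1) * p` (the R default quantile, type 7), so limits are
#' reproducible bit-for-bit. With `method = "fence"` the outer limits are
#' the Tukey fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; with
#' `method = "whisker"` (default, what a box plot visually draws) they are
#' the most extreme control values lying within those fences.
#'
#' @param control_values at least 4 finite control values (log scale).
#' @param method `"whisker"` or `"fence"`.
#' @return `control_limits` list: `q1`, `q3`, `iqr`, `lower`, `upper`,
#'   `method`, `n`.
#' @export
control_limits <- function(control_values, method = c("whisker", "fence")) {
  method <- match.arg(method)
  if (length(control_values) < 4L) {
    stop_input("need at least 4 control values (got %d)", length(control_values))
  }
  if (!all(is.finite(control_values))) stop_input("non-finite control value")
  qs <- unname(stats::quantile(control_values, c(0.25, 0.75), type = 7))
  iqr <- qs[2L] - qs[1L]
  fence <- c(qs[1L] - 1.5 * iqr, qs[2L] + 1.5 * iqr)
  if (method == "fence") {
    lims <- fence
  } else {
    inside <- control_values[control_values >= fence[1L] &
                               control_values <= fence[2L]]
    # quartiles are interpolated data values, so at least half the controls
    # lie inside the fences and `inside` is never empty
    lims <- range(inside)
  }
  structure(list(q1 = qs[1L], q3 = qs[2L], iqr = iqr,
                 lower = lims[1L], upper = lims[2L], method = method,
                 n = length(control_values)),
            class = "control_limits")
}

#' Classify one value against control limits
#'
#' Boundary values classify as `"within"` (conservative for calling
#' abnormality).
#'
#' @param value numeric scalar (log-scale summary).
#' @param limits a [control_limits()] object.
#' @return `"below"`, `"within"` or `"above"`.
#' @export
classify_value <- function(value, limits) {
  stopifnot(inherits(limits, "control_limits"), is.finite(value))
  if (value > limits$upper) "above"
  else if (value < limits$lower) "below"
  else "within"
}

#' Classify one patient across all wells
#'
#' For each well with a patient value and at least 4 control values,
#' computes the control limits and classifies the patient. Wells lacking a
#' patient value are skipped, not an error; they are reported in the
#' `"skipped"` attribute of the result.
#'
#' @param summaries per-sample well summaries from [summarize_dataset()].
#' @param samples sample sheet (`sample_id`, `group`, `sex`).
#' @param patient_id id of the patient line to classify.
#' @param control_selector [sample_selector()] for the normative cohort
#'   (default: `group == "control"`).
#' @param method `"whisker"` or `"fence"`, see [control_limits()].
#' @param layout optional `pm_layout` for compound names.
#' @return data.frame `patient_id, plate, well, compound, value, lower,
#'   upper, method, call`, ordered by (plate, row, column); attribute
#'   `"skipped"` lists wells without a patient value.
#' @export
call_wells <- function(summaries, samples, patient_id,
                       control_selector = sample_selector(group = "control"),
                       method = c("whisker", "fence"), layout = NULL) {
  method <- match.arg(method)
  require_columns(summaries, c("sample_id", "plate", "well", "log_value"),
                  "summaries")
  controls <- select_samples(samples, control_selector)
  controls <- setdiff(controls, patient_id)
  if (length(controls) < 4L) {
    stop_input("control selector matched %d sample(s); need at least 4",
               length(controls))
  }
  ctl <- summaries[summaries$sample_id %in% controls, ]
  pat <- summaries[summaries$sample_id == patient_id, ]
  wells <- unique(ctl[, c("plate", "well")])
  wells <- wells[order(well_order_key(wells$plate, wells$well)), ]
  key <- function(df) paste(df$plate, df$well)
  pat_val <- pat$log_value[match(key(wells), key(pat))]
  skipped <- wells[is.na(pat_val), , drop = FALSE]

  ctl_split <- split(ctl$log_value, key(ctl))
  keep <- !is.na(pat_val)
  rows <- lapply(which(keep), function(i) {
    lim <- control_limits(ctl_split[[key(wells)[i]]], method)
    data.frame(patient_id = patient_id,
               plate = wells$plate[i], well = wells$well[i],
               compound = NA_character_, value = pat_val[i],
               lower = lim$lower, upper = lim$upper, method = method,
               call = classify_value(pat_val[i], lim),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(patient_id = character(), plate = character(),
               well = character(), compound = character(), value = numeric(),
               lower = numeric(), upper = numeric(), method = character(),
               call = character(), stringsAsFactors = FALSE)
  if (!is.null(layout) && nrow(out) > 0L) {
    out$compound <- layout$compound[match(paste(out$plate, out$well),
                                          paste(layout$plate, layout$well))]
  }
  rownames(out) <- NULL
  rownames(skipped) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write single-case calls as TSV
#'
#' @param calls data.frame from [call_wells()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  for (cl in c("value", "lower", "upper")) out[[cl]] <- signif(out[[cl]], 6)
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
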