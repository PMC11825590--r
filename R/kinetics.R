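# Reduction of raw per-well measurements to energy-production summaries.
#
# Two readouts exist per well: a 24 h kinetic OD curve recorded every 15 min
# by the OmniLog reader (reduced to trapezoid AUC, in OD*min), and an
# endpoint two-wavelength plate-reader measurement (A590 minus the 750 nm
# background, "relative absorbance"). Either summary is carried to the
# statistics on a log10 scale.

#' Endpoint relative absorbance (A590-750)
#'
#' The 590 nm reading sits at the redox dye's absorbance peak; 750 nm
#' measures background. Their difference is the endpoint energy-production
#' summary; negative values are allowed and handled at the log step.
#'
#' @param a590,a750 finite numeric vectors of equal length.
#' @return `a590 - a750`.
#' @export
relative_absorbance <- function(a590, a750) {
  if (length(a590) != length(a750)) stop_input("a590 and a750 differ in length")
  if (!all(is.finite(a590)) || !all(is.finite(a750))) {
    stop_input("non-finite absorbance value")
  }
  a590 - a750
}

#' Trapezoid area under a kinetic curve
#'
#' Integrates OD over time (minutes) by the trapezoid rule; the standard
#' per-well reduction of an OmniLog kinetic read. Needs at least two points
#' on a strictly increasing time grid (the usual grid is 0-1440 min in
#' 15-min steps, i.e. 97 points, but any strictly increasing grid works).
#'
#' @param times time points in minutes, strictly increasing, `times[1] >= 0`.
#' @param od optical densities, same length as `times`.
#' @return area in OD*min.
#' @export
auc_trapezoid <- function(times, od) {
  if (length(times) < 2L) stop_input("AUC needs at least 2 time points")
  if (length(od) != length(times)) stop_input("times and od differ in length")
  if (!all(is.finite(times)) || !all(is.finite(od))) {
    stop_input("non-finite value in kinetic curve")
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop_input("times must be strictly increasing")
  if (times[1L] < 0) stop_input("times must start at or after 0")
  sum(dt * (od[-length(od)] + od[-1L]) / 2)
}

# trapezoid quadrature weights for a grid; AUC == sum(w * od)
trapezoid_weights <- function(times) {
  dt <- diff(times)
  c(dt / 2, 0) + c(0, dt / 2)
}

#' Log10 transform with a positivity floor
#'
#' Summaries are analysed on a log scale. Values at or below `floor_eps`
#' (e.g. negative background-subtracted endpoint reads) are floored at
#' `floor_eps` before taking log10, so the transform is defined everywhere.
#'
#' @param value numeric vector of raw summaries.
#' @param floor_eps positive floor (default `1e-3`).
#' @return `log10(pmax(value, floor_eps))`.
#' @export
log_transform <- function(value, floor_eps = 1e-3) {
  if (!is.numeric(floor_eps) || length(floor_eps) != 1L || !is.finite(floor_eps) ||
      floor_eps <= 0) {
    stop_input("floor_eps must be a positive number")
  }
  log10(pmax(value, floor_eps))
}

#' Summarise one well
#'
#' Reduces whatever raw measurements are available for a well (kinetic
#' curve and/or endpoint read) and sets the log-scale analysis value from
#' the configured source.
#'
#' @param curve optional list/data.frame with `times` and `od`.
#' @param endpoint optional list with `a590` and `a750` scalars.
#' @param source which summary feeds `log_value`: `"auc"` (default) or
#'   `"endpoint"`.
#' @param floor_eps positivity floor passed to [log_transform()].
#' @return list with `auc`, `rel_abs` (NA when the input is absent),
#'   `log_value` and `source`.
#' @export
summarize_well <- function(curve = NULL, endpoint = NULL,
                           source = c("auc", "endpoint"), floor_eps = 1e-3) {
  source <- match.arg(source)
  auc <- if (!is.null(curve)) auc_trapezoid(curve$times, curve$od) else NA_real_
  rel <- if (!is.null(endpoint)) {
    relative_absorbance(endpoint$a590, endpoint$a750)
  } else NA_real_
  raw <- if (source == "auc") auc else rel
  if (is.na(raw)) {
    stop_input("source = '%s' but the matching input is missing", source)
  }
  list(auc = auc, rel_abs = rel,
       log_value = log_transform(raw, floor_eps), source = source)
}

#' Read kinetic curves from long CSV
#'
#' Expects columns `sample_id,plate,well,time_min,od` (one row per read).
#' Well addresses are canonicalised.
#'
#' @param path CSV path.
#' @return data.frame in long format.
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stop_input("kinetics file not found: %s", path)
  dt <- data.table::fread(path, data.table = FALSE)
  require_columns(dt, c("sample_id", "plate", "well", "time_min", "od"),
                  basename(path))
  dt$well <- parse_well(dt$well)
  if (anyNA(dt$well)) stop_input("malformed well address in %s", basename(path))
  dt
}

#' Read endpoint two-wavelength reads from CSV
#'
#' Expects columns `sample_id,plate,well,a590,a750`.
#'
#' @param path CSV path.
#' @return data.frame, one row per well.
#' @export
read_endpoint <- function(path) {
  if (!file.exists(path)) stop_input("endpoint file not found: %s", path)
  dt <- data.table::fread(path, data.table = FALSE)
  require_columns(dt, c("sample_id", "plate", "well", "a590", "a750"),
                  basename(path))
  dt$well <- parse_well(dt$well)
  if (anyNA(dt$well)) stop_input("malformed well address in %s", basename(path))
  dt
}

#' Reduce a whole dataset to per-well summaries
#'
#' Applies [auc_trapezoid()] per (sample, plate, well) group of the kinetic
#' table and/or [relative_absorbance()] per endpoint row, then sets the
#' log-scale value from `source`.
#'
#' @param kinetics optional long data.frame from [read_kinetics()].
#' @param endpoint optional data.frame from [read_endpoint()].
#' @param source `"auc"` or `"endpoint"`; the corresponding input must be
#'   supplied.
#' @param floor_eps positivity floor for the log transform.
#' @return data.frame `sample_id, plate, well, auc, rel_abs, log_value`,
#'   ordered by sample then (plate, row, column).
#' @export
summarize_dataset <- function(kinetics = NULL, endpoint = NULL,
                              source = c("auc", "endpoint"), floor_eps = 1e-3) {
  source <- match.arg(source)
  if (source == "auc" && is.null(kinetics)) {
    stop_input("source = 'auc' requires a kinetics table")
  }
  if (source == "endpoint" && is.null(endpoint)) {
    stop_input("source = 'endpoint' requires an endpoint table")
  }
  auc_df <- NULL
  if (!is.null(kinetics)) {
    kdt <- data.table::as.data.table(kinetics)
    data.table::setorder(kdt, sample_id, plate, well, time_min)
    auc_df <- as.data.frame(kdt[, list(auc = auc_trapezoid(time_min, od)),
                                by = c("sample_id", "plate", "well")])
  }
  rel_df <- NULL
  if (!is.null(endpoint)) {
    rel_df <- endpoint[, c("sample_id", "plate", "well")]
    rel_df$rel_abs <- relative_absorbance(endpoint$a590, endpoint$a750)
  }
  out <- if (is.null(auc_df)) {
    cbind(rel_df[, c("sample_id", "plate", "well")], auc = NA_real_,
          rel_abs = rel_df$rel_abs)
  } else if (is.null(rel_df)) {
    cbind(auc_df, rel_abs = NA_real_)
  } else {
    merge(auc_df, rel_df, by = c("sample_id", "plate", "well"), all = TRUE)
  }
  raw <- if (source == "auc") out$auc else out$rel_abs
  if (anyNA(raw)) {
    stop_input("%d well(s) lack the '%s' measurement selected as source",
               sum(is.na(raw)), source)
  }
  out$log_value <- log_transform(raw, floor_eps)
  out <- out[order(out$sample_id, well_order_key(out$plate, out$well)), ]
  rownames(out) <- NULL
  out
}
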