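# Shared fixture builders. All data are generated in code under fixed seeds.

# summaries data.frame from a wells table and a named list sample -> values
make_summaries <- function(wells, values) {
  do.call(rbind, lapply(names(values), function(sid) {
    data.frame(sample_id = sid, plate = wells$plate, well = wells$well,
               auc = 10^values[[sid]], rel_abs = NA_real_,
               log_value = values[[sid]], stringsAsFactors = FALSE)
  }))
}

make_samples <- function(ids, groups, sexes = "F") {
  data.frame(sample_id = ids, group = groups,
             sex = rep_len(sexes, length(ids)), stringsAsFactors = FALSE)
}

# control cohort summaries: n_ctl controls plus optional patients, values
# drawn N(mean, sd) per well with per-sample shifts added
make_cohort_summaries <- function(wells, n_ctl = 50, patients = character(),
                                  patient_shift = 0, sd = 0.1, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("ctl_%02d", seq_len(n_ctl)), patients)
  shift <- c(rep(0, n_ctl), rep_len(patient_shift, length(patients)))
  values <- stats::setNames(lapply(seq_along(ids), function(i) {
    stats::rnorm(nrow(wells), 0, sd) + shift[i]
  }), ids)
  list(summaries = make_summaries(wells, values),
       samples = make_samples(ids, c(rep("control", n_ctl),
                                     rep("patient", length(patients)))))
}

# minimal single-case calls table (for aggregation tests)
make_calls <- function(patient_id, plate, well, compound, call) {
  data.frame(patient_id = patient_id, plate = plate, well = well,
             compound = compound, value = 0, lower = -1, upper = 1,
             method = "whisker", call = call, stringsAsFactors = FALSE)
}
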