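# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: a normative control cohort (50 lines: 26 female, 24 male) plus a
# small number of patient lines, each well read every 15 min for 24 h.
#
# The per-well NADH-production curve is modelled as a logistic rise
#   od(t) = b + A / (1 + exp(-(t - m)/s)) + eps(t),   eps iid N(0, sigma^2)
# with the amplitude A drawn per (sample, well) from a log-normal
# distribution; a per-(patient, well) log-amplitude shift delta encodes true
# biological effects (delta = 0 everywhere for controls).

#' Simulation configuration
#'
#' Defaults encode the study conditions (50 controls: 26 female, 24 male;
#' OD read every 15 min over 24 h) and a realistic curve model: baseline
#' 0.05 OD, amplitude log-normal with median 1.0 OD and sdlog 0.2 (about
#' 20% between-line spread), midpoint 720 min, steepness 120 min,
#' measurement noise sd 0.02 OD per read, and an endpoint 750 nm background
#' of mean 0.05 / sd 0.005.
#'
#' @param n_controls,n_female,n_male control cohort composition
#'   (`n_female + n_male` must equal `n_controls`).
#' @param plates plates to simulate.
#' @param times read grid in minutes.
#' @param baseline,amp_median,amp_sdlog,midpoint,steepness logistic curve
#'   parameters (OD / OD / log scale / min / min).
#' @param noise_sd per-read OD noise sd (must be >= 0).
#' @param bg_mean,bg_sd endpoint 750 nm background parameters.
#' @param patients optional data.frame `sample_id, group, sex` of patient
#'   lines to add to the cohort.
#' @param seed master seed; per-sample RNG streams are derived from it.
#' @return `simulation_config` list.
#' @export
simulation_config <- function(n_controls = 50L, n_female = 26L, n_male = 24L,
                              plates = pm_plates(),
                              times = seq(0, 1440, by = 15),
                              baseline = 0.05, amp_median = 1.0,
                              amp_sdlog = 0.2, midpoint = 720,
                              steepness = 120, noise_sd = 0.02,
                              bg_mean = 0.05, bg_sd = 0.005,
                              patients = NULL, seed = 1L) {
  if (n_female + n_male != n_controls) {
    stop_input("n_female + n_male (%d) must equal n_controls (%d)",
               n_female + n_male, n_controls)
  }
  if (noise_sd < 0 || amp_sdlog < 0 || bg_sd < 0) {
    stop_input("noise parameters must be non-negative")
  }
  if (any(diff(times) <= 0) || times[1L] < 0) {
    stop_input("times must be strictly increasing from >= 0")
  }
  stopifnot(all(plates %in% pm_plates()))
  if (!is.null(patients)) {
    require_columns(patients, c("sample_id", "group", "sex"), "patients")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_female = as.integer(n_female), n_male = as.integer(n_male),
                 plates = plates, times = times, baseline = baseline,
                 amp_median = amp_median, amp_sdlog = amp_sdlog,
                 midpoint = midpoint, steepness = steepness,
                 noise_sd = noise_sd, bg_mean = bg_mean, bg_sd = bg_sd,
                 patients = patients, seed = as.integer(seed)),
            class = "simulation_config")
}

# documented seed-splitting rule: one RNG stream per sample, so adding
# samples at the end never perturbs earlier ones
sample_stream_seed <- function(master_seed, sample_index) {
  as.integer((as.numeric(master_seed) + 104729 * sample_index) %% 2147483647)
}

#' Effect map entries
#'
#' Builds (patient, well) -> log-amplitude shift rows; `delta = 0` means a
#' null well. Vectors are recycled to a common length.
#'
#' @param sample_id patient id(s).
#' @param plate,well well address(es).
#' @param delta log-amplitude shift(s) (dimensionless, natural-log scale).
#' @return data.frame `sample_id, plate, well, delta`.
#' @export
effect_map <- function(sample_id, plate, well, delta) {
  data.frame(sample_id = sample_id, plate = plate, well = parse_well(well),
             delta = delta, stringsAsFactors = FALSE)
}

#' Simulate one kinetic curve
#'
#' Draws `od(t) = baseline + amplitude / (1 + exp(-(t - midpoint)/steepness))
#' + eps(t)` with iid Gaussian read noise, using the current RNG state.
#'
#' @param times read grid (minutes).
#' @param amplitude logistic plateau height (OD).
#' @param baseline baseline OD.
#' @param midpoint,steepness logistic location and scale (min).
#' @param noise_sd per-read noise sd (>= 0).
#' @return numeric od vector, same length as `times`.
#' @export
simulate_curve <- function(times, amplitude, baseline = 0.05, midpoint = 720,
                           steepness = 120, noise_sd = 0) {
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  det <- baseline + amplitude * stats::plogis((times - midpoint) / steepness)
  det + stats::rnorm(length(times), 0, noise_sd)
}

#' Simulate a full cohort
#'
#' Generates per-well kinetic curves and endpoint reads for every sample
#' (controls first, then patients) over all wells of the included plates.
#' Each sample uses its own RNG stream derived from the master seed, so the
#' output is bit-for-bit reproducible and earlier samples are unaffected by
#' appending new ones. Controls have `delta = 0` everywhere; patient shifts
#' come from the effect map. The endpoint 590 nm read is the final kinetic
#' read; the 750 nm read is a small positive background.
#'
#' @param config a [simulation_config()].
#' @param layout a `pm_layout`; only wells on `config$plates` are simulated.
#' @param effects optional [effect_map()] rows; wells must exist in the
#'   layout.
#' @return list with `kinetics` (long data.frame `sample_id, plate, well,
#'   time_min, od`), `endpoint` (`sample_id, plate, well, a590, a750`) and
#'   `samples` (`sample_id, group, sex, label`).
#' @export
simulate_cohort <- function(config, layout, effects = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(layout, "pm_layout"))
  wells <- as.data.frame(layout)[layout$plate %in% config$plates,
                                 c("plate", "well")]
  if (nrow(wells) == 0L) stop_input("layout has no wells on the configured plates")
  if (!is.null(effects)) {
    require_columns(effects, c("sample_id", "plate", "well", "delta"), "effects")
    known <- paste(wells$plate, wells$well)
    bad <- setdiff(paste(effects$plate, effects$well), known)
    if (length(bad) > 0L) {
      stop_input("effect references unknown well(s): %s",
                 paste(utils::head(bad, 3L), collapse = ", "))
    }
  }

  sexes <- c(rep("F", config$n_female), rep("M", config$n_male))
  samples <- data.frame(
    sample_id = sprintf("control_%02d", seq_len(config$n_controls)),
    group = "control", sex = sexes, label = "control",
    stringsAsFactors = FALSE)
  if (!is.null(config$patients)) {
    pat <- config$patients
    pat$label <- pat$label %||% pat$sample_id
    samples <- rbind(samples,
                     pat[, c("sample_id", "group", "sex", "label")])
  }
  if (anyDuplicated(samples$sample_id)) stop_input("duplicate sample ids")

  n_w <- nrow(wells); n_t <- length(config$times)
  logistic <- stats::plogis((config$times - config$midpoint) / config$steepness)
  well_key <- paste(wells$plate, wells$well)

  kin_parts <- vector("list", nrow(samples))
  end_parts <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    set.seed(sample_stream_seed(config$seed, i))
    delta <- rep(0, n_w)
    if (!is.null(effects)) {
      eff <- effects[effects$sample_id == sid, , drop = FALSE]
      if (nrow(eff) > 0L) {
        idx <- match(paste(eff$plate, eff$well), well_key)
        delta[idx] <- eff$delta
      }
    }
    amp <- exp(stats::rnorm(n_w, log(config$amp_median), config$amp_sdlog) + delta)
    od <- config$baseline + outer(amp, logistic) +
      matrix(stats::rnorm(n_w * n_t, 0, config$noise_sd), n_w, n_t)
    a750 <- abs(stats::rnorm(n_w, config$bg_mean, config$bg_sd))
    kin_parts[[i]] <- data.frame(
      sample_id = sid,
      plate = rep(wells$plate, times = n_t),
      well = rep(wells$well, times = n_t),
      time_min = rep(config$times, each = n_w),
      od = as.vector(od), stringsAsFactors = FALSE)
    end_parts[[i]] <- data.frame(
      sample_id = sid, plate = wells$plate, well = wells$well,
      a590 = od[, n_t], a750 = a750, stringsAsFactors = FALSE)
  }
  kinetics <- as.data.frame(data.table::rbindlist(kin_parts))
  endpoint <- as.data.frame(data.table::rbindlist(end_parts))
  list(kinetics = kinetics, endpoint = endpoint, samples = samples)
}

#' Write a simulated cohort to CSV files
#'
#' Emits `kinetics.csv`, `endpoint.csv` and `samples.csv` in exactly the
#' dialects consumed by [read_kinetics()], [read_endpoint()] and the
#' pipeline.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(kinetics = file.path(dir, "kinetics.csv"),
             endpoint = file.path(dir, "endpoint.csv"),
             samples = file.path(dir, "samples.csv"))
  data.table::fwrite(cohort$kinetics, paths[["kinetics"]])
  data.table::fwrite(cohort$endpoint, paths[["endpoint"]])
  data.table::fwrite(cohort$samples, paths[["samples"]])
  invisible(paths)
}

# Simulate log10 AUC summaries for n_wells independent wells without
# materialising curves: AUC of (deterministic curve + iid read noise) equals
# the deterministic AUC plus N(0, sigma^2 * sum(w^2)) with trapezoid
# weights w, so one Gaussian per curve suffices (identical in distribution).
simulate_summaries <- function(z_amp, e_auc, delta, config) {
  w <- trapezoid_weights(config$times)
  L <- sum(w * stats::plogis((config$times - config$midpoint) / config$steepness))
  total_t <- max(config$times) - min(config$times)
  amp <- exp(log(config$amp_median) + config$amp_sdlog * z_amp + delta)
  auc <- amp * L + config$baseline * total_t +
    config$noise_sd * sqrt(sum(w^2)) * e_auc
  log_transform(auc)
}

#' Power / type-I error recovery experiment
#'
#' For each log-amplitude shift `delta` in the grid, simulates `n_wells`
#' independent wells (`n_a` patient lines vs `n_b` controls drawn from the
#' configured curve model), tests each with [mann_whitney_two_sided()], and
#' reports the fraction of wells raw-significant and FDR-significant (BH
#' family = the `n_wells` wells of one replicate). Common random numbers
#' are used across the grid, so power is directly comparable between
#' deltas.
#'
#' @param config a [simulation_config()] (curve-model parameters are used;
#'   cohort composition is overridden by `n_a`/`n_b`).
#' @param effect_size_grid numeric vector of log-amplitude shifts.
#' @param n_wells wells per replicate (default 1000).
#' @param n_a,n_b group sizes (defaults 2 patient lines vs 50 controls).
#' @param alpha,q raw and FDR thresholds (strict).
#' @param n_reps replicates to average over.
#' @param seed RNG seed.
#' @return data.frame `delta, n_wells, raw_rate, raw_se, fdr_rate, fdr_se`.
#' @export
recovery_experiment <- function(config, effect_size_grid, n_wells = 1000L,
                                n_a = 2L, n_b = 50L, alpha = 0.05, q = 0.05,
                                n_reps = 1L, seed = 1L) {
  if (n_reps < 1L) stop_input("n_reps must be >= 1")
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  raw_hits <- fdr_hits <- matrix(0, n_reps, length(effect_size_grid))
  for (rep_i in seq_len(n_reps)) {
    z_b <- matrix(stats::rnorm(n_b * n_wells), n_b, n_wells)
    z_a <- matrix(stats::rnorm(n_a * n_wells), n_a, n_wells)
    e_b <- matrix(stats::rnorm(n_b * n_wells), n_b, n_wells)
    e_a <- matrix(stats::rnorm(n_a * n_wells), n_a, n_wells)
    for (j in seq_along(effect_size_grid)) {
      delta <- effect_size_grid[j]
      p <- vapply(seq_len(n_wells), function(wl) {
        va <- simulate_summaries(z_a[, wl], e_a[, wl], delta, config)
        vb <- simulate_summaries(z_b[, wl], e_b[, wl], 0, config)
        mann_whitney_two_sided(va, vb)$p
      }, numeric(1))
      raw_hits[rep_i, j] <- mean(p < alpha)
      fdr_hits[rep_i, j] <- mean(benjamini_hochberg(p, q)$flag)
    }
  }
  raw_rate <- colMeans(raw_hits); fdr_rate <- colMeans(fdr_hits)
  n_tot <- n_wells * n_reps
  data.frame(delta = effect_size_grid, n_wells = n_wells,
             raw_rate = raw_rate,
             raw_se = sqrt(raw_rate * (1 - raw_rate) / n_tot),
             fdr_rate = fdr_rate,
             fdr_se = sqrt(fdr_rate * (1 - fdr_rate) / n_tot))
}

#' Empirical FDR calibration with a fraction of truly shifted wells
#'
#' Simulates `n_wells` wells of which the first `round(prop_nonnull *
#' n_wells)` carry the shift `delta`, runs the per-well tests plus BH, and
#' reports the empirical false discovery proportion among flagged wells.
#'
#' @inheritParams recovery_experiment
#' @param delta log-amplitude shift of the non-null wells.
#' @param prop_nonnull fraction of non-null wells (default 0.10).
#' @return list `n_flagged, n_false, empirical_fdr, power_nonnull, q`.
#' @export
fdr_calibration <- function(config, delta, prop_nonnull = 0.1,
                            n_wells = 1000L, n_a = 2L, n_b = 50L, q = 0.05,
                            seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n_shift <- round(prop_nonnull * n_wells)
  deltas <- c(rep(delta, n_shift), rep(0, n_wells - n_shift))
  p <- vapply(seq_len(n_wells), function(wl) {
    va <- simulate_summaries(stats::rnorm(n_a), stats::rnorm(n_a), deltas[wl], config)
    vb <- simulate_summaries(stats::rnorm(n_b), stats::rnorm(n_b), 0, config)
    mann_whitney_two_sided(va, vb)$p
  }, numeric(1))
  flag <- benjamini_hochberg(p, q)$flag
  is_null <- deltas == 0
  n_flagged <- sum(flag)
  n_false <- sum(flag & is_null)
  list(n_flagged = n_flagged, n_false = n_false,
       empirical_fdr = if (n_flagged > 0L) n_false / n_flagged else 0,
       power_nonnull = if (n_shift > 0L) mean(flag[!is_null]) else NA_real_,
       q = q)
}
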