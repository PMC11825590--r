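test_that("the logistic curve model behaves analytically at zero noise", {
  t <- seq(0, 1440, 15)
  set.seed(1)
  od <- simulate_curve(720, amplitude = 1, baseline = 0, noise_sd = 0)
  expect_equal(od, 0.5)                       # logistic midpoint
  flat <- simulate_curve(t, amplitude = 0, baseline = 0.05, noise_sd = 0)
  expect_equal(auc_trapezoid(t, flat), 0.05 * 1440)   # AUC = b * T
  # mean AUC increases monotonically with amplitude
  aucs <- vapply(c(0.2, 0.5, 1, 2, 4), function(A) {
    auc_trapezoid(t, simulate_curve(t, amplitude = A, noise_sd = 0))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_error(simulate_curve(t, 1, noise_sd = -1), ">= 0")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_controls = 50, n_female = 20, n_male = 24),
               "must equal")
  expect_error(simulation_config(noise_sd = -0.1), "non-negative")
  expect_error(simulation_config(times = c(0, 10, 10)), "strictly increasing")
})

test_that("cohort simulation is deterministic and stream-stable", {
  lay <- example_layout("PM-M7")
  pats <- data.frame(sample_id = "p1", group = "RTT", sex = "F",
                     stringsAsFactors = FALSE)
  cfg <- simulation_config(n_controls = 4, n_female = 2, n_male = 2,
                           plates = "PM-M7", patients = pats, seed = 99)
  c1 <- simulate_cohort(cfg, lay)
  c2 <- simulate_cohort(cfg, lay)
  expect_identical(c1, c2)
  # written files are byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("kinetics.csv", "endpoint.csv", "samples.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # appending a patient must not perturb the control streams
  pats2 <- rbind(pats, data.frame(sample_id = "p2", group = "RTT", sex = "F"))
  cfg2 <- simulation_config(n_controls = 4, n_female = 2, n_male = 2,
                            plates = "PM-M7", patients = pats2, seed = 99)
  c3 <- simulate_cohort(cfg2, lay)
  ctl <- c1$kinetics$sample_id != "p1"
  expect_identical(c1$kinetics[ctl, ],
                   c3$kinetics[c3$kinetics$sample_id %in%
                                 unique(c1$kinetics$sample_id[ctl]), ])
  expect_identical(c1$kinetics[c1$kinetics$sample_id == "p1", ],
                   c3$kinetics[c3$kinetics$sample_id == "p1", ])
})

test_that("sample sheet encodes the cohort composition with sex labels", {
  lay <- example_layout("PM-M8")
  cfg <- simulation_config(plates = "PM-M8", seed = 1)
  coh <- simulate_cohort(cfg, lay)
  expect_equal(nrow(coh$samples), 50)
  expect_equal(sum(coh$samples$sex == "F"), 26)
  expect_equal(sum(coh$samples$sex == "M"), 24)
  expect_equal(nrow(coh$kinetics), 50 * 96 * 97)
  expect_equal(nrow(coh$endpoint), 50 * 96)
  # endpoint a590 equals the final kinetic read
  last <- coh$kinetics[coh$kinetics$time_min == 1440, ]
  key <- function(d) paste(d$sample_id, d$plate, d$well)
  expect_equal(coh$endpoint$a590,
               last$od[match(key(coh$endpoint), key(last))])
  expect_true(all(coh$endpoint$a750 > 0))
})

test_that("effect shifts move the affected patient wells", {
  lay <- example_layout("PM-M8")
  pats <- data.frame(sample_id = "p1", group = "RTT", sex = "F")
  cfg <- simulation_config(n_controls = 6, n_female = 3, n_male = 3,
                           plates = "PM-M8", patients = pats, seed = 5)
  eff <- effect_map("p1", "PM-M8", "D06", delta = -2)
  coh <- simulate_cohort(cfg, lay, eff)
  sm <- summarize_dataset(coh$kinetics, source = "auc")
  d06 <- sm[sm$well == "D06", ]
  expect_lt(d06$log_value[d06$sample_id == "p1"],
            min(d06$log_value[d06$sample_id != "p1"]))
  expect_error(simulate_cohort(cfg, lay, effect_map("p1", "PM-M1", "A01", -1)),
               "unknown well")
})

test_that("recovery_experiment reports calibrated null and monotone power", {
  cfg <- simulation_config(seed = 1)
  rec <- recovery_experiment(cfg, effect_size_grid = c(0, 0.5, 1.0),
                             n_wells = 200, n_a = 2, n_b = 20, seed = 42)
  expect_equal(nrow(rec), 3)
  # null rejection close to nominal (wide 4-SE guard at this size)
  expect_lt(abs(rec$raw_rate[1] - 0.05), 4 * sqrt(0.05 * 0.95 / 200))
  # power grows with the shift (common random numbers)
  expect_true(all(diff(rec$raw_rate) >= 0))
  expect_gt(rec$raw_rate[3], rec$raw_rate[1])
  expect_error(recovery_experiment(cfg, 0, n_reps = 0), "n_reps")
})
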