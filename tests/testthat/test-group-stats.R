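test_that("Mann-Whitney reproduces known exact cases", {
  r <- mann_whitney_two_sided(c(1, 2), c(3, 4, 5))
  expect_equal(r$u_stat, 0)
  expect_equal(r$p, 0.2)           # 2 of the C(5,2) = 10 splits are as extreme
  expect_equal(r$method, "exact")
  expect_equal(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_two_sided(c(1, 1), c(1, 1))$p, 1)
  expect_error(mann_whitney_two_sided(numeric(), 1:3), "non-empty")
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  set.seed(19)
  for (i in 1:20) {
    n_a <- sample(2:6, 1); n_b <- sample(2:8, 1)
    a <- stats::rnorm(n_a); b <- stats::rnorm(n_b)
    ours <- mann_whitney_two_sided(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$u_stat, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("p is symmetric in the groups and invariant to monotone transforms", {
  set.seed(23)
  for (i in 1:10) {
    a <- sample(1:6, 4, replace = TRUE)   # ties allowed
    b <- sample(1:6, 5, replace = TRUE)
    r1 <- mann_whitney_two_sided(a, b)
    r2 <- mann_whitney_two_sided(b, a)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$u_stat + r2$u_stat, length(a) * length(b))
    f <- function(x) exp(2 * x) - 5      # strictly increasing
    expect_equal(mann_whitney_two_sided(f(a), f(b))$p, r1$p)
  }
})

test_that("normal approximation tracks the exact p on small tie-free designs", {
  # within 0.05 absolute once both groups have >= 3 members (the exact law
  # is too coarse below that for any continuity-corrected approximation)
  set.seed(31)
  for (n_a in 3:7) for (n_b in 3:(10 - n_a)) {
    for (i in 1:5) {
      a <- stats::rnorm(n_a); b <- stats::rnorm(n_b)
      pe <- mann_whitney_two_sided(a, b, method = "exact")$p
      pn <- mann_whitney_two_sided(a, b, method = "normal")$p
      expect_lt(abs(pe - pn), 0.05)
    }
  }
})

test_that("Benjamini-Hochberg matches hand computations and p.adjust", {
  expect_equal(benjamini_hochberg(0.03)$p_adj, 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))$p_adj,
               rep(0.04, 4))
  bh <- benjamini_hochberg(c(0.005, 0.5))
  expect_equal(bh$p_adj, c(0.01, 0.5))
  expect_equal(bh$flag, c(TRUE, FALSE))
  set.seed(5)
  p <- stats::runif(100)^2
  ours <- benjamini_hochberg(p)
  expect_equal(ours$p_adj, stats::p.adjust(p, "BH"))
  expect_equal(ours$p_adj, oracle_bh(p))
  expect_true(all(ours$p_adj >= p))
  # flags at q = 0.01 are a subset of flags at q = 0.05
  f01 <- benjamini_hochberg(p, q = 0.01)$flag
  f05 <- benjamini_hochberg(p, q = 0.05)$flag
  expect_true(all(!f01 | f05))
  expect_error(benjamini_hochberg(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("run_comparison tests every well of the included plates", {
  plates7 <- setdiff(pm_plates(), "PM-M5")   # the ion plate can be absent
  lay <- example_layout(plates7)
  wells <- as.data.frame(lay)[, c("plate", "well")]
  fx <- make_cohort_summaries(wells, n_ctl = 12,
                              patients = c("rtt_1", "rtt_2"), seed = 101)
  spec <- comparison_spec("RTT-vs-control",
                          sample_selector(group = "patient"),
                          sample_selector(group = "control"),
                          plates = plates7)
  res <- run_comparison(fx$summaries, fx$samples, spec, layout = lay)
  expect_equal(nrow(res), 672)               # 7 plates x 96 wells
  expect_equal(unique(res$n_a), 2)
  expect_equal(unique(res$n_b), 12)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$fdr_sig <= res$raw_sig))  # q = alpha = 0.05
  expect_equal(res$compound[res$plate == "PM-M8" & res$well == "G10"],
               "TNF-alpha")
})

test_that("identical groups give p = 1 everywhere and no flags", {
  wells <- data.frame(plate = "PM-M8", well = all_wells())
  set.seed(2)
  v <- stats::rnorm(96)
  sm <- make_summaries(wells, list(a1 = v, a2 = v + 0.01,
                                   b1 = v, b2 = v + 0.01))
  samples <- make_samples(c("a1", "a2", "b1", "b2"),
                          c("A", "A", "B", "B"))
  spec <- comparison_spec("A-vs-B", sample_selector(group = "A"),
                          sample_selector(group = "B"), plates = "PM-M8")
  res <- run_comparison(sm, samples, spec)
  expect_true(all(res$p == 1))
  expect_true(all(!res$raw_sig))
  expect_true(all(res$direction == "none"))
})

test_that("a strongly shifted well attains the minimum achievable exact p", {
  wells <- data.frame(plate = "PM-M8", well = all_wells())
  fx <- make_cohort_summaries(wells, n_ctl = 50,
                              patients = c("p1", "p2"), seed = 77)
  sm <- fx$summaries
  shift_rows <- sm$sample_id %in% c("p1", "p2") & sm$well == "C03"
  sm$log_value[shift_rows] <- sm$log_value[shift_rows] - 10
  spec <- comparison_spec("pat-vs-ctl", sample_selector(group = "patient"),
                          sample_selector(group = "control"), plates = "PM-M8")
  res <- run_comparison(sm, fx$samples, spec)
  # both patients below all 50 controls: p = 2 / C(52, 2)
  expect_equal(res$p[res$well == "C03"], 2 / choose(52, 2))
  expect_equal(res$direction[res$well == "C03"], "decreased")
  expect_equal(min(res$p), res$p[res$well == "C03"])
})

test_that("selector validation rejects empty and overlapping groups", {
  wells <- data.frame(plate = "PM-M8", well = all_wells())
  fx <- make_cohort_summaries(wells, n_ctl = 5, patients = "p1", seed = 1)
  bad <- comparison_spec("x", sample_selector(group = "nope"),
                         sample_selector(group = "control"), plates = "PM-M8")
  expect_error(run_comparison(fx$summaries, fx$samples, bad), "no samples")
  overlap <- comparison_spec("y", sample_selector(group = "control"),
                             sample_selector(ids = "ctl_01"), plates = "PM-M8")
  expect_error(run_comparison(fx$summaries, fx$samples, overlap), "overlap")
})

test_that("percent_significant reports one-decimal half-up percentages", {
  res <- data.frame(raw_sig = rep(c(TRUE, FALSE), c(264, 672 - 264)),
                    fdr_sig = rep(c(TRUE, FALSE), c(95, 672 - 95)))
  expect_equal(percent_significant(res, "raw"),
               list(count = 264, total = 672, percent = 39.3))
  expect_equal(percent_significant(res, "fdr"),
               list(count = 95, total = 672, percent = 14.1))
  none <- data.frame(raw_sig = rep(FALSE, 672), fdr_sig = rep(FALSE, 672))
  expect_equal(percent_significant(none, "raw")$percent, 0)
  expect_error(percent_significant(res[0, ], "raw"), "empty")
})

test_that("comparison results round-trip through TSV", {
  wells <- data.frame(plate = "PM-M8", well = all_wells())
  fx <- make_cohort_summaries(wells, n_ctl = 6, patients = "p1", seed = 9)
  spec <- comparison_spec("pat-vs-ctl", sample_selector(group = "patient"),
                          sample_selector(group = "control"), plates = "PM-M8")
  res <- run_comparison(fx$summaries, fx$samples, spec,
                        layout = example_layout("PM-M8"))
  path <- tempfile(fileext = ".tsv")
  write_results_tsv(res, path)
  back <- read_results_tsv(path)
  expect_equal(back$well, res$well)
  expect_equal(back$p, signif(res$p, 6))
  expect_equal(back$fdr_sig, res$fdr_sig)
  expect_equal(back$compound, res$compound)
})
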