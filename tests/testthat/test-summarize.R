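# aggregation of calls/results into trend tables, opposite/shared lists and
# cluster fractions

make_group_calls <- function(patient, n_above, n_below, n_within = 0) {
  n <- n_above + n_below + n_within
  make_calls(patient,
             plate = "PM-M1",
             well = all_wells()[seq_len(n)],
             compound = sprintf("compound_%03d", seq_len(n)),
             call = rep(c("above", "below", "within"),
                        c(n_above, n_below, n_within)))
}

test_that("direction_table tallies per-compound trends per group", {
  dup <- make_group_calls("dup_patient", 66, 25)
  lof <- make_group_calls("lof_patient", 5, 64)
  tt <- direction_table(rbind(dup, lof))
  expect_equal(trend_counts(tt, "dup_patient"),
               list(increased = 66, decreased = 25, mixed = 0))
  expect_equal(trend_counts(tt, "lof_patient"),
               list(increased = 5, decreased = 64, mixed = 0))
  # all-within calls produce an empty table
  quiet <- make_group_calls("q", 0, 0, 10)
  expect_equal(nrow(direction_table(quiet)), 0)
  # conservation: above + below + within tallies cover every call
  cc <- attr(tt, "call_counts")
  expect_equal(sum(cc$Freq[cc$group == "dup_patient"]), 91)
})

test_that("multi-well compounds with disagreeing calls are mixed", {
  calls <- make_calls("p", "PM-M5", c("A01", "A02", "A03", "A04"),
                      rep("Sodium Chloride", 4),
                      c("above", "below", "within", "within"))
  tt <- direction_table(calls)
  expect_equal(tt$direction, "mixed")
  expect_equal(tt$n_wells_called, 2)
  # one-sided multi-well evidence keeps its direction
  calls2 <- make_calls("p", "PM-M5", c("B01", "B02", "B03", "B04"),
                       rep("Zinc Sulfate", 4),
                       c("below", "within", "within", "below"))
  expect_equal(direction_table(calls2)$direction, "decreased")
  # mixed compounds never enter opposite-trend lists
  other <- direction_table(make_calls("o", "PM-M5", "A01",
                                      "Sodium Chloride", "below"))
  expect_equal(opposite_trends(tt, other), character())
})

test_that("opposite_trends finds the compounds with opposing directions", {
  opp <- c("FGF-1(aFGF)", "IL-1beta", "Glu-Trp", "Gln-Gly", "Trp-Tyr")
  shared_names <- c("Pectin", "Adenosine", "Pyruvic Acid")
  dup <- make_calls("dup", "PM-M7", all_wells()[1:8],
                    c(opp, shared_names),
                    rep("above", 8))
  lof <- make_calls("lof", "PM-M7", all_wells()[1:8],
                    c(opp, shared_names),
                    c(rep("below", 5), rep("above", 3)))
  ta <- direction_table(dup); tb <- direction_table(lof)
  expect_equal(opposite_trends(ta, tb), sort(opp))
  expect_equal(opposite_trends(tb, ta), opposite_trends(ta, tb))  # symmetric
  expect_equal(opposite_trends(ta, ta), character())
  empty <- direction_table(make_calls("e", "PM-M7", "A01", "x", "within"))
  expect_equal(opposite_trends(ta, empty), character())
})

test_that("shared_trend intersects same-direction compounds across groups", {
  shared_names <- c("Pectin", "Adenosine", "Pyruvic Acid", "Ile-Gln", "Ser-Gln")
  dup <- make_calls("dup", "PM-M1", all_wells()[1:7],
                    c(shared_names, "only-dup-1", "only-dup-2"),
                    rep("above", 7))
  lof <- make_calls("lof", "PM-M1", all_wells()[1:7],
                    c(shared_names, "only-lof-1", "only-lof-2"),
                    c(rep("above", 5), "below", "below"))
  tabs <- list(direction_table(dup), direction_table(lof))
  expect_equal(shared_trend(tabs, "increased"), sort(shared_names))
  expect_equal(shared_trend(tabs, "decreased"), character())
  single <- make_calls("a", "PM-M1", "A01", "Pectin", "above")
  tabs2 <- list(direction_table(single), direction_table(single))
  expect_equal(shared_trend(tabs2, "increased"), "Pectin")
  expect_error(shared_trend(tabs[1], "increased"), "at least 2")
})

test_that("cluster_fraction computes one-decimal percentages", {
  lay <- example_layout()
  gly <- wells_matching(lay, "Gly")
  calls <- make_calls("p", gly$plate, gly$well, gly$compound,
                      rep(c("below", "within"), c(12, 18)))
  cf <- cluster_fraction(calls, gly, "decreased", cluster_name = "glycine")
  expect_equal(cf[c("k", "n", "percent")], list(k = 12, n = 30, percent = 40))
  tyr <- wells_matching(lay, "Tyr")
  calls_t <- make_calls("p", tyr$plate, tyr$well, tyr$compound,
                        rep(c("below", "within"), c(11, 16)))
  cf_t <- cluster_fraction(calls_t, tyr, "decreased")
  expect_equal(cf_t$percent, 40.7)
  # percent always recomputable from k and n
  expect_equal(cf_t$percent, round_half_up(100 * cf_t$k / cf_t$n, 1))
  # zero hits and error cases
  none <- make_calls("p", "PM-M1", all_wells()[1:5],
                     paste0("c", 1:5), rep("within", 5))
  expect_equal(cluster_fraction(none, none[, c("plate", "well")],
                                "decreased")$percent, 0)
  expect_error(cluster_fraction(calls, gly[0, ], "decreased"), "empty")
  expect_error(cluster_fraction(none, gly, "decreased"), "absent")
})

test_that("cluster_fraction on test results honours the significance flag", {
  res <- data.frame(plate = "PM-M3", well = all_wells()[1:10],
                    direction = rep(c("decreased", "increased"), each = 5),
                    raw_sig = rep(c(TRUE, FALSE), 5),
                    fdr_sig = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                rep(FALSE, 5)))
  cl <- res[, c("plate", "well")]
  expect_equal(cluster_fraction(res, cl, "decreased", criterion = "fdr")$k, 2)
  expect_equal(cluster_fraction(res, cl, "decreased", criterion = "raw")$k, 3)
  expect_equal(cluster_fraction(res, cl, "increased", criterion = "raw")$k, 2)
})
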