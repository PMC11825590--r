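# Per-well two-group comparison with FDR control.
#
# Each well is tested with a two-sided Mann-Whitney test (exact by full
# enumeration of group assignments whenever that is cheap, with midrank tie
# handling; normal approximation with tie and continuity corrections
# otherwise), and the Benjamini-Hochberg step-up correction is applied
# across all wells of one comparison run.

# cache of combn(N, k) index matrices, shared across wells of a run
.mw_cache <- new.env(parent = emptyenv())

mw_subsets <- function(N, k) {
  key <- paste0(N, "_", k)
  if (is.null(.mw_cache[[key]])) .mw_cache[[key]] <- utils::combn(N, k)
  .mw_cache[[key]]
}

# bound on C(n_a+n_b, n_a) below which the exact permutation null is used
MW_EXACT_LIMIT <- 20000

#' Two-sided Mann-Whitney test
#'
#' The U statistic counts pairs where an `a` value exceeds a `b` value, plus
#' half of the tied pairs (equivalently `U = R_a - n_a(n_a+1)/2` with
#' midranks). When `choose(n_a + n_b, n_a)` is at most 20,000, the two-sided
#' p-value is exact: all group-label assignments are enumerated and
#' `p = Pr(|U - n_a n_b / 2| >= |u_obs - n_a n_b / 2|)` under that
#' permutation null, which remains valid under ties. For larger designs a
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param method `"auto"` (default: exact when affordable), or force
#'   `"exact"` / `"normal"`.
#' @return list with `u_stat`, `p`, `n_a`, `n_b` and `method`
#'   (`"exact"`/`"normal"`).
#' @export
mann_whitney_two_sided <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop_input("both groups must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop_input("non-finite value in test input")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  r <- rank(c(a, b))                       # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  use_exact <- switch(method,
    auto = choose(N, n_a) <= MW_EXACT_LIMIT,
    exact = if (choose(N, n_a) <= MW_EXACT_LIMIT) TRUE else
      stop_input("exact enumeration infeasible for C(%d, %d) splits", N, n_a),
    normal = FALSE)
  if (use_exact) {
    m <- min(n_a, n_b)                     # |U - mu| has the same null law
    subs <- mw_subsets(N, m)               # for either group's statistic
    us <- colSums(matrix(r[subs], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, (abs(u - mu) - 0.5) / sqrt(sigma2))
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal"
  }
  list(u_stat = u, p = p, n_a = n_a, n_b = n_b, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are the standard step-up quantities `p_(i) * m / i` with
#' cumulative-minimum monotonisation, capped at 1 (as computed by
#' `stats::p.adjust(method = "BH")`). A well passes FDR control when its
#' adjusted value is strictly below `q`.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level in (0, 1); default 0.05.
#' @return list with `p_adj` and logical `flag` (`p_adj < q`).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0L) stop_input("empty p-value vector")
  if (!all(is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  if (!is.finite(q) || q <= 0 || q >= 1) stop_input("q must lie in (0, 1)")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = adj, flag = adj < q)
}

#' Sample selector
#'
#' Selects rows of a sample sheet by any conjunction of group label,
#' explicit sample ids, and sex.
#'
#' @param group,ids,sex optional filters (`NULL` = no constraint).
#' @return a `sample_selector` list.
#' @export
sample_selector <- function(group = NULL, ids = NULL, sex = NULL) {
  structure(list(group = group, ids = ids, sex = sex),
            class = "sample_selector")
}

#' Resolve a selector against a sample sheet
#'
#' @param samples data.frame with `sample_id`, `group`, `sex`.
#' @param selector a [sample_selector()].
#' @return character vector of matching sample ids.
#' @export
select_samples <- function(samples, selector) {
  require_columns(samples, c("sample_id", "group", "sex"), "sample sheet")
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(selector$group)) keep <- keep & samples$group %in% selector$group
  if (!is.null(selector$ids)) keep <- keep & samples$sample_id %in% selector$ids
  if (!is.null(selector$sex)) keep <- keep & samples$sex %in% selector$sex
  samples$sample_id[keep]
}

#' Define a two-group comparison
#'
#' Mirrors the study's comparison families: a patient group or a single
#' patient line versus the normative control cohort (optionally
#' sex-restricted), over a stated set of plates.
#'
#' @param name comparison label (used in outputs).
#' @param group_a,group_b [sample_selector()]s; must resolve to disjoint
#'   sample sets.
#' @param plates plates included in this comparison.
#' @return a `comparison_spec`.
#' @export
comparison_spec <- function(name, group_a, group_b, plates = pm_plates()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(group_a, "sample_selector"),
            inherits(group_b, "sample_selector"),
            all(plates %in% pm_plates()))
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 plates = plates),
            class = "comparison_spec")
}

#' Run one per-well group comparison
#'
#' For every well of the included plates, tests group A versus group B with
#' [mann_whitney_two_sided()] on the log-scale summaries, then applies
#' [benjamini_hochberg()] across all wells of this run (the multiplicity
#' family is the comparison). Direction is the sign of
#' `median(A) - median(B)` on log values (`"none"` when equal).
#'
#' @param summaries per-sample well summaries from [summarize_dataset()].
#' @param samples sample sheet (`sample_id`, `group`, `sex`).
#' @param spec a [comparison_spec()].
#' @param alpha raw significance threshold (strict `p < alpha`); default 0.05.
#' @param q FDR level (strict `p_adj < q`); default 0.05.
#' @param layout optional `pm_layout` used to attach compound names.
#' @return data.frame with one row per well: `comparison, plate, well,
#'   compound, n_a, n_b, u_stat, p, p_adj, direction, raw_sig, fdr_sig`.
#' @export
run_comparison <- function(summaries, samples, spec, alpha = 0.05, q = 0.05,
                           layout = NULL) {
  stopifnot(inherits(spec, "comparison_spec"))
  require_columns(summaries, c("sample_id", "plate", "well", "log_value"),
                  "summaries")
  ids_a <- select_samples(samples, spec$group_a)
  ids_b <- select_samples(samples, spec$group_b)
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop_input("comparison '%s': a selector matched no samples", spec$name)
  }
  if (length(intersect(ids_a, ids_b)) > 0L) {
    stop_input("comparison '%s': selectors overlap (%s)", spec$name,
               paste(intersect(ids_a, ids_b), collapse = ", "))
  }
  sub <- summaries[summaries$plate %in% spec$plates &
                     summaries$sample_id %in% c(ids_a, ids_b), ]
  if (nrow(sub) == 0L) stop_input("comparison '%s': no data on plates %s",
                                  spec$name, paste(spec$plates, collapse = ", "))
  wells <- unique(sub[, c("plate", "well")])
  wells <- wells[order(well_order_key(wells$plate, wells$well)), ]
  # completeness: every selected sample must cover every well in scope
  counts <- table(sub$sample_id)
  short <- names(counts)[counts < nrow(wells)]
  missing_ids <- setdiff(c(ids_a, ids_b), names(counts))
  if (length(short) > 0L || length(missing_ids) > 0L) {
    stop_input("comparison '%s': sample(s) %s lack values for some wells in scope",
               spec$name, paste(c(missing_ids, short), collapse = ", "))
  }

  wide <- data.table::dcast(data.table::as.data.table(sub),
                            plate + well ~ sample_id, value.var = "log_value")
  data.table::setorder(wide, plate, well)
  wide <- as.data.frame(wide)
  mat <- as.matrix(wide[, -(1:2), drop = FALSE])
  rows <- match(paste(wells$plate, wells$well),
                paste(wide$plate, wide$well))
  mat <- mat[rows, , drop = FALSE]
  col_a <- match(ids_a, colnames(mat)); col_b <- match(ids_b, colnames(mat))

  res <- lapply(seq_len(nrow(mat)), function(i) {
    va <- mat[i, col_a]; vb <- mat[i, col_b]
    tst <- mann_whitney_two_sided(va, vb)
    d <- stats::median(va) - stats::median(vb)
    list(u = tst$u_stat, p = tst$p,
         dir = if (d > 0) "increased" else if (d < 0) "decreased" else "none")
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  bh <- benjamini_hochberg(p, q)
  out <- data.frame(
    comparison = spec$name,
    plate = wells$plate, well = wells$well,
    compound = NA_character_,
    n_a = length(ids_a), n_b = length(ids_b),
    u_stat = vapply(res, `[[`, numeric(1), "u"),
    p = p, p_adj = bh$p_adj,
    direction = vapply(res, `[[`, character(1), "dir"),
    raw_sig = p < alpha, fdr_sig = bh$flag,
    stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    out$compound <- layout$compound[match(paste(out$plate, out$well),
                                          paste(layout$plate, layout$well))]
  }
  rownames(out) <- NULL
  out
}

#' Fraction of significant wells
#'
#' @param results data.frame from [run_comparison()].
#' @param criterion `"raw"` (`p < alpha`) or `"fdr"` (`p_adj < q`).
#' @return list with `count`, `total` and `percent` (one decimal, half up).
#' @export
percent_significant <- function(results, criterion = c("raw", "fdr")) {
  criterion <- match.arg(criterion)
  if (is.null(results) || nrow(results) == 0L) stop_input("empty result set")
  flag <- if (criterion == "raw") results$raw_sig else results$fdr_sig
  count <- sum(flag)
  total <- length(flag)
  list(count = count, total = total,
       percent = round_half_up(100 * count / total, 1))
}

#' Write / read per-well comparison results as TSV
#'
#' Floating-point columns are written with 6 significant digits.
#'
#' @param results data.frame from [run_comparison()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  for (cl in c("u_stat", "p", "p_adj")) out[[cl]] <- signif(out[[cl]], 6)
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  if (!file.exists(path)) stop_input("results file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ""))
}
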