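# End-to-end orchestration: raw reads -> per-well summaries -> group
# comparisons -> single-case calls -> trend/cluster outputs, with TSV
# outputs and a timestamped run log. A thin command-line wrapper over these
# functions ships in inst/cli/pmm.R.

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Read a pipeline run configuration from YAML
#'
#' The file holds input paths (`layout`, `kinetics`, `endpoint`, `samples`),
#' analysis settings (`source`: auc/endpoint, `alpha`, `q`, `method`:
#' whisker/fence, `seed`), `patients` (ids for single-case calling) and a
#' `comparisons` list, each with `name`, `plates`, and `group_a`/`group_b`
#' selectors (any of `group`, `ids`, `sex`).
#'
#' @param path YAML file.
#' @return list of arguments for [run_profile()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  for (p in c("alpha", "q")) {
    if (!is.null(cfg[[p]]) && (cfg[[p]] <= 0 || cfg[[p]] >= 1)) {
      stop_input("%s must lie in (0, 1)", p)
    }
  }
  to_sel <- function(x) sample_selector(group = x$group, ids = x$ids, sex = x$sex)
  cfg$comparisons <- lapply(cfg$comparisons, function(cmp) {
    comparison_spec(cmp$name, to_sel(cmp$group_a), to_sel(cmp$group_b),
                    plates = cmp$plates %||% pm_plates())
  })
  cfg
}

#' Run the full profiling pipeline
#'
#' Reduces raw measurements to per-well log-scale summaries, runs every
#' configured group comparison (Mann-Whitney + BH per comparison), computes
#' single-case box-and-whisker calls for every patient, and builds the
#' per-group trend table. When `out_dir` is given, writes
#' `summaries.tsv`, `comparison_<name>.tsv`, `calls_<patient>.tsv`,
#' `trends.tsv` and a `run.log` (settings echoed, row counts, seed).
#'
#' @param layout a `pm_layout` or path to a layout CSV.
#' @param kinetics,endpoint raw measurement tables (data.frames or CSV
#'   paths); at least the one matching `source` is required.
#' @param samples sample sheet (data.frame or CSV path).
#' @param comparisons list of [comparison_spec()]s (may be empty).
#' @param patients sample ids to classify single-case; default: every
#'   sample whose group is not `"control"`.
#' @param source `"auc"` or `"endpoint"` summary choice.
#' @param alpha,q raw / FDR significance thresholds.
#' @param method single-case limit method (`"whisker"`/`"fence"`).
#' @param floor_eps positivity floor for the log transform.
#' @param out_dir optional output directory.
#' @param seed echoed into the run log (the analysis itself is
#'   deterministic).
#' @return list with `summaries`, `results` (named by comparison), `calls`
#'   (named by patient), `trends`, and `paths` of written files.
#' @export
run_profile <- function(layout, kinetics = NULL, endpoint = NULL, samples,
                        comparisons = list(), patients = NULL,
                        source = c("auc", "endpoint"), alpha = 0.05, q = 0.05,
                        method = c("whisker", "fence"), floor_eps = 1e-3,
                        out_dir = NULL, seed = NULL) {
  source <- match.arg(source); method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1 || q <= 0 || q >= 1) {
    stop_input("alpha and q must lie in (0, 1)")
  }
  if (is.character(layout)) layout <- load_layout(layout)
  if (is.character(kinetics)) kinetics <- read_kinetics(kinetics)
  if (is.character(endpoint)) endpoint <- read_endpoint(endpoint)
  if (is.character(samples)) {
    samples <- as.data.frame(data.table::fread(samples))
  }
  require_columns(samples, c("sample_id", "group", "sex"), "sample sheet")

  con <- NULL
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(con), add = TRUE)
    log_line(con, "pmmprofiler %s | source=%s alpha=%g q=%g method=%s seed=%s",
             as.character(utils::packageVersion("pmmprofiler")), source,
             alpha, q, method, if (is.null(seed)) "-" else seed)
  }

  summaries <- summarize_dataset(kinetics, endpoint, source = source,
                                 floor_eps = floor_eps)
  log_line(con, "summarised %d wells x %d samples",
           nrow(unique(summaries[, c("plate", "well")])),
           length(unique(summaries$sample_id)))

  results <- list()
  for (spec in comparisons) {
    res <- run_comparison(summaries, samples, spec, alpha = alpha, q = q,
                          layout = layout)
    results[[spec$name]] <- res
    log_line(con, "comparison '%s': %d wells, %d raw-significant, %d FDR-significant",
             spec$name, nrow(res), sum(res$raw_sig), sum(res$fdr_sig))
  }

  if (is.null(patients)) {
    patients <- samples$sample_id[samples$group != "control"]
  }
  calls <- list()
  for (pid in patients) {
    cl <- call_wells(summaries, samples, pid, method = method, layout = layout)
    calls[[pid]] <- cl
    log_line(con, "patient '%s': %d above / %d below / %d within (%d skipped)",
             pid, sum(cl$call == "above"), sum(cl$call == "below"),
             sum(cl$call == "within"), nrow(attr(cl, "skipped")))
  }

  trends <- if (length(calls) > 0L) {
    direction_table(do.call(rbind, calls), samples)
  } else NULL

  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "summaries.tsv")
    sm <- summaries
    for (cl in c("auc", "rel_abs", "log_value")) sm[[cl]] <- signif(sm[[cl]], 6)
    data.table::fwrite(sm, p, sep = "\t", na = "", quote = FALSE)
    paths["summaries"] <- p
    for (nm in names(results)) {
      p <- file.path(out_dir, paste0("comparison_", gsub("\\W+", "_", nm), ".tsv"))
      write_results_tsv(results[[nm]], p)
      paths[paste0("comparison_", nm)] <- p
    }
    for (pid in names(calls)) {
      p <- file.path(out_dir, paste0("calls_", gsub("\\W+", "_", pid), ".tsv"))
      write_calls_tsv(calls[[pid]], p)
      paths[paste0("calls_", pid)] <- p
    }
    if (!is.null(trends)) {
      p <- file.path(out_dir, "trends.tsv")
      write_trend_tsv(trends, p)
      paths["trends"] <- p
    }
    log_line(con, "wrote %d output file(s) to %s", length(paths), out_dir)
  }

  list(summaries = summaries, results = results, calls = calls,
       trends = trends, paths = paths)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper chaining [simulate_cohort()] and [write_cohort()];
#' also writes the layout used, so the output directory is a complete,
#' self-describing pipeline input.
#'
#' @param config a [simulation_config()].
#' @param layout a `pm_layout` (default [example_layout()] restricted to the
#'   configured plates).
#' @param effects optional [effect_map()] rows.
#' @param dir output directory.
#' @return named file paths, invisibly.
#' @export
simulate_to_dir <- function(config, dir, layout = NULL, effects = NULL) {
  if (is.null(layout)) layout <- example_layout(config$plates)
  cohort <- simulate_cohort(config, layout, effects)
  paths <- write_cohort(cohort, dir)
  lp <- file.path(dir, "layout.csv")
  write_layout(layout, lp)
  invisible(c(paths, layout = lp))
}
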