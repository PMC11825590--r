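# Aggregation of per-well outcomes into compound-level reporting artifacts:
# per-group direction (trend) tables, opposite- and shared-trend compound
# lists, and compound-cluster fractions.

#' Per-compound direction table
#'
#' Collapses single-case calls to one direction per (group, compound).
#' `"within"` calls are excluded; a compound is `"increased"` when at least
#' one of its wells is called above and none below, `"decreased"` in the
#' mirror case, and `"mixed"` when wells disagree (compounds on
#' concentration series occupy several wells). Mixed compounds stay in the
#' table but are excluded from opposite- and shared-trend lists.
#'
#' @param calls data.frame from [call_wells()] (rows from several patients
#'   may be combined); must carry `compound`.
#' @param samples optional sample sheet used to map `patient_id` to a group
#'   label; without it each patient is its own group.
#' @return `trend_table` data.frame `group, plate, compound, direction,
#'   n_wells_called`, with attributes `counts` (increased/decreased totals
#'   per group and plate) and `call_counts` (above/below/within well tallies
#'   per group).
#' @export
direction_table <- function(calls, samples = NULL) {
  require_columns(calls, c("patient_id", "plate", "well", "compound", "call"),
                  "calls")
  if (anyNA(calls$compound)) {
    stop_input("calls lack compound annotation; pass a layout to call_wells()")
  }
  grp <- if (!is.null(samples)) {
    samples$group[match(calls$patient_id, samples$sample_id)]
  } else calls$patient_id
  df <- data.frame(group = grp, plate = calls$plate, compound = calls$compound,
                   call = calls$call, stringsAsFactors = FALSE)
  call_counts <- as.data.frame(table(group = df$group, call = df$call),
                               stringsAsFactors = FALSE)
  df <- df[df$call != "within", , drop = FALSE]
  empty <- data.frame(group = character(), plate = character(),
                      compound = character(), direction = character(),
                      n_wells_called = integer(), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    out <- empty
  } else {
    pieces <- lapply(split(df, paste(df$group, df$compound, sep = "\r")),
                     function(d) {
      has_up <- any(d$call == "above"); has_dn <- any(d$call == "below")
      data.frame(group = d$group[1L],
                 plate = paste(sort(unique(d$plate)), collapse = ";"),
                 compound = d$compound[1L],
                 direction = if (has_up && has_dn) "mixed"
                             else if (has_up) "increased" else "decreased",
                 n_wells_called = nrow(d), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$group, out$plate, out$compound), ]
    rownames(out) <- NULL
  }
  tallied <- out[out$direction != "mixed", , drop = FALSE]
  counts <- if (nrow(tallied) > 0L) {
    as.data.frame(table(group = tallied$group, plate = tallied$plate,
                        direction = tallied$direction),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(group = character(), plate = character(),
               direction = character(), Freq = integer(),
               stringsAsFactors = FALSE)
  }
  attr(out, "counts") <- counts[counts$Freq > 0L, , drop = FALSE]
  attr(out, "call_counts") <- call_counts
  class(out) <- c("trend_table", "data.frame")
  out
}

#' Direction tallies of a trend table
#'
#' @param table a `trend_table`.
#' @param group optional group label to restrict to.
#' @return named list `increased`, `decreased`, `mixed` compound counts.
#' @export
trend_counts <- function(table, group = NULL) {
  stopifnot(inherits(table, "trend_table"))
  df <- as.data.frame(table)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  list(increased = sum(df$direction == "increased"),
       decreased = sum(df$direction == "decreased"),
       mixed = sum(df$direction == "mixed"))
}

#' Compounds trending in opposite directions between two groups
#'
#' A compound qualifies when it appears in both tables with strictly
#' opposite directions (`increased` vs `decreased`; `mixed` never
#' qualifies). Symmetric in its arguments.
#'
#' @param table_a,table_b `trend_table`s built on the same layout.
#' @return sorted character vector of compound names.
#' @export
opposite_trends <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "trend_table"), inherits(table_b, "trend_table"))
  a <- as.data.frame(table_a); b <- as.data.frame(table_b)
  a <- a[a$direction %in% c("increased", "decreased"), ]
  b <- b[b$direction %in% c("increased", "decreased"), ]
  m <- merge(a[, c("compound", "direction")], b[, c("compound", "direction")],
             by = "compound", suffixes = c("_a", "_b"))
  sort(unique(m$compound[m$direction_a != m$direction_b]))
}

#' Compounds sharing one direction across all groups
#'
#' @param tables list of at least two `trend_table`s (one per group), or one
#'   combined `trend_table` covering at least two groups.
#' @param direction `"increased"` or `"decreased"`.
#' @return sorted character vector of compounds carrying `direction` in
#'   every group.
#' @export
shared_trend <- function(tables, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  if (inherits(tables, "trend_table")) {
    df <- as.data.frame(tables)
    tables <- split(df, df$group)
  }
  if (length(tables) < 2L) stop_input("shared_trend needs at least 2 groups")
  sets <- lapply(tables, function(t) {
    t <- as.data.frame(t)
    unique(t$compound[t$direction == direction])
  })
  sort(Reduce(intersect, sets))
}

#' Fraction of a compound cluster carrying one direction
#'
#' Given a well cluster (e.g. all glycine-containing wells from
#' [wells_matching()]), counts cluster wells with the stated direction.
#' Applied to [run_comparison()] results, a well counts when it is
#' significant under `criterion` *and* has that direction; applied to
#' [call_wells()] calls, a well counts when its call matches
#' (`increased` = above, `decreased` = below).
#'
#' @param x per-well results or calls.
#' @param cluster_wells data.frame with `plate` and `well`.
#' @param direction `"increased"` or `"decreased"`.
#' @param criterion significance criterion for results input: `"fdr"`
#'   (default) or `"raw"`.
#' @param cluster_name label carried into the output.
#' @return list `cluster_name, k, n, percent, direction` with `percent =
#'   100 k / n` to one decimal (half up).
#' @export
cluster_fraction <- function(x, cluster_wells,
                             direction = c("increased", "decreased"),
                             criterion = c("fdr", "raw"),
                             cluster_name = "cluster") {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  if (is.null(cluster_wells) || nrow(cluster_wells) == 0L) {
    stop_input("empty well cluster")
  }
  key <- paste(cluster_wells$plate, cluster_wells$well)
  xkey <- paste(x$plate, x$well)
  missing <- setdiff(key, xkey)
  if (length(missing) > 0L) {
    stop_input("cluster well(s) absent from results: %s",
               paste(utils::head(missing, 3L), collapse = ", "))
  }
  rows <- x[xkey %in% key, , drop = FALSE]
  hit <- if ("call" %in% names(rows)) {
    rows$call == c(increased = "above", decreased = "below")[[direction]]
  } else {
    sig <- if (criterion == "fdr") rows$fdr_sig else rows$raw_sig
    sig & rows$direction == direction
  }
  k <- sum(hit); n <- length(key)
  list(cluster_name = cluster_name, k = k, n = n,
       percent = round_half_up(100 * k / n, 1), direction = direction)
}

#' Write trend and cluster tables as TSV
#'
#' @param table a `trend_table` (for `write_trend_tsv`) or a list/data.frame
#'   of [cluster_fraction()] rows (for `write_cluster_tsv`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trend_tsv <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_trend_tsv
#' @export
write_cluster_tsv <- function(table, path) {
  if (!is.data.frame(table)) {
    table <- do.call(rbind, lapply(table, as.data.frame))
  }
  data.table::fwrite(table[, c("cluster_name", "k", "n", "percent", "direction")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
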