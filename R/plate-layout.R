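# Plate geometry and well -> compound annotation for Biolog PM-M plates.
#
# A PM-M plate has 96 wells addressed row A-H x column 01-12. Addresses are
# canonicalised with zero-padded columns ("D6" -> "D06"), matching the style
# used on instrument exports and figure captions.

#' Plate and category vocabularies
#'
#' `pm_plates()` returns the eight PM-M plate identifiers; `well_categories()`
#' the fixed compound-category vocabulary: carbon sources (PM-M1), amino
#' acids and dipeptides (PM-M2 to M4), ions (PM-M5), hormones and metabolic
#' effectors (PM-M6 to M8), plus `"other"` for blanks and fillers.
#'
#' @return character vector.
#' @export
pm_plates <- function() paste0("PM-M", 1:8)

#' @rdname pm_plates
#' @export
well_categories <- function() {
  c("carbon_source", "amino_acid", "dipeptide", "ion", "hormone",
    "metabolic_effector", "other")
}

#' All 96 canonical well addresses of one plate, in row-major order
#'
#' @return character vector `"A01"` ... `"H12"`.
#' @export
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Canonicalise well addresses
#'
#' Accepts padded (`"D06"`) and unpadded (`"D6"`) forms; returns the
#' zero-padded canonical form, or `NA` for strings that are not a row letter
#' A-H followed by a column number 1-12.
#'
#' @param well character vector of well addresses.
#' @return character vector of canonical addresses (`NA` where invalid).
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-H])0?([1-9]|1[0-2])$", well))
  vapply(m, function(g) {
    if (length(g) == 0L) NA_character_
    else paste0(g[2L], sprintf("%02d", as.integer(g[3L])))
  }, character(1))
}

# integer sort key: plate index * 1000 + row * 12 + column
well_order_key <- function(plate, well) {
  p <- match(plate, pm_plates())
  r <- match(substr(well, 1L, 1L), LETTERS[1:8])
  cc <- as.integer(substr(well, 2L, 3L))
  p * 1000L + (r - 1L) * 12L + cc
}

#' Construct and validate a plate layout
#'
#' A layout maps `(plate, well)` to a compound annotation: free-text compound
#' name, a category from [well_categories()], and optionally a
#' concentration-series membership (`series_id`) with a 1-based rank
#' (`conc_rank`) ordering replicate wells of one compound by increasing
#' concentration.
#'
#' Validation enforces: known plates; parseable well addresses; unique
#' `(plate, well)` pairs; known categories; each plate present annotated in
#' all 96 wells; within each series, distinct consecutive ranks starting
#' at 1. Rows are stored sorted by (plate, row, column) with zero-padded
#' wells, so a layout has one canonical form.
#'
#' @param entries data.frame with columns `plate`, `well`, `compound`,
#'   `category`, `series_id`, `conc_rank` (the last two may be `NA`).
#' @return a `pm_layout`: the validated, canonically ordered data.frame with
#'   attribute `plates_present`.
#' @export
pm_layout <- function(entries) {
  if (!is.data.frame(entries)) stop_input("layout entries must be a data.frame")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) > 0L) {
    if (!"series_id" %in% names(entries)) entries$series_id <- NA_character_
    if (!"conc_rank" %in% names(entries)) entries$conc_rank <- NA_integer_
    require_columns(entries, c("plate", "well", "compound", "category"), "layout")
  }

  if (nrow(entries) == 0L) {
    out <- data.frame(plate = character(), well = character(),
                      compound = character(), category = character(),
                      series_id = character(), conc_rank = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "plates_present") <- character()
    class(out) <- c("pm_layout", "data.frame")
    return(out)
  }

  entries$plate <- trimws(as.character(entries$plate))
  bad_plate <- which(!entries$plate %in% pm_plates())
  if (length(bad_plate) > 0L) {
    stop_input("unknown plate '%s' (row %d); expected one of %s",
               entries$plate[bad_plate[1L]], bad_plate[1L],
               paste(pm_plates(), collapse = ", "))
  }

  canon <- parse_well(entries$well)
  bad_well <- which(is.na(canon))
  if (length(bad_well) > 0L) {
    stop_input("malformed well address '%s' (row %d)",
               entries$well[bad_well[1L]], bad_well[1L])
  }
  entries$well <- canon

  entries$category <- trimws(as.character(entries$category))
  bad_cat <- which(!entries$category %in% well_categories())
  if (length(bad_cat) > 0L) {
    stop_input("unknown category '%s' (row %d); expected one of %s",
               entries$category[bad_cat[1L]], bad_cat[1L],
               paste(well_categories(), collapse = ", "))
  }

  key <- paste(entries$plate, entries$well)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_input("duplicate (plate, well) entry %s:%s (row %d)",
               entries$plate[dup[1L]], entries$well[dup[1L]], dup[1L])
  }

  entries$series_id <- as.character(entries$series_id)
  entries$series_id[!is.na(entries$series_id) & entries$series_id == ""] <- NA_character_
  entries$conc_rank <- suppressWarnings(as.integer(entries$conc_rank))
  in_series <- !is.na(entries$series_id)
  if (any(in_series & is.na(entries$conc_rank))) {
    stop_input("series member without a conc_rank (series '%s')",
               entries$series_id[which(in_series & is.na(entries$conc_rank))[1L]])
  }
  for (sid in unique(entries$series_id[in_series])) {
    ranks <- sort(entries$conc_rank[in_series & entries$series_id == sid])
    if (!identical(ranks, seq_along(ranks))) {
      stop_input("series '%s' has ranks (%s); expected 1..%d with no gaps or repeats",
                 sid, paste(ranks, collapse = ","), length(ranks))
    }
  }

  plates_present <- sort(unique(entries$plate))
  for (p in plates_present) {
    n <- sum(entries$plate == p)
    if (n != 96L) {
      stop_input("plate %s has %d annotated wells; a listed plate must have all 96",
                 p, n)
    }
  }

  entries <- entries[order(well_order_key(entries$plate, entries$well)),
                     c("plate", "well", "compound", "category", "series_id", "conc_rank")]
  rownames(entries) <- NULL
  attr(entries, "plates_present") <- plates_present
  class(entries) <- c("pm_layout", "data.frame")
  entries
}

#' Read a plate layout from CSV
#'
#' Expects a UTF-8 CSV with header
#' `plate,well,compound,category,series_id,conc_rank`; the series columns may
#' be empty. The result is validated by [pm_layout()].
#'
#' @param path path to the layout CSV.
#' @return a validated `pm_layout`.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop_input("layout file not found: %s", path)
  entries <- data.table::fread(path, colClasses = list(character = 1:5),
                               na.strings = c("", "NA", "-"), data.table = FALSE)
  require_columns(entries, c("plate", "well", "compound", "category",
                             "series_id", "conc_rank"), basename(path))
  pm_layout(entries)
}

#' Write a plate layout to CSV in canonical form
#'
#' Inverse of [load_layout()]: rows sorted by (plate, row, column), wells
#' zero-padded, empty series fields written as empty strings.
#'
#' @param layout a `pm_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "pm_layout"))
  data.table::fwrite(as.data.frame(layout), path, na = "", quote = "auto")
  invisible(path)
}

#' Find wells by compound-name substring or category
#'
#' Matches wells whose compound name contains `query` (case-insensitively) or
#' whose category equals `query`. Used to define compound clusters such as
#' "all wells containing glycine".
#'
#' @param layout a `pm_layout`.
#' @param query character scalar: name substring or a category.
#' @return data.frame with columns `plate`, `well`, `compound`, ordered by
#'   (plate, row, column); zero rows when nothing matches.
#' @export
wells_matching <- function(layout, query) {
  stopifnot(inherits(layout, "pm_layout"), is.character(query), length(query) == 1L)
  if (nrow(layout) == 0L) {
    return(data.frame(plate = character(), well = character(),
                      compound = character(), stringsAsFactors = FALSE))
  }
  hit <- grepl(query, layout$compound, ignore.case = TRUE, fixed = FALSE) |
    layout$category == query
  out <- as.data.frame(layout)[hit, c("plate", "well", "compound")]
  rownames(out) <- NULL
  out
}

#' Wells of one concentration series, in increasing-concentration order
#'
#' @param layout a `pm_layout`.
#' @param series_id series identifier present in the layout.
#' @return data.frame `plate`, `well`, `compound`, `conc_rank` sorted by
#'   ascending rank.
#' @export
concentration_series <- function(layout, series_id) {
  stopifnot(inherits(layout, "pm_layout"))
  rows <- which(!is.na(layout$series_id) & layout$series_id == series_id)
  if (length(rows) == 0L) stop_input("unknown series_id '%s'", series_id)
  out <- as.data.frame(layout)[rows, c("plate", "well", "compound", "conc_rank")]
  out <- out[order(out$conc_rank), ]
  rownames(out) <- NULL
  out
}
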