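# Synthetic stand-in for the proprietary Biolog PM-M1-M8 compound maps.
# Real plate maps are not redistributable; this layout places the well ->
# compound pairs that are public knowledge from figure captions and results
# text of PM-M studies of MECP2-related disorders (e.g. PM-M8 D06 = LH,
# PM-M7 G01 = IL-1beta) at their stated addresses, surrounds them with
# plausible compounds of each plate's category, and fills the rest with
# uniquely named neutral substrates.

# compounds pinned to a specific (plate, well)
pinned_wells <- function() {
  df <- function(plate, well, compound, category) {
    data.frame(plate = plate, well = well, compound = compound,
               category = category, stringsAsFactors = FALSE)
  }
  rbind(
    df("PM-M2", "H02", "Glu-Trp", "dipeptide"),
    df("PM-M2", "H07", "Gln-Gly", "dipeptide"),
    df("PM-M4", "F05", "Trp-Tyr", "dipeptide"),
    df("PM-M7", "F03", "FGF-1(aFGF)", "metabolic_effector"),
    df("PM-M7", "G01", "IL-1beta", "metabolic_effector"),
    df("PM-M7", "H04", "IL-6", "metabolic_effector"),
    df("PM-M7", "H07", "IL-8", "metabolic_effector"),
    df("PM-M8", "C08", "Calcitriol (1a,25-dihydroxyvitamin D3)", "hormone"),
    df("PM-M8", "D06", "Luteinizing Hormone (LH)", "hormone"),
    df("PM-M8", "D11", "Luteinizing Hormone Releasing Hormone (LH-RH)", "hormone"),
    df("PM-M8", "E06", "Chorionic Gonadotropin Human (HCG)", "hormone"),
    df("PM-M8", "E09", "Adrenocorticotrophic Hormone Human (ACTH)", "hormone"),
    df("PM-M8", "F12", "Thyrotropin Releasing Hormone Acetate Salt (TRH)", "hormone"),
    df("PM-M8", "G10", "TNF-alpha", "metabolic_effector")
  )
}

# glycine-containing wells total exactly 30 ("Gly" substring, incl. pinned
# Gln-Gly) and tyrosine-containing wells exactly 27 (incl. pinned Trp-Tyr),
# mirroring the cluster sizes reported for PM-M amino-acid plates.
amino_acid_queue <- function() {
  gly_partners <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Glu", "His", "Ile",
                    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Val")
  gly_rev <- c("Ala", "Arg", "Asn", "Asp", "Glu", "His", "Ile", "Leu", "Lys",
               "Met", "Ser")
  tyr_partners <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "His",
                    "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr",
                    "Trp", "Val")
  tyr_rev <- c("Ala", "Arg", "Asn", "Asp", "Gln", "Glu", "His")
  plain <- c("L-Alanine", "L-Arginine", "L-Asparagine", "L-Aspartic Acid",
             "L-Glutamic Acid", "L-Glutamine", "L-Histidine", "L-Isoleucine",
             "L-Leucine", "L-Lysine", "L-Methionine", "L-Phenylalanine",
             "L-Proline", "L-Serine", "L-Threonine", "L-Tryptophan", "L-Valine")
  data.frame(
    compound = c("Ile-Gln", "Ser-Gln",
                 "Glycine", paste0("Gly-", gly_partners), paste0(gly_rev, "-Gly"),
                 "L-Tyrosine", paste0("Tyr-", tyr_partners), paste0(tyr_rev, "-Tyr"),
                 plain),
    category = c("dipeptide", "dipeptide",
                 "amino_acid", rep("dipeptide", length(gly_partners) + length(gly_rev)),
                 "amino_acid", rep("dipeptide", length(tyr_partners) + length(tyr_rev)),
                 rep("amino_acid", length(plain))),
    stringsAsFactors = FALSE)
}

carbon_queue <- function() {
  data.frame(
    compound = c("Pectin", "Adenosine", "Pyruvic Acid", "D-Glucose",
                 "D-Fructose", "D-Mannose", "Maltose", "Sucrose", "Lactose",
                 "Inosine", "D-Ribose", "Dextrin", "Inulin", "D-Sorbitol",
                 "Citric Acid", "Succinic Acid"),
    category = "carbon_source", stringsAsFactors = FALSE)
}

effector_queue <- function() {
  data.frame(
    compound = c("IL-2", "Interferon gamma", "EGF", "PDGF-BB", "NGF-beta",
                 "Insulin", "IGF-1", "Leptin"),
    category = "metabolic_effector", stringsAsFactors = FALSE)
}

hormone_queue <- function(plate) {
  nm <- if (plate == "PM-M6") {
    c("Cortisol", "Melatonin", "Estradiol", "Progesterone", "Testosterone",
      "Thyroxine (T4)", "Aldosterone", "Prolactin")
  } else {
    c("Oxytocin", "Vasopressin", "Somatostatin", "Glucagon", "Growth Hormone",
      "Parathyroid Hormone", "Epinephrine", "Norepinephrine")
  }
  data.frame(compound = nm, category = "hormone", stringsAsFactors = FALSE)
}

ion_entries <- function() {
  ions <- c("Sodium Chloride", "Potassium Chloride", "Calcium Chloride",
            "Magnesium Chloride", "Zinc Sulfate", "Ferrous Sulfate",
            "Copper Sulfate", "Manganese Chloride", "Sodium Phosphate",
            "Potassium Phosphate", "Sodium Sulfate", "Ammonium Chloride",
            "Sodium Nitrate", "Sodium Selenite", "Cobalt Chloride",
            "Nickel Chloride", "Lithium Chloride", "Sodium Bicarbonate",
            "Sodium Citrate", "Potassium Iodide", "Chromium Chloride",
            "Sodium Molybdate", "Boric Acid", "Aluminum Sulfate")
  data.frame(
    plate = "PM-M5", well = all_wells(),
    compound = rep(ions, each = 4L), category = "ion",
    series_id = rep(sprintf("M5-S%02d", seq_along(ions)), each = 4L),
    conc_rank = rep(1:4, times = length(ions)),
    stringsAsFactors = FALSE)
}

#' Synthetic example plate layout
#'
#' Builds a complete, validated layout for the requested PM-M plates. Each
#' plate follows its real-world category (PM-M1 carbon sources, PM-M2-M4
#' amino acids and dipeptides, PM-M5 ions in 4-well increasing-concentration
#' series, PM-M6-M8 hormones and metabolic effectors), and the wells named in
#' published figure captions (e.g. PM-M8 D06 Luteinizing Hormone, PM-M7 G01
#' IL-1beta, PM-M8 G10 TNF-alpha) sit at their published addresses. Compound
#' membership elsewhere is synthetic: remaining wells carry plausible
#' compounds of the plate's category and uniquely named filler substrates.
#' The full layout contains exactly 30 glycine-containing and 27
#' tyrosine-containing wells, the cluster sizes used throughout the package
#' examples.
#'
#' @param plates plate identifiers to include (default all eight).
#' @return a validated `pm_layout`.
#' @export
example_layout <- function(plates = pm_plates()) {
  stopifnot(all(plates %in% pm_plates()))
  pins <- pinned_wells()
  default_cat <- c("PM-M1" = "carbon_source", "PM-M2" = "dipeptide",
                   "PM-M3" = "dipeptide", "PM-M4" = "dipeptide",
                   "PM-M5" = "ion", "PM-M6" = "hormone",
                   "PM-M7" = "metabolic_effector", "PM-M8" = "hormone")
  queues <- list(
    "PM-M1" = carbon_queue(),
    "PM-M2" = amino_acid_queue(),   # overflows into M3 then M4
    "PM-M6" = hormone_queue("PM-M6"),
    "PM-M7" = effector_queue(),
    "PM-M8" = hormone_queue("PM-M8"))

  build_plate <- function(plate, queue, cap = Inf) {
    if (plate == "PM-M5") return(list(entries = ion_entries(), queue = queue))
    wells <- all_wells()
    pin <- pins[pins$plate == plate, , drop = FALSE]
    free <- setdiff(wells, pin$well)
    n_take <- min(length(free), nrow(queue), cap)
    taken <- if (n_take > 0L) queue[seq_len(n_take), , drop = FALSE] else queue[0L, ]
    left <- free[seq_len(length(free)) > n_take]
    entries <- rbind(
      if (nrow(pin) > 0L)
        data.frame(plate = plate, well = pin$well, compound = pin$compound,
                   category = pin$category, stringsAsFactors = FALSE),
      if (n_take > 0L)
        data.frame(plate = plate, well = free[seq_len(n_take)],
                   compound = taken$compound, category = taken$category,
                   stringsAsFactors = FALSE),
      if (length(left) > 0L)
        data.frame(plate = plate, well = left,
                   compound = paste0("Substrate ", plate, "-", left),
                   category = default_cat[[plate]], stringsAsFactors = FALSE))
    entries$series_id <- NA_character_
    entries$conc_rank <- NA_integer_
    list(entries = entries,
         queue = queue[seq_len(nrow(queue)) > n_take, , drop = FALSE])
  }

  aa_plates <- c("PM-M2", "PM-M3", "PM-M4")
  aa_queue <- queues[["PM-M2"]]
  parts <- list()
  for (p in pm_plates()) {
    is_aa <- p %in% aa_plates
    q <- if (is_aa) aa_queue
         else queues[[p]] %||% data.frame(compound = character(),
                                          category = character())
    # amino-acid queue advances over skipped plates too, so each included
    # plate's contents do not depend on which other plates were requested
    res <- build_plate(p, q, cap = if (is_aa) 30L else Inf)
    if (is_aa) aa_queue <- res$queue
    if (p %in% plates) parts[[p]] <- res$entries
  }
  pm_layout(do.call(rbind, parts))
}
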