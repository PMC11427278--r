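## PT -> primary SOC mapping via a pluggable, user-replaceable dictionary.
## Full MedDRA is licensed; the package ships a small dictionary covering
## the neratinib signal PTs plus the synthetic vocabulary.

.soc_names <- c(
  "gastrointestinal disorders",
  "metabolism and nutrition disorders",
  "investigations",
  "skin and subcutaneous tissue disorders",
  "general disorders and administration site conditions",
  "nervous system disorders",
  "neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "hepatobiliary disorders",
  "injury, poisoning and procedural complications",
  "musculoskeletal and connective tissue disorders",
  "renal and urinary disorders",
  "respiratory, thoracic and mediastinal disorders",
  "infections and infestations",
  "reproductive system and breast disorders",
  "blood and lymphatic system disorders",
  "ear and labyrinth disorders",
  "vascular disorders",
  "endocrine disorders",
  "eye disorders",
  "psychiatric disorders",
  "cardiac disorders",
  "immune system disorders")

#' The standard system organ class names used by the toy dictionary
#' @return character vector of 22 SOC names.
#' @export
soc_names <- function() .soc_names

#' Marker returned for PTs absent from the dictionary
#' @return the string used as the unmapped SOC marker.
#' @export
meddra_unmapped <- function() "<unmapped>"

#' Load a PT -> SOC dictionary
#'
#' Two-column TSV (`pt`, `soc`) with header. Keys are case-folded; duplicate
#' rows mapping a PT to the same SOC collapse, conflicting duplicates are an
#' error (each PT has exactly one primary SOC).
#'
#' @param path TSV file.
#' @param version version label recorded on the dictionary (and logged into
#'   pipeline outputs).
#' @return object of class `meddra_dict`: a named character vector
#'   PT (lowercase) -> SOC, with a `version` attribute.
#' @export
load_meddra <- function(path, version = basename(path)) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("pt", "soc") %in% names(dt)))
    stop("dictionary needs columns 'pt' and 'soc'")
  if (nrow(dt) == 0L) stop("empty dictionary file")
  dt[, pt := tolower(trimws(pt))]
  dt[, soc := trimws(soc)]
  if (any(!nzchar(dt$pt)) || any(!nzchar(dt$soc)))
    stop("empty PT or SOC value in dictionary")
  dt <- unique(dt)
  conf <- dt[, .N, by = pt][N > 1L]
  if (nrow(conf))
    stop("conflicting SOC for PT(s): ", paste(utils::head(conf$pt, 5),
                                              collapse = ", "))
  d <- dt$soc
  names(d) <- dt$pt
  structure(d, class = "meddra_dict", version = version)
}

#' The shipped toy dictionary
#'
#' Covers the 48 neratinib signal PTs with their primary SOCs plus the
#' default synthetic PT vocabulary. Replace with a licensed MedDRA export
#' (same two-column layout) for real analyses.
#' @return a `meddra_dict`.
#' @export
meddra_toy <- function() load_meddra(fs_extdata("meddra_toy.tsv"),
                                     version = "toy-25.0")

#' Map PTs to their primary SOC
#'
#' Case-insensitive lookup; PTs absent from the dictionary map to
#' [meddra_unmapped()] (and are counted, never silently dropped).
#'
#' @param dict a `meddra_dict` from [load_meddra()].
#' @param pt character vector of PT strings.
#' @return character vector of SOCs, with attribute `n_unmapped`.
#' @export
map_pt <- function(dict, pt) {
  stopifnot(inherits(dict, "meddra_dict"))
  soc <- unname(unclass(dict)[tolower(trimws(pt))])
  soc[is.na(soc)] <- meddra_unmapped()
  attr(soc, "n_unmapped") <- sum(soc == meddra_unmapped())
  soc
}

#' Aggregate report-PT pairs to SOC level
#'
#' Replaces each pair's PT by its primary SOC and collapses within-report
#' repeats, so a report contributes one pair per SOC regardless of how many
#' of its PTs fall in that SOC. With `collapse = FALSE` every PT pair is
#' retained (event-level accounting: SOC counts are then sums of member PT
#' counts).
#'
#' @param pairs `data.table` from [drug_event_pairs()].
#' @param dict a `meddra_dict`.
#' @param collapse collapse within-report repeats after mapping
#'   (default `FALSE`: SOC case counts partition the PT pair total).
#' @return pairs table with `pt` replaced by the SOC (column `term`).
#' @export
pairs_to_soc <- function(pairs, dict, collapse = FALSE) {
  out <- copy(pairs)
  out[, pt := map_pt(dict, pt)]
  if (collapse) out <- unique(out, by = c("primaryid", "pt"))
  out[]
}
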