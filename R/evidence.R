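# Curated literature evidence on lithium's effect on BCL2 levels.
#
# The package ships a machine-readable transcription of a systematic
# literature screen: 49 experimental set-ups (one per tissue x dose x
# duration x assay combination within each study) recording species,
# tissue, dosing, sample size, assay, the normalizer used, the reported
# effect and its significance, together with a companion table of
# normalizing genes/proteins reported as altered by lithium or psychiatric
# disease state, and an explicit alias table for normalizer name matching.

evidence_outcomes <- c("NS", "sig_up", "sig_down", "direction_only")
evidence_assays <- c("qPCR", "WB", "MA", "NB", "IHC", "ELISA")

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "normsense")
  if (path == "") ns_io_error("packaged data file '%s' not found", file)
  path
}

#' Load the curated evidence table
#'
#' Reads and schema-validates the packaged transcription of published
#' experimental set-ups assessing lithium's effect on BCL2 transcript or
#' protein levels (or a user-supplied table with the same columns).
#'
#' @param path optional path to an alternative TSV; defaults to the
#'   packaged table.
#' @return data frame of class \code{evidence_table} with columns
#'   \code{study_ref}, \code{species}, \code{tissue}, \code{dose},
#'   \code{regimen}, \code{n}, \code{assay}, \code{normalizer},
#'   \code{effect_size}, \code{outcome}, \code{stars}, \code{note}.
#' @export
load_evidence_table <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("lithium_bcl2_evidence.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  required <- c("study_ref", "species", "tissue", "dose", "regimen", "n",
                "assay", "normalizer", "effect_size", "outcome", "stars")
  if (length(setdiff(required, names(df))))
    ns_format_error("evidence table missing column(s): %s",
                    paste(setdiff(required, names(df)), collapse = ", "))
  df$stars <- as.integer(df$stars)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$assay %in% evidence_assays)
      ns_validation_error("row %d (%s): unknown assay code '%s'",
                          i, row$study_ref, row$assay)
    if (!row$outcome %in% evidence_outcomes)
      ns_validation_error("row %d (%s): unknown outcome '%s'",
                          i, row$study_ref, row$outcome)
    if (is.na(row$stars) || row$stars < 0 || row$stars > 3)
      ns_validation_error("row %d (%s): stars must be 0..3", i, row$study_ref)
    if ((row$outcome == "NS") != (row$effect_size == "NS"))
      ns_validation_error("row %d (%s): NS outcome and NS effect size must coincide",
                          i, row$study_ref)
    if (row$outcome %in% c("sig_up", "sig_down") && row$stars < 1)
      ns_validation_error("row %d (%s): significant outcome requires stars >= 1",
                          i, row$study_ref)
    if (row$outcome == "direction_only" && row$stars != 0)
      ns_validation_error("row %d (%s): direction_only entries carry no stars",
                          i, row$study_ref)
  }
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' Load the affected-normalizer table
#'
#' Normalizing genes/proteins reported as differentially expressed in
#' lithium-treated animals or in psychiatric disease states; the name set
#' (at minimum Actb, Gapdh, Tuba, Tubb and family members) feeds
#' \code{\link{tally_affected_normalizers}}.
#'
#' @param path optional alternative TSV.
#' @return data frame with columns \code{name}, \code{level},
#'   \code{specimen}, \code{relative_change}, \code{study_ref}.
#' @export
load_affected_normalizers <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("affected_normalizers.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (length(setdiff(c("name", "level"), names(df))))
    ns_format_error("affected-normalizer table requires at least columns name, level")
  if (!nrow(df)) ns_validation_error("affected-normalizer table is empty")
  df
}

#' Load the normalizer alias table
#'
#' Explicit protein-name-to-gene-symbol aliases (e.g. beta-actin to Actb)
#' used for case-insensitive normalizer matching; packaged data, not
#' heuristics.
#'
#' @param path optional alternative TSV.
#' @return data frame with columns \code{alias}, \code{canonical}.
#' @export
load_normalizer_aliases <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("normalizer_aliases.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

canonical_normalizer <- function(x, aliases) {
  key <- tolower(trimws(x))
  hit <- match(key, tolower(aliases$alias))
  out <- ifelse(is.na(hit), x, aliases$canonical[hit])
  out
}

#' Tally evidence outcomes
#'
#' Counts the outcome categories of (a filtered subset of) the evidence
#' table. The categories partition the total: \code{ns + sig_up +
#' sig_down + direction_only = total} always holds.
#'
#' @param entries an \code{\link{load_evidence_table}} data frame (possibly
#'   row-filtered).
#' @return named integer vector: \code{total}, \code{ns}, \code{sig_up},
#'   \code{sig_down}, \code{direction_only}.
#' @export
tally_outcomes <- function(entries) {
  df <- as.data.frame(entries)
  cnt <- table(factor(df$outcome, levels = evidence_outcomes))
  c(total = nrow(df), ns = unname(cnt["NS"]), sig_up = unname(cnt["sig_up"]),
    sig_down = unname(cnt["sig_down"]),
    direction_only = unname(cnt["direction_only"]))
}

#' Count significant-upregulation set-ups normalized to affected genes
#'
#' Among set-ups reporting significant BCL2 upregulation, counts those
#' whose raw signal was normalized to a gene or protein in the affected
#' set. Matching is case-insensitive and runs through the packaged alias
#' table (beta-actin to Actb, beta-tubulin to Tubb, ...). Tissue sub-lines
#' of one experiment that share study, assay, dose, regimen and normalizer
#' reflect a single normalization decision and are counted once.
#'
#' @param entries evidence table (possibly filtered).
#' @param affected affected-normalizer table or character vector of names;
#'   defaults to the packaged table.
#' @param aliases alias table; defaults to the packaged table.
#' @return integer count; the matching entries are attached as attribute
#'   \code{detail}.
#' @export
tally_affected_normalizers <- function(entries, affected = NULL,
                                       aliases = NULL) {
  df <- as.data.frame(entries)
  if (!nrow(df)) ns_validation_error("no evidence entries supplied")
  if (is.null(affected)) affected <- load_affected_normalizers()
  if (is.null(aliases)) aliases <- load_normalizer_aliases()
  affected_names <- if (is.data.frame(affected)) affected$name else affected
  affected_canon <- tolower(canonical_normalizer(affected_names, aliases))

  up <- df[df$outcome == "sig_up" & !is.na(df$normalizer) &
             df$normalizer != "NA", , drop = FALSE]
  if (!nrow(up)) return(structure(0L, detail = up))
  canon <- canonical_normalizer(up$normalizer, aliases)
  hit <- up[tolower(canon) %in% affected_canon, , drop = FALSE]
  key <- unique(paste(hit$study_ref, hit$assay, hit$dose, hit$regimen,
                      tolower(canonical_normalizer(hit$normalizer, aliases)),
                      sep = "\r"))
  structure(length(key), detail = hit)
}
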