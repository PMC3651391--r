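# Packaged reference datasets.
#
# Reviewable TSV transcriptions of the published MSH6 variant tables, with a
# provenance column per row so transcription is diffable against the source.

#' The 34 evidence-classified MSH6 variant carriers
#'
#' The curated reference set: 15 carriers labeled "likely Lynch syndrome"
#' (LLS, pathogenic) and 19 "unlikely Lynch syndrome" (ULS, non-pathogenic),
#' with the clinical/molecular evidence behind each label, the published
#' criteria identifiers, and the training/test split (carriers with
#' biochemical functional-assay data form the test set; the rest trained
#' the model coefficients).
#'
#' @return Data frame with the [clinical_record()] evidence columns plus
#'   `variant`, `label`, `criteria`, `dataset` and `provenance`.
#' @examples
#' table(msh6_classified_variants()$label)
#' @export
msh6_classified_variants <- function() {
  x <- read_codp_tsv(.codp_extdata("msh6_classified_variants.tsv"))
  x$minor_allele_frequency <- as.numeric(x$minor_allele_frequency)
  .validate_records(x)
  x
}

#' The 260 unclassified MSH6 variants with published joint scores
#'
#' Transcription of the published classification of the 260 unclassified
#' variants (UVs): variant string, CoDP joint score (3 decimals) and the
#' published impact category (`no_impact`, `moderate`, `impact`).
#'
#' @return Data frame with `variant`, `score`, `printed_category`,
#'   `provenance`.
#' @examples
#' nrow(msh6_uv_scores())  # 260
#' @export
msh6_uv_scores <- function() {
  read_codp_tsv(.codp_extdata("msh6_uv_scores.tsv"))
}
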