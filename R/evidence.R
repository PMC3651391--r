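# Evidence-based classification of MSH6 variant carriers.
#
# A carrier is "likely Lynch syndrome" (LLS, pathogenic) or "unlikely Lynch
# syndrome" (ULS, non-pathogenic) when it fulfils one or more of the
# following criteria; anything else remains an unclassified variant (UV).
#
#   LLS-1: abnormal functional assay AND (abnormal IHC of only MSH6 OR MSI-H)
#   LLS-2: abnormal IHC of only MSH6 AND MSI-H
#   LLS-3: (abnormal IHC of only MSH6 OR supportive segregation) AND at
#          least two of {family history met, proband tumor feature met,
#          control allele frequency zero in >= 100 healthy controls}
#   ULS-1: polymorphism (minor allele frequency >= 0.01)
#   ULS-2: normal functional assay AND (MSS OR normal MSH6 IHC)
#   ULS-3: MSS AND normal MSH6 IHC
#
# Unknown evidence (nd/na/inconclusive) never fires a predicate. If criteria
# from both sides fire, the record is labeled "conflict" and surfaced,
# never silently resolved.

.EVIDENCE_COLUMNS <- c(
  "ihc_mlh1", "ihc_msh2", "ihc_msh6", "msi",
  "assay_mmr_activity", "assay_msh2_interaction", "assay_localization",
  "assay_atp_hydrolysis", "assay_mismatch_recognition",
  "segregation_supportive", "family_history_met", "proband_tumor_met",
  "control_freq_zero_n100", "minor_allele_frequency"
)

.ASSAY_COLUMNS <- c("assay_mmr_activity", "assay_msh2_interaction",
                    "assay_localization", "assay_atp_hydrolysis",
                    "assay_mismatch_recognition")

#' Construct a clinical evidence record
#'
#' One carrier's clinical and molecular evidence, in the shape consumed by
#' [classify_evidence()]. All fields default to "not determined".
#'
#' @param variant Variant string (e.g. `"E1193K"`); optional.
#' @param ihc_mlh1,ihc_msh2,ihc_msh6 Immunohistochemistry of the MMR
#'   proteins: `"normal"`, `"abnormal"`, `"inconclusive"`, `"nd"`, `"na"`.
#' @param msi Microsatellite instability: `"H"`, `"L"`, `"S"`, `"nd"`.
#' @param assay_mmr_activity,assay_msh2_interaction,assay_localization,assay_atp_hydrolysis,assay_mismatch_recognition
#'   The five biochemical functional assays: `"normal"`, `"abnormal"`,
#'   `"inconclusive"`, `"nd"`.
#' @param segregation_supportive,family_history_met,proband_tumor_met
#'   `"yes"`, `"no"`, `"nd"`.
#' @param control_freq_zero_n100 Allele absent from >= 100 healthy controls:
#'   `"yes"`, `"no"`, `"inconclusive"`, `"nd"`.
#' @param minor_allele_frequency Numeric in `[0, 1]`, or `NA` when unknown.
#' @return A one-row data frame with the evidence columns.
#' @examples
#' clinical_record("S1188N", ihc_mlh1 = "normal", ihc_msh2 = "normal",
#'                 ihc_msh6 = "abnormal", msi = "H",
#'                 assay_mmr_activity = "abnormal")
#' @export
clinical_record <- function(variant = NA_character_,
                            ihc_mlh1 = "nd", ihc_msh2 = "nd",
                            ihc_msh6 = "nd", msi = "nd",
                            assay_mmr_activity = "nd",
                            assay_msh2_interaction = "nd",
                            assay_localization = "nd",
                            assay_atp_hydrolysis = "nd",
                            assay_mismatch_recognition = "nd",
                            segregation_supportive = "nd",
                            family_history_met = "nd",
                            proband_tumor_met = "nd",
                            control_freq_zero_n100 = "nd",
                            minor_allele_frequency = NA_real_) {
  rec <- data.frame(
    variant = variant,
    ihc_mlh1 = ihc_mlh1, ihc_msh2 = ihc_msh2, ihc_msh6 = ihc_msh6,
    msi = msi,
    assay_mmr_activity = assay_mmr_activity,
    assay_msh2_interaction = assay_msh2_interaction,
    assay_localization = assay_localization,
    assay_atp_hydrolysis = assay_atp_hydrolysis,
    assay_mismatch_recognition = assay_mismatch_recognition,
    segregation_supportive = segregation_supportive,
    family_history_met = family_history_met,
    proband_tumor_met = proband_tumor_met,
    control_freq_zero_n100 = control_freq_zero_n100,
    minor_allele_frequency = minor_allele_frequency,
    stringsAsFactors = FALSE
  )
  .validate_records(rec)
  rec
}

.validate_records <- function(records) {
  miss <- setdiff(.EVIDENCE_COLUMNS, names(records))
  if (length(miss)) {
    stop("codp_invalid_record: missing evidence column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  chk <- function(col, allowed) {
    v <- records[[col]]
    bad <- !(v %in% allowed)
    if (any(bad)) {
      stop("codp_invalid_record: bad value '", v[bad][1L], "' in ", col,
           " (allowed: ", paste(allowed, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  for (col in c("ihc_mlh1", "ihc_msh2", "ihc_msh6")) {
    chk(col, c("normal", "abnormal", "inconclusive", "nd", "na"))
  }
  chk("msi", c("H", "L", "S", "nd"))
  for (col in .ASSAY_COLUMNS) {
    chk(col, c("normal", "abnormal", "inconclusive", "nd"))
  }
  for (col in c("segregation_supportive", "family_history_met",
                "proband_tumor_met")) {
    chk(col, c("yes", "no", "nd"))
  }
  chk("control_freq_zero_n100", c("yes", "no", "inconclusive", "nd"))
  maf <- records$minor_allele_frequency
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("codp_invalid_record: minor_allele_frequency must be in [0, 1]",
         call. = FALSE)
  }
  invisible(records)
}

#' Is the IHC loss restricted to MSH6?
#'
#' TRUE when MSH6 staining is abnormal and neither MLH1 nor MSH2 staining is
#' abnormal. Inconclusive / not-determined / not-applicable MLH1 or MSH2
#' results do not veto: the pattern only requires that no other MMR protein
#' is positively abnormal.
#'
#' @param record One or more evidence records (data frame rows).
#' @return Logical vector.
#' @export
ihc_only_msh6_abnormal <- function(record) {
  .validate_records(record)
  record$ihc_msh6 == "abnormal" &
    record$ihc_mlh1 != "abnormal" &
    record$ihc_msh2 != "abnormal"
}

#' Aggregate state of the five functional assays
#'
#' `"abnormal"` when any of the five assays (MMR activity, MSH2 interaction,
#' localization, ATP hydrolysis, mismatch recognition) is abnormal;
#' `"normal"` when at least one assay is normal and none abnormal;
#' `"unknown"` otherwise (everything not determined or inconclusive).
#'
#' @param record One or more evidence records.
#' @return Character vector: `"abnormal"`, `"normal"` or `"unknown"`.
#' @export
functional_assay_state <- function(record) {
  .validate_records(record)
  m <- as.matrix(record[, .ASSAY_COLUMNS, drop = FALSE])
  any_abn <- apply(m == "abnormal", 1L, any)
  any_nrm <- apply(m == "normal", 1L, any)
  ifelse(any_abn, "abnormal", ifelse(any_nrm, "normal", "unknown"))
}

#' Classify carriers as LLS / ULS / UV from clinical evidence
#'
#' Applies the six evidence criteria (see the package vignette) to each
#' record. A record firing criteria on both sides is labeled `"conflict"`
#' (optionally forced to `"UV"`); a record firing none stays `"UV"`.
#'
#' @param records Data frame of evidence records (see [clinical_record()];
#'   extra columns such as `variant` are carried through).
#' @param conflict_as_uv Force conflicting records to the UV label instead
#'   of `"conflict"` (default FALSE; conflicts are surfaced).
#' @return Data frame with `variant` (if present), `label` (LLS / ULS / UV /
#'   conflict), `criteria_met` (comma-separated identifiers among LLS-1..3,
#'   ULS-1..3) and `trace` (human-readable rule-firing log).
#' @examples
#' rec <- clinical_record("S1188N", ihc_mlh1 = "normal",
#'                        ihc_msh2 = "normal", ihc_msh6 = "abnormal",
#'                        msi = "H", assay_mmr_activity = "abnormal")
#' classify_evidence(rec)
#' @export
classify_evidence <- function(records, conflict_as_uv = FALSE) {
  records <- as.data.frame(records)
  .validate_records(records)

  only6 <- ihc_only_msh6_abnormal(records)
  fstate <- functional_assay_state(records)
  msi_h <- records$msi == "H"
  msi_s <- records$msi == "S"
  msh6_norm <- records$ihc_msh6 == "normal"
  seg <- records$segregation_supportive == "yes"
  clin3 <- (records$family_history_met == "yes") +
    (records$proband_tumor_met == "yes") +
    (records$control_freq_zero_n100 == "yes")
  maf <- records$minor_allele_frequency

  crit <- cbind(
    `LLS-1` = fstate == "abnormal" & (only6 | msi_h),
    `LLS-2` = only6 & msi_h,
    `LLS-3` = (only6 | seg) & clin3 >= 2,
    `ULS-1` = !is.na(maf) & maf >= 0.01,
    `ULS-2` = fstate == "normal" & (msi_s | msh6_norm),
    `ULS-3` = msi_s & msh6_norm
  )
  lls_any <- apply(crit[, 1:3, drop = FALSE], 1L, any)
  uls_any <- apply(crit[, 4:6, drop = FALSE], 1L, any)
  label <- ifelse(lls_any & uls_any, "conflict",
                  ifelse(lls_any, "LLS", ifelse(uls_any, "ULS", "UV")))
  if (conflict_as_uv) label[label == "conflict"] <- "UV"

  ids <- colnames(crit)
  criteria_met <- apply(crit, 1L, function(z) {
    paste(ids[z], collapse = ",")
  })
  trace <- vapply(seq_len(nrow(records)), function(i) {
    fired <- ids[crit[i, ]]
    paste0(
      "ihc_only_msh6=", tolower(only6[i]), "; assay=", fstate[i],
      "; msi=", records$msi[i], "; clinical_criteria_met=", clin3[i],
      "; maf=", ifelse(is.na(maf[i]), "unknown", format(maf[i])),
      " => ", if (length(fired)) paste(fired, collapse = "+") else "none"
    )
  }, character(1))

  out <- data.frame(label = label, criteria_met = criteria_met,
                    trace = trace, stringsAsFactors = FALSE)
  if ("variant" %in% names(records)) {
    out <- cbind(variant = records$variant, out)
  }
  out
}
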