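# PDB structure ingestion.
#
# Parsing of the standard format is delegated to bio3d; the wrapper enforces
# the contracts the accessibility engine relies on: only the first model of a
# multi-model file is kept, alternate locations are resolved to the highest
# occupancy (ties -> first listed), and waters / non-protein heteroatoms are
# flagged so the ASA computation can exclude them by default.

#' Read a protein structure from PDB text
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of record lines).
#' @return An object of class `codp_structure`: a list with `atoms` (a data
#'   frame with one row per retained atom: `type`, `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `element`, `x`, `y`, `z`, `occ`, `water`, `hetero`)
#'   and `model_index` (always 1; only the first model is retained).
#' @details Alternate-location groups (same chain, residue, insertion code and
#'   atom name) are reduced to the highest-occupancy record; ties keep the
#'   record listed first. The element symbol is taken from columns 77-78 when
#'   present, otherwise derived from the atom name.
#' @examples
#' s <- read_structure(synthetic_structure("isolated"), as_structure = FALSE)
#' @export
read_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L]) || !file.exists(pdb[1L])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  x <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("codp_parse_error: not parseable as PDB: ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- x$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("codp_parse_error: no ATOM/HETATM records found", call. = FALSE)
  }
  # first model only: bio3d stores model-1 coordinates in $atom rows, but for
  # files where MODEL blocks repeat the same atoms as extra rows, drop
  # duplicated (chain, resno, insert, elety, alt) keys beyond first occurrence
  key <- paste(at$chain, at$resno, at$insert, at$elety, at$alt, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]
  # alternate locations: keep highest occupancy within each atom site
  site <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(factor(site, levels = unique(site)), -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(site[ord]), , drop = FALSE]

  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  element <- toupper(trimws(element))
  fallback <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", trimws(at$elety)))
  element <- ifelse(is.na(element) | element == "", fallback, element)

  resid <- toupper(at$resid)
  water <- resid %in% c("HOH", "WAT", "DOD")
  atoms <- data.frame(
    type = at$type,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = resid,
    elety = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = occ,
    water = water,
    hetero = at$type == "HETATM" & !water,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("codp_parse_error: non-finite atom coordinates", call. = FALSE)
  }
  structure(list(atoms = atoms, model_index = 1L), class = "codp_structure")
}

#' @export
print.codp_structure <- function(x, ...) {
  a <- x$atoms
  cat("codp_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$insert)[!a$hetero & !a$water])),
      "polymer residues,", sum(a$hetero), "hetero atoms,",
      sum(a$water), "waters\n")
  invisible(x)
}

#' Render a structure as PDB text
#'
#' @param structure A `codp_structure`.
#' @return Character vector of PDB record lines (ATOM/HETATM + END).
#' @export
pdb_text <- function(structure) {
  a <- structure$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$type, seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety), "",
    a$resid, ifelse(a$chain == "", " ", a$chain), a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$occ, 0, a$element
  )
  c(lines, "END")
}
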