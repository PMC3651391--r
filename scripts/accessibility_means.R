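#!/usr/bin/env Rscript
# Optional check (requires a user-downloaded structure; nothing is fetched):
# mean relative solvent accessibility at the substituted positions of the
# pathogenic (LLS) vs benign (ULS) reference variants, computed on a
# MSH6/MSH2 crystal structure such as PDB entry 2o8b.
#
# usage: Rscript scripts/accessibility_means.R --pdb <file> [--chain B]
#
# Expect approximate agreement only: the published values (mean 0.141 for
# LLS, 0.589 for ULS) were computed on a loop-completed model with an
# unstated radius set and reference normalization, and deposited structures
# lack several of the 34 positions (reported here as skipped).

suppressPackageStartupMessages({
  library(codp)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--pdb", type = "character", help = "path to a PDB file"),
  make_option("--chain", type = "character", default = "B",
              help = "chain holding MSH6 [default %default]"),
  make_option("--n-points", type = "integer", default = 960L,
              dest = "n_points")
)))
if (is.null(opts$pdb)) stop("supply --pdb <file>")

s <- read_structure(opts$pdb)
res <- residue_accessibility(s, n_sphere_points = opts$n_points)
res <- res[res$chain == opts$chain, , drop = FALSE]
if (nrow(res) == 0) {
  stop("no residues on chain ", opts$chain, "; available: ",
       paste(unique(s$atoms$chain), collapse = ", "))
}

cv <- msh6_classified_variants()
pos <- parse_variant(cv$variant)$position
for (lab in c("LLS", "ULS")) {
  p <- pos[cv$label == lab]
  hit <- match(p, res$resno)
  ra <- res$rel_acc[hit[!is.na(hit)]]
  if (any(is.na(hit))) {
    cat(lab, ": skipped ", sum(is.na(hit)), " position(s) absent from the ",
        "structure: ", paste(p[is.na(hit)], collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("%s mean relative accessibility: %.3f (n = %d, median %.3f)\n",
              lab, mean(ra), length(ra), stats::median(ra)))
}
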