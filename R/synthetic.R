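# Synthetic structures and simulated datasets.
#
# The structure generator emits stylized but format-valid PDB text for three
# layouts used throughout the tests and for the self-consistent max-ASA
# reference: an isolated residue, an idealized poly-alanine alpha-helix and
# a residue fully caged inside a shell of occluding dummy atoms. Side chains
# are stylized: the correct number and elements of heavy atoms (standard PDB
# atom names) laid out as an extended zig-zag, not chemically exact
# geometry. This is sufficient for everything the package derives from a
# structure (occlusion, burial, self-normalized accessibility).

# atom table of a single stylized residue with CA at `origin`
.residue_template_atoms <- function(aa, resno = 1L, chain = "A",
                                    origin = c(0, 0, 0)) {
  three <- aa_property_table()$three_letter[aa_property_table()$one_letter == aa]
  sc <- .SIDE_CHAIN_ATOMS[[aa]]
  name <- c("N", "CA", "C", "O", sc)
  n_sc <- length(sc)
  j <- seq_len(n_sc)
  x <- c(-1.46, 0, 1.52, 2.15, ifelse(j %% 2 == 0, 0.9, 0))
  y <- c(0, 0, 0, -1.06, 1.53 + 1.30 * (j - 1))
  z <- rep(0, 4 + n_sc)
  data.frame(
    type = "ATOM", chain = chain, resno = as.integer(resno), insert = "",
    resid = three, elety = name,
    element = toupper(substr(sub("^[0-9]+", "", name), 1, 1)),
    x = x + origin[1], y = y + origin[2], z = z + origin[3],
    occ = 1, water = FALSE, hetero = FALSE, stringsAsFactors = FALSE
  )
}

.rotate_z <- function(m, theta) {
  cbind(m[, 1] * cos(theta) - m[, 2] * sin(theta),
        m[, 1] * sin(theta) + m[, 2] * cos(theta), m[, 3])
}

#' Generate a synthetic protein structure
#'
#' Deterministic synthetic scaffolds for testing and for the packaged
#' max-ASA reference constants.
#'
#' @param layout One of `"isolated"` (a single free residue), `"helix"` (an
#'   idealized poly-alanine alpha-helix: 1.5 A rise and 100 degrees twist per
#'   residue, radius 2.3 A, side chains pointing outward) or `"caged"` (a
#'   single residue enclosed in a shell of overlapping dummy carbon atoms, so
#'   its accessibility is exactly zero).
#' @param n_residues Number of residues (helix layout; others use 1).
#' @param aa One-letter residue type for the isolated/caged residue.
#' @param seed Unused by the deterministic layouts; kept so all generators
#'   share the seeded interface.
#' @return A `codp_structure`.
#' @examples
#' synthetic_structure("helix", n_residues = 10)
#' @export
synthetic_structure <- function(layout = c("isolated", "helix", "caged"),
                                n_residues = 1L, aa = "A", seed = 1L) {
  layout <- match.arg(layout)
  if (n_residues < 1) {
    stop("codp_invalid_argument: n_residues must be >= 1", call. = FALSE)
  }
  .check_aa(aa)
  atoms <- switch(
    layout,
    isolated = .residue_template_atoms(aa),
    helix = {
      rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
      do.call(rbind, lapply(seq_len(n_residues), function(i) {
        th <- (i - 1) * twist
        ca <- c(radius * cos(th), radius * sin(th), (i - 1) * rise)
        a <- .residue_template_atoms("A", resno = i)
        # local frame: side chain (CB) points radially outward
        xyz <- .rotate_z(cbind(a$y, a$x, a$z), th)  # swap so +y -> radial
        a$x <- xyz[, 1] + ca[1]; a$y <- xyz[, 2] + ca[2]
        a$z <- xyz[, 3] + ca[3]
        a
      }))
    },
    caged = {
      core <- .residue_template_atoms(aa)
      shell <- .sphere_points(200) * 5.5
      cage <- data.frame(
        type = "ATOM", chain = "C", resno = seq_len(nrow(shell)) + 100L,
        insert = "", resid = "DUM", elety = "C", element = "C",
        x = shell[, 1], y = shell[, 2] + 1.5, z = shell[, 3],
        occ = 1, water = FALSE, hetero = FALSE, stringsAsFactors = FALSE
      )
      rbind(core, cage)
    }
  )
  s <- structure(list(atoms = atoms, model_index = 1L),
                 class = "codp_structure")
  # round-trip through the PDB writer/parser so the output is guaranteed to
  # be format-valid text
  read_structure(pdb_text(s))
}

#' Simulate a labeled variant feature table
#'
#' Draws the five CoDP predictors uniformly from stated ranges and samples
#' pathogenic labels from the Bernoulli(q) law of a given logistic model;
#' used for parameter-recovery and jackknife tests.
#'
#' @param model A [codp_model()] (default: the packaged CoDP coefficients).
#' @param n Number of variants (>= 10).
#' @param seed Integer RNG seed; the generator never touches the global seed
#'   outside its own evaluation.
#' @param ranges Named list of feature ranges: `mapp_norm` and `rel_acc` as
#'   `c(min, max)`, `sift` and `pph2_humvar` fixed to `[0, 1]`,
#'   `delta_heavy` an integer set to sample from.
#' @return Data frame with the five feature columns, the true `q` and a
#'   binary `label` (1 = pathogenic).
#' @examples
#' head(simulate_variants(n = 20, seed = 1))
#' @export
simulate_variants <- function(model = codp_model(), n = 100L, seed = 1L,
                              ranges = list(mapp_norm = c(0, 4),
                                            delta_heavy = 0:10,
                                            rel_acc = c(0, 1))) {
  if (n < 10) stop("codp_invalid_argument: n must be >= 10", call. = FALSE)
  for (r in ranges) {
    if (length(r) < 2) {
      stop("codp_invalid_argument: empty feature range", call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- data.frame(
    mapp_norm = stats::runif(n, ranges$mapp_norm[1], ranges$mapp_norm[2]),
    sift = stats::runif(n),
    pph2_humvar = stats::runif(n),
    delta_heavy = sample(ranges$delta_heavy, n, replace = TRUE),
    rel_acc = stats::runif(n, ranges$rel_acc[1], ranges$rel_acc[2])
  )
  q <- joint_score(x, model)
  x$q <- q
  x$label <- as.integer(stats::runif(n) < q)
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
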