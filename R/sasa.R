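# Shrake-Rupley solvent-accessible surface area.
#
# Each atom's van der Waals sphere is expanded by the probe radius (water,
# 1.4 A) and covered with a deterministic golden-section spiral of
# quasi-uniform test points; the accessible area is the full sphere area
# times the fraction of points that fall inside no other expanded sphere.
# The point scheme is fixed in the global frame: translations leave every
# ASA exactly invariant, rotations within sampling tolerance.

#' Default van der Waals radius table
#'
#' Element-based radii in Angstrom used to build the probe-expanded spheres.
#' The set is deliberately small and overridable; structures containing an
#' element absent from the table are rejected with an error naming the atom.
#'
#' @return Named numeric vector of radii (A).
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

# deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); no RNG involved
.sphere_points <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# neighbor lists via a uniform cell grid; returns integer vectors of indices j
# with dist(i, j) < radii[i] + radii[j]. Produces results identical to the
# quadratic all-pairs scan (tested), just faster on large structures.
.neighbor_list <- function(xyz, radii) {
  n <- nrow(xyz)
  cell <- 2 * max(radii)
  ix <- floor(xyz[, 1] / cell); iy <- floor(xyz[, 2] / cell)
  iz <- floor(xyz[, 3] / cell)
  key <- paste(ix, iy, iz)
  cells <- split(seq_len(n), key)
  coords <- unique(data.frame(ix, iy, iz, key, stringsAsFactors = FALSE))
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  out <- vector("list", n)
  for (c_i in seq_len(nrow(coords))) {
    nb_keys <- paste(coords$ix[c_i] + off$dx, coords$iy[c_i] + off$dy,
                     coords$iz[c_i] + off$dz)
    cand <- unlist(cells[intersect(nb_keys, names(cells))], use.names = FALSE)
    for (i in cells[[coords$key[c_i]]]) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      nb <- cand[d2 < (radii[cand] + radii[i])^2 & cand != i]
      out[[i]] <- nb
    }
  }
  out
}

# core engine over an atom table (x, y, z, element)
.asa_atoms <- function(atoms, probe_radius, n_sphere_points, vdw) {
  if (nrow(atoms) == 0L) return(numeric(0))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("codp_invalid_structure: non-finite coordinates", call. = FALSE)
  }
  r_vdw <- vdw[atoms$element]
  if (any(is.na(r_vdw))) {
    i <- which(is.na(r_vdw))[1L]
    stop("codp_unknown_element: no van der Waals radius for element '",
         atoms$element[i], "' (atom ", atoms$elety[i], " in residue ",
         atoms$resid[i], " ", atoms$chain[i], atoms$resno[i], ")",
         call. = FALSE)
  }
  radii <- unname(r_vdw) + probe_radius
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- .sphere_points(n_sphere_points)
  nb <- .neighbor_list(xyz, radii)
  asa <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    p <- pts * radii[i]
    p <- cbind(p[, 1] + xyz[i, 1], p[, 2] + xyz[i, 2], p[, 3] + xyz[i, 3])
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb[[i]]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= radii[j]^2
      if (!any(exposed)) break
    }
    asa[i] <- 4 * pi * radii[i]^2 * mean(exposed)
  }
  asa
}

.select_atoms <- function(structure, include_hetero, include_water) {
  a <- structure$atoms
  keep <- (!a$water | include_water) & (!a$hetero | include_hetero)
  a[keep, , drop = FALSE]
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param structure A [read_structure()] object.
#' @param probe_radius Probe (water) radius in Angstrom; default 1.4.
#' @param n_sphere_points Number of quasi-uniform test points per atom
#'   (default 960; must be at least 10). Larger counts converge towards the
#'   exact area.
#' @param vdw Named vector of element van der Waals radii (A);
#'   see [default_vdw_radii()].
#' @param include_hetero,include_water Include non-protein heteroatoms /
#'   waters as both targets and occluders (default: excluded).
#' @return The selected atom table with an added `asa` column (A^2).
#' @examples
#' s <- synthetic_structure("isolated")
#' sum(shrake_rupley(s)$asa)
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4,
                          n_sphere_points = 960,
                          vdw = default_vdw_radii(),
                          include_hetero = FALSE, include_water = FALSE) {
  stopifnot(inherits(structure, "codp_structure"))
  if (!is.numeric(probe_radius) || probe_radius <= 0) {
    stop("codp_invalid_argument: probe_radius must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_sphere_points) || n_sphere_points < 10) {
    stop("codp_invalid_argument: n_sphere_points must be >= 10",
         call. = FALSE)
  }
  a <- .select_atoms(structure, include_hetero, include_water)
  a$asa <- .asa_atoms(a, probe_radius, as.integer(n_sphere_points), vdw)
  a
}

.max_asa_cache <- new.env(parent = emptyenv())

#' Reference maximum ASA per residue type
#'
#' Packaged normalization constants: the ASA the engine itself assigns to
#' each isolated (fully exposed) residue template, so that an isolated
#' residue has relative accessibility exactly 1. A user-supplied table (named
#' by three-letter code) can be passed to the accessibility functions
#' instead.
#'
#' @param probe_radius,n_sphere_points Engine settings the constants are
#'   computed under (cached per setting).
#' @return Named numeric vector (three-letter residue codes) of ASA in A^2.
#' @export
max_asa_reference <- function(probe_radius = 1.4, n_sphere_points = 960) {
  key <- paste0("p", probe_radius, "_n", n_sphere_points)
  if (!is.null(.max_asa_cache[[key]])) return(.max_asa_cache[[key]])
  codes <- aa_property_table()$one_letter
  out <- vapply(codes, function(aa) {
    s <- synthetic_structure("isolated", aa = aa)
    sum(shrake_rupley(s, probe_radius = probe_radius,
                      n_sphere_points = n_sphere_points)$asa)
  }, numeric(1))
  names(out) <- aa_property_table()$three_letter
  .max_asa_cache[[key]] <- out
  out
}

#' Per-residue relative solvent accessibility
#'
#' Sums the per-atom ASA over each residue and divides by the reference
#' maximum for that residue type. Values above 1 are possible for terminal
#' or unusually extended residues.
#'
#' @inheritParams shrake_rupley
#' @param max_asa Named reference table (three-letter codes -> A^2); defaults
#'   to [max_asa_reference()] under the same engine settings.
#' @param burial_threshold Relative-accessibility threshold separating buried
#'   from surface residues (default 0.1).
#' @return Data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `asa_A2`, `rel_acc` (NA for residue types absent from
#'   `max_asa`), `burial`.
#' @export
residue_accessibility <- function(structure, probe_radius = 1.4,
                                  n_sphere_points = 960,
                                  vdw = default_vdw_radii(),
                                  max_asa = NULL,
                                  burial_threshold = 0.1,
                                  include_hetero = FALSE,
                                  include_water = FALSE) {
  a <- shrake_rupley(structure, probe_radius, n_sphere_points, vdw,
                     include_hetero, include_water)
  if (is.null(max_asa)) {
    max_asa <- max_asa_reference(probe_radius, n_sphere_points)
  }
  key <- paste(a$chain, a$resno, a$insert, a$resid, sep = "\r")
  idx <- !duplicated(key)
  res <- data.frame(
    chain = a$chain[idx], resno = a$resno[idx], insert = a$insert[idx],
    resname = a$resid[idx], stringsAsFactors = FALSE
  )
  res$asa_A2 <- as.numeric(tapply(a$asa, factor(key, levels = key[idx]), sum))
  res$rel_acc <- res$asa_A2 / unname(max_asa[res$resname])
  res$burial <- NA_character_
  ok <- !is.na(res$rel_acc)
  res$burial[ok] <- classify_burial(pmax(res$rel_acc[ok], 0),
                                    burial_threshold)
  res
}

#' Relative accessibility of one residue
#'
#' @inheritParams residue_accessibility
#' @param chain Chain identifier (explicit; no default).
#' @param residue_number Author residue number (1-based, as in the PDB file).
#' @return A single relative-accessibility ratio.
#' @details A residue absent from the structure (for example an unmodeled
#'   loop position) raises a condition of class `codp_missing_residue`
#'   carrying the position, so callers can substitute a user-supplied value.
#' @export
residue_relative_accessibility <- function(structure, chain, residue_number,
                                           ...) {
  res <- residue_accessibility(structure, ...)
  hit <- res$chain == chain & res$resno == residue_number
  if (!any(hit)) {
    cond <- structure(
      class = c("codp_missing_residue", "error", "condition"),
      list(message = paste0("codp_missing_residue: residue ", chain,
                            residue_number, " is not in the structure"),
           call = sys.call(-1), chain = chain, resno = residue_number)
    )
    stop(cond)
  }
  res$rel_acc[hit][1L]
}

#' Classify residues as buried or surface
#'
#' A residue is buried when its relative accessibility is strictly below the
#' threshold (default 0.1); the boundary value itself is surface.
#'
#' @param relative_accessibility Non-negative numeric vector.
#' @param threshold Burial threshold (default 0.1).
#' @return Character vector, `"buried"` or `"surface"`.
#' @examples
#' classify_burial(c(0.05, 0.1, 0.583))
#' @export
classify_burial <- function(relative_accessibility, threshold = 0.1) {
  if (any(!is.finite(relative_accessibility)) ||
      any(relative_accessibility < 0)) {
    stop("codp_invalid_argument: relative accessibility must be finite and ",
         ">= 0", call. = FALSE)
  }
  ifelse(relative_accessibility < threshold, "buried", "surface")
}
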