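# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and closed forms only.

# AUC as the fraction of concordant (pathogenic, benign) score pairs, ties
# counting one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon rank-sum p-value by complete enumeration of all
# choose(n1 + n2, n1) rank assignments (tie-free data): doubled one-sided
# tail of the U distribution, capped at 1.
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u_all <- colSums(matrix(sort(r)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  # ranks are 1..N so sort(r)[sets] == sets; kept explicit for clarity
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Youden-optimal threshold by exhaustive sweep over candidate midpoints,
# smallest threshold on ties.
brute_cutoff <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  best <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    j <- mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1
    if (j > best + 1e-12) {
      best <- j
      best_t <- t
    }
  }
  best_t
}

# Exposed area of each of two equal spheres of radius R at center distance d
# (overlapping caps removed): 4*pi*R^2 - 2*pi*R*h with cap height h = R - d/2.
two_sphere_cap_area <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Minimal PDB ATOM line.
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, element = substr(name, 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          "", resid, chain, resno, " ", x, y, z, occ, 0, element)
}

# Strip the "LLS-"/"ULS-" prefixes so engine criteria strings compare
# directly against the published definition column ("1,2" style).
criteria_numbers <- function(criteria_met) {
  gsub("(LLS|ULS)-", "", criteria_met)
}
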