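---
title: "CoDP methods: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoDP methods: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Missense variants in *MSH6*, one of the DNA mismatch-repair genes behind
Lynch syndrome, are mostly "unclassified variants" (UVs): single amino-acid
substitutions whose clinical significance is unknown. General-purpose
predictors (SIFT, PolyPhen-2) are not tuned to MSH6, and the protein-specific
MAPP score alone is not accurate enough for genetic counselling. CoDP
(Combination of Different Properties) addresses this by combining the three
sequence-based scores with two features read directly off the MSH6 protein
structure.

## The model

CoDP is a logistic regression over five predictors:

$$\mathrm{logit}(q) = \ln\frac{q}{1-q} = Z + \sum_{i=1}^{5} b_i X_i$$

| predictor ($X_i$) | meaning | range | coefficient ($b_i$) |
|---|---|---|---|
| `mapp_norm` | domain-normalized MAPP impact score | $\ge 0$, boundary at 1 | 0.1581 |
| `sift` | SIFT score (low = damaging) | $[0,1]$ | -1.2824 |
| `pph2_humvar` | PolyPhen-2 HumVar score | $[0,1]$ | 4.6733 |
| `delta_heavy` | side-chain heavy-atom change | integers 0..10 | 1.0475 |
| `rel_acc` | relative solvent accessibility | $\ge 0$ | -8.0548 |

with intercept $Z = -3.7273$. These packaged coefficients are the published
MSH6 model (`codp_model()`); `codp_fit()` re-estimates them on any labeled
feature table. The joint score $q$ is the modeled probability that the
variant is pathogenic. Calls use two cut-offs: $q \le 0.56$ non-pathogenic
(minor impact), $0.56 < q \le 0.65$ moderate impact, $q > 0.65$ impaired
function. PolyPhen-2 HumDiv is deliberately not a predictor (it was the
weakest component score); input tables may carry a `pph2_humdiv` column but
it is ignored by the default model.

The model's assumptions are those of any logistic score ensemble: the
component scores are treated as fixed, exchangeable covariates (their own
estimation error is not propagated), the log-odds are linear in each
predictor, and the training labels are taken as ground truth.

### Numerical conventions of the classifier

* `classify_impact()` accepts the closed interval $[0,1]$ although exact
  logistic output lies in the open interval: published score tables are
  rounded to three decimals and legitimately contain 0.000 and 1.000.
* Rounding also affects the 0.65 boundary: a true score slightly above 0.65
  prints as 0.650 yet classifies as "moderate" when the printed value is
  re-classified. The packaged UV table contains exactly one such score; the
  0.56 boundary is unaffected, so pathogenic/non-pathogenic counts are
  exact.
* Per-tool binarization (`binarize_scores()`): SIFT pathogenic at
  $\le 0.05$, PolyPhen-2 at $\ge 0.446$, CoDP at $> 0.56$, normalized MAPP
  at $> 1.0$. The two "boundary damaging" and two "boundary benign"
  conventions follow each tool's published usage; all are overridable.

## Domain-normalized MAPP scores

The raw MAPP impact score measures how strongly a substitution clashes with
the physicochemical variation observed in an orthologue alignment, so its
decision threshold depends on local conservation. For MSH6 the optimal raw
thresholds are 8.5 for the whole sequence, 4.1 in the PCNA-binding motif
(residues 4-11), 5.0 in the PWWP domain (89-194) and 4.1 in the MutS domain
(362-1355). `normalize_mapp()` divides the raw score by the threshold of
the covering domain, which makes 1.0 the boundary everywhere. Positions
outside all three regions use the whole-sequence 8.5 — it is the only
threshold defined for unannotated sequence. The map is plain JSON
(`msh6_domain_map()`, `read_domain_map()`), so other proteins can reuse the
machinery. Computing raw MAPP (or SIFT/PolyPhen-2) scores is out of scope:
they are consumed as inputs.

## Solvent accessibility

`shrake_rupley()` implements the point-sampling accessible-surface
algorithm: each atom's van der Waals sphere is inflated by the probe radius
(water, 1.4 Å) and covered with $n$ quasi-uniform test points; the
accessible area is $4\pi R^2$ times the fraction of points inside no other
inflated sphere.

Engine choices, each made where the method leaves freedom:

* **Point scheme.** A deterministic golden-section spiral, default
  $n = 960$ points, fixed in the global frame. No RNG is involved;
  translations leave every ASA *exactly* invariant, rotations move it only
  within sampling tolerance (both behaviors are tested). At 960 points the
  two-sphere test case agrees with the analytic spherical-cap area to
  better than 2%, and the error decreases as $n$ grows.
* **Radii.** A deliberately small element table (C 1.70, N 1.55, O 1.52,
  S 1.80, P 1.80, H 1.20 Å), overridable per call; an element without a
  radius is an error naming the atom, never a silent default.
* **Neighbor search.** A uniform cell grid that provably returns the same
  neighbor sets as the quadratic all-pairs scan (tested), just faster.
* **Reference maxima.** Relative accessibility divides a residue's summed
  atom ASA by a per-type maximum. The packaged reference
  (`max_asa_reference()`) is *self-computed*: the engine's own ASA of each
  isolated residue template, so an isolated residue scores exactly 1.0 and
  the normalization never imports constants computed under different radii
  or probe settings. A user table can be substituted. Values above 1 are
  possible for unusually extended conformations and are not clipped.
* **Heteroatoms and waters** are excluded from occlusion by default
  (flags include them), since a ligand- or DNA-buried residue is not
  "buried" in the folding sense the burial feature intends.
* **Missing residues.** Crystal structures lack disordered loops. The
  package does not model them; `residue_relative_accessibility()` raises a
  distinct `codp_missing_residue` condition carrying the position, and the
  pipeline accepts per-position accessibility overrides instead.
* **Burial.** A residue is buried when relative accessibility is strictly
  below 0.1; the boundary value itself is surface. The threshold is a
  convention — only one side of it is tested.

## The evidence rule engine

The reference labels come from clinical and molecular evidence, not from
prediction. A carrier is **LLS** ("likely Lynch syndrome", pathogenic) when
any of these fire:

1. abnormal functional assay AND (IHC loss of only MSH6 OR MSI-H);
2. IHC loss of only MSH6 AND MSI-H;
3. (IHC loss of only MSH6 OR supportive segregation) AND at least two of:
   qualifying family history, qualifying proband tumor features, allele
   absent from ≥ 100 healthy controls.

**ULS** ("unlikely Lynch syndrome", non-pathogenic) when any of these fire:

1. polymorphism (minor allele frequency ≥ 0.01);
2. normal functional assay AND (MSS OR normal MSH6 IHC);
3. MSS AND normal MSH6 IHC.

Conventions the engine commits to:

* Unknown evidence (nd / na / inconclusive) never fires a predicate —
  predicates are conjunctions over positively known values. A consequence
  worth stating: *adding* evidence can in principle flip the "only MSH6"
  IHC pattern (a newly abnormal MLH1 stain vetoes it); what can never
  happen is a criterion firing off unknowns.
* "IHC loss of only MSH6" requires abnormal MSH6 and no *positively*
  abnormal MLH1/MSH2; inconclusive results on the other proteins do not
  veto. This is the only reading consistent with the reference set, which
  labels carriers with inconclusive MSH2 stains as criterion-2 LLS.
* One abnormal assay among the five (MMR activity, MSH2 interaction,
  localization, ATP hydrolysis, mismatch recognition) makes the aggregate
  abnormal; all-normal (with any number unknown) makes it normal.
* A record firing criteria on both sides is labeled `conflict` and
  surfaced, never silently resolved; `conflict_as_uv = TRUE` forces such
  records back to UV for metric computations.
* Mixed MSI readings ("L/H") are encoded as the more severe observation.

The packaged 34-carrier table (`msh6_classified_variants()`) re-derives
every published label (15 LLS, 19 ULS) and per-carrier criteria list; each
row carries a provenance tag so the transcription is reviewable.

## Fitting and evaluation protocol

`codp_fit()` maximizes the binomial likelihood by Newton/IRLS iterations,
declaring convergence when the largest coefficient change falls below
1e-8 (cap: 100 iterations). Complete separation — fitted probabilities
pinned to 0/1 or diverging estimates — is an explicit error suggesting the
`ridge` option, a quadratic penalty on the slopes (never the intercept)
that makes tiny separable sets fittable; with 34-variant training sets
separation is a realistic failure mode, so it must be loud. Standard errors
come from the inverse observed information. The implementation is checked
against an independent IRLS (`glm`) in the tests, and recovers known
generating coefficients within 3 standard errors in seeded simulations.

`roc_auc()` uses the midrank Mann-Whitney identity, which equals the
trapezoidal ROC area and (divided by $n_1 n_2$) the U statistic of
`wilcoxon_rank_sum()` — an identity the tests assert to 1e-12.
`optimal_cutoff()` maximizes Youden's J over midpoints between adjacent
distinct scores (ties toward the smaller threshold); the
closest-to-corner rule is available because the published cut-off-selection
method is not stated. The rank-sum test is exact (complete enumeration;
doubled one-sided tail capped at 1) for tie-free pooled samples up to 20,
otherwise a tie- and continuity-corrected normal approximation; both modes
are forcible since the original analysis does not say which it used.

`jackknife_loo()` refits the regression with each variant held out and
predicts it at the 0.56 cut-off. Only the regression is left out: MAPP-like
component scores are alignment-derived and cannot be meaningfully excluded
from their own training sequence set, so they are treated as fixed inputs.

## Synthetic data: what it does and does not emulate

`simulate_variants()` draws the five predictors independently and uniformly
(`mapp_norm` on [0, 4], the two probability scores on [0, 1],
`delta_heavy` uniform on 0..10, `rel_acc` on [0, 1]) and samples labels
from the Bernoulli law of a given model. This emulates the *shape* of the
prediction problem — mixed discrete/continuous features, class overlap
controlled by the coefficients — and supports exact self-consistency
checks (parameter recovery, jackknife behavior, prevalence). It does not
emulate real MSH6 data: real component scores are strongly correlated
(conserved positions score high on all three), `rel_acc` is bimodal rather
than uniform, and real labels carry curation noise. Passing the simulation
tests therefore demonstrates correctness of the machinery, not clinical
accuracy on new variants.

`synthetic_structure()` emits format-valid PDB text for an isolated
residue, an idealized poly-alanine helix (1.5 Å rise, 100° twist, radius
2.3 Å) and a fully caged residue. Side chains are stylized — correct atom
counts and elements laid out as an extended zig-zag, not real
stereochemistry — which is exactly sufficient for the occlusion, burial
and self-normalization properties the accessibility engine is tested on.

## Problem sizes

The shipped tests run the accessibility engine at 240-3840 sphere points
on structures up to ~100 atoms, parameter recovery at n = 500-8000 with
20 replicates at n = 2000, the jackknife at n = 200, and exhaustive
rank-sum enumeration for all layouts with pooled n ≤ 10 — sizes chosen so
the full suite completes in well under a minute while every oracle
comparison stays exact.

## Known limitations

* The published per-variant component scores for the 34 reference carriers
  are not available, so the packaged coefficients cannot be re-derived
  bit-exactly from shipped data; refitting is validated by simulation
  instead, and the published AUC (0.954), rank-sum p-value and jackknife
  accuracy (85.3%) are likewise not reproducible from shipped inputs.
* Reproducing the published mean accessibilities of the pathogenic and
  benign variant positions (0.141 / 0.589) requires the loop-completed
  MSH6/MSH2 crystal structure, an unstated radius set and an unstated
  reference normalization; with a user-downloaded structure the package's
  engine approximates but will not exactly match them.
* The rule engine encodes one published reference table emendation and a
  few OCR-style decodings, each documented in the fixture's comment header
  and provenance column.
* CoDP is MSH6-specific by construction; only the domain map and model
  coefficients are pluggable.
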