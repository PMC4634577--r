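---
title: "Catalytic-site pose comparison: models, choices, and limits"
author: "CatPose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic-site pose comparison: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CatPose)
```

## The question

An enzyme's catalytic site — the handful of residues directly engaged in
catalysis — commonly determines a single biochemical reaction. If two
enzymes arrange chemically similar residues in a geometrically similar 3D
pose, can we transfer the function (the EC number, or a GO term set) from
one to the other? CatPose implements the full assessment: curating a
reliable site set, superposing site pairs under several residue
representations, scoring pose similarity with size-normalized RMSD,
measuring function agreement via EC classes or GO term-set similarity, and
optimizing classification cutoffs by maximizing the Matthews correlation
coefficient (MCC). A companion census counts, per enzymatic function, how
many SCOP superfamilies realize it — the non-homologous isofunctional
enzymes (NISE) for which pose comparison is the only structural route to
annotation transfer.

## Site model and curation

A `CatalyticSite` holds 2–10 residues with heavy-atom coordinates plus EC,
SCOP-superfamily and GO labels. Sites are read from PDB coordinates (first
model only; hydrogens dropped; among alternate locations the
highest-occupancy one is kept, ties resolved toward altloc `A` for
determinism) and a CSA-style residue table. Residue identity is keyed by
chain and author residue number with the insertion code kept as part of the
label, because curated site tables use author numbering.

`curateSites()` applies a fixed exclusion cascade: single-residue sites
(their superposition is trivially perfect and thus uninformative),
non-canonical residues, sites spanning several chains, sites without a full
4-field EC number, multifunctional sites (more than one full EC), sites
without a SCOP superfamily, and sites flagged inconsistent between table
and coordinates. Each excluded site is logged under the *first* filter it
violates; published per-reason counts for this kind of cascade are disjoint,
and the listing order is the only ordering evidence available, so
first-match precedence in that order is used. Partial EC strings (fewer
than four fields) never count as functions: a site with only `"1.1.1"` is
excluded as lacking an EC, and multifunctionality is judged on distinct
full ECs only. The multi-chain test looks at the residues of the site, not
the whole structure, since only the site's own geometry matters here.

## Representations and superposition

Each residue contributes an ordered point list under one of four
representations: `CA` (the C-alpha), `CA_CB`, `CA_CENTROID` (C-alpha plus
the unweighted centroid of side-chain heavy atoms) and `ALL_ATOM` (all
heavy atoms, including the backbone, in canonical PDB atom-name order).
Glycine contributes only its C-alpha outside `ALL_ATOM` — it has no side
chain. Hydrogens are never used: they are absent from most crystal
structures, and heavy-atom matching is the standard choice.

`enumerateMatches(A, B, ...)` enumerates **every** injective,
type-compatible residue correspondence of at least `minSize = 2` residues
(the smallest size for which the normalized scores are defined) and
superposes the concatenated represented points of each mapping with the
Kabsch algorithm (`superposePoints()`): SVD of the cross-covariance matrix
with a determinant correction so that a reflection is never returned. Atom
points are paired by name; when an equivalence rule pairs two different
residue types (presets `YF_IL` and `YF_IV` are both provided, because
published descriptions of the aliphatic pair differ), atoms are paired on
the intersection of the two types' atom names. Chemically
indistinguishable labelings — carboxylate oxygens of Asp/Glu, guanidinium
nitrogens of Arg, and the aromatic ring flip of Phe/Tyr (which swaps the
CD and CE pairs *jointly*) — are tried exhaustively per mapping and the
lowest RMSD kept, so arbitrary atom naming cannot inflate a score.

Exhaustiveness is preserved under pruning: if a mapping of `N` represented
points superposes with RMSD ≤ `c`, then any two mapped C-alpha deviations
`d1, d2` satisfy `d1² + d2² ≤ N·c²`, so the C-alpha distance mismatch of
any two residue pairs is at most `c·sqrt(2N)`. Pairs violating that bound
are never co-mapped, which discards only mappings that provably exceed the
cutoff (the brute-force equivalence tests exercise exactly this claim). A
hard budget of 10⁶ candidate mappings per site pair turns pathological
inputs into an explicit error rather than an open-ended computation. The
enumeration core is compiled (C++ via Rcpp/RcppArmadillo), as is usual for
structural-bioinformatics hot paths.

## Scores

Raw RMSD ignores how much of a site was matched; two normalizations reward
larger matches: `rmsdN1 = RMSD/(|ms|−1)` and
`rmsdN2 = RMSD/max(1, 3|ms|−6)`, where `|ms|` is the number of matched
residues. The second decreases faster with match size and is the default
ranking score. Matches are ranked by exact floating-point score; scores
within 1e−9 are treated as tied and resolved toward the larger match, then
lexicographically on the mapping — without this numerical tie tolerance,
sub-mappings of a perfect match (all scores within floating noise of zero)
could shadow the full match. Additional literature scores whose formulas
are not reproduced here can be attached through `registerScore()` as
plug-ins; they are deliberately interface slots, not implementations.

## GO term-set similarity

Function agreement beyond the six EC classes uses a normalized similarity
`S_GO ∈ [0, 1]` between two enzymes' GO term sets. The similarity is
topology-only (independent of term frequencies in any corpus): a
Wang-style measure in which each term's ancestor DAG carries semantic
contributions decaying by 0.8 per `is_a` and 0.6 per `part_of` edge, term
pairs are scored by their shared ancestors' contributions, and term *sets*
aggregate by best-match averaging. Per selected annotation domain (CC, BP,
MF) where both enzymes have terms, a domain score is computed; `S_GO`
averages the per-domain scores. This per-namespace averaging is a design
choice — the aggregation across namespaces used in the literature source
is not specified — and is flagged as such. Pairs with no shared annotated
domain have undefined `S_GO` and are excluded from confusion counting,
mirroring how GO-based analyses cover only the annotated subset of a site
collection.

## Classification protocols and the grid search

All-vs-all comparison yields, per query site, the most similar other site
(`bestHits()`); in `DIFF_SF` mode candidates from the query's own SCOP
superfamily are excluded, so that only likely non-homologs are compared,
while `ALL` mode admits homologs too. Two protocols turn best hits into
counts:

* **Cutoff-free:** the best hit's EC class is transferred; TP when the
  first EC digits agree, FN otherwise. Because published sensitivities of
  this protocol leave the query denominator ambiguous,
  `evaluateBestHits()` reports both defensible denominators (queries with
  a valid hit, and all queries submitted) side by side.
* **Thresholded:** a prediction is positive when the pose score is below
  `cu_RMSD`; positives are TP/FP and non-positives FN/TN according to
  function agreement (EC class equality, or `S_GO ≥ cu_S_GO`).

`gridSearch()` maximizes the MCC over a cutoff grid, by default 0.01–1.50
in 0.01 steps for the pose score and 0.50–1.00 in 0.01 steps for
`cu_S_GO` — spanning every published cutoff of interest (0.21–1.10 and
0.70–0.90); the grid resolution itself is a package choice since none is
published. Ties break toward the smaller pose cutoff, then the larger
`S_GO` cutoff. MCC uses the convention that any zero factor in the
denominator yields 0. Queries without any comparable candidate are
excluded from the counts rather than counted as FN — consistent with
published totals in which per-analysis exclusions shrink the classified
set. Reported values are rounded half-up to two decimals, matching printed
precision; `best-of-k` selection (among the `k` lowest-score hits, take
the highest `S_GO`) reproduces the published protocol variant.

## The synthetic generator: what it emulates, and what it does not

`makeSites()` generates families of isofunctional sites: per family a
template site (residue types drawn from the 11 polar/charged residues that
dominate catalytic sites; C-alpha geometry with 3–12 Å inter-residue
distances; full heavy-atom side chains from idealized internal
coordinates — standard bond lengths and angles, analytic ring closure, no
rotamer library) and members that are rigid motions of the template with
i.i.d. Gaussian noise of `poseNoise` (σ, Å) on every coordinate, plus
optional Y→F / I→V substitutions. Defaults are the package's reference
study conditions, chosen once: 10 families × 5 sites; residue counts 2–6
with geometrically decaying weights (mean ≈ 3.3, ~40 % at the minimum of
2 — mirroring curated collections where the mean is 3.4 and ~30 % of sites
have two residues); σ = 0.1 Å; half of the functions planted in **two**
superfamilies that share the template pose. That last choice encodes the
NISE premise — the same function realized on non-homologous folds with a
conserved catalytic pose — and is what makes the DIFF_SF protocol
informative on synthetic data: multi-superfamily functions supply
recoverable positives (a non-homologous site with the same pose and
function exists), single-superfamily functions supply negatives (their
best non-homolog hit has a different function). Under `ALL` mode with
every family fully present, each query's best hit is trivially a family
sibling: every classified case is positive, the confusion table
degenerates, and the MCC is 0 by the zero-denominator convention — so
end-to-end recovery is validated in `DIFF_SF` mode.

Note on noise scale: with i.i.d. per-coordinate noise σ on *both* compared
members, the expected fitted RMSD is approximately `sqrt(6)·σ` (minus a
small fitted-transform correction), e.g. ≈ 0.22 Å at σ = 0.1. The test
suite checks the realized within-family RMSD against a Monte-Carlo
estimate computed with an independent fitting routine.

The generator does **not** emulate: physically realistic backbones or
rotamers, missing atoms and crystallographic disorder, annotation errors,
or the literature-curation process behind real site tables. Passing the
synthetic recovery tests therefore demonstrates correctness of the
pipeline's machinery under its own assumptions, not performance on real
structures — on real data the published finding is precisely that pose
comparison is a weak classifier.

`makeOntology()` builds three rooted DAGs (30 terms per namespace by
default, `is_a` with probability 0.8, else `part_of`) plus dedicated
per-function MF/BP leaf terms, so same-function enzymes share MF/BP
annotations and different functions never do; CC terms are drawn per
enzyme independently of function, so including CC must degrade GO-based
classification — a structural mirror of the published observation.
`makeCensusTable()` plants a known one-superfamily fraction (default 0.89,
the published value for substrate-specific functions) recoverable by the
census within binomial error.

## Numerical choices and degenerate inputs

* Kabsch superposition handles collinear/coincident points (rank-deficient
  SVD) and always returns a proper rotation.
* Matches need ≥ 2 residues; `rmsdN1`/`rmsdN2` are domain-errors below
  that.
* Score ties: 1e−9 tolerance, then larger match, then lexicographic
  mapping.
* Curation of an empty collection returns empty output without error;
  statistics of an empty collection are an explicit error.
* Altloc occupancy ties resolve toward `A`; atom order of a structure file
  is preserved.
* Problem sizes used in the validation suite: brute-force equivalence on
  200 random pairs of 2–4 residue sites; noise degradation over
  σ ∈ {0.1, 0.5, 1.0, 2.0} Å with 20 seeds per level at the reference
  study conditions; census recovery at 500 functions.

## Known limitations

* The exact term-set similarity of the literature method is not published;
  the Wang-style measure here satisfies its two stated properties
  (normalized to [0, 1]; corpus-independent) but is not guaranteed to be
  numerically identical.
* Whether the all-atom mode of the original comparison program includes
  backbone atoms is not published; this package includes them.
* No mmCIF input, no NMR multi-model handling, no metals/cofactors/waters
  in the site definition.
* Cutoffs are optimized on the full comparison set (no cross-validation),
  replicating the published protocol as-is; the resulting MCC is an upper
  bound on generalizing performance.
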