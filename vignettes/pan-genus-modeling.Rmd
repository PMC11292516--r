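---
title: "Species-aware pan-genus metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-aware pan-genus metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenus)
```

This vignette is the package's account of the science it implements: the
pan-genus model formulation, the community assembly conventions, the
evaluation metrics, and — importantly — the choices we made where the
design was genuinely open, with the reasoning behind each.

## Why pan-genus models

Amplicon (16S rRNA) profiling resolves a large share of taxa only to the
genus. Community-scale constraint-based modeling, however, is built
around species-level genome-scale metabolic models (GSMMs). A pan-genus
metabolic model (PGMM) fills the gap: one model carrying the union of
all reactions found in the genus's species, with enough bookkeeping to
be narrowed to any species composition after the fact. It is therefore
both a genus-level model (uniform composition) and a compressed archive
of all its species models (indicator compositions).

## Reconstruction

Given species GSMMs that share one reaction namespace and a biomass
database (per species: biomass reaction, biomass metabolite, drain):

1. **Union.** Every non-biomass reaction enters the merged model once.
   A reaction appearing in several species must have identical
   stoichiometry — differing stoichiometry under one id means the models
   do not share an annotation source, and is an error rather than a
   guess. Species membership is recorded in a binary presence matrix
   `P` (reactions × species).
2. **Merged bounds.** A shared reaction gets the widest bounds seen
   across species (minimum lower, maximum upper). The alternative —
   intersecting bounds — could starve species whose own model is more
   permissive; widest-bounds is the common pan-model practice and errs
   toward capability rather than restriction.
3. **panBiomass.** Each species' biomass reaction is added, producing a
   species biomass metabolite `bio_i`. One panBiomass reaction consumes
   each `bio_i` with stoichiometric coefficient `s_i` (the species
   probability vector, default `1/n`) and produces a drained panBiomass
   metabolite; panBiomass is the objective. Because `bio_i` has no other
   consumer (the species' own drain is excluded along with the biomass
   reaction), steady state forces `v_bio,i = s_i · v_panBiomass`: the
   composition is enforced through stoichiometry. The linear-combination
   equation `v_pan = Σ s_i v_bio,i` also admits a weighted-objective
   reading in which species grow in any proportions and only the
   objective is weighted; we implement the fixed-proportion reading,
   which matches how community biomass equations are written in
   community modeling, and which makes the indicator-vector extraction
   exact. The weighted-objective variant can be emulated by giving each
   `bio_i` its own drain; we did not expose it as an option because no
   analysis here needs it.
4. **Pruning.** Exact duplicate reactions (identical stoichiometry, or
   sign-flipped with correspondingly flipped bounds) collapse to one
   survivor with OR-merged presence and union bounds. We deliberately do
   not scale-normalize (2A→2B is not collapsed onto A→B): scaled
   duplicates change flux units and are rare under a single annotation
   source. Futile-cycle candidates are found as reactions with nonzero
   FVA range when every uptake is closed — any flux possible without
   imports must sit on an internal cycle. Candidates are removed
   greedily (descending closed-medium range, ties broken by reaction id
   for determinism); a removal is rolled back if the biomass optimum on
   the reference medium moves by more than a relative `growth_tol`
   (`1e-6`). This keeps the procedure conservative: a loop reaction that
   also carries essential flux survives.
5. **Growth check.** The finished PGMM must grow on the reference
   medium; the optimum is attached to the object.

## Customization

`apply_species_probabilities(pgmm, p)` silences every reaction whose
presence-weighted probability `(P p)_r` is zero — both bounds set to 0,
activation is a strict `> 0` with no epsilon flooring — restores merged
bounds for active reactions, and rewrites the panBiomass coefficients to
`p`. Reactions are silenced, never deleted, so the operation is fully
reversible and idempotent; re-applying a permissive vector restores the
as-built model (verified field-by-field in the tests). Extraction of a
single species is customization with the indicator vector; on fixture
genera it reproduces the source GSMM's biomass optimum and exchange FVA
to solver precision, because shared reactions carry identical bounds
there. On real collections, bound widening (step 2) can make extraction
slightly more permissive than the source model — that is a property of
merging, not a bug in extraction.

## Community assembly

Members are compartmentalized: all ids prefixed with the member tag,
each member exchange replaced by a transport between the member's
extracellular metabolite and an unprefixed shared lumen metabolite
(`[u]`). Transports carry bounds (−1000, 1000) — the convention used by
microbiome pipeline toolchains — so nutrient access is governed in one
place, the lumen exchanges, where the diet is applied (uptakes of
unlisted exchanges closed by default, the mgPipe-style convention; a
flag keeps them open instead). Diet tables address
single-organism exchange ids (`EX_glc(e)`); community assembly retargets
them to the lumen (`EX_glc(u)`). The community biomass reaction consumes
each member's biomass metabolite with its relative abundance as
coefficient. Personalization to a new sample rewrites only these
coefficients and silences zero-abundance members — the compartmentalized
structure is reused across samples.

Four member routings: `gsmm` (species GSMMs), `pgmm` (genus PGMMs,
customized with uniform or user-prior within-genus probabilities),
`lumped` (single-biomass genus models whose coefficients are averaged
across species), `hybrid` (species taxa → GSMMs, genus taxa → PGMMs).
For lumped averaging the convention is ambiguous ("averaging the
coefficients" does not say over which denominator): we default to
present-only means (only species containing a metabolite contribute) and
provide zero-filled means as a mode. Present-only is the stricter
reading — it never dilutes a requirement below any individual species's
coefficient — and the two modes are both exercised in the tests.
Member-flux coupling constraints (flux ≤ c·biomass) are not applied;
they belong to a particular community toolchain rather than to the
model structure itself.

## Evaluation metrics

All comparisons run on FVA maxima of exchange reactions at
`fraction_of_optimum = 0.9999`. Exactly 1.0 pins the solution to a
possibly degenerate optimal face and makes results solver-sensitive;
0.9999 is the near-optimal convention of the field's FVA tooling. The
metrics: net exchange flux (max + min: secretion plus uptake potential);
Jaccard distance on active sets (`|flux| > 1e-6`); Euclidean distance
divided by a batch-level normalization constant; and the fraction of
exchanges whose relative difference `|a−b| / max(|a|,|b|, 1e-9)` exceeds
10 %, with indices inactive on both sides excluded.

The flux-bandwidth landscape draws `n_combinations` species probability
vectors (uniform(0,1) per species, normalized; seeded), customizes,
applies the diet, and aggregates each exchange metabolite's average
maximum flux and flux range (highest minus lowest maximum). The range is
expressed in percent; the category thresholds are percentages, which
need a denominator, so we normalize by the highest maximum flux
magnitude (floored at 1e-9): `range_pct = 100·range / max|hi|`.
Categories: no production (average and range both zero), tightly
regulated (≤ 5 %), high variability (> 50 %), and low variability in
between. The conventional band limits (5–25 % low, > 50 % high) leave
(25 %, 50 %] unassigned; we assign it to low variability so the four
categories are exhaustive, and expose the 25 % upper limit as an
argument (which labels the gap `NA`).
Similarity trees are UPGMA (average-linkage `hclust`, exported as Newick
via `ape`) over binary presence features (Jaccard) or categorical
bandwidth profiles (Hamming).

Linear programs are solved serially with GLPK; distributed FBA layers
with commercial solvers change throughput, not mathematics, and are
unnecessary at these problem sizes.

## The synthetic fixtures

`make_toy_genus()` emulates the structure of a curated single-source
model collection without its biology: one shared carbon source cleaved
into C3 precursor units flowing down an irreversible core chain present
in every species; an alternative-nutrient module and reversible
precursor interconversions present in seeded random subsets (making the
presence matrix nontrivial and creating removable redundancy); one
private secreted metabolite per species (giving known nonzero Jaccard
distances between species); and per-species biomass reactions drawing
2–4 precursors with integer coefficients 1–3, adjusted if a draw makes
all species identical, so species-aware and lumped biomass formulations
cannot coincide. Everything is elementally balanced by construction
(carbon-only formulas, biomass metabolites carrying the summed
carbon), every species grows on the emitted diet, and the ground-truth
presence matrix is returned for exact union checks.

What the toys do not emulate: realistic network size (tens of reactions
versus thousands), gene rules, alternative optima landscapes, cofactor
and energy metabolism, or annotation noise. Passing tests therefore
demonstrate algorithmic correctness — exact union recovery, exact
extraction fidelity, exact metric arithmetic — not predictive accuracy
on real reconstructions, where merged bounds and annotation conflicts
make extraction only approximate.

Because the default toys are carbon-limited, every unit of carbon is
consumed by biomass at near-optimal FVA, which flattens secretion
bandwidths. Bandwidth behavior is therefore exercised on a dedicated
two-species construction (in the test helpers) with a growth-limiting
vitamin: the optimum is pinned by the vitamin, metabolite M is a biomass
byproduct of species 1 only (its maximum production equals `s₁` at the
optimum — compositionally driven by construction), and metabolite W is a
byproduct of both species (compositionally flat). This gives analytical
expectations for the bandwidth categories.

Synthetic abundance tables draw exactly `k` taxa per sample with
uniform(0,1) weights normalized to 1; genus masking re-tags a seeded
random fraction of species taxa and sums them per genus (row sums
conserved); rare-taxon filtering zeroes entries below 1e-3 and
renormalizes, erroring (with the sample named) if a sample loses all
taxa.

## Numerical choices and problem sizes

* Zero-flux / activity tolerance: 1e-6 absolute everywhere a flux is
  binarized; growth tolerance 1e-6 relative; probability vectors are
  normalized and checked to sum to 1 within 1e-9.
* Degenerate inputs error early: empty models, all-zero weight vectors,
  infeasible bound pairs (lb > ub), samples emptied by filtering.
* Determinism: every stochastic operation takes an explicit seed;
  GLPK's simplex is deterministic, so whole pipelines are reproducible
  byte-for-byte.
* The test and acceptance workloads use genera of 2–10 species
  (~12–35 reactions per model), 120 sampled compositions for the
  bandwidth landscape and 34 × k=10 abundance tables — sizes chosen so
  the full pipeline, including every LP, runs in well under a minute
  per analysis on one core while still exercising every code path at
  realistic sample counts for an amplicon cohort analysis.

## Known limitations

* SBML is the only on-disk model format (no MAT-file ingestion); the
  FBC subset written is what COBRA-family tools read, verified against
  COBRApy in the test suite.
* Merged widest bounds mean extraction from a PGMM of heterogeneous
  models is an upper envelope of the species model, not an exact copy.
* Duplicate detection is exact/sign-flip only; scaled duplicates
  survive.
* The futile-cycle criterion (nonzero range under closed uptakes) flags
  all members of a cycle; the greedy growth-guarded removal keeps the
  model growing but the surviving subset depends on the deterministic
  removal order.
* Communities share one lumen without separate diet/fecal faces;
  host compartments and member-biomass coupling constraints are out of
  scope.
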