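---
title: "Reconstructing the ancestral apoptosis machinery: methods and design"
author: "apoRecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the ancestral apoptosis machinery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoRecon)
```

# The question and the inference model

Apoptotic cell death is executed by a small set of protein families —
DNases (ENDOG, ZEN1, NUC1), cysteine proteases (caspases and
metacaspases), OMI/HTRA serine proteases, AIF oxidoreductases, and their
inhibitors (BIR/survivin, API5/AAC11). The machineries of animals, plants,
fungi and unicellular eukaryotes are built from homologous parts, which
raises a reconstruction problem: which of these families were already
present in the last eukaryotic common ancestor (LECA), and which of those
descend from the eubacterial endosymbiont that became the mitochondrion
(the protomitochondrion)?

`apoRecon` frames this as phylogenetic profiling plus tree interrogation:

1. **Profiles.** Family membership is collapsed to a boolean
   families-by-lineage-groups matrix over the five ancient eukaryotic
   supergroups (Opisthokonta, Amoebozoa, SAR, Excavata, Archaeplastida)
   plus Eubacteria, Archaea and Virus (`collapseToGroups()`).
2. **Ancestral rule.** A family is called ancestral iff it is present in
   at least *k* supergroups (default *k* = 2) or in a prokaryotic domain
   (`ancestralByRule()`). Viral presence alone never triggers the rule:
   viral homologs of apoptotic factors are best explained as host-derived
   acquisitions, not vertical inheritance from LECA.
3. **Dollo parsimony.** Independently of the rule, `dolloReconstruct()`
   places a single gain at the MRCA of the present leaves on a rooted
   supergroup tree and charges one loss per maximal absent subtree. Dollo
   (gain-once, lose-freely) rather than Fitch parsimony is used because
   the families here are large multidomain proteins whose convergent
   regain is not a plausible event at this timescale.
4. **Origin.** For families with a gene tree, `classifyFamilyOrigin()`
   asks whether the minimal clade holding the eukaryotic members, or its
   sister group, contains eubacterial but not archaeal sequences
   (eubacterial origin — the endosymbiotic signature), the converse
   (archaeal), neither (eukaryote-only) or both (ambiguous).
5. **Pre-eukaryotic divergence.** For paralog pairs (e.g. fungal-type vs
   animal-type OMI/HTRA), `predatesEukaryogenesis()` returns `TRUE` when
   each paralog clade is closer to its nearest eubacterial sequence than
   to the other clade *and* the two clades do not form a bipartition
   excluding all eubacteria. "Closer" defaults to mean patristic distance
   over the clade, which is robust to a single long terminal branch;
   nearest-leaf distance is available via `method = "nearest"` since the
   choice between the two is a genuinely open modelling decision.

## The rule threshold *k*

"Several supergroups" is operationalised as *k* = 2: every family claimed
ancestral in the worked examples is documented in at least two
supergroups, and *k* = 2 is the weakest reading that excludes
single-lineage innovations. It is exposed as a parameter because *k* = 3
is a defensible stricter reading; on the bundled matrices *k* = 3 changes
no AIF or DNase call (every one of those families is present in at least
three groups or in Eubacteria).

On a star supergroup tree with no prokaryotic evidence, the *k* = 2 rule
and the Dollo root state coincide exactly (both fire iff at least two
leaves are present); the test suite proves this over all 32 profiles.
This equivalence is the design argument for the default: the rule is a
closed form of Dollo parsimony at the root.

## The supergroup tree

The resolved branching order of the supergroups remains contested, so the
default tree is the five-leaf star rooted at LECA: it is agnostic about
inter-supergroup relationships and makes the Dollo reconstruction depend
only on how many groups carry the family. Any user-supplied rooted Newick
over the same leaf set is accepted, and `dolloReconstruct()` then counts
losses on that topology.

# Gene trees

Trees are inferred by neighbor joining on Poisson-corrected p-distances:

* `pDistanceMatrix()` uses pairwise deletion of gap columns; a pair with
  zero comparable columns is an error (not a silent `NaN`).
* `poissonDistance()` applies −ln(1 − p); saturated pairs (p ≥ 1) are
  clamped to 10 substitutions/site with a warning, keeping matrices
  finite while flagging saturation.
* `neighborJoining()` implements Saitou–Nei agglomeration with two
  documented determinism choices: ties in the Q criterion are broken by
  the first minimal pair in row-scan order, and negative branch-length
  estimates are clamped to zero with the deficit moved to the sister
  branch so the joined pair's summed length — and hence downstream
  patristic distances — is preserved.
* `bootstrapSupport()` resamples alignment columns with replacement,
  rebuilds the tree per replicate through the same pipeline, and
  annotates each internal edge of the reference tree with the percentage
  of replicates containing the same bipartition. A single seed governs
  all resampling; replicates with undefined distances are skipped,
  counted and reported.

Neighbor joining is the only tree method implemented: it is fully
specified, deterministic, provably consistent on additive matrices (the
suite verifies exact recovery of topology and branch lengths on random
10–12-taxon additive matrices), and sufficient to drive every downstream
inference. Maximum-likelihood and minimum-evolution estimation are out of
scope, which means printed support *ranges* from multi-method analyses
can only be compared qualitatively with the single NJ support values
produced here.

Rooting for origin calls uses archaeal leaves as the outgroup whenever
the tree contains them (archaea are the outside reference for the
eukaryote/eubacteria question); if the archaeal leaves are not
monophyletic in an estimated tree the first archaeal leaf roots the tree
so the call is always defined. Without archaea, midpoint rooting is used.

## Chronology

Relative dating of splits is deliberately simple: `chronology()` orders
internal nodes by node height (mean path length from the node to its
descendant leaves), oldest first, with preorder tie-breaking.
Rate-normalising relative-time methods belong to dedicated dating
software; node-height ordering is the part of such output the downstream
claims actually consume ("which split came first"). On clock-like trees
the root split is always the first event and the ordering is invariant
under rescaling all branch lengths; on strongly rate-heterogeneous trees
the mean-height ordering can place a deep, long-branched subtree above
the root, which is the known limitation of this stand-in.

# Alignment curation

Profile alignments arrive with HMM-style column states: lowercase
residues and `.` mark insertions, and runs of insert columns touching
either end are the N/C flanking states. Curation is:

1. `stripNonmatchColumns()` — keep match columns only;
2. `findNovel()` — a candidate joins the family iff its best identity to
   the database is below 90% *and* it covers at least 50% of itself
   against that best hit;
3. `mergeIntoProfile()` — accepted candidates are aligned to the master's
   position-specific profile; residues not assignable to match columns
   are dropped as insertions so the master's column count never changes;
4. `stripGappedColumns()` — finally every column with at least one gap is
   removed, leaving the gap-free match alignment the distance pipeline
   consumes.

Identity and coverage are computed from an exact global alignment
(match +1, mismatch 0, linear gap −1) rather than a heuristic database
search: at curated-family scale exactness is affordable and
determinism matters more than speed. The identity denominator is the set
of columns where both sequences place residues, matching the percent
identity a local-alignment search reports over its aligned region.
Coverage is defined on the *query* (candidate) side — whether the
threshold applies to query or hit is underdetermined, so the query side
was chosen (a fragment should not enter a family by covering 50% of a
short hit) and is configurable. The merge profile uses per-column
frequencies with a 1/20 pseudocount and log-odds scores against a
uniform background, with affine gaps (open −2, extend −1) and
diagonal-preferring traceback — the minimal position-specific scoring
model consistent with match-column semantics.

# The synthetic-data generators

Three generators provide ground truth for every stage:

* `simulateGeneContent()` evolves a Dollo character down a rooted tree:
  present at the root (configurable), lost with a fixed per-edge
  probability, never regained.
* `simulateAlignment()` evolves sites independently under the 20-state
  uniform-exchange analogue of Jukes–Cantor. This model is chosen
  precisely because it has closed forms — the expected p-distance over a
  path of length *d* is (19/20)(1 − e^(−20d/19)) — so statistical tests
  can compare observation with expectation exactly instead of against an
  empirical rate matrix.
* `simulateEndosymbiosis()` builds gene trees with the endosymbiotic
  signature baked in: eukaryotic tips (one per supergroup) nested inside
  a eubacterial caterpillar, optionally two paralog clades with distinct
  eubacterial sisters (a divergence predating eukaryogenesis), and an
  optional two-tip archaeal outgroup. Backbone branch lengths are drawn
  from U(0.1, 0.3) and within-eukaryote lengths from U(0.05, 0.15):
  moderate protein divergence, far from saturation, the regime in which
  curated single-domain family alignments are typically analysed.

What the generators deliberately do **not** emulate: insertions and
deletions, among-site rate heterogeneity, compositional bias, alignment
error, incomplete taxon sampling and horizontal transfer beyond the
single endosymbiotic pattern. Passing recovery tests therefore shows the
inference chain is correct and well-calibrated under its own model
assumptions — not that real proteome-scale data will be this clean.

## Recovery properties and problem sizes

The suite and the acceptance script verify, among others:

* Dollo reconstruction equals exhaustive single-gain/loss-subset
  enumeration over **all** presence rows of a fixture set of rooted trees
  with up to 8 leaves (384–768 rows depending on the set);
* root-state recovery on the supergroup star at per-edge loss probability
  0.1 over 10,000 replicates (threshold 95%; the binomial expectation is
  ~99.95%, since recovery fails only when fewer than two lineages retain
  the gene);
* end-to-end origin and predates recovery — scenario, 2,000-column
  alignment, NJ, classification — over 200 seeded replicates each
  (threshold 90%).

The 95%/90% thresholds are frozen repository constants from an initial
calibration; they are not tuned per run. These problem sizes (10,000
star replicates, 200 sequence-level replicates, 2,000 columns) keep the
whole suite in the tens of seconds on a single core while leaving the
recovery estimates with negligible Monte-Carlo error.

# Bundled presence matrices

`apoptosisPresence()` ships the phylogenetic profile of 13 families
(3 DNases, 4 proteases, 4 AIF lineages, 2 inhibitors) over the eight
lineage groups, with per-cell organism evidence in
`apoptosisEvidence()`. Transcription is conservative: a cell is 1 only
where a named organism or an explicit lineage statement backs it. Two
judgment calls are worth knowing about: the caspase and metacaspase rows
omit Eubacteria (the peptidase domain occurs in bacteria but the
family-level branches are attested only for eukaryotes and viruses), and
the API5 row records Opisthokonta and Archaeplastida as the two named
anchors of its multi-supergroup distribution. Neither affects the
headline counts: four ancestral AIF lineages (AIFM1, AIFM2, AIFM3,
NDI1) and three ancient apoptotic DNases (ENDOG, ZEN1, NUC1).

```{r headline}
rep <- reconstructRepertoire(apoptosisPresence())
categorySummary(rep)
```

# Numerical and degenerate-input choices

* Sequence alphabet: 20 amino acids plus X; other letters become X with
  a warning (tolerant ingestion of predicted proteomes). Gap dialects
  `-` and `.` are both read; output uses `-`.
* Support values parsed from internal Newick labels; values in [0, 1]
  are rescaled to percentages with a warning.
* Empty alignments, all-insert alignments, all-false presence rows and
  empty family lists are legal inputs with defined (empty) outputs.
* A presence row that is empty reconstructs as absent-everywhere with
  zero losses; a single-leaf row gains the family on that tip edge, so
  the root stays absent.
* All simulators are bit-reproducible given a seed; the pipeline derives
  per-family bootstrap seeds from the configured master seed, so reports
  are byte-identical across runs.

# Known limitations

* NJ only; no rate heterogeneity, no model selection.
* The origin call inspects the minimal clade and its sister; deeper
  paraphyletic arrangements of prokaryotic sequences are summarised as
  `ambiguous` rather than resolved.
* Node-height chronology is not a dating method; see above.
* The Dollo loss count on the default star tree is an upper bound for
  any resolved supergroup topology.
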