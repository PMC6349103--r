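---
title: "Methods: skeleton extraction, chemotaxonomic statistics, and candidate filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton extraction, chemotaxonomic statistics, and candidate filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`skeletax` turns compound structures and occurrence reports into
chemotaxonomic statistics that can guide terpene-synthase discovery. This
vignette documents the procedures, the assumptions they rest on, every
tunable parameter with its default and rationale, the numerical and design
choices made where more than one defensible option existed, and what the
synthetic-data generator does and does not emulate.

# Molecular graphs and standardization

A structure is held as an element-labeled, bond-order-labeled undirected
graph with implicit hydrogens. Parsing goes through OpenBabel (ChemmineOB),
and the package reads back the V2000 connection table, so three
normalizations happen by construction:

- **Stereochemistry is never represented.** Wedge flags, chiral atom
  flags, and InChI stereo layers are not read. The entire analysis is
  constitutional: any two stereoisomers of one constitution map to the
  same graph. This mirrors how skeleton-level chemotaxonomy is done —
  structure databases are inconsistent about stereo annotation, and the
  carbon skeleton is stereochemistry-free by definition. The cost is that
  stereochemically distinct skeleton classes (normal vs *ent* vs *syn*
  labdanes) are indistinguishable here; that is a deliberate non-goal.
- **Aromatic rings are kekulized deterministically** by OpenBabel into one
  fixed alternating single/double assignment. Downstream skeleton
  extraction sets all orders to 1, so the choice is invisible there; in
  positional pattern queries an aromatic bond (order 1.5, possible in
  user-supplied SDF) satisfies a solid double-bond constraint, because its
  order is delocalized rather than single.
- **Salts and multi-component records stay whole** as one graph with
  several connected components; component selection belongs to skeleton
  extraction, which operates on fragments anyway. Formal charges are
  parsed and retained but used by nothing downstream: skeleton identity
  and pattern matching are charge-blind.

`standardize()` is idempotent and total on valid graphs; records whose
structure text fails to parse are kept with a logged error and skipped by
the pipeline rather than aborting it, since occurrence databases
routinely contain a few malformed entries.

# Skeleton extraction

The skeleton of a compound is computed in two steps:

1. **Saturate and fragment.** Every bond order is set to 1; every bond
   involving at least one non-carbon atom is broken; non-carbon atoms are
   discarded. What remains is a set of connected, all-carbon,
   single-bonded fragments whose union is exactly the carbon atoms of the
   input (asserted on every extraction).
2. **Select the fragment closest to the target count.** The fragment
   minimizing |C(f) − T| is retained. The target `T` defaults to **20**,
   the diterpene carbon count, and is configurable so the same machinery
   applies to sesquiterpenes (15) or triterpenes (30).

Manual curation in database work resolves the rare cases where the
closest-to-20 rule picks the wrong fragment (e.g. an acyl side chain of
more than 20 carbons). The package mechanizes that as three pieces:

- a **deterministic tie rule** — more rings, then more carbons, then
  smaller canonical ID. Ring count leads because terpene cores are
  polycyclic while competing acyl/sugar fragments are acyclic or
  monocyclic;
- an **ambiguity flag**, raised whenever a runner-up fragment sits within
  `margin` (default 0, i.e. exact ties) of the winner's distance, so a
  reviewer can find every decision the tie rule made;
- an **override table** (compound id → fragment canonical ID) that
  replaces the automatic choice and marks the assignment
  `override_applied`, giving curation a reproducible, file-based channel.
  The shipped override set is empty: which records need correction is a
  property of a specific database snapshot.

Nor-skeletons are distinct skeletons: a C19 core missing one methyl is a
different graph from its C20 parent and receives its own identity, which
is how nor-diterpene skeletons are tabulated in the field. A carbon bonded
only to heteroatoms (a carbonate carbon, say) survives as a C1 fragment
and can only win selection if it is the sole fragment.

## Canonical identity

Two skeletons must compare equal exactly when their unlabeled graphs are
isomorphic. The ID is built by canonical labeling (BLISS, via
`igraph::canonical_permutation`) followed by serializing the sorted edge
list: `C20:1-16;2-19;…`. The contract is isomorphism-invariance, which the
test suite enforces against an independent VF2 check and a brute-force
backtracking matcher on random graphs; the particular canonical form is an
implementation detail and the IDs are opaque strings. The reference
library (kaurane Sk1, clerodane Sk2, abietane Sk3, labdane Sk4, pimarane
Sk6, atisane Sk14) is matched by canonical-ID equality, i.e. by graph
isomorphism, never by string heuristics.

# Taxonomy

Name resolution runs exact → normalized → fuzzy, in that strict order of
preference:

- **Normalization** lowercases, strips parenthesized annotations, hybrid
  signs, and marker tokens (`syn.`, `cf.`, `var.`, `subsp.`, …), and
  keeps the first two tokens, which also removes trailing authorities.
- **Fuzzy matching** uses similarity `1 − d/max(|a|, |b|)` where `d` is
  the optimal-string-alignment (restricted Damerau-Levenshtein) distance,
  with threshold **0.9** by default. Transpositions count as one edit
  because character swaps are the dominant typo class in hand-transcribed
  binomials; with plain Levenshtein a single transposition in a
  17-character binomial would already fall below 0.9. Every fuzzy match is
  flagged for review — the mechanized analogue of inspecting unmatched
  names by hand.
- When a binomial fails both exact and normalized matching but its genus
  token matches a genus-rank record exactly, the genus-level record is
  accepted. Genus precision is sufficient for all clade-level statistics,
  and species-level identifiers are not always assignable.

Clade assignment is a case-insensitive genus lookup against a 12-clade
map (the primary monophyletic Lamiaceae clades); unknown genera return
`"unassigned"`, which distribution statistics exclude from clade counts
while the denominator stays fixed at 12.

# Distribution statistics and pattern queries

`skeleton_distribution()` counts, per skeleton, distinct compounds,
distinct genera, and distinct clades; per genus, distinct compounds and
skeletons with per-source splits. Invariants tested: the per-skeleton
compound counts sum to the number of distinct occurring compounds, and
adding occurrence rows can only grow genus/clade cells. Name-only sources
(NAPRALERT-like) carry no structures; they participate in per-genus
compound counts and database overlap (by compound name/id) but cannot
contribute skeleton statistics.

Positional pattern queries count compounds with a structural feature at a
numbered skeleton position — e.g. a double bond between labdane positions
7 and 8, or the clerodane 4(18) epoxide. Semantics:

- the compound's skeleton must be isomorphic to the query's reference
  skeleton;
- **solid** constraints must hold in the original, pre-saturation
  structure under **at least one** isomorphism of the reference onto the
  skeleton (existential semantics). Skeletons have automorphisms, so a
  position number does not pin a unique atom; counting a compound once if
  any consistent numbering satisfies the constraints is the only
  convention that avoids both double counting and order dependence, and it
  is validated against an oracle that enumerates all mappings by
  backtracking;
- **dashed** positions are wildcards — any bond or substituent — and
  carry no computational constraint;
- `double_bond(p, q)` requires bond order 2 (or aromatic) between the
  mapped atoms; `epoxide_bridge(p, q)` requires the mapped atoms to be
  bonded and to share an oxygen neighbor (the three-membered C–O–C ring).

The five shipped queries (Δ7(8) and Δ8(9) labdane; Δ3(4), Δ4(18), and
4(18)-epoxy clerodane) encode the textual descriptions of the classic
diTPS product patterns; users supply their own `pattern_query()` objects
for anything else.

# Candidate filtering and merging

The filter retains a subject sequence iff its hit to the most similar
query reaches both thresholds. Choices, each configurable:

- **"Most similar query" = highest bit score** (ties: higher identity,
  then lexicographic query id). Bit score is the standard
  length-normalized ranking statistic.
- **Boundary inclusive**: removing subjects "below 70 % coverage or 35 %
  identity" means values exactly at 35.0/70.0 are kept.
- **Coverage basis** defaults to the single best HSP's span
  (`best_hsp`), the simplest reading; `merged_hsps` (union of the HSP
  intervals against the best query) is offered because split alignments
  understate single-HSP coverage. Merged coverage is provably ≥ best-HSP
  coverage, which the suite asserts.
- **Pairwise identity** is global (Needleman-Wunsch via Biostrings) with
  defaults match +1, mismatch −1, gap open 5, gap extend 1 (a gap of
  length L costs 5 + L), and the denominator is the **shorter** sequence
  — the convention of identity-threshold clustering tools, so that a
  fragment contained in a longer sequence scores near 100 % and merges.
- **Greedy clustering** sorts by length descending (ties: id) and joins
  the first representative at ≥ 95 % identity — deterministic, so the
  same input always yields the same clusters. Members are guaranteed
  ≥ threshold identity to their representative (asserted post hoc); the
  scheme does not guarantee globally optimal clusters, matching the
  behavior of the standard greedy tools.

Running the homology search itself, ORF prediction, and tree inference
are out of scope; the module consumes standard tabular output and FASTA.

# The synthetic-data generator

The generator stands in for the proprietary occurrence databases. It
emulates the **statistical structure the analysis assumes**: compounds
are reference skeletons decorated with the modification classes common in
diterpenoids; occurrences are (compound, species) incidences spread over
a genus/clade partition; hit tables have per-subject best hits with known
identity/coverage. Ground truth is computed exhaustively from the same
sampled objects (never re-derived through the code under test).

Default conditions, chosen once as a realistic desk-scale study and not
tuned afterwards: 200 compounds over all six shipped templates;
decoration probabilities hydroxylation 0.6 (up to three sites), carbonyl
0.3, desaturation 0.5, esterification 0.3 with acyl chains of 1–6
carbons, glycosylation 0.1 (a fixed C6 pyranose), demethylation 0;
24 genera × 3 species over all 12 clades (round-robin, so clade marginals
are exact by construction); occurrence density 0.05 across two
structure-bearing sources; 60–120 subjects against 8 queries with 10 % of
subjects planted exactly at the 35 %/70 % boundary. Acyl chains are capped
at C6 and the sugar is C6, far below the C19–C20 cores, so no competing
fragment can tie the selection rule and template recovery must be exact;
demethylation defaults to 0 because it intentionally changes the core
(the ground truth then records the nor-skeleton as expected). Decorations
mutate the graph under valence bookkeeping (C ≤ 4, O ≤ 2), so validity
needs no rejection sampling; structures serialize through canonical
SMILES, making a seeded rerun byte-identical.

What the generator does **not** emulate: realistic reaction chemistry or
decoration co-occurrence, database-specific curation noise (name
synonymy, misannotated taxa, duplicated records), skew in taxon sampling
(real databases oversample medicinal genera), or sequence-level homology
structure in hit tables (identities are drawn, not aligned). Passing
tests therefore demonstrate algorithmic correctness on inputs with known
truth, not robustness to real-database curation artifacts.

# Verification strategy and problem sizes

Every operation with a defensible independent route is tested against
one: fragment selection against an exhaustive argmin with the same tie
rule; canonical IDs against VF2 and against a brute-force backtracking
isomorphism search; pattern queries against an all-mappings backtracking
oracle; alignment identity against an affine-gap DP that enumerates all
optimal tracebacks (the implementation's identity must be attainable by
some optimal alignment — identity is alignment-dependent when optima
tie); filtering against a direct transcription of the rule; clustering
against an independent greedy replay. Suite sizes — 1,000 random
molecules for selection, 500 relabelings and 200 graph pairs for
canonicalization, 200 compounds for recovery, 60 fixtures for patterns —
keep the whole suite in the low minutes on one core while making
coincidental agreement implausible.

One validation depends on externally curated tables that are not
redistributable with the package: recomputing the published headline
counts of a specific database snapshot (239 skeletons, 233 without a
known route, and so on). The readers and counting functions for those
table schemas ship here (`read_skeleton_occurrence()`,
`read_enzyme_reference()`), and the corresponding acceptance test runs
whenever the tables are placed under `inst/extdata/supplementary/`; in
their absence it reports the missing-data failure rather than skipping
silently.

# Known limitations

- Skeleton identity is constitutional only; stereochemically distinct
  skeleton families collapse.
- The closest-to-20 rule with deterministic tie-breaks reproduces, not
  replaces, expert curation; genuinely ambiguous records need the
  override file.
- Greedy identity clustering is order-dependent by design (longest
  first); it matches the field's standard tool behavior, not an optimal
  partition.
- Fuzzy name matching mechanizes typo tolerance but cannot resolve true
  synonymy (different valid names for one taxon) beyond what the
  reference taxonomy encodes.
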