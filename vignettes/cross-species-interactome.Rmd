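---
title: "Cross-species IP-MS interactome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species IP-MS interactome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interologr)
```

## The analysis model

`interologr` identifies evolutionarily conserved bait–prey interactions
from two species' immunoprecipitation mass-spectrometry (IP-MS)
spectral-count data. The underlying reasoning is that nonspecific
binders are largely idiosyncratic to a purification system, while core
complex members are conserved: if a prey co-purifies with a bait in
*Drosophila* and its human ortholog co-purifies with the orthologous
bait in human cells, the interaction (an *interolog*) is unlikely to be
an artifact. The reference design the package models is a PI3K study:
TAP-tagged fly regulatory (Pi3k21B) and catalytic (Pi3k92e) subunit IPs
across an insulin time course, overlaid with p85 antibody IPs from a
panel of human cancer cell lines, which among 49 conserved interactors
exposed the direct, regulatory-subunit-preferring SHP2–p85 association.

The pipeline is deliberately simple and auditable: hard per-experiment
identification thresholds on spectral counts and unique peptides, pure
set subtractions for contaminants and controls, sequence-based ortholog
mapping with explicit reciprocity, and arithmetic means for
quantification. No interaction-scoring model (SAINT/CompPASS-style) is
involved; none is part of the analysis being reproduced.

## The filtering cascade

Evidence passes four steps, in the order of the study workflow:
contaminants → control subtraction → identification policy → sticky
removal. The first two are set subtractions and therefore commute (a
property the test suite checks); the identification policy must follow
them, since contaminant spectra would otherwise count as support.

Key parameters (`filter_policy()`):

* `min_counts_per_experiment = 3`, `min_unique_peptides = 2` — the
  per-run identification rule. The unique-peptide minimum applies to the
  human arm; the fly rule is counts-only, matching the asymmetry of the
  original acceptance rule (antibody IPs from complex lysates warrant
  the stricter test; TAP elutions are cleaner).
* `min_supporting_experiments_human = 2`, `..._fly = 1` — how many
  *experiment-condition units* must independently support a protein. A
  unit is a (species, bait, condition) combination; biological
  replicates of a unit are kept as separate rows but count once, through
  their best run. Counting units rather than replicate runs matches the
  design in which "16 human experiments" and "4 fly experiments" refer
  to condition units, and prevents a protein seen in two replicates of a
  single condition from masquerading as independently reproduced.
* Contaminant and sticky matching is case-insensitive substring matching
  on the protein description plus an accession blocklist. Matching by
  category name requires an exemption mechanism: the description
  "Activator of 90 kDa heat shock protein ATPase homolog 1" contains
  "heat shock" but denotes a co-chaperone that belongs in the conserved
  set; the default `sticky_exempt_patterns = "heat shock protein
  ATPase"` keeps it. The packaged 49-pair reference table fixes the
  intended outcome of this rule.
* Control subtraction defaults to exact-accession mode; a
  description-matching mode exists for datasets in which control and
  sample runs were searched against different database versions.

A record with zero spectral counts is legal input and treated as
absence. Candidate counts are reported at every checkpoint (pre/post
contaminants, post controls, post policy, post sticky) because published
intermediate totals in this kind of analysis are quoted at different
points of the cascade; both the post-control "candidate" totals and the
final accepted totals are first-class outputs.

## Ortholog mapping

Curated ortholog pair tables (a flattened HomoloGene/InParanoid-style
export, read as two columns of accessions) are merged with reciprocal
best-three-hits (RB3H) sequence search; curated pairs always win, and
sequence-derived pairs are added only for fly accessions absent from
every curated pair — the union reading of "curated first, sequence
search for the rest". Accessions are opaque tokens; no splice-variant
collapsing is attempted, and many-to-many pairs are retained
deliberately (the p55γ/p85α case shows why: both regulatory-subunit
variants are legitimate counterparts of Pi3k21B).

The internal aligner scores all-vs-all Smith–Waterman local alignments
(BLOSUM62, gap open 11, extend 1) through `Biostrings`, then converts
raw scores to bit scores and E-values with the standard gapped
Karlin–Altschul parameters (λ = 0.267, K = 0.041), using query length ×
total database length as the search space. This mimics a protein
sequence-search tool closely enough for desk-scale proteomes; genuine
proteome-scale searches should be run externally and imported as
12-column tabular hit files, which bypass the aligner entirely.

Hits are ranked per query by ascending E-value, then descending bit
score, then lexicographic subject accession. The last tie-break is a
repository decision — no convention exists for equal E-values — chosen
so that ranking is total and deterministic, which the order-invariance
and symmetry tests rely on. The E-value cutoff (1e−60) is strict
(`E < cutoff`), and `(a, b)` is a pair iff each is within the other's
top-3 surviving hits.

## Quantification and network export

Spectral counts are averaged arithmetically over the replicates of each
experiment-condition unit, counting a prey absent from a replicate as
zero. No between-run normalization is applied, matching the
raw-spectral-count averaging of the reference analysis; a total-count
scaling would be straightforward but is deliberately not a default.

Two statistics summarise the averaged table, both protected by a
pseudocount (default 1.0) because basal means of zero are common at
these depths:

* fold change `(mean_stim + pc) / (mean_basal + pc)` — insulin-induced
  binding;
* subunit preference `log2((mean_reg + pc) / (mean_cat + pc))` —
  positive for regulatory-subunit binders (the SHP2/Csw pattern),
  negative for catalytic-subunit binders (the IRS1/Chico pattern).

A prey absent from both sides of a ratio is reported as missing, never
as 1.0 (or 0.0): an undefined ratio and a no-change ratio are different
statements. Raising the pseudocount shrinks both statistics
monotonically toward their neutral values, so it acts as a conservative
regulariser. No significance cutoff is attached to fold changes — the
reference analysis states none — the pipeline reports ranked values and
leaves labelling to the analyst.

Network edges require a unit-averaged count of 3 or better, point from
bait to prey, and carry the condition color map (black/green/orange for
0/10/30 min insulin). Self-edges (the bait pulling itself) are
suppressed. SIF export collapses to unique bait–prey triples (the
format carries no attributes); TSV and GraphML carry the full attribute
set and round-trip exactly.

## The synthetic study and what it does (not) show

`simulation_config()` encodes the emulated design: 2 fly baits × 3
conditions × 3 biological replicates plus an empty-TAP control arm, and
16 human p85 experiment-condition units × 2 replicates plus IgG
controls. The planted universe per species is 12 conserved preys
(ortholog-paired), 30 species-specific preys (decoy sequences, no
ortholog), 20 sticky proteins and 15 named contaminants, with baseline
abundance 30 spectral counts and background rate 8. Sticky proteins are
planted *with* orthologs and appear in every IP including controls, so
the sticky and control-subtraction steps are load-bearing for
end-to-end precision; contaminants carry category-matching descriptions
and exercise the name filter. The two bait subunits are themselves
ortholog pairs present in the evidence (own IP at 3× baseline, partner
subunit at baseline), mirroring the reference conserved table that
contains both the bait row and the catalytic subunit; the planted
conserved truth is therefore `n_conserved_preys + 2` pairs. The first
two conserved preys are named analogues: a regulatory-preferring,
insulin-responsive prey (fold 3 on insulin, 8× preference) and a
catalytic-preferring one, so fold-change and preference outputs are
exercised qualitatively.

Counts are Poisson by default — the right choice for oracle tests with
law-of-large-numbers checks — with a negative-binomial option
(`dispersion`) because real spectral counts are overdispersed. Unique
peptides are drawn as `min(counts, 1 + Binomial(counts, 0.25))`, which
makes the two-unique-peptides rule realistically satisfiable at
baseline abundance and occasionally violated at low counts.

**Ortholog identity default.** Sequence lengths are drawn from 150–600
residues. The default planted identity is 0.85, fixed by a detection
power calculation before any end-to-end runs: under the gapped
Karlin–Altschul parameters, the E < 1e−60 cutoff at this database size
corresponds to roughly 220 bits; a 150-residue pair (the worst case) at
85% identity scores about 250 bits (≈ 3 SD of margin), while at 60%
identity it scores about 160 bits and is undetectable by design. In
other words, at the fly–human-like identity levels of real core
complexes, short proteins fall below this E-value cutoff — which is a
faithful property of the stringency, not a defect of the aligner; the
identity-degradation test asserts exactly this monotone loss of recall.

What the synthetic data does *not* emulate: peptide-level inference and
shared peptides, FDR behaviour, run-to-run normalisation artifacts,
abundance-dependent detectability, and correlated background structure
(the "frequent flyer" effect). Passing end-to-end tests therefore shows
the pipeline's set logic, thresholds and determinism are correct — not
that the thresholds are optimal for any particular real dataset.

## Numerical and degenerate-input choices

* All randomness flows through a single integer seed; the proteome and
  count generators use distinct sub-seeds (seed, seed + 1) and restore
  the caller's RNG state, so outputs are byte-identical across reruns.
* Thresholds are inclusive ("three or better" means ≥ 3; means of
  exactly 3.0 survive); the E-value cutoff is strictly exclusive.
* Empty inputs propagate quietly: empty evidence yields empty accepted
  sets, an empty ortholog map yields an empty conserved table, an empty
  edge list yields valid empty SIF/GraphML documents. A species with no
  experiments yields an empty accepted set with a log message.
* Malformed files raise classed errors (`interologr_format_error`,
  `interologr_validation_error`) naming the offending column, row or
  record; a stage invoked before its upstream stage names the stage to
  run first.

## Problem sizes in the test suite

The default simulated study (79 proteins per species, 55 IP runs,
all-vs-all alignment of both proteomes) runs end to end in well under a
minute; the oracle-equivalence suite uses 200 randomized miniature
datasets per operation, the monotonicity suite 50 randomized policies,
and sampling-distribution checks use a few hundred replicate draws.
These sizes were chosen so the full suite exercises every code path,
including the alignment kernel, while staying small enough to run
routinely during development.

## Known limitations

* The internal aligner's E-values use fixed gapped Karlin–Altschul
  parameters rather than composition-adjusted statistics; for borderline
  hits near the cutoff, an external search tool's tabular output should
  be imported instead.
* Control subtraction is all-or-nothing; a quantitative
  enrichment-over-control model is out of scope.
* The identification policy treats experiments as exchangeable; no
  cell-line or batch structure is modelled.
* The conserved-interactor table inherits any ambiguity of many-to-many
  ortholog pairs; `collapse_by_human()` is a convenience view, not a
  disambiguation.
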