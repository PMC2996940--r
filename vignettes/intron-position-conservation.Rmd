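---
title: "Methods: scoring intron position conservation across ortholog clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring intron position conservation across ortholog clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcon)
```

## The question and the model

Spliceosomal intron positions can persist over very long evolutionary
timescales, while intron sequence and length are essentially free to
drift. `ipcon` quantifies how well two proteins share intron positions
and asks whether orthologs — genes related through the last speciation —
share them better than the *closest non-orthologs*: sequences nearby in
similarity space that fall just outside the ortholog cluster. A positive
answer makes intron position conservation (IPC) a discriminating feature
for orthology assignment that is largely orthogonal to raw sequence
identity.

### From gene structure to marks

An intron's position is recorded on the protein. If `k` coding
nucleotides precede the intron, the mark is placed on residue
`⌊k/3⌋` with phase `k mod 3`. Phase-0 introns fall between codons,
phase-1/2 introns interrupt one; in all three cases the mark sits on the
codon the intron touches. Two positions count as *conserved* when they
mark the same codon after alignment, which is equivalent to allowing an
apparent slide of up to 2 nt. This codon-level criterion is deliberate:
wider slide windows blur the distinction between conserved and merely
nearby positions. A consequence is that two same-codon introns of
different phase in one gene collapse to a single marked residue for
counting.

### The IPC score

For a pair of aligned sequences with `n_A` and `n_B` marked residues of
which `shared` coincide column-wise,

    IPC = 2 · shared / (n_A + n_B).

This form is symmetric, lies in `[0, 1]`, and equals 1 exactly when the
two mark sets coincide. The normalization is a design choice of this
package: a Jaccard alternative `shared / (n_A + n_B − shared)` with the
same fixed points is exposed through `method = "jaccard"` everywhere a
score is computed, and the default is declared rather than inferred.
A pair in which both sequences are intronless carries no information and
is *undefined* (`NA`, excluded from every mean); a one-sided intronless
pair scores 0.

### Clusters and the four pair types

Two-species clusters follow the classic seed-and-attach scheme:
bidirectional best hits (after coverage filtering) are seed orthologs;
each within-species sequence whose similarity to its seed is at least
the seed score `S` joins as an inparalog with confidence
`(sim − S)/(self − S)` clamped to `[0, 1]`. Conflicts between seeds are
resolved greedily in descending `S`, removing members from the candidate
pool once assigned, so clusters are disjoint by construction. This
replaces the original algorithm's iterative cluster merging; the
downstream analysis only needs disjoint clusters with the stated
seed/inparalog semantics. When the two directional best-hit scores
differ, `S` is their mean. Intracluster bootstrap values for seeds are
consumed from the input cluster table, never computed.

Each member `m` is then paired with its closest non-ortholog `cno(m)`
(best non-member hit in the other species) and closest non-inparalog
`cni(m)` (same species). Only membership in the focal cluster excludes a
candidate — a cno may well be a member, even a seed, of another cluster.
Scoring enumerates: all cross-species member pairs (o–o), all
within-species member pairs (i–i), and for each member pair the mean of
its up to two defined cno (cni) pairs, giving o–cno and i–cni values.
IPC is maximized over the spliceform combinations of the two genes —
uniformly for all four pair types, to avoid biasing the members-only
comparison — with ties broken by higher identity, then lexicographic
spliceform ids. Sequence identity is matches over co-aligned columns
(both non-gap), 0 when none exist.

Clusters containing mitochondrial genes are dropped outright (all are
intronless), and shorter spliceforms of members are re-added before
scoring.

### Consistency and agreement

A multi-cluster (one with inparalogs) is *consistent* when the seed pair
attains the highest IPC among all o–o pairs; ties count as agreement,
since the seed then still attains the maximum. If the seed pair's IPC is
undefined while another pair's is defined, the cluster is inconsistent;
if no o–o pair is defined, consistency is `NA`. Agreement fractions are
reported separately for clusters whose minimum seed bootstrap is at
least the threshold (default 90%) and for the rest, with
unknown-bootstrap clusters counted but excluded.

## Statistics

* **Rank-sum tests.** o–o vs o–cno and i–i vs i–cni are compared with a
  two-sided Mann–Whitney–Wilcoxon test — exact when the combined sample
  is ≤ 20 without ties, otherwise the tie-corrected normal approximation
  without continuity correction. By default the test is applied to
  per-cluster per-type mean IPC values, which avoids pseudo-replication
  from large clusters contributing many correlated pairs; a per-pair
  mode is exposed (`mww_mode = "pairs"`).
* **Identity-controlled binning.** To separate IPC from sequence
  identity, both pair types are first split into `k` equal-count bins
  (default `k = 10`; the results are insensitive to `k` within reason,
  and only `k` is configurable). A sample's boundary `j` is the midpoint
  between the adjacent order statistics at the j-th k-quantile split —
  the quantile convention is this package's choice. The *combined*
  boundary is the mean of the two samples' boundaries, and both samples
  are re-binned by the combined boundaries (right-closed intervals; a
  value exactly on a boundary goes to the lower bin). Per bin,
  `log2(mean IPC type1 / mean IPC type2)` is reported; bins where either
  type is empty or has mean 0 are flagged undefined rather than `±Inf`.
  Identity ties can make combined boundaries non-strictly ascending; the
  package warns and proceeds (some bins may then be empty).
* **Spearman correlation** of IPC against identity per pair type uses
  average ranks with a t-approximation p-value; constant inputs or fewer
  than 3 pairs are flagged undefined.
* **Enrichment.** Genes found only in inconsistent multi-clusters form
  the foreground; the universe adds the genes found only in consistent
  ones. Genes seen in both kinds across species comparisons are
  ambiguous and excluded. Oversize clusters (default: more than 200
  genes, strictly) are removed first as likely orthology artifacts.
  Each term is tested hypergeometrically in both directions;
  significance is Benjamini–Hochberg on the two-sided p-value
  (doubled minimal tail, capped at 1) at FDR 1%, treating enrichment and
  depletion as one family by default (`family = "separate"` runs them
  as two). Term interdependence is handled empirically, not through
  ontology ancestors: term `B` is associated with term `A` when
  excluding `A`-annotated genes from the analysis de-significates `B`,
  and representatives are picked greedily by link count (ties: smallest
  term id), absorbing their neighbors. Pfam domains are rolled up to
  clans where mapped, and consecutive runs of the same Repeat/Motif-type
  domain collapse to one pseudo-domain before counting.

## The simulator

`simulate_dataset()` creates two-species families from one ancestral
gene: an optional pre-speciation duplication creates an outparalog
lineage (the material that later becomes cno/cni), speciation splits
every lineage, and optional post-speciation duplications create
inparalogs. Intron marks survive a branch of length `t` with probability
`exp(−loss_rate · t)`; gains are Poisson with mean
`gain_rate · t · |protosplice set|`, restricted to a per-family random
"protosplice" subset of sites (default 10% of residues), which encodes
the parallel-gain confound. Sequences evolve by per-residue substitution
and are indel-free, so the true alignment is the identity (shorter
spliceforms are padded with trailing gaps). Similarity scores decrease
monotonically with divergence time with 2% bounded relative noise;
coverage fractions are 1.

Defaults describe a moderately diverged comparison: 300-residue
proteins, 7 ancestral introns (a gene of typical vertebrate intron
density), speciation 1 time unit ago, inparalog duplications at 0.3,
the outparalog split at 1.8, loss rate 0.5 per intron per unit time
(ortholog retention ≈ `exp(−0.5) ≈ 0.61`), gain rate 0.01 per eligible
site per unit time. Under pure loss the expected pair score between
relatives whose common ancestor lived `t` units ago is approximately
`exp(−loss_rate · t)`, which orders the four pair types exactly as the
biology suggests and gives the simulator a closed form to recover.
(The `2·shared/(n_A+n_B)` ratio has a small finite-count bias of about
`−(1−s)/(2n)` for `n` ancestral introns; the recovery experiment uses
30 ancestral introns so this sits well inside the sampling noise of 500
families.)

Families with inparalogs are flagged "inconsistent by construction" with
probability 0.25; flagged families apply a 5-fold loss multiplier to the
focal seed's terminal branch, so a non-seed pair tends to attain the
highest IPC, and their clusters draw seed bootstraps from the low regime
(40–89) with probability 0.8 versus 0.15 otherwise — tying the
bootstrap-split agreement analysis to truth. A GO term is planted in
flagged-family genes at elevated frequency for the enrichment stage.

For the parallel-gain control, the outparalog split is placed *at* the
speciation time and families start intron-free with gain confined to the
protosplice set. Ortholog and closest-non-ortholog pairs are then
exchangeable by construction — every lineage is equally old and no
shared stem exists — so any IPC sharing is parallel gain, and the o–o
vs o–cno comparison must be null. This scenario is scored directly from
the simulator's truth relations (it tests the scoring, not the
clustering, which cannot distinguish exchangeable lineages).

What the simulator does *not* emulate: indels and alignment error (an
optional external-aligner hook exists but the packaged workflow consumes
true alignments), intron sliding, rate heterogeneity across sites or
lineages, codon structure in sequences, and genome-scale annotation
noise. Passing tests therefore demonstrate correctness of the pipeline's
logic and statistics under known truth, not robustness to the
data-quality problems of real genome annotation.

## Numerical and degenerate-input choices

* Coverage cutoffs and the inparalog threshold are inclusive (`≥`).
* Best-hit and spliceform ties break lexicographically; representative
  ties by smallest term id — all deterministic, so identical inputs give
  identical outputs regardless of row order.
* A seed whose self-hit is missing or not above `S` keeps confidence 1
  while other members get 0, with a warning.
* Marks landing in the stop codon are dropped with a warning, never
  clamped; fuzzy (`<`/`>`) CDS locations are skipped, not guessed; CDS
  features lacking a translation or protein id are skipped with a
  warning.
* Fully tied rank-sum inputs return p = 1.
* All-undefined spliceform grids yield an undefined pair excluded from
  means.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
statistical assertions sharp while staying desk-sized: 1000 random gene
models for the coordinate bijection, 100 random tables for the
clustering oracles, 200-family datasets (10-seed panels) for the
headline direction and its parallel-gain control, 500 one-to-one
families for closed-form recovery, and 100 seeded runs for
planted-enrichment detection. The packaged fixture is 20 families.

## Known limitations

* Two species per analysis; multi-species comparisons are handled by
  running per-pair and combining gene-level consistency sets.
* The flat-file reader covers the CDS feature/location/qualifier subset
  needed here, not the full EMBL/GenBank grammar.
* Cluster conflict resolution is greedy; pathological similarity tables
  could partition members differently than the original iterative
  algorithm.
* GO annotations are used as given — no ancestor propagation; the
  association network absorbs term interdependence empirically.
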