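# ipcon — intron position conservation analysis for ortholog clusters

Most spliceosomal introns sit at positions that can stay put for hundreds
of millions of years, which makes the *position* of an intron — unlike its
sequence or length — a usable phylogenetic character. `ipcon` asks the
question that motivates this package: **do orthologs conserve intron
positions better than sequences that are merely similar?** If they do, a
pair's intron position conservation (IPC) score is an extra, largely
sequence-independent line of evidence when assigning orthology.

The package is aimed at comparative genomicists working with two-species
ortholog collections (InParanoid-style clusters, or anything reducible to
a similarity table). It provides the full analysis path:

1. **Gene structures** — parse CDS `join(...)` locations from EMBL/GenBank
   flat files, map each intron onto its protein as a mark on the codon it
   precedes or interrupts (`residue = ⌊k/3⌋`, `phase = k mod 3` for coding
   offset `k`), and keep the longest spliceform per gene. Marked proteins
   round-trip through a "marked FASTA" format where a lower-case residue
   encodes a mark.
2. **Ortholog clusters** — bidirectional best hits seed a cluster; each
   within-species sequence at least as similar to the seed as the seed
   score *S* joins as an inparalog; every member is then paired with its
   closest non-ortholog (cno, best non-member hit in the other species)
   and closest non-inparalog (cni, same species) to form an *extended
   cluster*. Coverage cutoffs default to 0.5 (overlap) and 0.25 (longest
   segment).
3. **IPC scoring** — marks are projected through a multiple alignment;
   two introns count as the same position when they land in the same
   codon (a slide of at most 2 nt). For a pair with `n_A`, `n_B` introns
   of which `shared` coincide,

   ```
   IPC = 2 · shared / (n_A + n_B)
   ```

   (a Jaccard variant is available). IPC is maximized over spliceform
   combinations; pairs where both sequences are intronless are undefined
   and excluded. Four pair types are scored per cluster: o–o, o–cno,
   i–i, i–cni.
4. **Comparative statistics** — Mann–Whitney–Wilcoxon tests between pair
   types, sequence-identity binning with combined equal-count boundaries
   and per-bin `log2(mean IPC ratio)`, Spearman correlations of IPC
   against identity, and the agreement between seed assignment and IPC
   split by seed bootstrap support.
5. **Enrichment** — hypergeometric GO/Pfam enrichment (BH FDR, default
   1%) of genes found only in *inconsistent* clusters (where the seed
   pair does not attain the highest o–o IPC), with a term-association
   network built by exclusion re-testing, greedy representative
   selection, Pfam clan rollup, repeat-run collapsing and protein
   property comparisons.
6. **Simulator** — two-species gene families with known orthology,
   intron gain/loss histories, similarity tables, alignments and planted
   annotation enrichment, so every stage is testable offline and
   parameter recovery can be asserted against closed forms.

Everything takes a data frame first and returns a tibble; results
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

The package ships a 20-family simulated fixture with all pipeline
inputs:

```r
library(ipcon)
cfg <- read_pipeline_config(
  system.file("extdata", "fixture20", "config.yaml", package = "ipcon"))
cfg$out_dir <- tempfile()
res <- run_ipc_pipeline(cfg)
res$comparison
#> IPC pair-type comparison: spA-spB
#>   pair_type mean_ipc mean_identity n_pairs
#> 1 i-cni        0.382         0.501      20
#> 2 i-i          0.813         0.892      20
#> 3 o-cno        0.314         0.503      44
#> 4 o-o          0.495         0.683      44
#>
#> Rank-sum tests (cluster_means):
#>   comparison     n_1   n_2   p_value
#> 1 o-o vs o-cno    20    20 0.0715
#> 2 i-i vs i-cni    16    16 0.0000129
```

Orthologs conserve positions better than equally-similar non-orthologs
(mean IPC 0.50 vs 0.31), and inparalog pairs — which split most
recently — conserve them best of all (0.81 vs 0.38 against their closest
non-inparalogs). At this fixture size the i–i/i–cni contrast is already
decisive while o–o/o–cno is borderline; both become overwhelming at the
simulation's full scale. `autoplot(res$comparison)` draws the per-type
means, `autoplot(res$comparison, type = "bins")` the identity-controlled
log2 ratios, and `glance(res$comparison)` condenses the run to one row.

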