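# subgenomics

Tools for asking whether the two subgenomes of an allotetraploid differ
in their transcriptional and post-transcriptional activity — and for
answering with explicit statistics rather than eyeballed counts.

Allotetraploids such as the common carp (*Cyprinus carpio*) carry two
parallel chromosome sets (subgenomes A and B, chromosomes A1–A25 and
B1–B25) inherited from two parental species. Even when the subgenomes
are structurally symmetric, one of them often shows more activity — a
phenomenon called subgenome dominance. `subgenomics` quantifies four
event types per subgenome and tests the A/B contrast for each:

* **Alternative splicing (AS).** A gene is AS when it has ≥ 2 isoforms.
  Events are typed by intron-chain comparison against the gene's
  reference isoform (exon skipping, intron retention, alternative
  donor/acceptor, mutually exclusive exons), localised to CDS / 5'UTR /
  3'UTR, and genes are grouped by whether splicing changes their
  predicted proteins.
* **lncRNAs.** Transcripts > 200 bp whose best sense-strand ORF does
  not exceed 100 amino acids; lncRNA–mRNA interactions are predicted by
  ungapped reverse-complement matching (≥ 20 bp, ≥ 90% identity) and
  classified by expression: a pair with Euclidean distance ≤ 5.10 and
  correlation ≥ 0.667 on log2(TPM+1) organ profiles is *correlated*,
  one with distance > 5.10 and correlation < 0.667 is *divergent*.
* **circRNAs.** Back-splice junctions with ≥ 2 supporting reads,
  classified exonic / intronic / intergenic against the annotation and
  quantified as junction reads per million mapped reads.
* **RNA editing.** Sites called from paired RNA/DNA pileups: RNA and
  DNA coverage ≥ 10, substitution frequency ≥ 0.1, a unique alternative
  base, zero non-reference DNA reads, and agreement of ≥ 2 replicates
  within an organ; the 12 substitution types are strand-corrected and
  coding consequences derived from the codon table.

Tissue specificity uses Shannon entropy over organ-level TPM profiles,
`H = -Σ Pₙ log₂ Pₙ` with `Pₙ = TPMₙ / Σ TPM`: 0 for single-organ
expression, log₂(m) for uniform expression over m organs. Subgenome
contrasts use Yates-corrected χ² for 2×2 counts, Wilcoxon rank-sum for
distributions, Spearman correlation, and hypergeometric tests (with
Benjamini–Hochberg adjustment) for term enrichment and overlap.
Homoeologs — gene copies descended from the two parents — are paired
by synteny chaining (runs of ≥ 5 collinear homologs).

A synthetic two-subgenome data generator (`simulate_*`) produces a
complete toy dataset — genome, annotation, homoeolog pairs, expression,
BSJ tables, pileups — with known ground truth and configurable
B-subgenome excess for every event type, so the whole pipeline is
testable end to end without any sequencing data.

## Worked example

```r
library(subgenomics)
library(dplyr)

cfg <- simulate_config(n_chrom_per_subgenome = 5, genes_per_chrom = 40,
                       n_unanchored = 1, seed = 1)
ds  <- simulate_dataset(cfg)
rep <- run_full_comparison(ds)
tidy(rep)
#> # A tibble: 6 x 7
#>   event              test          statistic  p_value     n family   p_adjust
#>   <chr>              <chr>             <dbl>    <dbl> <int> <chr>       <dbl>
#> 1 as_genes           chisq_yates      0.0430 8.36e- 1   368 splicing 8.36e- 1
#> 2 lncrna             chisq_yates      0.495  4.82e- 1   706 lncrna   4.82e- 1
#> 3 circ_host_genes    chisq_yates      0.103  7.49e- 1   400 circrna  7.49e- 1
#> 4 editing_genes      chisq_yates      0.884  3.47e- 1   400 editing  3.47e- 1
#> 5 editing_frequency  wilcoxon    579975      1.14e-16  2404 editing  2.27e-16
#> 6 as_gene_expression wilcoxon      5342      6.46e- 1   203 splicing 8.36e- 1
```

Each row is one A-vs-B contrast. In this run the structural counts (AS
genes, lncRNAs, circRNA hosts, edited genes) do not differ between
subgenomes — the default generator plants only a mild asymmetry, far
below what 200 genes per subgenome can resolve — while the editing
*frequency* contrast is strongly significant, reflecting the higher
substitution frequency configured for the B subgenome
(`edit_freq_B = 0.30` vs `edit_freq_A = 0.25`). `glance(rep)` gives the
one-row summary and `autoplot(rep)` the contrast overview.

All stages are also usable on real tabular inputs: `read_gtf()` /
`read_genome()` / `read_bsj()` load standard formats, and each stage
(`detect_as_genes()`, `filter_lncrna()`, `filter_bsj()`,
`call_editing_sites()`, `chain_synteny()`, ...) takes and returns plain
tibbles.

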