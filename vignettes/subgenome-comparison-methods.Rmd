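---
title: "Methods: comparing transcriptional events between allotetraploid subgenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing transcriptional events between allotetraploid subgenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An allotetraploid genome carries two parental chromosome sets — here
labelled subgenome A and subgenome B, with paired chromosomes A1..An
and B1..Bn. A recurring observation in such genomes is *subgenome
dominance*: one subgenome hosts systematically more transcriptional
activity than the other. `subgenomics` operationalises this question
for four event types — alternative splicing (AS), long noncoding RNAs,
circular RNAs, and RNA editing — and pairs each with an explicit
statistical contrast. This vignette records the models, the defaults
and why they were chosen, the numerical decisions, and what the tests
do and do not establish.

# Data model and coordinates

All stages share one tabular gene-model container (`annotation_set`):
tibbles of genes, transcripts, exons and CDS intervals. Coordinates
are **1-based inclusive throughout**, the native convention of GTF and
of the R/Bioconductor ecosystem this package lives in; BED-like
back-splice junction tables are shifted (+1 on start) at read time, so
conversion in either direction is lossless. Exons within a transcript
are kept sorted and must be disjoint; abutting exons are legal and are
treated as one contiguous block by the intron-chain machinery (a
zero-length gap is not an intron).

# Stage by stage

## Isoform classification against a reference annotation

A query transcript is summarised by its *intron chain* — the ordered
intron intervals — and compared against a reference annotation into
seven mutually exclusive classes, evaluated in order: complete match
(identical chain, same chromosome and strand), partial match (the
query chain is a strict contiguous sub-chain of a reference chain),
opposite-strand chain match, pre-mRNA fragment (an intron-less query
inside a multi-exon reference span on the same strand), polymerase
run-on (touching only the 3' flank of a gene), novel isoform of a
known gene (same-strand exonic overlap), and novel gene. Mono-exon
equivalence uses 50% reciprocal overlap and the run-on window is
10 kb; both are configurable because reference tools leave them as
knobs, and the source conventions only name the classes. The evaluation
order places the structural matches first and the artifact classes
before the novelty classes, so that an intron chain mirrored on the
wrong strand is reported as a likely artifact rather than a novel
isoform.

## Alternative splicing

A gene is AS when it has at least two isoforms. Events are typed by
comparing each isoform with the gene's *reference isoform* — the one
with the longest CDS, ties broken by transcript length and then by
identifier, so the choice is deterministic. From each pairwise
comparison we derive: intron retention (an intron of one isoform fully
exonic in the other), exon skipping (an exon of one isoform inside an
intron of the other), mutually exclusive exons (a skip candidate on
each side, within overlapping introns, with disjoint exons), and
alternative donor/acceptor sites (overlapping introns sharing exactly
one boundary, the donor being the intron end nearer the 5' end of the
transcript, so the call is strand-aware). One boundary case needed a
rule: when two introns share a boundary and the differing region
swallows a whole exon of the other isoform, the difference *is* the
skipped exon, and no alternative-site event is emitted. Events are
deduplicated by (type, genomic interval) within the gene, so a variant
shared by several isoform pairs is counted once.

Event regions are assigned from the reference isoform's CDS span: any
overlap is `CDS` (including boundary-straddling events), otherwise the
event is 5'UTR or 3'UTR by its position on the coding strand. Genes
without a CDS are excluded from region distributions.

Protein-diversity grouping translates every CDS-bearing isoform with
the standard nuclear code (internal stops truncate) and groups genes
as: `unaffected` (one distinct protein), `all_differ` (all distinct),
`partial` (otherwise). Genes with fewer than two CDS-bearing isoforms
are excluded rather than guessed at.

## lncRNAs

The filter keeps transcripts whose spliced length is strictly greater
than 200 bp and whose best sense-strand ORF encodes at most 100 amino
acids; both boundaries are exclusive on purpose (a 200-bp transcript
and an exactly-100-aa ORF do not qualify). ORF search is sense-strand
only because transcripts are already oriented. The trained
coding-potential classifiers used in practice add further filtering;
that step is out of scope here and the length+ORF rule is the
operative definition.

lncRNA–mRNA interaction candidates come from ungapped
reverse-complement matching: maximal local matches of length ≥ 20 bp
and identity ≥ 90% between the lncRNA and the reverse complement of
the mRNA. The implementation locates candidate alignment diagonals by
shared exact 12-mers and then scans those diagonals exactly,
enumerating maximal qualifying intervals from the mismatch layout;
overlapping maximal intervals on a diagonal are merged to the
highest-identity one (ties: longest, then leftmost). The seed step is
the only approximation: a qualifying match whose mismatches break
every exact 12-mer would be missed. Such configurations are rare for
matches just above the 20-bp floor and essentially impossible for the
long near-perfect complements the analysis targets; a brute-force
all-window oracle guards the exact semantics in the test suite.

Each interacting pair is classified on organ-level mean `log2(TPM+1)`
profiles: *correlated* when Euclidean distance ≤ 5.10 and Pearson
correlation ≥ 0.667, *divergent* when distance > 5.10 and correlation
< 0.667, *intermediate* otherwise. The two thresholds are inherited
study constants; since the two named categories do not exhaust the
plane, the explicit intermediate class absorbs the remainder rather
than forcing a binary call. Whether the thresholds apply to raw or
log TPM is not fixed by convention; `log2(TPM+1)` is the documented
default (Spearman is available as an option).

## circRNAs

Back-splice junctions with fewer than 2 supporting reads in every
sample are discarded (the max-per-sample rule, inclusive at 2). A
junction is *exonic* when both ends coincide exactly — zero tolerance,
because junction tables derive from spliced alignment — with exon
boundaries of a single transcript; *intronic* when its span lies
within one intron; *intergenic* otherwise. Host-gene ambiguity is
resolved by longest overlap, then lexicographic id. Expression is
junction reads per million mapped reads, with the per-library total as
the denominator (configurable; junction-only denominators are a
stricter alternative). Flanking-intron features (lengths, RC matches
between flanks, repeat coverage fraction) reuse the RC matcher and
plain interval arithmetic; a circle at a terminal exon reports its
missing flank as `NA` rather than 0.

## RNA editing

A site is called per organ when at least two RNA replicates each have
coverage ≥ 10, exactly one observed alternative base, and alternative
frequency ≥ 0.1 (both thresholds inclusive); the supporting replicates
must agree on the base; and the single DNA library has coverage ≥ 10
with zero non-reference reads. "Unique mutation" is interpreted as
one distinct alternative base — a replicate showing two alternatives
supports nothing, and replicates disagreeing on the base invalidate
the site in that organ. Replicate agreement is required *within* an
organ; the same position may be called independently in several
organs. Sites absent from the DNA pileup are skipped as lacking
evidence, not treated as homozygous reference. Frequencies are pooled
over supporting replicates (alt reads / total reads). Whether the
frequency threshold should apply per replicate or pooled is not
settled by convention; per-replicate is the default here.

Substitution types are strand-corrected: bases are complemented when
the site lies in a minus-strand gene, intergenic sites are typed on
the plus strand, and a site covered by genes on both strands is typed
once per context and flagged ambiguous. Coding consequences substitute
the edited base into its codon in the covering transcript's CDS
(deterministically the lexicographically first covering transcript)
and compare translations. Region enrichment computes fold =
(site fraction) / (genome fraction) per feature, with the genome
partitioned by the same priority order as the site annotator so the
two fractions are commensurable, and an upper-tail hypergeometric
p-value over genome positions.

## Genic-position annotation

One shared annotator labels any interval with exactly one of:
lncRNA, promoter, 5'UTR, 3'UTR, CDS/exon, intron, downstream, distal
intergenic — in that priority order. lncRNA-exon overlap outranks the
genic labels of coding genes because lncRNA targets are reported as
their own category alongside genic ones. The promoter is TSS ± 3 kb
and downstream extends 3 kb past the 3' end; these are the common
defaults of genomic annotation tools, are configurable, and are an
assumption rather than a convention fixed by the analyses this package
reimplements.

## Tissue specificity and clustering

Shannon entropy is computed on organ-level mean TPM profiles:
`P_n = TPM_n / ΣTPM`, `H = −Σ P_n log2 P_n` with `0·log 0 = 0`. H is 0
for single-organ expression and log2(m) for uniform expression; an
all-zero profile is reported as missing rather than 0, since "not
expressed anywhere" is not "perfectly specific". Organ profiles are
replicate means; the aggregation statistic is a documented choice.
"Expressed in an organ" defaults to TPM > 0 (strict), configurable.
Feature clustering is Ward-linkage hierarchical clustering on
Euclidean distances of row-scaled profiles, cut at the requested k:
fully deterministic, unlike k-means, which matters because reports
must be byte-identical under a fixed seed. Constant rows are scaled to
zeros instead of erroring.

## Homoeolog pairing and the contrast battery

Synteny chaining takes candidate homolog pairs plus per-chromosome
gene ranks and extends chains while ranks progress monotonically on
both chromosomes (either orientation) with rank gaps ≤ 25; chains
with ≥ 5 pairs become blocks — the conventional minimum — and their
pairs become homoeolog pairs, each gene in at most one pair (larger
blocks claim genes first).

The 2×2 count contrasts use the χ² test *with Yates continuity
correction*: on the published AS-gene table (12,937 of 25,285 vs
14,258 of 26,583) the corrected test reproduces the printed
p = 1.87×10⁻⁸ exactly, while the uncorrected one gives 1.77×10⁻⁸, which
is how the correction convention was pinned down. Wilcoxon rank-sum
contrasts use exact enumeration for tie-free samples of ≤ 8 per group
and the tie-corrected normal approximation otherwise. Raw p-values are
reported and Benjamini–Hochberg adjustment is applied within each
event family, never replacing the raw values.

The homoeolog-overlap partition (both / A-only / B-only / neither)
also yields per-subgenome rates: the fraction of pairs whose A-side
(respectively B-side) gene carries the event. On the published AS
overlap counts these reproduce the printed 62.69% and 65.74%.

# The synthetic-data generator

The generator emulates the targeted study design: two subgenomes of
25 chromosomes each (A1..A25 / B1..B25) plus unanchored scaffolds,
nine organs, three RNA-seq replicates per organ, and a mild
B-subgenome excess in each event type. Genes are laid out one per
fixed 2-kb slot so homoeologs occupy the same rank on paired
chromosomes; the pair table therefore exists by construction *and* is
independently rediscoverable by the synteny chainer, which the tests
exploit as a cross-check. Each output family (genome, annotation,
expression, events) draws from its own seed stream derived from the
master seed, so regenerating one family leaves the others untouched
and the whole dataset is byte-reproducible.

Default asymmetry knobs follow the published per-subgenome summaries
where those exist: AS incidence 0.512 / 0.536, lncRNA incidence
0.09 / 0.11, circRNAs per gene 0.034 / 0.048 (the published totals
divided by gene counts), editing sites per gene 3.2 / 3.44. The mean
substitution frequencies (0.25 / 0.30) are a realistic choice — the
study reports a significant B excess but not the means themselves.
Structural defaults the source leaves open: 20 genes per chromosome
(a desk-scale count keeping the default genome near 2.5 Mb), coding
genes of 2–4 exons with a 110–200-codon CDS plus UTRs (so every mRNA
clears the 100-aa ORF cutoff, as real mRNAs would), lncRNA genes of
300–600 bp with any ≥100-aa ORF broken by planted stops, introns of
60–240 bp, negative-binomial dispersion 0.3, and 15% organ-restricted
transcripts. Replicate count defaults to 3 per organ (27 libraries
over nine organs).

Coding sequences are written into the genome as ATG + stop-free
codons + stop, flanked by UTRs; every isoform's CDS is then re-derived
from the longest ORF of its own spliced sequence, so structural
variants genuinely change the encoded protein. Alternative isoforms
of coding genes are re-drawn (up to 10 attempts) until they retain a
>100-aa ORF — otherwise the variant would contradict the planted
"coding" label and leak into the lncRNA set — with a pure 3'UTR trim
as the guaranteed fallback. CircRNAs are planted intronic (70%) or at
exact exon boundaries, with a quarter given only a single supporting
read so the read filter always has true negatives. Editing decoys
violating each filter branch — low coverage, low frequency, DNA
variant, multi-allelic, single replicate, missing DNA — are always
planted, so every negative path of the caller is exercised in every
generated dataset.

What the generator does *not* emulate: read-level sequencing noise,
alignment artifacts, GC or length biases, isoform-level expression
correlation structure, paralogy beyond the 1:1 homoeolog layout, and
realistic intergenic content. Passing tests therefore demonstrate that
the *operations* are correct on data satisfying their stated
assumptions, not that the upstream alignment-dependent steps (out of
scope here) would behave on real libraries.

# Verification strategy and problem sizes

Every non-trivial operation is checked against an independently coded
oracle at small scale: the ORF finder against a codon-walking
three-frame scan (1,000 random sequences up to 3 kb), the RC matcher
against an exhaustive all-window scan (100 random pairs up to 200 bp,
one fifth with planted complements), the AS event typer against an
exhaustive pairwise exon-presence comparison on genes with ≤ 6 exons,
the editing caller against a row-by-row rule evaluation on a
~1,000-site panel with all decoy classes present, the Yates χ² against
the closed-form corrected statistic, the small-sample Wilcoxon against
full rank enumeration, and the hypergeometric overlap test against
direct combinatorial summation on a small universe.

Parameter recovery uses two frozen designs. Under the null (all
asymmetry knobs equal, 200 genes per subgenome — large enough that the
χ² asymptotics are sound) the AS contrast is run over 200 seeds and
its rejection count is required to sit inside the central 95% binomial
band around α = 0.05. Under a 1.3× B excess in AS incidence
(0.40 vs 0.52) with 2,000 genes per subgenome, the contrast must flag
the excess (p < 0.01, B > A) in at least 95 of 100 seeds. These sizes
were chosen once, as the smallest designs that make the calibration
and power statements meaningful.

# Known limitations

* The RC matcher's seed step can in principle miss marginal matches
  (see above); the contract is exact on seeded diagonals.
* The AS typology is a five-type simplification; complex nested events
  are reported through their pairwise components rather than a
  composite event code, and event counts are per deduplicated genomic
  interval, not per isoform pair.
* The editing caller assumes pileups are pre-filtered for multi-mapping
  reads and does not model strand-specific libraries.
* Enrichment takes the gene→term map as given: no term-hierarchy
  propagation.
* The generator's homoeolog layout is strictly 1:1 and collinear;
  inversions and translocations only enter through the synteny
  chainer's antiparallel mode, not through the generator.
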