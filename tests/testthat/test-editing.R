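# The editing filter cascade, substitution typing, coding consequences
# and genic-region enrichment.

three_libs <- tibble::tibble(library = c("o1_r1", "o1_r2", "o1_r3"),
                             organ = "o1", replicate = 1:3)

pile_row <- function(chrom, pos, ref, counts, library) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                 A = counts[1], C = counts[2], G = counts[3],
                 T = counts[4], library = library)
}

test_that("each filter branch rejects its decoy and boundaries are
          inclusive", {
  dna_ok <- pile_row("c1", 1, "A", c(30L, 0L, 0L, 0L), "dna")
  # coverage 9 with high frequency: rejected
  rna_lowcov <- bind_rows(lapply(three_libs$library, function(l)
    pile_row("c1", 1, "A", c(5L, 0L, 4L, 0L), l)))
  expect_equal(nrow(call_editing_sites(rna_lowcov, dna_ok, three_libs)),
               0)
  # coverage 20, frequency exactly 0.10, two replicates: called
  rna_boundary <- bind_rows(
    pile_row("c1", 1, "A", c(18L, 0L, 2L, 0L), "o1_r1"),
    pile_row("c1", 1, "A", c(18L, 0L, 2L, 0L), "o1_r2"),
    pile_row("c1", 1, "A", c(20L, 0L, 0L, 0L), "o1_r3")
  )
  got <- call_editing_sites(rna_boundary, dna_ok, three_libs)
  expect_equal(nrow(got), 1)
  expect_equal(got$frequency, 4 / 40)
  expect_equal(got$n_replicates, 2L)
  # DNA with one alternative read: rejected
  dna_var <- pile_row("c1", 1, "A", c(29L, 0L, 1L, 0L), "dna")
  expect_equal(nrow(call_editing_sites(rna_boundary, dna_var,
                                       three_libs)), 0)
  # DNA coverage 9: rejected
  dna_low <- pile_row("c1", 1, "A", c(9L, 0L, 0L, 0L), "dna")
  expect_equal(nrow(call_editing_sites(rna_boundary, dna_low,
                                       three_libs)), 0)
  # multi-allelic replicates: rejected
  rna_multi <- bind_rows(lapply(three_libs$library, function(l)
    pile_row("c1", 1, "A", c(20L, 5L, 5L, 0L), l)))
  expect_equal(nrow(call_editing_sites(rna_multi, dna_ok, three_libs)),
               0)
  # replicates disagreeing on the alternative base: rejected
  rna_disagree <- bind_rows(
    pile_row("c1", 1, "A", c(15L, 0L, 5L, 0L), "o1_r1"),
    pile_row("c1", 1, "A", c(15L, 5L, 0L, 0L), "o1_r2"),
    pile_row("c1", 1, "A", c(20L, 0L, 0L, 0L), "o1_r3")
  )
  expect_equal(nrow(call_editing_sites(rna_disagree, dna_ok,
                                       three_libs)), 0)
  # site absent from the DNA pileup is skipped with a message
  expect_message(
    out <- call_editing_sites(rna_boundary,
                              pile_row("c1", 99, "A",
                                       c(30L, 0L, 0L, 0L), "dna"),
                              three_libs),
    "absent from DNA")
  expect_equal(nrow(out), 0)
})

test_that("the caller equals the brute-force rule evaluation on the
          simulated decoy panel", {
  cfg <- tiny_config(seed = 71, edit_rate_A = 3, edit_rate_B = 3)
  a <- simulate_annotation(simulate_genome(cfg), cfg)
  e <- simulate_expression(a$annotation, cfg)
  ev <- simulate_events(a$genome, a$annotation, cfg, e$samples)
  suppressMessages(
    got <- call_editing_sites(ev$rna_pileups, ev$dna_pileup,
                              ev$libraries))
  want <- editing_brute(ev$rna_pileups, ev$dna_pileup, ev$libraries)
  got_k <- paste(got$chrom, got$pos, got$organ, got$edited)
  want_k <- paste(want$chrom, want$pos, want$organ, want$edited)
  expect_setequal(got_k, want_k)
  m <- match(want_k, got_k)
  expect_equal(got$frequency[m], want$frequency)
  expect_equal(got$n_replicates[m], want$n_replicates)
})

test_that("substitution types are strand-corrected", {
  ex <- bind_rows(
    ex_rows("p.t1", "p", "c1", "+", 101, 200),
    ex_rows("m.t1", "m", "c1", "-", 301, 400)
  )
  ann <- annotation_set(ex)
  sites <- tibble::tibble(
    chrom = "c1", pos = c(150L, 350L, 900L),
    ref = c("A", "T", "C"), edited = c("G", "C", "T")
  )
  got <- substitution_type(sites, ann)
  expect_equal(got$type, c("A-to-G", "A-to-G", "C-to-T"))
  expect_false(any(got$ambiguous_strand))
  # opposite-strand gene overlap flags and duplicates the site
  ex2 <- bind_rows(ex, ex_rows("q.t1", "q", "c1", "-", 101, 200))
  got2 <- substitution_type(sites[1, ], annotation_set(ex2))
  expect_equal(nrow(got2), 2)
  expect_true(all(got2$ambiguous_strand))
  expect_setequal(got2$type, c("A-to-G", "T-to-C"))
})

test_that("coding consequences follow the codon table", {
  # + strand gene: CDS = ATG CTA TAA at 1..9
  genome <- c(c1 = "ATGCTATAACCCCC")
  ex <- ex_rows("t1", "g1", "c1", "+", 1, 14)
  cds <- ex_rows("t1", "g1", "c1", "+", 1, 9)
  ann <- annotation_set(ex, cds)
  # third position of codon 2: CTA(Leu) -> CTG(Leu): synonymous
  s1 <- tibble::tibble(chrom = "c1", pos = 6L, ref = "A", edited = "G")
  expect_equal(editing_consequence(s1, ann, genome)$consequence,
               "synonymous")
  # first position of codon 1: ATG -> GTG: nonsynonymous
  s2 <- tibble::tibble(chrom = "c1", pos = 1L, ref = "A", edited = "G")
  expect_equal(editing_consequence(s2, ann, genome)$consequence,
               "nonsynonymous")
  # reference mismatch triggers the phase error
  s3 <- tibble::tibble(chrom = "c1", pos = 1L, ref = "C", edited = "G")
  expect_error(editing_consequence(s3, ann, genome), "phase")
})

test_that("random CDS edits match a codon-table oracle, both strands", {
  set.seed(72)
  cfg <- tiny_config(seed = 72)
  ds <- simulate_annotation(simulate_genome(cfg), cfg)
  ann <- ds$annotation
  genome <- ds$genome
  cds <- ann$cds
  picks <- cds[sample(nrow(cds), 50, replace = TRUE), ]
  pos <- picks$start + vapply(seq_len(nrow(picks)), function(i)
    sample(0:(picks$end[i] - picks$start[i]), 1), integer(1))
  ref <- substring(genome[picks$chrom], pos, pos)
  edited <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  sites <- tibble::tibble(chrom = picks$chrom, pos = as.integer(pos),
                          ref = unname(ref), edited = unname(edited))
  got <- editing_consequence(sites, ann, genome)$consequence
  # oracle: rebuild each transcript CDS, substitute, translate fully
  oracle <- vapply(seq_len(nrow(sites)), function(i) {
    txs <- cds$transcript_id[cds$chrom == sites$chrom[i] &
                               cds$start <= sites$pos[i] &
                               cds$end >= sites$pos[i]]
    txid <- sort(txs)[1]
    iv <- cds[cds$transcript_id == txid, ]
    iv <- iv[order(iv$start), ]
    seq_ref <- paste(substring(genome[[iv$chrom[1]]], iv$start, iv$end),
                     collapse = "")
    chrom_mut <- genome[[iv$chrom[1]]]
    substr(chrom_mut, sites$pos[i], sites$pos[i]) <- sites$edited[i]
    seq_alt <- paste(substring(chrom_mut, iv$start, iv$end),
                     collapse = "")
    if (iv$strand[1] == "-") {
      seq_ref <- revcomp(seq_ref); seq_alt <- revcomp(seq_alt)
    }
    p_ref <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seq_ref)))
    p_alt <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seq_alt)))
    if (p_ref == p_alt) "synonymous" else "nonsynonymous"
  }, character(1))
  expect_equal(got, oracle)
})

test_that("region enrichment recovers planted folds and a uniform null", {
  cfg <- tiny_config(seed = 73)
  ds <- simulate_annotation(simulate_genome(cfg), cfg)
  genome <- ds$genome
  ann <- ds$annotation
  # uniform null: sites everywhere -> folds near 1
  set.seed(73)
  glen <- nchar(genome)
  chroms <- sample(names(genome), 4000, TRUE)
  pos <- vapply(chroms, function(ch) sample(glen[[ch]], 1), integer(1))
  null_sites <- tibble::tibble(chrom = chroms, pos = as.integer(pos))
  enr <- region_enrichment(null_sites, ann, genome)
  big <- enr[enr$feature_bp > 0.02 * sum(nchar(genome)), ]
  expect_true(all(abs(big$fold - 1) < 0.35))
  # all sites in lncRNA exons: fold equals 1 / genome fraction
  lnc_genes <- ann$genes$gene_id[ann$genes$biotype == "noncoding"]
  lex <- ann$exons[ann$exons$gene_id %in% lnc_genes, ]
  stopifnot(nrow(lex) > 0)
  lnc_sites <- tibble::tibble(
    chrom = rep(lex$chrom, 2),
    pos = as.integer(c(lex$start, pmin(lex$start + 5, lex$end))))
  enr2 <- region_enrichment(lnc_sites, ann, genome)
  row <- enr2[enr2$feature == "lncRNA", ]
  expect_equal(row$site_fraction, 1)
  expect_equal(row$fold, 1 / row$genome_fraction)
  expect_lt(row$p_value, 1e-10)
})
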