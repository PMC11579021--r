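# Contracts of the synthetic-data generator: naming, determinism,
# planted-feature recovery, and the configured asymmetries.

test_that("genome naming mirrors the paired karyotype", {
  cfg <- simulate_config(n_chrom_per_subgenome = 2, genes_per_chrom = 2,
                         n_unanchored = 1, seed = 1)
  g <- simulate_genome(cfg)
  expect_equal(names(g$genome), c("A1", "A2", "B1", "B2", "scaf1"))
  expect_equal(g$chrom_table$subgenome,
               c("A", "A", "B", "B", "unanchored"))
  cfg25 <- simulate_config(n_chrom_per_subgenome = 25,
                           genes_per_chrom = 1, n_unanchored = 0,
                           seed = 1)
  g25 <- simulate_genome(cfg25)
  expect_length(g25$genome, 50)
  expect_equal(names(g25$genome)[c(1, 25, 26, 50)],
               c("A1", "A25", "B1", "B25"))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 13)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$annotation$exons, d2$annotation$exons)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$bsj, d2$bsj)
  expect_identical(d1$rna_pileups, d2$rna_pileups)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genome(d1$genome, f1); write_genome(d2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the data
  d3 <- simulate_dataset(tiny_config(seed = 14))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_config(p_as_A = 1.4), "probability")
  expect_error(simulate_config(circ_rate_B = -1), "non-negative")
  expect_error(simulate_config(n_organs = 1), "n_organs")
})

test_that("AS flags follow the configured probabilities exactly at the
          boundaries and within binomial bounds otherwise", {
  cfg0 <- simulate_config(n_chrom_per_subgenome = 2, genes_per_chrom = 25,
                          n_unanchored = 0, p_as_A = 0, p_as_B = 0,
                          seed = 2)
  a0 <- simulate_annotation(simulate_genome(cfg0), cfg0)
  expect_true(all(a0$truth$n_isoforms == 1))
  cfg1 <- simulate_config(n_chrom_per_subgenome = 2, genes_per_chrom = 50,
                          n_unanchored = 0, p_as_A = 0, p_as_B = 1,
                          seed = 2)
  a1 <- simulate_annotation(simulate_genome(cfg1), cfg1)
  tr <- a1$truth
  expect_true(all(tr$is_as[tr$subgenome == "B"]))
  expect_false(any(tr$is_as[tr$subgenome == "A"]))
  expect_setequal(
    detect_as_genes(a1$annotation)$gene_id[
      detect_as_genes(a1$annotation)$is_as],
    tr$gene_id[tr$is_as])
  # binomial 3-sigma oracle on the default asymmetry
  cfg2 <- simulate_config(n_chrom_per_subgenome = 5, genes_per_chrom = 60,
                          n_unanchored = 0, seed = 3)
  a2 <- simulate_annotation(simulate_genome(cfg2), cfg2)
  nb <- sum(a2$truth$subgenome == "B")
  xb <- sum(a2$truth$is_as[a2$truth$subgenome == "B"])
  p <- cfg2$p_as_B
  expect_lt(abs(xb - nb * p), 3 * sqrt(nb * p * (1 - p)) + 1)
})

test_that("expression layer honours restriction, dispersion and TPM
          normalisation", {
  cfg <- tiny_config(seed = 4, tissue_specificity_mix = 1)
  a <- simulate_annotation(simulate_genome(cfg), cfg)
  e <- simulate_expression(a$annotation, cfg)
  per_organ <- e$expression %>%
    dplyr::inner_join(e$samples, by = "sample") %>%
    dplyr::group_by(feature_id, organ) %>%
    dplyr::summarise(tot = sum(count), .groups = "drop") %>%
    dplyr::group_by(feature_id) %>%
    dplyr::summarise(n_on = sum(tot > 0), .groups = "drop")
  expect_true(all(per_organ$n_on == 1))
  # dispersion 0: replicates identical within an organ
  cfg0 <- tiny_config(seed = 4, expr_dispersion = 0,
                      tissue_specificity_mix = 0)
  e0 <- simulate_expression(a$annotation, cfg0)
  spread <- e0$expression %>%
    dplyr::inner_join(e0$samples, by = "sample") %>%
    dplyr::group_by(feature_id, organ) %>%
    dplyr::summarise(d = diff(range(count)), .groups = "drop")
  expect_true(all(spread$d == 0))
  # TPM columns sum to 1e6
  sums <- e0$expression %>%
    dplyr::group_by(sample) %>%
    dplyr::summarise(s = sum(tpm), .groups = "drop")
  expect_true(all(abs(sums$s - 1e6) < 1e-6 * 1e6))
})

test_that("planted circRNAs follow the configured subgenome excess", {
  # Poisson oracle: with rates 0.5 vs 1.0 over 40 genes per subgenome,
  # the planted B count exceeds A with probability ~0.98 per seed
  wins <- 0L
  for (s in 1:10) {
    cfg <- simulate_config(n_chrom_per_subgenome = 2, genes_per_chrom = 20,
                           n_unanchored = 0, circ_rate_A = 0.5,
                           circ_rate_B = 1.0, edit_rate_A = 0,
                           edit_rate_B = 0, seed = s)
    a <- simulate_annotation(simulate_genome(cfg), cfg)
    e <- simulate_expression(a$annotation, cfg)
    ev <- simulate_events(a$genome, a$annotation, cfg, e$samples)
    n_a <- sum(ev$truth$circ$subgenome == "A")
    n_b <- sum(ev$truth$circ$subgenome == "B")
    wins <- wins + (n_b > n_a)
  }
  expect_gte(wins, 8)
})

test_that("event generation plants recoverable editing sites and decoys
          for every filter branch", {
  cfg <- tiny_config(seed = 6, edit_rate_A = 2, edit_rate_B = 2)
  a <- simulate_annotation(simulate_genome(cfg), cfg)
  e <- simulate_expression(a$annotation, cfg)
  ev <- simulate_events(a$genome, a$annotation, cfg, e$samples)
  tr <- ev$truth$edit
  expect_true(all(c("low_coverage", "low_frequency", "dna_variant",
                    "multi_allelic", "single_replicate", "no_dna") %in%
                    tr$decoy_class[!is.na(tr$decoy_class)]))
  suppressMessages(
    called <- call_editing_sites(ev$rna_pileups, ev$dna_pileup,
                                 ev$libraries))
  called_key <- unique(paste(called$chrom, called$pos))
  decoy_key <- paste(tr$chrom, tr$pos)[!is.na(tr$decoy_class)]
  planted_key <- paste(tr$chrom, tr$pos)[is.na(tr$decoy_class)]
  expect_length(intersect(called_key, decoy_key), 0)
  expect_true(all(called_key %in% planted_key))
  expect_gt(length(called_key) / length(planted_key), 0.8)
  # switching off editing yields no calls
  cfg0 <- tiny_config(seed = 6, edit_rate_A = 0, edit_rate_B = 0)
  a0 <- simulate_annotation(simulate_genome(cfg0), cfg0)
  e0 <- simulate_expression(a0$annotation, cfg0)
  ev0 <- simulate_events(a0$genome, a0$annotation, cfg0, e0$samples)
  suppressMessages(
    called0 <- call_editing_sites(ev0$rna_pileups, ev0$dna_pileup,
                                  ev0$libraries))
  expect_equal(nrow(called0), 0)
})

test_that("a planted clean site is recovered exactly by the caller", {
  libs <- tibble::tibble(library = c("o1_r1", "o1_r2", "o1_r3"),
                         organ = "o1", replicate = 1:3)
  rna <- tibble::tibble(
    chrom = "A1", pos = 100L, ref = "A",
    A = 10L, C = 0L, G = 10L, T = 0L,
    library = libs$library
  )
  dna <- tibble::tibble(chrom = "A1", pos = 100L, ref = "A",
                        A = 30L, C = 0L, G = 0L, T = 0L,
                        library = "dna")
  got <- call_editing_sites(rna, dna, libs)
  expect_equal(nrow(got), 1)
  expect_equal(got$edited, "G")
  expect_equal(got$frequency, 0.5)
  expect_equal(got$n_replicates, 3L)
})

test_that("ground truth is closed: every planted feature resolves to a
          generated record", {
  cfg <- tiny_config(seed = 8)
  ds <- simulate_dataset(cfg)
  # genes
  expect_setequal(ds$truth$genes$gene_id, ds$annotation$genes$gene_id)
  # homoeolog partner map is a bijection on paired genes
  p <- ds$truth$genes$homoeolog_partner
  paired <- ds$truth$genes$gene_id[!is.na(p)]
  expect_setequal(stats::na.omit(p), paired)
  back <- ds$truth$genes$homoeolog_partner[
    match(stats::na.omit(p), ds$truth$genes$gene_id)]
  expect_equal(back, paired)
  # circRNAs all map to generated BSJ rows
  if (nrow(ds$truth$circ)) {
    k_truth <- with(ds$truth$circ, paste(chrom, start, end, strand))
    k_bsj <- with(ds$bsj, paste(chrom, start, end, strand))
    expect_true(all(k_truth %in% k_bsj))
    expect_true(all(k_bsj %in% k_truth))
  }
  # editing truth rows all have pileup evidence
  k_edit <- with(ds$truth$edit, paste(chrom, pos))
  k_rna <- with(ds$rna_pileups, paste(chrom, pos))
  expect_true(all(k_edit %in% k_rna))
  expect_setequal(k_rna, k_edit)
  # dataset writer emits all files
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genome.fa", "annotation.gtf", "chromosomes.tsv",
      "homoeolog_pairs.tsv", "expression.tsv", "samples.tsv",
      "bsj.tsv", "rna_pileups.tsv", "dna_pileup.tsv",
      "ground_truth.json")))))
  # BSJ round trip through the BED-like 0-based file
  back_bsj <- read_bsj(file.path(dir, "bsj.tsv"))
  expect_equal(back_bsj$start, ds$bsj$start)
})
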