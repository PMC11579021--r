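# One-call generation of the complete synthetic dataset, plus writers
# for the on-disk exchange formats.

#' Generate the complete synthetic allotetraploid dataset
#'
#' Runs [simulate_genome()], [simulate_annotation()],
#' [simulate_expression()] and [simulate_events()] in sequence. Each
#' stage draws from its own seed stream derived from the master seed,
#' so the whole dataset is reproducible and regenerating one family
#' does not perturb the others.
#'
#' @param config A [simulate_config()].
#' @return List with `config`, `genome`, `chrom_table`, `annotation`,
#'   `pairs`, `expression`, `samples`, `bsj`, `rna_pileups`,
#'   `dna_pileup`, `libraries` and `truth` (list: `genes`, `pairs`,
#'   `expression`, `circ`, `edit`).
#' @export
simulate_dataset <- function(config = simulate_config()) {
  g <- simulate_genome(config)
  a <- simulate_annotation(g, config)
  e <- simulate_expression(a$annotation, config)
  ev <- simulate_events(a$genome, a$annotation, config, e$samples)
  list(
    config = config,
    genome = a$genome,
    chrom_table = g$chrom_table,
    annotation = a$annotation,
    pairs = a$pairs,
    expression = e$expression,
    samples = e$samples,
    bsj = ev$bsj,
    rna_pileups = ev$rna_pileups,
    dna_pileup = ev$dna_pileup,
    libraries = ev$libraries,
    truth = list(genes = a$truth, pairs = a$pairs,
                 expression = e$truth,
                 circ = ev$truth$circ, edit = ev$truth$edit)
  )
}

#' Write a synthetic dataset to a directory
#'
#' Emits the standard exchange formats: genome FASTA, annotation GTF
#' (1-based inclusive), chromosome/homoeolog/expression/sample TSVs,
#' BSJ table as 0-based half-open BED-like TSV, pileup TSVs, and the
#' ground truth as JSON.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(dataset$genome, file.path(dir, "genome.fa"))
  write_gtf(dataset$annotation, file.path(dir, "annotation.gtf"))
  write_tsv_plain(dataset$chrom_table, file.path(dir, "chromosomes.tsv"))
  write_tsv_plain(dataset$pairs, file.path(dir, "homoeolog_pairs.tsv"))
  write_tsv_plain(dataset$expression, file.path(dir, "expression.tsv"))
  write_tsv_plain(dataset$samples, file.path(dir, "samples.tsv"))
  bsj_bed <- dataset$bsj %>% mutate(start = .data$start - 1L)
  write_tsv_plain(bsj_bed, file.path(dir, "bsj.tsv"))
  write_tsv_plain(dataset$rna_pileups, file.path(dir, "rna_pileups.tsv"))
  write_tsv_plain(dataset$dna_pileup, file.path(dir, "dna_pileup.tsv"))
  jsonlite::write_json(dataset$truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
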