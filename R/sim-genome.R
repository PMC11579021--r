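# Synthetic genome: uniform random bases over paired chromosomes
# (A1..An / B1..Bn) plus unanchored scaffolds.

random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

#' Generate the synthetic genome
#'
#' Chromosomes are named `A1..An` and `B1..Bn` (mirroring the paired
#' karyotype of an allotetraploid with parallel subgenome structure)
#' plus `scaf1..scafk` unanchored scaffolds. Sequences are uniform
#' random bases; each chromosome reserves one fixed-size slot per gene
#' for the annotation stage. Deterministic given the config seed.
#'
#' @param config A [simulate_config()] object.
#' @return List with `genome` (named character vector) and `chrom_table`
#'   (tibble `chrom`, `length`, `subgenome`).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  nc <- config$n_chrom_per_subgenome
  chrom_len <- config$genes_per_chrom * config$slot_bp + 200L
  scaf_len <- config$genes_per_unanchored * config$slot_bp + 200L
  chroms <- c(paste0("A", seq_len(nc)), paste0("B", seq_len(nc)),
              if (config$n_unanchored > 0)
                paste0("scaf", seq_len(config$n_unanchored)))
  lens <- c(rep(chrom_len, 2L * nc),
            rep(scaf_len, config$n_unanchored))
  genome <- setNames(vapply(lens, random_dna, character(1)), chroms)
  chrom_table <- tibble::tibble(
    chrom = chroms,
    length = lens,
    subgenome = c(rep("A", nc), rep("B", nc),
                  rep("unanchored", config$n_unanchored))
  )
  list(genome = genome, chrom_table = chrom_table)
}
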