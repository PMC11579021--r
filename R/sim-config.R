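# Configuration for the synthetic two-subgenome dataset.

#' Configuration for the synthetic allotetraploid dataset
#'
#' Defaults emulate the study design the package targets: two parallel
#' subgenomes of 25 chromosomes each (A1..A25, B1..B25) plus unanchored
#' scaffolds, nine organs with three RNA-seq replicates, and a modest
#' B-subgenome excess in every event type (AS incidence, lncRNA
#' incidence, circRNA rate, editing rate and substitution frequency).
#' Structural parameters are identical across subgenomes; only the
#' stated asymmetry knobs differ.
#'
#' @param n_chrom_per_subgenome Chromosomes per subgenome (default 25).
#' @param genes_per_chrom Genes per chromosome (default 20).
#' @param n_unanchored Unanchored scaffolds (default 2).
#' @param genes_per_unanchored Genes per scaffold (default 4).
#' @param n_organs Number of organs (default 9, >= 2).
#' @param n_replicates RNA-seq replicates per organ (default 3).
#' @param p_as_A,p_as_B Probability a gene is multi-isoform.
#' @param p_lnc_A,p_lnc_B Probability a gene is a lncRNA gene.
#' @param circ_rate_A,circ_rate_B Expected circRNAs per gene.
#' @param edit_rate_A,edit_rate_B Expected editing sites per gene.
#' @param edit_freq_A,edit_freq_B Mean substitution frequency of planted
#'   editing sites.
#' @param expr_dispersion Negative-binomial dispersion of counts (0 =
#'   noise-free).
#' @param tissue_specificity_mix Fraction of transcripts restricted to a
#'   single organ.
#' @param seed Master seed; every output family derives its own stream
#'   from it.
#' @return A `sim_config` list.
#' @export
simulate_config <- function(n_chrom_per_subgenome = 25,
                            genes_per_chrom = 20,
                            n_unanchored = 2,
                            genes_per_unanchored = 4,
                            n_organs = 9,
                            n_replicates = 3,
                            p_as_A = 0.512, p_as_B = 0.536,
                            p_lnc_A = 0.09, p_lnc_B = 0.11,
                            circ_rate_A = 0.034, circ_rate_B = 0.048,
                            edit_rate_A = 3.2, edit_rate_B = 3.44,
                            edit_freq_A = 0.25, edit_freq_B = 0.30,
                            expr_dispersion = 0.3,
                            tissue_specificity_mix = 0.15,
                            seed = 1L) {
  cfg <- list(
    n_chrom_per_subgenome = as.integer(n_chrom_per_subgenome),
    genes_per_chrom = as.integer(genes_per_chrom),
    n_unanchored = as.integer(n_unanchored),
    genes_per_unanchored = as.integer(genes_per_unanchored),
    n_organs = as.integer(n_organs),
    n_replicates = as.integer(n_replicates),
    p_as_A = p_as_A, p_as_B = p_as_B,
    p_lnc_A = p_lnc_A, p_lnc_B = p_lnc_B,
    circ_rate_A = circ_rate_A, circ_rate_B = circ_rate_B,
    edit_rate_A = edit_rate_A, edit_rate_B = edit_rate_B,
    edit_freq_A = edit_freq_A, edit_freq_B = edit_freq_B,
    expr_dispersion = expr_dispersion,
    tissue_specificity_mix = tissue_specificity_mix,
    seed = as.integer(seed),
    slot_bp = 2000L               # genomic slot reserved per gene
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (p in c("p_as_A", "p_as_B", "p_lnc_A", "p_lnc_B",
              "tissue_specificity_mix",
              "edit_freq_A", "edit_freq_B")) {
    assert_prob(cfg[[p]], p)
  }
  for (p in c("circ_rate_A", "circ_rate_B", "edit_rate_A", "edit_rate_B",
              "expr_dispersion")) {
    assert_nonneg(cfg[[p]], p)
  }
  if (cfg$n_organs < 2) stop("n_organs must be >= 2")
  if (cfg$n_chrom_per_subgenome < 1) stop("need >= 1 chromosome")
  if (cfg$genes_per_chrom < 1) stop("need >= 1 gene per chromosome")
  if (cfg$n_replicates < 1) stop("need >= 1 replicate")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_chrom_per_subgenome, " chrom/subgenome x ",
      x$genes_per_chrom, " genes, ", x$n_organs, " organs x ",
      x$n_replicates, " reps, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

organ_names <- function(n) {
  base <- c("brain", "gill", "heart", "intestine", "kidney",
            "liver", "muscle", "skin", "spleen")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("organ", seq_len(n - length(base))))
}
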