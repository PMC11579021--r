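# Synthetic expression: negative-binomial counts around gene base levels
# with a configurable fraction of organ-restricted transcripts, plus the
# TPM layer.

#' Generate the synthetic expression matrix
#'
#' Per-transcript means are gene base level x transcript share x organ
#' factor; a `tissue_specificity_mix` fraction of transcripts is
#' restricted to one organ (zero elsewhere, at least one count in the
#' home organ). Counts are negative-binomial with dispersion
#' `expr_dispersion` (0 gives deterministic, replicate-identical
#' counts). The TPM layer is computed by [tpm()] with spliced transcript
#' lengths, so per-sample TPM columns sum to 1e6.
#'
#' @param annotation An [annotation_set()] from [simulate_annotation()].
#' @param config A [simulate_config()].
#' @return List: `expression` (long tibble `feature_id`, `sample`,
#'   `count`, `tpm`), `samples` (tibble `sample`, `organ`, `replicate`,
#'   `mapped_reads`), `truth` (tibble `feature_id`, `restricted`,
#'   `home_organ`).
#' @export
simulate_expression <- function(annotation, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "expression"))
  organs <- organ_names(config$n_organs)
  samples <- tidyr::expand_grid(organ = organs,
                                replicate = seq_len(config$n_replicates)) %>%
    mutate(sample = paste0(.data$organ, "_r", .data$replicate),
           mapped_reads = round(2e6 * exp(rnorm(n(), 0, 0.1)))) %>%
    select("sample", "organ", "replicate", "mapped_reads")

  tx <- annotation$transcripts
  genes <- unique(tx$gene_id)
  base_level <- setNames(rlnorm(length(genes), log(100), 1), genes)
  share <- rgamma(nrow(tx), shape = 1.5, rate = 1)
  tx_mu <- base_level[tx$gene_id] * share /
    stats::ave(share, tx$gene_id, FUN = sum)

  n_tx <- nrow(tx)
  restricted <- runif(n_tx) < config$tissue_specificity_mix
  home <- sample(organs, n_tx, replace = TRUE)
  # organ factor matrix (transcripts x organs)
  fac <- matrix(exp(rnorm(n_tx * length(organs), 0, 0.3)),
                nrow = n_tx)
  colnames(fac) <- organs
  for (o in organs) {
    fac[restricted & home != o, o] <- 0
    fac[restricted & home == o, o] <- 1
  }

  grid <- tidyr::expand_grid(
    idx = seq_len(n_tx),
    sample = samples$sample
  ) %>%
    mutate(feature_id = tx$transcript_id[.data$idx],
           organ = samples$organ[match(.data$sample, samples$sample)],
           mu = tx_mu[.data$idx] * fac[cbind(.data$idx,
                                             match(.data$organ, organs))])
  if (config$expr_dispersion == 0) {
    grid$count <- round(grid$mu)
  } else {
    grid$count <- rnbinom(nrow(grid), mu = grid$mu,
                          size = 1 / config$expr_dispersion)
  }
  # restricted transcripts are guaranteed detectable in the home organ
  home_cell <- restricted[grid$idx] & grid$organ == home[grid$idx]
  grid$count[home_cell] <- pmax(grid$count[home_cell], 1)

  lens <- transcript_lengths(annotation)
  expression <- grid %>%
    select("feature_id", "sample", "count") %>%
    tpm(setNames(lens$length, lens$transcript_id))

  truth <- tibble::tibble(feature_id = tx$transcript_id,
                          restricted = restricted,
                          home_organ = if_else(restricted, home,
                                               NA_character_))
  list(expression = expression, samples = samples, truth = truth)
}
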