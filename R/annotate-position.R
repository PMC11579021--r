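# Genic-feature labelling of genomic intervals, shared by the lncRNA
# target-distribution and RNA-editing stages.

feature_priority <- c(lncRNA = 1, promoter = 2, five_prime_UTR = 3,
                      three_prime_UTR = 4, CDS_exon = 5, intron = 6,
                      downstream = 7, distal_intergenic = 8)

# internal: labelled interval table derived from an annotation_set
feature_intervals <- function(annotation, promoter_window = 3000,
                              downstream_window = 3000) {
  genes <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons
  cds <- annotation$cds

  nc_genes <- genes$gene_id[genes$biotype == "noncoding"]
  lnc <- ex %>%
    dplyr::filter(.data$gene_id %in% nc_genes) %>%
    mutate(label = "lncRNA") %>%
    select("chrom", "start", "end", "label")

  tss <- if_else(genes$strand == "+", genes$start, genes$end)
  tes <- if_else(genes$strand == "+", genes$end, genes$start)
  prom <- tibble::tibble(
    chrom = genes$chrom,
    start = pmax(1L, as.integer(tss - promoter_window)),
    end = as.integer(tss + promoter_window),
    label = "promoter"
  )
  down <- tibble::tibble(
    chrom = genes$chrom,
    start = as.integer(if_else(genes$strand == "+", tes + 1L,
                               pmax(1L, tes - downstream_window))),
    end = as.integer(if_else(genes$strand == "+", tes + downstream_window,
                             pmax(1L, tes - 1L))),
    label = "downstream"
  ) %>% dplyr::filter(.data$start <= .data$end)

  cds_span <- cds %>%
    group_by(.data$transcript_id) %>%
    summarise(cstart = if (n()) min(.data$start) else NA_integer_,
              cend = if (n()) max(.data$end) else NA_integer_,
              .groups = "drop")
  exc <- ex %>%
    select("transcript_id", "chrom", "strand", "start", "end") %>%
    inner_join(cds_span, by = "transcript_id")
  left_part <- exc %>%
    dplyr::filter(.data$start < .data$cstart) %>%
    mutate(end = pmin(.data$end, .data$cstart - 1L),
           label = if_else(.data$strand == "+",
                           "five_prime_UTR", "three_prime_UTR"))
  right_part <- exc %>%
    dplyr::filter(.data$end > .data$cend) %>%
    mutate(start = pmax(.data$start, .data$cend + 1L),
           label = if_else(.data$strand == "+",
                           "three_prime_UTR", "five_prime_UTR"))
  utr <- bind_rows(left_part, right_part) %>%
    select("chrom", "start", "end", "label")

  cds_iv <- cds %>% mutate(label = "CDS_exon") %>%
    select("chrom", "start", "end", "label")
  # exons of coding genes not covered elsewhere still count as CDS/exon
  coding_ex <- ex %>%
    dplyr::filter(.data$gene_id %in% genes$gene_id[genes$biotype == "coding"]) %>%
    mutate(label = "CDS_exon") %>%
    select("chrom", "start", "end", "label")
  gene_iv <- genes %>% mutate(label = "intron") %>%
    select("chrom", "start", "end", "label")

  bind_rows(lnc, prom, utr, cds_iv, coding_ex, gene_iv, down) %>%
    mutate(priority = feature_priority[.data$label])
}

#' Annotate genomic intervals with their genic context
#'
#' Each interval receives exactly one label from
#' promoter, 5'UTR, 3'UTR, CDS/exon, intron, downstream,
#' distal intergenic, lncRNA, resolved by a fixed priority order
#' (lncRNA-exon overlap wins over all genic labels of coding genes;
#' then promoter > 5'UTR > 3'UTR > CDS/exon > intron > downstream;
#' intervals touching nothing are distal intergenic). The promoter is
#' TSS +/- `promoter_window`; downstream extends `downstream_window`
#' past the 3' end.
#'
#' @param sites Tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive; a single position has `start == end`).
#' @param annotation An [annotation_set()].
#' @param promoter_window,downstream_window Window sizes in bp.
#' @return `sites` with an added `feature` column (factor with the eight
#'   levels in priority order).
#' @export
annotate_position <- function(sites, annotation, promoter_window = 3000,
                              downstream_window = 3000) {
  stopifnot(is_annotation_set(annotation),
            all(c("chrom", "start", "end") %in% names(sites)))
  sites <- tibble::as_tibble(sites)
  feats <- feature_intervals(annotation, promoter_window, downstream_window)
  sites$.site_id <- seq_len(nrow(sites))
  hits <- sites %>%
    select(".site_id", "chrom", s_start = "start", s_end = "end") %>%
    inner_join(feats, by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(overlaps1(.data$s_start, .data$s_end,
                            .data$start, .data$end)) %>%
    group_by(.data$.site_id) %>%
    summarise(feature = .data$label[which.min(.data$priority)],
              .groups = "drop")
  out <- sites %>%
    left_join(hits, by = ".site_id") %>%
    mutate(feature = factor(
      if_else(is.na(.data$feature), "distal_intergenic", .data$feature),
      levels = names(feature_priority)
    )) %>%
    select(-".site_id")
  out
}
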