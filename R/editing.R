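# RNA editing from paired RNA/DNA pileups: the filter cascade, the twelve
# strand-corrected substitution types, coding consequences, and
# genic-region enrichment against the genome background.

BASES <- c("A", "C", "G", "T")

# per-row pileup summaries: coverage, the single observed alternative
# base (NA when zero or several), its count and frequency
pileup_alt_summary <- function(pileup) {
  cnt <- as.matrix(pileup[BASES])
  cov <- rowSums(cnt)
  ref_idx <- match(pileup$ref, BASES)
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  alt_mat <- cnt
  alt_mat[cbind(seq_len(nrow(cnt)), ref_idx)] <- 0L
  n_alt_bases <- rowSums(alt_mat > 0)
  top_alt <- max.col(alt_mat, ties.method = "first")
  alt_base <- ifelse(n_alt_bases == 1L, BASES[top_alt], NA_character_)
  alt_count <- ifelse(n_alt_bases == 1L,
                      alt_mat[cbind(seq_len(nrow(cnt)), top_alt)], NA_integer_)
  pileup %>%
    mutate(coverage = cov, ref_count = ref_count,
           n_alt_bases = n_alt_bases, alt_base = alt_base,
           alt_count = alt_count,
           alt_freq = ifelse(cov > 0, alt_count / cov, NA_real_))
}

#' Call RNA-editing sites from paired RNA/DNA pileups
#'
#' A site is called, per organ, when (i) at least `min_replicates` RNA
#' replicates of that organ each have coverage >= `min_cov`, exactly one
#' observed alternative base (unique mutation) and an alternative-base
#' frequency >= `min_freq`; (ii) all supporting replicates agree on the
#' alternative base; and (iii) the DNA library has coverage >= `min_cov`
#' with zero non-reference reads at the site. Sites absent from the DNA
#' pileup are skipped (insufficient DNA evidence).
#'
#' @param rna_pileups Tibble `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `library` for every RNA library.
#' @param dna_pileup Same columns for the single DNA library.
#' @param libraries Tibble `library`, `organ`, `replicate` mapping RNA
#'   libraries to organs.
#' @param min_cov,min_freq,min_replicates Filter thresholds; all
#'   comparisons are inclusive (defaults 10, 0.1, 2).
#' @return Tibble of editing sites: `chrom`, `pos`, `ref`, `edited`,
#'   `organ`, `frequency` (alt reads / total reads pooled over the
#'   supporting replicates), `n_replicates`.
#' @export
call_editing_sites <- function(rna_pileups, dna_pileup, libraries,
                               min_cov = 10, min_freq = 0.1,
                               min_replicates = 2) {
  stopifnot(all(c("chrom", "pos", "ref", BASES, "library") %in%
                  names(rna_pileups)),
            all(c("library", "organ") %in% names(libraries)))
  empty <- tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), edited = character(0),
                          organ = character(0), frequency = double(0),
                          n_replicates = integer(0))
  if (!nrow(rna_pileups)) return(empty)

  dna <- pileup_alt_summary(dna_pileup) %>%
    mutate(dna_ok = .data$coverage >= min_cov &
             .data$coverage == .data$ref_count) %>%
    select("chrom", "pos", "dna_ok")

  rna <- pileup_alt_summary(rna_pileups) %>%
    left_join(libraries, by = "library") %>%
    mutate(supports = .data$coverage >= min_cov &
             .data$n_alt_bases == 1L &
             !is.na(.data$alt_freq) & .data$alt_freq >= min_freq)

  candidates <- rna %>%
    dplyr::filter(.data$supports) %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$organ) %>%
    dplyr::filter(dplyr::n_distinct(.data$alt_base) == 1L) %>%
    summarise(edited = .data$alt_base[1],
              frequency = sum(.data$alt_count) / sum(.data$coverage),
              n_replicates = dplyr::n_distinct(.data$library),
              .groups = "drop") %>%
    dplyr::filter(.data$n_replicates >= min_replicates)
  if (!nrow(candidates)) return(empty)

  merged <- candidates %>% left_join(dna, by = c("chrom", "pos"))
  n_missing <- sum(is.na(merged$dna_ok))
  if (n_missing > 0) {
    message(n_missing,
            " candidate site(s) absent from DNA pileup were skipped")
  }
  merged %>%
    dplyr::filter(!is.na(.data$dna_ok), .data$dna_ok) %>%
    select("chrom", "pos", "ref", "edited", "organ",
           "frequency", "n_replicates") %>%
    arrange(.data$chrom, .data$pos, .data$organ)
}

#' Strand-corrected substitution types
#'
#' Sites inside a gene are typed after complementing reference and edited
#' bases when the gene is on the minus strand; intergenic sites are typed
#' on the plus strand. A site covered by genes on both strands yields one
#' row per strand context, flagged `ambiguous_strand`.
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `edited`.
#' @param annotation An [annotation_set()].
#' @return `sites` with `gene_strand`, `type` (e.g. `"A-to-G"`, one of
#'   the 12 ordered ref-to-alt types) and `ambiguous_strand`.
#' @export
substitution_type <- function(sites, annotation) {
  stopifnot(is_annotation_set(annotation))
  genes <- annotation$genes
  hit <- sites %>%
    mutate(.row = row_number()) %>%
    inner_join(genes %>% select("chrom", g_start = "start",
                                g_end = "end", "strand"),
               by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(.data$pos >= .data$g_start, .data$pos <= .data$g_end) %>%
    distinct(.data$.row, .data$strand)
  strands <- hit %>%
    group_by(.data$.row) %>%
    summarise(n_strands = n(), .groups = "drop")
  out <- sites %>%
    mutate(.row = row_number()) %>%
    left_join(hit, by = ".row", relationship = "many-to-many") %>%
    left_join(strands, by = ".row") %>%
    mutate(gene_strand = if_else(is.na(.data$strand), "+", .data$strand),
           ambiguous_strand = !is.na(.data$n_strands) & .data$n_strands > 1,
           ref_t = if_else(.data$gene_strand == "-",
                           chartr("ACGT", "TGCA", .data$ref), .data$ref),
           alt_t = if_else(.data$gene_strand == "-",
                           chartr("ACGT", "TGCA", .data$edited),
                           .data$edited),
           type = paste0(.data$ref_t, "-to-", .data$alt_t)) %>%
    select(-"strand", -"n_strands", -"ref_t", -"alt_t", -".row")
  out
}

#' Coding consequence of editing sites
#'
#' Sites falling in an annotated CDS are evaluated by substituting the
#' edited base into its codon (strand-corrected) and translating:
#' `synonymous` when the amino acid is unchanged, `nonsynonymous`
#' otherwise. All other sites are labelled via [annotate_position()]
#' (`UTR5`, `UTR3`, `intron`, `lncRNA`, `intergenic`).
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `edited`.
#' @param annotation An [annotation_set()].
#' @param genome Named character vector of chromosome sequences.
#' @return `sites` with a `consequence` column.
#' @export
editing_consequence <- function(sites, annotation, genome) {
  stopifnot(is_annotation_set(annotation))
  sites <- tibble::as_tibble(sites)
  n <- nrow(sites)
  consequence <- rep(NA_character_, n)

  cds <- annotation$cds %>% arrange(.data$transcript_id, .data$start)
  cds_by_tx <- split(cds, cds$transcript_id)

  # covering transcript per site (deterministic: first id)
  cov_hit <- sites %>%
    mutate(.row = row_number()) %>%
    inner_join(cds %>% select("transcript_id", "chrom",
                              c_start = "start", c_end = "end"),
               by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(.data$pos >= .data$c_start, .data$pos <= .data$c_end) %>%
    group_by(.data$.row) %>%
    arrange(.data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  for (k in seq_len(nrow(cov_hit))) {
    i <- cov_hit$.row[k]
    txid <- cov_hit$transcript_id[k]
    iv <- cds_by_tx[[txid]]
    strand <- iv$strand[1]
    # CDS-space offset of the site (1-based, 5'->3')
    widths <- iv$end - iv$start + 1L
    cum <- cumsum(widths)
    seg <- which(iv$start <= sites$pos[i] & sites$pos[i] <= iv$end)[1]
    off_plus <- (if (seg > 1) cum[seg - 1] else 0L) +
      (sites$pos[i] - iv$start[seg] + 1L)
    total <- sum(widths)
    off <- if (strand == "+") off_plus else total - off_plus + 1L
    if (((total %/% 3L) * 3L) < off) {       # incomplete trailing codon
      consequence[i] <- "synonymous"
      next
    }
    codon_idx <- (off - 1L) %/% 3L
    codon_pos <- (off - 1L) %% 3L + 1L
    cds_seq <- cds_sequence(annotation, txid, genome)[[1]]
    codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    ref_b <- sites$ref[i]; alt_b <- sites$edited[i]
    if (strand == "-") {
      ref_b <- chartr("ACGT", "TGCA", ref_b)
      alt_b <- chartr("ACGT", "TGCA", alt_b)
    }
    if (substr(codon, codon_pos, codon_pos) != ref_b) {
      stop("CDS phase inconsistency at ", sites$chrom[i], ":",
           sites$pos[i], " (reference base mismatch)")
    }
    codon_alt <- codon
    substr(codon_alt, codon_pos, codon_pos) <- alt_b
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(codon), no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(codon_alt), no.init.codon = TRUE))
    consequence[i] <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  }

  todo <- which(is.na(consequence))
  if (length(todo)) {
    lab <- annotate_position(
      tibble::tibble(chrom = sites$chrom[todo],
                     start = sites$pos[todo], end = sites$pos[todo]),
      annotation)$feature
    consequence[todo] <- dplyr::recode(as.character(lab),
      five_prime_UTR = "UTR5", three_prime_UTR = "UTR3",
      intron = "intron", lncRNA = "lncRNA",
      .default = "intergenic")
  }
  sites %>% mutate(consequence = consequence)
}

# merged bp extent per feature label, claimed in priority order so the
# labels partition the genome exactly like annotate_position does
feature_extents <- function(annotation, genome, promoter_window = 3000,
                            downstream_window = 3000) {
  feats <- feature_intervals(annotation, promoter_window, downstream_window)
  chroms <- names(genome)
  total <- sum(nchar(genome))
  claimed <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) claimed[[ch]] <- IRanges::IRanges()
  out <- tibble::tibble(feature = names(feature_priority), bp = 0)
  for (lab in names(feature_priority)) {
    if (lab == "distal_intergenic") next
    fl <- feats %>% dplyr::filter(.data$label == lab)
    bp <- 0
    for (ch in intersect(unique(fl$chrom), chroms)) {
      fc <- fl %>% dplyr::filter(.data$chrom == ch)
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1L, fc$start),
        end = pmin(nchar(genome[[ch]]), fc$end)))
      new <- IRanges::setdiff(ir, claimed[[ch]])
      bp <- bp + sum(IRanges::width(new))
      claimed[[ch]] <- IRanges::reduce(IRanges::union(claimed[[ch]], new))
    }
    out$bp[out$feature == lab] <- bp
  }
  out$bp[out$feature == "distal_intergenic"] <- total - sum(out$bp)
  out$genome_fraction <- out$bp / total
  out
}

#' Genic-region enrichment of editing sites
#'
#' Fold enrichment is the fraction of sites in a feature over the
#' fraction of the genome the feature covers (features claimed in the
#' same priority order as [annotate_position()], so labels partition
#' both the sites and the genome). The p-value is the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' in-feature sites when placing all sites uniformly over genome
#' positions.
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param annotation An [annotation_set()].
#' @param genome Named character vector of sequences.
#' @param ... Window sizes passed to the feature partition.
#' @return Tibble `feature`, `n_sites`, `site_fraction`, `feature_bp`,
#'   `genome_fraction`, `fold`, `p_value`. Features with zero genomic
#'   extent are excluded.
#' @export
region_enrichment <- function(sites, annotation, genome, ...) {
  ext <- feature_extents(annotation, genome, ...)
  lab <- annotate_position(
    tibble::tibble(chrom = sites$chrom, start = sites$pos,
                   end = sites$pos),
    annotation, ...)
  counts <- tibble::tibble(feature = as.character(lab$feature)) %>%
    count(.data$feature, name = "n_sites")
  n_total <- nrow(sites)
  genome_bp <- sum(nchar(genome))
  ext %>%
    left_join(counts, by = "feature") %>%
    mutate(n_sites = if_else(is.na(.data$n_sites), 0L, .data$n_sites),
           site_fraction = .data$n_sites / n_total,
           fold = .data$site_fraction / .data$genome_fraction,
           p_value = phyper(.data$n_sites - 1, .data$bp,
                            genome_bp - .data$bp, n_total,
                            lower.tail = FALSE)) %>%
    dplyr::filter(.data$bp > 0) %>%
    select("feature", "n_sites", "site_fraction", feature_bp = "bp",
           "genome_fraction", "fold", "p_value")
}
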