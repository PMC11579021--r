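# Homoeolog pairing by synteny chaining and the subgenome contrast
# battery: chi-squared counts contrasts (Yates-corrected 2x2), Wilcoxon
# distribution contrasts, Spearman correlations, homoeolog event
# overlap, hypergeometric term enrichment and overlap tests, and the
# end-to-end report.

new_contrast <- function(event, test, statistic, p_value, ...) {
  tibble::tibble(event = event, test = test,
                 statistic = unname(statistic),
                 p_value = unname(p_value), ...)
}

#' Chain collinear homolog pairs into synteny blocks
#'
#' Candidate pairs are chained per chromosome pair: a chain extends
#' while ranks progress monotonically on both chromosomes (same
#' direction throughout) with gaps of at most `max_gap` ranks; chains
#' with at least `min_pairs` pairs are kept as synteny blocks and their
#' pairs become homoeolog pairs (each gene in at most one pair).
#'
#' @param homolog_pairs Tibble `gene_a`, `gene_b` of candidate pairs.
#' @param gene_order Tibble `gene_id`, `chrom`, `rank` giving the gene
#'   order along each chromosome.
#' @param min_pairs Minimum pairs per retained block (default 5).
#' @param max_gap Maximum rank gap inside a chain (default 25).
#' @return List with `blocks` (tibble `block_id`, `chrom_a`, `chrom_b`,
#'   `n_pairs`) and `pairs` (tibble `gene_a`, `gene_b`, `block_id`).
#' @export
chain_synteny <- function(homolog_pairs, gene_order, min_pairs = 5,
                          max_gap = 25) {
  missing_g <- setdiff(c(homolog_pairs$gene_a, homolog_pairs$gene_b),
                       gene_order$gene_id)
  if (length(missing_g)) {
    stop("gene(s) absent from order index: ",
         paste(head(missing_g, 5), collapse = ", "))
  }
  ord <- gene_order
  cand <- homolog_pairs %>%
    left_join(ord, by = c(gene_a = "gene_id")) %>%
    rename(chrom_a = "chrom", rank_a = "rank") %>%
    left_join(ord, by = c(gene_b = "gene_id")) %>%
    rename(chrom_b = "chrom", rank_b = "rank") %>%
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)

  blocks <- vector("list", 0)
  for (grp in split(cand, paste(cand$chrom_a, cand$chrom_b))) {
    grp <- arrange(grp, .data$rank_a, .data$rank_b)
    chain <- list(); dir <- 0L
    flush <- function() {
      if (length(chain) >= min_pairs) {
        blocks[[length(blocks) + 1L]] <<- bind_rows(chain)
      }
      chain <<- list(); dir <<- 0L
    }
    for (i in seq_len(nrow(grp))) {
      row <- grp[i, ]
      if (!length(chain)) {
        chain <- list(row)
        next
      }
      prev <- chain[[length(chain)]]
      da <- row$rank_a - prev$rank_a
      db <- row$rank_b - prev$rank_b
      step_dir <- sign(db)
      ok <- da >= 1 && da <= max_gap && abs(db) >= 1 &&
        abs(db) <= max_gap && (dir == 0L || step_dir == dir)
      if (ok) {
        chain <- c(chain, list(row))
        dir <- step_dir
      } else {
        flush()
        chain <- list(row)
      }
    }
    flush()
  }
  if (!length(blocks)) {
    return(list(
      blocks = tibble::tibble(block_id = character(0),
                              chrom_a = character(0),
                              chrom_b = character(0), n_pairs = integer(0)),
      pairs = tibble::tibble(gene_a = character(0), gene_b = character(0),
                             block_id = character(0))
    ))
  }
  # larger blocks claim genes first; each gene in at most one pair
  blocks <- blocks[order(-vapply(blocks, nrow, integer(1)))]
  seen <- character(0)
  pairs_out <- vector("list", 0)
  block_rows <- vector("list", 0)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]] %>%
      dplyr::filter(!.data$gene_a %in% seen, !.data$gene_b %in% seen)
    if (nrow(b) < min_pairs) next
    bid <- sprintf("block_%03d", length(block_rows) + 1L)
    seen <- c(seen, b$gene_a, b$gene_b)
    pairs_out[[length(pairs_out) + 1L]] <-
      tibble::tibble(gene_a = b$gene_a, gene_b = b$gene_b, block_id = bid)
    block_rows[[length(block_rows) + 1L]] <-
      tibble::tibble(block_id = bid, chrom_a = b$chrom_a[1],
                     chrom_b = b$chrom_b[1], n_pairs = nrow(b))
  }
  list(blocks = bind_rows(block_rows), pairs = bind_rows(pairs_out))
}

#' Chi-squared contrast on a 2x2 count table
#'
#' Yates continuity correction, df = 1, two-sided.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = subgenomes, columns = event / no event).
#' @param event Label for the contrast.
#' @return One-row tibble: `event`, `test`, `statistic`, `p_value`.
#' @export
count_contrast <- function(tab, event = "counts") {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  new_contrast(event, "chisq_yates", ct$statistic, ct$p.value,
               n = sum(tab))
}

#' Wilcoxon rank-sum contrast between two samples
#'
#' Exact enumeration when both samples have at most 8 values and no
#' ties; otherwise the tie-corrected normal approximation.
#'
#' @param values_a,values_b Numeric vectors.
#' @param event Label for the contrast.
#' @return One-row tibble: `event`, `test`, `statistic` (W), `p_value`.
#' @export
distribution_contrast <- function(values_a, values_b,
                                  event = "distribution") {
  if (!length(values_a) || !length(values_b)) stop("empty group")
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     exact = exact, correct = FALSE))
  new_contrast(event, "wilcoxon", wt$statistic, wt$p.value,
               n = length(values_a) + length(values_b))
}

#' Spearman rank correlation
#'
#' Ties are mid-ranked; p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param event Label.
#' @return One-row tibble with `statistic` (rho) and `p_value`.
#' @export
spearman_contrast <- function(x, y, event = "correlation") {
  if (length(x) != length(y)) stop("length mismatch")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  new_contrast(event, "spearman", ct$estimate, ct$p.value,
               n = length(x))
}

#' Partition homoeolog pairs by an event flag
#'
#' @param pairs Tibble `gene_a`, `gene_b`.
#' @param event_flags Named logical vector (gene id -> flag) or tibble
#'   `gene_id`, `flag`. Genes without a flag count as `FALSE` (with a
#'   message).
#' @return List with `counts` (both / A_only / B_only / neither),
#'   `percent` (of the pair total) and `rate_A`, `rate_B` (fraction of
#'   pairs whose A- resp. B-side gene carries the event).
#' @export
homoeolog_event_overlap <- function(pairs, event_flags) {
  if (is.data.frame(event_flags)) {
    event_flags <- setNames(event_flags$flag, event_flags$gene_id)
  }
  fa <- event_flags[pairs$gene_a]
  fb <- event_flags[pairs$gene_b]
  n_missing <- sum(is.na(fa)) + sum(is.na(fb))
  if (n_missing) {
    message(n_missing, " paired gene(s) without a flag treated as FALSE")
  }
  fa[is.na(fa)] <- FALSE
  fb[is.na(fb)] <- FALSE
  counts <- c(both = sum(fa & fb), A_only = sum(fa & !fb),
              B_only = sum(!fa & fb), neither = sum(!fa & !fb))
  total <- nrow(pairs)
  list(counts = counts,
       total = total,
       percent = 100 * counts / total,
       rate_A = unname((counts["both"] + counts["A_only"]) / total),
       rate_B = unname((counts["both"] + counts["B_only"]) / total))
}

#' Hypergeometric term enrichment with BH adjustment
#'
#' @param gene_set Character vector of genes of interest.
#' @param gene2term Tibble `gene_id`, `term`.
#' @param universe Character vector of background genes.
#' @param alpha Adjusted-p cutoff flagged as enriched (default 0.05).
#' @return Tibble per term: overlap counts, raw and BH-adjusted upper
#'   tail hypergeometric p, and `enriched`.
#' @export
go_enrichment <- function(gene_set, gene2term, universe, alpha = 0.05) {
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stop("gene(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  }
  g2t <- gene2term %>% dplyr::filter(.data$gene_id %in% universe)
  N <- length(unique(universe))
  n <- length(unique(gene_set))
  res <- g2t %>%
    group_by(.data$term) %>%
    summarise(term_size = dplyr::n_distinct(.data$gene_id),
              overlap = dplyr::n_distinct(
                intersect(.data$gene_id, gene_set)),
              .groups = "drop") %>%
    mutate(p_value = phyper(.data$overlap - 1, .data$term_size,
                            N - .data$term_size, n, lower.tail = FALSE),
           p_adjust = p.adjust(.data$p_value, method = "BH"),
           enriched = .data$p_adjust <= alpha) %>%
    arrange(.data$p_value)
  res
}

#' Hypergeometric test for the overlap of two term sets
#'
#' Upper-tail probability of observing at least the realised overlap
#' when the two sets are drawn independently from the universe.
#'
#' @param terms_a,terms_b Character vectors.
#' @param term_universe Character vector of all possible terms.
#' @return One-row tibble with `overlap`, `expected`, `p_value`.
#' @export
term_overlap_test <- function(terms_a, terms_b, term_universe) {
  a <- unique(terms_a); b <- unique(terms_b)
  u <- unique(term_universe)
  if (length(setdiff(c(a, b), u))) {
    stop("terms outside the universe")
  }
  x <- length(intersect(a, b))
  N <- length(u)
  p <- phyper(x - 1, length(a), N - length(a), length(b),
              lower.tail = FALSE)
  tibble::tibble(overlap = x,
                 expected = length(a) * length(b) / N,
                 p_value = p)
}

#' Run the full subgenome comparison on a dataset
#'
#' Executes every stage on a (typically simulated) dataset: AS
#' detection, lncRNA filtering, circRNA filtering/classification,
#' editing calling, homoeolog overlap, entropy summaries, and the
#' contrast battery. Raw p-values are kept and BH-adjusted within each
#' event family.
#'
#' @param dataset A list shaped like [simulate_dataset()] output.
#' @return A `subgenome_report` object.
#' @export
run_full_comparison <- function(dataset) {
  ann <- dataset$annotation
  genome <- dataset$genome
  contrasts <- vector("list", 0)
  counts <- list()
  # degenerate stages (e.g. no event of a type in a small dataset) drop
  # their contrast from the report instead of failing the whole battery
  safe_contrast <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      message("contrast '", label, "' skipped: ", conditionMessage(e))
      NULL
    })
  }

  # ---- alternative splicing ---------------------------------------
  as_genes <- detect_as_genes(ann)
  coding <- as_genes %>% dplyr::filter(.data$biotype == "coding",
                                       .data$subgenome %in% c("A", "B"))
  as_tab <- with(coding, table(factor(subgenome, c("A", "B")),
                               factor(is_as, c(TRUE, FALSE))))
  counts$as <- coding %>%
    group_by(.data$subgenome) %>%
    summarise(n_genes = n(), n_as = sum(.data$is_as),
              prop_as = mean(.data$is_as), .groups = "drop")
  contrasts$as <- safe_contrast(
    count_contrast(unclass(as_tab), "as_genes") %>%
      mutate(family = "splicing"), "as_genes")

  # ---- lncRNAs -----------------------------------------------------
  lnc <- filter_lncrna(ann, genome)
  tx_sub <- ann$transcripts %>%
    left_join(ann$genes[c("gene_id", "subgenome")], by = "gene_id") %>%
    dplyr::filter(.data$subgenome %in% c("A", "B")) %>%
    mutate(is_lnc = .data$transcript_id %in% lnc$transcript_id)
  lnc_tab <- with(tx_sub, table(factor(subgenome, c("A", "B")),
                                factor(is_lnc, c(TRUE, FALSE))))
  counts$lncrna <- tx_sub %>%
    group_by(.data$subgenome) %>%
    summarise(n_transcripts = n(), n_lncrna = sum(.data$is_lnc),
              .groups = "drop")
  contrasts$lnc <- safe_contrast(
    count_contrast(unclass(lnc_tab), "lncrna") %>%
      mutate(family = "lncrna"), "lncrna")

  # ---- circRNAs ----------------------------------------------------
  circ_kept <- filter_bsj(dataset$bsj)
  circ <- classify_circrna(circ_kept, ann)
  gene_sub <- ann$genes %>%
    dplyr::filter(.data$subgenome %in% c("A", "B"))
  host_flag <- gene_sub %>%
    mutate(has_circ = .data$gene_id %in% circ$host_gene)
  circ_tab <- with(host_flag, table(factor(subgenome, c("A", "B")),
                                    factor(has_circ, c(TRUE, FALSE))))
  counts$circ <- circ %>%
    dplyr::filter(.data$subgenome %in% c("A", "B")) %>%
    count(.data$subgenome, .data$class, name = "n_circ")
  contrasts$circ <- safe_contrast(
    count_contrast(unclass(circ_tab), "circ_host_genes") %>%
      mutate(family = "circrna"), "circ_host_genes")

  # ---- RNA editing -------------------------------------------------
  sites <- call_editing_sites(dataset$rna_pileups, dataset$dna_pileup,
                              dataset$libraries)
  site_pos <- sites %>% distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  edit_genes <- site_pos %>%
    inner_join(gene_sub %>% select("gene_id", "chrom",
                                   g_start = "start", g_end = "end"),
               by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(.data$pos >= .data$g_start, .data$pos <= .data$g_end) %>%
    distinct(.data$gene_id)
  gene_hit <- gene_sub %>%
    mutate(has_edit = .data$gene_id %in% edit_genes$gene_id)
  edit_tab <- with(gene_hit, table(factor(subgenome, c("A", "B")),
                                   factor(has_edit, c(TRUE, FALSE))))
  chrom_sub <- setNames(dataset$chrom_table$subgenome,
                        dataset$chrom_table$chrom)
  sites$subgenome <- unname(chrom_sub[sites$chrom])
  counts$editing <- sites %>%
    dplyr::filter(.data$subgenome %in% c("A", "B")) %>%
    distinct(.data$chrom, .data$pos, .data$subgenome) %>%
    count(.data$subgenome, name = "n_sites")
  contrasts$edit <- safe_contrast(
    count_contrast(unclass(edit_tab), "editing_genes") %>%
      mutate(family = "editing"), "editing_genes")
  freq_a <- sites$frequency[sites$subgenome == "A"]
  freq_b <- sites$frequency[sites$subgenome == "B"]
  if (length(freq_a) && length(freq_b)) {
    contrasts$edit_freq <-
      distribution_contrast(freq_a, freq_b, "editing_frequency") %>%
      mutate(family = "editing")
  }

  # ---- homoeolog overlap (AS) -------------------------------------
  as_flags <- setNames(as_genes$is_as, as_genes$gene_id)
  overlap_as <- homoeolog_event_overlap(dataset$pairs, as_flags)

  # ---- expression & entropy ---------------------------------------
  prof <- organ_profiles(dataset$expression %>%
                           select("feature_id", "sample", "tpm"),
                         dataset$samples)
  ent <- shannon_entropy(prof)
  lnc_ids <- lnc$transcript_id
  ent$kind <- if_else(ent$feature_id %in% lnc_ids, "lncRNA", "mRNA")
  entropy_summary <- ent %>%
    group_by(.data$kind) %>%
    summarise(median_entropy = stats::median(.data$entropy, na.rm = TRUE),
              n = n(), .groups = "drop")
  gene_expr <- dataset$expression %>%
    left_join(ann$transcripts[c("transcript_id", "gene_id")],
              by = c(feature_id = "transcript_id")) %>%
    group_by(.data$gene_id, .data$sample) %>%
    summarise(tpm = sum(.data$tpm), .groups = "drop") %>%
    group_by(.data$gene_id) %>%
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") %>%
    left_join(ann$genes[c("gene_id", "subgenome")], by = "gene_id")
  as_expr <- gene_expr %>%
    semi_join(dplyr::filter(as_genes, .data$is_as), by = "gene_id") %>%
    dplyr::filter(.data$subgenome %in% c("A", "B"))
  if (nrow(as_expr) > 4) {
    contrasts$as_expr <- distribution_contrast(
      log2(as_expr$mean_tpm[as_expr$subgenome == "A"] + 1),
      log2(as_expr$mean_tpm[as_expr$subgenome == "B"] + 1),
      "as_gene_expression") %>%
      mutate(family = "splicing")
  }

  contrast_tbl <- bind_rows(contrasts) %>%
    group_by(.data$family) %>%
    mutate(p_adjust = p.adjust(.data$p_value, method = "BH")) %>%
    ungroup()

  structure(
    list(counts = counts,
         contrasts = contrast_tbl,
         overlap_as = overlap_as,
         entropy = entropy_summary,
         n_editing_sites = nrow(site_pos),
         n_circrna = nrow(circ),
         n_lncrna = nrow(lnc),
         seed = dataset$config$seed %||% NA_integer_),
    class = "subgenome_report"
  )
}

#' @export
print.subgenome_report <- function(x, ...) {
  cat("<subgenome_report>\n")
  cat("  lncRNAs:", x$n_lncrna, " circRNAs:", x$n_circrna,
      " editing sites:", x$n_editing_sites, "\n")
  cat("  contrasts:\n")
  print(as.data.frame(x$contrasts[c("event", "test", "statistic",
                                    "p_value", "p_adjust")]),
        row.names = FALSE)
  invisible(x)
}
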