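# Intron-chain classification of query isoforms against a reference
# annotation: the seven structural groups used to audit a reannotation
# (two match classes, two novelty classes, three likely artifacts).

#' Intron chains of every transcript
#'
#' Introns are the gaps between consecutive exons; zero-length gaps
#' (abutting exons) are dropped, so a transcript whose exons tile a single
#' contiguous block has an empty chain, like a mono-exon transcript.
#'
#' @param annotation An [annotation_set()].
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (transcript span), `n_introns`, and
#'   `chain`, the canonical `start-end;start-end` intron-chain string
#'   (empty for mono-exon transcripts).
#' @export
intron_chains <- function(annotation) {
  stopifnot(is_annotation_set(annotation))
  introns <- annotation$exons %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(i_start = .data$end + 1L, i_end = lead(.data$start) - 1L) %>%
    dplyr::filter(!is.na(.data$i_end), .data$i_end >= .data$i_start) %>%
    summarise(chain = paste(sprintf("%d-%d", .data$i_start, .data$i_end),
                            collapse = ";"),
              n_introns = n(), .groups = "drop")
  annotation$transcripts %>%
    left_join(introns, by = "transcript_id") %>%
    mutate(chain = if_else(is.na(.data$chain), "", .data$chain),
           n_introns = if_else(is.na(.data$n_introns), 0L,
                               as.integer(.data$n_introns)))
}

#' Intron intervals of every transcript
#'
#' Long-format companion of [intron_chains()].
#'
#' @inheritParams intron_chains
#' @return Tibble `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_index`.
#' @export
intron_table <- function(annotation) {
  stopifnot(is_annotation_set(annotation))
  annotation$exons %>%
    group_by(.data$transcript_id, .data$gene_id,
             .data$chrom, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(i_start = .data$end + 1L, i_end = lead(.data$start) - 1L) %>%
    dplyr::filter(!is.na(.data$i_end), .data$i_end >= .data$i_start) %>%
    mutate(intron_index = row_number()) %>%
    ungroup() %>%
    select("transcript_id", "gene_id", "chrom", "strand",
           start = "i_start", end = "i_end", "intron_index")
}

isoform_class_levels <- c("complete_match", "partial_chain_match",
                          "opposite_strand_intron_match", "premrna_fragment",
                          "polymerase_runon", "novel_isoform_known_gene",
                          "novel_gene")

# is `qchain` a strict contiguous sub-chain of any chain in `ref_chains`?
# Both sides are canonical chain strings; matching at intron boundaries is
# enforced by wrapping with the separator.
chain_is_infix <- function(qchain, ref_chains) {
  if (!length(ref_chains)) return(0L)
  ref_w <- paste0(";", ref_chains, ";")
  pat <- paste0(";", qchain, ";")
  hit <- which(stringr::str_detect(ref_w, stringr::fixed(pat)) &
                 ref_chains != qchain)
  if (length(hit)) hit[1] else 0L
}

#' Classify query isoforms against a reference annotation
#'
#' Each query transcript receives exactly one of seven structural classes
#' by intron-chain comparison with the reference:
#' \describe{
#'   \item{complete_match}{identical intron chain on the same chromosome
#'     and strand (mono-exon: >= `mono_overlap` reciprocal exon overlap
#'     with a mono-exon reference transcript).}
#'   \item{partial_chain_match}{the query chain is a strict contiguous
#'     sub-chain of a reference chain.}
#'   \item{opposite_strand_intron_match}{the chain matches a reference
#'     chain (identically or as a contiguous sub-chain) on the other
#'     strand: a likely artifact.}
#'   \item{premrna_fragment}{an intron-less query lying within the span of
#'     a multi-exon reference transcript on the same strand: unspliced
#'     pre-mRNA signal.}
#'   \item{polymerase_runon}{the query touches no reference exon and lies
#'     in the <= `runon_window` bp 3' flank of a reference gene on the
#'     same strand.}
#'   \item{novel_isoform_known_gene}{exonic overlap with a reference gene
#'     on the same strand, but none of the above.}
#'   \item{novel_gene}{no exonic overlap with any reference gene.}
#' }
#' Classes are evaluated in that order, so the labels are mutually
#' exclusive. A query on a chromosome the reference does not know is
#' classified against an empty reference (hence `novel_gene`) with a
#' warning.
#'
#' @param query,reference [annotation_set()] objects.
#' @param mono_overlap Reciprocal-overlap fraction for mono-exon
#'   equivalence (default 0.5).
#' @param runon_window 3' flank size in bp for the run-on class
#'   (default 10000).
#' @return Tibble `transcript_id`, `gene_id`, `class` (factor),
#'   `matched_reference_id`, plus the query gene's `subgenome`.
#' @export
classify_isoforms <- function(query, reference, mono_overlap = 0.5,
                              runon_window = 10000) {
  stopifnot(is_annotation_set(query), is_annotation_set(reference))
  qc <- intron_chains(query)
  rc <- intron_chains(reference)
  unknown <- setdiff(unique(qc$chrom), unique(rc$chrom))
  if (length(unknown)) {
    warning("query chromosome(s) absent from reference: ",
            paste(unknown, collapse = ", "))
  }
  rex <- reference$exons
  rgenes <- reference$genes

  n <- nrow(qc)
  class <- character(n)
  match_id <- rep(NA_character_, n)

  # reference lookup tables
  rc_multi <- rc[rc$chain != "", ]
  key_multi <- split(seq_len(nrow(rc_multi)),
                     paste(rc_multi$chrom, rc_multi$strand))
  rc_mono <- rc[rc$chain == "", ]
  key_mono <- split(seq_len(nrow(rc_mono)),
                    paste(rc_mono$chrom, rc_mono$strand))
  rex_key <- split(seq_len(nrow(rex)), paste(rex$chrom, rex$strand))
  rtx_key <- split(seq_len(nrow(rc)), paste(rc$chrom, rc$strand))
  rg_key <- split(seq_len(nrow(rgenes)),
                  paste(rgenes$chrom, rgenes$strand))

  other <- function(s) if (s == "+") "-" else "+"

  for (i in seq_len(n)) {
    ch <- qc$chrom[i]; st <- qc$strand[i]
    qs <- qc$start[i]; qe <- qc$end[i]; chain <- qc$chain[i]
    k_same <- paste(ch, st); k_opp <- paste(ch, other(st))

    # exonic overlap with reference exons, same strand
    exi <- rex_key[[k_same]] %||% integer(0)
    exi <- exi[overlaps1(qs, qe, rex$start[exi], rex$end[exi])]
    if (chain != "") {
      cand <- key_multi[[k_same]] %||% integer(0)
      hit <- cand[rc_multi$chain[cand] == chain]
      if (length(hit)) {
        class[i] <- "complete_match"
        match_id[i] <- rc_multi$transcript_id[hit[1]]
        next
      }
      sub <- chain_is_infix(chain, rc_multi$chain[cand])
      if (sub > 0L) {
        class[i] <- "partial_chain_match"
        match_id[i] <- rc_multi$transcript_id[cand[sub]]
        next
      }
      cand_o <- key_multi[[k_opp]] %||% integer(0)
      hit_o <- cand_o[rc_multi$chain[cand_o] == chain]
      sub_o <- chain_is_infix(chain, rc_multi$chain[cand_o])
      if (length(hit_o) || sub_o > 0L) {
        class[i] <- "opposite_strand_intron_match"
        match_id[i] <- rc_multi$transcript_id[
          if (length(hit_o)) hit_o[1] else cand_o[sub_o]]
        next
      }
    } else {
      cand <- key_mono[[k_same]] %||% integer(0)
      ov <- pmin(qe, rc_mono$end[cand]) - pmax(qs, rc_mono$start[cand]) + 1
      recip <- ov >= mono_overlap * (qe - qs + 1) &
        ov >= mono_overlap * (rc_mono$end[cand] - rc_mono$start[cand] + 1)
      hit <- cand[!is.na(recip) & ov > 0 & recip]
      if (length(hit)) {
        class[i] <- "complete_match"
        match_id[i] <- rc_mono$transcript_id[hit[1]]
        next
      }
      # pre-mRNA fragment: inside a multi-exon transcript span, same strand
      cand_tx <- key_multi[[k_same]] %||% integer(0)
      inside <- cand_tx[rc_multi$start[cand_tx] <= qs &
                          rc_multi$end[cand_tx] >= qe]
      if (length(inside)) {
        class[i] <- "premrna_fragment"
        match_id[i] <- rc_multi$transcript_id[inside[1]]
        next
      }
    }
    if (length(exi)) {
      class[i] <- "novel_isoform_known_gene"
      match_id[i] <- rex$gene_id[exi[1]]
      next
    }
    # any-strand exonic overlap at all?
    exi_any <- c(exi, {
      j <- rex_key[[k_opp]] %||% integer(0)
      j[overlaps1(qs, qe, rex$start[j], rex$end[j])]
    })
    gi <- rg_key[[k_same]] %||% integer(0)
    flank_s <- if_else(rgenes$strand[gi] == "+", rgenes$end[gi] + 1,
                       pmax(1, rgenes$start[gi] - runon_window))
    flank_e <- if_else(rgenes$strand[gi] == "+",
                       rgenes$end[gi] + runon_window,
                       rgenes$start[gi] - 1)
    run <- gi[overlaps1(qs, qe, flank_s, flank_e)]
    if (!length(exi_any) && length(run)) {
      class[i] <- "polymerase_runon"
      match_id[i] <- rgenes$gene_id[run[1]]
      next
    }
    class[i] <- "novel_gene"
  }

  qgenes <- query$genes[c("gene_id", "subgenome")]
  tibble::tibble(transcript_id = qc$transcript_id, gene_id = qc$gene_id,
                 class = factor(class, levels = isoform_class_levels),
                 matched_reference_id = match_id) %>%
    left_join(qgenes, by = "gene_id")
}

#' Summarise isoform classes
#'
#' @param classified Output of [classify_isoforms()].
#' @param by_subgenome Also break counts down by subgenome?
#' @return Tibble with `class`, `n`, `fraction` (and `subgenome` when
#'   requested); counts sum to the input size.
#' @export
summarize_classes <- function(classified, by_subgenome = FALSE) {
  grp <- if (by_subgenome) c("subgenome", "class") else "class"
  classified %>%
    mutate(class = factor(.data$class, levels = isoform_class_levels)) %>%
    count(dplyr::across(dplyr::all_of(grp)), .drop = FALSE, name = "n") %>%
    group_by(dplyr::across(dplyr::all_of(grp[grp != "class"]))) %>%
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) %>%
    ungroup()
}
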