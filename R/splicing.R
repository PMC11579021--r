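# Alternative splicing: AS-gene detection, event typing by pairwise
# isoform comparison against a reference isoform, event localisation to
# transcript regions, and the effect of AS on protein diversity.

#' Detect alternatively spliced genes
#'
#' A gene is alternatively spliced when it has two or more isoforms.
#'
#' @param annotation An [annotation_set()].
#' @return Tibble with one row per gene: `gene_id`, `subgenome`,
#'   `biotype`, `n_isoforms`, `is_as`.
#' @export
detect_as_genes <- function(annotation) {
  stopifnot(is_annotation_set(annotation))
  annotation$transcripts %>%
    count(.data$gene_id, name = "n_isoforms") %>%
    left_join(annotation$genes[c("gene_id", "subgenome", "biotype")],
              by = "gene_id") %>%
    mutate(is_as = .data$n_isoforms >= 2L) %>%
    select("gene_id", "subgenome", "biotype", "n_isoforms", "is_as")
}

#' Summarise alternative splicing over genes
#'
#' @param as_genes Output of [detect_as_genes()].
#' @return List with `histogram` (isoforms-per-gene counts),
#'   `n_as_genes`, `n_as_isoforms` and `mean_isoforms_per_as_gene`
#'   (isoforms of AS genes / AS genes).
#' @export
summarize_as <- function(as_genes) {
  as_set <- dplyr::filter(as_genes, .data$is_as)
  list(
    histogram = count(as_genes, .data$n_isoforms, name = "n_genes"),
    n_as_genes = nrow(as_set),
    n_as_isoforms = sum(as_set$n_isoforms),
    mean_isoforms_per_as_gene =
      if (nrow(as_set)) sum(as_set$n_isoforms) / nrow(as_set) else NA_real_
  )
}

# spliced exon length per transcript
transcript_lengths <- function(annotation) {
  annotation$exons %>%
    group_by(.data$transcript_id) %>%
    summarise(length = sum(.data$end - .data$start + 1L), .groups = "drop")
}

# reference isoform per gene: longest CDS, ties -> longest transcript,
# ties -> lexicographically first id (deterministic)
reference_isoforms <- function(annotation) {
  cds_len <- annotation$cds %>%
    group_by(.data$transcript_id) %>%
    summarise(cds_length = sum(.data$end - .data$start + 1L),
              .groups = "drop")
  annotation$transcripts %>%
    left_join(cds_len, by = "transcript_id") %>%
    left_join(transcript_lengths(annotation), by = "transcript_id") %>%
    mutate(cds_length = if_else(is.na(.data$cds_length), 0L,
                                as.integer(.data$cds_length))) %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$cds_length), dplyr::desc(.data$length),
            .data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", reference_transcript_id = "transcript_id")
}

# introns as a two-column matrix-like tibble from sorted exon intervals
gaps_of <- function(starts, ends) {
  if (length(starts) < 2) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  s <- ends[-length(ends)] + 1L
  e <- starts[-1] - 1L
  keep <- e >= s
  tibble::tibble(start = s[keep], end = e[keep])
}

# AS events between one alternative isoform and the reference isoform.
# ex_* are tibbles with start/end (sorted, disjoint).
pair_as_events <- function(ex_ref, ex_alt, strand) {
  ir_r <- gaps_of(ex_ref$start, ex_ref$end)
  ir_a <- gaps_of(ex_alt$start, ex_alt$end)
  ev <- list()

  within_any <- function(s, e, iv) {
    if (!nrow(iv)) return(rep(FALSE, length(s)))
    vapply(seq_along(s), function(i) {
      any(iv$start <= s[i] & e[i] <= iv$end)
    }, logical(1))
  }
  containing_idx <- function(s, e, iv) {
    hit <- which(iv$start <= s & e <= iv$end)
    if (length(hit)) hit[1] else NA_integer_
  }

  # intron retention: an intron of one isoform fully exonic in the other
  if (nrow(ir_r)) {
    ret <- within_any(ir_r$start, ir_r$end, ex_alt)
    if (any(ret)) {
      ev <- c(ev, list(tibble::tibble(type = "intron_retention",
                                      start = ir_r$start[ret],
                                      end = ir_r$end[ret])))
    }
  }
  if (nrow(ir_a)) {
    ret <- within_any(ir_a$start, ir_a$end, ex_ref)
    if (any(ret)) {
      ev <- c(ev, list(tibble::tibble(type = "intron_retention",
                                      start = ir_a$start[ret],
                                      end = ir_a$end[ret])))
    }
  }

  # skipped-exon candidates: an exon of one isoform inside an intron of
  # the other; mutually-exclusive pairs are promoted afterwards
  sk_r <- which(within_any(ex_ref$start, ex_ref$end, ir_a))
  sk_a <- which(within_any(ex_alt$start, ex_alt$end, ir_r))
  mxe <- list()
  used_r <- logical(length(sk_r)); used_a <- logical(length(sk_a))
  for (i in seq_along(sk_r)) {
    er_s <- ex_ref$start[sk_r[i]]; er_e <- ex_ref$end[sk_r[i]]
    ia <- containing_idx(er_s, er_e, ir_a)
    for (j in seq_along(sk_a)) {
      if (used_a[j]) next
      ea_s <- ex_alt$start[sk_a[j]]; ea_e <- ex_alt$end[sk_a[j]]
      ir <- containing_idx(ea_s, ea_e, ir_r)
      if (is.na(ia) || is.na(ir)) next
      overlap_iv <- overlaps1(ir_a$start[ia], ir_a$end[ia],
                              ir_r$start[ir], ir_r$end[ir])
      exons_disjoint <- !overlaps1(er_s, er_e, ea_s, ea_e)
      if (overlap_iv && exons_disjoint) {
        mxe <- c(mxe, list(tibble::tibble(
          type = "mutually_exclusive",
          start = min(er_s, ea_s), end = max(er_e, ea_e))))
        used_r[i] <- TRUE; used_a[j] <- TRUE
        break
      }
    }
  }
  skip_iv <- bind_rows(
    tibble::tibble(start = ex_ref$start[sk_r[!used_r]],
                   end = ex_ref$end[sk_r[!used_r]]),
    tibble::tibble(start = ex_alt$start[sk_a[!used_a]],
                   end = ex_alt$end[sk_a[!used_a]])
  )
  if (nrow(skip_iv)) {
    ev <- c(ev, list(mutate(skip_iv, type = "exon_skip")))
  }
  ev <- c(ev, mxe)

  # alternative donor / acceptor: overlapping introns sharing exactly one
  # boundary; which boundary differs decides the type, strand-aware
  if (nrow(ir_r) && nrow(ir_a)) {
    for (i in seq_len(nrow(ir_r))) {
      ov <- overlaps1(ir_r$start[i], ir_r$end[i], ir_a$start, ir_a$end)
      for (j in which(ov)) {
        same_s <- ir_r$start[i] == ir_a$start[j]
        same_e <- ir_r$end[i] == ir_a$end[j]
        if (same_s == same_e) next       # identical or both-differ introns
        if (same_s) {
          d <- sort(c(ir_r$end[i], ir_a$end[j]))
          boundary <- "right"
        } else {
          d <- sort(c(ir_r$start[i], ir_a$start[j]))
          boundary <- "left"
        }
        # if the differing region swallows a whole exon this is an
        # exon-skip / mutually-exclusive context, not an alt site
        if (any(ex_ref$start >= d[1] & ex_ref$end <= d[2]) ||
            any(ex_alt$start >= d[1] & ex_alt$end <= d[2])) next
        # + strand: intron left end is the donor site; - strand: acceptor
        type <- if (strand == "+") {
          if (boundary == "left") "alt_donor" else "alt_acceptor"
        } else {
          if (boundary == "left") "alt_acceptor" else "alt_donor"
        }
        ev <- c(ev, list(tibble::tibble(type = type,
                                        start = d[1], end = d[2])))
      }
    }
  }
  if (!length(ev)) {
    return(tibble::tibble(type = character(0), start = integer(0),
                          end = integer(0)))
  }
  bind_rows(ev)
}

#' Type alternative-splicing events per gene
#'
#' Each non-reference isoform is compared against the gene's reference
#' isoform (longest CDS, ties broken by transcript length, then id).
#' Events are typed as exon skipping, intron retention, alternative
#' donor/acceptor (strand-aware) or mutually exclusive exons, and
#' deduplicated by (type, genomic interval) within the gene.
#'
#' @param annotation An [annotation_set()].
#' @param genes Optional character vector restricting to these gene ids.
#' @return Tibble `gene_id`, `chrom`, `strand`, `type`, `start`, `end`.
#' @export
type_as_events <- function(annotation, genes = NULL) {
  stopifnot(is_annotation_set(annotation))
  as_tbl <- detect_as_genes(annotation)
  targets <- as_tbl$gene_id[as_tbl$is_as]
  if (!is.null(genes)) {
    mono <- setdiff(genes, targets)
    if (length(mono)) {
      stop("gene(s) without multiple isoforms: ",
           paste(mono, collapse = ", "))
    }
    targets <- intersect(targets, genes)
  }
  refs <- reference_isoforms(annotation)
  ex_by_tx <- split(annotation$exons[c("start", "end")],
                    annotation$exons$transcript_id)
  tx <- annotation$transcripts
  tx_by_gene <- split(tx$transcript_id, tx$gene_id)
  gene_info <- annotation$genes
  out <- purrr::map(targets, function(g) {
    ref_tx <- refs$reference_transcript_id[refs$gene_id == g]
    alts <- setdiff(tx_by_gene[[g]], ref_tx)
    strand <- gene_info$strand[gene_info$gene_id == g]
    ex_ref <- ex_by_tx[[ref_tx]]
    ev <- purrr::map(alts, function(a) {
      pair_as_events(ex_ref, ex_by_tx[[a]], strand)
    })
    ev <- bind_rows(ev)
    if (!nrow(ev)) return(NULL)
    ev %>%
      mutate(gene_id = g,
             chrom = gene_info$chrom[gene_info$gene_id == g],
             strand = strand) %>%
      distinct(.data$type, .data$start, .data$end, .keep_all = TRUE)
  })
  bind_rows(out) %>%
    select(dplyr::any_of(c("gene_id", "chrom", "strand",
                           "type", "start", "end")))
}

#' Localise AS events to transcript regions
#'
#' Events are placed relative to the reference isoform's CDS genomic
#' span: any overlap (including boundary-straddling events) is `CDS`;
#' otherwise the event is 5'UTR or 3'UTR by its position on the coding
#' strand. Events of genes without an annotated CDS get `NA` and are
#' excluded from region distributions.
#'
#' @param events Output of [type_as_events()].
#' @param annotation An [annotation_set()].
#' @return `events` with an added `region` column
#'   (`CDS` / `five_prime_UTR` / `three_prime_UTR` / `NA`).
#' @export
localize_events <- function(events, annotation) {
  stopifnot(is_annotation_set(annotation))
  refs <- reference_isoforms(annotation)
  cds_span <- annotation$cds %>%
    group_by(.data$transcript_id) %>%
    summarise(cds_start = if (n()) min(.data$start) else NA_integer_,
              cds_end = if (n()) max(.data$end) else NA_integer_,
              .groups = "drop")
  ref_cds <- refs %>%
    left_join(cds_span, by = c(reference_transcript_id = "transcript_id"))
  events %>%
    left_join(ref_cds, by = "gene_id") %>%
    mutate(region = dplyr::case_when(
      is.na(.data$cds_start) ~ NA_character_,
      overlaps1(.data$start, .data$end, .data$cds_start, .data$cds_end) ~
        "CDS",
      (.data$end < .data$cds_start) == (.data$strand == "+") ~
        "five_prime_UTR",
      TRUE ~ "three_prime_UTR"
    )) %>%
    select(-"reference_transcript_id", -"cds_start", -"cds_end")
}

# spliced CDS nucleotide sequence of one transcript (strand-corrected)
cds_sequence <- function(annotation, transcript_ids, genome) {
  cds <- annotation$cds %>%
    dplyr::filter(.data$transcript_id %in% transcript_ids)
  if (!nrow(cds)) return(setNames(character(0), character(0)))
  cds$seq <- substr(genome[cds$chrom], cds$start, cds$end)
  out <- cds %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(seq = paste(.data$seq, collapse = ""),
              strand = .data$strand[1], .groups = "drop") %>%
    mutate(seq = if_else(.data$strand == "-", revcomp(.data$seq), .data$seq))
  setNames(out$seq, out$transcript_id)
}

# translate a nucleotide string with the standard code; internal stops
# truncate the protein (with a warning from the caller's side)
translate_cds <- function(nt) {
  nt <- substr(nt, 1, (nchar(nt) %/% 3) * 3)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt), if.fuzzy.codon = "solve"))
  trunc <- sub("\\*.*$", "", aa)
  if (any(nchar(trunc) < nchar(sub("\\*$", "", aa)))) {
    # internal stop encountered: protein truncated at the first stop
  }
  trunc
}

#' Group AS genes by the effect of splicing on protein diversity
#'
#' Each CDS-bearing isoform is translated with the standard nuclear code
#' (internal stop codons truncate the protein). A gene is `unaffected`
#' when all predicted proteins are identical, `all_differ` when all are
#' pairwise distinct, and `partial` otherwise. Genes with fewer than two
#' CDS-bearing isoforms are excluded.
#'
#' @param annotation An [annotation_set()].
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble `gene_id`, `subgenome`, `n_proteins`, `group` (factor
#'   `unaffected` / `all_differ` / `partial`).
#' @export
protein_diversity_groups <- function(annotation, genome) {
  stopifnot(is_annotation_set(annotation))
  cds_tx <- unique(annotation$cds$transcript_id)
  cds_seqs <- cds_sequence(annotation, cds_tx, genome)
  prot <- setNames(translate_cds(cds_seqs), names(cds_seqs))
  tx <- annotation$transcripts %>%
    dplyr::filter(.data$transcript_id %in% cds_tx) %>%
    mutate(protein = prot[.data$transcript_id])
  tx %>%
    group_by(.data$gene_id) %>%
    dplyr::filter(n() >= 2) %>%
    summarise(
      n_proteins = dplyr::n_distinct(.data$protein),
      n_iso = n(),
      group = dplyr::case_when(
        n_proteins == 1 ~ "unaffected",
        n_proteins == n_iso ~ "all_differ",
        TRUE ~ "partial"
      ),
      .groups = "drop"
    ) %>%
    left_join(annotation$genes[c("gene_id", "subgenome")], by = "gene_id") %>%
    mutate(group = factor(.data$group,
                          levels = c("unaffected", "all_differ",
                                     "partial"))) %>%
    select("gene_id", "subgenome", "n_proteins", "group")
}
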