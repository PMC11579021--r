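# The tabular gene-model container used by every stage.
#
# An annotation_set is a list of four tibbles sharing 1-based inclusive
# coordinates:
#   genes:       gene_id, chrom, strand, start, end, biotype, subgenome
#   transcripts: transcript_id, gene_id, chrom, strand, start, end
#   exons:       transcript_id, gene_id, chrom, strand, start, end
#   cds:         transcript_id, gene_id, chrom, strand, start, end
# Exons are stored sorted by (transcript_id, start) and must be pairwise
# disjoint within a transcript; CDS intervals are a subset of exon space.

#' Build an annotation set from exon (and optional CDS) tables
#'
#' Gene and transcript spans are derived from the exon table. A gene is
#' `coding` if at least one of its transcripts carries CDS intervals,
#' `noncoding` otherwise. Subgenome labels come from `chrom_table`
#' (columns `chrom`, `subgenome`); chromosomes absent from it are labelled
#' `"unanchored"`.
#'
#' @param exons Tibble with columns transcript_id, gene_id, chrom, strand,
#'   start, end (1-based inclusive).
#' @param cds Optional tibble with the same columns for coding intervals.
#' @param chrom_table Optional tibble mapping chrom to subgenome.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons, cds = NULL, chrom_table = NULL) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(req %in% names(exons)))
  exons <- tibble::as_tibble(exons)
  exons <- exons[c(req, setdiff(names(exons), req))]
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be + or -")
  exons <- exons[order(exons$transcript_id, exons$start), ]
  n_ex <- nrow(exons)
  if (n_ex > 1) {
    same_tx <- exons$transcript_id[-1] == exons$transcript_id[-n_ex]
    bad <- same_tx & exons$start[-1] <= exons$end[-n_ex]
    if (any(bad)) {
      stop("overlapping exons within transcript(s): ",
           paste(unique(exons$transcript_id[-1][bad]), collapse = ", "))
    }
  }
  if (!is.null(cds) && nrow(cds)) {
    cds <- tibble::as_tibble(cds)[req]
    cds <- cds[order(cds$transcript_id, cds$start), ]
  } else {
    cds <- exons[0, req]
  }
  # first/last row per transcript after sorting gives the span
  first <- !duplicated(exons$transcript_id)
  tx_end <- vapply(split(exons$end, exons$transcript_id), max, numeric(1))
  transcripts <- tibble::tibble(
    transcript_id = exons$transcript_id[first],
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    start = exons$start[first],
    end = as.integer(tx_end[exons$transcript_id[first]])
  )
  g_first <- !duplicated(transcripts$gene_id)
  g_start <- vapply(split(transcripts$start, transcripts$gene_id),
                    min, numeric(1))
  g_end <- vapply(split(transcripts$end, transcripts$gene_id),
                  max, numeric(1))
  gid <- transcripts$gene_id[g_first]
  genes <- tibble::tibble(
    gene_id = gid,
    chrom = transcripts$chrom[g_first],
    strand = transcripts$strand[g_first],
    start = as.integer(g_start[gid]),
    end = as.integer(g_end[gid]),
    biotype = if_else(gid %in% unique(cds$gene_id),
                      "coding", "noncoding")
  )
  if (!is.null(chrom_table)) {
    genes <- genes %>%
      left_join(chrom_table[c("chrom", "subgenome")], by = "chrom") %>%
      mutate(subgenome = if_else(is.na(.data$subgenome),
                                 "unanchored", .data$subgenome))
  } else {
    genes$subgenome <- "unanchored"
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ",
      nrow(x$exons), " exons, ",
      nrow(x$cds), " CDS intervals\n", sep = "")
  invisible(x)
}

#' @export
format.annotation_set <- function(x, ...) {
  sprintf("<annotation_set: %d genes / %d transcripts>",
          nrow(x$genes), nrow(x$transcripts))
}

is_annotation_set <- function(x) inherits(x, "annotation_set")

# exon table for one transcript, sorted
transcript_exons <- function(annotation, transcript_id) {
  dplyr::filter(annotation$exons, .data$transcript_id == .env$transcript_id)
}
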