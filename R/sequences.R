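# Spliced sequences and ORF search.

#' Spliced, strand-corrected transcript sequence
#'
#' Concatenates exon sequences 5' to 3'; minus-strand transcripts are
#' reverse-complemented.
#'
#' @param annotation An [annotation_set()].
#' @param transcript_id Transcript identifier (vectorised).
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector of spliced sequences.
#' @export
transcript_sequence <- function(annotation, transcript_id, genome) {
  stopifnot(is_annotation_set(annotation))
  ex <- annotation$exons %>%
    dplyr::filter(.data$transcript_id %in% .env$transcript_id)
  missing_tx <- setdiff(transcript_id, ex$transcript_id)
  if (length(missing_tx)) {
    stop("unknown transcript(s): ", paste(missing_tx, collapse = ", "))
  }
  missing_chr <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  ex$seq <- substr(genome[ex$chrom], ex$start, ex$end)
  spliced <- ex %>%
    group_by(.data$transcript_id) %>%
    summarise(seq = paste(.data$seq, collapse = ""),
              strand = .data$strand[1], .groups = "drop") %>%
    mutate(seq = if_else(.data$strand == "-", revcomp(.data$seq), .data$seq))
  setNames(spliced$seq, spliced$transcript_id)[transcript_id]
}

#' Longest open reading frame on the sense strand
#'
#' Scans all three sense-strand frames for the longest ATG-to-stop ORF.
#' Returns `NULL` when the longest ORF encodes `min_aa` amino acids or
#' fewer (the lncRNA filter keeps transcripts whose best ORF is not
#' *more than* `min_aa` residues).
#'
#' @param seq A single nucleotide sequence (A/C/G/T/N).
#' @param min_aa Minimum protein length, exclusive (default 100).
#' @return `NULL`, or a list with `start`, `end` (1-based on `seq`,
#'   including the stop codon when present), `frame` and `aa_length`.
#' @export
find_longest_orf <- function(seq, min_aa = 100) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGTNacgtn]", seq)) stop("non-ACGTN symbols in sequence")
  orf_scan(toupper(seq), min_aa)
}

# base codes A=1 C=2 G=3 T=4 (N and others -> NA, never ATG nor stop)
.base_code <- {
  tb <- rep(NA_integer_, 128)
  tb[utf8ToInt("ACGT")] <- 1:4
  tb
}

# validation-free integer-coded scan used by find_longest_orf and the
# simulator's hot loops
orf_scan <- function(seq, min_aa = 100) {
  v <- .base_code[utf8ToInt(seq)]
  n <- length(v)
  if (n < 3) return(NULL)
  code <- 16L * v[1:(n - 2L)] + 4L * v[2:(n - 1L)] + v[3:n]
  atg_all <- which(code == 35L)                       # ATG starts
  if (!length(atg_all)) return(NULL)
  stp_all <- which(code == 69L | code == 71L | code == 77L)
  best <- NULL
  for (f in 0:2) {
    a <- atg_all[(atg_all - 1L) %% 3L == f]
    if (!length(a)) next
    s <- stp_all[(stp_all - 1L) %% 3L == f]
    # last in-frame codon start
    lcs <- n - 2L - ((n - 2L) - (f + 1L)) %% 3L
    # first in-frame stop strictly after each ATG (NA if none)
    nxt <- s[findInterval(a, s) + 1L]
    na <- is.na(nxt)
    aa_len <- (nxt - a) %/% 3L
    end <- nxt + 2L
    aa_len[na] <- (lcs - a[na]) %/% 3L + 1L
    end[na] <- lcs + 2L
    k <- which.max(aa_len)
    if (is.null(best) || aa_len[k] > best$aa_length ||
        (aa_len[k] == best$aa_length && a[k] < best$start)) {
      best <- list(start = a[k], end = end[k], frame = f,
                   aa_length = aa_len[k])
    }
  }
  if (is.null(best) || best$aa_length <= min_aa) return(NULL)
  best
}
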