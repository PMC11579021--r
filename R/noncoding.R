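# Long noncoding RNAs: length/ORF filtering, ungapped reverse-complement
# matching, lncRNA-mRNA interaction pairing, and the genomic distribution
# of precomputed target sites.

#' Filter transcripts to lncRNA candidates
#'
#' A transcript is kept when its spliced length is strictly greater than
#' `min_len` (default 200 bp) and its best sense-strand ORF does not
#' exceed `min_aa` (default 100) amino acids.
#'
#' @param annotation An [annotation_set()].
#' @param genome Named character vector of chromosome sequences.
#' @param min_len Length cutoff in bp, exclusive.
#' @param min_aa ORF cutoff in amino acids, exclusive.
#' @return Tibble `transcript_id`, `gene_id`, `subgenome`, `length`,
#'   `is_lncrna`, restricted to transcripts passing both filters.
#' @export
filter_lncrna <- function(annotation, genome, min_len = 200, min_aa = 100) {
  stopifnot(is_annotation_set(annotation))
  lens <- transcript_lengths(annotation)
  cand <- lens %>% dplyr::filter(.data$length > min_len)
  if (!nrow(cand)) {
    return(tibble::tibble(transcript_id = character(0),
                          gene_id = character(0),
                          subgenome = character(0),
                          length = integer(0), is_lncrna = logical(0)))
  }
  seqs <- transcript_sequence(annotation, cand$transcript_id, genome)
  has_orf <- vapply(seqs, function(s) {
    !is.null(find_longest_orf(s, min_aa = min_aa))
  }, logical(1))
  cand %>%
    dplyr::filter(!has_orf) %>%
    left_join(annotation$transcripts[c("transcript_id", "gene_id")],
              by = "transcript_id") %>%
    left_join(annotation$genes[c("gene_id", "subgenome")], by = "gene_id") %>%
    mutate(is_lncrna = TRUE) %>%
    select("transcript_id", "gene_id", "subgenome", "length", "is_lncrna")
}

# maximal qualifying intervals along one alignment diagonal.
# mv: logical match vector; returns tibble(start, end, mm) in diagonal
# coordinates (1-based along the aligned stretch).
diagonal_matches <- function(mv, min_len, min_identity) {
  L <- length(mv)
  if (L < min_len) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          mm = integer(0)))
  }
  bounds <- c(0L, which(!mv), L + 1L)   # sentinel-augmented mismatches
  k <- length(bounds)
  cand <- list()
  for (p in 1:(k - 1)) {
    for (q in (p + 1):k) {
      s <- bounds[p] + 1L
      e <- bounds[q] - 1L
      len <- e - s + 1L
      if (len < min_len) next
      mm <- q - p - 1L
      if ((len - mm) / len < min_identity) next
      cand <- c(cand, list(c(s, e, mm, p, q)))
    }
  }
  if (!length(cand)) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          mm = integer(0)))
  }
  cm <- do.call(rbind, cand)
  # drop intervals contained in another qualifying interval (maximality)
  keep <- vapply(seq_len(nrow(cm)), function(i) {
    !any(cm[, 1] <= cm[i, 1] & cm[, 2] >= cm[i, 2] &
           (cm[, 1] < cm[i, 1] | cm[, 2] > cm[i, 2]))
  }, logical(1))
  cm <- cm[keep, , drop = FALSE]
  tibble::tibble(start = cm[, 1], end = cm[, 2], mm = cm[, 3])
}

#' Ungapped reverse-complement matches between two sequences
#'
#' Finds maximal ungapped local matches between `seq_a` and the reverse
#' complement of `seq_b` with length >= `min_len` and identity >=
#' `min_identity`. Candidate diagonals are located by shared exact
#' `seed_len`-mers and then scanned exactly; overlapping maximal matches
#' on the same diagonal are merged to the highest-identity one (ties:
#' longest, then leftmost). Subject coordinates are reported on the
#' original (unreversed) `seq_b`.
#'
#' @param seq_a,seq_b Nucleotide sequences (single strings).
#' @param min_len Minimum match length in bp (default 20).
#' @param min_identity Minimum identity fraction (default 0.90).
#' @param seed_len Exact-seed length used to locate candidate diagonals.
#' @return Tibble `a_start`, `a_end`, `b_start`, `b_end`, `length`,
#'   `identity`.
#' @export
find_rc_matches <- function(seq_a, seq_b, min_len = 20, min_identity = 0.90,
                            seed_len = 12) {
  empty <- tibble::tibble(a_start = integer(0), a_end = integer(0),
                          b_start = integer(0), b_end = integer(0),
                          length = integer(0), identity = double(0))
  if (!nchar(seq_a) || !nchar(seq_b)) return(empty)
  a <- toupper(seq_a)
  b2 <- revcomp(seq_b)          # match a against RC of b
  n <- nchar(a); m <- nchar(b2)
  if (n < min_len || m < min_len) return(empty)
  ra <- charToRaw(a); rb <- charToRaw(b2)

  # candidate diagonals from shared exact seeds
  k <- min(seed_len, min_len)
  sa <- substring(a, 1:(n - k + 1), k:n)
  sb <- substring(b2, 1:(m - k + 1), k:m)
  pos_a <- split(seq_along(sa), sa)
  pos_b <- split(seq_along(sb), sb)
  shared <- intersect(names(pos_a), names(pos_b))
  if (!length(shared)) return(empty)
  diags <- unique(unlist(lapply(shared, function(km) {
    as.vector(outer(pos_a[[km]], pos_b[[km]], "-"))
  })))

  out <- list()
  for (d in sort(diags)) {
    j1 <- max(1L, 1L - d); j2 <- min(m, n - d)
    if (j2 - j1 + 1L < min_len) next
    jr <- j1:j2
    mv <- ra[jr + d] == rb[jr]
    hits <- diagonal_matches(mv, min_len, min_identity)
    if (!nrow(hits)) next
    hits <- hits %>%
      mutate(length = .data$end - .data$start + 1L,
             identity = (.data$length - .data$mm) / .data$length) %>%
      arrange(dplyr::desc(.data$identity), dplyr::desc(.data$length),
              .data$start)
    # merge overlapping maximal intervals on this diagonal: best first
    acc <- hits[0, ]
    for (i in seq_len(nrow(hits))) {
      if (!nrow(acc) ||
          !any(overlaps1(hits$start[i], hits$end[i], acc$start, acc$end))) {
        acc <- bind_rows(acc, hits[i, ])
      }
    }
    a_start <- acc$start + j1 - 1L + d
    j_start <- acc$start + j1 - 1L
    out <- c(out, list(tibble::tibble(
      a_start = a_start,
      a_end = a_start + acc$length - 1L,
      b_start = nchar(seq_b) - (j_start + acc$length - 1L) + 1L,
      b_end = nchar(seq_b) - j_start + 1L,
      length = acc$length,
      identity = acc$identity
    )))
  }
  if (!length(out)) return(empty)
  bind_rows(out) %>% arrange(.data$a_start, .data$b_start)
}

#' Pair lncRNAs with mRNAs by reverse-complement matching and expression
#'
#' A candidate pair exists when [find_rc_matches()] reports at least one
#' match between the lncRNA and mRNA sequences. For every pair the
#' Euclidean distance and the correlation of the two `log2(TPM + 1)`
#' organ-level profiles are computed and the pair is classed as
#' `correlated` (distance <= `dist_threshold` and correlation >=
#' `cor_threshold`), `divergent` (distance above and correlation below),
#' or `intermediate` otherwise.
#'
#' @param lnc_seqs,mrna_seqs Named character vectors of transcript
#'   sequences.
#' @param profiles Tibble of organ-level mean TPM with columns
#'   `feature_id`, `organ`, `tpm`.
#' @param dist_threshold,cor_threshold Classification thresholds
#'   (defaults 5.10 and 0.667).
#' @param min_len,min_identity Passed to [find_rc_matches()].
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @param subgenome_map Optional tibble `feature_id`, `subgenome` used to
#'   flag intra-subgenome pairs.
#' @return Tibble with one row per interacting pair: ids, best match
#'   length/identity, `distance`, `correlation`, `class`, and
#'   `intra_subgenome` when a map is supplied. Pairs whose partner is
#'   absent from `profiles` are skipped with a warning.
#' @export
pair_lncrna_mrna <- function(lnc_seqs, mrna_seqs, profiles,
                             dist_threshold = 5.10, cor_threshold = 0.667,
                             min_len = 20, min_identity = 0.90,
                             method = c("pearson", "spearman"),
                             subgenome_map = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("feature_id", "organ", "tpm") %in% names(profiles)))
  organs <- sort(unique(profiles$organ))
  prof_wide <- profiles %>%
    mutate(ltpm = log2(.data$tpm + 1)) %>%
    select("feature_id", "organ", "ltpm") %>%
    tidyr::pivot_wider(names_from = "organ", values_from = "ltpm",
                       values_fill = 0)
  prof_mat <- as.matrix(prof_wide[, as.character(organs)])
  rownames(prof_mat) <- prof_wide$feature_id

  combos <- tidyr::expand_grid(lnc_id = names(lnc_seqs),
                               mrna_id = names(mrna_seqs))
  rows <- purrr::pmap(combos, function(lnc_id, mrna_id) {
    mt <- find_rc_matches(lnc_seqs[[lnc_id]], mrna_seqs[[mrna_id]],
                          min_len = min_len, min_identity = min_identity)
    if (!nrow(mt)) return(NULL)
    best <- mt %>%
      arrange(dplyr::desc(.data$identity), dplyr::desc(.data$length)) %>%
      slice(1)
    tibble::tibble(lnc_id = lnc_id, mrna_id = mrna_id,
                   match_length = best$length,
                   match_identity = best$identity)
  })
  pairs <- bind_rows(rows)
  if (!nrow(pairs)) {
    return(tibble::tibble(lnc_id = character(0), mrna_id = character(0),
                          match_length = integer(0),
                          match_identity = double(0),
                          distance = double(0), correlation = double(0),
                          class = character(0)))
  }
  have <- pairs$lnc_id %in% rownames(prof_mat) &
    pairs$mrna_id %in% rownames(prof_mat)
  if (any(!have)) {
    warning(sum(!have), " pair(s) skipped: partner absent from profiles")
    pairs <- pairs[have, ]
  }
  if (!nrow(pairs)) return(pairs)
  pairs$distance <- vapply(seq_len(nrow(pairs)), function(i) {
    sqrt(sum((prof_mat[pairs$lnc_id[i], ] - prof_mat[pairs$mrna_id[i], ])^2))
  }, double(1))
  pairs$correlation <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(stats::cor(prof_mat[pairs$lnc_id[i], ],
                                prof_mat[pairs$mrna_id[i], ],
                                method = method))
  }, double(1))
  pairs <- pairs %>%
    mutate(class = dplyr::case_when(
      .data$distance <= dist_threshold &
        .data$correlation >= cor_threshold ~ "correlated",
      .data$distance > dist_threshold &
        .data$correlation < cor_threshold ~ "divergent",
      TRUE ~ "intermediate"
    ))
  if (!is.null(subgenome_map)) {
    sg <- setNames(subgenome_map$subgenome, subgenome_map$feature_id)
    pairs <- pairs %>%
      mutate(intra_subgenome = sg[.data$lnc_id] == sg[.data$mrna_id])
  }
  arrange(pairs, .data$lnc_id, .data$mrna_id)
}

#' Genomic distribution of lncRNA target sites
#'
#' Applies [annotate_position()] to each site and tabulates label
#' frequencies (fractions sum to 1 on non-empty input).
#'
#' @param sites Tibble `chrom`, `start`, `end`.
#' @param annotation An [annotation_set()].
#' @param ... Passed to [annotate_position()].
#' @return Tibble `feature`, `n`, `fraction`.
#' @export
target_site_distribution <- function(sites, annotation, ...) {
  if (!nrow(sites)) {
    return(tibble::tibble(feature = character(0), n = integer(0),
                          fraction = double(0)))
  }
  annotate_position(sites, annotation, ...) %>%
    count(.data$feature, .drop = FALSE, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}
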