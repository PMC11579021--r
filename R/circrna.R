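# Circular RNAs from back-splice junction (BSJ) tables: read-count
# filtering, exonic/intronic/intergenic classification, per-sample
# expression, flanking-intron features and alternative back-splicing.

#' Read a BED-like BSJ table
#'
#' Input columns: chrom, start (0-based), end, strand, sample, count.
#' Coordinates are converted to the package's 1-based inclusive
#' convention on read.
#'
#' @param path TSV path with a header.
#' @return Tibble `chrom`, `start`, `end`, `strand`, `sample`, `count`.
#' @export
read_bsj <- function(path) {
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c(chrom = "character",
                                          sample = "character")) %>%
    tibble::as_tibble()
  stopifnot(all(c("chrom", "start", "end", "strand",
                  "sample", "count") %in% names(tab)))
  tab %>% mutate(start = .data$start + 1L)
}

#' Filter back-splice junctions by read support
#'
#' A junction (identified by chrom/start/end/strand) is retained when its
#' maximum per-sample BSJ read count is at least `min_reads` (default 2).
#'
#' @param junctions Tibble `chrom`, `start`, `end`, `strand`, `sample`,
#'   `count` (1-based inclusive coordinates).
#' @param min_reads Read-support cutoff, inclusive.
#' @return The retained rows of `junctions`.
#' @export
filter_bsj <- function(junctions, min_reads = 2) {
  if (any(junctions$count < 0)) stop("negative BSJ read counts")
  junctions %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
    dplyr::filter(max(.data$count) >= min_reads) %>%
    ungroup()
}

#' Classify circRNAs and assign host genes
#'
#' A junction is `exonic` when both of its ends coincide exactly with
#' exon boundaries of a single host transcript, `intronic` when its span
#' lies within one intron of a host gene, and `intergenic` otherwise.
#' The host is the gene containing the span; ambiguity is resolved by
#' longest overlap, then lexicographic gene id.
#'
#' @param junctions Tibble of distinct junctions (`chrom`, `start`,
#'   `end`, `strand`).
#' @param annotation An [annotation_set()].
#' @return `junctions` with `circ_id`, `class` (factor exonic /
#'   intronic / intergenic), `host_gene` and the host's `subgenome`.
#' @export
classify_circrna <- function(junctions, annotation) {
  stopifnot(is_annotation_set(annotation))
  junc <- junctions %>%
    distinct(.data$chrom, .data$start, .data$end, .data$strand) %>%
    mutate(circ_id = sprintf("circ_%s_%d_%d_%s", .data$chrom,
                             .data$start, .data$end, .data$strand))
  genes <- annotation$genes
  exons <- annotation$exons
  introns <- intron_table(annotation)

  # host gene: longest overlap, then lexicographic id
  hosts <- junc %>%
    inner_join(genes %>%
                 select("gene_id", "chrom", g_start = "start",
                        g_end = "end", "subgenome"),
               by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(overlaps1(.data$start, .data$end,
                            .data$g_start, .data$g_end)) %>%
    mutate(ov = pmin(.data$end, .data$g_end) -
             pmax(.data$start, .data$g_start) + 1L) %>%
    group_by(.data$circ_id) %>%
    arrange(dplyr::desc(.data$ov), .data$gene_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("circ_id", host_gene = "gene_id", "subgenome")

  # exonic: both ends are exon boundaries of the same transcript
  left_hit <- junc %>%
    inner_join(exons %>% select("transcript_id", "chrom",
                                e_start = "start"),
               by = c("chrom", start = "e_start")) %>%
    distinct(.data$circ_id, .data$transcript_id)
  right_hit <- junc %>%
    inner_join(exons %>% select("transcript_id", "chrom", e_end = "end"),
               by = c("chrom", end = "e_end")) %>%
    distinct(.data$circ_id, .data$transcript_id)
  exonic_ids <- inner_join(left_hit, right_hit,
                           by = c("circ_id", "transcript_id")) %>%
    pull("circ_id") %>% unique()

  # intronic: span within a single intron of some gene
  intronic_ids <- junc %>%
    inner_join(introns %>% select("gene_id", "chrom",
                                  i_start = "start", i_end = "end"),
               by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(.data$i_start <= .data$start,
                  .data$end <= .data$i_end) %>%
    pull("circ_id") %>% unique()

  junc %>%
    left_join(hosts, by = "circ_id") %>%
    mutate(
      class = dplyr::case_when(
        .data$circ_id %in% exonic_ids ~ "exonic",
        .data$circ_id %in% intronic_ids ~ "intronic",
        TRUE ~ "intergenic"
      ),
      class = factor(.data$class,
                     levels = c("exonic", "intronic", "intergenic")),
      host_gene = if_else(.data$class == "intergenic",
                          NA_character_, .data$host_gene),
      subgenome = if_else(.data$class == "intergenic",
                          NA_character_, .data$subgenome)
    )
}

#' Back-splice junction reads per million mapped reads
#'
#' @param bsj_count BSJ read count(s).
#' @param mapped_reads Per-sample mapped-read total(s), > 0.
#' @return `bsj_count / mapped_reads * 1e6`.
#' @export
circ_expression <- function(bsj_count, mapped_reads) {
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  bsj_count / mapped_reads * 1e6
}

#' Per-sample circRNA expression table
#'
#' Joins junction counts with sample metadata and normalises each count
#' to junction reads per million mapped reads.
#'
#' @param junctions Filtered junction tibble (with `sample`, `count`).
#' @param samples Tibble `sample`, `organ`, `replicate`, `mapped_reads`.
#' @return Tibble with one row per junction x sample carrying `rpm`.
#' @export
circ_expression_table <- function(junctions, samples) {
  stopifnot(all(c("sample", "mapped_reads") %in% names(samples)))
  junctions %>%
    mutate(circ_id = sprintf("circ_%s_%d_%d_%s", .data$chrom,
                             .data$start, .data$end, .data$strand)) %>%
    inner_join(samples, by = "sample") %>%
    mutate(rpm = circ_expression(.data$count, .data$mapped_reads))
}

#' Flanking-intron features of a circRNA
#'
#' For each classified circRNA with a host gene, reports the lengths of
#' the host-transcript introns immediately upstream and downstream of
#' the circle, the number of reverse-complement matches between the two
#' flanking intron sequences (via [find_rc_matches()]), and the fraction
#' of the flanks covered by repeat intervals. Missing flanks (terminal
#' exons) are reported as `NA`.
#'
#' @param circ Output of [classify_circrna()] (one row per circRNA).
#' @param annotation An [annotation_set()].
#' @param genome Named character vector of sequences.
#' @param repeats Optional tibble `chrom`, `start`, `end` (1-based) of
#'   repeat intervals.
#' @param ... Passed to [find_rc_matches()].
#' @return `circ` with `up_intron_len`, `down_intron_len`,
#'   `rc_match_count`, `repeat_fraction` columns.
#' @export
flanking_features <- function(circ, annotation, genome, repeats = NULL,
                              ...) {
  stopifnot(is_annotation_set(annotation))
  introns <- intron_table(annotation)
  n <- nrow(circ)
  up_len <- down_len <- rep(NA_integer_, n)
  rc_n <- rep(NA_integer_, n)
  rep_frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- circ$host_gene[i]
    if (is.na(g)) next
    gi <- introns %>% dplyr::filter(.data$gene_id == g,
                                    .data$chrom == circ$chrom[i])
    up <- gi %>% dplyr::filter(.data$end < circ$start[i]) %>%
      arrange(dplyr::desc(.data$end)) %>% slice(1)
    down <- gi %>% dplyr::filter(.data$start > circ$end[i]) %>%
      arrange(.data$start) %>% slice(1)
    flanks <- character(0)
    if (nrow(up)) {
      up_len[i] <- up$end - up$start + 1L
      flanks <- c(flanks,
                  up = substr(genome[[circ$chrom[i]]], up$start, up$end))
    }
    if (nrow(down)) {
      down_len[i] <- down$end - down$start + 1L
      flanks <- c(flanks,
                  down = substr(genome[[circ$chrom[i]]], down$start, down$end))
    }
    if (length(flanks) == 2) {
      rc_n[i] <- nrow(find_rc_matches(flanks[["up"]], flanks[["down"]], ...))
    }
    if (!is.null(repeats) && length(flanks)) {
      iv <- bind_rows(
        if (nrow(up)) tibble::tibble(start = up$start, end = up$end),
        if (nrow(down)) tibble::tibble(start = down$start, end = down$end)
      )
      rp <- repeats %>% dplyr::filter(.data$chrom == circ$chrom[i])
      covered <- 0L
      for (r in seq_len(nrow(iv))) {
        if (nrow(rp)) {
          s <- pmax(rp$start, iv$start[r]); e <- pmin(rp$end, iv$end[r])
          seg <- tibble::tibble(start = s[e >= s], end = e[e >= s])
          if (nrow(seg)) {
            seg <- seg %>% arrange(.data$start) %>%
              mutate(grp = cumsum(.data$start >
                                    dplyr::lag(cummax(.data$end),
                                               default = -1L) + 1L)) %>%
              group_by(.data$grp) %>%
              summarise(start = min(.data$start), end = max(.data$end),
                        .groups = "drop")
            covered <- covered + sum(seg$end - seg$start + 1L)
          }
        }
      }
      rep_frac[i] <- covered / sum(iv$end - iv$start + 1L)
    }
  }
  circ %>%
    mutate(up_intron_len = up_len, down_intron_len = down_len,
           rc_match_count = rc_n, repeat_fraction = rep_frac)
}

#' Host genes with alternative back-splicing
#'
#' @param circ Output of [classify_circrna()].
#' @return Tibble of host genes producing >= 2 distinct circRNAs, with
#'   their circRNA counts.
#' @export
alternative_backsplicing <- function(circ) {
  circ %>%
    dplyr::filter(!is.na(.data$host_gene)) %>%
    distinct(.data$host_gene, .data$chrom, .data$start, .data$end,
             .data$strand) %>%
    count(.data$host_gene, name = "n_circ") %>%
    dplyr::filter(.data$n_circ >= 2)
}
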