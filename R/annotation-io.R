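# GTF / FASTA / table I/O. GTF is written 1-based inclusive (native GTF
# convention, identical to the internal representation); BED-like inputs
# elsewhere are converted on read.

#' Read a GTF file into an annotation set
#'
#' Parses `exon` and `CDS` features; other feature lines (gene, transcript,
#' UTR...) are ignored because the model derives spans from exons. The
#' `gene_id` and `transcript_id` attributes are required; the full attribute
#' string of each exon line is preserved verbatim in an `attributes` column
#' and re-emitted by [write_gtf()].
#'
#' @param path Path to a GTF file.
#' @param chrom_table Optional tibble mapping `chrom` to `subgenome`.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path, chrom_table = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty GTF: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("malformed GTF line(s) (expected 9 tab-separated fields) at line ",
         paste(which(nf != 9)[1], collapse = ","), " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  tab <- tibble::tibble(
    chrom = m[, 1], feature = m[, 3],
    start = suppressWarnings(as.integer(m[, 4])),
    end = suppressWarnings(as.integer(m[, 5])),
    strand = m[, 7], attributes = m[, 9]
  )
  if (any(is.na(tab$start) | is.na(tab$end))) {
    stop("malformed GTF coordinates at line ",
         which(is.na(tab$start) | is.na(tab$end))[1], " of ", path)
  }
  tab <- dplyr::filter(tab, .data$feature %in% c("exon", "CDS"))
  gid <- stringr::str_match(tab$attributes, 'gene_id "([^"]+)"')[, 2]
  tid <- stringr::str_match(tab$attributes, 'transcript_id "([^"]+)"')[, 2]
  if (any(is.na(gid)) || any(is.na(tid))) {
    stop("GTF line without gene_id/transcript_id attribute in ", path)
  }
  tab$gene_id <- gid
  tab$transcript_id <- tid
  exons <- dplyr::filter(tab, .data$feature == "exon") %>%
    select("transcript_id", "gene_id", "chrom", "strand",
           "start", "end", "attributes")
  cds <- dplyr::filter(tab, .data$feature == "CDS") %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  annotation_set(exons, cds = if (nrow(cds)) cds else NULL,
                 chrom_table = chrom_table)
}

#' Write an annotation set as GTF
#'
#' Emits one `exon` line per exon (re-using the preserved attribute string
#' when present) and one `CDS` line per coding interval. Rows are ordered
#' by chrom, gene, transcript, coordinate so output is deterministic.
#'
#' @param annotation An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(is_annotation_set(annotation))
  ex <- annotation$exons
  attrs <- if ("attributes" %in% names(ex)) {
    ex$attributes
  } else {
    sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id)
  }
  ex_lines <- tibble::tibble(
    chrom = ex$chrom, gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    start = ex$start, end = ex$end, strand = ex$strand,
    feature = "exon", attr = attrs
  )
  cd <- annotation$cds
  cd_lines <- if (nrow(cd)) {
    tibble::tibble(
      chrom = cd$chrom, gene_id = cd$gene_id, transcript_id = cd$transcript_id,
      start = cd$start, end = cd$end, strand = cd$strand,
      feature = "CDS",
      attr = sprintf('gene_id "%s"; transcript_id "%s";',
                     cd$gene_id, cd$transcript_id)
    )
  } else {
    ex_lines[0, ]
  }
  all_lines <- bind_rows(ex_lines, cd_lines) %>%
    arrange(.data$chrom, .data$gene_id, .data$transcript_id,
            .data$start, dplyr::desc(.data$feature))
  out <- sprintf("%s\tsubgenomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                 all_lines$chrom, all_lines$feature, all_lines$start,
                 all_lines$end, all_lines$strand, all_lines$attr)
  writeLines(out, path)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings keeping the in-memory genome as a named
#' character vector of upper-case sequences.
#'
#' @param path FASTA path.
#' @return `read_genome()`: named character vector. `write_genome()`:
#'   `path`, invisibly.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_genome
#' @param genome Named character vector of sequences.
#' @export
write_genome <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
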