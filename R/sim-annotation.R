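# Synthetic annotation: collinear gene layout (homoeologs share ranks on
# paired chromosomes), multi-isoform genes with injected AS events,
# coding sequences written into the genome, ORF-free lncRNA genes, and a
# ground-truth record for every planted feature.

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# split `total` into n parts, each >= min_part
split_lengths <- function(total, n, min_part) {
  if (n == 1) return(total)
  rem <- total - n * min_part
  stopifnot(rem >= 0)
  cuts <- sort(sample.int(rem + n - 1, n - 1))
  parts <- diff(c(0L, cuts, rem + n))
  as.integer(min_part + parts - 1L)
}

# derive one alternative isoform (exon intervals, genomic order) from a
# base structure; returns list(starts, ends, event)
variant_isoform <- function(starts, ends) {
  n_ex <- length(starts)
  introns_ok <- n_ex >= 2
  choice <- if (n_ex >= 3 && runif(1) < 0.45) {
    "skip"
  } else if (introns_ok && runif(1) < 0.5) {
    "retention"
  } else if (introns_ok) {
    "altb"
  } else {
    "trim"
  }
  if (choice == "skip") {
    j <- if (n_ex == 3) 2L else sample(2:(n_ex - 1), 1)
    list(starts = starts[-j], ends = ends[-j], event = "skip")
  } else if (choice == "retention") {
    j <- if (n_ex == 2) 1L else sample(n_ex - 1, 1)
    ns <- starts[-(j + 1)]
    ne <- ends[-j]
    list(starts = ns, ends = ne, event = "retention")
  } else if (choice == "altb") {
    j <- if (n_ex == 2) 1L else sample(n_ex - 1, 1)
    intron_len <- starts[j + 1] - ends[j] - 1L
    delta <- 3L * sample(2:8, 1)
    if (delta > intron_len - 20L) {
      ns <- starts[-(j + 1)]
      ne <- ends[-j]
      return(list(starts = ns, ends = ne, event = "retention"))
    }
    if (runif(1) < 0.5) {
      ends[j] <- ends[j] + delta
    } else {
      starts[j + 1] <- starts[j + 1] - delta
    }
    list(starts = starts, ends = ends, event = "altb")
  } else {
    # mono-exon: 5'-trimmed variant
    starts[1] <- starts[1] + 60L
    list(starts = starts, ends = ends, event = "trim")
  }
}

# map a transcript-coordinate interval to genomic intervals
spliced_to_genomic <- function(starts, ends, strand, s, e) {
  ord <- if (strand == "-") rev(seq_along(starts)) else seq_along(starts)
  st <- starts[ord]; en <- ends[ord]
  lens <- en - st + 1L
  ce <- cumsum(lens); cs <- ce - lens + 1L
  gs <- ge <- integer(0)
  for (i in seq_along(st)) {
    os <- max(s, cs[i]); oe <- min(e, ce[i])
    if (os > oe) next
    if (strand == "+") {
      gs <- c(gs, st[i] + (os - cs[i])); ge <- c(ge, st[i] + (oe - cs[i]))
    } else {
      gs <- c(gs, en[i] - (oe - cs[i])); ge <- c(ge, en[i] - (os - cs[i]))
    }
  }
  o <- order(gs)
  list(start = gs[o], end = ge[o])
}

# build one gene inside its slot; returns modified slot string plus
# per-transcript exon intervals (slot-relative)
build_gene <- function(slot_seq, is_lnc, is_as) {
  strand <- if (runif(1) < 0.5) "+" else "-"
  offset <- sample(40:200, 1)
  if (!is_lnc) {
    n_ex <- sample(2:4, 1)
    utr5 <- 3L * sample(10:30, 1)
    # always above the 100-aa lncRNA cutoff, as for real mRNAs
    cds_codons <- sample(110:200, 1)
    utr3 <- 3L * sample(20:50, 1)
    spliced_len <- utr5 + 3L * (cds_codons + 2L) + utr3
    lens_t <- split_lengths(spliced_len, n_ex, 40L)
    spliced <- paste0(
      random_dna(utr5),
      "ATG",
      paste(sample(NONSTOP_CODONS, cds_codons, replace = TRUE),
            collapse = ""),
      sample(c("TAA", "TAG", "TGA"), 1),
      random_dna(utr3)
    )
  } else {
    n_ex <- sample(1:2, 1)
    spliced_len <- sample(300:600, 1)
    lens_t <- split_lengths(spliced_len, n_ex, 120L)
    spliced <- random_dna(spliced_len)
    # break any ORF of >= 100 aa so the lncRNA filter keeps it
    repeat {
      orf <- orf_scan(spliced, min_aa = 99)
      if (is.null(orf)) break
      p <- orf$start + 30L
      substr(spliced, p, p + 2L) <- "TAA"
    }
  }
  lens_g <- if (strand == "-") rev(lens_t) else lens_t
  introns <- if (n_ex > 1) sample(60:240, n_ex - 1, replace = TRUE)
             else integer(0)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- offset
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + lens_g[i] - 1L
    pos <- ends[i] + 1L + (if (i < n_ex) introns[i] else 0L)
  }
  gseq <- if (strand == "-") revcomp(spliced) else spliced
  cum <- cumsum(lens_g)
  for (i in seq_len(n_ex)) {
    piece <- substr(gseq, cum[i] - lens_g[i] + 1L, cum[i])
    substr(slot_seq, starts[i], ends[i]) <- piece
  }
  tx <- list(list(starts = starts, ends = ends))
  if (is_as) {
    spliced_of <- function(st, en) {
      s <- paste(substring(slot_seq, st, en), collapse = "")
      if (strand == "-") revcomp(s) else s
    }
    n_extra <- sample(1:2, 1)
    for (k in seq_len(n_extra)) {
      v <- NULL
      if (!is_lnc) {
        # coding isoforms must keep a >100 aa ORF or they would leak
        # into the lncRNA set; rejected variants fall back to a pure
        # 3'UTR trim which never touches the ORF
        for (try in 1:10) {
          cand <- variant_isoform(starts, ends)
          s <- spliced_of(cand$starts, cand$ends)
          if (!is.null(orf_scan(s, min_aa = 100))) {
            v <- cand
            break
          }
        }
        if (is.null(v)) {
          ns <- starts; ne <- ends
          if (strand == "+") {
            ne[n_ex] <- ne[n_ex] - 30L
          } else {
            ns[1] <- ns[1] + 30L
          }
          v <- list(starts = ns, ends = ne)
        }
      } else {
        v <- variant_isoform(starts, ends)
      }
      tx <- c(tx, list(v[c("starts", "ends")]))
    }
  }
  list(slot_seq = slot_seq, strand = strand, transcripts = tx)
}

#' Generate the synthetic annotation with ground truth
#'
#' Genes are laid out collinearly, one per fixed-size slot, so that
#' homoeologs occupy the same rank on paired chromosomes (gene r of Ai
#' pairs with gene r of Bi). With probability `p_as_*` a gene carries
#' one or two extra isoforms derived from its base isoform by exon
#' skipping, intron retention or an alternative donor/acceptor shift;
#' with probability `p_lnc_*` a gene is a lncRNA gene (spliced length
#' 300-600 bp, no ORF of 100+ aa). Coding genes get a clean
#' ATG..stop CDS (plus UTRs) written into the genome; the CDS of every
#' isoform is then re-derived from its spliced sequence's longest ORF,
#' so frame-disrupting variants naturally truncate their protein.
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param config A [simulate_config()].
#' @param with_cds Derive CDS intervals for every coding-gene isoform
#'   (default `TRUE`). Structural studies that only need gene and exon
#'   models can skip this step; the random draws are unaffected.
#' @return List: `annotation` ([annotation_set()]), `genome` (with the
#'   coding sequences written in), `pairs` (homoeolog table `gene_a`,
#'   `gene_b`, `block_id`), and `truth` (per-gene tibble with planted
#'   `is_as`, `is_lnc`, `homoeolog_partner`).
#' @export
simulate_annotation <- function(genome_obj, config, with_cds = TRUE) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "annotation"))
  genome <- genome_obj$genome
  chrom_table <- genome_obj$chrom_table

  ex_acc <- vector("list", 0)
  gene_rows <- vector("list", 0)
  slot_bp <- config$slot_bp

  for (ci in seq_len(nrow(chrom_table))) {
    chrom <- chrom_table$chrom[ci]
    sg <- chrom_table$subgenome[ci]
    n_genes <- if (sg == "unanchored") config$genes_per_unanchored
               else config$genes_per_chrom
    p_as <- switch(sg, A = config$p_as_A, B = config$p_as_B,
                   mean(c(config$p_as_A, config$p_as_B)))
    p_lnc <- switch(sg, A = config$p_lnc_A, B = config$p_lnc_B,
                    mean(c(config$p_lnc_A, config$p_lnc_B)))
    seq_ch <- genome[[chrom]]
    slots <- substring(seq_ch,
                       (seq_len(n_genes) - 1L) * slot_bp + 1L,
                       seq_len(n_genes) * slot_bp)
    is_lnc <- runif(n_genes) < p_lnc
    is_as <- runif(n_genes) < p_as
    for (r in seq_len(n_genes)) {
      g <- build_gene(slots[r], is_lnc[r], is_as[r])
      slots[r] <- g$slot_seq
      gid <- sprintf("g%s_%03d", chrom, r)
      base <- (r - 1L) * slot_bp
      for (t in seq_along(g$transcripts)) {
        tr <- g$transcripts[[t]]
        ex_acc[[length(ex_acc) + 1L]] <- list(
          transcript_id = sprintf("%s.t%d", gid, t),
          gene_id = gid, chrom = chrom, strand = g$strand,
          start = as.integer(base + tr$starts),
          end = as.integer(base + tr$ends)
        )
      }
      gene_rows[[length(gene_rows) + 1L]] <- list(
        gene_id = gid, chrom = chrom, subgenome = sg, rank = r,
        is_lnc = is_lnc[r], is_as = is_as[r], strand = g$strand,
        n_isoforms = length(g$transcripts)
      )
    }
    genome[[chrom]] <- paste0(paste(slots, collapse = ""),
                              substr(seq_ch, n_genes * slot_bp + 1L,
                                     nchar(seq_ch)))
  }

  n_ex_each <- vapply(ex_acc, function(x) length(x$start), integer(1))
  exons <- tibble::tibble(
    transcript_id = rep(vapply(ex_acc, `[[`, "", "transcript_id"),
                        n_ex_each),
    gene_id = rep(vapply(ex_acc, `[[`, "", "gene_id"), n_ex_each),
    chrom = rep(vapply(ex_acc, `[[`, "", "chrom"), n_ex_each),
    strand = rep(vapply(ex_acc, `[[`, "", "strand"), n_ex_each),
    start = unlist(lapply(ex_acc, `[[`, "start")),
    end = unlist(lapply(ex_acc, `[[`, "end"))
  )
  gene_truth <- tibble::tibble(
    gene_id = vapply(gene_rows, `[[`, "", "gene_id"),
    chrom = vapply(gene_rows, `[[`, "", "chrom"),
    subgenome = vapply(gene_rows, `[[`, "", "subgenome"),
    rank = vapply(gene_rows, function(x) as.integer(x$rank), integer(1)),
    is_lnc = vapply(gene_rows, `[[`, NA, "is_lnc"),
    is_as = vapply(gene_rows, `[[`, NA, "is_as"),
    n_isoforms = vapply(gene_rows,
                        function(x) as.integer(x$n_isoforms), integer(1))
  )
  if (any(exons$end > chrom_table$length[match(exons$chrom,
                                               chrom_table$chrom)])) {
    stop("gene layout exceeds chromosome length; increase slot_bp")
  }

  # CDS of every transcript of a coding gene: longest ORF of its spliced
  # sequence mapped back to genomic intervals
  coding_set <- if (with_cds) gene_truth$gene_id[!gene_truth$is_lnc]
                else character(0)
  keep <- exons$gene_id %in% coding_set
  ctx <- exons[keep & !duplicated(exons$transcript_id), ]
  coding_tx <- ctx[c("transcript_id", "gene_id", "chrom", "strand")]
  ex_by_tx <- split(exons[c("start", "end")], exons$transcript_id)
  cds_rows <- vector("list", 0)
  for (i in seq_len(nrow(coding_tx))) {
    exi0 <- ex_by_tx[[coding_tx$transcript_id[i]]]
    sp <- paste(substring(genome[[coding_tx$chrom[i]]],
                          exi0$start, exi0$end), collapse = "")
    if (coding_tx$strand[i] == "-") sp <- revcomp(sp)
    orf <- orf_scan(sp, min_aa = 19)
    if (is.null(orf)) next
    exi <- ex_by_tx[[coding_tx$transcript_id[i]]]
    gv <- spliced_to_genomic(exi$start, exi$end, coding_tx$strand[i],
                             orf$start, orf$end)
    cds_rows[[length(cds_rows) + 1L]] <- list(
      transcript_id = coding_tx$transcript_id[i],
      gene_id = coding_tx$gene_id[i],
      chrom = coding_tx$chrom[i], strand = coding_tx$strand[i],
      start = gv$start, end = gv$end
    )
  }
  n_cds_each <- vapply(cds_rows, function(x) length(x$start), integer(1))
  cds <- if (length(cds_rows)) {
    tibble::tibble(
      transcript_id = rep(vapply(cds_rows, `[[`, "", "transcript_id"),
                          n_cds_each),
      gene_id = rep(vapply(cds_rows, `[[`, "", "gene_id"), n_cds_each),
      chrom = rep(vapply(cds_rows, `[[`, "", "chrom"), n_cds_each),
      strand = rep(vapply(cds_rows, `[[`, "", "strand"), n_cds_each),
      start = unlist(lapply(cds_rows, `[[`, "start")),
      end = unlist(lapply(cds_rows, `[[`, "end"))
    )
  } else NULL

  annotation <- annotation_set(exons, cds = cds, chrom_table = chrom_table)

  # homoeolog pairs by construction: same rank on paired chromosomes
  nc <- config$n_chrom_per_subgenome
  pairs <- purrr::map_dfr(seq_len(nc), function(i) {
    tibble::tibble(
      gene_a = sprintf("gA%d_%03d", i, seq_len(config$genes_per_chrom)),
      gene_b = sprintf("gB%d_%03d", i, seq_len(config$genes_per_chrom)),
      block_id = sprintf("block_%d", i)
    )
  })
  partner <- c(setNames(pairs$gene_b, pairs$gene_a),
               setNames(pairs$gene_a, pairs$gene_b))
  gene_truth$homoeolog_partner <- unname(partner[gene_truth$gene_id])

  list(annotation = annotation, genome = genome, pairs = pairs,
       truth = gene_truth)
}
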