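# Synthetic back-splice junctions and RNA/DNA pileups, with decoy
# records violating every filter branch of the downstream callers.

# A/C/G/T count columns for one pileup row
pileup_counts <- function(ref, cov, alt_bases = character(0),
                          alt_counts = integer(0)) {
  v <- setNames(c(0L, 0L, 0L, 0L), BASES)
  v[ref] <- cov - sum(alt_counts)
  if (length(alt_bases)) v[alt_bases] <- alt_counts
  as.list(v)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate back-splice junctions and RNA/DNA pileups
#'
#' CircRNAs are planted per gene at `circ_rate_*` (intronic with
#' probability 0.7, exonic at exact exon boundaries otherwise); a
#' quarter of them receive only a single supporting read so the >= 2
#' read filter always has negatives. Editing sites are planted in
#' exonic positions at `edit_rate_*` per gene with true frequencies
#' around `edit_freq_*`, active in 1-3 organs, with homozygous-reference
#' DNA; decoy sites violating each filter branch (low coverage, low
#' frequency, DNA variant, multi-allelic, single replicate, missing
#' DNA) are always planted.
#'
#' @param genome Named character vector (post-annotation, CDS written).
#' @param annotation An [annotation_set()].
#' @param config A [simulate_config()].
#' @param samples Sample table from [simulate_expression()].
#' @return List: `bsj` (tibble `chrom`, `start`, `end`, `strand`,
#'   `sample`, `count`, 1-based), `rna_pileups`, `dna_pileup`,
#'   `libraries`, and `truth` (list with `circ` and `edit` tibbles, the
#'   latter including decoys with their `decoy_class`).
#' @export
simulate_events <- function(genome, annotation, config, samples) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "events"))
  organs <- unique(samples$organ)
  genes <- annotation$genes %>%
    left_join(dplyr::count(annotation$transcripts, .data$gene_id,
                           name = "n_tx"), by = "gene_id")
  base_tx <- annotation$transcripts %>%
    group_by(.data$gene_id) %>%
    arrange(.data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>% ungroup()
  ex_by_tx <- split(annotation$exons[c("start", "end")],
                    annotation$exons$transcript_id)
  introns <- intron_table(annotation)
  introns_by_gene <- split(introns, introns$gene_id)

  rate_of <- function(sg, a, b) switch(sg, A = a, B = b, mean(c(a, b)))

  ## ---- circRNAs ----------------------------------------------------
  circ_truth <- vector("list", 0)
  bsj_rows <- vector("list", 0)
  for (gi in seq_len(nrow(genes))) {
    sg <- genes$subgenome[gi]
    n_c <- rpois(1, rate_of(sg, config$circ_rate_A, config$circ_rate_B))
    if (n_c == 0) next
    g <- genes$gene_id[gi]
    t1 <- base_tx$transcript_id[base_tx$gene_id == g]
    ex <- ex_by_tx[[t1]]
    gin <- introns_by_gene[[g]]
    gin <- gin[gin$transcript_id == t1, , drop = FALSE]
    for (k in seq_len(n_c)) {
      intronic <- !is.null(gin) && nrow(gin) > 0 && runif(1) < 0.7
      if (intronic) {
        j <- if (nrow(gin) == 1) 1L else sample(nrow(gin), 1)
        cs <- gin$start[j] + 3L; ce <- gin$end[j] - 3L
        class <- "intronic"
      } else {
        i1 <- if (nrow(ex) == 1) 1L else sample(nrow(ex), 1)
        i2 <- if (nrow(ex) == 1) 1L else sample(nrow(ex), 1)
        cs <- ex$start[min(i1, i2)]; ce <- ex$end[max(i1, i2)]
        class <- "exonic"
      }
      if (ce > nchar(genome[[genes$chrom[gi]]]) || cs < 1) {
        stop("circRNA planted outside chromosome ", genes$chrom[gi])
      }
      passes <- runif(1) < 0.75
      if (passes) {
        act <- sample(organs, sample(min(3, length(organs)), 1))
        for (o in act) {
          reps <- samples$sample[samples$organ == o]
          lead <- sample(length(reps), 1)
          for (ri in seq_along(reps)) {
            cnt <- if (ri == lead) rpois(1, 2) + 2L else rpois(1, 1)
            if (cnt > 0) {
              bsj_rows[[length(bsj_rows) + 1L]] <- list(
                chrom = genes$chrom[gi], start = cs, end = ce,
                strand = genes$strand[gi], sample = reps[ri],
                count = as.integer(cnt))
            }
          }
        }
      } else {
        bsj_rows[[length(bsj_rows) + 1L]] <- list(
          chrom = genes$chrom[gi], start = cs, end = ce,
          strand = genes$strand[gi],
          sample = sample(samples$sample, 1), count = 1L)
      }
      circ_truth[[length(circ_truth) + 1L]] <- list(
        chrom = genes$chrom[gi], start = cs, end = ce,
        strand = genes$strand[gi], host_gene = g, subgenome = sg,
        class = class, passes_filter = passes)
    }
  }
  bsj <- bind_rows(lapply(bsj_rows, tibble::as_tibble))
  if (!nrow(bsj)) {
    bsj <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          sample = character(0), count = integer(0))
  }
  circ_tt <- if (length(circ_truth)) {
    bind_rows(lapply(circ_truth, tibble::as_tibble)) %>%
      distinct(.data$chrom, .data$start, .data$end, .data$strand,
               .keep_all = TRUE)
  } else {
    tibble::tibble(chrom = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   host_gene = character(0), subgenome = character(0),
                   class = character(0), passes_filter = logical(0))
  }
  # a junction planted twice may mix pass/fail draws; recompute from bsj
  if (nrow(circ_tt)) {
    maxn <- bsj %>%
      group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
      summarise(max_count = max(.data$count), .groups = "drop")
    circ_tt <- circ_tt %>%
      left_join(maxn, by = c("chrom", "start", "end", "strand")) %>%
      mutate(passes_filter = .data$max_count >= 2) %>%
      select(-"max_count")
  }

  ## ---- RNA editing -------------------------------------------------
  # candidate exonic positions per gene (base isoform)
  edit_truth <- vector("list", 0)
  rna_rows <- vector("list", 0)
  dna_rows <- vector("list", 0)
  used_pos <- new.env(parent = emptyenv())

  pick_positions <- function(gi, n) {
    g <- genes$gene_id[gi]
    t1 <- base_tx$transcript_id[base_tx$gene_id == g]
    ex <- ex_by_tx[[t1]]
    all_pos <- unlist(Map(seq.int, ex$start, ex$end))
    key <- genes$chrom[gi]
    taken <- get0(key, envir = used_pos, ifnotfound = integer(0))
    free <- setdiff(all_pos, taken)
    if (length(free) < n) n <- length(free)
    if (n == 0) return(integer(0))
    pos <- if (length(free) == 1) free else sample(free, n)
    assign(key, c(taken, pos), envir = used_pos)
    sort(pos)
  }

  emit_rna <- function(chrom, pos, ref, lib, cov,
                       alt_bases = character(0), alt_counts = integer(0)) {
    rna_rows[[length(rna_rows) + 1L]] <<- c(
      list(chrom = chrom, pos = pos, ref = ref),
      pileup_counts(ref, cov, alt_bases, alt_counts),
      list(library = lib))
  }
  emit_dna <- function(chrom, pos, ref, cov, alt_bases = character(0),
                       alt_counts = integer(0)) {
    dna_rows[[length(dna_rows) + 1L]] <<- c(
      list(chrom = chrom, pos = pos, ref = ref),
      pileup_counts(ref, cov, alt_bases, alt_counts),
      list(library = "dna"))
  }
  draw_alt <- function(ref) {
    others <- setdiff(BASES, ref)
    w <- ifelse(others == transition_of[[ref]], 2, 1)
    sample(others, 1, prob = w)
  }

  n_edit <- rpois(nrow(genes),
                  vapply(genes$subgenome, rate_of, numeric(1),
                         config$edit_rate_A, config$edit_rate_B))
  for (gi in seq_len(nrow(genes))) {
    if (n_edit[gi] == 0) next
    sg <- genes$subgenome[gi]
    chrom <- genes$chrom[gi]
    pos <- pick_positions(gi, n_edit[gi])
    if (!length(pos)) next
    f0 <- rate_of(sg, config$edit_freq_A, config$edit_freq_B)
    for (p in pos) {
      if (p > nchar(genome[[chrom]])) {
        stop("editing site planted outside chromosome ", chrom)
      }
      ref <- substr(genome[[chrom]], p, p)
      alt <- draw_alt(ref)
      freq <- min(0.95, max(0.12, rbeta(1, f0 * 12, (1 - f0) * 12)))
      act <- sample(organs, sample(min(3, length(organs)), 1))
      for (o in act) {
        for (lib in samples$sample[samples$organ == o]) {
          cov <- rpois(1, 25) + 10L
          ac <- rbinom(1, cov, freq)
          emit_rna(chrom, p, ref, lib, cov,
                   if (ac > 0) alt else character(0),
                   if (ac > 0) ac else integer(0))
        }
      }
      emit_dna(chrom, p, ref, rpois(1, 30) + 15L)
      edit_truth[[length(edit_truth) + 1L]] <- list(
        chrom = chrom, pos = p, ref = ref, alt = alt,
        true_freq = freq, subgenome = sg,
        n_organs_active = length(act),
        organs = paste(act, collapse = ","),
        decoy_class = NA_character_)
    }
  }

  ## ---- decoys: one batch per filter branch -------------------------
  n_planted <- length(edit_truth)
  n_decoy <- max(2L, round(0.03 * n_planted))
  decoy_types <- c("low_coverage", "low_frequency", "dna_variant",
                   "multi_allelic", "single_replicate", "no_dna")
  chrom_genes <- which(genes$subgenome %in% c("A", "B"))
  for (type in decoy_types) {
    for (d in seq_len(n_decoy)) {
      gi <- chrom_genes[sample(length(chrom_genes), 1)]
      pos <- pick_positions(gi, 1L)
      if (!length(pos)) next
      chrom <- genes$chrom[gi]
      ref <- substr(genome[[chrom]], pos, pos)
      alt <- draw_alt(ref)
      o <- sample(organs, 1)
      libs <- samples$sample[samples$organ == o]
      dna_cov <- rpois(1, 30) + 15L
      switch(type,
        low_coverage = {
          for (lib in libs) {
            cov <- sample(3:8, 1)
            emit_rna(chrom, pos, ref, lib, cov, alt,
                     max(1L, round(cov * 0.5)))
          }
          emit_dna(chrom, pos, ref, dna_cov)
        },
        low_frequency = {
          for (lib in libs) emit_rna(chrom, pos, ref, lib, 40L, alt, 2L)
          emit_dna(chrom, pos, ref, dna_cov)
        },
        dna_variant = {
          for (lib in libs) emit_rna(chrom, pos, ref, lib, 30L, alt, 12L)
          emit_dna(chrom, pos, ref, dna_cov, alt, round(dna_cov * 0.4))
        },
        multi_allelic = {
          alt2 <- setdiff(BASES, c(ref, alt))[1]
          for (lib in libs) {
            emit_rna(chrom, pos, ref, lib, 30L, c(alt, alt2), c(6L, 6L))
          }
          emit_dna(chrom, pos, ref, dna_cov)
        },
        single_replicate = {
          emit_rna(chrom, pos, ref, libs[1], 30L, alt, 12L)
          for (lib in libs[-1]) emit_rna(chrom, pos, ref, lib, 30L)
          emit_dna(chrom, pos, ref, dna_cov)
        },
        no_dna = {
          for (lib in libs) emit_rna(chrom, pos, ref, lib, 30L, alt, 12L)
        }
      )
      edit_truth[[length(edit_truth) + 1L]] <- list(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        true_freq = NA_real_, subgenome = genes$subgenome[gi],
        n_organs_active = 1L, organs = o, decoy_class = type)
    }
  }

  rna_pileups <- bind_rows(lapply(rna_rows, tibble::as_tibble))
  dna_pileup <- bind_rows(lapply(dna_rows, tibble::as_tibble))
  libraries <- samples %>%
    select(library = "sample", "organ", "replicate")
  list(
    bsj = bsj,
    rna_pileups = rna_pileups,
    dna_pileup = dna_pileup,
    libraries = libraries,
    truth = list(
      circ = circ_tt,
      edit = bind_rows(lapply(edit_truth, tibble::as_tibble))
    )
  )
}
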