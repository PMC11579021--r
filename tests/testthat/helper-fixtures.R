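# Hand-built miniature annotations and independent oracles used across
# the suite. Everything is constructed in code; nothing is read from
# disk.

# minimal exon-table builder: ex("tx1","g1","chr1","+", 1,100, 201,300)
ex_rows <- function(transcript_id, gene_id, chrom, strand, ...) {
  co <- c(...)
  stopifnot(length(co) %% 2 == 0)
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand,
    start = as.integer(co[seq(1, length(co), 2)]),
    end = as.integer(co[seq(2, length(co), 2)])
  )
}

tiny_config <- function(seed = 1, ...) {
  simulate_config(n_chrom_per_subgenome = 2, genes_per_chrom = 8,
                  n_unanchored = 1, genes_per_unanchored = 3,
                  seed = seed, ...)
}

# --- independent oracle: three-frame ORF scan by explicit codon walk ---
orf_brute <- function(seq, min_aa) {
  n <- nchar(seq)
  best <- NULL
  if (n < 3) return(NULL)
  for (st in 1:(n - 2)) {
    if (substr(seq, st, st + 2) != "ATG") next
    len <- 0; p <- st; stopped <- FALSE
    while (p + 2 <= n) {
      cd <- substr(seq, p, p + 2)
      if (p > st && cd %in% c("TAA", "TAG", "TGA")) {
        stopped <- TRUE
        break
      }
      len <- len + 1; p <- p + 3
    }
    e <- if (stopped) p + 2 else p - 1
    if (is.null(best) || len > best$aa_length) {
      best <- list(start = st, end = e, aa_length = len)
    }
  }
  if (is.null(best) || best$aa_length <= min_aa) NULL else best
}

# --- independent oracle: O(n*m*L) reverse-complement match scan -------
rc_brute <- function(seq_a, seq_b, min_len = 20, min_identity = 0.9) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b2 <- strsplit(revcomp(seq_b), "")[[1]]
  n <- length(a); m <- length(b2)
  hits <- list()
  for (d in (1 - m):(n - 1)) {
    j1 <- max(1, 1 - d); j2 <- min(m, n - d)
    L <- j2 - j1 + 1
    if (L < min_len) next
    mv <- a[(j1:j2) + d] == b2[j1:j2]
    cs <- c(0, cumsum(!mv))
    # prescreen: a qualifying interval always contains a 20-window with
    # <= 3 mismatches (disjoint-block argument), so skip diagonals
    # without one
    if (L >= min_len) {
      win_mm <- cs[(min_len + 1):(L + 1)] - cs[1:(L - min_len + 1)]
      if (min(win_mm) > 3) next
    }
    # all qualifying intervals, then drop those contained in another
    qual <- list()
    for (s in 1:(L - min_len + 1)) {
      e <- (s + min_len - 1):L
      mm <- cs[e + 1] - cs[s]
      len <- e - s + 1
      ok <- (len - mm) / len >= min_identity
      for (k in which(ok)) {
        qual <- c(qual, list(c(s, e[k], mm[k])))
      }
    }
    if (!length(qual)) next
    qm <- do.call(rbind, qual)
    keep <- vapply(seq_len(nrow(qm)), function(i) {
      !any(qm[, 1] <= qm[i, 1] & qm[, 2] >= qm[i, 2] &
             (qm[, 1] < qm[i, 1] | qm[, 2] > qm[i, 2]))
    }, logical(1))
    qm <- qm[keep, , drop = FALSE]
    len <- qm[, 2] - qm[, 1] + 1
    idy <- (len - qm[, 3]) / len
    o <- order(-idy, -len, qm[, 1])
    qm <- qm[o, , drop = FALSE]; len <- len[o]; idy <- idy[o]
    acc <- integer(0)
    for (i in seq_len(nrow(qm))) {
      if (!length(acc) ||
          !any(qm[i, 1] <= qm[acc, 2] & qm[acc, 1] <= qm[i, 2])) {
        acc <- c(acc, i)
      }
    }
    for (i in acc) {
      js <- qm[i, 1] + j1 - 1
      hits <- c(hits, list(tibble::tibble(
        a_start = js + d, a_end = js + d + len[i] - 1,
        b_start = nchar(seq_b) - (js + len[i] - 1) + 1,
        b_end = nchar(seq_b) - js + 1,
        length = len[i], identity = idy[i]
      )))
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(a_start = integer(0), a_end = integer(0),
                          b_start = integer(0), b_end = integer(0),
                          length = integer(0), identity = double(0)))
  }
  dplyr::arrange(dplyr::bind_rows(hits), a_start, b_start)
}

# --- independent oracle: editing filter rules applied row by row ------
editing_brute <- function(rna, dna, libraries, min_cov = 10,
                          min_freq = 0.1, min_reps = 2) {
  key <- function(ch, p) paste(ch, p)
  dna_ok <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dna))) {
    cov <- dna$A[i] + dna$C[i] + dna$G[i] + dna$T[i]
    refn <- dna[[dna$ref[i]]][i]
    assign(key(dna$chrom[i], dna$pos[i]), cov >= min_cov && refn == cov,
           envir = dna_ok)
  }
  org <- setNames(libraries$organ, libraries$library)
  out <- list()
  rna$organ <- org[rna$library]
  for (grp in split(rna, list(rna$chrom, rna$pos, rna$organ),
                    drop = TRUE)) {
    support <- list()
    for (i in seq_len(nrow(grp))) {
      cnt <- c(A = grp$A[i], C = grp$C[i], G = grp$G[i], T = grp$T[i])
      cov <- sum(cnt)
      alt <- cnt[setdiff(names(cnt), grp$ref[i])]
      alt <- alt[alt > 0]
      if (cov >= min_cov && length(alt) == 1 &&
          alt / cov >= min_freq) {
        support <- c(support, list(list(base = names(alt),
                                        alt = unname(alt), cov = cov)))
      }
    }
    if (length(support) < min_reps) next
    bases <- unique(vapply(support, `[[`, "", "base"))
    if (length(bases) != 1) next
    k <- key(grp$chrom[1], grp$pos[1])
    ok <- get0(k, envir = dna_ok, ifnotfound = NA)
    if (!isTRUE(ok)) next
    out <- c(out, list(tibble::tibble(
      chrom = grp$chrom[1], pos = grp$pos[1], ref = grp$ref[1],
      edited = bases, organ = grp$organ[1],
      frequency = sum(vapply(support, `[[`, 0, "alt")) /
        sum(vapply(support, `[[`, 0, "cov")),
      n_replicates = length(support)
    )))
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), edited = character(0),
                          organ = character(0), frequency = double(0),
                          n_replicates = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, pos, organ)
}

# --- independent oracle: pairwise AS events via exon-presence logic ---
as_events_brute <- function(ex_ref, ex_alt, strand) {
  iv_gaps <- function(x) {
    x <- x[order(x$start), ]
    if (nrow(x) < 2) return(data.frame(start = integer(0),
                                       end = integer(0)))
    data.frame(start = x$end[-nrow(x)] + 1, end = x$start[-1] - 1)
  }
  ir_r <- iv_gaps(ex_ref); ir_a <- iv_gaps(ex_alt)
  ev <- data.frame(type = character(0), start = integer(0),
                   end = integer(0))
  add <- function(t, s, e) {
    ev <<- rbind(ev, data.frame(type = t, start = s, end = e))
  }
  inside <- function(s, e, iv) {
    any(iv$start <= s & e <= iv$end)
  }
  for (i in seq_len(nrow(ir_r))) {
    if (inside(ir_r$start[i], ir_r$end[i], ex_alt)) {
      add("intron_retention", ir_r$start[i], ir_r$end[i])
    }
  }
  for (i in seq_len(nrow(ir_a))) {
    if (inside(ir_a$start[i], ir_a$end[i], ex_ref)) {
      add("intron_retention", ir_a$start[i], ir_a$end[i])
    }
  }
  sk_r <- which(vapply(seq_len(nrow(ex_ref)), function(i)
    inside(ex_ref$start[i], ex_ref$end[i], ir_a), logical(1)))
  sk_a <- which(vapply(seq_len(nrow(ex_alt)), function(i)
    inside(ex_alt$start[i], ex_alt$end[i], ir_r), logical(1)))
  used_r <- logical(length(sk_r)); used_a <- logical(length(sk_a))
  cont_idx <- function(s, e, iv) {
    h <- which(iv$start <= s & e <= iv$end)
    if (length(h)) h[1] else NA
  }
  for (i in seq_along(sk_r)) {
    ia <- cont_idx(ex_ref$start[sk_r[i]], ex_ref$end[sk_r[i]], ir_a)
    for (j in seq_along(sk_a)) {
      if (used_a[j]) next
      ir <- cont_idx(ex_alt$start[sk_a[j]], ex_alt$end[sk_a[j]], ir_r)
      if (is.na(ia) || is.na(ir)) next
      iv_overlap <- ir_a$start[ia] <= ir_r$end[ir] &&
        ir_r$start[ir] <= ir_a$end[ia]
      disjoint <- ex_ref$end[sk_r[i]] < ex_alt$start[sk_a[j]] ||
        ex_alt$end[sk_a[j]] < ex_ref$start[sk_r[i]]
      if (iv_overlap && disjoint) {
        add("mutually_exclusive",
            min(ex_ref$start[sk_r[i]], ex_alt$start[sk_a[j]]),
            max(ex_ref$end[sk_r[i]], ex_alt$end[sk_a[j]]))
        used_r[i] <- TRUE; used_a[j] <- TRUE
        break
      }
    }
  }
  for (i in seq_along(sk_r)) {
    if (!used_r[i]) add("exon_skip", ex_ref$start[sk_r[i]],
                        ex_ref$end[sk_r[i]])
  }
  for (j in seq_along(sk_a)) {
    if (!used_a[j]) add("exon_skip", ex_alt$start[sk_a[j]],
                        ex_alt$end[sk_a[j]])
  }
  for (i in seq_len(nrow(ir_r))) {
    for (j in seq_len(nrow(ir_a))) {
      if (ir_r$start[i] > ir_a$end[j] || ir_a$start[j] > ir_r$end[i]) next
      ss <- ir_r$start[i] == ir_a$start[j]
      se <- ir_r$end[i] == ir_a$end[j]
      if (ss == se) next
      if (ss) {
        d <- sort(c(ir_r$end[i], ir_a$end[j])); boundary <- "right"
      } else {
        d <- sort(c(ir_r$start[i], ir_a$start[j])); boundary <- "left"
      }
      swallows <- any(ex_ref$start >= d[1] & ex_ref$end <= d[2]) ||
        any(ex_alt$start >= d[1] & ex_alt$end <= d[2])
      if (swallows) next
      type <- if (strand == "+") {
        if (boundary == "left") "alt_donor" else "alt_acceptor"
      } else {
        if (boundary == "left") "alt_acceptor" else "alt_donor"
      }
      add(type, d[1], d[2])
    }
  }
  unique(ev)
}
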