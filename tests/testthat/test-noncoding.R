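# lncRNA filtering, the reverse-complement matcher and its brute-force
# oracle, expression pairing, and target-site distributions.

test_that("lncRNA filter applies both boundaries strictly", {
  # 200 bp ORF-free exon: excluded (length must exceed 200)
  g200 <- paste(rep("C", 400), collapse = "")
  ex <- bind_rows(
    ex_rows("t200", "g1", "c1", "+", 1, 200),
    ex_rows("t201", "g2", "c1", "+", 1, 201)
  )
  ann <- annotation_set(ex)
  got <- filter_lncrna(ann, c(c1 = g200))
  expect_equal(got$transcript_id, "t201")
  # 500 bp transcript with a 150-aa ORF: excluded
  orf_nt <- paste0("ATG", paste(rep("GCT", 150), collapse = ""), "TAA")
  chr2 <- paste0(orf_nt, paste(rep("C", 100), collapse = ""))
  ex2 <- ex_rows("twithorf", "g3", "c2", "+", 1, 500)
  expect_equal(nrow(filter_lncrna(annotation_set(ex2),
                                  c(c2 = chr2))), 0)
})

test_that("planted lncRNAs are recovered exactly from synthetic data", {
  cfg <- tiny_config(seed = 41, p_lnc_A = 0.3, p_lnc_B = 0.3)
  ds <- simulate_annotation(simulate_genome(cfg), cfg)
  got <- filter_lncrna(ds$annotation, ds$genome)
  want <- ds$annotation$transcripts$transcript_id[
    ds$annotation$transcripts$gene_id %in%
      ds$truth$gene_id[ds$truth$is_lnc]]
  expect_setequal(got$transcript_id, want)
})

test_that("rc matcher finds constructed complements and honours the
          length boundary", {
  set.seed(51)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  win <- substr(a, 101, 125)            # 25 bp
  b <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                    collapse = ""),
              revcomp(win),
              paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                    collapse = ""))
  got <- find_rc_matches(a, b)
  expect_gte(nrow(got), 1)
  best <- got[which.max(got$length), ]
  expect_gte(best$length, 25)
  expect_lte(best$a_start, 101)
  expect_gte(best$a_end, 125)
  # maximal intervals may extend past the perfect window, but stay
  # above the identity floor and cover the planted complement
  expect_gte(best$identity, 0.9)
  expect_lte(best$b_start, 41)
  expect_gte(best$b_end, 65)
  # 19 bp perfect complement: below min_len, no match
  win19 <- substr(a, 101, 119)
  b19 <- revcomp(win19)
  expect_equal(nrow(find_rc_matches(a, b19)), 0)
  expect_equal(nrow(find_rc_matches(a, substr(a, 101, 120))) >= 0, TRUE)
  # empty input
  expect_equal(nrow(find_rc_matches("", a)), 0)
})

test_that("rc matcher equals the brute-force all-window scan", {
  set.seed(52)
  n_checked <- 0
  for (i in 1:12) {
    la <- sample(60:150, 1); lb <- sample(60:150, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    # half the cases get a planted complement so matches exist
    if (i %% 2 == 0) {
      w <- sample(20:35, 1)
      s <- sample(1:(la - w), 1)
      piece <- substr(a, s, s + w - 1)
      # inject up to 2 mismatches
      pc <- strsplit(piece, "")[[1]]
      nmm <- sample(0:2, 1)
      if (nmm > 0) {
        at <- sample(seq_along(pc), nmm)
        pc[at] <- sample(c("A", "C", "G", "T"), nmm, TRUE)
      }
      ins <- sample(1:(lb - w), 1)
      substr(b, ins, ins + w - 1) <- revcomp(paste(pc, collapse = ""))
    }
    got <- find_rc_matches(a, b, min_len = 20, min_identity = 0.9)
    want <- rc_brute(a, b, min_len = 20, min_identity = 0.9)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(got)) {
      expect_equal(got$a_start, want$a_start, info = paste("case", i))
      expect_equal(got$length, want$length, info = paste("case", i))
      expect_equal(got$identity, want$identity, info = paste("case", i))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 12)
})

test_that("rc matching is symmetric up to the coordinate transform", {
  set.seed(53)
  a <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  b <- paste0(substr(a, 1, 30), revcomp(substr(a, 51, 80)))
  m_ab <- find_rc_matches(a, b)
  m_ba <- find_rc_matches(b, a)
  expect_equal(nrow(m_ab), nrow(m_ba))
  if (nrow(m_ab)) {
    expect_setequal(paste(m_ab$a_start, m_ab$a_end),
                    paste(m_ba$b_start, m_ba$b_end))
    expect_setequal(paste(m_ab$b_start, m_ab$b_end),
                    paste(m_ba$a_start, m_ba$a_end))
  }
})

test_that("lncRNA-mRNA pairs are classified by the distance and
          correlation thresholds", {
  organs <- paste0("o", 1:9)
  lseq <- paste(rep("ACGT", 30), collapse = "")
  mseq_hit <- revcomp(substr(lseq, 1, 30))
  mseq_miss <- paste(rep("AACC", 30), collapse = "")
  prof <- bind_rows(
    tibble::tibble(feature_id = "l1", organ = organs,
                   tpm = c(10, 20, 30, 40, 50, 60, 70, 80, 90)),
    tibble::tibble(feature_id = "m_same", organ = organs,
                   tpm = c(10, 20, 30, 40, 50, 60, 70, 80, 90)),
    tibble::tibble(feature_id = "m_anti", organ = organs,
                   tpm = c(90, 80, 70, 60, 50, 40, 30, 20, 10))
  )
  got <- suppressWarnings(pair_lncrna_mrna(
    c(l1 = lseq), c(m_same = mseq_hit, m_anti = mseq_hit,
                    m_none = mseq_miss), prof))
  expect_setequal(got$mrna_id, c("m_same", "m_anti"))
  same <- got[got$mrna_id == "m_same", ]
  expect_equal(same$distance, 0)
  expect_equal(same$correlation, 1)
  expect_equal(same$class, "correlated")
  anti <- got[got$mrna_id == "m_anti", ]
  expect_lt(anti$correlation, 0.667)
  expect_gt(anti$distance, 5.10)
  expect_equal(anti$class, "divergent")
  # partner missing from the profiles is skipped with a warning
  expect_warning(
    pair_lncrna_mrna(c(l1 = lseq), c(mx = mseq_hit), prof),
    "skipped")
  # class partition is total
  expect_true(all(got$class %in% c("correlated", "divergent",
                                   "intermediate")))
})

test_that("random profile pairs obey the threshold rule exactly", {
  set.seed(54)
  organs <- paste0("o", 1:9)
  lseq <- paste(rep("ACGT", 30), collapse = "")
  hit <- revcomp(substr(lseq, 1, 30))
  n <- 30
  prof <- bind_rows(purrr::map(seq_len(n), function(i) {
    bind_rows(
      tibble::tibble(feature_id = paste0("l", i), organ = organs,
                     tpm = stats::runif(9, 0, 200)),
      tibble::tibble(feature_id = paste0("m", i), organ = organs,
                     tpm = stats::runif(9, 0, 200))
    )
  }))
  for (i in sample(n, 6)) {
    lid <- paste0("l", i); mid <- paste0("m", i)
    got <- pair_lncrna_mrna(setNames(lseq, lid), setNames(hit, mid),
                            prof)
    lt <- log2(prof$tpm[prof$feature_id == lid][match(organs,
           prof$organ[prof$feature_id == lid])] + 1)
    mt <- log2(prof$tpm[prof$feature_id == mid][match(organs,
           prof$organ[prof$feature_id == mid])] + 1)
    d <- sqrt(sum((lt - mt)^2)); r <- stats::cor(lt, mt)
    want <- if (d <= 5.10 && r >= 0.667) "correlated"
            else if (d > 5.10 && r < 0.667) "divergent"
            else "intermediate"
    expect_equal(got$class, want)
    expect_equal(got$distance, d)
    expect_equal(got$correlation, r)
  }
})

test_that("target-site distributions sum to one and match plantings", {
  ex <- bind_rows(
    ex_rows("t1", "g1", "c1", "+", 50001, 50200, 50501, 51000)
  )
  cds <- ex_rows("t1", "g1", "c1", "+", 50101, 50200, 50501, 50800)
  ann <- annotation_set(ex, cds)
  sites <- tibble::tibble(
    chrom = "c1",
    start = c(rep(49900, 3), rep(50400, 2), rep(30000, 5)),
    end = c(rep(49900, 3), rep(50400, 2), rep(30000, 5))
  )
  got <- target_site_distribution(sites, ann, promoter_window = 300,
                                  downstream_window = 300)
  expect_equal(sum(got$fraction), 1)
  expect_equal(got$fraction[got$feature == "promoter"], 0.3)
  expect_equal(got$fraction[got$feature == "intron"], 0.2)
  expect_equal(got$fraction[got$feature == "distal_intergenic"], 0.5)
  expect_equal(nrow(target_site_distribution(sites[0, ], ann)), 0)
})
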