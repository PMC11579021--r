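# Synteny chaining, the contrast statistics with their oracles,
# homoeolog overlap, enrichment tests, and the full report.

test_that("synteny chaining keeps runs of >= 5 collinear pairs only", {
  order_tbl <- bind_rows(
    tibble::tibble(gene_id = paste0("a", 1:20), chrom = "A1",
                   rank = 1:20),
    tibble::tibble(gene_id = paste0("b", 1:20), chrom = "B1",
                   rank = 1:20)
  )
  six <- tibble::tibble(gene_a = paste0("a", 1:6),
                        gene_b = paste0("b", 1:6))
  got6 <- chain_synteny(six, order_tbl)
  expect_equal(nrow(got6$blocks), 1)
  expect_equal(got6$blocks$n_pairs, 6L)
  expect_equal(nrow(got6$pairs), 6)
  four <- tibble::tibble(gene_a = paste0("a", 1:4),
                         gene_b = paste0("b", 1:4))
  got4 <- chain_synteny(four, order_tbl)
  expect_equal(nrow(got4$blocks), 0)
  expect_equal(nrow(got4$pairs), 0)
  # antiparallel runs chain too
  inv <- tibble::tibble(gene_a = paste0("a", 1:6),
                        gene_b = paste0("b", 16:11))
  expect_equal(nrow(chain_synteny(inv, order_tbl)$blocks), 1)
  # a large rank gap breaks the chain
  gap <- tibble::tibble(gene_a = paste0("a", c(1:5, 10:14)),
                        gene_b = paste0("b", c(1:5, 10:14)))
  gotg <- chain_synteny(gap, order_tbl, max_gap = 3)
  expect_equal(sort(gotg$blocks$n_pairs), c(5L, 5L))
  expect_error(chain_synteny(tibble::tibble(gene_a = "zz",
                                            gene_b = "b1"),
                             order_tbl), "absent")
})

test_that("synteny recovers the generator's homoeolog pairing", {
  cfg <- tiny_config(seed = 91)
  ds <- simulate_annotation(simulate_genome(cfg), cfg)
  gene_order <- ds$annotation$genes %>%
    dplyr::group_by(chrom) %>%
    dplyr::arrange(start, .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select(gene_id, chrom, rank)
  got <- chain_synteny(ds$pairs[c("gene_a", "gene_b")], gene_order)
  expect_setequal(paste(got$pairs$gene_a, got$pairs$gene_b),
                  paste(ds$pairs$gene_a, ds$pairs$gene_b))
})

test_that("chi-squared contrast matches the closed-form Yates formula", {
  flat <- count_contrast(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(count_contrast(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
  yates_manual <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    # correction is capped at |O - E| so the statistic stays >= 0
    y <- min(0.5, abs(m - E)[1, 1])
    stat <- sum((abs(m - E) - y)^2 / E)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  set.seed(92)
  for (i in 1:200) {
    m <- matrix(stats::rpois(4, sample(c(20, 200, 2000), 1)) + 1L, 2, 2)
    expect_equal(count_contrast(m)$p_value, yates_manual(m),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon contrast agrees with exact rank enumeration for
          small samples", {
  exact_oracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    idx <- utils::combn(nx + ny, nx)
    ws <- apply(idx, 2, function(k) sum(r[k])) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
    p
  }
  set.seed(93)
  for (i in 1:20) {
    x <- sample(1:1000, sample(3:8, 1))
    y <- sample(2000:3000, sample(3:8, 1)) + 0.5   # tie-free by design
    got <- distribution_contrast(x, y)
    expect_equal(got$p_value, exact_oracle(x, y), tolerance = 1e-9)
  }
  # identical large samples: p near 1; separation: tiny p
  z <- stats::rnorm(50)
  expect_gt(distribution_contrast(z, z)$p_value, 0.9)
  expect_lt(distribution_contrast(z, z + 100)$p_value, 1e-6)
  expect_error(distribution_contrast(numeric(0), z), "empty")
})

test_that("spearman contrast matches the rank formula", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(spearman_contrast(sort(x), sort(x) * 2)$statistic, 1)
  expect_equal(spearman_contrast(sort(x), rev(sort(x)))$statistic, -1)
  set.seed(94)
  for (i in 1:20) {
    a <- stats::rnorm(30); b <- stats::rnorm(30)
    got <- spearman_contrast(a, b)$statistic
    want <- stats::cor(rank(a), rank(b))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(spearman_contrast(1:3, 1:4), "mismatch")
})

test_that("homoeolog overlap partitions pairs and reproduces rates", {
  pairs <- tibble::tibble(gene_a = paste0("a", 1:10),
                          gene_b = paste0("b", 1:10))
  flags <- setNames(c(rep(TRUE, 6), rep(FALSE, 4),
                      rep(TRUE, 8), rep(FALSE, 2)),
                    c(paste0("a", 1:10), paste0("b", 1:10)))
  got <- homoeolog_event_overlap(pairs, flags)
  expect_equal(sum(got$counts), 10)
  expect_equal(unname(got$counts["both"]),
               sum(flags[paste0("a", 1:10)] & flags[paste0("b", 1:10)]))
  expect_equal(got$rate_A, 0.6)
  expect_equal(got$rate_B, 0.8)
  # all-on pairs
  all_on <- homoeolog_event_overlap(
    pairs, setNames(rep(TRUE, 20), names(flags)))
  expect_equal(unname(all_on$percent["both"]), 100)
  # missing flags default to FALSE with a message
  expect_message(
    part <- homoeolog_event_overlap(pairs, flags[1:15]),
    "treated as FALSE")
  expect_equal(sum(part$counts), 10)
})

test_that("term enrichment is calibrated and BH-adjusted", {
  set.seed(95)
  universe <- paste0("g", 1:500)
  gene2term <- bind_rows(purrr::map(1:60, function(t) {
    tibble::tibble(term = paste0("T", t),
                   gene_id = sample(universe, 25))
  }))
  # planted signal: a term fully contained in the gene set
  special <- tibble::tibble(term = "Tspecial",
                            gene_id = paste0("g", 1:25))
  got <- go_enrichment(paste0("g", 1:40),
                       bind_rows(gene2term, special), universe)
  expect_true(got$enriched[got$term == "Tspecial"])
  # null: random gene set, ~5% raw rejections, none after BH
  null_set <- sample(universe, 40)
  null_res <- go_enrichment(null_set, gene2term, universe)
  expect_lt(mean(null_res$p_value < 0.05), 0.2)
  expect_equal(sum(null_res$enriched), 0)
  expect_error(go_enrichment(c("nope"), gene2term, universe),
               "outside")
  # BH is monotone after the step-up transform
  expect_true(all(diff(sort(null_res$p_adjust)) >= -1e-12))
  expect_equal(nrow(go_enrichment(character(0), gene2term,
                                  universe) %>%
                      dplyr::filter(enriched)), 0)
})

test_that("term overlap test matches direct hypergeometric
          enumeration on small universes", {
  hyper_manual <- function(a, b, N, x) {
    ks <- x:min(a, b)
    sum(choose(a, ks) * choose(N - a, b - ks)) / choose(N, b)
  }
  u <- paste0("t", 1:18)
  a <- u[1:7]; b <- u[4:12]
  got <- term_overlap_test(a, b, u)
  expect_equal(got$overlap, 4)
  expect_equal(got$p_value, hyper_manual(7, 9, 18, 4),
               tolerance = 1e-12)
  # disjoint small sets: p near 1; identical sets: small p
  expect_gt(term_overlap_test(u[1:2], u[10:11], u)$p_value, 0.5)
  expect_lt(term_overlap_test(u[1:6], u[1:6],
                              paste0("t", 1:100))$p_value, 1e-6)
  expect_error(term_overlap_test(c("zz"), b, u), "outside")
})

test_that("the full report runs, is deterministic, and its accessors
          work", {
  cfg <- tiny_config(seed = 96, circ_rate_A = 0.3, circ_rate_B = 0.3)
  ds <- simulate_dataset(cfg)
  suppressMessages({
    r1 <- run_full_comparison(ds)
    r2 <- run_full_comparison(ds)
  })
  expect_identical(tidy(r1), tidy(r2))
  expect_s3_class(tidy(r1), "tbl_df")
  expect_true(all(tidy(r1)$p_adjust >= tidy(r1)$p_value - 1e-12))
  expect_true(all(tidy(r1)$p_value >= 0 & tidy(r1)$p_value <= 1))
  g <- glance(r1)
  expect_equal(nrow(g), 1)
  expect_equal(sum(r1$overlap_as$counts), nrow(ds$pairs))
  expect_s3_class(autoplot(r1), "ggplot")
  expect_output(print(r1), "subgenome_report")
})
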