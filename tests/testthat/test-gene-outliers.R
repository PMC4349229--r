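test_that("1 kb flank assignment honours boundaries and strand", {
  genes <- data.table::data.table(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10000L, 50000L), end = c(12000L, 53000L),
    strand = c("+", "-"))
  sig <- data.table::data.table(
    chrom = "chr1",
    start = c(9500L,   # 500 bp upstream of plus-strand TSS -> in
              8999L,   # 1,001 bp upstream -> out
              9000L,   # exactly 1,000 bp upstream -> in
              53999L,  # last base of the 1 kb flank past the higher end -> in
              54000L), # 1,001 bp -> out
    score = 1:5)
  sig[, end := start + 1L]
  a <- assign_signals_to_genes(sig, genes, flank = 1000L)
  expect_setequal(a$signal_idx, c(1L, 3L, 4L))
  expect_equal(sort(unique(a$gene_id[a$signal_idx %in% c(1, 3)])), "plus")
  expect_equal(unique(a$gene_id[a$signal_idx == 4]), "minus")
  # a window overlapping the flanked span by >= 1 bp is assigned
  win <- data.table::data.table(chrom = "chr1", start = 8000L, end = 9001L,
                                score = 9)
  expect_equal(assign_signals_to_genes(win, genes)$gene_id, "plus")
  win0 <- data.table::data.table(chrom = "chr1", start = 8000L, end = 9000L,
                                 score = 9)
  expect_equal(nrow(assign_signals_to_genes(win0, genes)), 0L)
})

test_that("assignment agrees with the all-pairs brute-force oracle", {
  withr::with_seed(19, {
    genes <- data.table::data.table(
      gene_id = sprintf("g%03d", 1:60), chrom = "chr1",
      start = sort(sample.int(1e6, 60)))
    genes[, end := start + sample(500:20000, 60, replace = TRUE)]
    genes[, strand := sample(c("+", "-"), 60, replace = TRUE)]
    sig <- data.table::data.table(chrom = "chr1",
                                  start = sample.int(1.1e6, 300))
    sig[, end := start + sample(c(1L, 5000L), 300, replace = TRUE)]
    sig[, score := rnorm(300)]
    got <- assign_signals_to_genes(sig, genes, flank = 1000L)
    want <- 0L
    for (i in seq_len(nrow(sig))) {
      for (j in seq_len(nrow(genes))) {
        lo <- genes$start[j] - 1000L
        hi <- genes$end[j] + 1000L
        if (sig$start[i] < hi && sig$end[i] > lo) {
          want <- want + 1L
          expect_true(any(got$signal_idx == i & got$gene_id == genes$gene_id[j]))
        }
      }
    }
    expect_equal(nrow(got), want)
  })
})

test_that("best-per-gene and outlier calling reproduce the 1% contract", {
  # 19,990-gene universe -> exactly 200 outliers
  withr::with_seed(33, {
    scores <- data.table::data.table(
      gene_id = sprintf("g%05d", 1:19990), best_score = rnorm(19990),
      chrom = "chr1", start = seq_len(19990) * 100L,
      end = seq_len(19990) * 100L + 50L)
    rk <- rank_and_call_outliers(scores, universe_size = 19990L)
    expect_equal(sum(rk$outlier), 200L)
    expect_equal(attr(rk, "n_outliers"), 200L)
    # outlier set invariant to input order
    rk2 <- rank_and_call_outliers(scores[sample(.N)], universe_size = 19990L)
    expect_setequal(rk[outlier == TRUE, gene_id], rk2[outlier == TRUE, gene_id])
  })
  # 100 genes at 1% -> 1 outlier
  small <- data.table::data.table(gene_id = sprintf("s%03d", 1:100),
                                  best_score = runif(100), chrom = "chr1",
                                  start = 1:100, end = 2:101)
  expect_equal(sum(rank_and_call_outliers(small, 100L)$outlier), 1L)
  expect_error(rank_and_call_outliers(small[1:2], 19990L), "outlier count")
})

test_that("ties at the cutoff break by genomic position, deterministically", {
  g <- data.table::data.table(
    gene_id = c("a", "b", "c", "d"),
    best_score = c(5, 1, 1, 0.5),
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    start = c(10L, 5L, 900L, 2L), end = c(20L, 6L, 901L, 3L))
  rk <- rank_and_call_outliers(g, universe_size = 200L)  # 2 outliers
  expect_equal(rk[outlier == TRUE, gene_id], c("a", "c"))  # chr1 before chr2
})

test_that("gene_best_scores keeps the strongest signal per gene", {
  a <- data.table::data.table(
    gene_id = c("g1", "g1", "g2"), signal_idx = 1:3, chrom = "chr1",
    start = c(10L, 50L, 70L), end = c(11L, 51L, 71L), score = c(2, 7, 1))
  best <- gene_best_scores(a)
  expect_equal(best[gene_id == "g1", best_score], 7)
  expect_equal(best[gene_id == "g1", start], 50L)
})

test_that("between-breed overlap p-values behave at the extremes and null", {
  universe <- sprintf("u%04d", 1:1000)
  s1 <- universe[1:50]
  o <- overlap_between_breeds(s1, s1, universe, B = 1000L, seed = 2)
  expect_equal(o$observed, 50L)
  expect_equal(o$p_value, 1 / 1001)
  d <- overlap_between_breeds(universe[1:50], universe[51:100], universe,
                              B = 500L, seed = 2)
  expect_equal(d$observed, 0L)
  expect_gt(d$p_value, 0.5)
  # null mean of the random overlap is k1 k2 / G
  withr::with_seed(3, {
    obs <- replicate(300, {
      a <- sample(universe, 40); b <- sample(universe, 40)
      length(intersect(a, b))
    })
  })
  expect_lt(abs(mean(obs) - 40 * 40 / 1000), 3 * sd(obs) / sqrt(300))
})
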