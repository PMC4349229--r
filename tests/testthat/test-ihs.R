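test_that("EHH matches hand values and the pair-counting oracle", {
  # 4 carriers of allele 1 splitting 2+2 at the next site: EHH = 2/6
  m <- rbind(c(1, 0), c(1, 0), c(1, 1), c(1, 1), c(0, 0))
  cv <- ehh(m, positions = c(0, 100), core = 1, core_allele = 1L)
  expect_equal(cv$right$ehh, 1 / 3)
  expect_equal(cv$right$offset, 100)
  # all carriers identical over the chromosome: EHH = 1 throughout, edge
  m2 <- cbind(1L, matrix(0L, 6, 9))
  cv2 <- ehh(m2, positions = 0:9 * 10, core = 1, core_allele = 1L)
  expect_true(all(cv2$right$ehh == 1))
  expect_equal(cv2$truncation_right, "edge")
  expect_equal(nrow(cv2$left), 0L)   # no left flank at the chromosome start
  expect_error(ehh(rbind(c(1, 0), c(0, 0)), c(0, 1), 1, 1L), "unscored")
  # exhaustive check against explicit carrier-pair identity enumeration
  withr::with_seed(17, {
    for (rep in 1:10) {
      m <- random_hap_matrix(sample(4:20, 1), sample(10:100, 1))
      core <- sample(2:(ncol(m) - 1), 1)
      for (al in 0:1) {
        if (sum(m[, core] == al) < 2) next
        cv <- ehh(m, seq_len(ncol(m)) * 7, core, al, cutoff = 0)
        want <- ehh_bruteforce(m, core, al, +1)
        expect_equal(cv$right$ehh, want[seq_len(nrow(cv$right))])
        wantL <- ehh_bruteforce(m, core, al, -1)
        expect_equal(cv$left$ehh, wantL[seq_len(nrow(cv$left))])
      }
    }
  })
})

test_that("EHH curves are non-increasing and start below 1 only off-core", {
  withr::with_seed(23, {
    m <- random_hap_matrix(12, 60)
    core <- 30
    for (al in 0:1) {
      cv <- ehh(m, seq_len(60) * 50, core, al, cutoff = 0)
      expect_true(all(diff(cv$right$ehh) <= 1e-12))
      expect_true(all(cv$left$ehh >= 0 & cv$left$ehh <= 1))
    }
  })
})

test_that("iHH integrates trapezoids with interpolation to the cutoff", {
  curve <- function(left, right, tl, tr)
    structure(list(core = 1, core_pos = 0, allele = 1, n_carriers = 4,
                   left = left, right = right, truncation_left = tl,
                   truncation_right = tr, cutoff = 0.05),
              class = "EhhCurve")
  # EHH == 1 over a 1,000 bp flank, other flank empty: rectangle = 1,000
  c1 <- curve(data.frame(offset = numeric(), ehh = numeric()),
              data.frame(offset = c(400, 1000), ehh = c(1, 1)),
              "edge", "edge")
  expect_equal(ihh(c1)$ihh, 1000)
  expect_true(ihh(c1)$edge_truncated)
  # 1 at core, 0.5 at +-100 bp, then 0.02 at 200 bp:
  # per flank 100 * 0.75 + interpolated tail to the 0.05 crossing
  fl <- data.frame(offset = c(100, 200), ehh = c(0.5, 0.02))
  c2 <- curve(fl, fl, "cutoff", "cutoff")
  dstar <- 100 + (0.5 - 0.05) * 100 / (0.5 - 0.02)
  expect_equal(ihh(c2)$ihh, 2 * (100 * 0.75 + (dstar - 100) * (0.5 + 0.05) / 2))
  expect_false(ihh(c2)$edge_truncated)
  # symmetric ancestral/derived curves give raw iHS = 0
  expect_equal(log(ihh(c2)$ihh / ihh(c2)$ihh), 0)
})

test_that("core selection applies strict MAF, polarization and carrier rules", {
  # 10 breed haplotypes: engineer MAF exactly 0.2, above, and ambiguity
  m <- matrix(0L, 20, 4)
  m[1:2, 1] <- 1L                      # breed MAF 0.2 exactly -> excluded
  m[1:4, 2] <- 1L                      # breed MAF 0.4 -> eligible
  m[1:4, 3] <- 1L; m[11:15, 3] <- 1L   # outgroup freq 0.5 -> ambiguous
  m[1:4, 4] <- 1L; m[11:12, 4] <- 1L   # eligible, outgroup freq 0.2
  x <- haplotype_set(m, chrom = "chr1", pos = c(0, 10, 20, 30),
                     pop = rep(c("Landrace", "WildBoar"), each = 10))
  ann <- site_annotation(x, "WildBoar")
  cores <- select_cores(ann, "Landrace", maf_min = 0.2)
  expect_equal(cores, c(2L, 4L))
})

test_that("standardization yields exact per-class mean 0 / variance 1", {
  withr::with_seed(29, {
    rec <- data.table::data.table(raw = rnorm(500, 1, 2),
                                  freq_derived = runif(500, 0.02, 0.98))
    std <- standardize_ihs(rec, n_bins = 20L, min_class = 10L)
    agg <- std[, .(m = mean(ihs_std), v = var(ihs_std), n = .N),
               by = freq_class]
    expect_true(all(abs(agg$m) < 1e-12))
    expect_true(all(abs(agg$v - 1) < 1e-12))
    expect_true(all(agg$n >= 10))
    # brute-force per-class z-score oracle on two disjoint classes
    rec2 <- data.table::data.table(
      raw = c(1:12, 101:112),
      freq_derived = c(runif(12, 0.05, 0.10), runif(12, 0.90, 0.95)))
    std2 <- standardize_ihs(rec2, n_bins = 20L, min_class = 10L)
    z <- function(v) (v - mean(v)) / sd(v)
    expect_equal(std2$ihs_std, c(z(1:12), z(101:112)))
    expect_equal(std2$ihs_abs, abs(std2$ihs_std))
  })
  # zero-variance class flagged
  expect_warning(
    std0 <- standardize_ihs(data.table::data.table(
      raw = rep(2, 15), freq_derived = runif(15, 0.4, 0.45))),
    "zero score variance")
  expect_true(all(is.na(std0$ihs_std)))
})

test_that("|iHS| is invariant to flipping allele coding with polarization", {
  x <- toy_hapset(n_site = 80, seed = 37,
                  n_hap = c(Yorkshire = 12, Landrace = 12, WildBoar = 10))
  # drop outgroup-ambiguous sites so both codings score identical core sets
  ann <- site_annotation(x, "WildBoar")
  x <- subset_haps(x, sites = !ann$polarization_ambiguous)
  flipped <- haplotype_set(1L - x$alleles, chrom = x$chrom, pos = x$pos,
                           pop = x$pop, sample = x$sample,
                           ref = x$alt, alt = x$ref)
  a <- ihs_scan(x, "Landrace", "WildBoar", min_class = 5L)
  b <- ihs_scan(flipped, "Landrace", "WildBoar", min_class = 5L)
  expect_equal(a$site, b$site)
  expect_equal(a$freq_derived, b$freq_derived)
  expect_equal(a$ihs_abs, b$ihs_abs)
})

test_that("neutral standardized iHS has a roughly normal 2-sigma tail", {
  md <- demography_model()
  reps <- simulate_neutral_coalescent(md, theta = 30, n_replicates = 60,
                                      seed = 41)
  x <- combine_replicates(reps)
  sc <- ihs_scan(x, "Yorkshire", "WildBoar", keep_truncated = TRUE)
  z <- sc$ihs_std[!is.na(sc$ihs_std)]
  expect_gt(length(z), 500)
  frac <- mean(abs(z) > 2)
  # two-sided normal tail is ~4.6%; allow generous Monte-Carlo/model slack
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})
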