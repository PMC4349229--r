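test_that("hudson_fst reproduces hand-derived and brute-force values", {
  # pop1 = {00, 01}, pop2 = {11, 10}: pi1 = pi2 = 1, pi_w = 1, pi_t = 8/6
  f <- hudson_fst(rbind(c(0, 0), c(0, 1)), rbind(c(1, 1), c(1, 0)))
  expect_equal(f$pi1, 1); expect_equal(f$pi2, 1)
  expect_equal(f$pi_w, 1); expect_equal(f$pi_t, 8 / 6)
  expect_equal(f$fst, 0.25)
  # fixed difference: pi_w = 0, F_ST = 1
  f1 <- hudson_fst(matrix(0L, 3, 2), matrix(1L, 3, 2))
  expect_equal(f1$fst, 1); expect_equal(f1$pi_w, 0)
  # identical haplotype distributions: raw estimate <= 0, clamped to 0
  f0 <- hudson_fst(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(0, 1)))
  expect_equal(f0$fst, 0)
  expect_true(f0$fst_raw <= 0)
  # monomorphic pair flagged
  fm <- hudson_fst(matrix(0L, 2, 3), matrix(0L, 2, 3))
  expect_true(is.na(fm$fst)); expect_equal(fm$flag, "monomorphic")
  # random instances against the brute-force pair-enumeration oracle
  withr::with_seed(13, {
    for (i in 1:20) {
      m1 <- random_hap_matrix(sample(2:8, 1), 25)
      m2 <- random_hap_matrix(sample(2:8, 1), 25)
      exp_fst <- fst_bruteforce(m1, m2)
      got <- hudson_fst(m1, m2)
      if (is.na(exp_fst)) expect_true(is.na(got$fst))
      else expect_equal(got$fst_raw, exp_fst)
    }
  })
})

test_that("divergence time is -ln(1 - F_ST) with a finite cap at F_ST = 1", {
  expect_equal(divergence_time(0, 10), 0)
  expect_equal(divergence_time(1 - exp(-1), 10), 1)
  expect_equal(divergence_time(1, 10), log(2 * 10))
  expect_error(divergence_time(1.2, 10), "outside")
  expect_error(divergence_time(-0.1, 10), "outside")
})

test_that("PBS branch formulas and their triple identity hold", {
  expect_equal(pbs_branches(0, 0, 0), list(pbs_1 = 0, pbs_2 = 0, pbs_w = 0))
  # T_LW = T_LY = 0.2, T_WY = 0 (branch 1 = L): PBS_L = 0.2, others 0
  p <- pbs_branches(t_12 = 0.2, t_1w = 0.2, t_2w = 0)
  expect_equal(p, list(pbs_1 = 0.2, pbs_2 = 0, pbs_w = 0))
  # F_ST^LW = F_ST^LY = 0.5, F_ST^WY = 0 -> PBS_L = ln 2
  p2 <- pbs_branches(t_12 = divergence_time(0.5, 10),
                     t_1w = divergence_time(0.5, 10),
                     t_2w = divergence_time(0, 10))
  expect_equal(p2$pbs_1, log(2))
  expect_error(pbs_branches(-0.1, 0, 0), "non-negative")
})

test_that("window layout: full windows only, floor((N - w)/s) + 1 per chromosome", {
  count_windows <- function(n_sites) {
    x <- toy_hapset(n_site = n_sites, seed = n_sites)
    nrow(pbs_scan(x, c("Yorkshire", "Landrace"), "WildBoar",
                  window_snps = 200L, step_snps = 50L))
  }
  expect_equal(count_windows(200), 1L)
  expect_equal(count_windows(300), 3L)   # starts at SNP offsets 0, 50, 100
  expect_equal(count_windows(199), 0L)
  # brute-force enumeration of valid starts for assorted N
  for (N in c(200, 249, 250, 437)) {
    starts <- which((seq_len(N) - 1L) %% 50L == 0 & seq_len(N) + 199L <= N)
    expect_equal(count_windows(N), length(starts))
  }
})

test_that("pbs_scan equals the brute-force window oracle and its identity", {
  x <- toy_hapset(n_site = 130, seed = 21,
                  n_hap = c(Yorkshire = 10, Landrace = 10, WildBoar = 10))
  sc <- pbs_scan(x, c("Yorkshire", "Landrace"), "WildBoar",
                 window_snps = 40L, step_snps = 20L)
  expect_equal(nrow(sc), (130 - 40) %/% 20 + 1)
  m1 <- x$alleles[pop_rows(x, "Yorkshire"), ]
  m2 <- x$alleles[pop_rows(x, "Landrace"), ]
  mw <- x$alleles[pop_rows(x, "WildBoar"), ]
  for (i in seq_len(nrow(sc))) {
    win <- sc$first_snp[i]:sc$last_snp[i]
    expect_equal(sc$pi_1[i], pi_bruteforce(m1[, win]))
    f12 <- fst_bruteforce(m1[, win], m2[, win])
    expect_equal(sc$fst_raw_12[i], f12)
    f1w <- max(0, fst_bruteforce(m1[, win], mw[, win]))
    f2w <- max(0, fst_bruteforce(m2[, win], mw[, win]))
    pbs_l <- (divergence_time(f1w, 20) + divergence_time(max(0, f12), 20) -
                divergence_time(f2w, 20)) / 2
    expect_equal(sc$pbs_1[i], pbs_l)
  }
  # triple identity to machine precision on every window
  expect_equal(sc$pbs_1 + sc$pbs_2 + sc$pbs_w,
               (sc$T_12 + sc$T_1w + sc$T_2w) / 2, tolerance = 1e-12)
})

test_that("PBS is negatively related to relative breed diversity", {
  md <- demography_model()
  reps <- simulate_neutral_coalescent(md, theta = 60, n_replicates = 30,
                                      seed = 31)
  x <- combine_replicates(reps)
  sc <- pbs_scan(x, c("Yorkshire", "Landrace"), "WildBoar",
                 window_snps = 30L, step_snps = 30L)
  sc <- sc[flag == "" & pi_1 > 0 & pi_w_pop > 0]
  expect_gt(nrow(sc), 20)
  rho <- stats::cor(sc$pbs_1, log(sc$pi_1 / sc$pi_w_pop), method = "spearman")
  expect_lt(rho, 0)
})
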