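test_that("panmictic coalescent matches E(pi) = theta and E(S) = theta * a_n", {
  md <- demography_model(N_anc = 1000, T_dom = 0, T_split = 0, m = 0)
  n_rep <- 10000
  reps <- simulate_neutral_coalescent(md, c(a = 2, b = 2, w = 2), theta = 1,
                                      n_replicates = n_rep, seed = 101)
  # E(pi) = theta for the first two haplotypes (one panmictic pair)
  pis <- vapply(reps, function(r)
    if (ncol(r$alleles) == 0) 0 else sum(r$alleles[1, ] != r$alleles[2, ]),
    numeric(1))
  se <- sd(pis) / sqrt(n_rep)
  expect_lt(abs(mean(pis) - 1), 3 * se)
  # E(S) = theta * sum(1/i) over the full sample of n = 6
  a_n <- sum(1 / 1:5)
  S <- vapply(reps, function(r) ncol(r$alleles), numeric(1))
  expect_lt(abs(mean(S) - a_n), 3 * sd(S) / sqrt(n_rep))
})

test_that("vanishing theta gives zero segregating sites", {
  md <- demography_model(N_anc = 100, T_dom = 0, T_split = 0, m = 0)
  reps <- simulate_neutral_coalescent(md, c(a = 2, b = 2, w = 2),
                                      theta = 1e-9, n_replicates = 20,
                                      seed = 5)
  expect_true(all(vapply(reps, function(r) ncol(r$alleles), numeric(1)) == 0))
  expect_error(simulate_neutral_coalescent(md, c(a = 2, b = 2, w = 2),
                                           theta = -1), "positive")
})

test_that("coalescent replicates are byte-identical under a fixed seed", {
  md <- demography_model()
  r1 <- simulate_neutral_coalescent(md, theta = 10, n_replicates = 3,
                                    seed = 77)
  r2 <- simulate_neutral_coalescent(md, theta = 10, n_replicates = 3,
                                    seed = 77)
  expect_identical(r1, r2)
  r3 <- simulate_neutral_coalescent(md, theta = 10, n_replicates = 3,
                                    seed = 78)
  expect_false(identical(r1, r3))
})

test_that("sampling more haplotypes than 2N errors", {
  md <- demography_model(N_anc = 5, T_dom = 0, T_split = 0, m = 0)
  expect_error(
    simulate_neutral_coalescent(md, c(a = 40, b = 2, w = 2), theta = 1),
    "exceeds")
})

test_that("breed diversity is below outgroup diversity under the demography", {
  md <- demography_model()
  reps <- simulate_neutral_coalescent(md, theta = 60, n_replicates = 100,
                                      seed = 42)
  lower <- vapply(reps, function(r) {
    y <- nucleotide_diversity(r$alleles[r$pop == "Yorkshire", , drop = FALSE])
    l <- nucleotide_diversity(r$alleles[r$pop == "Landrace", , drop = FALSE])
    w <- nucleotide_diversity(r$alleles[r$pop == "WildBoar", , drop = FALSE])
    c(y < w, l < w)
  }, logical(2))
  expect_gte(mean(lower), 0.95)   # per (breed, replicate) comparison
})

test_that("forward simulator with s = 0 is neutral in expectation", {
  # track-mode allele introduced at frequency 0.5 with s = 0: the mean
  # per-generation frequency change over replicates is 0
  md <- fwd_test_model(N_anc = 60, T_dom = 40, T_split = 20,
                       N_bottleneck1 = 40, D_bottleneck1 = 5,
                       N_bottleneck2 = 40, D_bottleneck2 = 5, N_breed = 60)
  deltas <- vapply(1:60, function(i) {
    sw <- sweep_spec("Landrace", 5e4, s = 1e-9, onset_generation = 10,
                     mode = "track", initial_frequency = 0.5)
    res <- simulate_forward_wf(md, sweeps = list(sw), region_length = 1e5,
                               n_haplotypes = c(Yorkshire = 4, Landrace = 4,
                                                WildBoar = 4),
                               seed = 1000 + i, burn_in = 20)
    traj <- res$truth$sweeps[[1]]$trajectory
    mean(diff(traj))
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("mu = 0 forward run is monomorphic except the selected site", {
  md <- fwd_test_model(mu = 0, N_anc = 50, T_dom = 30, T_split = 15,
                       N_bottleneck1 = 30, D_bottleneck1 = 5,
                       N_bottleneck2 = 30, D_bottleneck2 = 5, N_breed = 50)
  sw <- sweep_spec("Yorkshire", 5e4, s = 0.5, onset_generation = 10,
                   mode = "partial", target_frequency = 0.5,
                   frequency_tol = 0.25)
  res <- simulate_forward_wf(md, sweeps = list(sw), region_length = 1e5,
                             n_haplotypes = c(Yorkshire = 10, Landrace = 10,
                                              WildBoar = 10),
                             seed = 31, burn_in = 30)
  expect_lte(ncol(res$haps$alleles), 1L)
  if (ncol(res$haps$alleles) == 1L) {
    expect_equal(res$haps$pos, res$truth$sweeps[[1]]$position)
  }
})

test_that("a strong complete sweep fixes in the target and stays out of the outgroup", {
  md <- fwd_test_model()
  sw <- sweep_spec("Yorkshire", 2.5e5, s = 0.5, onset_generation = 40,
                   mode = "complete")
  res <- simulate_forward_wf(md, sweeps = list(sw), region_length = 5e5,
                             seed = 9)
  f <- res$truth$sweeps[[1]]$final_frequency
  expect_equal(unname(f["Yorkshire"]), 1)
  expect_lt(f["WildBoar"], 0.05)
  expect_gte(res$truth$rejections, 0)
  # determinism
  res2 <- simulate_forward_wf(md, sweeps = list(sw), region_length = 5e5,
                              seed = 9)
  expect_identical(res$haps, res2$haps)
})

test_that("partial sweeps are conditioned into the target frequency band", {
  md <- fwd_test_model()
  sw <- sweep_spec("Landrace", 2.5e5, s = 0.5, onset_generation = 14,
                   mode = "partial", target_frequency = 0.5,
                   frequency_tol = 0.1)
  res <- simulate_forward_wf(md, sweeps = list(sw), region_length = 5e5,
                             seed = 21)
  f <- res$truth$sweeps[[1]]$final_frequency["Landrace"]
  expect_gte(f, 0.4); expect_lte(f, 0.6)
})

test_that("sweep validation errors fire", {
  md <- fwd_test_model()
  expect_error(sweep_spec("Landrace", 1e5, s = -0.1, onset_generation = 5),
               "s must be > 0")
  expect_error(
    simulate_forward_wf(md, sweeps = list(
      sweep_spec("Landrace", 5e4, s = 0.5, onset_generation = 70)),
      region_length = 1e5),
    "predates")
  expect_error(
    simulate_forward_wf(md, sweeps = list(
      sweep_spec("WildBoar", 5e4, s = 0.5, onset_generation = 10)),
      region_length = 1e5),
    "breeds")
  expect_error(
    simulate_forward_wf(md, sweeps = list(
      sweep_spec("Landrace", 9e9, s = 0.5, onset_generation = 10)),
      region_length = 1e5),
    "outside")
})

test_that("toy annotations: non-overlapping genes, four QTL categories, determinism", {
  ann <- make_toy_annotations(5e5, n_genes = 25, n_qtl = 12, seed = 3)
  g <- ann$genes[order(start)]
  expect_equal(nrow(g), 25L)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))   # no overlap
  expect_true(all(g$strand %in% c("+", "-")))
  expect_true(all(ann$qtl$category %in%
                    c("production", "reproduction", "exterior", "health")))
  expect_identical(ann, make_toy_annotations(5e5, n_genes = 25, n_qtl = 12,
                                             seed = 3))
  one <- make_toy_annotations(1e4, n_genes = 1, n_qtl = 0, seed = 1)
  expect_equal(nrow(one$genes), 1L)
  expect_true(one$genes$start >= 0 && one$genes$end <= 1e4)
  expect_equal(nrow(one$qtl), 0L)
})
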