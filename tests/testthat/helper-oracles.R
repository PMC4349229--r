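# Independent brute-force oracles. These deliberately re-derive every
# statistic from its definition (pair/string enumeration), never sharing code
# with the implementation they check.

# mean pairwise difference by explicit pair enumeration
pi_bruteforce <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / (n * (n - 1) / 2)
}

# Hudson K_ST from the printed definition, via pi_bruteforce
fst_bruteforce <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  pi_w <- (n1 * pi_bruteforce(m1) + n2 * pi_bruteforce(m2)) / (n1 + n2)
  pi_t <- pi_bruteforce(rbind(m1, m2))
  if (pi_t == 0) return(NA_real_)
  1 - pi_w / pi_t
}

# EHH at every extension step by explicit carrier-pair identity counting
ehh_bruteforce <- function(m, core, allele, dir) {
  carriers <- which(m[, core] == allele)
  n <- length(carriers)
  stopifnot(n >= 2)
  sites <- if (dir < 0) rev(seq_len(core - 1)) else
    seq_len(ncol(m))[-seq_len(core)]
  out <- numeric(length(sites))
  for (k in seq_along(sites)) {
    span <- if (dir < 0) sites[k]:(core - 1) else (core + 1):sites[k]
    ident <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (all(m[carriers[i], span] == m[carriers[j], span])) {
          ident <- ident + 1
        }
      }
    }
    out[k] <- ident / (n * (n - 1) / 2)
  }
  out
}

# distinct haplotype strings
h_bruteforce <- function(m, cols) {
  length(unique(apply(m[, cols, drop = FALSE], 1, paste, collapse = "")))
}

# random small haplotype matrix
random_hap_matrix <- function(n_hap, n_site, p = 0.4) {
  matrix(rbinom(n_hap * n_site, 1L, p), nrow = n_hap)
}

# tiny three-population HaplotypeSet fixture (deterministic given seed)
toy_hapset <- function(n_site = 60, seed = 1,
                       n_hap = c(Yorkshire = 8, Landrace = 6, WildBoar = 6)) {
  withr::with_seed(seed, {
    repeat {
      m <- random_hap_matrix(sum(n_hap), n_site)
      cs <- colSums(m)
      if (all(cs > 0 & cs < sum(n_hap))) break
    }
    haplotype_set(m, chrom = "chr1",
                  pos = sort(sample.int(n_site * 100, n_site)) - 1L,
                  pop = rep(names(n_hap), times = n_hap))
  })
}

# shared small forward-simulation model (desk scale)
fwd_test_model <- function(...) {
  args <- list(N_anc = 200, T_dom = 150, T_split = 60,
               N_bottleneck1 = 40, D_bottleneck1 = 20,
               N_bottleneck2 = 30, D_bottleneck2 = 10,
               N_breed = 150, m = 0.002, mu = 4.4e-7, r = 2e-6)
  over <- list(...)
  args[names(over)] <- over
  do.call(demography_model, args)
}
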