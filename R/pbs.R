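#' Hudson-style F_ST between two sets of haplotypes
#'
#' Hudson's K_ST: `F_ST = 1 - pi_w / pi_t`, where `pi_t` is the nucleotide
#' diversity of the pooled sample and `pi_w = (n1 pi1 + n2 pi2) / (n1 + n2)`
#' the sample-size-weighted mean within-population diversity. Negative
#' estimates are clamped to 0 for the divergence-time transform (the raw
#' value is returned alongside); a window monomorphic across the pair
#' (`pi_t = 0`) leaves `fst` undefined (`NA`) with `flag = "monomorphic"`.
#'
#' @param h1,h2 0/1 haplotype matrices of the two populations
#' @param sites optional window column index applied to both matrices
#' @return a list: `fst` (clamped), `fst_raw`, `pi1`, `pi2`, `pi_w`, `pi_t`,
#'   `n1`, `n2`, `flag`
#' @export
hudson_fst <- function(h1, h2, sites = NULL) {
  m1 <- if (inherits(h1, "HaplotypeSet")) h1$alleles else as.matrix(h1)
  m2 <- if (inherits(h2, "HaplotypeSet")) h2$alleles else as.matrix(h2)
  if (!is.null(sites)) {
    m1 <- m1[, sites, drop = FALSE]
    m2 <- m2[, sites, drop = FALSE]
  }
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 haplotypes per population",
                               call. = FALSE)
  pi1 <- nucleotide_diversity(m1)
  pi2 <- nucleotide_diversity(m2)
  pi_w <- (n1 * pi1 + n2 * pi2) / (n1 + n2)
  pi_t <- nucleotide_diversity(rbind(m1, m2))
  if (pi_t == 0) {
    return(list(fst = NA_real_, fst_raw = NA_real_, pi1 = pi1, pi2 = pi2,
                pi_w = pi_w, pi_t = pi_t, n1 = n1, n2 = n2,
                flag = "monomorphic"))
  }
  raw <- 1 - pi_w / pi_t
  list(fst = max(0, raw), fst_raw = raw, pi1 = pi1, pi2 = pi2,
       pi_w = pi_w, pi_t = pi_t, n1 = n1, n2 = n2, flag = "")
}

#' Effective divergence time from F_ST
#'
#' `T = -ln(1 - F_ST)` (natural log). `F_ST = 1` (a fixed difference) would be
#' infinite and is capped in a sample-size-aware way by substituting
#' `1 - 1/(2 n_total)`, i.e. `T_max = ln(2 n_total)`.
#'
#' @param fst numeric vector of F_ST values in `[0, 1]` (`NA` passes through)
#' @param n_total pooled haplotype count of the pair, used for the cap
#' @return numeric vector of divergence times
#' @export
divergence_time <- function(fst, n_total) {
  bad <- !is.na(fst) & (fst < 0 | fst > 1)
  if (any(bad)) stop("F_ST outside [0, 1]", call. = FALSE)
  fst_eff <- ifelse(!is.na(fst) & fst == 1, 1 - 1 / (2 * n_total), fst)
  -log(1 - fst_eff)
}

#' Population branch statistics from three pairwise divergence times
#'
#' With breeds 1 and 2 and the wild outgroup w:
#' `PBS_1 = (T_1w + T_12 - T_2w)/2`, `PBS_2 = (T_2w + T_12 - T_1w)/2`,
#' `PBS_w = (T_1w + T_2w - T_12)/2`. Values may be negative and are reported
#' as computed; the three branches always sum to half the sum of the three
#' times.
#'
#' @param t_12 divergence time between the two breeds
#' @param t_1w,t_2w divergence times breed/outgroup
#' @return a list (vectorized) with `pbs_1`, `pbs_2`, `pbs_w`
#' @export
pbs_branches <- function(t_12, t_1w, t_2w) {
  if (any(c(t_12, t_1w, t_2w) < 0, na.rm = TRUE)) {
    stop("divergence times must be non-negative", call. = FALSE)
  }
  list(pbs_1 = (t_1w + t_12 - t_2w) / 2,
       pbs_2 = (t_2w + t_12 - t_1w) / 2,
       pbs_w = (t_1w + t_2w - t_12) / 2)
}

#' Sliding-window PBS scan over a three-population haplotype set
#'
#' The SNP set is the sites variable in the combined three-population sample
#' (so the three pairwise F_ST values of a window share identical sites).
#' Per chromosome, windows of `window_snps` SNPs start at SNP offsets 0,
#' `step_snps`, ... ; trailing partial windows are dropped, giving
#' `floor((N - window)/step) + 1` windows for `N >= window` sites and none
#' otherwise.
#'
#' @param x a `HaplotypeSet` carrying exactly three populations
#' @param breeds character vector of the two breed labels (PBS branches 1, 2)
#' @param outgroup wild outgroup label
#' @param window_snps,step_snps window size and step in SNPs (defaults 200/50)
#' @return a `data.table` with one row per window: chromosome, SNP-index and
#'   base spans, per-population `n_*`/`pi_*`, per-pair `pi_w_*`, `pi_t_*`,
#'   `fst_*` (clamped), `fst_raw_*`, `T_*`, the three `pbs_*` branches and a
#'   `flag` column (`"monomorphic_pair"` when any pair had `pi_t = 0`)
#' @export
pbs_scan <- function(x, breeds, outgroup, window_snps = 200L,
                     step_snps = 50L) {
  stopifnot(inherits(x, "HaplotypeSet"))
  stop_if_not_scalar_count(window_snps, "window_snps", min = 2L)
  stop_if_not_scalar_count(step_snps, "step_snps")
  labs <- c(breeds, outgroup)
  if (length(labs) != 3L || !all(labs %in% x$pop)) {
    stop("breeds and outgroup must name the three populations in `x`",
         call. = FALSE)
  }
  x <- segregating_sites(x)   # variable in the combined sample
  rows <- lapply(labs, function(p) pop_rows(x, p))
  n <- vapply(rows, length, integer(1))
  cnt <- lapply(rows, function(r) colSums(x$alleles[r, , drop = FALSE]))

  persite_pi <- function(c_, n_) c_ * (n_ - c_) / choose2(n_)
  d1 <- persite_pi(cnt[[1]], n[1])
  d2 <- persite_pi(cnt[[2]], n[2])
  dw <- persite_pi(cnt[[3]], n[3])
  d12 <- persite_pi(cnt[[1]] + cnt[[2]], n[1] + n[2])
  d1w <- persite_pi(cnt[[1]] + cnt[[3]], n[1] + n[3])
  d2w <- persite_pi(cnt[[2]] + cnt[[3]], n[2] + n[3])

  out <- vector("list", 0L)
  for (ch in unique(x$chrom)) {
    sidx <- which(x$chrom == ch)
    N <- length(sidx)
    if (N < window_snps) next
    starts <- seq(1L, N - window_snps + 1L, by = step_snps)
    ends <- starts + window_snps - 1L
    wsum <- function(d) {
      cs <- c(0, cumsum(d[sidx]))
      cs[ends + 1L] - cs[starts]
    }
    pi_1 <- wsum(d1); pi_2 <- wsum(d2); pi_o <- wsum(dw)
    pi_t_12 <- wsum(d12); pi_t_1w <- wsum(d1w); pi_t_2w <- wsum(d2w)
    pi_w_12 <- (n[1] * pi_1 + n[2] * pi_2) / (n[1] + n[2])
    pi_w_1w <- (n[1] * pi_1 + n[3] * pi_o) / (n[1] + n[3])
    pi_w_2w <- (n[2] * pi_2 + n[3] * pi_o) / (n[2] + n[3])
    fst_of <- function(pw, pt) ifelse(pt == 0, NA_real_, 1 - pw / pt)
    raw_12 <- fst_of(pi_w_12, pi_t_12)
    raw_1w <- fst_of(pi_w_1w, pi_t_1w)
    raw_2w <- fst_of(pi_w_2w, pi_t_2w)
    f12 <- pmax(0, raw_12); f1w <- pmax(0, raw_1w); f2w <- pmax(0, raw_2w)
    T_12 <- divergence_time(f12, n[1] + n[2])
    T_1w <- divergence_time(f1w, n[1] + n[3])
    T_2w <- divergence_time(f2w, n[2] + n[3])
    pbs <- pbs_branches(T_12, T_1w, T_2w)
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = ch, first_snp = starts, last_snp = ends,
      start = x$pos[sidx[starts]], end = x$pos[sidx[ends]] + 1L,
      n_1 = n[1], n_2 = n[2], n_w = n[3],
      pi_1 = pi_1, pi_2 = pi_2, pi_w_pop = pi_o,
      pi_w_12 = pi_w_12, pi_t_12 = pi_t_12,
      pi_w_1w = pi_w_1w, pi_t_1w = pi_t_1w,
      pi_w_2w = pi_w_2w, pi_t_2w = pi_t_2w,
      fst_12 = f12, fst_1w = f1w, fst_2w = f2w,
      fst_raw_12 = raw_12, fst_raw_1w = raw_1w, fst_raw_2w = raw_2w,
      T_12 = T_12, T_1w = T_1w, T_2w = T_2w,
      pbs_1 = pbs$pbs_1, pbs_2 = pbs$pbs_2, pbs_w = pbs$pbs_w,
      flag = ifelse(is.na(raw_12) | is.na(raw_1w) | is.na(raw_2w),
                    "monomorphic_pair", ""))
  }
  res <- if (length(out) == 0L) {
    data.table::data.table(chrom = character(), first_snp = integer(),
                           last_snp = integer(), start = integer(),
                           end = integer(), pbs_1 = numeric(),
                           pbs_2 = numeric(), pbs_w = numeric(),
                           flag = character())
  } else data.table::rbindlist(out)
  data.table::setattr(res, "breeds", breeds)
  data.table::setattr(res, "outgroup", outgroup)
  res
}
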