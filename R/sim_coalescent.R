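#' Neutral coalescent simulation under the domestication demography
#'
#' Structured-coalescent simulator without recombination (the classic ms-style
#' neutral mode): lineages sampled from the two breeds and the wild outgroup
#' coalesce backwards in time through the breed-formation bottlenecks, the
#' breed split, the domestication bottleneck and the wild/domestic split, with
#' symmetric migration between the breed demes while they exist. Mutations are
#' dropped on the realized genealogy under the infinite-sites model with
#' uniform positions on `[0, region_length)`.
#'
#' @param model a [demography_model()]
#' @param n_haplotypes named integer vector of sampled haplotype counts; the
#'   first two entries are the breeds, the third the wild outgroup. Defaults
#'   to the 2 x (16, 14, 10) design of a Yorkshire/Landrace/wild-boar study.
#' @param theta per-locus scaled mutation rate `4 N_anc mu_locus`; when `NULL`
#'   the locus rate is `model$mu * region_length`
#' @param n_sites if non-`NULL`, condition each replicate on exactly this many
#'   segregating sites (ms `-s` semantics) instead of Poisson mutation
#' @param region_length locus length in bases (positions are scaled to it)
#' @param n_replicates number of independent loci
#' @param seed single integer seed; a fixed seed reproduces replicates exactly
#' @return a list of `n_replicates` [haplotype_set()] objects; replicate `i`
#'   is placed on chromosome `"locus<i>"`. Alleles are polarized 0 =
#'   ancestral, 1 = derived.
#' @export
simulate_neutral_coalescent <- function(model,
                                        n_haplotypes = c(Yorkshire = 32,
                                                         Landrace = 28,
                                                         WildBoar = 20),
                                        theta = NULL, n_sites = NULL,
                                        region_length = 1e6,
                                        n_replicates = 1L, seed = 1L) {
  stopifnot(inherits(model, "DemographyModel"))
  if (length(n_haplotypes) != 3L || is.null(names(n_haplotypes))) {
    stop("n_haplotypes must be a named vector: breed1, breed2, outgroup",
         call. = FALSE)
  }
  if (any(n_haplotypes < 2L)) {
    stop("need >= 2 sampled haplotypes per population", call. = FALSE)
  }
  if (!is.null(theta) && theta <= 0) {
    stop("theta must be positive", call. = FALSE)
  }
  stop_if_not_scalar_count(n_replicates, "n_replicates")
  mu_loc <- if (is.null(theta)) model$mu * region_length else {
    theta / (4 * model$N_anc)
  }
  check_sampling_sizes(model, n_haplotypes)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      coalescent_replicate(model, n_haplotypes, mu_loc, n_sites,
                           region_length, chrom = sprintf("locus%d", i))
    })
  })
}

check_sampling_sizes <- function(model, n_hap) {
  # present-day deme sizes (diploids)
  breed_now <- if (model$T_split <= 0) {
    if (model$T_dom <= 0) model$N_anc else model$N_breed
  } else if (model$T_split <= model$D_bottleneck2) {
    model$N_bottleneck2
  } else model$N_breed
  lim <- c(2 * breed_now, 2 * breed_now, 2 * model$N_anc)
  if (any(n_hap > lim)) {
    stop("sample count exceeds 2 x population size at sampling time",
         call. = FALSE)
  }
  invisible(TRUE)
}

# One genealogy + infinite-sites mutations. Demes: 1 = breed1, 2 = breed2,
# 3 = wild, 4 = domestic (exists on [T_split, T_dom) backwards in time).
coalescent_replicate <- function(model, n_hap, mu_loc, n_sites,
                                 region_length, chrom) {
  n_tot <- sum(n_hap)
  deme <- rep(c(1L, 2L, 3L), times = n_hap)
  if (model$T_split <= 0) deme[deme %in% c(1L, 2L)] <- 4L
  if (model$T_dom <= 0) deme[deme == 4L] <- 3L
  desc <- as.list(seq_len(n_tot))
  birth <- rep(0, n_tot)
  alive <- rep(TRUE, n_tot)
  seg_desc <- vector("list", 2L * n_tot)
  seg_len <- numeric(2L * n_tot)
  n_seg <- 0L

  deme_size <- function(d, t) {
    if (d == 3L) return(model$N_anc)
    if (d == 4L) {
      if (t >= model$T_dom - model$D_bottleneck1) {
        return(model$N_bottleneck1)
      }
      return(model$N_breed)
    }
    if (t >= model$T_split - model$D_bottleneck2) {
      return(model$N_bottleneck2)
    }
    model$N_breed
  }

  bps <- sort(unique(c(
    if (model$T_split > 0) max(0, model$T_split - model$D_bottleneck2),
    if (model$T_split > 0) model$T_split,
    if (model$T_dom > 0) max(model$T_split, model$T_dom - model$D_bottleneck1),
    if (model$T_dom > 0) model$T_dom)))
  bps <- c(bps[bps > 0], Inf)
  bp_i <- 1L

  t <- 0
  while (sum(alive) > 1L) {
    idx <- which(alive)
    demes_now <- deme[idx]
    present <- sort(unique(demes_now[duplicated(demes_now)]))  # k >= 2 only
    coal_rate <- vapply(present, function(d) {
      k <- sum(demes_now == d)
      choose2(k) / (2 * deme_size(d, t))
    }, numeric(1))
    mig_rate <- if (t < model$T_split && model$m > 0) {
      model$m * sum(demes_now %in% c(1L, 2L))
    } else 0
    total <- sum(coal_rate) + mig_rate
    dt <- if (total > 0) rexp(1L, total) else Inf
    if (t + dt >= bps[bp_i]) {
      t_new <- bps[bp_i]
      bp_i <- bp_i + 1L
      if (is.finite(t_new)) {
        t <- t_new
        if (t >= model$T_split && model$T_split >= 0) {
          deme[alive & deme %in% c(1L, 2L)] <- 4L
        }
        if (t >= model$T_dom) deme[alive & deme == 4L] <- 3L
        next
      }
      stop("internal error: no events possible before final breakpoint")
    }
    t <- t + dt
    u <- runif(1L) * total
    if (u < sum(coal_rate)) {
      d <- present[findInterval(u, cumsum(coal_rate), left.open = TRUE) + 1L]
      in_d <- idx[demes_now == d]
      pair <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
      for (l in pair) {
        n_seg <- n_seg + 1L
        seg_desc[[n_seg]] <- desc[[l]]
        seg_len[n_seg] <- t - birth[l]
        alive[l] <- FALSE
      }
      desc[[length(desc) + 1L]] <- sort(c(desc[[pair[1]]], desc[[pair[2]]]))
      deme <- c(deme, d)
      birth <- c(birth, t)
      alive <- c(alive, TRUE)
    } else {
      breed_idx <- idx[demes_now %in% c(1L, 2L)]
      l <- if (length(breed_idx) == 1L) breed_idx else sample(breed_idx, 1L)
      deme[l] <- if (deme[l] == 1L) 2L else 1L
    }
  }

  seg_desc <- seg_desc[seq_len(n_seg)]
  seg_len <- seg_len[seq_len(n_seg)]
  n_mut_per_seg <- if (is.null(n_sites)) {
    rpois(n_seg, seg_len * mu_loc)
  } else {
    drop(stats::rmultinom(1L, n_sites, prob = seg_len))
  }
  S <- sum(n_mut_per_seg)
  mat <- matrix(0L, nrow = n_tot, ncol = S)
  if (S > 0L) {
    col <- 1L
    for (i in seq_len(n_seg)) {
      if (n_mut_per_seg[i] > 0L) {
        for (j in seq_len(n_mut_per_seg[i])) {
          mat[seg_desc[[i]], col] <- 1L
          col <- col + 1L
        }
      }
    }
    pos <- unique_positions(S, region_length)
    ord <- sample.int(S)   # detach mutation order from branch order
    mat <- mat[, ord, drop = FALSE]
  } else {
    pos <- integer(0)
  }
  haplotype_set(mat, chrom = rep(chrom, S), pos = pos,
                pop = rep(names(n_hap), times = n_hap))
}

# S distinct integer positions, uniform on [0, L), sorted
unique_positions <- function(S, L) {
  if (S == 0L) return(integer(0))
  if (S > L) stop("region too short for the requested site count",
                  call. = FALSE)
  pos <- unique(as.integer(floor(runif(S) * L)))
  while (length(pos) < S) {
    pos <- unique(c(pos, as.integer(floor(runif(S - length(pos)) * L))))
  }
  sort(pos)
}
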