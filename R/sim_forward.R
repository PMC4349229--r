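#' Forward Wright-Fisher simulation with recombination and planted sweeps
#'
#' Discrete-generation diploid Wright-Fisher simulation of the two-split,
#' two-bottleneck demography with uniform recombination, finite-sites
#' biallelic mutation (recurrent hits rejected) and optional planted sweeps
#' under additive viability selection (fitness 1, 1+s, 1+2s) in the target
#' breed. `complete`-mode sweeps condition the output on fixation of the
#' selected allele at sampling time, `partial`-mode sweeps on an intermediate
#' frequency, both by rejection-resampling the post-onset segment of the
#' simulation with fresh randomness (the rejection count is reported);
#' `track`-mode sweeps are unconditioned diagnostics that record the allele
#' trajectory. Population sizes should be desk-scale (<= ~2,000 diploids);
#' use [scale_demography()] to rescale a natural parameterization.
#'
#' @param model a [demography_model()] with `T_dom > T_split >= 1` (all three
#'   populations must exist at sampling time)
#' @param sweeps list of [sweep_spec()] objects (possibly empty)
#' @param region_length simulated region in bases (>= 1000)
#' @param n_haplotypes named vector of even sampled haplotype counts
#'   (breed1, breed2, outgroup)
#' @param seed integer seed
#' @param burn_in generations of ancestral evolution before `T_dom`;
#'   default `4 * N_anc` approaches mutation-drift equilibrium
#' @param max_attempts rejection-resampling cap for conditioned sweeps
#' @return a list with elements `haps` (a [haplotype_set()], alleles polarized
#'   0 ancestral / 1 derived, sites segregating in the pooled sample, sorted
#'   by position) and `truth` (a `GroundTruth` list: per-sweep realized
#'   position, final population frequencies, trajectory, rejection count,
#'   seed, and the realized demographic event list)
#' @export
simulate_forward_wf <- function(model, sweeps = list(),
                                region_length = 5e5,
                                n_haplotypes = c(Yorkshire = 32,
                                                 Landrace = 28,
                                                 WildBoar = 20),
                                seed = 1L,
                                burn_in = 4 * model$N_anc,
                                max_attempts = 1000L) {
  stopifnot(inherits(model, "DemographyModel"))
  if (region_length < 1000) stop("region_length must be >= 1 kb", call. = FALSE)
  if (model$T_split < 1 || model$T_dom <= model$T_split) {
    stop("forward mode needs T_dom > T_split >= 1", call. = FALSE)
  }
  npop_max <- max(model$N_anc, model$N_breed, model$N_bottleneck1)
  if (npop_max > 2000) {
    stop("population sizes above 2,000 diploids: rescale with scale_demography()",
         call. = FALSE)
  }
  if (length(n_haplotypes) != 3L || any(n_haplotypes %% 2L != 0L)) {
    stop("n_haplotypes must give an even haplotype count for three populations",
         call. = FALSE)
  }
  if (inherits(sweeps, "SweepSpec")) sweeps <- list(sweeps)
  pop_labels <- names(n_haplotypes)
  t_start <- model$T_dom + burn_in
  sweeps_cpp <- lapply(sweeps, function(sw) {
    stopifnot(inherits(sw, "SweepSpec"))
    tgt <- match(sw$target_population, pop_labels[1:2])
    if (is.na(tgt)) {
      stop("sweep target must be one of the two breeds", call. = FALSE)
    }
    if (sw$position < 0 || sw$position >= region_length) {
      stop("sweep position outside the simulated region", call. = FALSE)
    }
    if (sw$onset_generation >= model$T_split) {
      stop("sweep onset predates the target breed's existence", call. = FALSE)
    }
    if (sw$onset_generation < 1 || sw$onset_generation > t_start - 1) {
      stop("sweep onset outside the simulated time span", call. = FALSE)
    }
    list(target = tgt - 1L, s = sw$s, onset = as.integer(sw$onset_generation),
         mode = match(sw$mode, c("complete", "partial", "track")) - 1L,
         target_frequency = sw$target_frequency,
         frequency_tol = sw$frequency_tol,
         initial_frequency = sw$initial_frequency %||% -1,
         position = as.integer(sw$position))
  })
  raw <- with_seed(seed, {
    .forward_wf_cpp(unclass(model), sweeps_cpp, region_length,
                    as.integer(n_haplotypes), as.integer(burn_in),
                    as.integer(max_attempts))
  })
  ord <- order(raw$pos)
  m <- raw$alleles[, ord, drop = FALSE]
  pos <- raw$pos[ord]
  cs <- colSums(m)
  keep <- cs > 0L & cs < nrow(m)
  hs <- haplotype_set(m[, keep, drop = FALSE], chrom = "chr1",
                      pos = pos[keep],
                      pop = rep(pop_labels, times = n_haplotypes))
  truth <- ground_truth(model, sweeps, raw, pop_labels, seed)
  list(haps = hs, truth = truth)
}

ground_truth <- function(model, sweeps, raw, pop_labels, seed) {
  sweep_truth <- lapply(seq_along(sweeps), function(k) {
    f <- raw$sweep_freq[k, ]
    names(f) <- pop_labels
    list(target_population = sweeps[[k]]$target_population,
         mode = sweeps[[k]]$mode, s = sweeps[[k]]$s,
         onset_generation = sweeps[[k]]$onset_generation,
         position = raw$sweep_pos[k],
         final_frequency = f,
         trajectory = raw$trajectories[[k]])
  })
  events <- data.table::data.table(
    generations_before_present = c(model$T_dom, model$T_dom,
                                   model$T_split, model$T_split,
                                   vapply(sweeps, `[[`, numeric(1),
                                          "onset_generation")),
    event = c("wild/domestic split",
              sprintf("domestication bottleneck N=%g for %g gen",
                      model$N_bottleneck1, model$D_bottleneck1),
              "breed split",
              sprintf("breed bottlenecks N=%g for %g gen",
                      model$N_bottleneck2, model$D_bottleneck2),
              vapply(sweeps, function(sw)
                sprintf("%s sweep introduced in %s (s=%g)", sw$mode,
                        sw$target_population, sw$s), character(1))))
  structure(list(sweeps = sweep_truth, rejections = raw$rejections,
                 seed = seed, events = events[order(-generations_before_present)]),
            class = "GroundTruth")
}

#' Toy gene and QTL annotation tracks for a simulated region
#'
#' Generates `n_genes` non-overlapping gene spans with strand, and `n_qtl`
#' QTL intervals each carrying one of the four AnimalQTLdb-style trait
#' categories ("production", "reproduction", "exterior", "health") and a
#' subcategory label.
#'
#' @param region_length region size in bases
#' @param n_genes number of genes (>= 1); genes are placed inside equal slots
#'   so they can never overlap
#' @param n_qtl number of QTL intervals (0 gives an empty table)
#' @param seed integer seed; fixed seed reproduces the tables exactly
#' @param chrom chromosome id used in both tables
#' @return a list with `genes` (`data.table`: gene_id, chrom, start, end,
#'   strand; 0-based half-open) and `qtl` (`data.table`: chrom, start, end,
#'   category, subcategory, size_cm)
#' @export
make_toy_annotations <- function(region_length, n_genes = 20L, n_qtl = 8L,
                                 seed = 1L, chrom = "chr1") {
  stop_if_not_scalar_count(n_genes, "n_genes")
  stop_if_not_scalar_count(n_qtl, "n_qtl", min = 0L)
  slot <- floor(region_length / n_genes)
  if (slot < 200) stop("genes cannot fit without overlap", call. = FALSE)
  subcats <- list(
    production = c("average daily gain", "backfat thickness", "feed intake"),
    reproduction = c("total number born alive", "litter size",
                     "age at puberty"),
    exterior = c("coat color", "ear size", "teat number"),
    health = c("immune capacity", "leg weakness"))
  with_seed(seed, {
    len <- pmax(100L, as.integer(floor(runif(n_genes, 0.2, 0.8) * slot)))
    offset <- vapply(slot - len, function(room)
      as.integer(floor(runif(1) * max(1, room))), integer(1))
    start <- as.integer((seq_len(n_genes) - 1L) * slot + offset)
    genes <- data.table::data.table(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    if (n_qtl > 0L) {
      width <- as.integer(floor(runif(n_qtl, 0.02, 0.10) * region_length))
      qstart <- as.integer(floor(runif(n_qtl) * (region_length - width)))
      category <- sample(names(subcats), n_qtl, replace = TRUE)
      qtl <- data.table::data.table(
        chrom = chrom, start = qstart, end = qstart + width,
        category = category,
        subcategory = vapply(category, function(cc)
          sample(subcats[[cc]], 1L), character(1)),
        size_cm = round(width / 1e6, 4))  # ~1 cM per Mbp
    } else {
      qtl <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), category = character(),
                                    subcategory = character(),
                                    size_cm = numeric())
    }
    list(genes = genes, qtl = qtl)
  })
}
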