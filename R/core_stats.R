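#' Nucleotide diversity (pi) over a set of haplotypes
#'
#' Mean number of pairwise differences over all unordered haplotype pairs,
#' computed as the per-site sum of `c (n - c) / choose(n, 2)` where `c` is the
#' alternate-allele count — algebraically identical to enumerating every pair.
#' Reported per window (a sum over sites); divide by the physical span for a
#' per-bp value (the PBS ratio pi_w / pi_t is normalisation-free).
#'
#' @param haps 0/1 matrix, haplotypes x sites (or a `HaplotypeSet`)
#' @param sites optional column index restricting the window
#' @return a single numeric value
#' @export
nucleotide_diversity <- function(haps, sites = NULL) {
  m <- if (inherits(haps, "HaplotypeSet")) haps$alleles else as.matrix(haps)
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("pi needs at least 2 haplotypes", call. = FALSE)
  if (ncol(m) == 0L) return(0)
  cnt <- colSums(m)
  sum(cnt * (n - cnt)) / choose2(n)
}

#' Per-site allele counts, frequencies, MAF and outgroup polarization
#'
#' @param x a `HaplotypeSet`
#' @param outgroup label of the outgroup (wild) population used to polarize
#'   alleles into ancestral/derived states
#' @return a `data.table` with one row per site: per-population alt counts
#'   (`n_alt_<pop>`), haplotype totals (`n_hap_<pop>`), alt frequencies
#'   (`freq_<pop>`), MAF (`maf_<pop>`), plus `derived_allele` ("ref"/"alt"/NA)
#'   and `polarization_ambiguous` from [polarize_against_outgroup()].
#' @export
site_annotation <- function(x, outgroup) {
  stopifnot(inherits(x, "HaplotypeSet"))
  pops <- unique(x$pop)
  if (!outgroup %in% pops) {
    stop(sprintf("outgroup '%s' not among populations", outgroup),
         call. = FALSE)
  }
  dt <- data.table::data.table(site = seq_len(ncol(x$alleles)),
                               chrom = x$chrom, pos = x$pos,
                               ref = x$ref, alt = x$alt)
  for (p in pops) {
    rows <- pop_rows(x, p)
    cnt <- colSums(x$alleles[rows, , drop = FALSE])
    f <- cnt / length(rows)
    data.table::set(dt, j = paste0("n_alt_", p), value = as.integer(cnt))
    data.table::set(dt, j = paste0("n_hap_", p), value = length(rows))
    data.table::set(dt, j = paste0("freq_", p), value = f)
    data.table::set(dt, j = paste0("maf_", p), value = pmin(f, 1 - f))
  }
  pol <- polarize_against_outgroup(dt[[paste0("freq_", outgroup)]])
  dt[, `:=`(derived_allele = pol$derived_allele,
            polarization_ambiguous = pol$ambiguous)]
  dt[]
}

#' Polarize alleles against the outgroup
#'
#' Operational derived-allele rule for a domesticated lineage: the allele that
#' is minor, or absent, in the wild outgroup is called derived. A site where
#' both alleles sit at exactly 0.5 in the outgroup cannot be polarized and is
#' flagged ambiguous (such sites are excluded from iHS cores).
#'
#' @param outgroup_alt_freq numeric vector of alt-allele frequencies in the
#'   outgroup
#' @return a list with `derived_allele` (character, "ref"/"alt"/`NA`) and
#'   logical `ambiguous`
#' @export
polarize_against_outgroup <- function(outgroup_alt_freq) {
  f <- as.numeric(outgroup_alt_freq)
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("outgroup frequencies must lie in [0, 1]", call. = FALSE)
  }
  derived <- ifelse(f < 0.5, "alt", ifelse(f > 0.5, "ref", NA_character_))
  list(derived_allele = derived, ambiguous = f == 0.5)
}

#' Count distinct haplotypes in a window (the H statistic)
#'
#' @param haps 0/1 matrix of one population's haplotypes
#' @param sites column index of the window (typically 30 within-population
#'   variable sites)
#' @return integer count of distinct haplotype strings
#' @export
count_distinct_haplotypes <- function(haps, sites = NULL) {
  m <- if (inherits(haps, "HaplotypeSet")) haps$alleles else as.matrix(haps)
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  if (nrow(m) < 1L) stop("no haplotypes", call. = FALSE)
  length(unique(do.call(paste0, as.data.frame(m))))
}

#' Scan the H statistic in bins of within-population variable sites
#'
#' Windows advance in non-overlapping steps of `window_snps` sites that are
#' variable *within the focal population* (sites fixed in that population are
#' skipped when composing windows); a trailing window with fewer sites is
#' dropped. Windows never span chromosomes.
#'
#' @param x a `HaplotypeSet`
#' @param pop focal population label
#' @param window_snps sites per window (default 30)
#' @param step_snps step between window starts in variable-site units;
#'   defaults to `window_snps` (non-overlapping bins)
#' @return a `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open physical span), `first_site`, `last_site` (column indices into
#'   `x`), and `H`
#' @export
h_scan <- function(x, pop, window_snps = 30L, step_snps = window_snps) {
  stopifnot(inherits(x, "HaplotypeSet"))
  stop_if_not_scalar_count(window_snps, "window_snps")
  stop_if_not_scalar_count(step_snps, "step_snps")
  rows <- pop_rows(x, pop)
  if (length(rows) < 2L) stop("population needs >= 2 haplotypes", call. = FALSE)
  m <- x$alleles[rows, , drop = FALSE]
  cnt <- colSums(m)
  variable <- which(cnt > 0L & cnt < length(rows))
  out <- vector("list", 0L)
  for (ch in unique(x$chrom)) {
    v <- variable[x$chrom[variable] == ch]
    n <- length(v)
    if (n < window_snps) next
    starts <- seq(1L, n - window_snps + 1L, by = step_snps)
    H <- integer(length(starts))
    for (i in seq_along(starts)) {
      cols <- v[starts[i]:(starts[i] + window_snps - 1L)]
      H[i] <- count_distinct_haplotypes(m, cols)
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = ch,
      start = x$pos[v[starts]],
      end = x$pos[v[starts + window_snps - 1L]] + 1L,
      first_site = v[starts],
      last_site = v[starts + window_snps - 1L],
      H = H)
  }
  if (length(out) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), first_site = integer(),
                                  last_site = integer(), H = integer()))
  }
  data.table::rbindlist(out)
}

#' Histogram of the H statistic over all windows
#'
#' @inheritParams h_scan
#' @return a `data.table` with columns `H` and `n_windows`; the counts sum to
#'   the number of eligible windows
#' @export
h_distribution <- function(x, pop, window_snps = 30L,
                           step_snps = window_snps) {
  scan <- h_scan(x, pop, window_snps = window_snps, step_snps = step_snps)
  if (nrow(scan) == 0L) stop("no eligible windows", call. = FALSE)
  tab <- table(scan$H)
  data.table::data.table(H = as.integer(names(tab)),
                         n_windows = as.integer(tab))
}
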