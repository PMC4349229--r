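#' Phased haplotype set
#'
#' The substrate of every statistic in the package: a matrix of 0/1 alleles
#' with one row per phased haplotype and one column per biallelic SNP,
#' together with site coordinates and a population label per haplotype.
#' Coordinates are 0-based half-open throughout the package; VCF input is
#' converted at the boundary.
#'
#' @param alleles integer matrix in `{0,1}`, haplotypes x sites
#' @param chrom character vector of chromosome ids, one per site
#' @param pos integer vector of 0-based site positions, strictly increasing
#'   within each chromosome
#' @param pop character vector of population labels, one per haplotype row
#' @param sample character vector of sample ids, one per haplotype row; each
#'   diploid sample owns exactly two consecutive rows. Defaults to pairing
#'   rows `(1,2), (3,4), ...`.
#' @param ref,alt single-character reference / alternate alleles per site
#' @return an object of class `HaplotypeSet`
#' @export
haplotype_set <- function(alleles, chrom, pos, pop,
                          sample = NULL, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_hap <- nrow(alleles)
  n_site <- ncol(alleles)
  if (length(chrom) == 1L) chrom <- rep(chrom, n_site)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  pop <- as.character(pop)
  if (is.null(sample)) {
    if (n_hap %% 2L != 0L) {
      stop("odd number of haplotype rows: supply `sample` or pair rows",
           call. = FALSE)
    }
    sample <- rep(sprintf("s%04d", seq_len(n_hap / 2L)), each = 2L)
  }
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("C", n_site)
  x <- structure(
    list(alleles = alleles, chrom = chrom, pos = pos, pop = pop,
         sample = as.character(sample), ref = as.character(ref),
         alt = as.character(alt)),
    class = "HaplotypeSet")
  validate_haplotype_set(x)
  x
}

#' @rdname haplotype_set
#' @param x a `HaplotypeSet`
#' @export
validate_haplotype_set <- function(x) {
  a <- x$alleles
  if (length(x$chrom) != ncol(a) || length(x$pos) != ncol(a) ||
      length(x$ref) != ncol(a) || length(x$alt) != ncol(a)) {
    stop("site annotation length does not match the allele matrix",
         call. = FALSE)
  }
  if (length(x$pop) != nrow(a) || length(x$sample) != nrow(a)) {
    stop("haplotype annotation length does not match the allele matrix",
         call. = FALSE)
  }
  if (ncol(a) > 0L && !all(a == 0L | a == 1L)) {
    stop("allele matrix entries must be 0 or 1", call. = FALSE)
  }
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop(sprintf("positions not strictly increasing on chromosome %s", ch),
           call. = FALSE)
    }
  }
  tab <- table(x$sample)
  if (any(tab != 2L)) {
    stop("each diploid sample must contribute exactly two haplotype rows",
         call. = FALSE)
  }
  if (any(tapply(x$pop, x$sample, function(p) length(unique(p))) != 1L)) {
    stop("the two haplotypes of a sample must share one population label",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat(sprintf(
    "HaplotypeSet: %d haplotypes (%d samples) x %d sites on %d chromosome(s)\n",
    nrow(x$alleles), length(unique(x$sample)), ncol(x$alleles),
    length(unique(x$chrom))))
  for (p in unique(x$pop)) {
    cat(sprintf("  %-12s %3d haplotypes\n", p, sum(x$pop == p)))
  }
  invisible(x)
}

#' @export
dim.HaplotypeSet <- function(x) dim(x$alleles)

#' Subset a haplotype set by haplotype rows and/or sites
#'
#' @param x a `HaplotypeSet`
#' @param haps logical/integer index over haplotype rows
#' @param sites logical/integer index over site columns
#' @return a `HaplotypeSet`
#' @export
subset_haps <- function(x, haps = NULL, sites = NULL) {
  if (is.null(haps)) haps <- seq_len(nrow(x$alleles))
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  haplotype_set(x$alleles[haps, sites, drop = FALSE],
                chrom = x$chrom[sites], pos = x$pos[sites],
                pop = x$pop[haps], sample = x$sample[haps],
                ref = x$ref[sites], alt = x$alt[sites])
}

#' Rows of the allele matrix belonging to one population
#'
#' @param x a `HaplotypeSet`
#' @param pop population label
#' @return integer row indices
#' @export
pop_rows <- function(x, pop) {
  idx <- which(x$pop == pop)
  if (length(idx) == 0L) {
    stop(sprintf("no haplotypes labelled '%s'", pop), call. = FALSE)
  }
  idx
}

#' Drop sites that are monomorphic across a set of rows
#'
#' @param x a `HaplotypeSet`
#' @param rows haplotype rows defining the sample in which variability is
#'   assessed (default: all rows)
#' @return a `HaplotypeSet` restricted to segregating sites
#' @export
segregating_sites <- function(x, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  cs <- colSums(x$alleles[rows, , drop = FALSE])
  keep <- cs > 0L & cs < length(rows)
  subset_haps(x, sites = keep)
}
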