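#' Write a haplotype set as a phased VCF
#'
#' Emits minimal VCF 4.2: biallelic SNP records with phased `GT` (`|`
#' separator) and contig header lines. Internal 0-based positions are
#' converted to the VCF 1-based convention at this boundary.
#'
#' @param x a `HaplotypeSet`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(x, path) {
  stopifnot(inherits(x, "HaplotypeSet"))
  samples <- unique(x$sample)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    vapply(unique(x$chrom), function(ch)
      sprintf("##contig=<ID=%s,length=%d>", ch,
              max(x$pos[x$chrom == ch]) + 1L), character(1)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  a_rows <- match(samples, x$sample)            # first haplotype of sample
  gt <- matrix(paste0(x$alleles[a_rows, , drop = FALSE], "|",
                      x$alleles[a_rows + 1L, , drop = FALSE]),
               nrow = length(samples))
  body <- paste(x$chrom, x$pos + 1L, ".", x$ref, x$alt, ".", ".", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Parses with Bioconductor's VariantAnnotation. Multiallelic, non-SNP,
#' unphased or missing-genotype records are dropped and the drop count is
#' reported via `message()` and the `"n_dropped"` attribute. Positions are
#' converted to the internal 0-based convention; haplotype rows come out in
#' sample order, two per sample (left then right allele of the `|` genotype).
#'
#' @param path VCF file path
#' @param population_map named character vector mapping every sample name to
#'   its population label
#' @return a `HaplotypeSet`
#' @export
read_phased_vcf <- function(path, population_map) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_phased_vcf() needs the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  missing_samp <- setdiff(samples, names(population_map))
  if (length(missing_samp) > 0L) {
    stop(sprintf("samples missing from population_map: %s",
                 paste(missing_samp, collapse = ", ")), call. = FALSE)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  alt_list <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  biallelic_snp <- lengths(alt_list) == 1L & nchar(ref) == 1L &
    vapply(as.list(alt_list), function(a) nchar(as.character(a[1])) == 1L,
           logical(1))
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- biallelic_snp & phased
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_phased_vcf: dropped %d record(s) (multiallelic/non-SNP/unphased/missing)",
                    n_dropped))
  }
  if (!any(keep)) stop("no usable phased biallelic SNP records", call. = FALSE)
  vcf <- vcf[keep, ]
  gt <- gt[keep, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  hapA <- matrix(as.integer(substr(t(gt), 1L, 1L)), nrow = length(samples))
  hapB <- matrix(as.integer(substr(t(gt), 3L, 3L)), nrow = length(samples))
  n_site <- sum(keep)
  alleles <- matrix(0L, nrow = 2L * length(samples), ncol = n_site)
  alleles[seq(1L, by = 2L, length.out = length(samples)), ] <- hapA
  alleles[seq(2L, by = 2L, length.out = length(samples)), ] <- hapB
  out <- haplotype_set(
    alleles,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr) - 1L,
    pop = rep(unname(population_map[samples]), each = 2L),
    sample = rep(samples, each = 2L),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(VariantAnnotation::alt(vcf)),
                 function(a) as.character(a[1]), character(1)))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Internal plain-text haplotype matrix format
#'
#' One row per haplotype (`sample`, `pop`, then one 0/1 column per site); the
#' single header line names the site columns as `chrom:pos:ref:alt`.
#' `write_hap_text(read_hap_text(p))` is bit-stable.
#'
#' @param x a `HaplotypeSet`
#' @param path file path
#' @return `path` / a `HaplotypeSet`
#' @export
write_hap_text <- function(x, path) {
  stopifnot(inherits(x, "HaplotypeSet"))
  header <- paste(c("sample", "pop",
                    sprintf("%s:%d:%s:%s", x$chrom, x$pos, x$ref, x$alt)),
                  collapse = "\t")
  rows <- paste(x$sample, x$pop,
                apply(x$alleles, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_hap_text
#' @export
read_hap_text <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  site_tok <- strsplit(names(dt)[-(1:2)], ":", fixed = TRUE)
  haplotype_set(as.matrix(dt[, -(1:2)]),
                chrom = vapply(site_tok, `[`, character(1), 1L),
                pos = as.integer(vapply(site_tok, `[`, character(1), 2L)),
                pop = dt[[2L]], sample = dt[[1L]],
                ref = vapply(site_tok, `[`, character(1), 3L),
                alt = vapply(site_tok, `[`, character(1), 4L))
}

#' Read a gene model table
#'
#' Accepts either a headered TSV with columns `gene_id`, `chrom`, `start`,
#' `end`, `strand`, or header-less BED6 (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`). Coordinates are 0-based half-open (BED native).
#'
#' @param path file path
#' @return a `data.table` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty gene table")
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  }
  if (grepl("gene_id", first, fixed = TRUE)) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    dt <- dt[, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]
  } else {
    dt <- data.table::fread(path, sep = "\t", header = FALSE)
    data.table::setnames(dt, seq_len(6L)[seq_len(min(6L, ncol(dt)))],
                         c("chrom", "start", "end", "gene_id", "score",
                           "strand")[seq_len(min(6L, ncol(dt)))])
    dt <- dt[, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]
  }
  if (any(dt$start >= dt$end)) stop("gene with start >= end", call. = FALSE)
  if (!all(dt$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  dup <- duplicated(dt$gene_id)
  if (any(dup)) {
    stop(sprintf("duplicated gene ids: %s",
                 paste(unique(dt$gene_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  dt[]
}

#' Read a QTL interval table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `category`,
#' `subcategory` and optionally `size_cm`. Intervals with reported size
#' `>= max_cm` are excluded (the scan uses small, well-localized QTL only;
#' when `size_cm` is absent it is derived from the physical span at the
#' conventional ~1 cM per Mbp). Exact duplicates (same span and subcategory)
#' collapse to one row.
#'
#' @param path file path
#' @param max_cm exclusive upper size bound in centimorgans (default 5)
#' @return a `data.table` with columns `chrom`, `start`, `end`, `category`,
#'   `subcategory`, `size_cm`
#' @export
read_qtl_table <- function(path, max_cm = 5) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), category = character(),
                                  subcategory = character(),
                                  size_cm = numeric())
  dt <- tryCatch(suppressWarnings(
    data.table::fread(path, sep = "\t", header = TRUE)),
    error = function(e) empty)
  if (nrow(dt) == 0L) {
    warning("empty QTL table")
    return(empty)
  }
  categories <- c("production", "reproduction", "exterior", "health")
  if (!all(dt$category %in% categories)) {
    stop(sprintf("unknown QTL category: %s",
                 paste(setdiff(dt$category, categories), collapse = ", ")),
         call. = FALSE)
  }
  if (any(dt$start >= dt$end)) stop("QTL with start >= end", call. = FALSE)
  if (!"size_cm" %in% names(dt)) {
    dt[, size_cm := (end - start) / 1e6]   # ~1 cM per Mbp
  }
  dt[is.na(size_cm), size_cm := (end - start) / 1e6]
  n0 <- nrow(dt)
  dt <- dt[size_cm < max_cm]
  n_size <- n0 - nrow(dt)
  dt <- unique(dt, by = c("chrom", "start", "end", "subcategory"))
  n_dup <- n0 - n_size - nrow(dt)
  if (n_size + n_dup > 0L) {
    message(sprintf("read_qtl_table: excluded %d oversized and %d redundant loci",
                    n_size, n_dup))
  }
  dt[, c("chrom", "start", "end", "category", "subcategory", "size_cm"),
     with = FALSE]
}

#' Write gene / QTL tables
#'
#' Genes go out as headered TSV readable by [read_gene_table()]; QTL as the
#' headered TSV of [read_qtl_table()].
#'
#' @param genes,qtl tables as produced by [make_toy_annotations()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_gene_table <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
write_qtl_table <- function(qtl, path) {
  data.table::fwrite(qtl, path, sep = "\t")
  invisible(path)
}
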