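#' QTL-candidate genes
#'
#' A gene is a QTL candidate for a subcategory iff its span (no flank)
#' overlaps a QTL interval of that subcategory by at least 1 bp; a gene may
#' carry several categories/subcategories.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`)
#' @param qtls filtered, de-duplicated QTL table from [read_qtl_table()] or
#'   [make_toy_annotations()]
#' @return `data.table` with one row per (gene, subcategory): `gene_id`,
#'   `category`, `subcategory`
#' @export
qtl_candidate_genes <- function(genes, qtls) {
  genes <- data.table::as.data.table(genes)
  qtls <- data.table::as.data.table(qtls)
  out <- vector("list", 0L)
  for (ch in unique(genes$chrom)) {
    g <- genes[chrom == ch]
    q <- qtls[chrom == ch]
    if (nrow(q) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = g$start + 1L, end = g$end),
      IRanges::IRanges(start = q$start + 1L, end = q$end))
    if (length(hits) == 0L) next
    out[[length(out) + 1L]] <- data.table::data.table(
      gene_id = g$gene_id[S4Vectors::queryHits(hits)],
      category = q$category[S4Vectors::subjectHits(hits)],
      subcategory = q$subcategory[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) {
    return(data.table::data.table(gene_id = character(),
                                  category = character(),
                                  subcategory = character()))
  }
  unique(data.table::rbindlist(out))
}

#' Resampling enrichment test of an outlier set against a QTL gene set
#'
#' Observed overlap `|outliers  intersect  qtl_genes|` against a null of `B`
#' uniform same-size gene sets drawn without replacement from the universe
#' (equivalently the hypergeometric null, which the resampling p-value
#' converges to); `p = (#{null >= observed} + 1) / (B + 1)`.
#'
#' @param outliers character vector of outlier gene ids (subset of universe)
#' @param qtl_genes character vector of QTL-candidate gene ids
#' @param universe character vector of all annotated gene ids
#' @param B resampling replicates (default 100,000)
#' @param seed integer seed (bit-for-bit reproducible)
#' @param stratum label carried into the result (default `"all"`)
#' @return one-row `data.table`: `stratum`, `observed`, `n_candidates`,
#'   `n_qtl_genes`, `n_universe`, `B`, `p_value`
#' @export
enrichment_test <- function(outliers, qtl_genes, universe, B = 100000L,
                            seed = 1L, stratum = "all") {
  if (length(outliers) == 0L) stop("empty outlier set", call. = FALSE)
  stop_if_not_scalar_count(B, "B")
  stopifnot(all(outliers %in% universe), all(qtl_genes %in% universe))
  G <- length(universe)
  k <- length(outliers)
  qflag <- universe %in% qtl_genes
  obs <- sum(outliers %in% qtl_genes)
  r <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(B)) {
      if (sum(qflag[sample.int(G, k)]) >= obs) hits <- hits + 1L
    }
    hits
  })
  data.table::data.table(stratum = stratum, observed = obs,
                         n_candidates = k, n_qtl_genes = sum(qflag),
                         n_universe = G, B = as.integer(B),
                         p_value = (r + 1) / (B + 1))
}

#' Stratified QTL enrichment with Bonferroni correction
#'
#' Runs [enrichment_test()] for the pooled QTL gene set (`all`), each of the
#' four categories, and each subcategory. Subcategory p-values are Bonferroni
#' adjusted within this family (multiplied by the number of testable
#' subcategory strata, capped at 1). Strata whose QTL gene set is empty are
#' reported untestable (`NA` p-values).
#'
#' @param outliers character vector of outlier gene ids
#' @param qtl_map output of [qtl_candidate_genes()]
#' @param universe character vector of all annotated gene ids
#' @param B resampling replicates per stratum
#' @param seed integer master seed (one derived seed per stratum)
#' @return `data.table` with one row per stratum: `stratum_type`, `stratum`,
#'   `observed`, `n_candidates`, `n_qtl_genes`, `n_universe`, `B`, `p_value`,
#'   `p_bonferroni` (subcategory rows only)
#' @export
stratified_enrichment <- function(outliers, qtl_map, universe, B = 10000L,
                                  seed = 1L) {
  qtl_map <- data.table::as.data.table(qtl_map)
  strata <- data.table::rbindlist(list(
    data.table::data.table(stratum_type = "all", stratum = "all"),
    unique(qtl_map[, .(stratum_type = "category", stratum = category)]),
    unique(qtl_map[, .(stratum_type = "subcategory", stratum = subcategory)])))
  res <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    genes_i <- if (strata$stratum_type[i] == "all") {
      unique(qtl_map$gene_id)
    } else if (strata$stratum_type[i] == "category") {
      unique(qtl_map[category == strata$stratum[i], gene_id])
    } else {
      unique(qtl_map[subcategory == strata$stratum[i], gene_id])
    }
    if (length(genes_i) == 0L) {
      res[[i]] <- data.table::data.table(
        stratum = strata$stratum[i], observed = NA_integer_,
        n_candidates = length(outliers), n_qtl_genes = 0L,
        n_universe = length(universe), B = as.integer(B),
        p_value = NA_real_)
    } else {
      res[[i]] <- enrichment_test(outliers, genes_i, universe, B = B,
                                  seed = derive_seed(seed, i),
                                  stratum = strata$stratum[i])
    }
  }
  res <- data.table::rbindlist(res)
  res[, stratum_type := strata$stratum_type]
  n_sub <- sum(strata$stratum_type == "subcategory" & !is.na(res$p_value))
  res[, p_bonferroni := ifelse(stratum_type == "subcategory",
                               pmin(1, p_value * n_sub), NA_real_)]
  data.table::setcolorder(res, c("stratum_type", "stratum"))
  res[]
}
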