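#' Extended haplotype homozygosity decay from a core allele
#'
#' Among the carriers of the core allele, EHH at an extension covering site
#' set S is the probability that two randomly drawn carriers are identical
#' over S: `sum_h C(n_h,2) / C(n_c,2)` over distinct extended haplotypes.
#' The curve is computed outward site-by-site on each flank, using every SNP
#' regardless of its frequency, and truncated at the first site where EHH
#' drops below `cutoff` (that point is kept for interpolation) or at the
#' chromosome edge.
#'
#' @param haps 0/1 matrix of one population's haplotypes on one chromosome,
#'   columns in position order
#' @param positions base positions of the columns
#' @param core column index of the core SNP
#' @param core_allele 0 or 1: the allele whose carriers are followed
#' @param cutoff EHH truncation threshold (default 0.05)
#' @return an `EhhCurve`: core index/position/allele, carrier count, `left`
#'   and `right` data frames (`offset` in bases from the core, `ehh`) and a
#'   truncation reason per flank (`"cutoff"` or `"edge"`)
#' @export
ehh <- function(haps, positions, core, core_allele, cutoff = 0.05) {
  m <- if (inherits(haps, "HaplotypeSet")) haps$alleles else as.matrix(haps)
  storage.mode(m) <- "integer"
  stopifnot(length(positions) == ncol(m), core >= 1L, core <= ncol(m),
            core_allele %in% c(0L, 1L))
  carriers <- which(m[, core] == core_allele)
  if (length(carriers) < 2L) {
    stop("fewer than 2 carriers of the core allele: site unscored",
         call. = FALSE)
  }
  pos <- as.numeric(positions)
  left <- .ehh_flank_cpp(m, core - 1L, -1L, carriers - 1L, pos, cutoff)
  right <- .ehh_flank_cpp(m, core - 1L, 1L, carriers - 1L, pos, cutoff)
  structure(list(core = core, core_pos = positions[core],
                 allele = core_allele, n_carriers = length(carriers),
                 left = data.frame(offset = left$offset, ehh = left$ehh),
                 right = data.frame(offset = right$offset, ehh = right$ehh),
                 truncation_left = left$truncation,
                 truncation_right = right$truncation,
                 cutoff = cutoff),
            class = "EhhCurve")
}

#' Integrated EHH (iHH) of a decay curve
#'
#' Trapezoidal integral of EHH over physical distance, both flanks summed,
#' anchored at EHH = 1 at the core. A flank that reached the cutoff is
#' integrated up to the linearly interpolated crossing of `cutoff`; a flank
#' truncated by the chromosome edge is integrated over all its points and the
#' curve is flagged (edge-truncated integrals are biased and such cores are
#' excluded from ranking by default).
#'
#' @param curve an [ehh()] curve
#' @return a list with `ihh` (bases) and logical `edge_truncated`
#' @export
ihh <- function(curve) {
  stopifnot(inherits(curve, "EhhCurve"))
  cutoff <- curve$cutoff
  flank_integral <- function(fl, trunc) {
    d <- c(0, fl$offset)
    e <- c(1, fl$ehh)
    k <- length(d)
    if (k == 1L) return(0)
    if (trunc == "cutoff") {
      # last point is the first one below cutoff: integrate to the crossing
      full <- if (k > 2L) {
        sum((d[2:(k - 1)] - d[1:(k - 2)]) * (e[2:(k - 1)] + e[1:(k - 2)]) / 2)
      } else 0
      d0 <- d[k - 1]; e0 <- e[k - 1]; d1 <- d[k]; e1 <- e[k]
      dstar <- d0 + (e0 - cutoff) * (d1 - d0) / (e0 - e1)
      full + (dstar - d0) * (e0 + cutoff) / 2
    } else {
      sum(diff(d) * (head(e, -1) + tail(e, -1)) / 2)
    }
  }
  list(ihh = flank_integral(curve$left, curve$truncation_left) +
         flank_integral(curve$right, curve$truncation_right),
       edge_truncated = curve$truncation_left == "edge" ||
         curve$truncation_right == "edge")
}

#' Eligible iHS core SNPs for one breed
#'
#' Cores are sites with within-breed MAF strictly above `maf_min` (the scan
#' default 0.2 targets intermediate-frequency selected alleles, where iHS has
#' maximal power), unambiguous outgroup polarization, and at least two
#' carriers of each allele in the breed.
#'
#' @param annot a [site_annotation()] table
#' @param breed focal breed label
#' @param maf_min strict lower MAF bound (default 0.2)
#' @return integer vector of eligible site indices (rows of `annot`)
#' @export
select_cores <- function(annot, breed, maf_min = 0.2) {
  maf <- annot[[paste0("maf_", breed)]]
  n_alt <- annot[[paste0("n_alt_", breed)]]
  n_hap <- annot[[paste0("n_hap_", breed)]]
  if (is.null(maf)) stop(sprintf("no MAF column for breed '%s'", breed),
                         call. = FALSE)
  which(maf > maf_min &
          !annot$polarization_ambiguous &
          !is.na(annot$derived_allele) &
          n_alt >= 2L & (n_hap - n_alt) >= 2L)
}

#' Standardize raw iHS scores within derived-allele-frequency classes
#'
#' Records are partitioned into `n_bins` equal-width derived-frequency classes
#' on (0, 1); classes with fewer than `min_class` records are merged with the
#' nearest (by bin centre) occupied class. Within each final class the signed
#' raw score is centred and scaled to sample mean 0 and variance 1; the
#' ranking statistic is the absolute standardized score.
#'
#' @param records `data.table` with columns `raw` and `freq_derived`
#' @param n_bins number of frequency classes (default 20)
#' @param min_class minimum records per class before merging (default 10)
#' @return the records with added columns `freq_class` (integer id after
#'   merging), `ihs_std` and `ihs_abs`; a class with zero variance gets `NA`
#'   scores and a warning
#' @export
standardize_ihs <- function(records, n_bins = 20L, min_class = 10L) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) {
    records[, `:=`(freq_class = integer(), ihs_std = numeric(),
                   ihs_abs = numeric())]
    return(records[])
  }
  stopifnot(all(records$freq_derived > 0 & records$freq_derived < 1))
  bin <- pmin(as.integer(ceiling(records$freq_derived * n_bins)), n_bins)
  cls <- merge_small_classes(bin, n_bins, min_class)
  records[, freq_class := cls]
  records[, ihs_std := {
    s <- sd(raw)
    if (!is.na(s) && s > 0) (raw - mean(raw)) / s else NA_real_
  }, by = freq_class]
  if (anyNA(records$ihs_std)) {
    warning("frequency class with zero score variance: scores set to NA")
  }
  records[, ihs_abs := abs(ihs_std)]
  records[]
}

# merge classes with < min_class members into the nearest occupied class
# (bin-centre distance; ties resolve to the lower class)
merge_small_classes <- function(bin, n_bins, min_class) {
  repr <- seq_len(n_bins)   # class representative per original bin
  repeat {
    tab <- table(factor(repr[bin], levels = seq_len(n_bins)))
    occupied <- as.integer(names(tab))[tab > 0]
    small <- occupied[tab[occupied] < min_class]
    if (length(small) == 0L || length(occupied) == 1L) break
    s <- small[1L]
    others <- setdiff(occupied, s)
    target <- others[order(abs(others - s), others)][1L]
    repr[repr == s] <- target
  }
  repr[bin]
}

#' Genome-wide iHS scan for one breed
#'
#' For every eligible core SNP ([select_cores()]): EHH decay curves for the
#' derived and ancestral alleles (derived = the allele minor or absent in the
#' wild outgroup), trapezoidal integration to `iHH_D` / `iHH_A`, the raw score
#' `ln(iHH_A / iHH_D)`, and per-frequency-class standardization
#' ([standardize_ihs()]). EHH extension uses all SNPs of the combined sample,
#' whatever their breed MAF.
#'
#' @param x a `HaplotypeSet`
#' @param breed focal breed label
#' @param outgroup wild outgroup label used for polarization
#' @param maf_min strict MAF threshold for cores (default 0.2)
#' @param cutoff EHH truncation threshold (default 0.05)
#' @param n_bins,min_class standardization classes, see [standardize_ihs()]
#' @param keep_truncated include edge-truncated cores in standardization and
#'   ranking (default `FALSE`: they are reported but unscored)
#' @return a `data.table` with one row per eligible core: `site`, `chrom`,
#'   `pos`, `freq_derived`, `ihh_a`, `ihh_d`, `raw`, `edge_truncated`,
#'   `freq_class`, `ihs_std`, `ihs_abs`
#' @export
ihs_scan <- function(x, breed, outgroup, maf_min = 0.2, cutoff = 0.05,
                     n_bins = 20L, min_class = 10L, keep_truncated = FALSE) {
  stopifnot(inherits(x, "HaplotypeSet"))
  annot <- site_annotation(x, outgroup)
  cores <- select_cores(annot, breed, maf_min)
  rows <- pop_rows(x, breed)
  recs <- vector("list", 0L)
  for (ch in unique(x$chrom)) {
    sidx <- which(x$chrom == ch)
    ch_cores <- intersect(cores, sidx)
    if (length(ch_cores) == 0L) next
    m <- x$alleles[rows, sidx, drop = FALSE]
    storage.mode(m) <- "integer"
    pos <- as.numeric(x$pos[sidx])
    local_core <- match(ch_cores, sidx)
    der_is_alt <- annot$derived_allele[ch_cores] == "alt"
    n <- length(ch_cores)
    ihh_a <- ihh_d <- numeric(n)
    edge <- logical(n)
    for (i in seq_len(n)) {
      der_allele <- if (der_is_alt[i]) 1L else 0L
      cd <- ehh(m, pos, local_core[i], der_allele, cutoff)
      ca <- ehh(m, pos, local_core[i], 1L - der_allele, cutoff)
      id <- ihh(cd); ia <- ihh(ca)
      ihh_d[i] <- id$ihh; ihh_a[i] <- ia$ihh
      edge[i] <- id$edge_truncated || ia$edge_truncated
    }
    f_alt <- annot[[paste0("freq_", breed)]][ch_cores]
    recs[[length(recs) + 1L]] <- data.table::data.table(
      site = ch_cores, chrom = ch, pos = x$pos[ch_cores],
      freq_derived = ifelse(der_is_alt, f_alt, 1 - f_alt),
      ihh_a = ihh_a, ihh_d = ihh_d, edge_truncated = edge)
  }
  if (length(recs) == 0L) {
    stop("no eligible iHS cores", call. = FALSE)
  }
  recs <- data.table::rbindlist(recs)
  recs[, raw := ifelse(ihh_a > 0 & ihh_d > 0, log(ihh_a / ihh_d), NA_real_)]
  scorable <- !is.na(recs$raw) & (keep_truncated | !recs$edge_truncated)
  scored <- standardize_ihs(recs[scorable], n_bins = n_bins,
                            min_class = min_class)
  recs[, `:=`(freq_class = NA_integer_, ihs_std = NA_real_,
              ihs_abs = NA_real_)]
  recs[scorable, `:=`(freq_class = scored$freq_class,
                      ihs_std = scored$ihs_std,
                      ihs_abs = scored$ihs_abs)]
  data.table::setattr(recs, "breed", breed)
  recs[]
}
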