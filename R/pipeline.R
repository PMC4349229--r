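#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> scan -> gene -> enrichment
#' pipeline. Defaults are the scan's canonical values: 200-SNP PBS windows
#' with step 50, 30-SNP H bins, MAF > 0.2 iHS cores, EHH cutoff 0.05, 1 kb
#' gene flank, top 1% outliers.
#'
#' @param breeds,outgroup the three population labels
#' @param vcf optional path to a phased VCF (otherwise data are simulated)
#' @param population_map named sample -> population vector (VCF input only)
#' @param genes,qtl optional paths to gene / QTL tables; when absent, toy
#'   annotations are generated over the simulated region
#' @param sim `"coalescent"` or `"forward"`; `sim_args` is passed on to the
#'   simulator (e.g. `n_replicates`, `theta`, `region_length`, `sweeps`)
#' @param model a [demography_model()] (defaults to the package default)
#' @param window_snps,step_snps,h_window,maf_min,ehh_cutoff,flank,percentile,B
#'   scan tunables (see module functions)
#' @param seed master integer seed; stage seeds are derived via [derive_seed()]
#' @return a `RunConfig` list
#' @export
run_config <- function(breeds = c("Yorkshire", "Landrace"),
                       outgroup = "WildBoar",
                       vcf = NULL, population_map = NULL,
                       genes = NULL, qtl = NULL,
                       sim = c("coalescent", "forward"), sim_args = list(),
                       model = demography_model(),
                       window_snps = 200L, step_snps = 50L, h_window = 30L,
                       maf_min = 0.2, ehh_cutoff = 0.05, flank = 1000L,
                       percentile = 0.01, B = 10000L, seed = 1L) {
  sim <- match.arg(sim)
  structure(list(breeds = breeds, outgroup = outgroup, vcf = vcf,
                 population_map = population_map, genes = genes, qtl = qtl,
                 sim = sim, sim_args = sim_args, model = model,
                 window_snps = window_snps, step_snps = step_snps,
                 h_window = h_window, maf_min = maf_min,
                 ehh_cutoff = ehh_cutoff, flank = flank,
                 percentile = percentile, B = B, seed = seed),
            class = "RunConfig")
}

#' Load a `RunConfig` from a JSON file
#'
#' @param path JSON file; fields mirror [run_config()] arguments, with `model`
#'   given as a named list of [demography_model()] fields
#' @return a `RunConfig`
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(js$model)) js$model <- do.call(demography_model, as.list(js$model))
  if (!is.null(js$sim_args)) {
    js$sim_args <- as.list(js$sim_args)
    if (!is.null(js$sim_args$sweeps)) {
      sw <- js$sim_args$sweeps
      if (is.data.frame(sw)) sw <- split(sw, seq_len(nrow(sw)))
      js$sim_args$sweeps <- lapply(sw, function(s)
        do.call(sweep_spec, as.list(s)))
    }
  }
  do.call(run_config, js)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full sweep-scan pipeline
#'
#' simulate (or load) -> PBS scan -> iHS scan per breed -> H scan per
#' population -> gene outlier calling per (breed, method) -> between-breed
#' overlap -> QTL enrichment. Writes a deterministic directory layout
#' (`data/`, `scans/`, `genes/`, `enrichment/`, `manifest.json`); re-running
#' with the same config reproduces all outputs byte-identically.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the in-memory stage results and the manifest
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("data", "scans", "genes", "enrichment")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  counts <- list()
  labs <- c(config$breeds, config$outgroup)

  hs <- pipeline_stage("input", {
    x <- if (!is.null(config$vcf)) {
      if (is.null(config$population_map)) {
        stop("VCF input needs a population_map")
      }
      read_phased_vcf(config$vcf, unlist(config$population_map))
    } else if (config$sim == "coalescent") {
      args <- config$sim_args
      reps <- do.call(simulate_neutral_coalescent, c(
        list(model = config$model, seed = derive_seed(config$seed, 1L)),
        args[setdiff(names(args), "sweeps")]))
      combine_replicates(reps)
    } else {
      res <- do.call(simulate_forward_wf, c(
        list(model = config$model, seed = derive_seed(config$seed, 1L)),
        config$sim_args))
      attr(res$haps, "truth") <- res$truth
      res$haps
    }
  })
  if (!all(labs %in% hs$pop)) {
    stop(sprintf("pipeline stage 'input' failed: missing population label(s): %s",
                 paste(setdiff(labs, hs$pop), collapse = ", ")),
         call. = FALSE)
  }
  truth <- attr(hs, "truth")
  write_hap_text(hs, file.path(out_dir, "data", "haplotypes.tsv"))
  write_phased_vcf(hs, file.path(out_dir, "data", "haplotypes.vcf"))
  counts$sites_in <- ncol(hs$alleles)

  ann <- pipeline_stage("annotations", {
    if (!is.null(config$genes)) {
      list(genes = read_gene_table(config$genes),
           qtl = if (is.null(config$qtl)) NULL else read_qtl_table(config$qtl))
    } else {
      # toy annotations over every simulated chromosome
      chroms <- unique(hs$chrom)
      n_genes <- max(2L, ceiling(24L / length(chroms)))
      n_qtl <- max(1L, ceiling(8L / length(chroms)))
      per_chrom <- lapply(seq_along(chroms), function(i) {
        region <- max(hs$pos[hs$chrom == chroms[i]]) + 1L
        ann <- make_toy_annotations(region, n_genes = n_genes, n_qtl = n_qtl,
                                    seed = derive_seed(config$seed, 100L + i),
                                    chrom = chroms[i])
        ann$genes[, gene_id := sprintf("%s_%s", chroms[i], gene_id)]
        ann
      })
      list(genes = data.table::rbindlist(lapply(per_chrom, `[[`, "genes")),
           qtl = data.table::rbindlist(lapply(per_chrom, `[[`, "qtl")))
    }
  })
  write_gene_table(ann$genes, file.path(out_dir, "data", "genes.tsv"))
  if (!is.null(ann$qtl)) {
    write_qtl_table(ann$qtl, file.path(out_dir, "data", "qtl.tsv"))
  }

  pbs <- pipeline_stage("pbs_scan", {
    pbs_scan(hs, config$breeds, config$outgroup,
             window_snps = config$window_snps, step_snps = config$step_snps)
  })
  data.table::fwrite(pbs, file.path(out_dir, "scans", "pbs.tsv"), sep = "\t")
  counts$pbs_windows <- nrow(pbs)

  ihs <- pipeline_stage("ihs_scan", {
    setNames(lapply(config$breeds, function(b) {
      ihs_scan(hs, b, config$outgroup, maf_min = config$maf_min,
               cutoff = config$ehh_cutoff)
    }), config$breeds)
  })
  for (b in config$breeds) {
    data.table::fwrite(ihs[[b]],
                       file.path(out_dir, "scans", sprintf("ihs_%s.tsv", b)),
                       sep = "\t")
    counts[[sprintf("ihs_cores_%s", b)]] <- nrow(ihs[[b]])
    counts[[sprintf("ihs_scored_%s", b)]] <- sum(!is.na(ihs[[b]]$ihs_abs))
  }

  hstat <- pipeline_stage("h_scan", {
    setNames(lapply(labs, function(p)
      h_scan(hs, p, window_snps = config$h_window)), labs)
  })
  for (p in labs) {
    data.table::fwrite(hstat[[p]],
                       file.path(out_dir, "scans", sprintf("h_%s.tsv", p)),
                       sep = "\t")
  }

  ranked <- pipeline_stage("gene_outliers", {
    res <- list()
    for (b in config$breeds) {
      win <- pbs[flag == "" & is.finite(get(pbs_col(config$breeds, b)))]
      sig_pbs <- win[, .(chrom, start, end,
                         score = get(pbs_col(config$breeds, b)))]
      scored <- ihs[[b]][!is.na(ihs_abs)]
      sig_ihs <- scored[, .(chrom, start = pos, end = pos + 1L,
                            score = ihs_abs)]
      for (method in c("PBS", "iHS")) {
        sig <- if (method == "PBS") sig_pbs else sig_ihs
        asg <- assign_signals_to_genes(sig, ann$genes, flank = config$flank)
        if (nrow(asg) == 0L) next
        rk <- rank_and_call_outliers(gene_best_scores(asg),
                                     universe_size = nrow(ann$genes),
                                     percentile = config$percentile)
        rk[, `:=`(breed = b, method = method)]
        res[[paste(b, method, sep = "_")]] <- rk
      }
    }
    res
  })
  for (nm in names(ranked)) {
    data.table::fwrite(ranked[[nm]],
                       file.path(out_dir, "genes",
                                 sprintf("ranked_%s.tsv", nm)), sep = "\t")
    out_bed <- merge(ranked[[nm]][outlier == TRUE, .(gene_id)],
                     ann$genes, by = "gene_id")[
      order(chrom, start),
      .(chrom, start, end, gene_id, score = 0L, strand)]
    data.table::fwrite(out_bed,
                       file.path(out_dir, "genes",
                                 sprintf("outliers_%s.bed", nm)),
                       sep = "\t", col.names = FALSE)
  }
  # BED of top-1% PBS windows per breed
  for (b in config$breeds) {
    col <- pbs_col(config$breeds, b)
    ok <- pbs[flag == "" & is.finite(get(col))]
    if (nrow(ok) > 0L) {
      ntop <- max(1L, round(0.01 * nrow(ok)))
      top <- ok[order(-get(col))][seq_len(ntop),
                                  .(chrom, start, end,
                                    name = sprintf("pbs_%s", b),
                                    score = get(col))]
      data.table::fwrite(top[order(chrom, start)],
                         file.path(out_dir, "scans",
                                   sprintf("pbs_top_%s.bed", b)),
                         sep = "\t", col.names = FALSE)
    }
  }

  overlaps <- pipeline_stage("breed_overlap", {
    res <- list()
    for (method in c("PBS", "iHS")) {
      k1 <- paste(config$breeds[1], method, sep = "_")
      k2 <- paste(config$breeds[2], method, sep = "_")
      if (!is.null(ranked[[k1]]) && !is.null(ranked[[k2]])) {
        res[[method]] <- overlap_between_breeds(
          ranked[[k1]][outlier == TRUE, gene_id],
          ranked[[k2]][outlier == TRUE, gene_id],
          universe = ann$genes$gene_id, B = config$B,
          seed = derive_seed(config$seed, 3L))
      }
    }
    res
  })

  enr <- pipeline_stage("qtl_enrichment", {
    if (is.null(ann$qtl) || nrow(ann$qtl) == 0L) {
      NULL   # no QTL: enrichment is a no-test result
    } else {
      qmap <- qtl_candidate_genes(ann$genes, ann$qtl)
      res <- list()
      for (nm in names(ranked)) {
        out_genes <- ranked[[nm]][outlier == TRUE, gene_id]
        e <- stratified_enrichment(out_genes, qmap, ann$genes$gene_id,
                                   B = config$B,
                                   seed = derive_seed(config$seed, 4L))
        e[, set := nm]
        res[[nm]] <- e
      }
      data.table::rbindlist(res)
    }
  })
  if (!is.null(enr) && ncol(enr) > 0L) {
    data.table::fwrite(enr, file.path(out_dir, "enrichment", "qtl.tsv"),
                       sep = "\t")
  }

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    config = config_as_json(config),
    counts = counts,
    overlaps = lapply(overlaps, function(o)
      list(observed = o$observed, p_value = o$p_value, B = o$B)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(haps = hs, truth = truth, pbs = pbs, ihs = ihs, h = hstat,
                 ranked = ranked, overlaps = overlaps, enrichment = enr,
                 manifest = manifest))
}

pbs_col <- function(breeds, b) {
  c("pbs_1", "pbs_2")[match(b, breeds)]
}

config_as_json <- function(config) {
  cfg <- unclass(config)
  cfg$model <- unclass(cfg$model)
  cfg$sim_args <- lapply(cfg$sim_args, function(a)
    if (inherits(a, "SweepSpec") || is.list(a)) "(object)" else a)
  cfg
}

#' Concatenate coalescent replicates into one multi-locus haplotype set
#'
#' Replicates share the sample layout; their site columns are concatenated,
#' each replicate keeping its own chromosome id (independent loci).
#'
#' @param reps list of `HaplotypeSet` objects from
#'   [simulate_neutral_coalescent()]
#' @return a single `HaplotypeSet`
#' @export
combine_replicates <- function(reps) {
  stopifnot(length(reps) >= 1L)
  haplotype_set(do.call(cbind, lapply(reps, function(r) r$alleles)),
                chrom = unlist(lapply(reps, `[[`, "chrom")),
                pos = unlist(lapply(reps, `[[`, "pos")),
                pop = reps[[1]]$pop, sample = reps[[1]]$sample,
                ref = unlist(lapply(reps, `[[`, "ref")),
                alt = unlist(lapply(reps, `[[`, "alt")))
}
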