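#' @keywords internal
write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full parallelism pipeline
#'
#' Executes the stages in order — expression/detection filtering, per-population
#' differential calling for both omics, pairwise parallelism statistics,
#' heterogeneity permutation nulls, the downsampling-equalized cross-level
#' comparison, and (when pathway files are given) the joint pathway analysis —
#' and writes one output table per stage plus a JSON run manifest into
#' `outdir`. Any stage failure aborts with the stage name in the message. Two
#' runs with the same inputs, config and seed produce byte-identical outputs.
#'
#' @param config A [run_config()] list.
#' @param counts Path to the RNA counts TSV (or a counts [omics_matrix()]).
#' @param meta_rna Path to the RNA sample metadata TSV (ignored when `counts`
#'   is already an `omics_matrix`).
#' @param metabolites,meta_met Metabolite matrix/metadata (paths or an
#'   `omics_matrix`); optional — metabolome stages are skipped when absent.
#' @param gmt_genes,gmt_mets Optional GMT paths (or `pathway_annotation`s)
#'   enabling the joint pathway stage; the metabolite matrix is then required.
#' @param outdir Output directory (created).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, counts, meta_rna = NULL,
                         metabolites = NULL, meta_met = NULL,
                         gmt_genes = NULL, gmt_mets = NULL,
                         outdir = "parallevol_run") {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    pv_log("stage %-14s done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if ((!is.null(gmt_genes) || !is.null(gmt_mets)) && is.null(metabolites)) {
    stop("configuration error: pathway stage enabled but no metabolite matrix supplied")
  }

  rna <- stage("load_rna", {
    if (inherits(counts, "omics_matrix")) counts
    else read_omics_matrix(counts, meta_rna, "counts")
  })
  met <- if (!is.null(metabolites)) stage("load_met", {
    if (inherits(metabolites, "omics_matrix")) metabolites
    else read_omics_matrix(metabolites, meta_met, "log_area")
  }) else NULL

  de_rna <- stage("de_rna", de_call(rna, config))
  write_stage_tsv(de_rna, file.path(outdir, "de_rna.tsv"))
  de_met <- NULL
  if (!is.null(met)) {
    de_met <- stage("de_met", met_de_call(met, config))
    write_stage_tsv(de_met, file.path(outdir, "de_met.tsv"))
  }

  par_tab <- stage("parallelism", {
    tab <- pairwise_parallelism(de_rna, mode = "both", level = "transcriptome")
    if (!is.null(de_met)) {
      tab <- rbind(tab, pairwise_parallelism(de_met, mode = "both", level = "metabolome"))
    }
    tab
  })
  write_stage_tsv(par_tab, file.path(outdir, "parallelism.tsv"))

  nulls <- stage("null_test", {
    levels <- list(list(x = rna, level = "transcriptome"))
    if (!is.null(met)) levels <- c(levels, list(list(x = met, level = "metabolome")))
    res <- list()
    for (lv in levels) {
      for (st in config$null_statistics) {
        r <- heterogeneity_test(lv$x, config, statistic = st, level = lv$level)
        res[[paste(lv$level, st, sep = ".")]] <- unclass(r)
      }
    }
    res
  })
  jsonlite::write_json(c(nulls, list(seed = config$rng_seed)),
                       file.path(outdir, "null_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  hier <- NULL
  if (!is.null(de_met)) {
    hier <- stage("hierarchy", hierarchy_compare(de_rna, de_met, config))
    hj <- list(populations = hier$populations,
               pearson = unclass(hier$pearson),
               jaccard = if (!is.null(hier$jaccard)) unclass(hier$jaccard))
    jsonlite::write_json(hj, file.path(outdir, "hierarchy.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  pathways <- NULL
  if (!is.null(gmt_genes) && !is.null(gmt_mets)) {
    pathways <- stage("pathways", {
      gs <- if (inherits(gmt_genes, "pathway_annotation")) gmt_genes else read_gmt(gmt_genes)
      ms <- if (inherits(gmt_mets, "pathway_annotation")) gmt_mets else read_gmt(gmt_mets)
      joint_pathway_analysis(rna, met, gs, ms, config)
    })
    write_stage_tsv(pathways$table, file.path(outdir, "pathways.tsv"))
    write_stage_tsv(pathways$shared, file.path(outdir, "pathways_shared.tsv"))
  }

  manifest <- list(package = "parallevol",
                   version = as.character(utils::packageVersion("parallevol")),
                   seed = config$rng_seed,
                   config = unclass(config),
                   stages = c("de_rna", if (!is.null(de_met)) "de_met",
                              "parallelism", "null_test",
                              if (!is.null(hier)) "hierarchy",
                              if (!is.null(pathways)) "pathways"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(de_rna = de_rna, de_met = de_met, parallelism = par_tab,
                 nulls = nulls, hierarchy = hier, pathways = pathways,
                 outdir = outdir))
}
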