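#' Simulation parameters for the hierarchical redundancy model
#'
#' The generator emulates a two-level experimental-evolution study design:
#' `n_anc` ancestral replicate samples; `n_pops_rna` evolved populations with
#' `n_rep` replicate samples each for the transcriptome; the first
#' `n_pops_met` of those populations (with `n_rep` replicates) for the
#' metabolome. Genes are organized into disjoint modules of `genes_per_module`
#' genes, one module per metabolite; a module gene is "active" (responding) in
#' a given population with probability `redundancy_fraction`, and an active
#' gene's true log2 effect is the sum of a module-shared component
#' (`shared_effect_sd`) and a population-specific component
#' (`specific_effect_sd`). Each metabolite's true effect is an aggregation
#' (default: mean) of its module genes' effects, so with partial redundancy
#' the metabolome is more parallel across populations than the transcriptome
#' by construction.
#'
#' Default effect scales: shared module effects with SD 1.0 on the log2 scale
#' (typical ~2-fold shifts, the size of response seen in strong laboratory
#' adaptation), population-specific effects with SD 0.5, and activation
#' probability 0.5 (each population recruits about half of each module).
#'
#' @param n_genes Number of genes (default 2000). Genes not in any module are
#'   effect-free "background".
#' @param n_metabolites Number of metabolites = number of modules (default 200).
#' @param genes_per_module Module size k (default 5).
#' @param n_pops_rna Evolved populations with transcriptome data (default 10).
#' @param n_pops_met Evolved populations with metabolome data (default 6);
#'   always the first `n_pops_met` populations.
#' @param n_anc Ancestral replicate samples (default 5).
#' @param n_rep Replicate samples per evolved population (default 3).
#' @param shared_effect_sd SD of the module-shared log2 effect (default 1).
#' @param specific_effect_sd SD of the population-specific log2 effect
#'   (default 0.5).
#' @param redundancy_fraction Probability that a module gene is active in a
#'   given population (default 0.5).
#' @param nb_dispersion Negative-binomial dispersion phi, variance
#'   `mu + phi * mu^2` (default 0.05).
#' @param met_noise_sd Replicate noise SD for metabolite log areas (default 0.2).
#' @param lib_size_mean Mean RNA library size (default 2e6).
#' @param lib_size_cv Coefficient of variation of library sizes (default 0.1).
#' @param baseline_log2_cpm_range Range from which per-gene baseline log2-CPM
#'   is drawn uniformly (default `c(-4, 9)`; the low end deliberately falls
#'   below a 0.1-CPM expression filter).
#' @param met_baseline_range Range above the detection floor from which
#'   metabolite baseline log areas are drawn (default `c(10.5, 14)`).
#' @param aggregation How module gene effects map to the metabolite effect:
#'   `"mean"` (default), `"sum"`, or `"max"` (absolute-largest, signed).
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000, n_metabolites = 200, genes_per_module = 5,
                       n_pops_rna = 10, n_pops_met = 6, n_anc = 5, n_rep = 3,
                       shared_effect_sd = 1.0, specific_effect_sd = 0.5,
                       redundancy_fraction = 0.5, nb_dispersion = 0.05,
                       met_noise_sd = 0.2, lib_size_mean = 2e6, lib_size_cv = 0.1,
                       baseline_log2_cpm_range = c(-4, 9),
                       met_baseline_range = c(10.5, 14),
                       aggregation = c("mean", "sum", "max"), seed = 1L) {
  aggregation <- match.arg(aggregation)
  p <- list(n_genes = as.integer(n_genes), n_metabolites = as.integer(n_metabolites),
            genes_per_module = as.integer(genes_per_module),
            n_pops_rna = as.integer(n_pops_rna), n_pops_met = as.integer(n_pops_met),
            n_anc = as.integer(n_anc), n_rep = as.integer(n_rep),
            shared_effect_sd = shared_effect_sd, specific_effect_sd = specific_effect_sd,
            redundancy_fraction = redundancy_fraction, nb_dispersion = nb_dispersion,
            met_noise_sd = met_noise_sd, lib_size_mean = lib_size_mean,
            lib_size_cv = lib_size_cv,
            baseline_log2_cpm_range = baseline_log2_cpm_range,
            met_baseline_range = met_baseline_range,
            aggregation = aggregation, seed = as.integer(seed))
  if (p$genes_per_module < 1L) stop("parameter error: genes_per_module must be >= 1")
  if (p$n_metabolites * p$genes_per_module > p$n_genes) {
    stop("parameter error: n_metabolites * genes_per_module must not exceed n_genes")
  }
  if (p$nb_dispersion <= 0) stop("parameter error: nb_dispersion must be > 0")
  if (p$shared_effect_sd < 0 || p$specific_effect_sd < 0 || p$met_noise_sd < 0) {
    stop("parameter error: standard deviations must be >= 0")
  }
  if (p$redundancy_fraction < 0 || p$redundancy_fraction > 1) {
    stop("parameter error: redundancy_fraction must be in [0, 1]")
  }
  if (p$n_pops_met > p$n_pops_rna) stop("parameter error: n_pops_met > n_pops_rna")
  structure(p, class = "sim_params")
}

#' Draw true per-population effects under the hierarchical redundancy model
#'
#' Each metabolite owns a disjoint module of `genes_per_module` genes. Per
#' population, each module gene is active with probability
#' `redundancy_fraction`; an active gene's log2 effect is
#' `s_m + u_gp`, where `s_m ~ N(0, shared_effect_sd^2)` is drawn once per
#' module (shared across populations) and `u_gp ~ N(0, specific_effect_sd^2)`
#' per gene and population. Inactive genes (and genes outside every module)
#' have effect 0. The metabolite effect per population aggregates its module
#' genes' effects (mean by default).
#'
#' @param params A [sim_params()] list.
#' @return A `sim_truth` list: `gene_effects` (genes x populations),
#'   `met_effects` (metabolites x populations), `modules` (named list,
#'   metabolite id -> gene ids), `params`.
#' @export
simulate_effects <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  gene_ids <- sprintf("g%04d", seq_len(p$n_genes))
  met_ids <- sprintf("m%03d", seq_len(p$n_metabolites))
  pops <- sprintf("pop%d", seq_len(p$n_pops_rna))
  with_seed(derive_seed(p$seed, "effects"), {
    modules <- split(gene_ids[seq_len(p$n_metabolites * p$genes_per_module)],
                     rep(seq_len(p$n_metabolites), each = p$genes_per_module))
    names(modules) <- met_ids
    s_m <- stats::rnorm(p$n_metabolites, 0, p$shared_effect_sd)
    gene_eff <- matrix(0, p$n_genes, p$n_pops_rna, dimnames = list(gene_ids, pops))
    for (m in seq_len(p$n_metabolites)) {
      idx <- match(modules[[m]], gene_ids)
      active <- matrix(stats::runif(length(idx) * p$n_pops_rna) < p$redundancy_fraction,
                       length(idx), p$n_pops_rna)
      u <- matrix(stats::rnorm(length(idx) * p$n_pops_rna, 0, p$specific_effect_sd),
                  length(idx), p$n_pops_rna)
      gene_eff[idx, ] <- active * (s_m[m] + u)
    }
    agg <- switch(p$aggregation,
                  mean = function(v) mean(v),
                  sum = function(v) sum(v),
                  max = function(v) v[which.max(abs(v))])
    met_eff <- matrix(0, p$n_metabolites, p$n_pops_rna, dimnames = list(met_ids, pops))
    for (m in seq_len(p$n_metabolites)) {
      idx <- match(modules[[m]], gene_ids)
      met_eff[m, ] <- apply(gene_eff[idx, , drop = FALSE], 2, agg)
    }
    structure(list(gene_effects = gene_eff, met_effects = met_eff,
                   modules = modules, params = p),
              class = "sim_truth")
  })
}

#' @keywords internal
sim_meta <- function(pops, n_anc, n_rep, prefix) {
  data.frame(
    sample_id = c(sprintf("anc_%s%d", prefix, seq_len(n_anc)),
                  unlist(lapply(pops, function(pp) sprintf("%s_%s%d", pp, prefix, seq_len(n_rep))))),
    population = c(rep("anc", n_anc), rep(pops, each = n_rep)),
    role = c(rep("ancestral", n_anc), rep("evolved", length(pops) * n_rep)),
    replicate = c(seq_len(n_anc), rep(seq_len(n_rep), length(pops))),
    stringsAsFactors = FALSE)
}

#' Simulate an RNA-seq count matrix from true effects
#'
#' Per-gene baseline log2-CPM is drawn uniformly over
#' `baseline_log2_cpm_range`; library sizes are log-normal around
#' `lib_size_mean`; an evolved sample's expected CPM is the baseline shifted
#' by the population's true log2 effect; counts are negative binomial with
#' dispersion `nb_dispersion` (variance `mu + phi mu^2`).
#'
#' @param truth A [simulate_effects()] result.
#' @param params A [sim_params()] list (defaults to `truth$params`).
#' @return An [omics_matrix()] with `value_kind = "counts"`.
#' @export
simulate_counts <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- params
  pops <- colnames(truth$gene_effects)
  meta <- sim_meta(pops, p$n_anc, p$n_rep, "r")
  n <- nrow(meta)
  G <- p$n_genes
  with_seed(derive_seed(p$seed, "counts"), {
    base_cpm <- 2^stats::runif(G, p$baseline_log2_cpm_range[1], p$baseline_log2_cpm_range[2])
    sdlog <- sqrt(log1p(p$lib_size_cv^2))
    lib <- stats::rlnorm(n, log(p$lib_size_mean) - sdlog^2 / 2, sdlog)
    log2fc_mat <- cbind(matrix(0, G, p$n_anc),
                        truth$gene_effects[, meta$population[meta$role == "evolved"]])
    mu <- (base_cpm * 2^log2fc_mat) * rep(lib / 1e6, each = G)
    counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / p$nb_dispersion), G, n)
    dimnames(counts) <- list(rownames(truth$gene_effects), meta$sample_id)
    omics_matrix(counts, meta, "counts")
  })
}

#' Simulate a metabolite log-abundance matrix from true effects
#'
#' Per-metabolite baseline log area is drawn uniformly over
#' `met_baseline_range` (above the detection floor); a sample's value is the
#' baseline, plus the population effect for evolved samples, plus
#' `N(0, met_noise_sd^2)` replicate noise. Only the first `n_pops_met`
#' populations are profiled, mirroring a design where the metabolome is
#' assayed in a subset of the evolved populations.
#'
#' @inheritParams simulate_counts
#' @return An [omics_matrix()] with `value_kind = "log_area"`.
#' @export
simulate_metabolites <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- params
  pops <- colnames(truth$met_effects)[seq_len(p$n_pops_met)]
  meta <- sim_meta(pops, p$n_anc, p$n_rep, "m")
  n <- nrow(meta)
  M <- p$n_metabolites
  with_seed(derive_seed(p$seed, "metabolites"), {
    base <- stats::runif(M, p$met_baseline_range[1], p$met_baseline_range[2])
    eff <- cbind(matrix(0, M, p$n_anc),
                 truth$met_effects[, meta$population[meta$role == "evolved"]])
    vals <- base + eff + matrix(stats::rnorm(M * n, 0, p$met_noise_sd), M, n)
    dimnames(vals) <- list(rownames(truth$met_effects), meta$sample_id)
    omics_matrix(vals, meta, "log_area")
  })
}

#' Write ground-truth tables and paired GMT pathway files
#'
#' Each module becomes one pathway in both GMT files: the gene file lists the
#' module's genes, the metabolite file the module's single metabolite.
#'
#' @param truth A [simulate_effects()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_truth_and_gmt <- function(truth, outdir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(truth_genes = file.path(outdir, "truth_genes.tsv"),
             truth_mets = file.path(outdir, "truth_mets.tsv"),
             gmt_genes = file.path(outdir, "pathways_genes.gmt"),
             gmt_mets = file.path(outdir, "pathways_mets.gmt"))
  write_effect_table <- function(eff, path) {
    df <- data.frame(feature_id = rownames(eff), eff, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_effect_table(truth$gene_effects, paths["truth_genes"])
  write_effect_table(truth$met_effects, paths["truth_mets"])
  path_ids <- sprintf("PW%03d", seq_along(truth$modules))
  gene_sets <- stats::setNames(truth$modules, path_ids)
  met_sets <- stats::setNames(as.list(names(truth$modules)), path_ids)
  desc <- stats::setNames(sprintf("module_%s", names(truth$modules)), path_ids)
  write_gmt(gene_sets, paths["gmt_genes"], descriptions = desc)
  write_gmt(met_sets, paths["gmt_mets"], descriptions = desc)
  invisible(paths)
}

#' Simulate a full two-level experiment and write it to disk
#'
#' Convenience wrapper: draws effects, count and metabolite matrices, and
#' writes `counts.tsv`, `metabolites.tsv`, `meta_rna.tsv`, `meta_met.tsv`,
#' truth tables and paired GMT files into `outdir`.
#'
#' @param params A [sim_params()] list.
#' @param outdir Output directory.
#' @return Invisibly, a list with `truth`, `counts`, `metabolites`, and the
#'   written `paths`.
#' @export
simulate_experiment <- function(params, outdir) {
  truth <- simulate_effects(params)
  counts <- simulate_counts(truth, params)
  mets <- simulate_metabolites(truth, params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             meta_rna = file.path(outdir, "meta_rna.tsv"),
             metabolites = file.path(outdir, "metabolites.tsv"),
             meta_met = file.path(outdir, "meta_met.tsv"))
  write_omics_matrix(counts, paths["counts"], paths["meta_rna"])
  write_omics_matrix(mets, paths["metabolites"], paths["meta_met"])
  paths <- c(paths, write_truth_and_gmt(truth, outdir))
  invisible(list(truth = truth, counts = counts, metabolites = mets, paths = paths))
}
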