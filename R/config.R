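#' Run configuration
#'
#' All tunable thresholds and permutation counts of the pipeline in one
#' validated list. Defaults follow the analysis conventions of the study
#' design: adjusted p < 0.05 significance, 0.1-CPM expression filter,
#' detection floor 10 on the log area scale, 100 permutations for the
#' heterogeneity null and 100 downsampling repetitions, exhaustive
#' enumeration for the metabolite test.
#'
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param n_permutations_null Permutations for the heterogeneity null
#'   (default 100).
#' @param n_permutations_met_test `"exhaustive"` (default) or an integer of
#'   random reassignments for the metabolite permutation test.
#' @param n_downsample_reps Downsampling repetitions for the cross-level
#'   comparison (default 100).
#' @param n_permutations_pathway Permutations per pathway global test
#'   (default 1000).
#' @param cpm_filter Expression filter threshold in CPM (default 0.1).
#' @param filter_mode `"mean"` (default) or `"min"` CPM filter reading.
#' @param met_detection_floor Metabolite detection floor on the log scale
#'   (default 10).
#' @param met_log_base Log base for metabolite areas (default natural log).
#' @param pseudocount Pseudocount in CPM units for log2 fold changes
#'   (default 0.5).
#' @param min_pathway_members Minimum usable members for a pathway global
#'   test (default 2).
#' @param t_test_variant `"welch"` (default) or `"student"`.
#' @param null_statistics Heterogeneity statistics to run in the pipeline.
#' @param rng_seed Master seed; per-stage child seeds are derived with
#'   [derive_seed()].
#' @return A `run_config` list.
#' @export
run_config <- function(fdr_threshold = 0.05, n_permutations_null = 100L,
                       n_permutations_met_test = "exhaustive",
                       n_downsample_reps = 100L, n_permutations_pathway = 1000L,
                       cpm_filter = 0.1, filter_mode = c("mean", "min"),
                       met_detection_floor = 10, met_log_base = exp(1),
                       pseudocount = 0.5, min_pathway_members = 2L,
                       t_test_variant = c("welch", "student"),
                       null_statistics = c("mean_pearson", "mean_jaccard"),
                       rng_seed = 1L) {
  filter_mode <- match.arg(filter_mode)
  t_test_variant <- match.arg(t_test_variant)
  cfg <- list(fdr_threshold = fdr_threshold,
              n_permutations_null = as.integer(n_permutations_null),
              n_permutations_met_test = n_permutations_met_test,
              n_downsample_reps = as.integer(n_downsample_reps),
              n_permutations_pathway = as.integer(n_permutations_pathway),
              cpm_filter = cpm_filter, filter_mode = filter_mode,
              met_detection_floor = met_detection_floor,
              met_log_base = met_log_base, pseudocount = pseudocount,
              min_pathway_members = as.integer(min_pathway_members),
              t_test_variant = t_test_variant,
              null_statistics = match.arg(null_statistics,
                                          c("mean_pearson", "mean_jaccard"),
                                          several.ok = TRUE),
              rng_seed = as.integer(rng_seed))
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1) {
    stop("validation error: fdr_threshold must be in (0, 1)")
  }
  if (cfg$cpm_filter < 0 || cfg$met_detection_floor < 0 || cfg$pseudocount < 0) {
    stop("validation error: thresholds must be non-negative")
  }
  if (!identical(cfg$n_permutations_met_test, "exhaustive")) {
    cfg$n_permutations_met_test <- as.integer(cfg$n_permutations_met_test)
    if (cfg$n_permutations_met_test < 1L) {
      stop("validation error: n_permutations_met_test must be >= 1 or 'exhaustive'")
    }
  }
  if (cfg$n_permutations_null < 1L || cfg$n_downsample_reps < 1L ||
      cfg$n_permutations_pathway < 1L) {
    stop("validation error: permutation/repetition counts must be >= 1")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  keep <- intersect(names(raw), names(formals(run_config)))
  do.call(run_config, raw[keep])
}
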