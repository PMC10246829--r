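#' Downsampled pairwise log2FC correlations
#'
#' Equalizes feature counts between molecular levels: per repetition, draws
#' `n_target` features without replacement from the log2FC table, computes all
#' pairwise Pearson correlations between populations, and averages each pair
#' over repetitions.
#'
#' @param lfc Numeric matrix of log2 fold changes, features x populations.
#' @param n_target Number of features to draw per repetition.
#' @param reps Number of repetitions (default 100).
#' @param seed Optional integer seed.
#' @return Data frame `popA`, `popB`, `mean_r` (one row per pair).
#' @export
downsample_pearson <- function(lfc, n_target, reps = 100L, seed = NULL) {
  stopifnot(is.matrix(lfc), ncol(lfc) >= 2L)
  if (n_target > nrow(lfc)) {
    stop("validation error: n_target (", n_target, ") exceeds number of features (",
         nrow(lfc), ")")
  }
  run <- function() {
    acc <- NULL
    for (r in seq_len(reps)) {
      sub <- lfc[sample(nrow(lfc), n_target), , drop = FALSE]
      cm <- stats::cor(sub, use = "pairwise.complete.obs")
      acc <- if (is.null(acc)) cm else acc + cm
    }
    acc / reps
  }
  cm <- if (is.null(seed)) run() else with_seed(seed, run())
  pairs <- population_pairs(colnames(lfc))
  pairs$mean_r <- cm[cbind(match(pairs$popA, colnames(lfc)),
                           match(pairs$popB, colnames(lfc)))]
  pairs
}

#' Downsampled pairwise Jaccard indices
#'
#' Per repetition, each population's significant-feature set is subsampled
#' without replacement to its target size; pairwise Jaccard indices are
#' computed on the subsampled sets and averaged over repetitions.
#'
#' @param sig_sets Named list (population -> character vector of significant
#'   features).
#' @param targets Named integer vector of target sizes per population.
#' @param reps Number of repetitions (default 100).
#' @param seed Optional integer seed.
#' @return Data frame `popA`, `popB`, `mean_jaccard`.
#' @export
downsample_jaccard <- function(sig_sets, targets, reps = 100L, seed = NULL) {
  pops <- names(sig_sets)
  stopifnot(length(pops) >= 2L, all(pops %in% names(targets)))
  bad <- pops[targets[pops] > lengths(sig_sets)]
  if (length(bad)) {
    stop("validation error: downsampling target exceeds DE set size for population(s): ",
         paste(bad, collapse = ", "))
  }
  pairs <- population_pairs(pops)
  run <- function() {
    acc <- numeric(nrow(pairs))
    for (r in seq_len(reps)) {
      subs <- lapply(pops, function(pp) sample(sig_sets[[pp]], targets[[pp]]))
      names(subs) <- pops
      acc <- acc + mapply(function(a, b) jaccard(subs[[a]], subs[[b]]),
                          pairs$popA, pairs$popB)
    }
    acc / reps
  }
  pairs$mean_jaccard <- if (is.null(seed)) run() else with_seed(seed, run())
  pairs
}

#' Exact expected Jaccard index of independently subsampled sets
#'
#' Closed-form expectation (by hypergeometric sums over intersection overlap)
#' of the Jaccard index when a `t_A`-subset of `A` and a `t_B`-subset of `B`
#' are drawn independently and uniformly. Serves as the analytic counterpart
#' of [downsample_jaccard()] for validation at small sizes.
#'
#' @param n_A,n_B Set sizes.
#' @param n_common Size of the intersection of `A` and `B`.
#' @param t_A,t_B Subsample sizes.
#' @return Expected Jaccard index.
#' @export
expected_downsample_jaccard <- function(n_A, n_B, n_common, t_A, t_B) {
  stopifnot(n_common <= min(n_A, n_B), t_A <= n_A, t_B <= n_B)
  e <- 0
  for (i in 0:min(t_A, n_common)) {        # |S_A| falling in the intersection
    pi <- stats::dhyper(i, n_common, n_A - n_common, t_A)
    if (pi == 0) next
    for (j in 0:min(t_B, n_common)) {      # |S_B| falling in the intersection
      pj <- stats::dhyper(j, n_common, n_B - n_common, t_B)
      if (pj == 0) next
      for (w in max(0, i + j - n_common):min(i, j)) {  # |S_A ∩ S_B|
        pw <- stats::dhyper(w, i, n_common - i, j)
        if (pw == 0) next
        u <- t_A + t_B - w
        e <- e + pi * pj * pw * (if (u == 0) 0 else w / u)
      }
    }
  }
  e
}

#' Compare parallelism distributions between molecular levels
#'
#' Two-sample t-test of the per-pair parallelism values of the two levels
#' (Welch's unequal-variance test by default; Student's pooled test as
#' option). The reported direction is metabolite minus gene.
#'
#' @param gene_values,metabolite_values Per-pair statistics (same pairs, same
#'   order).
#' @param statistic Label: `"pearson"` or `"jaccard"`.
#' @param variant `"welch"` (default) or `"student"`.
#' @return A `level_comparison` list: per-level values and means,
#'   `t_statistic`, `df`, `p_value`, `direction`.
#' @export
compare_levels <- function(gene_values, metabolite_values,
                           statistic = c("pearson", "jaccard"),
                           variant = c("welch", "student")) {
  statistic <- match.arg(statistic)
  variant <- match.arg(variant)
  if (length(gene_values) < 3L || length(metabolite_values) < 3L) {
    stop("validation error: need >= 3 population pairs per level for the t-test")
  }
  tt <- stats::t.test(metabolite_values, gene_values,
                      var.equal = (variant == "student"))
  structure(list(statistic = statistic, variant = variant,
                 gene_values = gene_values, metabolite_values = metabolite_values,
                 gene_mean = mean(gene_values), metabolite_mean = mean(metabolite_values),
                 t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 direction = mean(metabolite_values) - mean(gene_values)),
            class = "level_comparison")
}

#' @export
print.level_comparison <- function(x, ...) {
  cat(sprintf("level comparison [%s, %s t-test]\n", x$statistic, x$variant))
  cat(sprintf("  metabolome mean %.4f vs transcriptome mean %.4f (diff %+.4f)\n",
              x$metabolite_mean, x$gene_mean, x$direction))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g\n", x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Cross-level hierarchy comparison on matched populations
#'
#' Restricts both omics to the populations present in both, equalizes feature
#' counts by downsampling (expressed genes to the number of tested
#' metabolites for the Pearson comparison; each population's DE gene set to
#' its significant-metabolite count for the Jaccard comparison), and t-tests
#' the per-pair distributions.
#'
#' @param de_rna [de_call()] output.
#' @param de_met [met_de_call()] output.
#' @param config A [run_config()] list.
#' @return List with `pearson` and `jaccard` [compare_levels()] results plus
#'   the per-pair tables.
#' @export
hierarchy_compare <- function(de_rna, de_met, config = run_config()) {
  pops <- intersect(unique(de_rna$population), unique(de_met$population))
  if (length(pops) < 2L) stop("validation error: < 2 populations shared between levels")
  rna <- de_rna[de_rna$population %in% pops, ]
  met <- de_met[de_met$population %in% pops, ]

  genes <- unique(rna$gene)
  lfc_rna <- vapply(pops, function(pp)
    stats::setNames(rna$log2FC[rna$population == pp], rna$gene[rna$population == pp])[genes],
    numeric(length(genes)))
  rownames(lfc_rna) <- genes
  pw_met <- pairwise_parallelism(met, mode = "both", level = "metabolome")
  n_met <- length(unique(met$metabolite))

  ds_r <- downsample_pearson(lfc_rna, n_target = min(n_met, nrow(lfc_rna)),
                             reps = config$n_downsample_reps,
                             seed = derive_seed(config$rng_seed, "ds_pearson"))
  cmp_pearson <- compare_levels(ds_r$mean_r, pw_met$pearson_r, "pearson",
                                config$t_test_variant)

  sig_rna <- lapply(pops, function(pp)
    unique(rna$gene[rna$population == pp & rna$significant %in% TRUE]))
  names(sig_rna) <- pops
  targets <- vapply(pops, function(pp)
    length(unique(met$metabolite[met$population == pp & met$significant %in% TRUE])),
    integer(1))
  targets <- pmin(targets, lengths(sig_rna))  # target never exceeds the DE set
  cmp_jaccard <- NULL
  ds_j <- NULL
  if (all(targets > 0)) {
    ds_j <- downsample_jaccard(sig_rna, targets, reps = config$n_downsample_reps,
                               seed = derive_seed(config$rng_seed, "ds_jaccard"))
    cmp_jaccard <- compare_levels(ds_j$mean_jaccard, pw_met$jaccard, "jaccard",
                                  config$t_test_variant)
  } else {
    pv_log("hierarchy_compare: population(s) without significant features at one level; Jaccard comparison skipped")
  }
  list(populations = pops, pearson = cmp_pearson, jaccard = cmp_jaccard,
       pairs_gene_pearson = ds_r, pairs_met = pw_met, pairs_gene_jaccard = ds_j)
}
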