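#' Permute feature values across evolved samples
#'
#' For each feature independently, the values of the evolved samples are
#' reshuffled among the evolved sample slots; ancestral columns are left
#' untouched. This destroys population-specific structure while conserving
#' each feature's multiset of evolved values — the null of "no
#' population-specific effects". `mode = "columns"` instead shuffles whole
#' evolved columns' population assignments (a stricter null that preserves
#' within-sample correlation between features).
#'
#' For count matrices the permutation must not separate a count from its
#' library size, or unequal sequencing depths would masquerade as
#' heterogeneity: when `x` carries an `offsets` matrix (per-observation log
#' library sizes), it is permuted in lockstep with the values.
#'
#' @param x An [omics_matrix()].
#' @param mode `"per_feature"` (default) or `"columns"`.
#' @return An `omics_matrix` of the same shape.
#' @export
permute_evolved <- function(x, mode = c("per_feature", "columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "omics_matrix"))
  evo <- which(x$meta$role == "evolved")
  ne <- length(evo)
  if (ne < 2L) return(x)
  out <- x
  G <- nrow(x$values)
  if (mode == "per_feature") {
    # idx[g, j]: which evolved slot feeds slot j for feature g
    idx <- t(apply(matrix(stats::runif(G * ne), G, ne), 1, order))
    take <- cbind(rep(seq_len(G), ne), as.vector(idx))
    v <- x$values[, evo, drop = FALSE]
    out$values[, evo] <- matrix(v[take], G, ne)
    if (!is.null(x$offsets)) {
      o <- x$offsets[, evo, drop = FALSE]
      out$offsets[, evo] <- matrix(o[take], G, ne)
    }
  } else {
    perm <- evo[sample(ne)]
    out$values[, evo] <- x$values[, perm, drop = FALSE]
    if (!is.null(x$offsets)) out$offsets[, evo] <- x$offsets[, perm, drop = FALSE]
  }
  out
}

#' Permutation test for population-specific heterogeneity
#'
#' Tests whether the observed mean pairwise parallelism (mean Jaccard index
#' or mean Pearson correlation over all population pairs) is smaller than
#' expected under a null with no population-specific effects. Each of
#' `n_permutations` rounds permutes the evolved samples' values per feature
#' ([permute_evolved()]), re-runs the per-population analysis against the
#' fixed ancestral samples (full DE calling for the Jaccard statistic; log2
#' fold changes only for the Pearson statistic), and records the mean pairwise
#' statistic. The one-sided p-value is the proportion of permuted means
#' strictly smaller than the observed mean (`p_plain`); the add-one variant
#' `(k + 1)/(B + 1)` is reported alongside.
#'
#' @param x An [omics_matrix()] (`counts` for the transcriptome, areas/log
#'   areas for the metabolome).
#' @param config A [run_config()] list (`n_permutations_null`, seeds,
#'   thresholds).
#' @param statistic `"mean_pearson"` (default) or `"mean_jaccard"`.
#' @param level `"transcriptome"` or `"metabolome"`; inferred from
#'   `x$value_kind` when missing.
#' @param permute_mode Passed to [permute_evolved()].
#' @return A `null_distribution` list: `statistic`, `level`,
#'   `observed_mean`, `permuted_means`, `p_plain`, `p_add_one`,
#'   `n_permutations`.
#' @export
heterogeneity_test <- function(x, config = run_config(),
                               statistic = c("mean_pearson", "mean_jaccard"),
                               level = NULL,
                               permute_mode = c("per_feature", "columns")) {
  statistic <- match.arg(statistic)
  permute_mode <- match.arg(permute_mode)
  B <- config$n_permutations_null
  if (B < 1L) stop("validation error: n_permutations_null must be >= 1")
  level <- level %||% if (x$value_kind == "counts") "transcriptome" else "metabolome"
  is_rna <- level == "transcriptome"

  anc <- samples_of(x, role = "ancestral")
  pops <- evolved_populations(x)

  if (is_rna) {
    # filter once on the observed data; the kept-gene universe is fixed
    # across permutations
    cpm_f <- filter_expressed(cpm_normalize(x), config$cpm_filter, config$filter_mode)
    kept <- attr(cpm_f, "kept_features")
    if (statistic == "mean_pearson") {
      # the permuted quantity is the normalized expression value, so the
      # permutation cannot mistake library-size differences for heterogeneity
      work <- cpm_f
    } else {
      work <- x
      work$values <- x$values[kept, , drop = FALSE]
      # per-observation offsets travel with the counts under permutation
      work$offsets <- matrix(log(colSums(x$values)), length(kept), ncol(x$values),
                             byrow = TRUE,
                             dimnames = list(kept, colnames(x$values)))
      # common dispersions estimated once on the observed contrasts and
      # reused across permutations (per-feature permutation conserves each
      # gene's value multiset, leaving the profile-likelihood estimate
      # essentially unchanged)
      dispersions <- vapply(pops, function(pp)
        fit_nb_lrt(work, pp)$dispersion[1], numeric(1))
    }
  } else {
    work <- log_transform_filter(x, config$met_detection_floor, config$met_log_base)
  }

  rna_sig_sets <- function(mat) {
    lapply(pops, function(pp) {
      fit <- fit_nb_lrt(mat, pp, dispersion = dispersions[[pp]])
      padj <- bh_adjust(fit$p)
      fit$gene[!is.na(padj) & padj < config$fdr_threshold]
    })
  }

  stat_of <- function(mat) {
    if (statistic == "mean_pearson") {
      lf <- if (is_rna) {
        vapply(pops, function(pp)
          log2fc(mat, samples_of(mat, population = pp, role = "evolved"), anc,
                 config$pseudocount), numeric(nrow(mat$values)))
      } else {
        vapply(pops, function(pp)
          log2fc_from_log(mat, samples_of(mat, population = pp, role = "evolved"),
                          anc, config$met_log_base), numeric(nrow(mat$values)))
      }
      cm <- stats::cor(lf)
      mean(cm[upper.tri(cm)])
    } else if (is_rna) {
      sets <- rna_sig_sets(mat)
      pairs <- utils::combn(length(sets), 2L)
      mean(vapply(seq_len(ncol(pairs)), function(i) {
        A <- sets[[pairs[1L, i]]]; B <- sets[[pairs[2L, i]]]
        u <- length(union(A, B))
        if (u == 0L) 0 else length(intersect(A, B)) / u
      }, numeric(1)))
    } else {
      de <- met_de_call(mat, config)
      pw <- pairwise_parallelism(de, mode = "jaccard", level = level)
      mean(pw$jaccard)
    }
  }

  obs_mat <- work
  observed <- stat_of(obs_mat)
  permuted <- with_seed(derive_seed(config$rng_seed, paste0("null_", level, "_", statistic)), {
    vapply(seq_len(B), function(b) stat_of(permute_evolved(obs_mat, permute_mode)),
           numeric(1))
  })
  k <- sum(permuted < observed)
  structure(list(statistic = statistic, level = level,
                 observed_mean = observed, permuted_means = permuted,
                 p_plain = k / B, p_add_one = (k + 1) / (B + 1),
                 n_permutations = B),
            class = "null_distribution")
}

#' @keywords internal
# log2FC for matrices already on a log scale: difference of group means,
# converted to log2 units
log2fc_from_log <- function(x, evolved, ancestral, log_base = exp(1)) {
  d <- rowMeans(x$values[, evolved, drop = FALSE]) -
    rowMeans(x$values[, ancestral, drop = FALSE])
  d / log(2, base = log_base)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("heterogeneity null [%s, %s]: observed mean %.4f, %d permutations\n",
              x$level, x$statistic, x$observed_mean, x$n_permutations))
  cat(sprintf("  p (plain) = %.4g, p (add-one) = %.4g\n", x$p_plain, x$p_add_one))
  invisible(x)
}
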