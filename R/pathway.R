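#' Global test of a feature set's association with the evolution contrast
#'
#' The quadratic score statistic
#' `Q = y_c' X X' y_c / (m * y_c' y_c)`,
#' where `y_c` is the centered group indicator over the contrast samples
#' (ancestral vs one evolved population), `X` the samples x m matrix of the
#' pathway's member features with each column standardized (mean 0,
#' variance 1), and `m` the member count. Large `Q` means the members jointly
#' separate the groups. The p-value is a permutation p over random
#' relabelings of the group indicator: strict exceedance with the add-one
#' convention, `p = (1 + #\{Q* > Q\}) / (n_perm + 1)`.
#'
#' @param x An [omics_matrix()] (any value kind; member rows are used as-is,
#'   so counts should normally arrive CPM-normalized or logged).
#' @param members Character vector of member feature ids.
#' @param population Evolved population for the contrast.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param min_members Minimum member features that must be present and
#'   non-constant (default 2); below it the test is skipped (`NA` returned).
#' @return List: `Q`, `p`, `m` (members used). `Q`/`p` are `NA` when skipped.
#' @export
global_test <- function(x, members, population, n_perm = 1000L, seed = NULL,
                        min_members = 2L) {
  stopifnot(inherits(x, "omics_matrix"))
  anc <- samples_of(x, role = "ancestral")
  evo <- samples_of(x, population = population, role = "evolved")
  sel <- c(anc, evo)
  present <- intersect(members, rownames(x$values))
  X <- t(x$values[present, sel, drop = FALSE])  # samples x m
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (sum(keep) < length(present)) {
    pv_log("global_test: dropped %d constant member column(s)", sum(!keep))
  }
  X <- X[, keep, drop = FALSE]
  m <- ncol(X)
  if (m < min_members) {
    pv_log("global_test[%s]: only %d usable member(s) (< %d), skipped",
           population, m, min_members)
    return(list(Q = NA_real_, p = NA_real_, m = m))
  }
  X <- scale(X)
  yy <- c(rep(0, length(anc)), rep(1, length(evo)))
  q_stat <- function(yb) {
    yc <- yb - mean(yb)
    s <- crossprod(X, yc)           # m x 1
    sum(s^2) / (m * sum(yc^2))
  }
  Q <- q_stat(yy)
  run <- function() vapply(seq_len(n_perm), function(b) q_stat(sample(yy)), numeric(1))
  nulls <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- (1 + sum(nulls > Q)) / (n_perm + 1)
  list(Q = Q, p = p, m = m)
}

#' Combine per-omic p-values with Fisher's method
#'
#' `S = -2 * sum(log(p_i))`, referred to a chi-square with `2k` degrees of
#' freedom (`k` = number of p-values). With `k = 1` the combined p equals the
#' input. Zero p-values are floored (to `floor`) before combining so the log
#' is finite.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]` (NAs dropped).
#' @param floor Floor applied to zero p-values (default `1e-12`).
#' @return List: `S`, `p`, `k`.
#' @export
fisher_combine <- function(p_values, floor = 1e-12) {
  p_values <- p_values[!is.na(p_values)]
  k <- length(p_values)
  if (k == 0L) return(list(S = NA_real_, p = NA_real_, k = 0L))
  if (any(p_values < 0 | p_values > 1)) stop("validation error: p-values must be in [0, 1]")
  if (any(p_values == 0)) {
    pv_log("fisher_combine: %d zero p-value(s) floored to %g", sum(p_values == 0), floor)
    p_values <- pmax(p_values, floor)
  }
  S <- -2 * sum(log(p_values))
  list(S = S, p = stats::pchisq(S, df = 2 * k, lower.tail = FALSE), k = k)
}

#' Joint pathway analysis across transcriptome and metabolome
#'
#' Per evolved population shared by both omics and per pathway: a global test
#' of the pathway's gene members on the (CPM-normalized, log2-transformed)
#' expression matrix and of its metabolite members on the log-area matrix;
#' Fisher combination of the two raw p-values (a pathway annotated, or
#' testable, in only one omic contributes a k = 1 combination, flagged);
#' BH adjustment across pathways within each population. Also reports the
#' pathways significant in every population, with their mean adjusted p.
#'
#' @param rna A counts [omics_matrix()].
#' @param met An areas/log-areas [omics_matrix()].
#' @param gene_sets A `pathway_annotation` (pathway -> gene members).
#' @param met_sets A `pathway_annotation` (pathway -> metabolite members).
#' @param config A [run_config()] list (`n_permutations_pathway`,
#'   `fdr_threshold`, seed).
#' @return List: `table` (population, pathway, p_gene, p_met, S, p_combined,
#'   padj, n_omics, significant) and `shared` (pathways significant in all
#'   populations with mean padj).
#' @export
joint_pathway_analysis <- function(rna, met, gene_sets, met_sets,
                                   config = run_config()) {
  pops <- intersect(evolved_populations(rna), evolved_populations(met))
  if (length(pops) < 1L) stop("validation error: no populations shared between omics")
  pathways <- union(names(gene_sets), names(met_sets))
  if (length(pathways) < 1L) stop("validation error: empty pathway annotation")

  cpm <- cpm_normalize(rna)
  cpm_f <- filter_expressed(cpm, config$cpm_filter, config$filter_mode)
  expr <- cpm_f
  expr$values <- log2(cpm_f$values + config$pseudocount)
  met_f <- log_transform_filter(met, config$met_detection_floor, config$met_log_base)

  n_perm <- config$n_permutations_pathway
  rows <- list()
  for (pp in pops) {
    for (pw in pathways) {
      pg <- pm <- NA_real_
      if (pw %in% names(gene_sets)) {
        g <- global_test(expr, gene_sets[[pw]], pp, n_perm = n_perm,
                         seed = derive_seed(config$rng_seed, paste0("gt_g_", pp, "_", pw)),
                         min_members = config$min_pathway_members)
        pg <- g$p
      }
      if (pw %in% names(met_sets)) {
        g <- global_test(met_f, met_sets[[pw]], pp, n_perm = n_perm,
                         seed = derive_seed(config$rng_seed, paste0("gt_m_", pp, "_", pw)),
                         min_members = config$min_pathway_members)
        pm <- g$p
      }
      fc <- fisher_combine(c(pg, pm))
      if (fc$k == 0L) next  # pathway testable in neither omic
      rows[[length(rows) + 1L]] <-
        data.frame(population = pp, pathway = pw, p_gene = pg, p_met = pm,
                   S = fc$S, p_combined = fc$p, n_omics = fc$k,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(tab, tab$population), function(d) {
    d$padj <- bh_adjust(d$p_combined)
    d$significant <- d$padj < config$fdr_threshold
    d
  }))
  rownames(tab) <- NULL
  sig_by_pop <- lapply(split(tab, tab$population), function(d) d$pathway[d$significant])
  shared_ids <- Reduce(intersect, sig_by_pop)
  shared <- data.frame(pathway = shared_ids,
                       mean_padj = vapply(shared_ids, function(pw)
                         mean(tab$padj[tab$pathway == pw]), numeric(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, shared = shared,
       n_significant = vapply(sig_by_pop, length, integer(1)))
}
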