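#' Log transform and detection filter for metabolite areas
#'
#' Raw normalized peak areas (`value_kind = "area"`) are log-transformed
#' (natural log by default; only the ordering of values matters for the
#' permutation test, so the base is configurable). Matrices already on the
#' log scale (`value_kind = "log_area"`) are filtered only. A metabolite is
#' considered detected when its log value strictly exceeds `floor` in every
#' sample. Non-positive raw areas cannot be log-transformed; the metabolite
#' is dropped with a logged count.
#'
#' @param areas An [omics_matrix()] with `value_kind` `"area"` or `"log_area"`.
#' @param floor Detection floor on the log scale (default 10).
#' @param log_base Base for the transform of raw areas (default `exp(1)`).
#' @return A filtered [omics_matrix()] with `value_kind = "log_area"`; kept
#'   ids in `attr(, "kept_features")`.
#' @export
log_transform_filter <- function(areas, floor = 10, log_base = exp(1)) {
  stopifnot(inherits(areas, "omics_matrix"), floor >= 0)
  v <- areas$values
  if (areas$value_kind == "area") {
    pos <- apply(v > 0, 1, all)
    if (!all(pos)) {
      pv_log("log_transform_filter: dropped %d metabolite(s) with non-positive areas", sum(!pos))
    }
    v <- log(v[pos, , drop = FALSE], base = log_base)
  } else if (areas$value_kind != "log_area") {
    stop("log_transform_filter expects value_kind 'area' or 'log_area'")
  }
  keep <- apply(v > floor, 1, all)
  out <- areas
  out$values <- v[keep, , drop = FALSE]
  out$value_kind <- "log_area"
  attr(out, "kept_features") <- rownames(v)[keep]
  out
}

#' @keywords internal
# all C(n, k) 0/1 assignment columns for choosing k "evolved" of n slots
evolved_assignments <- function(n, k) {
  idx <- utils::combn(n, k)
  apply(idx, 2, function(j) { v <- numeric(n); v[j] <- 1; v })
}

#' Two-group permutation test for one metabolite
#'
#' The observed statistic is `mean(evolved) - mean(ancestral)` of the
#' log-transformed values. The null reassigns the pooled observations into
#' groups of the same sizes; the p-value is the proportion of reassignments
#' whose absolute mean difference strictly exceeds the observed absolute
#' difference. `mode = "exhaustive"` (default) enumerates all distinct
#' assignments — `C(8,3) = 56` for the 5-vs-3 design — giving an exact test;
#' `mode = "random"` samples `n_perm` reassignments with replacement. So that
#' downstream FDR adjustment never receives 0, an exceedance count of zero is
#' reported as `1/(n_assignments + 1)` (exhaustive) or `1/(n_perm + 1)`
#' (random).
#'
#' @param values Numeric vector: ancestral then evolved observations.
#' @param n_evolved Number of evolved observations (default 3; they are the
#'   last `n_evolved` entries of `values`).
#' @param mode `"exhaustive"` or `"random"`.
#' @param n_perm Number of random reassignments (random mode).
#' @param seed Optional seed (random mode).
#' @return A list: `observed` (mean difference), `p` (floored, as reported),
#'   `exceedance` (raw count of null assignments beating the observed),
#'   `n_null`.
#' @export
perm_test_metabolite <- function(values, n_evolved = 3L,
                                 mode = c("exhaustive", "random"),
                                 n_perm = 100L, seed = NULL) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < n_evolved + 2L) stop("validation error: fewer observations than the contrast needs")
  obs_x <- c(rep(0, n - n_evolved), rep(1, n_evolved))
  mean_diff <- function(x) sum(values * x) / sum(x) - sum(values * (1 - x)) / sum(1 - x)
  observed <- mean_diff(obs_x)
  if (stats::sd(values) == 0) {
    return(list(observed = 0, p = 1, exceedance = NA_integer_, n_null = NA_integer_))
  }
  if (mode == "exhaustive") {
    A <- evolved_assignments(n, n_evolved)
    nulls <- apply(A, 2, mean_diff)
    B <- ncol(A)
  } else {
    draw <- function() mean_diff(sample(obs_x))
    nulls <- if (is.null(seed)) replicate(n_perm, draw()) else
      with_seed(seed, replicate(n_perm, draw()))
    B <- n_perm
  }
  k <- sum(abs(nulls) > abs(observed))
  p <- if (k == 0) 1 / (B + 1) else k / B
  list(observed = observed, p = p, exceedance = k, n_null = B)
}

#' @keywords internal
# vectorized exhaustive test across all metabolites of one contrast:
# rows of `v` are metabolites, columns ordered ancestral-first.
perm_test_exhaustive_matrix <- function(v, n_evolved) {
  n <- ncol(v)
  A <- evolved_assignments(n, n_evolved)           # n x 56
  w <- A / n_evolved - (1 - A) / (n - n_evolved)   # contrast weights per assignment
  nulls <- v %*% w                                 # M x 56 mean differences
  obs <- nulls[, ncol(nulls)]                      # last combn column = observed labels
  k <- rowSums(abs(nulls) > abs(obs))
  B <- ncol(A)
  p <- ifelse(k == 0, 1 / (B + 1), k / B)
  const <- apply(v, 1, function(r) stats::sd(r) == 0)
  p[const] <- 1
  obs[const] <- 0
  list(observed = obs, p = p, n_null = B)
}

#' Per-population differential-abundance calling for metabolites
#'
#' Detection filter, per-metabolite permutation test against the ancestral
#' samples, BH FDR within each population. The reported `log2FC` is the
#' difference of group means after conversion of the (natural-)log values to
#' the log2 scale, i.e. the log2 ratio of geometric means.
#'
#' @param areas An [omics_matrix()] (`"area"` or `"log_area"`).
#' @param config A [run_config()] list.
#' @return Data frame with one row per (population, metabolite):
#'   `population`, `metabolite`, `log2FC`, `mean_diff`, `p`, `padj`,
#'   `significant`; filtered universe in `attr(, "features")`.
#' @export
met_de_call <- function(areas, config = run_config()) {
  filt <- log_transform_filter(areas, config$met_detection_floor, config$met_log_base)
  pops <- evolved_populations(filt)
  if (length(pops) < 1L) stop("validation error: no evolved populations in metadata")
  anc <- samples_of(filt, role = "ancestral")
  mode <- config$n_permutations_met_test
  res <- lapply(pops, function(pp) {
    evo <- samples_of(filt, population = pp, role = "evolved")
    v <- filt$values[, c(anc, evo), drop = FALSE]
    if (identical(mode, "exhaustive")) {
      tt <- perm_test_exhaustive_matrix(v, length(evo))
    } else {
      sd0 <- derive_seed(config$rng_seed, paste0("met_test_", pp))
      tt <- with_seed(sd0, {
        obs <- numeric(nrow(v)); p <- numeric(nrow(v))
        for (i in seq_len(nrow(v))) {
          r <- perm_test_metabolite(v[i, ], length(evo), mode = "random",
                                    n_perm = as.integer(mode))
          obs[i] <- r$observed; p[i] <- r$p
        }
        list(observed = obs, p = p)
      })
    }
    padj <- bh_adjust(tt$p)
    data.frame(population = pp, metabolite = rownames(v),
               log2FC = tt$observed / log(2, base = config$met_log_base),
               mean_diff = tt$observed, p = tt$p, padj = padj,
               significant = padj < config$fdr_threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "features") <- rownames(filt$values)
  attr(out, "level") <- "metabolome"
  out
}
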