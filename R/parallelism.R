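#' Jaccard index of two feature sets
#'
#' `|A intersect B| / |A union B|`; by convention 0 (with a warning) when both
#' sets are empty.
#'
#' @param setA,setB Character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0L) {
    warning("jaccard of two empty sets; returning 0 by convention")
    return(0)
  }
  length(intersect(setA, setB)) / u
}

#' Log2 fold change of evolved versus ancestral group means
#'
#' `log2((mean_evo + c) / (mean_anc + c))` per feature, with pseudocount `c`;
#' `c = 0` is the plain log2 ratio of group mean abundances (CPM for
#' expression data). With `c = 0` and both means zero the value is undefined
#' and returned as `NA` (logged).
#'
#' @param x An [omics_matrix()] on the abundance scale (e.g. CPM).
#' @param evolved,ancestral Sample id vectors for the two groups.
#' @param pseudocount Pseudocount `c` (same units as the matrix; default 0.5).
#' @return Named numeric vector (one value per feature).
#' @export
log2fc <- function(x, evolved, ancestral, pseudocount = 0.5) {
  stopifnot(inherits(x, "omics_matrix"), length(evolved) > 0, length(ancestral) > 0)
  me <- rowMeans(x$values[, evolved, drop = FALSE]) + pseudocount
  ma <- rowMeans(x$values[, ancestral, drop = FALSE]) + pseudocount
  out <- ifelse(me == 0 & ma == 0, NA_real_, log2(me) - log2(ma))
  if (anyNA(out)) pv_log("log2fc: %d feature(s) with both means zero -> NA", sum(is.na(out)))
  names(out) <- rownames(x$values)
  out
}

#' @keywords internal
population_pairs <- function(pops) {
  stopifnot(length(pops) >= 2L)
  idx <- utils::combn(length(pops), 2L)
  data.frame(popA = pops[idx[1L, ]], popB = pops[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise parallelism statistics across evolved populations
#'
#' For every unordered pair of evolved populations (`C(P, 2)` pairs), the
#' Jaccard index of the two significant-feature sets and/or the Pearson
#' correlation of the two full log2 fold-change vectors (all tested features,
#' not only significant ones; missing values dropped pairwise).
#'
#' @param de Per-population DE table as returned by [de_call()] or
#'   [met_de_call()] (columns `population`, feature id, `log2FC`,
#'   `significant`).
#' @param mode `"both"` (default), `"jaccard"`, or `"pearson"`.
#' @param level Label stored in the output (`"transcriptome"` /
#'   `"metabolome"`); taken from `de`'s attribute when available.
#' @return Data frame: `level`, `popA`, `popB`, `jaccard`, `pearson_r`,
#'   `n_intersection`, `n_union`, `n_features`.
#' @export
pairwise_parallelism <- function(de, mode = c("both", "jaccard", "pearson"),
                                 level = NULL) {
  mode <- match.arg(mode)
  level <- level %||% attr(de, "level") %||% "unknown"
  id_col <- intersect(c("gene", "metabolite", "feature"), names(de))[1]
  if (is.na(id_col)) stop("DE table needs a feature id column (gene/metabolite/feature)")
  pops <- unique(de$population)
  pairs <- population_pairs(pops)
  sig_sets <- lapply(split(de[de$significant %in% TRUE, id_col],
                           factor(de$population[de$significant %in% TRUE], levels = pops)),
                     unique)
  lfc <- split(stats::setNames(de$log2FC, de[[id_col]]), factor(de$population, levels = pops))
  out <- pairs
  out$jaccard <- NA_real_; out$pearson_r <- NA_real_
  out$n_intersection <- NA_integer_; out$n_union <- NA_integer_
  out$n_features <- NA_integer_
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$popA[i]; b <- pairs$popB[i]
    if (mode %in% c("both", "jaccard")) {
      A <- sig_sets[[a]]; B <- sig_sets[[b]]
      out$n_intersection[i] <- length(intersect(A, B))
      out$n_union[i] <- length(union(A, B))
      out$jaccard[i] <- if (out$n_union[i] == 0L) 0 else
        out$n_intersection[i] / out$n_union[i]
    }
    if (mode %in% c("both", "pearson")) {
      va <- lfc[[a]]; vb <- lfc[[b]][names(lfc[[a]])]
      ok <- !is.na(va) & !is.na(vb)
      out$n_features[i] <- sum(ok)
      if (sum(ok) >= 3L && stats::sd(va[ok]) > 0 && stats::sd(vb[ok]) > 0) {
        out$pearson_r[i] <- stats::cor(va[ok], vb[ok])
      }
    }
  }
  cbind(level = level, out, stringsAsFactors = FALSE)
}
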