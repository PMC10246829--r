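#' Counts-per-million normalization
#'
#' `cpm[g, s] = count[g, s] * 1e6 / libsize[s]`, with the library size the
#' column total of the counts matrix.
#'
#' @param counts An [omics_matrix()] with `value_kind = "counts"`.
#' @return An [omics_matrix()] with `value_kind = "cpm"`.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$value_kind != "counts") stop("cpm_normalize expects a counts matrix")
  lib <- colSums(counts$values)
  if (any(lib <= 0)) stop("validation error: zero library size in sample(s) ",
                          paste(colnames(counts$values)[lib <= 0], collapse = ", "))
  cpm <- sweep(counts$values, 2, 1e6 / lib, `*`)
  out <- counts
  out$values <- cpm
  out$value_kind <- "cpm"
  out
}

#' Expression filter on CPM
#'
#' Keeps genes considered expressed. In `"mean"` mode (default) a gene is kept
#' when its mean CPM across all samples is at least `threshold`; in `"min"`
#' mode every sample must reach the threshold. The boundary is inclusive
#' ("at least").
#'
#' @param cpm A CPM [omics_matrix()].
#' @param threshold CPM threshold (default 0.1).
#' @param mode `"mean"` or `"min"`.
#' @return The filtered `omics_matrix`; kept ids in
#'   `attr(, "kept_features")`.
#' @export
filter_expressed <- function(cpm, threshold = 0.1, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cpm, "omics_matrix"), threshold >= 0)
  stat <- if (mode == "mean") rowMeans(cpm$values) else apply(cpm$values, 1, min)
  keep <- stat >= threshold
  out <- cpm
  out$values <- cpm$values[keep, , drop = FALSE]
  attr(out, "kept_features") <- rownames(cpm$values)[keep]
  out
}

# ---- vectorized negative-binomial GLM machinery -----------------------------
#
# All genes share the same design (intercept, or intercept + evolved
# indicator) so the IRLS normal equations reduce to closed-form 1x1 / 2x2
# solves that vectorize across genes. Log link with log-library-size offset.

#' @keywords internal
nb_loglik_rows <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  rowSums(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

#' @keywords internal
nb_fit_vec <- function(y, x, offset, phi, tol = 1e-8, maxit = 50L) {
  # y: G x n counts; x: length-n 0/1 indicator (or NULL for intercept-only);
  # offset: length-n vector, or G x n matrix (per-observation offsets, as
  # produced by per-feature permutation of evolved samples)
  # returns list(beta0, beta1, loglik, deviance, iter, converged)
  G <- nrow(y); n <- ncol(y)
  off <- if (is.matrix(offset)) offset else matrix(offset, G, n, byrow = TRUE)
  eo <- exp(off)
  has_x <- !is.null(x)
  if (has_x) {
    i0 <- which(x == 0); i1 <- which(x == 1)
    b0 <- log((rowSums(y[, i0, drop = FALSE]) + 0.5) / rowSums(eo[, i0, drop = FALSE]))
    b1 <- log((rowSums(y[, i1, drop = FALSE]) + 0.5) / rowSums(eo[, i1, drop = FALSE])) - b0
  } else {
    b0 <- log((rowSums(y) + 0.5) / rowSums(eo))
    b1 <- rep(0, G)
  }
  xm <- if (has_x) matrix(x, G, n, byrow = TRUE) else NULL
  ll_old <- rep(-Inf, G)
  converged <- rep(FALSE, G)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- b0 + (if (has_x) b1 * xm else 0) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    if (has_x) {
      sw <- rowSums(w); swx <- rowSums(w * xm)
      swz <- rowSums(w * z); swxz <- rowSums(w * xm * z)
      det <- sw * swx - swx^2           # x binary: sum(w x^2) = sum(w x)
      det <- ifelse(abs(det) < 1e-12, NA_real_, det)
      b1_new <- (sw * swxz - swx * swz) / det
      b0_new <- (swz - swx * b1_new) / sw
      b1_new[is.na(b1_new)] <- b1[is.na(b1_new)]
      b0_new[is.na(b0_new)] <- b0[is.na(b0_new)]
    } else {
      b0_new <- rowSums(w * z) / rowSums(w)
      b1_new <- b1
    }
    b0 <- ifelse(converged, b0, pmin(pmax(b0_new, -50), 50))
    b1 <- ifelse(converged, b1, pmin(pmax(b1_new, -50), 50))
    eta <- b0 + (if (has_x) b1 * xm else 0) + off
    eta <- pmin(pmax(eta, -30), 30)
    ll <- nb_loglik_rows(y, exp(eta), phi)
    converged <- converged | (abs(ll - ll_old) < tol * (abs(ll) + 1))
    ll_old <- ll
    if (all(converged) || iter >= maxit) break
  }
  ll_sat <- nb_loglik_rows(y, pmax(y, 1e-10), phi)
  list(beta0 = b0, beta1 = b1, loglik = ll_old,
       deviance = 2 * (ll_sat - ll_old), iter = iter, converged = converged)
}

#' Estimate a common negative-binomial dispersion by profile likelihood
#'
#' Maximizes the summed Cox-Reid adjusted full-model NB log-likelihood across
#' all genes of a contrast over the dispersion, on a log scale (coarse grid
#' then golden section refinement). The Cox-Reid term
#' `-0.5 log det(X'WX)` per gene corrects the downward bias of plain maximum
#' likelihood that comes from estimating the two mean parameters per gene in
#' an 8-sample contrast. All genes in the contrast share the fitted value.
#'
#' @param y Counts matrix (genes x contrast samples).
#' @param x 0/1 evolved indicator over the contrast samples.
#' @param offset Log library sizes.
#' @param phi_range Search range for the dispersion (default `c(1e-6, 10)`).
#' @return The estimated dispersion (scalar, > 0).
#' @export
estimate_common_dispersion <- function(y, x, offset, phi_range = c(1e-6, 10)) {
  off <- if (is.matrix(offset)) offset else matrix(offset, nrow(y), ncol(y), byrow = TRUE)
  xm <- matrix(x, nrow(y), ncol(y), byrow = TRUE)
  prof <- function(lphi) {
    phi <- exp(lphi)
    fit <- nb_fit_vec(y, x, offset, phi, tol = 1e-6, maxit = 25L)
    eta <- pmin(pmax(fit$beta0 + fit$beta1 * xm + off, -30), 30)
    w <- exp(eta) / (1 + phi * exp(eta))
    sw <- rowSums(w); swx <- rowSums(w * xm)
    det <- pmax(sw * swx - swx^2, 1e-300)
    sum(fit$loglik - 0.5 * log(det))
  }
  grid <- seq(log(phi_range[1]), log(phi_range[2]), length.out = 9)
  vals <- vapply(grid, prof, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]; hi <- grid[min(k + 1L, length(grid))]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-3)
  exp(opt$maximum)
}

#' Negative-binomial GLM likelihood-ratio test for one evolved population
#'
#' Contrasts all replicate samples of one evolved population against all
#' ancestral samples. Per gene, a negative-binomial GLM (log link,
#' log-library-size offset) is fitted under the full model
#' (intercept + evolution indicator) and the null model (intercept only) with
#' a common dispersion shared across genes; the likelihood-ratio statistic
#' (null deviance minus full deviance) is referred to a chi-square with 1 df.
#' Genes with zero counts in every contrast sample are removed before fitting;
#' non-converged genes get `NA` p-values.
#'
#' @param counts A counts [omics_matrix()] (typically already restricted to
#'   expressed genes).
#' @param population Evolved population label to contrast.
#' @param dispersion Optional fixed common dispersion; estimated by
#'   [estimate_common_dispersion()] when `NULL`.
#' @return A data frame: `gene`, `beta0`, `beta1`, `dispersion`,
#'   `null_deviance`, `full_deviance`, `lrt_stat`, `p`, `converged`.
#' @export
fit_nb_lrt <- function(counts, population, dispersion = NULL) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  anc <- samples_of(counts, role = "ancestral")
  evo <- samples_of(counts, population = population, role = "evolved")
  if (length(evo) < 2L || length(anc) < 2L) {
    stop("validation error: need >= 2 replicates per group; population ",
         population, " has ", length(evo), ", ancestral has ", length(anc))
  }
  sel <- c(anc, evo)
  y <- counts$values[, sel, drop = FALSE]
  x <- as.numeric(colnames(y) %in% evo)
  offset <- if (!is.null(counts$offsets)) {
    # per-observation offsets (permuted data); index by position so the
    # offsets matrix does not need dimnames
    counts$offsets[, match(sel, colnames(counts$values)), drop = FALSE]
  } else {
    log(colSums(counts$values)[sel])
  }
  nonzero <- rowSums(y) > 0
  if (!all(nonzero)) {
    pv_log("fit_nb_lrt[%s]: removed %d all-zero gene(s)", population, sum(!nonzero))
  }
  yz <- y[nonzero, , drop = FALSE]
  off_z <- if (is.matrix(offset)) offset[nonzero, , drop = FALSE] else offset
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(yz, x, off_z)
  }
  full <- nb_fit_vec(yz, x, off_z, dispersion)
  null <- nb_fit_vec(yz, NULL, off_z, dispersion)
  stat <- pmax(null$deviance - full$deviance, 0)
  converged <- full$converged & null$converged
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[!converged] <- NA_real_
  if (any(!converged)) {
    pv_log("fit_nb_lrt[%s]: %d gene(s) failed to converge; p set to NA",
           population, sum(!converged))
  }
  out <- data.frame(gene = rownames(y), beta0 = NA_real_, beta1 = NA_real_,
                    dispersion = dispersion, null_deviance = NA_real_,
                    full_deviance = NA_real_, lrt_stat = NA_real_, p = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  out[nonzero, c("beta0", "beta1", "null_deviance", "full_deviance",
                 "lrt_stat", "p", "converged")] <-
    data.frame(full$beta0, full$beta1, null$deviance, full$deviance,
               stat, p, converged)
  rownames(out) <- NULL
  out
}

#' Per-population differential-expression calling
#'
#' The full transcriptome DE stage: CPM normalization, expression filter,
#' negative-binomial LRT per evolved population, BH FDR within each
#' population, and log2 fold changes computed from the filtered CPM matrix
#' with the configured pseudocount.
#'
#' @param counts A counts [omics_matrix()].
#' @param config A [run_config()] list.
#' @param dispersions Optional named numeric vector of per-population common
#'   dispersions to reuse (skips estimation).
#' @return A data frame with one row per (population, gene):
#'   `population`, `gene`, `log2FC`, `p`, `padj`, `significant`.
#'   The filtered gene universe is in `attr(, "features")`; estimated
#'   dispersions in `attr(, "dispersions")`.
#' @export
de_call <- function(counts, config = run_config(), dispersions = NULL) {
  stopifnot(inherits(counts, "omics_matrix"))
  cpm <- cpm_normalize(counts)
  cpm_f <- filter_expressed(cpm, config$cpm_filter, config$filter_mode)
  kept <- attr(cpm_f, "kept_features")
  counts_f <- counts
  counts_f$values <- counts$values[kept, , drop = FALSE]
  pops <- evolved_populations(counts)
  if (length(pops) < 1L) stop("validation error: no evolved populations in metadata")
  anc <- samples_of(counts, role = "ancestral")
  disp_out <- stats::setNames(numeric(length(pops)), pops)
  res <- lapply(pops, function(pp) {
    fit <- fit_nb_lrt(counts_f, pp,
                      dispersion = if (!is.null(dispersions)) dispersions[[pp]] else NULL)
    disp_out[[pp]] <<- fit$dispersion[1]
    evo <- samples_of(counts, population = pp, role = "evolved")
    lfc <- log2fc(cpm_f, evolved = evo, ancestral = anc,
                  pseudocount = config$pseudocount)
    padj <- bh_adjust(fit$p)
    data.frame(population = pp, gene = fit$gene, log2FC = lfc[fit$gene],
               p = fit$p, padj = padj,
               significant = !is.na(padj) & padj < config$fdr_threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "features") <- kept
  attr(out, "dispersions") <- disp_out
  attr(out, "level") <- "transcriptome"
  out
}
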