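test_that("CPM normalization matches its definition and invariances", {
  x <- make_counts(n_genes = 10, n_pops = 1, seed = 2)
  x$values[1, 1] <- 50
  x$values[, 1] <- c(50, rep((1e6 - 50) / 9, 9))  # library of exactly 1e6
  cpm <- cpm_normalize(x)
  expect_equal(cpm$values[1, 1], 50)
  expect_equal(unname(colSums(cpm$values)), rep(1e6, ncol(x$values)))
  # doubling every count of a sample leaves its CPM column unchanged
  y <- x; y$values[, 2] <- 2 * y$values[, 2]
  expect_equal(cpm_normalize(y)$values[, 2], cpm$values[, 2])
})

test_that("expression filter keeps the boundary and respects mode", {
  meta <- make_meta(1)
  v <- rbind(g1 = rep(0, 8),
             g2 = rep(0.1, 8),       # mean exactly at threshold: kept
             g3 = c(0.8, rep(0, 7)), # mean 0.1 via one sample
             g4 = rep(5, 8))
  x <- structure(list(values = v, meta = meta, value_kind = "cpm"),
                 class = "omics_matrix")
  f_mean <- filter_expressed(x, 0.1, "mean")
  expect_setequal(attr(f_mean, "kept_features"), c("g2", "g3", "g4"))
  f_min <- filter_expressed(x, 0.1, "min")
  expect_setequal(attr(f_min, "kept_features"), c("g2", "g4"))
  expect_length(attr(filter_expressed(x, 0), "kept_features"), 4)
})

test_that("NB LRT is null at identical groups and invariant to library-size scaling", {
  meta <- make_meta(1)
  v <- matrix(rep(c(40L, 80L, 120L), each = 8), 3, 8, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), meta$sample_id))
  x <- omics_matrix(v, meta, "counts")
  fit <- fit_nb_lrt(x, "pop1", dispersion = 0.1)
  expect_equal(fit$beta1, rep(0, 3), tolerance = 1e-6)
  expect_equal(fit$lrt_stat, rep(0, 3), tolerance = 1e-8)
  expect_equal(fit$p, rep(1, 3), tolerance = 1e-4)
  expect_true(all(fit$full_deviance <= fit$null_deviance + 1e-8))

  # scaling all library sizes by a constant leaves the LRT unchanged
  y <- make_counts(n_genes = 30, n_pops = 1, seed = 9)
  n <- ncol(y$values)
  base_off <- matrix(log(colSums(y$values)), nrow(y$values), n, byrow = TRUE)
  y1 <- y; y1$offsets <- base_off
  y2 <- y; y2$offsets <- base_off + log(7)
  f1 <- fit_nb_lrt(y1, "pop1", dispersion = 0.05)
  f2 <- fit_nb_lrt(y2, "pop1", dispersion = 0.05)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-6)
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-6)
})

test_that("NB GLM fit and LRT agree with edgeR at a fixed common dispersion", {
  skip_if_not_installed("edgeR")
  x <- make_counts(n_genes = 200, n_pops = 1, seed = 31, mu = 60)
  # inject some real effects so the comparison spans small and large statistics
  evo <- x$meta$sample_id[x$meta$role == "evolved"]
  x$values[1:40, evo] <- withr::with_seed(32, matrix(
    rnbinom(40 * length(evo), mu = 240, size = 20), 40))
  phi <- 0.07
  mine <- fit_nb_lrt(x, "pop1", dispersion = phi)
  lib <- colSums(x$values)
  sel <- c(x$meta$sample_id[x$meta$role == "ancestral"], evo)
  design <- stats::model.matrix(~c(rep(0, 5), rep(1, 3)))
  gf <- edgeR::glmFit(x$values[, sel], design, dispersion = phi,
                      offset = log(lib[sel]), prior.count = 0)
  lrt <- edgeR::glmLRT(gf)
  expect_equal(mine$p, lrt$table$PValue, tolerance = 1e-5)
  expect_equal(mine$beta1, lrt$table$logFC * log(2), tolerance = 1e-5)
})

test_that("common dispersion estimate recovers the generative value", {
  p <- sim_params(n_genes = 1500, n_metabolites = 1, genes_per_module = 1,
                  shared_effect_sd = 0, specific_effect_sd = 0,
                  nb_dispersion = 0.1, baseline_log2_cpm_range = c(3, 8), seed = 12)
  cnt <- simulate_counts(simulate_effects(p), p)
  anc <- cnt$meta$sample_id[cnt$meta$role == "ancestral"]
  evo <- cnt$meta$sample_id[cnt$meta$population == "pop1"]
  y <- cnt$values[, c(anc, evo)]
  phi_hat <- estimate_common_dispersion(y, c(rep(0, 5), rep(1, 3)),
                                        log(colSums(cnt$values)[c(anc, evo)]))
  expect_equal(phi_hat, 0.1, tolerance = 0.25)
})

test_that("de_call produces one table per population over a common universe, with BH guarantees", {
  x <- make_counts(n_genes = 60, n_pops = 3, seed = 13)
  cfg <- run_config(rng_seed = 13)
  de <- de_call(x, cfg)
  expect_setequal(unique(de$population), c("pop1", "pop2", "pop3"))
  universes <- lapply(split(de$gene, de$population), sort)
  expect_identical(universes[[1]], universes[[2]])
  expect_identical(universes[[2]], universes[[3]])
  ok <- !is.na(de$p)
  expect_true(all(de$padj[ok] >= de$p[ok]))
  expect_identical(de$significant, !is.na(de$padj) & de$padj < 0.05)
  # significant set at 0.01 nested in set at 0.05
  sig01 <- de$gene[!is.na(de$padj) & de$padj < 0.01]
  sig05 <- de$gene[!is.na(de$padj) & de$padj < 0.05]
  expect_true(all(sig01 %in% sig05))
  # population with < 2 replicates rejected
  bad <- x
  keep <- bad$meta$sample_id != "pop3_2" & bad$meta$sample_id != "pop3_3"
  bad$meta <- bad$meta[keep, ]
  bad$values <- bad$values[, keep]
  expect_error(de_call(bad, cfg), ">= 2 replicates")
})

test_that("column order of the input does not change the inference", {
  x <- make_counts(n_genes = 40, n_pops = 2, seed = 15)
  perm <- withr::with_seed(16, sample(ncol(x$values)))
  y <- x
  y$values <- x$values[, perm]
  y$meta <- x$meta[perm, ]
  rownames(y$meta) <- NULL
  cfg <- run_config(rng_seed = 15)
  d1 <- de_call(x, cfg)
  d2 <- de_call(y, cfg)
  m <- merge(d1, d2, by = c("population", "gene"))
  expect_equal(m$p.x, m$p.y, tolerance = 1e-9)
  expect_equal(m$log2FC.x, m$log2FC.y, tolerance = 1e-12)
})

test_that("power is monotone in the true effect size under coupled noise", {
  # quantile coupling: identical uniforms, counts = qnbinom(U, mu),
  # so raising the effect cannot decrease the evidence by noise alone
  meta <- make_meta(1)
  G <- 120
  withr::with_seed(21, {
    U <- matrix(runif(G * 8), G, 8)
  })
  n_sig <- vapply(c(0, 1, 2), function(eff) {
    mu <- matrix(80, G, 8)
    mu[1:60, 6:8] <- 80 * 2^eff
    v <- matrix(qnbinom(U, mu = mu, size = 20), G, 8,
                dimnames = list(sprintf("g%03d", 1:G), meta$sample_id))
    x <- omics_matrix(v, meta, "counts")
    fit <- fit_nb_lrt(x, "pop1", dispersion = 0.05)
    sum(bh_adjust(fit$p) < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(n_sig) >= 0))
  expect_gt(n_sig[3], n_sig[1])
})
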