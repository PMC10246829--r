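test_that("modules partition the module genes and conserve sizes", {
  p <- sim_params(n_genes = 120, n_metabolites = 20, genes_per_module = 5, seed = 2)
  tr <- simulate_effects(p)
  all_members <- unlist(tr$modules)
  expect_length(all_members, 20 * 5)
  expect_identical(anyDuplicated(all_members), 0L)  # disjoint modules
  expect_length(tr$modules, 20)
  expect_error(sim_params(n_metabolites = 50, genes_per_module = 5, n_genes = 100),
               "parameter error")
  expect_error(sim_params(genes_per_module = 0), "parameter error")
})

test_that("degenerate limits: full redundancy collapses to identical effects, zero SDs to none", {
  p <- sim_params(n_genes = 100, n_metabolites = 10, specific_effect_sd = 0,
                  redundancy_fraction = 1, seed = 3)
  tr <- simulate_effects(p)
  # every module gene has the module effect in every population
  expect_true(all(apply(tr$gene_effects, 1, function(r) length(unique(r)) == 1L)))
  in_mod <- rownames(tr$gene_effects) %in% unlist(tr$modules)
  nz <- tr$gene_effects[in_mod, 1] != 0
  expect_equal(cor(tr$gene_effects[in_mod, 1][nz], tr$gene_effects[in_mod, 2][nz]), 1)
  expect_equal(cor(tr$met_effects[, 1], tr$met_effects[, 2]), 1)
  # metabolite = mean of module genes (default aggregation)
  agg <- vapply(names(tr$modules), function(m)
    mean(tr$gene_effects[tr$modules[[m]], 1]), numeric(1))
  expect_equal(unname(agg), unname(tr$met_effects[, 1]))

  p0 <- sim_params(n_genes = 100, n_metabolites = 10, shared_effect_sd = 0,
                   specific_effect_sd = 0, seed = 3)
  expect_true(all(simulate_effects(p0)$gene_effects == 0))
})

test_that("partial redundancy makes true metabolite effects more parallel than gene effects", {
  # Monte-Carlo on the generative model itself: 20 replicate draws
  wins <- vapply(1:20, function(i) {
    p <- sim_params(n_genes = 300, n_metabolites = 50, genes_per_module = 5,
                    redundancy_fraction = 0.5, specific_effect_sd = 1,
                    shared_effect_sd = 1, seed = 1000 + i)
    tr <- simulate_effects(p)
    cg <- cor(tr$gene_effects); cm <- cor(tr$met_effects)
    mean(cm[upper.tri(cm)]) > mean(cg[upper.tri(cg)])
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("count noise model matches negative-binomial moments (Poisson limit)", {
  # constant mu = 100 across the whole matrix: baseline pinned at 50 CPM,
  # library sizes fixed at 2e6, no effects
  p <- sim_params(n_genes = 2000, n_metabolites = 1, genes_per_module = 1,
                  shared_effect_sd = 0, specific_effect_sd = 0,
                  nb_dispersion = 1e-6, lib_size_cv = 0,
                  baseline_log2_cpm_range = log2(c(50, 50)), seed = 8)
  cnt <- simulate_counts(simulate_effects(p), p)
  draws <- as.vector(cnt$values)
  expect_gt(length(draws), 10000)
  expect_true(var(draws) / mean(draws) > 0.9 && var(draws) / mean(draws) < 1.1)

  # at phi = 0.25 the NB variance mu + phi mu^2 should show
  p2 <- sim_params(n_genes = 2000, n_metabolites = 1, genes_per_module = 1,
                   shared_effect_sd = 0, specific_effect_sd = 0,
                   nb_dispersion = 0.25, lib_size_cv = 0,
                   baseline_log2_cpm_range = log2(c(50, 50)), seed = 8)
  d2 <- as.vector(simulate_counts(simulate_effects(p2), p2)$values)
  expect_equal(var(d2), 100 + 0.25 * 100^2, tolerance = 0.1)
})

test_that("generation is fully deterministic under a fixed seed", {
  p <- sim_params(n_genes = 50, n_metabolites = 5, seed = 77)
  a <- simulate_counts(simulate_effects(p), p)
  b <- simulate_counts(simulate_effects(p), p)
  expect_identical(a$values, b$values)
  ma <- simulate_metabolites(simulate_effects(p), p)
  mb <- simulate_metabolites(simulate_effects(p), p)
  expect_identical(ma$values, mb$values)
  # different seed, different data
  p2 <- sim_params(n_genes = 50, n_metabolites = 5, seed = 78)
  expect_false(identical(simulate_counts(simulate_effects(p2), p2)$values, a$values))
})

test_that("metabolite generator respects the noiseless limit and the detection floor", {
  p <- sim_params(n_genes = 60, n_metabolites = 10, met_noise_sd = 0, seed = 5)
  tr <- simulate_effects(p)
  m <- simulate_metabolites(tr, p)
  # replicates within a population identical without noise
  for (pp in unique(m$meta$population[m$meta$role == "evolved"])) {
    cols <- m$meta$sample_id[m$meta$population == pp]
    expect_true(all(apply(m$values[, cols], 1, function(r) diff(range(r)) == 0)))
  }
  # baselines drawn above the floor: ancestral samples all exceed it
  anc_cols <- m$meta$sample_id[m$meta$role == "ancestral"]
  expect_true(all(m$values[, anc_cols] > 10))
})

test_that("truth and GMT files round-trip module membership", {
  p <- sim_params(n_genes = 60, n_metabolites = 12, genes_per_module = 5, seed = 6)
  tr <- simulate_effects(p)
  out <- withr::local_tempdir()
  paths <- write_truth_and_gmt(tr, out)
  gg <- read_gmt(paths[["gmt_genes"]])
  mm <- read_gmt(paths[["gmt_mets"]])
  expect_length(gg, 12)
  expect_length(mm, 12)
  expect_true(all(lengths(gg) == 5))
  expect_true(all(lengths(mm) == 1))
  expect_equal(unname(unclass(gg)), unname(tr$modules), ignore_attr = TRUE)
})
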