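test_that("fisher_combine closed forms hold", {
  r <- fisher_combine(c(1, 1))
  expect_equal(r$S, 0)
  expect_equal(r$p, 1)
  r2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(r2$S, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(r2$S, 11.98293, tolerance = 1e-4)
  expect_equal(r2$p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE), tolerance = 1e-12)
  # k = 1: the chi-square(2) inversion is the identity on p
  for (p in c(0.001, 0.05, 0.31, 0.9, 1)) {
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
  }
  expect_error(fisher_combine(c(0.5, 1.2)), "validation error")
  # zero input floored, not propagated as -Inf
  expect_true(is.finite(fisher_combine(c(0, 0.5))$S))
})

test_that("fisher statistic is chi-square distributed under uniform inputs", {
  # dual route: Monte-Carlo of -2 sum log U against the chi-square tail
  withr::with_seed(17, {
    S <- -2 * (log(runif(4000)) + log(runif(4000)))
    expect_equal(mean(S > qchisq(0.95, 4)), 0.05, tolerance = 0.015)
    expect_equal(mean(S), 4, tolerance = 0.15)
  })
})

test_that("combined p is monotone decreasing in each input", {
  grid <- c(0.001, 0.01, 0.1, 0.5, 1)
  for (fixed in c(0.02, 0.4)) {
    ps <- vapply(grid, function(q) fisher_combine(c(fixed, q))$p, numeric(1))
    expect_true(all(diff(ps) > 0))
  }
})

test_that("global test statistic is affine-invariant and detects forced separation", {
  x <- make_log_areas(n_mets = 10, n_pops = 1, seed = 51)
  members <- sprintf("m%03d", 1:4)
  g1 <- global_test(x, members, "pop1", n_perm = 200, seed = 1)
  y <- x
  y$values["m001", ] <- 10 - 3 * y$values["m001", ]  # affine rescale of one member
  g2 <- global_test(y, members, "pop1", n_perm = 200, seed = 1)
  expect_equal(g2$Q, g1$Q, tolerance = 1e-12)
  expect_equal(g2$p, g1$p)

  # all members shifted strongly in the evolved group: p at the permutation floor
  z <- x
  evo <- z$meta$sample_id[z$meta$population == "pop1"]
  z$values[members, evo] <- z$values[members, evo] + 5
  g3 <- global_test(z, members, "pop1", n_perm = 200, seed = 2)
  # floor is not exactly 1/(B+1) because label permutations repeat at n = 8
  expect_lte(g3$p, (1 + choose(8, 3)^-1 * 200) / 201)
  expect_lt(g3$p, 0.05)

  # fewer than min_members usable members: skipped
  g4 <- global_test(x, "m001", "pop1", n_perm = 50)
  expect_true(is.na(g4$p))
  g5 <- global_test(x, "m001", "pop1", n_perm = 200, seed = 3, min_members = 1)
  expect_false(is.na(g5$p))
})

test_that("global test p-values are calibrated under the permutation null", {
  withr::with_seed(29, {
    meta <- make_meta(1)
    ps <- replicate(400, {
      v <- matrix(rnorm(3 * 8), 3, 8,
                  dimnames = list(c("a", "b", "c"), meta$sample_id))
      x <- omics_matrix(v, meta, "log_area")
      global_test(x, c("a", "b", "c"), "pop1", n_perm = 99)$p
    })
    # add-one permutation p is stochastically >= uniform; check both bounds
    frac <- mean(ps <= 0.05)
    expect_lt(frac, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 400))
    expect_gt(frac, 0.05 - 3.5 * sqrt(0.05 * 0.95 / 400))
  })
})

test_that("joint analysis integrates both omics, ranks true modules first, keeps BH nesting", {
  p <- sim_params(n_genes = 200, n_metabolites = 40, genes_per_module = 4,
                  shared_effect_sd = 1.5, specific_effect_sd = 0.3,
                  redundancy_fraction = 0.8, n_pops_rna = 3, n_pops_met = 2,
                  met_baseline_range = c(13, 16),  # headroom over the floor
                  seed = 61)
  tr <- simulate_effects(p)
  cnt <- simulate_counts(tr, p)
  met <- simulate_metabolites(tr, p)
  # 5 true module pathways + 5 noise pathways from background genes/metabolites
  mod_ids <- sprintf("TRUE%02d", 1:5)
  noise_ids <- sprintf("NOISE%02d", 1:5)
  gene_sets <- c(stats::setNames(tr$modules[1:5], mod_ids),
                 stats::setNames(lapply(1:5, function(i)
                   sprintf("g%04d", 160 + (i - 1) * 4 + 1:4)), noise_ids))
  met_sets <- c(stats::setNames(lapply(1:5, function(i)
                  names(tr$modules)[c(i, 20 + i)]), mod_ids),
                stats::setNames(lapply(1:5, function(i)
                  names(tr$modules)[c(25 + i, 30 + i)]), noise_ids))
  class(gene_sets) <- class(met_sets) <- "pathway_annotation"
  cfg <- run_config(rng_seed = 61, n_permutations_pathway = 200)
  jp <- joint_pathway_analysis(cnt, met, gene_sets, met_sets, cfg)
  tab <- jp$table
  # a metabolite lost to the detection filter demotes its pathway to a
  # one-omic (k = 1) combination; most pathways integrate both omics
  expect_true(all(tab$n_omics %in% c(1L, 2L)))
  expect_gt(mean(tab$n_omics == 2), 0.7)
  expect_true(all(tab$padj >= tab$p_combined - 1e-12))
  # module pathways should out-rank noise pathways within each population
  for (pp in unique(tab$population)) {
    d <- tab[tab$population == pp, ]
    ranks <- rank(d$p_combined)
    expect_lt(mean(ranks[d$pathway %in% mod_ids]),
              mean(ranks[d$pathway %in% noise_ids]))
  }
  # significance nesting in the threshold
  sig01 <- with(tab, paste(population, pathway)[padj < 0.01])
  sig05 <- with(tab, paste(population, pathway)[padj < 0.05])
  expect_true(all(sig01 %in% sig05))
  expect_true(is.data.frame(jp$shared))
})
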