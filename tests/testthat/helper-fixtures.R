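# fixtures are built in code: small metadata/matrix constructors shared by
# the unit tests

options(parallevol.quiet = TRUE)

make_meta <- function(n_pops = 2, n_anc = 5, n_rep = 3) {
  pops <- sprintf("pop%d", seq_len(n_pops))
  data.frame(
    sample_id = c(sprintf("anc%d", seq_len(n_anc)),
                  unlist(lapply(pops, function(p) sprintf("%s_%d", p, seq_len(n_rep))))),
    population = c(rep("anc", n_anc), rep(pops, each = n_rep)),
    role = c(rep("ancestral", n_anc), rep("evolved", n_pops * n_rep)),
    replicate = c(seq_len(n_anc), rep(seq_len(n_rep), n_pops)),
    stringsAsFactors = FALSE)
}

make_counts <- function(n_genes = 20, n_pops = 2, seed = 1, mu = 100) {
  meta <- make_meta(n_pops)
  withr::with_seed(seed, {
    v <- matrix(rnbinom(n_genes * nrow(meta), mu = mu, size = 10),
                n_genes, nrow(meta),
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), meta$sample_id))
    omics_matrix(v, meta, "counts")
  })
}

make_log_areas <- function(n_mets = 15, n_pops = 2, seed = 1, base = 12) {
  meta <- make_meta(n_pops)
  withr::with_seed(seed, {
    v <- matrix(base + rnorm(n_mets * nrow(meta), 0, 0.3), n_mets, nrow(meta),
                dimnames = list(sprintf("m%03d", seq_len(n_mets)), meta$sample_id))
    omics_matrix(v, meta, "log_area")
  })
}

# brute-force BH, the definitional oracle: sort, p * n / rank, cumulative
# minimum from the largest rank, cap at 1
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force exhaustive 5-vs-3 style permutation p, independent of the
# package's vectorized path
perm_p_brute <- function(values, n_evolved) {
  n <- length(values)
  obs <- mean(values[(n - n_evolved + 1):n]) - mean(values[1:(n - n_evolved)])
  splits <- utils::combn(n, n_evolved)
  nulls <- apply(splits, 2, function(j) mean(values[j]) - mean(values[-j]))
  k <- sum(abs(nulls) > abs(obs))
  if (k == 0) 1 / (ncol(splits) + 1) else k / ncol(splits)
}
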