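# shared fixtures and independent oracles

# brute-force quantile normalization: sort each column, average across
# columns, write the averages back in each column's rank order
# (distinct values only — tie handling is tested separately)
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) ref[rank(col)])
}

# exhaustive per-gene panel check, independent of select_panel's vectorized path
panel_oracle <- function(records, comparisons, direction, threshold) {
  survivors <- character(0)
  for (g in unique(records$gene_id)) {
    sub <- records[records$gene_id == g & records$pair %in% comparisons, ]
    ok <- nrow(sub) == length(comparisons) &&
      all(sub$direction == direction) && min(sub$ratio) >= threshold
    if (ok) survivors <- c(survivors, g)
  }
  survivors
}

# enumeration oracle: P(overlap >= k) by counting every possible draw of
# n genes from a universe of N containing K set members
hyper_enum_oracle <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # members are items 1..K
}

# random long fold-change table over a comparison set
random_records <- function(genes, comparisons, seed) {
  set.seed(seed)
  do.call(rbind, lapply(comparisons, function(p) {
    data.frame(gene_id = genes, pair = p,
               ratio = exp(abs(rnorm(length(genes), 0, 1.5))),
               direction = sample(c("up", "down"), length(genes),
                                  replace = TRUE),
               stringsAsFactors = FALSE)
  }))
}

# minimal noise-free study with known planted signal
tiny_config <- function(seed = 11, noise_sd = 0, ...) {
  simulation_config(n_subjects_per_arm = 3, n_genes = 40,
                    probes_per_gene = 2, noise_sd = noise_sd,
                    seed = seed, ...)
}

# saturated / patterned DESS records
flat_dess_records <- function(level, sample_id = "S1") {
  dess_record(sample_id, rep(level, 64))
}
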