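# Shared fixtures: small simulation configs and hand-rolled oracles used
# across test files. Everything is generated in code at test time.

# A compact genome config: 2 chromosomes x 200 kb, 50-kb windows, MSR on
# the first 50 kb of chr02. Fast enough for multi-seed loops.
small_config <- function(seed = 1L, ...) {
  base <- list(seed = seed, n_chroms = 2L, chrom_length = 2e5,
               msr_interval = c(0, 5e4), window_size = 5e4,
               centromere_copies = 100L, snp_density = 1)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# The spec scenario scale: 2-Mb chromosomes, 100-kb windows, MSR [0, 400 kb].
msr_scenario_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

# Independent Hudson FST oracle: literal transcription of the estimator,
# scalar arithmetic only.
oracle_hudson <- function(alt1, tot1, alt2, tot2) {
  p1 <- alt1 / tot1
  p2 <- alt2 / tot2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (tot1 - 1) - p2 * (1 - p2) / (tot2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) NA_real_ else num / den
}

# Brute-force per-site pi: average pairwise difference over all allele pairs.
oracle_pi <- function(alt, total) {
  alleles <- c(rep(1L, alt), rep(0L, total - alt))
  pairs <- utils::combn(total, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Exhaustive single-split least-squares oracle for a step series.
oracle_single_split <- function(x, min_seg = 1L) {
  n <- length(x)
  best <- NULL
  for (b in seq(min_seg, n - min_seg)) {
    sse <- sum((x[1:b] - mean(x[1:b]))^2) +
      sum((x[(b + 1):n] - mean(x[(b + 1):n]))^2)
    if (is.null(best) || sse < best$sse) best <- list(b = b, sse = sse)
  }
  best$b
}

# O(N^2) brute-force mutual-rank oracle over a candidate pair table.
oracle_mutual_rank <- function(candidates) {
  genes <- sort(unique(c(candidates$gene1, candidates$gene2)))
  n <- length(genes)
  rank_of <- function(g, partner) {
    rows <- candidates[candidates$gene1 == g | candidates$gene2 == g, ]
    partners <- ifelse(rows$gene1 == g, rows$gene2, rows$gene1)
    ord <- order(-abs(rows$pcc), partners)
    which(partners[ord] == partner)
  }
  raw <- mr <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r12 <- rank_of(candidates$gene1[i], candidates$gene2[i])
    r21 <- rank_of(candidates$gene2[i], candidates$gene1[i])
    raw[i] <- sqrt(r12 * r21)
    mr[i] <- if (n > 1) 1 - (raw[i] - 1) / (n - 1) else 1
  }
  list(raw = raw, mr = mr)
}

# One-sided Fisher tail by explicit hypergeometric point-probability sums.
oracle_fisher_greater <- function(a, b, c, d) {
  # P(X >= a) where X ~ Hypergeom(m = a + b draws, from (a + c) successes
  # in a + b + c + d)
  n_tot <- a + b + c + d
  k_succ <- a + c
  n_draw <- a + b
  xs <- max(0, n_draw + k_succ - n_tot):min(n_draw, k_succ)
  xs <- xs[xs >= a]
  sum(stats::dhyper(xs, k_succ, n_tot - k_succ, n_draw))
}

# Planted unordered within-module pairs ("TF target" and sibling pairs).
planted_module_pairs <- function(truth) {
  unlist(lapply(names(truth$tf_target_map), function(tf) {
    members <- c(tf, truth$tf_target_map[[tf]])
    pairs <- utils::combn(sort(members), 2)
    paste(pairs[1, ], pairs[2, ])
  }))
}

planted_tf_target_pairs <- function(truth) {
  unlist(lapply(names(truth$tf_target_map), function(tf) {
    tg <- truth$tf_target_map[[tf]]
    paste(pmin(tf, tg), pmax(tf, tg))
  }))
}

pair_keys <- function(df) paste(df$gene1, df$gene2)
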