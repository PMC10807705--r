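test_that("DEG filtering applies BH and the joint fold-change/FDR rule", {
  # hand BH: {0.001, 0.002, 0.03, 0.8} at m = 4 -> {0.004, 0.004, 0.04, 0.8}
  expect_equal(p.adjust(c(0.001, 0.002, 0.03, 0.8), "BH"),
               c(0.004, 0.004, 0.04, 0.8))
  tab <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2_fold_change = c(1.5, 0.8, -2, 3),
    p_value = c(1e-5, 1e-6, 2e-5, 0.5),
    stringsAsFactors = FALSE
  )
  degs <- filter_degs(tab)
  # b: |log2FC| < 1 dropped despite tiny p; d: high p dropped
  expect_setequal(degs$gene, c("a", "c"))
  expect_equal(degs$direction[degs$gene == "c"], "down")
  # number kept is non-increasing as the FDR threshold tightens
  set.seed(3)
  big <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2_fold_change = rnorm(200, sd = 2),
                    p_value = runif(200)^3, stringsAsFactors = FALSE)
  kept <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
    nrow(filter_degs(big, fdr_max = a))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("genes with missing p-values are excluded from the BH family", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    log2_fold_change = c(2, 2, 2),
                    p_value = c(0.001, NA, 0.002), stringsAsFactors = FALSE)
  expect_warning(degs <- filter_degs(tab, fdr_max = 0.05), "missing p-values")
  expect_equal(attr(degs, "n_missing_p"), 1L)
  expect_setequal(degs$gene, c("a", "c"))
  # BH m = 2, not 3
  expect_equal(degs$fdr[degs$gene == "c"], 0.002)
})

test_that("correlation candidates match the textbook formula and threshold", {
  expr <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = -c(1, 2, 3),
                d = c(1, 2, 4), e = c(5, 5, 5))
  colnames(expr) <- paste0("s", 1:3)
  expect_warning(cand <- pcc_candidates(expr, threshold = 0.9), "zero-variance")
  k <- pair_keys(cand)
  expect_true(all(c("a b", "a c") %in% k))
  expect_equal(cand$pcc[k == "a b"], 1)
  expect_equal(cand$pcc[k == "a c"], -1)
  # textbook PCC for (1,2,3) vs (1,2,4): 0.9819805
  r <- sum((c(1,2,3) - 2) * (c(1,2,4) - 7/3)) /
    sqrt(sum((c(1,2,3) - 2)^2) * sum((c(1,2,4) - 7/3)^2))
  expect_equal(cand$pcc[k == "a d"], r, tolerance = 1e-12)
  expect_false("e" %in% c(cand$gene1, cand$gene2))
})

test_that("the mutual-rank formula reproduces hand arithmetic", {
  expect_equal(msrpipe:::mr_score(1, 1, 10), 1)
  # stated normalisation at N = 2, ranks (2, 1): 1 - (sqrt(2) - 1)/1
  expect_equal(msrpipe:::mr_score(2, 1, 2), 1 - (sqrt(2) - 1),
               tolerance = 1e-12)
  expect_equal(msrpipe:::mr_score(1, 1, 1), 1)
})

test_that("mutual ranks agree with the brute-force oracle on random matrices", {
  for (seed in 1:3) {
    set.seed(seed)
    expr <- matrix(rnorm(50 * 18), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
    cand <- pcc_candidates(expr, threshold = 0.2)
    expect_gt(nrow(cand), 50)
    scores <- mutual_rank(cand)
    oracle <- oracle_mutual_rank(cand)
    expect_equal(scores$mr_raw, oracle$raw, tolerance = 1e-12)
    expect_equal(scores$mr, oracle$mr, tolerance = 1e-12)
    # invariants: mr in (0, 1], equal to 1 iff both ranks are 1
    expect_true(all(scores$mr > 0 & scores$mr <= 1))
    both_one <- scores$rank_1to2 == 1 & scores$rank_2to1 == 1
    expect_equal(scores$mr == 1, both_one)
  }
})

test_that("mutual rank is order-invariant and decreasing in either rank", {
  expr <- rbind(a = c(1, 2, 3, 5, 4), b = c(1, 2, 3, 4, 5),
                c = c(2, 1, 3, 4, 5), d = c(5, 4, 3, 2, 1))
  cand <- pcc_candidates(expr, threshold = 0.3)
  s1 <- mutual_rank(cand)
  set.seed(1)
  s2 <- mutual_rank(cand[sample(nrow(cand)), ])
  s2 <- s2[match(pair_keys(s1), pair_keys(s2)), ]
  expect_equal(s1$mr, s2$mr)
  expect_equal(s1$rank_1to2, s2$rank_1to2)
  expect_lt(msrpipe:::mr_score(2, 3, 10), msrpipe:::mr_score(2, 2, 10))
  expect_lt(msrpipe:::mr_score(3, 2, 10), msrpipe:::mr_score(2, 2, 10))
})

test_that("the MR threshold is inclusive and pipeline order-invariant", {
  scores <- data.frame(gene1 = c("a", "c", "e"), gene2 = c("b", "d", "f"),
                       pcc = c(0.95, -0.95, 0.99),
                       rank_1to2 = 1L, rank_2to1 = 1L, mr_raw = 1,
                       mr = c(0.95, 0.90, 0.89))
  g <- build_coexpression_network(scores, 0.90)
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to), c("a b", "c d"))
  expect_equal(sort(el$sign), c("+", "-")[order(c("+", "-"))])
})

test_that("planted networks are recovered with high recall and precision", {
  recalls <- precisions <- numeric(20)
  for (seed in 1:20) {
    cfg <- small_config(seed = seed, expr_noise_sd = 0.05)
    gen <- simulate_genome(cfg)
    ex <- simulate_expression(cfg, gen$truth)
    cand <- pcc_candidates(ex$expr, threshold = 0.9)
    scores <- mutual_rank(cand)
    kept <- scores[scores$mr >= 0.90, ]
    keys <- pair_keys(kept)
    planted <- planted_tf_target_pairs(gen$truth)
    module <- planted_module_pairs(gen$truth)
    recalls[seed] <- mean(planted %in% keys)
    precisions[seed] <- if (length(keys)) mean(keys %in% module) else NA
  }
  expect_gte(mean(recalls), 0.9)
  expect_gte(mean(precisions, na.rm = TRUE), 0.9)
})

test_that("promoters are strand-aware, truncated at edges, and slice-exact", {
  set.seed(12)
  seq <- msrpipe:::rand_dna(10000)
  g <- c(chrA = seq)
  genes <- data.frame(
    gene_id = c("plus", "minus", "edge"), chrom = "chrA",
    start = c(5000, 1000, 500), end = c(6000, 2000, 800),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE
  )
  pr <- extract_promoters(genes, g, 2000)
  expect_equal(pr$seq[1], substr(seq, 3001, 5000))
  expect_equal(pr$seq[2], msrpipe:::revcomp(substr(seq, 2001, 4000)))
  expect_equal(pr$length[3], 500)
  expect_equal(pr$seq[3], substr(seq, 1, 500))
  # gene flush at position 0 on + strand: zero-length promoter
  flush <- data.frame(gene_id = "z", chrom = "chrA", start = 0, end = 100,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(extract_promoters(flush, g)$length, 0)
})

test_that("motif scanning finds consensus hits and matches a brute-force scorer", {
  pwm <- msrpipe:::consensus_pwms(c(m = "ACGTACGT"))[[1]]
  set.seed(31)
  promoter <- paste0(msrpipe:::rand_dna(500), "ACGTACGT",
                     msrpipe:::rand_dna(500))
  hit <- scan_motif(promoter, pwm)
  expect_true(hit$hit)
  expect_equal(hit$best_pos, 501L)
  # a C-only PWM cannot hit an all-A promoter
  cpwm <- msrpipe:::consensus_pwms(c(m = "CCCCCC"))[[1]]
  expect_false(scan_motif(strrep("A", 100), cpwm)$hit)
  # promoter shorter than the motif: no hit
  expect_false(scan_motif("ACG", pwm)$hit)

  # brute force per-position scorer over 50 random promoters
  brute <- function(seqs, pwm, frac = 0.85, pc = 0.01) {
    lo <- msrpipe:::pwm_logodds(pwm, pc)
    w <- ncol(lo)
    vapply(seqs, function(s) {
      best <- -Inf
      for (str in c(s, msrpipe:::revcomp(s))) {
        ch <- strsplit(str, "")[[1]]
        if (length(ch) < w) next
        for (i in 1:(length(ch) - w + 1)) {
          sc <- 0
          for (j in 1:w) sc <- sc + lo[ch[i + j - 1], j]
          best <- max(best, sc)
        }
      }
      best >= frac * sum(apply(lo, 2, max))
    }, logical(1))
  }
  set.seed(17)
  proms <- vapply(1:50, function(i) {
    core <- if (i %% 3 == 0) "ACGTACGT" else msrpipe:::rand_dna(8)
    paste0(msrpipe:::rand_dna(40), core, msrpipe:::rand_dna(40))
  }, character(1))
  got <- vapply(proms, function(s) scan_motif(s, pwm)$hit, logical(1))
  expect_equal(unname(got), unname(brute(proms, pwm)))
})

test_that("Fisher enrichment equals exact hypergeometric tail sums", {
  # spot tables including the closed-form perfect separation case
  p <- motif_enrichment(
    stats::setNames(rep("ACGTACGTAA", 10), paste0("d", 1:10)),
    stats::setNames(rep("TTTTTTTTTT", 10), paste0("b", 1:10)),
    list(m = msrpipe:::consensus_pwms(c(m = "ACGTACGT"))[[1]])
  )
  expect_equal(p$n_deg_with_hit, 10)
  expect_equal(p$n_bg_with_hit, 0)
  expect_equal(p$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(p$enriched)

  # identical hit rates are never enriched
  same <- motif_enrichment(
    stats::setNames(rep(c("ACGTACGTAA", "TTTTTTTTTT"), 5), paste0("d", 1:10)),
    stats::setNames(rep(c("ACGTACGTAA", "TTTTTTTTTT"), 5), paste0("b", 1:10)),
    list(m = msrpipe:::consensus_pwms(c(m = "ACGTACGT"))[[1]])
  )
  expect_gte(same$p_value, 0.5)
  expect_false(same$enriched)

  expect_error(motif_enrichment(stats::setNames("ACGT", "d1"), character(0),
                                list(m = msrpipe:::consensus_pwms(c(m = "AC"))[[1]])),
               "empty")

  # the [[5,5],[1,9]] table against the dhyper oracle
  expect_equal(fisher.test(matrix(c(5, 5, 1, 9), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               oracle_fisher_greater(5, 5, 1, 9), tolerance = 1e-12)
})

test_that("Fisher p-values match the oracle on all tables with margins <= 12", {
  for (n1 in c(3, 7, 12)) {
    for (n2 in c(4, 9, 12)) {
      for (a in 0:n1) {
        for (c_ in 0:n2) {
          got <- fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2,
                                    byrow = TRUE),
                             alternative = "greater")$p.value
          expect_equal(got, oracle_fisher_greater(a, n1 - a, c_, n2 - c_),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("regulatory edges require DEG status, enrichment and a promoter hit", {
  coex <- build_coexpression_network(
    data.frame(gene1 = "tf1", gene2 = "t1", pcc = 0.99, rank_1to2 = 1L,
               rank_2to1 = 1L, mr_raw = 1, mr = 1), 0.9
  )
  hits <- matrix(c(TRUE, FALSE, FALSE, TRUE), nrow = 2, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), c("m1", "m2")))
  map <- data.frame(motif_id = c("m1", "m2"), tf_id = c("tf1", "tf2"),
                    stringsAsFactors = FALSE)
  grn <- assemble_grn(coex, tf_ids = c("tf1", "tf2"),
                      enriched_motifs = "m1", motif_tf_map = map,
                      deg_genes = c("tf1", "t1", "t2"),
                      promoter_hits = hits)
  reg <- grn$edges[grn$edges$edge_type == "regulation", ]
  expect_equal(reg$source, "tf1")
  expect_equal(reg$target, "t1")   # t2 lacks an m1 hit
  # a TF that is not differentially expressed contributes no edges
  grn2 <- assemble_grn(coex, c("tf1", "tf2"), "m1", map,
                       deg_genes = c("t1", "t2"), promoter_hits = hits)
  expect_equal(sum(grn2$edges$edge_type == "regulation"), 0L)
  # unmapped motifs warn and are skipped; no enrichment -> coexpression only
  expect_warning(
    grn3 <- assemble_grn(coex, "tf1", "mX", map, c("tf1", "t1"), hits),
    "without TF mapping"
  )
  expect_equal(grn3$edges$edge_type, "coexpression")
})

test_that("planted regulation edges are recovered end to end without noise", {
  cfg <- small_config(seed = 27, expr_noise_sd = 0)
  gen <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, gen$truth)
  cand <- pcc_candidates(ex$expr, threshold = 0.9)
  coex <- build_coexpression_network(mutual_rank(cand), 0.9)
  pr <- extract_promoters(gen$truth$genes, gen$genome)
  pwms <- msrpipe:::consensus_pwms(gen$truth$motifs)
  network_genes <- c(gen$truth$tf_ids, unlist(gen$truth$tf_target_map))
  hits <- sapply(pwms, function(p) {
    vapply(pr$seq, function(s) scan_motif(s, p)$hit, logical(1))
  })
  rownames(hits) <- pr$gene_id
  map <- data.frame(motif_id = names(pwms), tf_id = names(pwms),
                    stringsAsFactors = FALSE)
  grn <- assemble_grn(coex, gen$truth$tf_ids, names(pwms), map,
                      deg_genes = network_genes, promoter_hits = hits)
  reg <- grn$edges[grn$edges$edge_type == "regulation", ]
  for (tf in gen$truth$tf_ids) {
    for (tg in gen$truth$tf_target_map[[tf]]) {
      expect_true(any(reg$source == tf & reg$target == tg),
                  label = paste("edge", tf, "->", tg))
    }
  }
})

test_that("network statistics reproduce closed forms", {
  tri <- igraph::make_full_graph(3)
  st <- network_stats(tri)
  expect_equal(st$n_nodes, 3L)
  expect_equal(st$n_edges, 3L)
  expect_equal(st$avg_neighbors, 2)
  expect_equal(st$characteristic_path_length, 1)
  expect_equal(st$clustering_coefficient, 1)

  path3 <- igraph::make_graph(~ a - b, b - c)
  st <- network_stats(path3)
  expect_equal(st$clustering_coefficient, 0)
  expect_equal(st$characteristic_path_length, 4 / 3)

  # adding an edge never decreases average neighbours
  st2 <- network_stats(igraph::add_edges(path3, c("a", "c")))
  expect_gte(st2$avg_neighbors, st$avg_neighbors)

  empty <- network_stats(igraph::make_empty_graph(0, directed = FALSE))
  expect_true(is.na(empty$n_nodes))
})

test_that("peak stage annotation tracks the maximal mean per stage", {
  expr <- rbind(g1 = c(5, 5, 1, 1, 0, 0), g2 = c(0, 0, 9, 9, 1, 1))
  colnames(expr) <- paste0("s", 1:6)
  samples <- data.frame(sample = paste0("s", 1:6),
                        stage = rep(c("A", "B", "C"), each = 2))
  ps <- peak_stage(expr, samples)
  expect_equal(unname(ps[c("g1", "g2")]), c("A", "B"))
})
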