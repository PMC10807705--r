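test_that("Hudson FST matches closed forms and a hand oracle", {
  # identical populations at p = 0.5 -> 0 within O(1/n) bias correction
  expect_lt(abs(site_fst(500, 1000, 500, 1000)), 2e-3)
  # fixed difference: exactly 1 (bias terms vanish at p in {0, 1})
  expect_equal(site_fst(20, 20, 0, 20), 1)
  # frozen hand evaluation for p1 = 8/20, p2 = 2/20
  expect_equal(site_fst(8, 20, 2, 20), 0.0726315789473684 / 0.42,
               tolerance = 1e-12)
  # 100 random allele-count configurations against the independent oracle
  set.seed(101)
  for (i in 1:100) {
    t1 <- sample(4:60, 1); t2 <- sample(4:60, 1)
    a1 <- sample(0:t1, 1); a2 <- sample(0:t2, 1)
    got <- site_fst(a1, t1, a2, t2)
    want <- oracle_hudson(a1, t1, a2, t2)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("FST is symmetric in populations and invariant to allele relabelling", {
  set.seed(5)
  for (i in 1:25) {
    t1 <- sample(4:40, 1); t2 <- sample(4:40, 1)
    a1 <- sample(0:t1, 1); a2 <- sample(0:t2, 1)
    for (m in c("hudson", "wc")) {
      f <- site_fst(a1, t1, a2, t2, method = m)
      expect_equal(f, site_fst(a2, t2, a1, t1, method = m), tolerance = 1e-12)
      expect_equal(f, site_fst(t1 - a1, t1, t2 - a2, t2, method = m),
                   tolerance = 1e-12)
    }
  }
})

test_that("insufficient allele counts give NA with a warning", {
  expect_warning(f <- site_fst(1, 1, 3, 10), "fewer than 2")
  expect_true(is.na(f))
  expect_true(is.na(site_pi(0, 1)))
})

test_that("per-site pi matches closed forms and brute-force pairwise counting", {
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  set.seed(7)
  for (i in 1:100) {
    tot <- sample(2:30, 1)
    alt <- sample(0:tot, 1)
    expect_equal(site_pi(alt, tot), oracle_pi(alt, tot), tolerance = 1e-12)
  }
  # haplotypes {AAA, AAT, ATT}: mean pairwise differences 4/3 over 3 sites
  alts <- c(0, 1, 2)  # per-site alternate counts among 3 haplotypes
  window_pi <- sum(vapply(alts, site_pi, numeric(1), total = 3)) / 3
  expect_equal(window_pi, 4 / 9, tolerance = 1e-12)
})

make_geno <- function(sites, geno, sex) {
  structure(list(sites = sites, geno = geno,
                 sex = stats::setNames(factor(sex, c("male", "female")),
                                       colnames(geno))),
            class = "sexed_genotypes")
}

flat_depth <- function(chroms, len, w, samples, value = 30) {
  starts <- seq(0, len - 1, by = w)
  do.call(rbind, lapply(chroms, function(ch) {
    do.call(rbind, lapply(samples, function(s) {
      data.frame(chrom = ch, window_start = starts,
                 window_end = pmin(starts + w, len), sample = s,
                 mean_depth = value, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("window_scan handles monomorphic and single-SNP windows", {
  samples <- c("m1", "m2", "f1", "f2")
  sex <- c("male", "male", "female", "female")
  sites <- data.frame(chrom = "chrA", pos = c(5, 150), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  geno <- matrix(c(2L, 0L, 0L, 0L,   # site 1: fixed difference male/female? no: m=2,2? see below
                   1L, 1L, 1L, 1L), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, samples))
  geno[1, ] <- c(2L, 2L, 0L, 0L)  # fixed difference between sexes
  gt <- make_geno(sites, geno, sex)
  depth <- flat_depth("chrA", 300, 100, samples)
  w <- window_scan(gt, depth, 100)
  expect_equal(nrow(w), 3L)
  # window 1 holds only site 1: mean FST equals that site's FST = 1
  expect_equal(w$mean_fst[1], site_fst(4, 4, 0, 4))
  expect_equal(w$n_snps, c(1, 1, 0))
  # window 3 has no SNPs: FST missing, pi zero, depth intact
  expect_true(is.na(w$mean_fst[3]))
  expect_equal(w$pi_male[3], 0)
  expect_equal(w$male_depth, rep(30, 3))
  # window pi = site heterozygosity / window length
  expect_equal(w$pi_male[2], site_pi(2, 4) / 100)
})

test_that("window statistics are invariant to sample ordering", {
  cfg <- small_config(seed = 14)
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  perm <- sample(ncol(vs$genotypes$geno))
  gt2 <- vs$genotypes
  gt2$geno <- gt2$geno[, perm]
  gt2$sex <- gt2$sex[perm]
  w1 <- window_scan(vs$genotypes, vs$depth, cfg$window_size)
  w2 <- window_scan(gt2, vs$depth, cfg$window_size)
  expect_equal(w1, w2)
})

test_that("window depth contrast separates MSR from autosomal windows", {
  cfg <- small_config(seed = 21)
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  w <- window_scan(vs$genotypes, vs$depth, cfg$window_size)
  msr <- w$chrom == gen$truth$msr_chrom & w$end <= 5e4
  ratio <- w$female_depth / w$male_depth
  expect_true(all(ratio[msr] <= 0.2))
  expect_true(all(ratio[!msr] >= 0.8 & ratio[!msr] <= 1.25))
})

test_that("missing chromosomes in the depth table are reported by name", {
  samples <- c("m1", "m2", "f1", "f2")
  gt <- make_geno(
    data.frame(chrom = "chrB", pos = 10, ref = "A", alt = "T"),
    matrix(0L, 1, 4, dimnames = list(NULL, samples)),
    c("male", "male", "female", "female")
  )
  depth <- flat_depth("chrA", 200, 100, samples)
  expect_error(window_scan(gt, depth, 100), "chrB")
})

test_that("noiseless step series yields the exact breakpoint", {
  x <- c(rep(0.05, 50), rep(0.60, 50))
  expect_equal(changepoint_segment(x), 50L)
  expect_equal(oracle_single_split(x), 50L)
})

test_that("constant series yields no breakpoints", {
  expect_equal(changepoint_segment(rep(0.3, 80)), integer(0))
  expect_equal(changepoint_segment(numeric(0)), integer(0))
})

test_that("noisy step recovery lands within two windows in most seeds", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rep(0.05, 50), rep(0.60, 50)) + rnorm(100, sd = 0.05)
    bp <- changepoint_segment(x)
    if (length(bp) > 0 && min(abs(bp - 50)) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("binary segmentation agrees with the exhaustive single-split oracle", {
  set.seed(33)
  for (i in 1:10) {
    left <- runif(1, 0, 0.2); right <- left + runif(1, 0.3, 0.6)
    x <- c(rep(left, 40), rep(right, 60)) + rnorm(100, sd = 0.02)
    bp <- changepoint_segment(x, min_seg = 3)
    expect_equal(bp[1], oracle_single_split(x, min_seg = 3))
  }
})

test_that("residual error never increases as breakpoints are added", {
  set.seed(44)
  x <- c(rep(0, 30), rep(1, 30), rep(0.2, 40)) + rnorm(100, sd = 0.1)
  sse_for <- function(bps) {
    bounds <- c(0, sort(bps), length(x))
    sum(vapply(seq_len(length(bounds) - 1), function(k) {
      seg <- x[(bounds[k] + 1):bounds[k + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  bps <- changepoint_segment(x)
  expect_gte(length(bps), 1L)
  prev <- sse_for(integer(0))
  for (k in seq_along(bps)) {
    cur <- sse_for(bps[1:k])
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("the planted MSR is called exactly and both flags are required", {
  cfg <- msr_scenario_config(seed = 2)
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  res <- detect_msr(vs$genotypes, vs$depth)
  expect_s3_class(res$call, "msr_call")
  expect_equal(res$call$chrom, gen$truth$msr_chrom)
  expect_equal(res$call$start, 0)
  expect_equal(res$call$end, 4e5)
  expect_true(res$call$fst_elevated && res$call$female_depth_depleted)

  # elevated FST but normal female depth -> no call (AND semantics)
  w <- res$windows
  flat <- w
  flat$female_depth <- flat$male_depth
  expect_null(call_msr(flat, res$breakpoints))

  # depleted depth but flat FST -> no call either
  nofst <- w
  nofst$mean_fst <- 0.001
  nofst$mean_fst[1] <- -0.001  # keep a nonzero spread so the median is defined
  expect_null(call_msr(nofst, lapply(res$breakpoints, function(b) integer(0))))
})

test_that("autosome-only simulations never produce an MSR call", {
  cfg <- small_config(seed = 3, msr_fixed_diff_fraction = 0,
                      msr_female_depth_factor = 1)
  # neutralise the depth contrast too: females keep full depth
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  res <- detect_msr(vs$genotypes, vs$depth, window_size = cfg$window_size)
  expect_null(res$call)
})

test_that("sex-label permutation kills the MSR call on autosomal data", {
  cfg <- small_config(seed = 8, msr_fixed_diff_fraction = 0,
                      msr_female_depth_factor = 1)
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  accepted <- 0L
  set.seed(99)
  for (p in 1:20) {
    gt <- vs$genotypes
    gt$sex[] <- sample(gt$sex)
    res <- detect_msr(gt, vs$depth, window_size = cfg$window_size)
    if (!is.null(res$call)) accepted <- accepted + 1L
  }
  expect_equal(accepted, 0L)
})

test_that("copy number arithmetic and planted hemizygosity are exact", {
  # direct arithmetic: gene depth 15 vs median 30 -> cn 1; 30 vs 30 -> 2
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrA",
                      start = c(0, 100), end = c(100, 200),
                      stringsAsFactors = FALSE)
  depth <- data.frame(chrom = "chrA",
                      window_start = c(0, 100, 200, 300, 400),
                      window_end = c(100, 200, 300, 400, 500),
                      sample = "s1",
                      mean_depth = c(15, 30, 30, 30, 30))
  cn <- estimate_copy_number(genes, depth)
  expect_equal(cn$cn, c(1, 2))
  expect_equal(cn$rounded_cn, c(1L, 2L))

  cfg <- small_config(seed = 6)
  gen <- simulate_genome(cfg)
  vs <- simulate_sexed_variation(cfg, gen$truth, gen$genome)
  cn <- estimate_copy_number(gen$truth$genes, vs$depth)
  cn$sex <- substr(cn$sample, 1, 1)
  msr_genes <- gen$truth$msr_gene_ids
  expect_gt(length(msr_genes), 0)
  in_msr <- cn$gene_id %in% msr_genes
  expect_true(all(cn$rounded_cn[in_msr & cn$sex == "M"] == 1L))
  expect_true(all(cn$rounded_cn[in_msr & cn$sex == "F"] == 0L))
  expect_true(all(cn$rounded_cn[!in_msr] == 2L))
})

test_that("a gene with no covering depth window yields NA copy number", {
  genes <- data.frame(gene_id = "g1", chrom = "chrB", start = 0, end = 100,
                      stringsAsFactors = FALSE)
  depth <- data.frame(chrom = "chrA", window_start = 0, window_end = 100,
                      sample = "s1", mean_depth = 30)
  cn <- estimate_copy_number(genes, depth)
  expect_true(is.na(cn$cn))
})
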