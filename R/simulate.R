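# Deterministic simulator for every pipeline input, with planted ground
# truth. All randomness flows from a single integer seed; each stage draws
# from its own derived stream (see stage_seed) so outputs are byte-stable.

#' Simulation configuration
#'
#' Builds and validates the configuration object that fully determines a
#' simulated dataset. Defaults describe the study conditions the pipeline is
#' benchmarked under: a few-hundred-kb multi-chromosome genome with telomeric
#' heptamer arrays at every end, one 162-bp centromeric tandem array, a
#' male-limited region (MSR) at the start of the last chromosome with
#' male-specific alleles and near-zero female read depth, binomial cytosine
#' methylation with an MSR hypermethylation boost, and an expression design of
#' 2 sexes x 3 developmental stages x 3 replicates with planted TF-to-target
#' regulation.
#'
#' @param seed Integer seed; fully determines every emitted file.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @param telomere_copies_per_end Tandem copies of the 7-bp telomere motif at
#'   each chromosome end.
#' @param centromere_monomer Monomer sequence for the centromeric array;
#'   `NULL` draws a random 162-bp monomer.
#' @param centromere_copies Tandem copies of the monomer.
#' @param centromere_chrom Chromosome (index) carrying the centromeric array.
#' @param msr_chrom Chromosome (index) carrying the male-specific region.
#' @param msr_interval Numeric `(start, end)` of the MSR in 0-based half-open
#'   bp on `msr_chrom`.
#' @param n_males,n_females Number of sexed samples (>= 2 each).
#' @param snp_density SNP sites per kb.
#' @param msr_fixed_diff_fraction Fraction of MSR SNP sites carrying
#'   male-limited alleles (all males heterozygous carriers, all females
#'   homozygous reference).
#' @param depth_mean Mean autosomal read depth per sample.
#' @param msr_female_depth_factor Mean female depth inside the MSR as a
#'   fraction of `depth_mean` (hemizygous males get 0.5).
#' @param window_size Depth/scan window in bp (default 100 kb).
#' @param n_genes Total single-exon gene models.
#' @param gene_length Gene length in bp.
#' @param n_tfs Number of transcription-factor genes.
#' @param targets_per_tf Targets regulated by each TF.
#' @param expr_noise_sd Gaussian noise sd on target abundances (log2 units).
#' @param meth_depth_range Integer `(min, max)` read depth per cytosine.
#' @param meth_level_by_context Named baseline methylation fractions for
#'   CG/CHG/CHH. Defaults are typical plant genome-wide levels.
#' @param msr_meth_boost Additive methylation fraction inside the MSR.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       telomere_copies_per_end = 300L,
                       centromere_monomer = NULL,
                       centromere_copies = 200L,
                       centromere_chrom = 1L,
                       msr_chrom = n_chroms,
                       msr_interval = c(0, 4e5),
                       n_males = 10L,
                       n_females = 10L,
                       snp_density = 0.5,
                       msr_fixed_diff_fraction = 0.8,
                       depth_mean = 30,
                       msr_female_depth_factor = 0.02,
                       window_size = 1e5,
                       n_genes = 60L,
                       gene_length = 1000L,
                       n_tfs = 5L,
                       targets_per_tf = 2L,
                       expr_noise_sd = 0.05,
                       meth_depth_range = c(10L, 50L),
                       meth_level_by_context = c(CG = 0.498, CHG = 0.279, CHH = 0.028),
                       msr_meth_boost = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.numeric(chrom_length),
    telomere_copies_per_end = as.integer(telomere_copies_per_end),
    centromere_monomer = centromere_monomer,
    centromere_copies = as.integer(centromere_copies),
    centromere_chrom = as.integer(centromere_chrom),
    msr_chrom = as.integer(msr_chrom),
    msr_interval = as.numeric(msr_interval),
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    snp_density = snp_density,
    msr_fixed_diff_fraction = msr_fixed_diff_fraction,
    depth_mean = depth_mean,
    msr_female_depth_factor = msr_female_depth_factor,
    window_size = as.numeric(window_size),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
    expr_noise_sd = expr_noise_sd,
    meth_depth_range = as.integer(meth_depth_range),
    meth_level_by_context = meth_level_by_context,
    msr_meth_boost = msr_meth_boost
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0)
  tel_len <- 7 * cfg$telomere_copies_per_end
  if (2 * tel_len >= cfg$chrom_length) {
    stop("telomere arrays longer than the chromosome")
  }
  if (cfg$msr_chrom < 1L || cfg$msr_chrom > cfg$n_chroms) {
    stop("msr_chrom out of range")
  }
  mi <- cfg$msr_interval
  if (length(mi) != 2L || mi[1] < 0 || mi[2] <= mi[1] || mi[2] > cfg$chrom_length) {
    stop("msr_interval must be a half-open interval within [0, chrom_length)")
  }
  fracs <- c(cfg$msr_fixed_diff_fraction, cfg$msr_meth_boost,
             cfg$msr_female_depth_factor, cfg$meth_level_by_context)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$meth_level_by_context))) {
    stop("meth_level_by_context needs CG, CHG and CHH entries")
  }
  stopifnot(cfg$meth_depth_range[1] >= 1L,
            cfg$meth_depth_range[2] >= cfg$meth_depth_range[1])
  if (cfg$n_tfs + cfg$n_tfs * cfg$targets_per_tf > cfg$n_genes) {
    stop("regulatory network larger than gene catalogue: ",
         "n_tfs * (1 + targets_per_tf) must be <= n_genes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: seed", x$seed, "|", x$n_chroms, "chromosomes x",
      format(x$chrom_length, big.mark = ",", scientific = FALSE), "bp\n")
  cat("  MSR: chr", x$msr_chrom, sprintf("[%.0f, %.0f)", x$msr_interval[1],
      x$msr_interval[2]), "| fixed-diff fraction",
      x$msr_fixed_diff_fraction, "\n")
  cat("  Samples:", x$n_males, "males,", x$n_females,
      "females | depth", x$depth_mean, "\n")
  cat("  Genes:", x$n_genes, "| TFs:", x$n_tfs, "x", x$targets_per_tf,
      "targets | noise sd", x$expr_noise_sd, "\n")
  invisible(x)
}

#' Simulate a genome with planted telomeres, centromere, genes and motifs
#'
#' Each chromosome begins with tandem `CCCTAAA` copies and ends with tandem
#' `TTTAGGG` copies; exactly one chromosome carries a centromeric tandem
#' array; background sequence is i.i.d. uniform ACGT. Single-exon gene models
#' are laid out on alternating strands; each TF's 8-bp consensus motif is
#' planted in the 2-kb promoter of each of its targets so promoter scanning
#' can recover the regulatory structure. All planted features are recorded in
#' the returned ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `truth` (a `ground_truth` list recording all planted intervals, gene
#'   models, the TF-to-target map and motif consensi).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "genome", {
    n <- config$n_chroms
    len <- config$chrom_length
    tel5 <- strrep("CCCTAAA", config$telomere_copies_per_end)
    tel3 <- strrep("TTTAGGG", config$telomere_copies_per_end)
    tel_len <- nchar(tel5)
    chrom_names <- sprintf("chr%02d", seq_len(n))

    seqs <- vapply(seq_len(n), function(i) {
      paste0(tel5, rand_dna(len - 2 * tel_len), tel3)
    }, character(1))
    names(seqs) <- chrom_names

    telomeres <- data.frame(
      chrom = rep(chrom_names, each = 2L),
      start = rep(c(0, len - tel_len), n),
      end = rep(c(tel_len, len), n),
      end_of_chrom = rep(c("five_prime", "three_prime"), n),
      stringsAsFactors = FALSE
    )

    monomer <- config$centromere_monomer
    if (is.null(monomer)) monomer <- rand_dna(162L)
    array_seq <- strrep(monomer, config$centromere_copies)
    cen_len <- nchar(array_seq)
    cen_chrom <- chrom_names[config$centromere_chrom]
    cen_start <- floor((len - cen_len) / 2)
    if (cen_start < tel_len || cen_start + cen_len > len - tel_len) {
      stop("centromeric array overlaps a telomere; shorten the array or ",
           "lengthen the chromosome")
    }
    if (config$centromere_chrom == config$msr_chrom &&
        interval_overlap(cen_start, cen_start + cen_len,
                         config$msr_interval[1], config$msr_interval[2]) > 0) {
      stop("centromeric array overlaps the planted MSR interval")
    }
    seqs[cen_chrom] <- splice_string(seqs[cen_chrom], cen_start, array_seq)

    genes <- place_genes(config, chrom_names, tel_len,
                         cen_chrom, cen_start, cen_start + cen_len)

    ## regulatory structure: TFs are the first n_tfs genes outside the MSR,
    ## targets the following genes (non-TF only, acyclic at depth 1)
    msr_chrom_name <- chrom_names[config$msr_chrom]
    in_msr <- genes$chrom == msr_chrom_name &
      genes$start < config$msr_interval[2] &
      genes$end > config$msr_interval[1]
    non_msr_ids <- genes$gene_id[!in_msr]
    need <- config$n_tfs * (1L + config$targets_per_tf)
    if (length(non_msr_ids) < need) {
      stop("not enough non-MSR genes to host the planted regulatory network")
    }
    tf_ids <- non_msr_ids[seq_len(config$n_tfs)]
    target_pool <- non_msr_ids[config$n_tfs + seq_len(config$n_tfs * config$targets_per_tf)]
    tf_target_map <- split(target_pool,
                           rep(tf_ids, each = config$targets_per_tf))
    tf_target_map <- tf_target_map[tf_ids]

    ## plant each TF's consensus motif mid-promoter of each target
    motifs <- stats::setNames(vapply(tf_ids, function(i) rand_dna(8L),
                                     character(1)), tf_ids)
    for (tf in tf_ids) {
      cons <- motifs[[tf]]
      for (tg in tf_target_map[[tf]]) {
        g <- genes[genes$gene_id == tg, ]
        if (g$strand == "+") {
          at <- g$start - 1000L
          seqs[g$chrom] <- splice_string(seqs[g$chrom], at, cons)
        } else {
          at <- g$end + 1000L - 8L
          seqs[g$chrom] <- splice_string(seqs[g$chrom], at, revcomp(cons))
        }
      }
    }

    truth <- list(
      chrom_names = chrom_names,
      chrom_length = len,
      msr_chrom = msr_chrom_name,
      msr_interval = config$msr_interval,
      telomere_intervals = telomeres,
      centromere_interval = list(chrom = cen_chrom, start = cen_start,
                                 end = cen_start + cen_len, monomer = monomer),
      genes = genes,
      msr_gene_ids = genes$gene_id[in_msr],
      tf_ids = tf_ids,
      tf_target_map = tf_target_map,
      motifs = motifs,
      meth_level_by_context = config$meth_level_by_context,
      msr_meth_boost = config$msr_meth_boost
    )
    class(truth) <- "ground_truth"
    list(genome = Biostrings::DNAStringSet(seqs), truth = truth)
  })
}

# Deterministic gene layout: evenly spaced single-exon genes on alternating
# strands, clear of telomeres and the centromeric array (incl. 2-kb promoter
# clearance on both sides).
place_genes <- function(config, chrom_names, tel_len, cen_chrom,
                        cen_start, cen_end) {
  n <- length(chrom_names)
  per_chrom <- diff(c(0, round(seq_len(n) * config$n_genes / n)))
  glen <- config$gene_length
  margin <- 2500L
  rows <- list()
  k <- 0L
  for (i in seq_len(n)) {
    chrom <- chrom_names[i]
    lo <- tel_len + margin
    hi <- config$chrom_length - tel_len - margin - glen
    if (per_chrom[i] == 0L) next
    starts <- round(seq(lo, hi, length.out = per_chrom[i]))
    if (chrom == cen_chrom) {
      bad <- starts + glen + margin > cen_start & starts - margin < cen_end
      starts[bad] <- NA
    }
    starts <- starts[!is.na(starts)]
    for (s in starts) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("gene%04d", k), chrom = chrom,
        start = s, end = s + glen,
        strand = if (k %% 2L == 1L) "+" else "-",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate sexed genotypes and windowed read depth
#'
#' Outside the MSR, allele frequencies are drawn once per site and shared by
#' both sexes. Inside the MSR, a fraction `msr_fixed_diff_fraction` of sites
#' is male-limited: every male is an 0/1 heterozygous carrier (the diploid
#' VCF encoding of hemizygosity) and every female is homozygous reference.
#' Window depth is Poisson-like around `depth_mean`, except in MSR windows
#' where male depth has mean `0.5 * depth_mean` (one haplotype) and female
#' depth mean `msr_female_depth_factor * depth_mean`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @param genome Genome from [simulate_genome()] (used for reference alleles).
#' @return List with `genotypes` (class `sexed_genotypes`: `sites` data frame,
#'   integer dosage `geno` matrix sites x samples, `sex` factor) and `depth`
#'   (long data frame: chrom, window_start, window_end, sample, mean_depth).
#' @export
simulate_sexed_variation <- function(config, truth, genome) {
  validate_sim_config(config)
  if (config$n_males < 2L || config$n_females < 2L) {
    stop("need at least 2 samples per sex (FST is undefined otherwise)")
  }
  chars <- genome_chars(genome)
  with_stage_seed(config$seed, "variation", {
    tel_len <- 7 * config$telomere_copies_per_end
    len <- config$chrom_length
    samples <- c(sprintf("M%02d", seq_len(config$n_males)),
                 sprintf("F%02d", seq_len(config$n_females)))
    sex <- factor(rep(c("male", "female"), c(config$n_males, config$n_females)),
                  levels = c("male", "female"))

    site_rows <- list()
    geno_rows <- list()
    for (chrom in truth$chrom_names) {
      n_sites <- round(config$snp_density * len / 1000)
      pos0 <- sort(unique(floor(runif(n_sites, tel_len, len - tel_len))))
      refs <- substring(chars[chrom], pos0 + 1, pos0 + 1)
      alts <- vapply(refs, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }, character(1), USE.NAMES = FALSE)
      in_msr <- chrom == truth$msr_chrom &
        pos0 >= truth$msr_interval[1] & pos0 < truth$msr_interval[2]
      limited <- in_msr & runif(length(pos0)) < config$msr_fixed_diff_fraction

      g <- matrix(0L, nrow = length(pos0), ncol = length(samples),
                  dimnames = list(NULL, samples))
      shared <- !limited
      p <- runif(sum(shared), 0.05, 0.95)
      g[shared, ] <- matrix(rbinom(sum(shared) * length(samples), 2L,
                                   rep(p, length(samples))),
                            nrow = sum(shared))
      g[limited, sex == "male"] <- 1L
      g[limited, sex == "female"] <- 0L

      site_rows[[chrom]] <- data.frame(
        chrom = chrom, pos = pos0 + 1L, ref = refs, alt = alts,
        msr_limited = limited, stringsAsFactors = FALSE
      )
      geno_rows[[chrom]] <- g
    }
    sites <- do.call(rbind, site_rows)
    rownames(sites) <- NULL
    geno <- do.call(rbind, geno_rows)

    depth <- simulate_depth(config, truth, samples, sex)

    genotypes <- structure(
      list(sites = sites, geno = geno, sex = stats::setNames(sex, samples)),
      class = "sexed_genotypes"
    )
    list(genotypes = genotypes, depth = depth)
  })
}

simulate_depth <- function(config, truth, samples, sex) {
  len <- config$chrom_length
  w <- config$window_size
  starts <- seq(0, len - 1, by = w)
  ends <- pmin(starts + w, len)
  rows <- list()
  for (chrom in truth$chrom_names) {
    msr_frac <- if (chrom == truth$msr_chrom) {
      interval_overlap(starts, ends, truth$msr_interval[1],
                       truth$msr_interval[2]) / (ends - starts)
    } else {
      rep(0, length(starts))
    }
    for (j in seq_along(samples)) {
      factor_msr <- if (sex[j] == "male") 0.5 else config$msr_female_depth_factor
      lambda <- config$depth_mean * (1 - msr_frac) +
        config$depth_mean * factor_msr * msr_frac
      kb <- (ends - starts) / 1000
      mean_depth <- rpois(length(starts), lambda * kb) / kb
      rows[[paste(chrom, samples[j])]] <- data.frame(
        chrom = chrom, window_start = starts, window_end = ends,
        sample = samples[j], mean_depth = mean_depth,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sexed_genotypes <- function(x, ...) {
  cat("Sexed genotypes:", nrow(x$sites), "biallelic SNP sites x",
      ncol(x$geno), "samples (", sum(x$sex == "male"), "male /",
      sum(x$sex == "female"), "female )\n")
  invisible(x)
}

#' Simulate the expression matrix and differential-expression statistics
#'
#' The design is 2 sexes x 3 developmental stages (A, B, C) x 3 replicates.
#' Each TF's abundance (log2 scale) has a sex-by-stage group mean drawn from
#' N(0, 1) plus replicate noise; each planted target equals
#' `weight * TF + N(0, expr_noise_sd)` with `weight` drawn from {-1, +1}.
#' Non-network genes are independent N(0, 1). A two-sample t-test between
#' sexes per gene supplies the fold-change/p-value table that downstream
#' differential-expression filtering consumes (emulating an external DE tool).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @return List with `expr` (genes x samples numeric matrix, log2 abundance),
#'   `samples` (data frame: sample, sex, stage, rep), `deg_stats` (gene,
#'   log2_fold_change, p_value) and `weights` (named per-target weights).
#' @export
simulate_expression <- function(config, truth) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "expression", {
    stages <- c("A", "B", "C")
    design <- expand.grid(rep = 1:3, stage = stages, sex = c("F", "M"),
                          stringsAsFactors = FALSE)[, 3:1]
    sample_names <- sprintf("%s%s_r%d", design$sex, design$stage, design$rep)
    n_samp <- nrow(design)
    group <- paste(design$sex, design$stage)

    genes <- truth$genes$gene_id
    expr <- matrix(rnorm(length(genes) * n_samp), nrow = length(genes),
                   dimnames = list(genes, sample_names))

    weights <- numeric(0)
    for (tf in truth$tf_ids) {
      mu <- stats::setNames(rnorm(length(unique(group))), unique(group))
      tf_prof <- mu[group] + rnorm(n_samp, sd = config$expr_noise_sd)
      expr[tf, ] <- tf_prof
      for (tg in truth$tf_target_map[[tf]]) {
        w <- sample(c(-1, 1), 1L)
        weights[tg] <- w
        expr[tg, ] <- w * tf_prof + rnorm(n_samp, sd = config$expr_noise_sd)
      }
    }

    male <- design$sex == "M"
    deg_stats <- data.frame(
      gene = genes,
      log2_fold_change = rowMeans(expr[, male, drop = FALSE]) -
        rowMeans(expr[, !male, drop = FALSE]),
      p_value = apply(expr, 1L, function(v) {
        stats::t.test(v[male], v[!male])$p.value
      }),
      stringsAsFactors = FALSE
    )
    rownames(deg_stats) <- NULL

    list(expr = expr,
         samples = data.frame(sample = sample_names, sex = design$sex,
                              stage = design$stage, rep = design$rep,
                              stringsAsFactors = FALSE),
         deg_stats = deg_stats,
         weights = weights)
  })
}

#' Simulate a per-cytosine methylome
#'
#' Every cytosine on both strands receives its sequence context (CG/CHG/CHH),
#' a total read count drawn uniformly from `meth_depth_range`, and a
#' methylated read count drawn binomially with the per-context baseline
#' probability, boosted additively by `msr_meth_boost` inside the MSR
#' (clamped to 1).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @param genome Genome from [simulate_genome()].
#' @return Data frame: chrom, pos (1-based), strand, context, n_meth, n_total.
#' @export
simulate_methylome <- function(config, truth, genome) {
  validate_sim_config(config)
  chars <- genome_chars(genome)
  with_stage_seed(config$seed, "methylome", {
    rows <- lapply(truth$chrom_names, function(chrom) {
      ctx <- cytosine_contexts(chars[[chrom]])
      if (nrow(ctx) == 0L) return(NULL)
      n <- nrow(ctx)
      depth <- sample(seq(config$meth_depth_range[1], config$meth_depth_range[2]),
                      n, replace = TRUE)
      p <- unname(config$meth_level_by_context[ctx$context])
      in_msr <- chrom == truth$msr_chrom &
        (ctx$pos - 1L) >= truth$msr_interval[1] &
        (ctx$pos - 1L) < truth$msr_interval[2]
      p <- pmin(1, p + config$msr_meth_boost * in_msr)
      data.frame(chrom = chrom, pos = ctx$pos, strand = ctx$strand,
                 context = ctx$context, n_meth = rbinom(n, depth, p),
                 n_total = depth, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# All cytosines of one chromosome string (both strands) with their contexts,
# vectorised. Sites within 2 bp of the relevant sequence end are dropped.
cytosine_contexts <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  # + strand: C at i, context from b[i+1], b[i+2]
  ip <- which(b == "C")
  ip <- ip[ip <= n - 2L]
  ctx_p <- ifelse(b[ip + 1L] == "G", "CG",
                  ifelse(b[ip + 2L] == "G", "CHG", "CHH"))
  # - strand: G at i (C on the reverse strand), context from b[i-1], b[i-2]
  im <- which(b == "G")
  im <- im[im >= 3L]
  ctx_m <- ifelse(b[im - 1L] == "C", "CG",
                  ifelse(b[im - 2L] == "C", "CHG", "CHH"))
  out <- data.frame(
    pos = c(ip, im),
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(ctx_p, ctx_m),
    stringsAsFactors = FALSE
  )
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Simulate a complete dataset and write every pipeline input to disk
#'
#' Runs all simulation stages and writes: genome FASTA, variants VCF v4.2,
#' sex-label TSV, windowed depth TSV, methylation TSV, expression TSV,
#' DE-statistics TSV, gene models GFF3, TF list TSV, motif library
#' (JASPAR-style) and the ground-truth JSON.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config)
  vs <- simulate_sexed_variation(config, gen$truth, gen$genome)
  ex <- simulate_expression(config, gen$truth)
  me <- simulate_methylome(config, gen$truth, gen$genome)

  p <- list(
    genome = file.path(dir, "genome.fasta"),
    vcf = file.path(dir, "variants.vcf"),
    sex = file.path(dir, "sex_labels.tsv"),
    depth = file.path(dir, "depth.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    deg_stats = file.path(dir, "deg_stats.tsv"),
    genes = file.path(dir, "genes.gff3"),
    tf_list = file.path(dir, "tf_list.tsv"),
    motifs = file.path(dir, "motifs.jaspar"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_genome_fasta(gen$genome, p$genome)
  write_vcf(vs$genotypes, p$vcf)
  write_sex_labels(vs$genotypes$sex, p$sex)
  write_depth_tsv(vs$depth, p$depth)
  write_meth_tsv(me, p$methylation)
  write_expression_tsv(ex$expr, p$expression)
  utils::write.table(ex$deg_stats, p$deg_stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gff3(gen$truth$genes, p$genes)
  utils::write.table(
    data.frame(tf_id = gen$truth$tf_ids, motif_id = gen$truth$tf_ids),
    p$tf_list, sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_jaspar(consensus_pwms(gen$truth$motifs), p$motifs)
  write_ground_truth(gen$truth, p$truth)
  invisible(list(paths = p, truth = gen$truth))
}

# Strong count PWMs (97:1:1:1 per column) from consensus strings.
consensus_pwms <- function(motifs) {
  lapply(motifs, function(cons) {
    b <- strsplit(cons, "", fixed = TRUE)[[1]]
    m <- matrix(1, nrow = 4, ncol = length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(b)) m[b[j], j] <- 97
    m
  })
}
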