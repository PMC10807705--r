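# Male-specific-region detection: per-site FST and pi, windowed statistics,
# penalised changepoint segmentation, the MSR call, and depth-based gene
# copy number.

#' Per-site FST between two populations from allele counts
#'
#' Default is the Hudson estimator with finite-sample bias correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, where `p` are alternate-allele frequencies and `n`
#' total allele counts. Values may be negative (retained, not clamped);
#' a zero denominator yields `NA`. `method = "wc"` gives the Weir-Cockerham
#' theta for haploid allele-count data as an alternative.
#'
#' @param alt1,total1 Alternate and total allele counts in population 1
#'   (vectors recycle).
#' @param alt2,total2 Same for population 2.
#' @param method `"hudson"` (default) or `"wc"`.
#' @return Numeric vector of per-site FST values (`NA` where undefined).
#' @export
site_fst <- function(alt1, total1, alt2, total2, method = c("hudson", "wc")) {
  method <- match.arg(method)
  bad <- total1 < 2 | total2 < 2
  if (any(bad)) {
    warning("sites with fewer than 2 alleles in a group set to NA")
  }
  p1 <- alt1 / total1
  p2 <- alt2 / total2
  if (method == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (total1 - 1) -
      p2 * (1 - p2) / (total2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(den == 0, NA_real_, num / den)
  } else {
    n1 <- total1; n2 <- total2
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # df = r - 1 = 1
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
    nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
    den <- msp + (nc - 1) * msg
    fst <- ifelse(den == 0, NA_real_, (msp - msg) / den)
  }
  fst[bad] <- NA_real_
  fst
}

#' Per-site nucleotide diversity (pi) from allele counts
#'
#' Unbiased per-site heterozygosity `2 * alt * (total - alt) /
#' (total * (total - 1))`, i.e. the probability that two alleles drawn
#' without replacement differ. Window-level pi is the sum over SNP sites
#' divided by the window length in bp (computed in [window_scan()]).
#'
#' @param alt Alternate-allele count(s).
#' @param total Total allele count(s); values below 2 yield `NA`.
#' @return Numeric vector.
#' @export
site_pi <- function(alt, total) {
  ifelse(total < 2, NA_real_, 2 * alt * (total - alt) / (total * (total - 1)))
}

# Per-sex allele counts at every site (missing genotypes excluded).
sex_allele_counts <- function(genotypes) {
  male <- names(genotypes$sex)[genotypes$sex == "male"]
  female <- names(genotypes$sex)[genotypes$sex == "female"]
  gm <- genotypes$geno[, male, drop = FALSE]
  gf <- genotypes$geno[, female, drop = FALSE]
  list(
    alt_m = rowSums(gm, na.rm = TRUE),
    tot_m = 2 * rowSums(!is.na(gm)),
    alt_f = rowSums(gf, na.rm = TRUE),
    tot_f = 2 * rowSums(!is.na(gf))
  )
}

#' Windowed FST, pi and depth along the genome
#'
#' Tiles each chromosome with the non-overlapping windows of the depth table
#' (which must align to `window_size`; the last window may be short) and
#' summarises per window: the mean of defined per-site Hudson FST values,
#' per-sex pi (sum of per-site heterozygosity / window length), per-sex mean
#' depth, and the SNP count. Windows without SNPs carry `NA` FST and zero pi
#' (a monomorphic window has no diversity) but always valid depth.
#'
#' @param genotypes A `sexed_genotypes` object (see
#'   [simulate_sexed_variation()] or [read_vcf()]).
#' @param depth Long-format depth table: chrom, window_start, window_end,
#'   sample, mean_depth.
#' @param window_size Window width in bp.
#' @return Data frame of class `window_stats`: chrom, start, end, mean_fst,
#'   pi_male, pi_female, male_depth, female_depth, n_snps.
#' @export
window_scan <- function(genotypes, depth, window_size = 1e5) {
  frame <- unique(depth[, c("chrom", "window_start", "window_end")])
  frame <- frame[order(frame$chrom, frame$window_start), ]
  widths <- frame$window_end - frame$window_start
  if (any(widths <= 0) || any(widths > window_size)) {
    stop("malformed depth windows")
  }
  if (!all(frame$window_start %% window_size == 0)) {
    stop("depth windows do not align to window_size = ", window_size)
  }

  missing_chrom <- setdiff(unique(genotypes$sites$chrom), frame$chrom)
  if (length(missing_chrom) > 0L) {
    stop("chromosome absent from depth table: ",
         paste(missing_chrom, collapse = ", "))
  }

  cnt <- sex_allele_counts(genotypes)
  fst <- suppressWarnings(
    site_fst(cnt$alt_m, cnt$tot_m, cnt$alt_f, cnt$tot_f)
  )
  pim <- site_pi(cnt$alt_m, cnt$tot_m)
  pif <- site_pi(cnt$alt_f, cnt$tot_f)

  key <- paste(genotypes$sites$chrom,
               sprintf("%.0f", (genotypes$sites$pos - 1) %/% window_size * window_size))
  fkey <- paste(frame$chrom, sprintf("%.0f", frame$window_start))

  agg <- function(x, f) {
    v <- tapply(x, key, f)
    out <- as.numeric(v[fkey])
    out
  }
  mean_fst <- agg(fst, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  sum_pi_m <- agg(pim, function(v) sum(v, na.rm = TRUE))
  sum_pi_f <- agg(pif, function(v) sum(v, na.rm = TRUE))
  n_snps <- agg(rep(1L, length(key)), length)
  n_snps[is.na(n_snps)] <- 0L
  sum_pi_m[is.na(sum_pi_m)] <- 0
  sum_pi_f[is.na(sum_pi_f)] <- 0

  is_male <- depth$sample %in% names(genotypes$sex)[genotypes$sex == "male"]
  dkey <- paste(depth$chrom, sprintf("%.0f", depth$window_start))
  md <- tapply(depth$mean_depth[is_male], dkey[is_male], mean)
  fd <- tapply(depth$mean_depth[!is_male], dkey[!is_male], mean)

  out <- data.frame(
    chrom = frame$chrom, start = frame$window_start, end = frame$window_end,
    mean_fst = mean_fst,
    pi_male = sum_pi_m / widths, pi_female = sum_pi_f / widths,
    male_depth = as.numeric(md[fkey]), female_depth = as.numeric(fd[fkey]),
    n_snps = n_snps, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Penalised binary-segmentation changepoints of a window-mean series
#'
#' Recursive binary segmentation minimising within-segment squared error.
#' A split is accepted when its squared-error reduction exceeds a BIC-style
#' per-breakpoint penalty `penalty * log(n) * sigma2`, with `sigma2`
#' estimated robustly as `var(diff(series)) / 2`. Missing values are linearly
#' imputed from neighbours before segmentation. Breakpoints are reported as
#' the number of windows left of each boundary, so boundary positions in bp
#' are `breakpoint * window_size`.
#'
#' @param series Numeric vector of window means (may contain `NA`).
#' @param penalty Penalty multiplier (unitless).
#' @param min_seg Minimum segment length in windows.
#' @return Sorted integer vector of breakpoints (possibly empty).
#' @export
changepoint_segment <- function(series, penalty = 1, min_seg = 3L) {
  n <- length(series)
  if (n < 2L * min_seg) return(integer(0))
  x <- impute_linear(series)
  s2 <- stats::var(diff(x))
  sigma2 <- if (is.finite(s2)) s2 / 2 else 0
  pen <- penalty * log(n) * sigma2
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_sse <- function(i, j) {  # inclusive 1-based bounds
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    q <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    q - s^2 / (j - i + 1L)
  }
  bps <- integer(0)
  recurse <- function(i, j) {
    if (j - i + 1L < 2L * min_seg) return(invisible())
    cand <- seq.int(i + min_seg - 1L, j - min_seg)
    sses <- vapply(cand, function(b) seg_sse(i, b) + seg_sse(b + 1L, j),
                   numeric(1))
    b <- cand[which.min(sses)]
    gain <- seg_sse(i, j) - min(sses)
    if (gain > pen + 1e-12) {
      bps <<- c(bps, b)
      recurse(i, b)
      recurse(b + 1L, j)
    }
    invisible()
  }
  recurse(1L, n)
  sort(bps)
}

impute_linear <- function(x) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) return(rep(0, length(x)))
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
}

#' Call the male-specific region from windowed statistics
#'
#' Segments each chromosome's window-mean FST series at the supplied
#' breakpoints and accepts segments that satisfy both lines of evidence:
#' mean FST at least `fst_fold` times the genome-wide median window FST
#' (elevated between-sex differentiation) AND a female-to-male mean depth
#' ratio at most `depth_ratio_max` (female depletion expected under male
#' hemizygosity). If several segments qualify, the one with the highest mean
#' FST is returned; `NULL` if none does.
#'
#' @param windows A `window_stats` data frame from [window_scan()].
#' @param breakpoints Named list (per chromosome) of breakpoint vectors from
#'   [changepoint_segment()]; `NULL` computes them with the given `penalty`
#'   and `min_seg`.
#' @param fst_fold FST elevation factor over the genome-wide median.
#' @param depth_ratio_max Maximum female/male depth ratio.
#' @param penalty,min_seg Passed to [changepoint_segment()] when
#'   `breakpoints` is `NULL`.
#' @return A list of class `msr_call` (chrom, start, end, mean_fst_inside,
#'   mean_fst_outside, female_to_male_depth_ratio, evidence flags), or
#'   `NULL` when no segment qualifies.
#' @export
call_msr <- function(windows, breakpoints = NULL, fst_fold = 3,
                     depth_ratio_max = 0.2, penalty = 1, min_seg = 3L) {
  chroms <- unique(windows$chrom)
  if (is.null(breakpoints)) {
    breakpoints <- lapply(stats::setNames(chroms, chroms), function(ch) {
      changepoint_segment(windows$mean_fst[windows$chrom == ch],
                          penalty = penalty, min_seg = min_seg)
    })
  }
  med_fst <- stats::median(windows$mean_fst, na.rm = TRUE)
  best <- NULL
  for (ch in chroms) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    bp <- breakpoints[[ch]]
    bounds <- c(0L, sort(bp), nrow(w))
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      seg <- w[idx, , drop = FALSE]
      mfst <- mean(seg$mean_fst, na.rm = TRUE)
      if (!is.finite(mfst)) next
      ratio <- mean(seg$female_depth) / mean(seg$male_depth)
      fst_ok <- mfst >= fst_fold * med_fst
      depth_ok <- ratio <= depth_ratio_max
      if (fst_ok && depth_ok && (is.null(best) || mfst > best$mean_fst_inside)) {
        outside <- windows$mean_fst[!(windows$chrom == ch &
                                        windows$start >= seg$start[1] &
                                        windows$end <= seg$end[nrow(seg)])]
        best <- structure(list(
          chrom = ch, start = seg$start[1], end = seg$end[nrow(seg)],
          mean_fst_inside = mfst,
          mean_fst_outside = mean(outside, na.rm = TRUE),
          female_to_male_depth_ratio = ratio,
          fst_elevated = fst_ok, female_depth_depleted = depth_ok
        ), class = "msr_call")
      }
    }
  }
  best
}

#' @export
print.msr_call <- function(x, ...) {
  cat(sprintf("MSR call: %s:[%s, %s) | FST inside %.3f vs outside %.3f | F/M depth %.3f\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$mean_fst_inside,
              x$mean_fst_outside, x$female_to_male_depth_ratio))
  invisible(x)
}

#' One-call MSR detection from genotypes and depth
#'
#' Convenience wrapper: [window_scan()] then per-chromosome
#' [changepoint_segment()] then [call_msr()].
#'
#' @inheritParams window_scan
#' @inheritParams call_msr
#' @return List with `windows`, `breakpoints` and `call`.
#' @export
detect_msr <- function(genotypes, depth, window_size = 1e5, penalty = 1,
                       min_seg = 3L, fst_fold = 3, depth_ratio_max = 0.2) {
  windows <- window_scan(genotypes, depth, window_size)
  chroms <- unique(windows$chrom)
  breakpoints <- lapply(stats::setNames(chroms, chroms), function(ch) {
    changepoint_segment(windows$mean_fst[windows$chrom == ch],
                        penalty = penalty, min_seg = min_seg)
  })
  call <- call_msr(windows, breakpoints, fst_fold = fst_fold,
                   depth_ratio_max = depth_ratio_max)
  list(windows = windows, breakpoints = breakpoints, call = call)
}

#' Depth-based gene copy number
#'
#' For each gene and sample, copy number is `2 * (mean depth over the gene
#' interval) / (genome-wide median window depth of that sample)`: a diploid
#' locus scores ~2, a hemizygous locus ~1, an absent locus ~0. Gene depth is
#' the overlap-weighted mean of window depths.
#'
#' @param genes Data frame: gene_id, chrom, start, end (0-based half-open).
#' @param depth Long-format windowed depth table (as in [window_scan()]).
#' @param samples Samples to estimate; default all in `depth`.
#' @return Data frame: gene_id, sample, cn, rounded_cn (`NA` when the gene
#'   interval is covered by no depth window).
#' @export
estimate_copy_number <- function(genes, depth, samples = NULL) {
  if (is.null(samples)) samples <- unique(depth$sample)
  out <- list()
  for (smp in samples) {
    d <- depth[depth$sample == smp, , drop = FALSE]
    med <- stats::median(d$mean_depth)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      dd <- d[d$chrom == g$chrom, , drop = FALSE]
      ov <- interval_overlap(dd$window_start, dd$window_end, g$start, g$end)
      covered <- sum(ov)
      cn <- if (covered == 0) {
        NA_real_
      } else {
        2 * sum(dd$mean_depth * ov) / covered / med
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, sample = smp, cn = cn,
        rounded_cn = if (is.na(cn)) NA_integer_ else as.integer(round(cn)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
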