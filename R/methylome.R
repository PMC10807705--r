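# Site, gene, region and metagene methylation summaries from per-cytosine
# read-support counts.

#' Classify the sequence context of a cytosine
#'
#' Inspects the two bases following the cytosine in strand orientation:
#' `CG` if the next base is G; `CHG` if the next base is A/C/T and the one
#' after is G; otherwise `CHH` (H = A, C or T). On the minus strand the
#' reference base at `pos` must be G (a C on the reverse strand) and the
#' "following" bases are the reference bases at `pos - 1` and `pos - 2`,
#' complemented. Returns `NA` for sites too close to the sequence end to
#' classify.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param strand `"+"` or `"-"` (vectorised).
#' @return Character vector in `{CG, CHG, CHH, NA}`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  chars <- genome_chars(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (ch in unique(chrom)) {
    seq <- chars[[ch]]
    if (is.null(seq)) stop("unknown chromosome: ", ch)
    len <- nchar(seq)
    sel <- which(chrom == ch)
    base <- substring(seq, pos[sel], pos[sel])
    plus <- strand[sel] == "+"
    if (any(base[plus] != "C") || any(base[!plus] != "G")) {
      stop("reference base is not a cytosine on the given strand")
    }
    p <- pos[sel]
    n1 <- ifelse(plus, p + 1L, p - 1L)
    n2 <- ifelse(plus, p + 2L, p - 2L)
    b1 <- ifelse(n1 >= 1 & n1 <= len, substring(seq, n1, n1), NA)
    b2 <- ifelse(n2 >= 1 & n2 <= len, substring(seq, n2, n2), NA)
    # on the minus strand a following G corresponds to a reference C
    g1 <- ifelse(plus, b1 == "G", b1 == "C")
    g2 <- ifelse(plus, b2 == "G", b2 == "C")
    out[sel] <- ifelse(is.na(g1), NA,
                ifelse(g1, "CG",
                ifelse(is.na(g2), NA, ifelse(g2, "CHG", "CHH"))))
  }
  out
}

#' Call a cytosine site methylated, unmethylated or filtered
#'
#' Sites with read coverage below `min_depth` are filtered (removed as
#' likely false positives). A covered site is methylated iff the fraction of
#' methylation-supporting reads strictly exceeds `level_threshold`; a ratio
#' of exactly 0.5 is unmethylated.
#'
#' @param n_meth,n_total Methylated and total read counts (vectorised).
#' @param min_depth Minimum coverage to call (default 5).
#' @param level_threshold Strict methylation-ratio threshold (default 0.5).
#' @return Character vector in `{methylated, unmethylated, filtered}`.
#' @export
call_site <- function(n_meth, n_total, min_depth = 5L, level_threshold = 0.5) {
  if (any(n_meth > n_total)) stop("n_meth exceeds n_total")
  ifelse(n_total < min_depth, "filtered",
         ifelse(n_meth / n_total > level_threshold, "methylated",
                "unmethylated"))
}

#' Per-gene methylation status from CDS overlap
#'
#' A gene is flagged methylated in a context when any methylated-called site
#' of that context overlaps any of its CDS intervals.
#'
#' @param genes Data frame of gene models: gene_id (one row per gene).
#' @param cds Data frame of CDS intervals: gene_id, chrom, start, end
#'   (0-based half-open).
#' @param sites Methylation table: chrom, pos (1-based), strand, context,
#'   n_meth, n_total.
#' @param min_depth,level_threshold Passed to [call_site()].
#' @return Data frame: gene_id, CG, CHG, CHH (logical).
#' @export
gene_methylation_status <- function(genes, cds, sites, min_depth = 5L,
                                    level_threshold = 0.5) {
  called <- sites[call_site(sites$n_meth, sites$n_total, min_depth,
                            level_threshold) == "methylated", , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id, CG = FALSE, CHG = FALSE,
                    CHH = FALSE, stringsAsFactors = FALSE)
  no_cds <- setdiff(genes$gene_id, cds$gene_id)
  if (length(no_cds) > 0L) {
    warning("genes without CDS flagged unmethylated: ",
            paste(no_cds, collapse = ", "))
  }
  if (nrow(called) == 0L || nrow(cds) == 0L) return(out)
  site_gr <- GenomicRanges::GRanges(
    called$chrom, IRanges::IRanges(called$pos, width = 1L)
  )
  cds_gr <- GenomicRanges::GRanges(
    cds$chrom, IRanges::IRanges(cds$start + 1L, cds$end)
  )
  ov <- GenomicRanges::findOverlaps(site_gr, cds_gr)
  if (length(ov) == 0L) return(out)
  hit_gene <- cds$gene_id[S4Vectors::subjectHits(ov)]
  hit_ctx <- called$context[S4Vectors::queryHits(ov)]
  for (ctx in c("CG", "CHG", "CHH")) {
    out[[ctx]] <- out$gene_id %in% unique(hit_gene[hit_ctx == ctx])
  }
  out
}

#' Pooled methylation level of a set of sites
#'
#' The level of a region is the pooled read ratio: the sum of methylation-
#' supporting reads over the sum of all reads at the region's sites of the
#' requested context, restricted to sites with coverage within
#' `[min_depth, max_depth]`. An empty selection yields `NA`.
#'
#' @param sites Methylation table rows already restricted to the region.
#' @param context One of `CG`, `CHG`, `CHH`, or `NULL` for all contexts.
#' @param min_depth,max_depth Inclusive coverage bounds.
#' @return List: level, n_sites_used, n_meth, n_total.
#' @export
region_level <- function(sites, context = NULL, min_depth = 5L,
                         max_depth = 400L) {
  keep <- sites$n_total >= min_depth & sites$n_total <= max_depth
  if (!is.null(context)) keep <- keep & sites$context == context
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(list(level = NA_real_, n_sites_used = 0L, n_meth = 0L, n_total = 0L))
  }
  list(level = sum(s$n_meth) / sum(s$n_total), n_sites_used = nrow(s),
       n_meth = sum(s$n_meth), n_total = sum(s$n_total))
}

#' Subset a methylation table to a genomic interval
#'
#' @param sites Methylation table.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return The matching rows.
#' @export
sites_in_region <- function(sites, chrom, start, end) {
  sites[sites$chrom == chrom & (sites$pos - 1) >= start &
          (sites$pos - 1) < end, , drop = FALSE]
}

#' Metagene methylation profile over scaled gene bodies and fixed flanks
#'
#' For each gene the body is divided into `bin_number` equal-width bins and
#' each flank into `flank / bin_length` fixed 200-bp bins; minus-strand genes
#' are traversed 5' to 3' (their bins are reversed). The per-bin level is the
#' pooled read ratio across all genes (counts are summed over genes, not
#' averaged per gene). Genes shorter than `bin_number` bp are skipped and
#' counted.
#'
#' @param genes Gene models: gene_id, chrom, start, end, strand.
#' @param sites Methylation table.
#' @param context `CG`, `CHG` or `CHH`.
#' @param bin_number Number of scaled gene-body bins.
#' @param flank Flank width in bp.
#' @param bin_length Fixed flank bin width in bp.
#' @param min_depth,max_depth Inclusive coverage bounds per site.
#' @return Data frame of class `metagene_profile`: bin (1-based along
#'   upstream -> body -> downstream), zone, context, level, n_meth, n_total;
#'   attribute `skipped_genes` counts genes too short to bin.
#' @export
metagene_profile <- function(genes, sites, context, bin_number = 20L,
                             flank = 2000L, bin_length = 200L,
                             min_depth = 5L, max_depth = 400L) {
  stopifnot(flank %% bin_length == 0)
  fb <- flank %/% bin_length
  total_bins <- 2L * fb + bin_number
  s <- sites[sites$context == context & sites$n_total >= min_depth &
               sites$n_total <= max_depth, , drop = FALSE]
  n_meth <- integer(total_bins)
  n_total <- integer(total_bins)
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- g$end - g$start
    if (w < bin_number) { skipped <- skipped + 1L; next }
    ss <- s[s$chrom == g$chrom & (s$pos - 1) >= g$start - flank &
              (s$pos - 1) < g$end + flank, , drop = FALSE]
    if (nrow(ss) == 0L) next
    rel <- if (g$strand == "-") (g$end - 1) - (ss$pos - 1) else
      (ss$pos - 1) - g$start
    bin <- ifelse(rel < 0, floor((rel + flank) / bin_length),
           ifelse(rel < w, fb + floor(rel * bin_number / w),
                  fb + bin_number + floor((rel - w) / bin_length)))
    bin <- bin + 1L
    ok <- bin >= 1L & bin <= total_bins
    for (b in unique(bin[ok])) {
      sel <- ok & bin == b
      n_meth[b] <- n_meth[b] + sum(ss$n_meth[sel])
      n_total[b] <- n_total[b] + sum(ss$n_total[sel])
    }
  }
  out <- data.frame(
    bin = seq_len(total_bins),
    zone = rep(c("upstream", "body", "downstream"), c(fb, bin_number, fb)),
    context = context,
    level = ifelse(n_total > 0, n_meth / n_total, NA_real_),
    n_meth = n_meth, n_total = n_total, stringsAsFactors = FALSE
  )
  attr(out, "skipped_genes") <- skipped
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Pooled methylation levels (and repeat content) for named region sets
#'
#' For each named set of intervals and each context, computes the pooled
#' methylation level over all sites falling in the set (overlapping intervals
#' within a set are merged first so no site is double-counted). When a repeat
#' annotation is supplied, the repeat-base fraction of each region set is
#' appended.
#'
#' @param region_sets Named list of interval data frames (chrom, start, end;
#'   0-based half-open).
#' @param sites Methylation table.
#' @param repeats Optional repeat annotation (chrom, start, end).
#' @param min_depth,max_depth Inclusive coverage bounds per site.
#' @return Data frame: region, context, level, n_sites_used, n_meth, n_total,
#'   and repeat_fraction when `repeats` is given.
#' @export
compare_regions <- function(region_sets, sites, repeats = NULL,
                            min_depth = 5L, max_depth = 400L) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  rows <- list()
  for (nm in names(region_sets)) {
    r <- region_sets[[nm]]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(r$start + 1L, r$end)
    ))
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos, width = 1L))
    inside <- IRanges::overlapsAny(site_gr, gr)
    rep_frac <- NA_real_
    if (!is.null(repeats)) {
      rep_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end)
      ))
      inter <- GenomicRanges::intersect(gr, rep_gr)
      rep_frac <- sum(GenomicRanges::width(inter)) /
        sum(GenomicRanges::width(gr))
    }
    for (ctx in c("CG", "CHG", "CHH")) {
      lv <- region_level(sites[inside, , drop = FALSE], ctx,
                         min_depth, max_depth)
      rows[[paste(nm, ctx)]] <- data.frame(
        region = nm, context = ctx, level = lv$level,
        n_sites_used = lv$n_sites_used, n_meth = lv$n_meth,
        n_total = lv$n_total, repeat_fraction = rep_frac,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(repeats)) out$repeat_fraction <- NULL
  out
}

#' Rank correlation between gene-body methylation and expression
#'
#' Spearman correlation between per-gene pooled gene-body methylation level
#' (one context) and mean log2 abundance, a robust summary of the usual
#' negative association between body/promoter methylation and transcription.
#'
#' @param genes Gene models: gene_id, chrom, start, end.
#' @param sites Methylation table.
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param context Methylation context.
#' @param min_depth,max_depth Coverage bounds.
#' @return List: rho, n_genes (genes with both a defined level and
#'   expression).
#' @export
methylation_expression_correlation <- function(genes, sites, expr,
                                               context = "CG",
                                               min_depth = 5L,
                                               max_depth = 400L) {
  lv <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    region_level(sites_in_region(sites, g$chrom, g$start, g$end),
                 context, min_depth, max_depth)$level
  }, numeric(1))
  names(lv) <- genes$gene_id
  common <- intersect(names(lv)[!is.na(lv)], rownames(expr))
  if (length(common) < 3L) return(list(rho = NA_real_, n_genes = length(common)))
  rho <- stats::cor(lv[common], rowMeans(expr[common, , drop = FALSE]),
                    method = "spearman")
  list(rho = rho, n_genes = length(common))
}
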