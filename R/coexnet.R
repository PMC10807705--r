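# Gene regulatory networks: DEG filtering, Pearson correlation candidates,
# mutual-rank scoring, promoter extraction and PWM scanning, Fisher motif
# enrichment, network assembly and topology statistics.

#' Filter differentially expressed genes
#'
#' Applies Benjamini-Hochberg adjustment over all genes with a p-value and
#' keeps genes with fold change at least `fc_min` in either direction
#' (|log2 fold change| >= log2(fc_min)) and FDR at most `fdr_max`. Genes with
#' missing p-values are excluded from the BH family and flagged.
#'
#' @param table Data frame: gene, log2_fold_change, p_value.
#' @param fc_min Minimum linear fold change (default 2).
#' @param fdr_max Maximum BH-adjusted p (default 0.01).
#' @return Data frame of kept genes: gene, log2_fold_change, p_value, fdr,
#'   direction (`up`/`down`); attribute `n_missing_p` counts flagged genes.
#' @export
filter_degs <- function(table, fc_min = 2, fdr_max = 0.01) {
  stopifnot(all(c("gene", "log2_fold_change", "p_value") %in% names(table)))
  miss <- is.na(table$p_value)
  if (any(miss)) {
    warning(sum(miss), " genes with missing p-values excluded from testing")
  }
  tab <- table[!miss, , drop = FALSE]
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  keep <- abs(tab$log2_fold_change) >= log2(fc_min) & tab$fdr <= fdr_max
  out <- tab[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_fold_change >= 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "n_missing_p") <- sum(miss)
  out
}

#' Correlated gene pairs above a Pearson threshold
#'
#' Pearson correlation between all pairs of the requested genes across the
#' supplied samples; pairs with `pcc >= threshold` (positive) or
#' `pcc <= -threshold` (negative) are retained. Zero-variance genes cannot be
#' correlated and are excluded with a warning.
#'
#' @param expr Numeric matrix genes x samples.
#' @param genes Genes to consider (default all rows).
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return Data frame of unordered pairs: gene1, gene2 (gene1 < gene2), pcc.
#' @export
pcc_candidates <- function(expr, genes = rownames(expr), threshold = 0.9) {
  genes <- intersect(genes, rownames(expr))
  m <- expr[genes, , drop = FALSE]
  v <- apply(m, 1L, stats::var)
  if (any(v == 0 | is.na(v))) {
    warning("zero-variance genes excluded: ",
            paste(genes[v == 0 | is.na(v)], collapse = ", "))
    m <- m[v > 0 & !is.na(v), , drop = FALSE]
  }
  if (nrow(m) < 2L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      pcc = numeric(), stringsAsFactors = FALSE))
  }
  cc <- stats::cor(t(m))
  idx <- which(upper.tri(cc) & abs(cc) >= threshold, arr.ind = TRUE)
  g1 <- rownames(cc)[idx[, 1]]
  g2 <- rownames(cc)[idx[, 2]]
  swap <- g1 > g2
  out <- data.frame(gene1 = ifelse(swap, g2, g1),
                    gene2 = ifelse(swap, g1, g2),
                    pcc = cc[idx], stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mutual-rank score from reciprocal ranks, normalised to (0, 1].
mr_score <- function(rank_1to2, rank_2to1, n_genes) {
  raw <- sqrt(rank_1to2 * rank_2to1)
  if (n_genes <= 1L) return(rep(1, length(raw)))
  pmax(1 - (raw - 1) / (n_genes - 1), .Machine$double.eps)
}

#' Mutual-rank scores for candidate co-expression pairs
#'
#' Within each gene's retained candidate list, partners are ranked by
#' descending absolute correlation (rank 1 = strongest; ties broken by
#' partner id, lexicographically, for determinism). The raw mutual rank of a
#' pair is the geometric mean `sqrt(r_12 * r_21)` of the two reciprocal
#' ranks; it is mapped to `(0, 1]` as `mr = 1 - (raw - 1) / (N - 1)` with `N`
#' the number of genes in the candidate graph, so `mr = 1` exactly when both
#' ranks are 1. The raw geometric mean is also returned.
#'
#' @param candidates Data frame from [pcc_candidates()].
#' @return Data frame: gene1, gene2, pcc, rank_1to2, rank_2to1, mr_raw, mr.
#' @export
mutual_rank <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(cbind(candidates, data.frame(rank_1to2 = integer(),
                                        rank_2to1 = integer(),
                                        mr_raw = numeric(), mr = numeric())))
  }
  genes <- sort(unique(c(candidates$gene1, candidates$gene2)))
  n <- length(genes)
  long <- rbind(
    data.frame(from = candidates$gene1, to = candidates$gene2,
               pcc = candidates$pcc, stringsAsFactors = FALSE),
    data.frame(from = candidates$gene2, to = candidates$gene1,
               pcc = candidates$pcc, stringsAsFactors = FALSE)
  )
  long <- long[order(long$from, -abs(long$pcc), long$to), , drop = FALSE]
  long$rank <- stats::ave(seq_len(nrow(long)), long$from,
                          FUN = seq_along)
  key <- function(a, b) paste(a, b, sep = "\r")
  rank_of <- stats::setNames(long$rank, key(long$from, long$to))
  r12 <- rank_of[key(candidates$gene1, candidates$gene2)]
  r21 <- rank_of[key(candidates$gene2, candidates$gene1)]
  out <- candidates
  out$rank_1to2 <- as.integer(r12)
  out$rank_2to1 <- as.integer(r21)
  out$mr_raw <- sqrt(out$rank_1to2 * out$rank_2to1)
  out$mr <- mr_score(out$rank_1to2, out$rank_2to1, n)
  rownames(out) <- NULL
  out
}

#' Build the co-expression network from mutual-rank scores
#'
#' Keeps pairs with `mr >= mr_threshold`; edge sign is the sign of the
#' correlation.
#'
#' @param scores Data frame from [mutual_rank()].
#' @param mr_threshold Minimum mutual-rank score (default 0.90).
#' @return An undirected [igraph::graph] with edge attributes `mr`, `pcc`,
#'   `sign` and `edge_type = "coexpression"`.
#' @export
build_coexpression_network <- function(scores, mr_threshold = 0.90) {
  keep <- scores[scores$mr >= mr_threshold, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = keep$gene1, to = keep$gene2, mr = keep$mr,
               pcc = keep$pcc, sign = ifelse(keep$pcc >= 0, "+", "-"),
               edge_type = "coexpression", stringsAsFactors = FALSE),
    directed = FALSE
  )
  g
}

#' Strand-aware promoter sequences
#'
#' The promoter is the `length` bp immediately upstream of the gene start in
#' transcription orientation: `[start - length, start)` for plus-strand genes
#' and the reverse complement of `[end, end + length)` for minus-strand
#' genes. Promoters are truncated at chromosome edges and the realised
#' length recorded; a gene flush against the edge gets a zero-length
#' promoter.
#'
#' @param genes Gene models: gene_id, chrom, start, end, strand (0-based
#'   half-open).
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param length Promoter length in bp (default 2000).
#' @return Data frame: gene_id, chrom, start, end, strand, length, seq.
#' @export
extract_promoters <- function(genes, genome, length = 2000L) {
  chars <- genome_chars(genome)
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), length = numeric(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrlen <- nchar(chars[[g$chrom]])
    if (g$strand == "+") {
      s <- max(0, g$start - length); e <- g$start
      seq <- if (e > s) substr(chars[[g$chrom]], s + 1, e) else ""
    } else {
      s <- g$end; e <- min(chrlen, g$end + length)
      seq <- if (e > s) revcomp(substr(chars[[g$chrom]], s + 1, e)) else ""
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = s, end = e,
               strand = g$strand, length = e - s, seq = seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Log-odds PWM from a count (or probability) matrix with rows A, C, G, T.
pwm_logodds <- function(pwm, pseudocount = 0.01) {
  stopifnot(nrow(pwm) == 4L)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  probs <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  log2(probs / 0.25)
}

#' Scan a promoter with a position weight matrix
#'
#' Scores every position on both strands with the log-odds of the PWM
#' against a uniform background; a hit is declared when the best score
#' reaches `score_fraction` of the PWM's maximum attainable score. Promoters
#' shorter than the motif cannot hit.
#'
#' @param promoter Promoter sequence (character scalar).
#' @param pwm 4 x w count or probability matrix (rows A, C, G, T).
#' @param score_fraction Fraction of the maximum score required for a hit.
#' @param pseudocount Added to each PWM cell before normalisation.
#' @return List: hit (logical), best_score, max_score, best_pos (1-based on
#'   the given sequence; `NA` when no position was scored), best_strand.
#' @export
scan_motif <- function(promoter, pwm, score_fraction = 0.85,
                       pseudocount = 0.01) {
  lo <- pwm_logodds(pwm, pseudocount)
  w <- ncol(lo)
  max_score <- sum(apply(lo, 2L, max))
  n <- nchar(promoter)
  if (n < w || n == 0L) {
    return(list(hit = FALSE, best_score = -Inf, max_score = max_score,
                best_pos = NA_integer_, best_strand = NA_character_))
  }
  score_strand <- function(seq) {
    idx <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
    np <- nchar(seq) - w + 1L
    sc <- numeric(np)
    for (j in seq_len(w)) {
      col <- lo[, j]
      b <- idx[seq.int(j, j + np - 1L)]
      contrib <- ifelse(is.na(b), min(col), col[b])
      sc <- sc + contrib
    }
    sc
  }
  fwd <- score_strand(promoter)
  rev <- score_strand(revcomp(promoter))
  best_f <- which.max(fwd); best_r <- which.max(rev)
  if (fwd[best_f] >= rev[best_r]) {
    best <- fwd[best_f]; pos <- best_f; strand <- "+"
  } else {
    best <- rev[best_r]; pos <- n - w + 2L - best_r; strand <- "-"
  }
  list(hit = best >= score_fraction * max_score, best_score = best,
       max_score = max_score, best_pos = as.integer(pos),
       best_strand = strand)
}

#' Promoter motif enrichment by one-sided Fisher exact test
#'
#' For each motif, promoters with at least one hit are counted in the
#' differentially-expressed set and in the background set, and the one-sided
#' (enrichment) Fisher exact p-value of the 2 x 2 table is computed. Motifs
#' with `p < alpha` are flagged enriched.
#'
#' @param deg_promoters,background_promoters Data frames from
#'   [extract_promoters()] (columns gene_id, seq), or named character
#'   vectors of sequences.
#' @param pwm_library Named list of 4 x w PWMs.
#' @param alpha Enrichment p-value cutoff (default 0.001).
#' @param score_fraction,pseudocount Passed to [scan_motif()].
#' @return Data frame: motif, n_deg_with_hit, n_deg_total, n_bg_with_hit,
#'   n_bg_total, p_value, enriched; attribute `deg_hits` is the logical
#'   gene x motif hit matrix for the DEG set.
#' @export
motif_enrichment <- function(deg_promoters, background_promoters,
                             pwm_library, alpha = 0.001,
                             score_fraction = 0.85, pseudocount = 0.01) {
  as_seqs <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$seq, x$gene_id) else x
  }
  deg <- as_seqs(deg_promoters)
  bg <- as_seqs(background_promoters)
  if (length(bg) == 0L) stop("background promoter set is empty")
  hit_mat <- function(seqs, pwm) {
    vapply(seqs, function(s) {
      scan_motif(s, pwm, score_fraction, pseudocount)$hit
    }, logical(1))
  }
  deg_hits <- sapply(pwm_library, function(p) hit_mat(deg, p))
  deg_hits <- matrix(deg_hits, nrow = length(deg),
                     dimnames = list(names(deg), names(pwm_library)))
  rows <- lapply(names(pwm_library), function(mid) {
    dh <- sum(deg_hits[, mid])
    bh <- sum(hit_mat(bg, pwm_library[[mid]]))
    tab <- matrix(c(dh, length(deg) - dh, bh, length(bg) - bh), nrow = 2L,
                  byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(motif = mid, n_deg_with_hit = dh, n_deg_total = length(deg),
               n_bg_with_hit = bh, n_bg_total = length(bg), p_value = p,
               enriched = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "deg_hits") <- deg_hits
  out
}

#' Assemble the gene regulatory network
#'
#' Starts from the co-expression graph and adds directed regulation edges
#' TF -> target for every enriched motif mapped to a differentially
#' expressed TF, targeting each differentially expressed gene whose promoter
#' carries a hit of that motif. Motifs without a TF mapping are skipped with
#' a warning.
#'
#' @param coex_graph Undirected co-expression graph from
#'   [build_coexpression_network()].
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @param enriched_motifs Character vector of enriched motif ids.
#' @param motif_tf_map Data frame: motif_id, tf_id.
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param promoter_hits Logical gene x motif matrix (e.g. the `deg_hits`
#'   attribute of [motif_enrichment()]).
#' @return List with `edges` (source, target, edge_type, mr, sign, motif)
#'   and `graph` (igraph, regulation edges directed by convention
#'   source -> target).
#' @export
assemble_grn <- function(coex_graph, tf_ids, enriched_motifs, motif_tf_map,
                         deg_genes, promoter_hits) {
  coex_edges <- if (igraph::ecount(coex_graph) > 0L) {
    el <- igraph::as_data_frame(coex_graph, what = "edges")
    data.frame(source = el$from, target = el$to, edge_type = "coexpression",
               mr = el$mr, sign = el$sign, motif = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               edge_type = character(), mr = numeric(), sign = character(),
               motif = character(), stringsAsFactors = FALSE)
  }
  reg_rows <- list()
  for (mid in enriched_motifs) {
    tf <- motif_tf_map$tf_id[motif_tf_map$motif_id == mid]
    if (length(tf) == 0L) {
      warning("motif without TF mapping skipped: ", mid)
      next
    }
    tf <- tf[1]
    if (!(tf %in% tf_ids) || !(tf %in% deg_genes)) next
    if (!(mid %in% colnames(promoter_hits))) next
    targets <- rownames(promoter_hits)[promoter_hits[, mid]]
    targets <- setdiff(intersect(targets, deg_genes), tf)
    for (tg in targets) {
      reg_rows[[paste(mid, tg)]] <- data.frame(
        source = tf, target = tg, edge_type = "regulation", mr = NA_real_,
        sign = NA_character_, motif = mid, stringsAsFactors = FALSE
      )
    }
  }
  edges <- rbind(coex_edges, do.call(rbind, reg_rows))
  rownames(edges) <- NULL
  graph <- if (nrow(edges) > 0L) {
    igraph::graph_from_data_frame(edges[, c("source", "target", "edge_type",
                                            "mr", "sign", "motif")],
                                  directed = TRUE)
  } else {
    igraph::make_empty_graph(0)
  }
  list(edges = edges, graph = graph)
}

#' Topology statistics of a network
#'
#' Treats the input as an undirected simple graph. The clustering
#' coefficient is the mean local clustering with vertices of degree < 2
#' contributing 0; the characteristic path length is the mean shortest-path
#' length over connected ordered pairs; `avg_neighbors = 2 * n_edges /
#' n_nodes`.
#'
#' @param graph An igraph object, or an edge data frame with columns
#'   source/target (or from/to).
#' @return List: n_nodes, n_edges, avg_neighbors, characteristic_path_length,
#'   clustering_coefficient (all `NA` for an empty graph).
#' @export
network_stats <- function(graph) {
  if (is.data.frame(graph)) {
    cols <- intersect(c("source", "target", "from", "to"), names(graph))
    graph <- igraph::graph_from_data_frame(graph[, cols[1:2]],
                                           directed = FALSE)
  }
  g <- igraph::as_undirected(igraph::simplify(graph), mode = "collapse")
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(list(n_nodes = NA_integer_, n_edges = NA_integer_,
                avg_neighbors = NA_real_,
                characteristic_path_length = NA_real_,
                clustering_coefficient = NA_real_))
  }
  e <- igraph::ecount(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  list(
    n_nodes = n, n_edges = e, avg_neighbors = 2 * e / n,
    characteristic_path_length = igraph::mean_distance(g, directed = FALSE,
                                                       unconnected = TRUE),
    clustering_coefficient = mean(loc)
  )
}

#' Stage of peak expression per gene
#'
#' Node attribute used when rendering networks: the developmental stage with
#' the highest mean abundance for each gene.
#'
#' @param expr Expression matrix genes x samples.
#' @param samples Data frame with columns sample, stage (as from
#'   [simulate_expression()]).
#' @return Named character vector gene -> stage.
#' @export
peak_stage <- function(expr, samples) {
  stages <- unique(samples$stage)
  means <- vapply(stages, function(st) {
    rowMeans(expr[, samples$sample[samples$stage == st], drop = FALSE])
  }, numeric(nrow(expr)))
  stats::setNames(stages[max.col(means, ties.method = "first")],
                  rownames(expr))
}
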