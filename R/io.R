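# Format adapters. External files use the field's conventions (FASTA, VCF
# v4.2, GFF3 and BED are 1-based or 0-based as their specs dictate);
# everything internal is 0-based half-open, and the conversion lives here.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet]; names truncated at first whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome DNAStringSet or named character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome_chars(genome)), path,
                              width = 80L)
  invisible(path)
}

#' Write sexed genotypes as VCF v4.2
#'
#' Biallelic SNPs only, GT-only FORMAT, positions 1-based and sorted per
#' chromosome. Hemizygous male genotypes in the male-specific region are
#' encoded as 0/1 heterozygotes (diploid VCF has no hemizygosity encoding);
#' downstream FST treats genotypes as allele counts, which under-counts the
#' male-limited allele by construction — a documented limitation.
#'
#' @param genotypes A `sexed_genotypes` object.
#' @param path Output file.
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=msrpipe",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  samples <- colnames(genotypes$geno)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  s <- genotypes$sites
  ord <- order(s$chrom, s$pos)
  g <- genotypes$geno[ord, , drop = FALSE]
  s <- s[ord, , drop = FALSE]
  gt <- matrix(ifelse(is.na(g), "./.", gt_code[g + 1L]), nrow = nrow(g))
  lines <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a sexed-genotypes object
#'
#' Multiallelic and non-SNP records are dropped. Genotypes become alternate-
#' allele dosages (0/1/2, `NA` for missing).
#'
#' @param path VCF file (v4.x, plain text).
#' @param sex Named factor/character sample -> `male`/`female`, or a TSV path
#'   with columns sample, sex.
#' @return A `sexed_genotypes` object.
#' @export
read_vcf <- function(path, sex) {
  if (is.character(sex) && length(sex) == 1L && file.exists(sex)) {
    sex <- read_sex_labels(sex)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dos <- apply(gt, 2L, function(col) {
    col <- gsub("|", "/", col, fixed = TRUE)
    ifelse(is.na(col) | col == "./.", NA_integer_,
           vapply(strsplit(col, "/", fixed = TRUE),
                  function(a) sum(a == "1"), integer(1)))
  })
  dos <- matrix(as.integer(dos), nrow = sum(keep),
                dimnames = list(NULL, colnames(gt)))
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sex <- factor(as.character(sex[colnames(dos)]),
                levels = c("male", "female"))
  names(sex) <- colnames(dos)
  if (anyNA(sex)) stop("sex label missing for some VCF samples")
  if (sum(sex == "male") < 2L || sum(sex == "female") < 2L) {
    stop("need at least 2 samples per sex")
  }
  structure(list(sites = sites[ord, , drop = FALSE],
                 geno = dos[ord, , drop = FALSE], sex = sex),
            class = "sexed_genotypes")
}

#' @rdname read_vcf
#' @param labels Named sex labels to write.
#' @export
write_sex_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample = names(labels), sex = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname read_vcf
#' @export
read_sex_labels <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(t$sex, t$sample)
}

#' Windowed depth table IO
#'
#' TSV with columns chrom, window_start, window_end, sample, mean_depth
#' (0-based half-open windows).
#'
#' @param depth Depth data frame.
#' @param path File path.
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Per-cytosine methylation table IO
#'
#' TSV with columns chrom, pos (1-based), strand, context, n_meth, n_total.
#'
#' @param sites Methylation data frame.
#' @param path File path.
#' @export
write_meth_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_tsv
#' @export
read_meth_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  bad <- out$n_meth > out$n_total
  if (any(bad)) {
    stop("methylation table ", path, ": n_meth > n_total at line ",
         which(bad)[1] + 1L)
  }
  out
}

#' Expression matrix IO
#'
#' TSV with a `gene` column followed by one column per sample.
#'
#' @param expr Numeric matrix genes x samples.
#' @param path File path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Gene models IO (GFF3)
#'
#' Writes `gene` and `CDS` features (single-exon models: CDS equals the gene
#' body). GFF3 is 1-based inclusive; internal coordinates are 0-based
#' half-open, converted on the way in and out.
#'
#' @param genes Data frame: gene_id, chrom, start, end, strand.
#' @param path File path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(c(
      paste(g$chrom, "msrpipe", "gene", g$start + 1, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "msrpipe", "CDS", g$start + 1, g$end, ".", g$strand,
            "0", paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id),
            sep = "\t")
    ), con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @return For `read_gff3`: list with `genes` and `cds` data frames
#'   (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  as_df <- function(x, id_field) {
    if (length(x) == 0L) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    ids <- if (id_field == "Parent") {
      vapply(x$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else {
      x$ID
    }
    data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1,
      end = GenomicRanges::end(x),
      strand = as.character(GenomicRanges::strand(x)),
      stringsAsFactors = FALSE
    )
  }
  genes <- as_df(gr[gr$type == "gene"], "ID")
  cds <- as_df(gr[gr$type == "CDS"], "Parent")
  list(genes = genes, cds = cds)
}

#' JASPAR-style PWM text IO
#'
#' Format: a `>motif_id name` header followed by four lines
#' `A [ 1 2 ... ]`, `C [...]`, `G [...]`, `T [...]` of per-position counts.
#'
#' @param pwms Named list of 4 x w matrices (rows A, C, G, T).
#' @param path File path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(paste0(">", nm, " ", nm), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ", paste(m[b, ], collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' @rdname write_jaspar
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  pwms <- list()
  for (h in heads) {
    id <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]][1]
    block <- lines[(h + 1):(h + 4)]
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    bases <- toupper(substr(trimws(block), 1L, 1L))
    m <- do.call(rbind, rows)
    rownames(m) <- bases
    pwms[[id]] <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  pwms
}

#' BED6 export for telomere and centromere annotation
#'
#' Telomere rows use the end label as name and the copy number as score;
#' centromere rows use the monomer length as name and the occupancy
#' percentage as score.
#'
#' @param telomeres Data frame from [scan_telomeres()].
#' @param centromeres Data frame from [call_centromeres()].
#' @param path File path.
#' @export
write_features_bed <- function(telomeres, centromeres, path) {
  rows <- character(0)
  if (nrow(telomeres) > 0L) {
    rows <- c(rows, paste(telomeres$chrom, telomeres$start, telomeres$end,
                          telomeres$end_of_chrom, telomeres$n_copies, "+",
                          sep = "\t"))
  }
  if (nrow(centromeres) > 0L) {
    rows <- c(rows, paste(centromeres$chrom, centromeres$start,
                          centromeres$end,
                          paste0("monomer_", centromeres$monomer_length),
                          round(100 * centromeres$occupancy), "+",
                          sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Ground truth JSON IO
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$genes <- as.data.frame(x$genes, stringsAsFactors = FALSE)
  x$telomere_intervals <- as.data.frame(x$telomere_intervals,
                                        stringsAsFactors = FALSE)
  x$msr_interval <- as.numeric(x$msr_interval)
  x$tf_target_map <- lapply(x$tf_target_map, unlist)
  class(x) <- "ground_truth"
  x
}

#' Write a network edge list and GraphML export
#' @param edges Edge data frame from [assemble_grn()].
#' @param graph igraph object.
#' @param edges_path,graphml_path Output paths.
#' @export
write_network <- function(edges, graph, edges_path, graphml_path = NULL) {
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path) && igraph::vcount(graph) > 0L) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}
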