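# End-to-end pipeline: configuration, stage orchestration, run manifest.

#' Default pipeline configuration
#'
#' Builds the nested parameter list that fully determines a pipeline run.
#' Every analysis threshold is a configuration default here, never a
#' hard-coded constant inside a stage.
#'
#' @param outdir Output directory.
#' @param seed Integer seed (drives the simulation stage when enabled).
#' @param simulate `TRUE` to generate inputs with [simulate_dataset()] into
#'   `file.path(outdir, "inputs")`; otherwise `inputs` must name existing
#'   files.
#' @param inputs Named list of input paths (genome, vcf, sex, depth,
#'   methylation, expression, deg_stats, genes, tf_list, motifs). Filled in
#'   automatically when `simulate = TRUE`.
#' @param sim Arguments for [sim_config()] (list).
#' @param telomere,centromere,msr,methylation,grn Per-stage parameter lists;
#'   see Details for keys and defaults.
#' @details Stage parameters: telomere (motif `CCCTAAA`, min_copies 50,
#'   max_offset 10000, max_mismatch_frac 0.1); centromere (min_period 50,
#'   max_period 200, min_array_length 10000, occupancy_threshold 0.5,
#'   window 1000); msr (window_size 1e5, penalty 1, min_seg 3, fst_fold 3,
#'   depth_ratio_max 0.2); methylation (min_depth 5, max_depth 400,
#'   level_threshold 0.5, bin_number 20, flank 2000, bin_length 200);
#'   grn (fc_min 2, fdr_max 0.01, pcc_threshold 0.9, mr_threshold 0.9,
#'   promoter_length 2000, score_fraction 0.85, pseudocount 0.01,
#'   alpha 0.001).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            inputs = list(), sim = list(),
                            telomere = list(), centromere = list(),
                            msr = list(), methylation = list(),
                            grn = list()) {
  defaults <- list(
    outdir = outdir, seed = as.integer(seed), simulate = isTRUE(simulate),
    inputs = inputs,
    sim = sim,
    telomere = list(motif = "CCCTAAA", min_copies = 50L, max_offset = 10000L,
                    max_mismatch_frac = 0.1),
    centromere = list(min_period = 50L, max_period = 200L,
                      min_array_length = 10000L, occupancy_threshold = 0.5,
                      window = 1000L),
    msr = list(window_size = 1e5, penalty = 1, min_seg = 3L, fst_fold = 3,
               depth_ratio_max = 0.2),
    methylation = list(min_depth = 5L, max_depth = 400L,
                       level_threshold = 0.5, bin_number = 20L,
                       flank = 2000L, bin_length = 200L),
    grn = list(fc_min = 2, fdr_max = 0.01, pcc_threshold = 0.9,
               mr_threshold = 0.9, promoter_length = 2000L,
               score_fraction = 0.85, pseudocount = 0.01, alpha = 0.001)
  )
  for (block in c("telomere", "centromere", "msr", "methylation", "grn")) {
    user <- get(block)
    unknown <- setdiff(names(user), names(defaults[[block]]))
    if (length(unknown) > 0L) {
      stop("unknown ", block, " config keys: ", paste(unknown, collapse = ", "))
    }
    defaults[[block]][names(user)] <- user
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level or stage-level keys are rejected so a typo cannot
#' silently fall back to a default.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "simulate", "inputs", "sim", "telomere",
             "centromere", "msr", "methylation", "grn")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(y$outdir)) stop("config must set outdir")
  do.call(pipeline_config, y)
}

validate_pipeline_inputs <- function(config) {
  if (!config$simulate) {
    needed <- c("genome", "vcf", "sex", "depth")
    missing <- needed[!vapply(config$inputs[needed], function(p) {
      !is.null(p) && file.exists(p)
    }, logical(1))]
    if (length(missing) > 0L) {
      stop("missing input files for: ", paste(missing, collapse = ", "))
    }
  }
  # fail fast on depth windows that do not align to the scan window
  dp <- config$inputs$depth
  if (!is.null(dp) && file.exists(dp)) {
    d <- read_depth_tsv(dp)
    w <- config$msr$window_size
    if (any(d$window_start %% w != 0) ||
        any(d$window_end - d$window_start > w)) {
      stop("depth windows do not align to msr window_size = ", w)
    }
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> telomere/centromere annotation -> MSR
#' scan -> methylation summaries -> regulatory network, writing each stage's
#' outputs under `outdir` and a JSON run manifest with per-file MD5
#' checksums. A failure stops with the failing stage's name; outputs of
#' completed stages are left intact.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return The manifest, invisibly (also written to
#'   `file.path(outdir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[msrpipe] ", ...)
  manifest <- list(
    tool = "msrpipe", version = as.character(utils::packageVersion("msrpipe")),
    config_hash = config_hash(config), started = format(Sys.time()),
    stages = list()
  )
  stage_files <- function(stage, paths) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(unname(tools::md5sum(unlist(paths))),
                                        basename(unlist(paths))))
    )
  }
  run_stage <- function(stage, fn) {
    log_msg("stage: ", stage)
    tryCatch(fn(), error = function(e) {
      stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$simulate) {
    indir <- file.path(outdir, "inputs")
    run_stage("simulate", function() {
      cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      sim <- simulate_dataset(cfg, indir)
      config$inputs <<- sim$paths
      stage_files("simulate", sim$paths)
    })
  }
  validate_pipeline_inputs(config)
  inp <- config$inputs

  genome <- read_genome_fasta(inp$genome)
  log_msg(length(genome), " chromosomes read")

  run_stage("seqfeatures", function() {
    tl <- config$telomere
    tel <- scan_telomeres(genome, tl$motif, tl$min_copies, tl$max_offset,
                          tl$max_mismatch_frac)
    cn <- config$centromere
    mono <- infer_genome_monomer(genome, cn$min_period, cn$max_period)
    cen <- if (!is.na(mono$monomer_length)) {
      call_centromeres(genome, mono$monomer, cn$min_array_length,
                       cn$occupancy_threshold, cn$window)
    } else {
      call_centromeres(genome, "NN", cn$min_array_length)
    }
    log_msg(nrow(tel), " telomeres, ", nrow(cen), " centromere calls")
    bed <- file.path(outdir, "features.bed")
    rep <- file.path(outdir, "seqfeatures.json")
    write_features_bed(tel, cen, bed)
    jsonlite::write_json(list(telomeres = tel, centromeres = cen,
                              monomer = mono),
                         rep, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    stage_files("seqfeatures", c(bed, rep))
  })

  run_stage("sexscan", function() {
    gt <- read_vcf(inp$vcf, inp$sex)
    depth <- read_depth_tsv(inp$depth)
    ms <- config$msr
    res <- detect_msr(gt, depth, ms$window_size, ms$penalty, ms$min_seg,
                      ms$fst_fold, ms$depth_ratio_max)
    log_msg(nrow(res$windows), " windows scanned; MSR ",
            if (is.null(res$call)) "not called" else
              sprintf("%s:[%.0f, %.0f)", res$call$chrom, res$call$start,
                      res$call$end))
    wtsv <- file.path(outdir, "window_stats.tsv")
    utils::write.table(res$windows, wtsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mbed <- file.path(outdir, "msr_call.bed")
    if (!is.null(res$call)) {
      writeLines(paste(res$call$chrom, res$call$start, res$call$end,
                       sprintf("msr;fst_in=%.4f;fst_out=%.4f;fm_depth=%.4f",
                               res$call$mean_fst_inside,
                               res$call$mean_fst_outside,
                               res$call$female_to_male_depth_ratio),
                       sep = "\t"), mbed)
    } else {
      writeLines(character(0), mbed)
    }
    outs <- c(wtsv, mbed)
    if (!is.null(inp$genes) && file.exists(inp$genes)) {
      genes <- read_gff3(inp$genes)$genes
      cnv <- estimate_copy_number(genes, depth)
      ctsv <- file.path(outdir, "copy_number.tsv")
      utils::write.table(cnv, ctsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, ctsv)
    }
    stage_files("sexscan", outs)
  })
  msr_call <- NULL  # recovered from the written BED (stage isolation)
  bed <- file.path(outdir, "msr_call.bed")
  if (file.exists(bed) && length(readLines(bed)) > 0L) {
    f <- strsplit(readLines(bed)[1], "\t")[[1]]
    msr_call <- list(chrom = f[1], start = as.numeric(f[2]),
                     end = as.numeric(f[3]))
  }

  run_stage("methylome", function() {
    if (is.null(inp$methylation) || !file.exists(inp$methylation)) {
      log_msg("no methylation input; stage skipped")
      return(invisible())
    }
    sites <- read_meth_tsv(inp$methylation)
    me <- config$methylation
    ann <- read_gff3(inp$genes)
    status <- gene_methylation_status(ann$genes, ann$cds, sites,
                                      me$min_depth, me$level_threshold)
    log_msg(sum(status$CG | status$CHG | status$CHH), " of ",
            nrow(status), " genes methylated in some context")
    stsv <- file.path(outdir, "gene_methylation.tsv")
    utils::write.table(status, stsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    chrlens <- stats::setNames(Biostrings::width(genome), names(genome))
    whole <- data.frame(chrom = names(chrlens), start = 0,
                        end = as.numeric(chrlens))
    sets <- list(whole_genome = whole)
    if (!is.null(msr_call)) {
      chrl <- chrlens[[msr_call$chrom]]
      sets$msr <- data.frame(chrom = msr_call$chrom, start = msr_call$start,
                             end = msr_call$end)
      sets$chrom_non_msr <- data.frame(
        chrom = rep(msr_call$chrom, 2),
        start = c(0, msr_call$end), end = c(msr_call$start, chrl)
      )
      sets$chrom_non_msr <-
        sets$chrom_non_msr[sets$chrom_non_msr$end >
                             sets$chrom_non_msr$start, , drop = FALSE]
      sets$msr_chrom <- data.frame(chrom = msr_call$chrom, start = 0,
                                   end = chrl)
    }
    reg <- compare_regions(sets, sites, min_depth = me$min_depth,
                           max_depth = me$max_depth)
    rtsv <- file.path(outdir, "region_methylation.tsv")
    utils::write.table(reg, rtsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    profs <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx) {
      metagene_profile(ann$genes, sites, ctx, me$bin_number, me$flank,
                       me$bin_length, me$min_depth, me$max_depth)
    }))
    ptsv <- file.path(outdir, "metagene_profile.tsv")
    utils::write.table(profs, ptsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_files("methylome", c(stsv, rtsv, ptsv))
  })

  run_stage("coexnet", function() {
    if (is.null(inp$expression) || !file.exists(inp$expression)) {
      log_msg("no expression input; stage skipped")
      return(invisible())
    }
    gp <- config$grn
    expr <- read_expression_tsv(inp$expression)
    deg_tab <- utils::read.table(inp$deg_stats, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    degs <- filter_degs(deg_tab, gp$fc_min, gp$fdr_max)
    log_msg(nrow(degs), " DEGs of ", nrow(deg_tab), " genes")
    gene_set <- if (nrow(degs) >= 2L) {
      degs$gene
    } else {
      log_msg("fewer than 2 DEGs; building the network over all genes")
      rownames(expr)
    }
    cand <- pcc_candidates(expr, gene_set, gp$pcc_threshold)
    scores <- mutual_rank(cand)
    coex <- build_coexpression_network(scores, gp$mr_threshold)
    log_msg(igraph::ecount(coex), " co-expression edges (MR >= ",
            gp$mr_threshold, ")")
    ann <- read_gff3(inp$genes)
    tf_map <- utils::read.table(inp$tf_list, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    pwms <- read_jaspar(inp$motifs)
    deg_genes <- intersect(gene_set, ann$genes$gene_id)
    dp <- extract_promoters(ann$genes[ann$genes$gene_id %in% deg_genes, ,
                                      drop = FALSE],
                            genome, gp$promoter_length)
    bgp <- extract_promoters(ann$genes[!(ann$genes$gene_id %in% deg_genes), ,
                                       drop = FALSE],
                             genome, gp$promoter_length)
    edges_df <- NULL
    if (nrow(bgp) > 0L && nrow(dp) > 0L) {
      enr <- motif_enrichment(dp, bgp, pwms, gp$alpha, gp$score_fraction,
                              gp$pseudocount)
      etsv <- file.path(outdir, "motif_enrichment.tsv")
      utils::write.table(enr, etsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      grn <- assemble_grn(coex, unique(tf_map$tf_id),
                          enr$motif[enr$enriched],
                          data.frame(motif_id = tf_map$motif_id,
                                     tf_id = tf_map$tf_id),
                          deg_genes, attr(enr, "deg_hits"))
    } else {
      grn <- assemble_grn(coex, unique(tf_map$tf_id), character(0),
                          data.frame(motif_id = character(),
                                     tf_id = character()),
                          deg_genes,
                          matrix(FALSE, 0, 0))
      etsv <- NULL
    }
    ntsv <- file.path(outdir, "network_edges.tsv")
    gml <- file.path(outdir, "network.graphml")
    write_network(grn$edges, grn$graph, ntsv,
                  if (igraph::vcount(grn$graph) > 0L) gml else NULL)
    st <- network_stats(grn$graph)
    sttsv <- file.path(outdir, "network_stats.tsv")
    utils::write.table(as.data.frame(st), sttsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(ntsv, sttsv, if (!is.null(etsv)) etsv,
              if (file.exists(gml)) gml)
    stage_files("coexnet", outs)
  })

  manifest$finished <- format(Sys.time())
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  log_msg("manifest written: ", mpath)
  invisible(manifest)
}

# Stable hash of the analysis parameters (paths excluded so the same
# parameter set hashes identically wherever it runs): canonical
# serialisation written to a temp file, MD5-summed.
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x$inputs <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(x[order(names(x))], file = tmp)
  unname(tools::md5sum(tmp))
}
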