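# Telomere and centromeric tandem-repeat annotation.

#' Scan chromosome ends for tandem telomere-motif runs
#'
#' Looks for maximal tandem runs of the plant telomere heptamer (`CCCTAAA`
#' at the 5' end; its reverse complement `TTTAGGG` at the 3' end) anchored
#' within `max_offset` of the relevant chromosome end. A run grows copy by
#' copy while the adjacent copy matches the motif in a majority of its
#' positions and the run's cumulative mismatch fraction stays at or below
#' `max_mismatch_frac`. At most one hit (the longest) is reported per
#' chromosome end; runs shorter than `min_copies` are dropped.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param motif 5'-end motif (default `CCCTAAA`); the 3' end is scanned with
#'   its reverse complement.
#' @param min_copies Minimum tandem copies to report a hit.
#' @param max_offset Maximum distance (bp) between the run and the chromosome
#'   end.
#' @param max_mismatch_frac Maximum fraction of mismatching bases in the run.
#' @return Data frame: chrom, start, end (0-based half-open), end_of_chrom
#'   (`five_prime`/`three_prime`), n_copies, purity.
#' @export
scan_telomeres <- function(genome, motif = "CCCTAAA", min_copies = 50L,
                           max_offset = 10000L, max_mismatch_frac = 0.1) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be a non-empty ACGT string")
  chars <- genome_chars(genome)
  motif3 <- revcomp(motif)
  hits <- list()
  for (chrom in names(chars)) {
    seq <- chars[[chrom]]
    len <- nchar(seq)
    h5 <- best_tandem_run(seq, motif, anchor_lo = 0L,
                          anchor_hi = min(max_offset, len),
                          max_mismatch_frac = max_mismatch_frac)
    if (!is.null(h5) && h5$n_copies >= min_copies && h5$start <= max_offset) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = h5$start, end = h5$end,
        end_of_chrom = "five_prime", n_copies = h5$n_copies,
        purity = h5$purity, stringsAsFactors = FALSE
      )
    }
    h3 <- best_tandem_run(seq, motif3, anchor_lo = max(0L, len - max_offset),
                          anchor_hi = len, max_mismatch_frac = max_mismatch_frac)
    if (!is.null(h3) && h3$n_copies >= min_copies && len - h3$end <= max_offset) {
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = h3$start, end = h3$end,
        end_of_chrom = "three_prime", n_copies = h3$n_copies,
        purity = h3$purity, stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), end_of_chrom = character(),
                      n_copies = integer(), purity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Longest tandem run of `motif` whose first copy starts in
# [anchor_lo, anchor_hi) (0-based). Exact occurrences of the motif serve as
# anchors; each run is extended in both directions, accepting an adjacent
# copy while cumulative mismatches / run length <= max_mismatch_frac.
best_tandem_run <- function(seq, motif, anchor_lo, anchor_hi,
                            max_mismatch_frac) {
  w <- nchar(motif)
  len <- nchar(seq)
  region <- substr(seq, anchor_lo + 1L, min(len, anchor_hi + w))
  m <- gregexpr(motif, region, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  anchors <- anchor_lo + as.integer(m) - 1L   # 0-based
  best <- NULL
  claimed_up_to <- -1L
  for (a in anchors) {
    if (a <= claimed_up_to) next
    run_start <- a
    run_end <- a + w
    mism <- 0L
    copies <- 1L
    repeat {  # extend right
      nxt <- substr(seq, run_end + 1L, run_end + w)
      if (nchar(nxt) < w) break
      d <- hamming(nxt, motif)
      if (d > w / 2 || (mism + d) / (w * (copies + 1L)) > max_mismatch_frac) break
      mism <- mism + d
      copies <- copies + 1L
      run_end <- run_end + w
    }
    repeat {  # extend left
      if (run_start - w < 0L) break
      prv <- substr(seq, run_start - w + 1L, run_start)
      d <- hamming(prv, motif)
      if (d > w / 2 || (mism + d) / (w * (copies + 1L)) > max_mismatch_frac) break
      mism <- mism + d
      copies <- copies + 1L
      run_start <- run_start - w
    }
    claimed_up_to <- run_end - 1L
    if (is.null(best) || copies > best$n_copies) {
      best <- list(start = run_start, end = run_end, n_copies = copies,
                   purity = 1 - mism / (w * copies))
    }
  }
  best
}

#' Infer the period and consensus of a tandem-repeat monomer
#'
#' For every candidate period `p` in `[min_period, max_period]` computes the
#' fraction of positions `i` with `seq[i] == seq[i + p]` and returns the
#' period maximising that fraction (ties broken toward the smallest period,
#' which avoids reporting multiples of the true monomer). The consensus
#' monomer is the per-column majority base over the array chopped at that
#' period, reported in canonical rotation (lexicographically smallest among
#' rotations of itself and its reverse complement) so calls are independent
#' of array phase and orientation.
#'
#' @param seq Character scalar; the candidate array sequence.
#' @param min_period,max_period Period bounds in bp.
#' @param max_scan Use at most this many leading bases when scoring periods.
#' @return List with `monomer_length`, `monomer` (canonical rotation),
#'   `match_fraction`. If the best match fraction is below 0.5 the sequence
#'   has no usable tandem structure and `monomer_length`/`monomer` are `NA`.
#' @export
infer_tandem_monomer <- function(seq, min_period = 50L, max_period = 200L,
                                 max_scan = 50000L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L * max_period) {
    stop("sequence shorter than 2 * max_period")
  }
  if (nchar(seq) > max_scan) seq <- substr(seq, 1L, max_scan)
  x <- utf8ToInt(seq)
  n <- length(x)
  periods <- seq.int(min_period, max_period)
  score <- vapply(periods, function(p) {
    mean(x[seq_len(n - p)] == x[seq.int(p + 1L, n)])
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)[1]
  p <- periods[best]
  frac <- score[best]
  if (frac < 0.5) {
    return(list(monomer_length = NA_integer_, monomer = NA_character_,
                match_fraction = frac))
  }
  k <- n %/% p
  m <- matrix(x[seq_len(k * p)], nrow = p)
  cons_int <- apply(m, 1L, function(col) {
    tab <- tabulate(match(col, DNA_INTS), nbins = 4L)
    DNA_INTS[which.max(tab)]
  })
  consensus <- intToUtf8(cons_int)
  list(monomer_length = p, monomer = canonical_rotation(consensus),
       match_fraction = frac)
}

#' Locate the best tandem-array window genome-wide and infer its monomer
#'
#' Coarse helper for running [infer_tandem_monomer()] without prior knowledge
#' of the array location: slides fixed windows along each chromosome, scores
#' each window's best within-period self-match, and runs the full inference
#' on the highest-scoring window.
#'
#' @inheritParams infer_tandem_monomer
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @return As [infer_tandem_monomer()], plus `chrom` and `window_start`.
#' @export
infer_genome_monomer <- function(genome, min_period = 50L, max_period = 200L,
                                 window = 10000L, step = 10000L) {
  chars <- genome_chars(genome)
  best <- list(score = -Inf)
  for (chrom in names(chars)) {
    seq <- chars[[chrom]]
    len <- nchar(seq)
    if (len < window) next
    starts <- seq.int(0L, len - window, by = step)
    for (s in starts) {
      win <- substr(seq, s + 1L, s + window)
      x <- utf8ToInt(win)
      sc <- max(vapply(seq.int(min_period, max_period), function(p) {
        mean(x[seq_len(window - p)] == x[seq.int(p + 1L, window)])
      }, numeric(1)))
      if (sc > best$score) best <- list(score = sc, chrom = chrom, start = s)
    }
  }
  if (!is.finite(best$score) || best$score < 0.5) {
    return(list(monomer_length = NA_integer_, monomer = NA_character_,
                match_fraction = if (is.finite(best$score)) best$score else NA_real_,
                chrom = NA_character_, window_start = NA_real_))
  }
  win <- substr(chars[[best$chrom]], best$start + 1L, best$start + window)
  res <- infer_tandem_monomer(win, min_period, max_period)
  res$chrom <- best$chrom
  res$window_start <- best$start
  res
}

#' Call centromeric arrays from monomer occupancy
#'
#' Marks, in fixed scan windows, the fraction of bases covered by exact
#' occurrences of the monomer or its reverse complement (a tandem array
#' contains exact copies of every rotation of its monomer, so a single
#' rotation per orientation suffices); merges
#' consecutive windows with occupancy at or above `occupancy_threshold` into
#' maximal intervals; keeps intervals at least `min_array_length` long; and
#' reports at most one call (the longest) per chromosome. Boundaries are
#' snapped to scan-window edges.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param monomer Monomer string, e.g. from [infer_tandem_monomer()].
#' @param min_array_length Minimum interval length in bp.
#' @param occupancy_threshold Minimum covered-base fraction per window.
#' @param window Scan window in bp (default 1 kb).
#' @return Data frame: chrom, start, end, monomer, monomer_length, occupancy.
#' @export
call_centromeres <- function(genome, monomer, min_array_length = 10000L,
                             occupancy_threshold = 0.5, window = 1000L) {
  chars <- genome_chars(genome)
  w <- nchar(monomer)
  stopifnot(w >= 2L)
  calls <- list()
  for (chrom in names(chars)) {
    seq <- chars[[chrom]]
    len <- nchar(seq)
    starts0 <- integer(0)
    for (pat in unique(c(monomer, revcomp(monomer)))) {
      m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      if (m[1] != -1L) starts0 <- c(starts0, as.integer(m) - 1L)
    }
    if (length(starts0) == 0L) next
    cov <- logical(len)
    for (s in starts0) cov[(s + 1L):(s + w)] <- TRUE
    n_win <- ceiling(len / window)
    win_idx <- rep(seq_len(n_win), each = window, length.out = len)
    occ <- tapply(cov, win_idx, mean)
    pass <- occ >= occupancy_threshold
    r <- rle(as.vector(pass))
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values)
    best <- NULL
    for (ri in runs) {
      a <- (starts_i[ri] - 1L) * window
      b <- min(ends_i[ri] * window, len)
      if (b - a < min_array_length) next
      if (is.null(best) || (b - a) > (best$end - best$start)) {
        occ_run <- mean(cov[(a + 1L):b])
        best <- list(start = a, end = b, occupancy = occ_run)
      }
    }
    if (!is.null(best)) {
      calls[[chrom]] <- data.frame(
        chrom = chrom, start = best$start, end = best$end,
        monomer = monomer, monomer_length = w, occupancy = best$occupancy,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      monomer = character(), monomer_length = integer(),
                      occupancy = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
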