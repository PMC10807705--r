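# Shared low-level helpers: seeded RNG streams, sequence utilities, intervals.

DNA_INTS <- c(A = 65L, C = 67L, G = 71L, T = 84L)

#' Derive a reproducible sub-seed for a named simulation stage
#'
#' Each simulation stage draws from its own stream derived from the global
#' seed and the stage name, so adding or reordering stages never perturbs the
#' output of earlier ones.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer in `[1, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(as.numeric(seed)) * 69077 + h * 131 + 7) %% (2^31 - 3)
  as.integer(s) + 1L
}

# Evaluate `expr` under the stage's RNG stream, restoring caller RNG state.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Fast i.i.d. uniform ACGT sequence of length n as a single string.
rand_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(sample(DNA_INTS, n, replace = TRUE))
}

#' Reverse complement of a DNA string
#' @param x Character scalar over ACGTN.
#' @return Character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hamming distance between two equal-length strings (integer vectors of code
# points compared elementwise).
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Canonical rotation of a tandem-repeat monomer
#'
#' Returns the lexicographically smallest string among all rotations of the
#' monomer and of its reverse complement, so monomer calls are independent of
#' array phase and orientation.
#'
#' @param monomer Character scalar.
#' @return Character scalar of the same length.
#' @export
canonical_rotation <- function(monomer) {
  stopifnot(is.character(monomer), length(monomer) == 1L, nzchar(monomer))
  rots <- function(s) {
    n <- nchar(s)
    d <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
  }
  min(c(rots(monomer), rots(revcomp(monomer))))
}

# Overlap length between [s1, e1) and [s2, e2).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Replace seq[at .. at+nchar(what)-1] (0-based `at`) with `what`.
splice_string <- function(seq, at, what) {
  stopifnot(at >= 0, at + nchar(what) <= nchar(seq))
  paste0(substr(seq, 1L, at), what, substr(seq, at + nchar(what) + 1L, nchar(seq)))
}

# Coerce a genome to a named character vector; accepts DNAStringSet or
# named character.
genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    stopifnot(!is.null(names(genome)))
    genome
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
}

as_dnastringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(x)
}
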