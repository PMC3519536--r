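#' Generate random DNA sequences
#'
#' Draws independent bases with a specified GC content. Lengths may be given
#' as a single value, a vector (one per sequence), or a 2-vector range from
#' which integer lengths are drawn uniformly.
#'
#' @param n Number of sequences.
#' @param length Sequence length, scalar or one per sequence (recycled).
#' @param gc GC content in (0, 1); A/T and C/G are split evenly.
#' @return Character vector of `n` sequences over ACGT. Uses the current RNG
#'   state; call `set.seed()` for reproducibility.
#' @export
random_dna <- function(n, length, gc = 0.5) {
  stopifnot(n >= 1)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    abort("`gc` must lie strictly between 0 and 1")
  }
  lens <- rep_len(as.integer(length), n)
  if (any(lens < 1)) abort("sequence lengths must be positive")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE, prob = probs)
  big <- paste(bases, collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences (ACGTN; other characters map to N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCATGCA", x))
}

#' Point-substitute bases at a given per-position rate
#'
#' Each position of each sequence is independently substituted with
#' probability `rate` (scalar, or one rate per position when all sequences
#' share a length); the replacement base is uniform over the three
#' alternatives. Non-ACGT positions are left untouched.
#'
#' @param x Character vector of equal- or unequal-length sequences.
#' @param rate Substitution probability; a vector is interpreted per position
#'   and recycled across sequences of equal length.
#' @return List with `seq` (mutated sequences) and `positions` (list of
#'   0-based substituted positions per sequence).
#' @keywords internal
mutate_bases <- function(x, rate) {
  chars <- strsplit(x, "", fixed = TRUE)
  lens <- lengths(chars)
  if (length(rate) > 1L && length(unique(lens)) != 1L) {
    abort("per-position rates require equal-length sequences")
  }
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  out_pos <- vector("list", length(x))
  for (i in seq_along(chars)) {
    r <- rep_len(rate, lens[i])
    hit <- which(runif(lens[i]) < r)
    hit <- hit[chars[[i]][hit] %in% c("A", "C", "G", "T")]
    if (length(hit)) {
      picks <- sample.int(3L, length(hit), replace = TRUE)
      chars[[i]][hit] <- vapply(seq_along(hit), function(j) {
        alt[[chars[[i]][hit[j]]]][picks[j]]
      }, character(1))
    }
    out_pos[[i]] <- hit - 1L
  }
  list(seq = vapply(chars, paste, character(1), collapse = ""),
       positions = out_pos)
}

validate_read_seqs <- function(reads) {
  bad <- grepl("[^ACGTN]", reads$seq)
  if (any(bad)) {
    abort(sprintf("read '%s' contains characters outside ACGTN",
                  reads$read_id[which(bad)[1]]))
  }
  invisible(reads)
}

#' Mean Phred quality per read
#' @param qual Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities (`Inf` for `NA` strings, so reads
#'   without qualities are never rejected as low quality).
#' @keywords internal
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(Inf)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}
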