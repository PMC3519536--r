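#' Parameters of the coincidental-match model
#'
#' Describes the chance that a random read of length `L` has at least one
#' placement with at most `m` mismatches somewhere in an unrelated database
#' offering `N` searchable positions (summed over strands and sequences).
#'
#' @param read_length Read length `L` in nt.
#' @param max_mismatches Allowance `m` (must not exceed `L`).
#' @param n_positions Searchable positions `N`:
#'   sum over the database of strands x (sequence length - L + 1).
#' @param composition Background base probabilities (A, C, G, T), summing
#'   to 1.
#' @return A `coincidence_params` list.
#' @export
coincidence_params <- function(read_length, max_mismatches, n_positions,
                               composition = rep(0.25, 4)) {
  if (max_mismatches > read_length) {
    abort("max_mismatches must not exceed read_length")
  }
  if (n_positions < 0) abort("n_positions must be non-negative")
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-12) {
    abort("composition must be 4 probabilities summing to 1")
  }
  structure(list(read_length = as.integer(read_length),
                 max_mismatches = as.integer(max_mismatches),
                 n_positions = n_positions,
                 composition = composition),
            class = "coincidence_params")
}

#' Expected fraction of reads matching an unrelated database by chance
#'
#' At one position, a random read base matches a random reference base with
#' probability `sum(composition^2)` (1/4 under the uniform model), so the
#' per-position probability of a placement with at most `m` mismatches is
#' the binomial tail `P(Binom(L, q) <= m)` with `q` the per-base mismatch
#' probability. Treating the `N` positions as independent gives the exact
#' occupancy form `1 - (1 - p)^N`; the Poisson approximation
#' `1 - exp(-N p)` agrees to under 1% relative error whenever `N p < 0.01`.
#'
#' @param params A [coincidence_params()].
#' @param method `"exact"` or `"poisson"`.
#' @return A probability.
#' @export
expected_coincidental_fraction <- function(params,
                                           method = c("exact", "poisson")) {
  stopifnot(inherits(params, "coincidence_params"))
  method <- match.arg(method)
  q_mismatch <- 1 - sum(params$composition^2)
  p <- pbinom(params$max_mismatches, params$read_length, q_mismatch)
  if (params$n_positions == 0) return(0)
  if (method == "exact") {
    -expm1(params$n_positions * log1p(-p))
  } else {
    -expm1(-params$n_positions * p)
  }
}

#' Searchable positions offered by a database
#' @param db A [reference_db()]; genomic kinds count both strands.
#' @param read_length Read length in nt.
#' @return Total number of placements `N`.
#' @export
searchable_positions <- function(db, read_length) {
  lens <- nchar(db$sequences$seq)
  strands <- if (is_genome_kind(db)) 2 else 1
  strands * sum(pmax(lens - read_length + 1, 0))
}

#' Empirical coincidental-match fraction by simulation
#'
#' Draws random reads from the background composition and counts the
#' fraction with at least one placement within the mismatch allowance,
#' using the pigeonhole matcher.
#'
#' @param db A [reference_db()].
#' @param n_reads Number of random reads to draw.
#' @param read_length Read length in nt.
#' @param max_mismatches Allowance (0, 1 or 2).
#' @param seed Integer seed.
#' @param composition Background base probabilities (A, C, G, T); defaults
#'   to the database's empirical base frequencies.
#' @return One-row tibble: `fraction`, `n_matched`, `n_reads`, `n_positions`
#'   and the analytic `expected` fraction under the same composition.
#' @export
simulate_coincidence <- function(db, n_reads, read_length, max_mismatches,
                                 seed, composition = NULL) {
  set.seed(as.integer(seed))
  if (is.null(composition)) {
    counts <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(db$sequences$seq))[, c("A", "C", "G", "T"),
                                                  drop = FALSE])
    composition <- counts / sum(counts)
  }
  bases <- sample(c("A", "C", "G", "T"), n_reads * read_length,
                  replace = TRUE, prob = composition)
  big <- paste(bases, collapse = "")
  ends <- seq_len(n_reads) * read_length
  reads <- tibble(read_id = sprintf("rc%06d", seq_len(n_reads)),
                  seq = substring(big, ends - read_length + 1L, ends))
  eligible <- nchar(db$sequences$seq) >= read_length
  n_matched <- 0L
  if (any(eligible)) {
    idx <- build_index(db, read_length, max_mismatches)
    hits <- find_matches(idx, reads)
    n_matched <- length(unique(hits$read_id))
  }
  params <- coincidence_params(read_length, max_mismatches,
                               searchable_positions(db, read_length),
                               composition)
  tibble(fraction = n_matched / n_reads, n_matched = n_matched,
         n_reads = n_reads, n_positions = params$n_positions,
         expected = expected_coincidental_fraction(params))
}
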