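#' Build a pigeonhole seed index over a reference database
#'
#' For matching reads of one fixed length with up to `max_mismatches`
#' (0, 1 or 2) mismatches, the read is conceptually split into
#' `max_mismatches + 1` contiguous segments; any placement within the
#' mismatch budget leaves at least one segment exact (pigeonhole principle),
#' so exact lookup of each segment in a sorted k-mer table of the reference
#' enumerates a complete candidate set, which is verified by full Hamming
#' comparison. Genomic database kinds (`genome`, `microbiome`, `nt`) are
#' indexed on both strands; transcript kinds on the sense strand only.
#' `N` never matches anything, in reads or references.
#'
#' @param db A [reference_db()].
#' @param read_length Length of the reads this index will serve.
#' @param max_mismatches Mismatch budget: 0, 1 or 2.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(db, read_length, max_mismatches) {
  stopifnot(inherits(db, "reference_db"))
  if (!max_mismatches %in% 0:2) abort("max_mismatches must be 0, 1 or 2")
  if (read_length < max_mismatches + 1) {
    abort("read_length must be at least max_mismatches + 1")
  }
  if (nrow(db$sequences) == 0L) {
    abort(sprintf("database '%s' contains no sequences", db$id))
  }
  ptr <- si_build(toupper(db$sequences$seq), as.integer(read_length),
                  as.integer(max_mismatches), is_genome_kind(db))
  structure(list(ptr = ptr, db_id = db$id, kind = db$kind,
                 seq_ids = db$sequences$seq_id,
                 read_length = as.integer(read_length),
                 max_mismatches = as.integer(max_mismatches)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  info <- si_info(x$ptr)
  cat(sprintf(
    "<seed_index on '%s'> read length %d | <=%d mismatches | k=%d | %s postings (%s)\n",
    x$db_id, x$read_length, x$max_mismatches, info$k,
    format(info$n_postings, big.mark = ","),
    if (info$both_strands) "both strands" else "sense strand"))
  invisible(x)
}

#' Index statistics (segment length, posting count, strandedness)
#' @param index A `seed_index`.
#' @return A list of index parameters and sizes.
#' @export
index_info <- function(index) {
  si_info(index$ptr)
}

#' Find all k-mismatch placements of reads in an indexed reference
#'
#' Returns exactly the set of placements with Hamming distance at most
#' `max_mismatches` between each read and a reference window, strand
#' resolved: a `-` strand hit means the read matches the reverse complement
#' of the reference window `[start, end)`. Coordinates are 0-based half-open
#' on the reference forward strand.
#'
#' @param index A [build_index()] result.
#' @param reads Reads tibble (`read_id`, `seq`) or a character vector of
#'   sequences; all reads must have the index's read length.
#' @param max_mismatches Optional tighter budget than the index was built
#'   for (must not exceed it).
#' @return Tibble of hits: `read_id`, `db`, `seq_id`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @export
find_matches <- function(index, reads, max_mismatches = NULL) {
  stopifnot(inherits(index, "seed_index"))
  m <- max_mismatches %||% index$max_mismatches
  if (m > index$max_mismatches) {
    abort("index was built for a smaller mismatch budget")
  }
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("q%d", seq_along(reads)), seq = reads)
  }
  seqs <- toupper(reads$seq)
  if (any(nchar(seqs) != index$read_length)) {
    abort(sprintf("all reads must have length %d for this index",
                  index$read_length))
  }
  raw <- si_query(index$ptr, seqs)
  out <- tibble(read_id = reads$read_id[raw$read],
                db = index$db_id,
                seq_id = index$seq_ids[raw$seq],
                start = raw$start,
                end = raw$start + index$read_length,
                strand = raw$strand,
                mismatches = raw$mismatches)
  if (m < index$max_mismatches) out <- out[out$mismatches <= m, ]
  out
}

#' Export hits as TSV or SAM
#'
#' The SAM flavor is minimal interoperability output: flag 0/16, 1-based
#' POS, full-length `M` CIGAR and an `NM` tag; minus-strand records store
#' the reverse complement of the read, as SAM requires.
#'
#' @param hits Hits tibble from [find_matches()].
#' @param path Output path.
#' @param reads Reads tibble (needed for SAM SEQ fields).
#' @param db The [reference_db()] the hits refer to (for SAM `@SQ` headers).
#' @return The hits tibble, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(hits)
}

#' @rdname write_hits_tsv
#' @export
write_hits_sam <- function(hits, reads, db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", db$sequences$seq_id,
                     nchar(db$sequences$seq)), con)
  seq_of <- setNames(reads$seq, reads$read_id)
  if (nrow(hits)) {
    s <- seq_of[hits$read_id]
    minus <- hits$strand == "-"
    s[minus] <- revcomp(s[minus])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       hits$read_id, ifelse(minus, 16L, 0L), hits$seq_id,
                       hits$start + 1L, nchar(s), s, hits$mismatches), con)
  }
  invisible(hits)
}
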