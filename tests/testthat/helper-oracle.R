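# Independent oracles used across tests: a naive all-positions Hamming scan
# (vectorized over window starts, nothing shared with the pigeonhole path)
# and a set-intersection LCA.

ACGT_CODES <- utf8ToInt("ACGT")

# All placements of `read` in `ref` (single strand) with <= m mismatches.
# Returns a data.frame(start, mismatches), start 0-based.
oracle_scan <- function(ref, read, m) {
  r <- utf8ToInt(ref)
  q <- utf8ToInt(read)
  L <- length(q)
  n <- length(r)
  if (n < L) return(data.frame(start = integer(), mismatches = integer()))
  nw <- n - L + 1L
  mm <- integer(nw)
  r_ok <- r %in% ACGT_CODES
  q_ok <- q %in% ACGT_CODES
  for (j in seq_len(L)) {
    win <- seq.int(j, j + nw - 1L)
    mm <- mm + as.integer(r[win] != q[j] | !r_ok[win] | !q_ok[j])
  }
  keep <- which(mm <= m)
  data.frame(start = keep - 1L, mismatches = mm[keep])
}

# Full-database oracle with the same output columns as find_matches().
oracle_hits <- function(db, reads, m) {
  both <- db$kind %in% c("genome", "microbiome", "nt")
  out <- list()
  for (s in seq_len(nrow(db$sequences))) {
    ref <- db$sequences$seq[s]
    n <- nchar(ref)
    for (i in seq_len(nrow(reads))) {
      fw <- oracle_scan(ref, reads$seq[i], m)
      if (nrow(fw)) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = reads$read_id[i], db = db$id,
          seq_id = db$sequences$seq_id[s], start = fw$start,
          end = fw$start + nchar(reads$seq[i]), strand = "+",
          mismatches = fw$mismatches)
      }
      if (both) {
        rv <- oracle_scan(exosieve::revcomp(ref), reads$seq[i], m)
        if (nrow(rv)) {
          L <- nchar(reads$seq[i])
          out[[length(out) + 1L]] <- data.frame(
            read_id = reads$read_id[i], db = db$id,
            seq_id = db$sequences$seq_id[s],
            start = n - rv$start - L, end = n - rv$start, strand = "-",
            mismatches = rv$mismatches)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(read_id = character(), db = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               mismatches = integer())
  }
  res[order(res$read_id, res$seq_id, res$start, res$strand), ]
}

sort_hits <- function(h) {
  h <- as.data.frame(h)[, c("read_id", "db", "seq_id", "start", "end",
                            "strand", "mismatches")]
  h <- h[order(h$read_id, h$seq_id, h$start, h$strand), ]
  rownames(h) <- NULL
  h
}

# Independent LCA: deepest node among the intersection of full ancestor sets.
oracle_lca <- function(taxonomy, taxids) {
  anc_set <- function(t) {
    out <- t
    while (TRUE) {
      p <- taxonomy$parent_taxid[taxonomy$taxid == t]
      if (p == t) break
      out <- c(out, p)
      t <- p
    }
    out
  }
  depth <- function(t) length(anc_set(t))
  common <- Reduce(intersect, lapply(unique(taxids), anc_set))
  common[which.max(vapply(common, depth, integer(1)))]
}

# Leftmost acceptable adapter alignment, scanned naively.
oracle_trim_pos <- function(seq, adapter, min_overlap, max_rate) {
  n <- nchar(seq)
  a <- utf8ToInt(adapter)
  s <- utf8ToInt(seq)
  for (pos in 0:(n - min_overlap)) {
    if (pos + min_overlap > n) break
    ov <- min(length(a), n - pos)
    piece <- s[(pos + 1):(pos + ov)]
    ap <- a[1:ov]
    mm <- sum(piece != ap | !(piece %in% ACGT_CODES))
    if (mm / ov <= max_rate + 1e-9) return(pos)
  }
  -1L
}
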