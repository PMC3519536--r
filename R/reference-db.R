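#' Reference database for one classification tier
#'
#' A reference database bundles the sequences searched by one tier of the
#' map-and-remove cascade, their taxon labels, and optional structural-RNA
#' (rRNA/tRNA) feature intervals used for masking.
#'
#' Tier kinds determine strandedness: `genome`, `microbiome` and `nt`
#' databases are genomic and are searched (and simulated) on both strands;
#' `miRNA`, `transcripts` and `exo_miRNA` are stranded transcript pools
#' searched on the sense strand only.
#'
#' @param id Database identifier (string).
#' @param kind One of `"miRNA"`, `"transcripts"`, `"genome"`,
#'   `"microbiome"`, `"exo_miRNA"`, `"nt"`.
#' @param sequences Tibble with columns `seq_id` (unique), `seq`
#'   (ACGTN string) and `taxid` (integer taxon label).
#' @param features Optional tibble of structural-RNA intervals with columns
#'   `seq_id`, `start`, `end` (0-based half-open) and `kind`
#'   (`"rRNA"` or `"tRNA"`).
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(id, kind, sequences, features = NULL) {
  kinds <- c("miRNA", "transcripts", "genome", "microbiome", "exo_miRNA", "nt")
  if (!is.character(id) || length(id) != 1L) abort("`id` must be a string")
  kind <- match.arg(kind, kinds)
  sequences <- as_tibble(sequences)
  stopifnot(all(c("seq_id", "seq", "taxid") %in% names(sequences)))
  if (anyDuplicated(sequences$seq_id)) {
    abort(sprintf("duplicate sequence ids in database '%s'", id))
  }
  if (is.null(features)) {
    features <- tibble(seq_id = character(), start = integer(),
                       end = integer(), kind = character())
  }
  features <- as_tibble(features)
  stopifnot(all(c("seq_id", "start", "end", "kind") %in% names(features)))
  if (nrow(features)) {
    lens <- setNames(nchar(sequences$seq), sequences$seq_id)
    if (!all(features$seq_id %in% sequences$seq_id)) {
      abort(sprintf("feature refers to unknown sequence in database '%s'", id))
    }
    bad <- features$start < 0 | features$end > lens[features$seq_id] |
      features$start >= features$end
    if (any(bad)) abort(sprintf("feature interval out of bounds in '%s'", id))
    if (!all(features$kind %in% c("rRNA", "tRNA"))) {
      abort("feature kind must be 'rRNA' or 'tRNA'")
    }
  }
  structure(list(id = id, kind = kind, sequences = sequences,
                 features = features),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db '%s'> kind: %s | %d sequences (%.2f Mb) | %d features\n",
              x$id, x$kind, nrow(x$sequences),
              sum(nchar(x$sequences$seq)) / 1e6, nrow(x$features)))
  invisible(x)
}

#' Is a database kind genomic (searched on both strands)?
#' @param db A `reference_db`.
#' @return Logical.
#' @export
is_genome_kind <- function(db) {
  db$kind %in% c("genome", "microbiome", "nt")
}

#' Write / read reference databases as FASTA (+ BED sidecar)
#'
#' FASTA headers carry the taxon label as `seq_id taxid=NNN`; feature
#' intervals go to a 4-column BED-style sidecar (`seq_id`, `start`, `end`,
#' `kind`; 0-based half-open).
#'
#' @param db A `reference_db`.
#' @param fasta Path to the FASTA file.
#' @param bed Optional path for the feature sidecar (written/read only when
#'   given).
#' @return `write_reference_fasta()` returns `db` invisibly;
#'   `read_reference_fasta()` returns a `reference_db`.
#' @export
write_reference_fasta <- function(db, fasta, bed = NULL) {
  x <- Biostrings::DNAStringSet(db$sequences$seq)
  names(x) <- sprintf("%s taxid=%d", db$sequences$seq_id, db$sequences$taxid)
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(bed) && nrow(db$features)) {
    readr::write_tsv(db$features, bed, col_names = FALSE)
  }
  invisible(db)
}

#' @param id,kind Passed to [reference_db()] when reading.
#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(fasta, id, kind, bed = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  hdr <- names(x)
  seq_id <- unname(sub("\\s.*$", "", hdr))
  taxid <- suppressWarnings(as.integer(sub(".*taxid=(\\d+).*", "\\1", hdr)))
  features <- NULL
  if (!is.null(bed) && file.exists(bed)) {
    features <- readr::read_tsv(bed, col_names = c("seq_id", "start", "end", "kind"),
                                col_types = "ciic", progress = FALSE)
  }
  reference_db(id, kind,
               tibble(seq_id = seq_id, seq = unname(toupper(as.character(x))),
                      taxid = unname(taxid)),
               features)
}
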