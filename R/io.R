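#' Read and write short reads as FASTQ / FASTA
#'
#' Qualities are Phred+33. `read_reads_fastq()` returns the reads tibble the
#' rest of the package consumes (`read_id`, `seq`, `qual`).
#'
#' @param reads Tibble with columns `read_id`, `seq` and (for FASTQ) `qual`.
#' @param path File path.
#' @return The reads tibble (invisibly for writers).
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qual)
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(reads)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  # Biostrings warns that the FASTQ metadata columns are dropped on the
  # QualityScaledDNAStringSet cast; they are empty here, so that is fine
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- suppressWarnings(as.character(methods::as(x, "DNAStringSet")))
  tibble(read_id = unname(sub("\\s.*$", "", names(x))),
         seq = unname(toupper(seqs)),
         qual = unname(as.character(methods::slot(x, "quality"))))
}

#' @rdname write_reads_fastq
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path)
  invisible(reads)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(read_id = unname(sub("\\s.*$", "", names(x))),
         seq = unname(toupper(as.character(x))), qual = NA_character_)
}

#' Read and write the simplified taxonomy table
#'
#' Four tab-separated columns with header: `taxid`, `parent_taxid`, `rank`,
#' `name` — a flattened nodes+names dialect. The root is its own parent.
#'
#' @param taxonomy Tibble with the four columns above.
#' @param path File path.
#' @return The taxonomy tibble (invisibly for the writer).
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path)
  invisible(taxonomy)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path) {
  readr::read_tsv(path, col_types = "iicc", progress = FALSE)
}

#' Read and write simulation truth tables
#'
#' The `error_pos` list-column is serialized as a comma-separated string
#' (empty for error-free reads).
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param path File path.
#' @return The truth tibble (invisibly for the writer).
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth
  out$error_pos <- vapply(truth$error_pos, paste, character(1), collapse = ",")
  readr::write_tsv(out, path)
  invisible(truth)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccciiicci", progress = FALSE)
  raw <- ifelse(is.na(out$error_pos), "", out$error_pos)
  out$error_pos <- lapply(strsplit(raw, ",", fixed = TRUE), function(x) {
    as.integer(x[nzchar(x)])
  })
  out
}

#' Read and write community configurations as YAML
#'
#' @param config A [community_config()].
#' @param path File path.
#' @return `write_community_config()` returns `config` invisibly;
#'   `read_community_config()` returns a `community_config`.
#' @export
write_community_config <- function(config, path) {
  as_plain <- list(
    tiers = lapply(config$tiers, function(t) {
      list(id = t$id, kind = t$kind,
           species = lapply(t$species, function(s) {
             list(name = s$name, lineage = as.list(s$lineage),
                  n_seqs = s$n_seqs, length = s$length, gc = s$gc)
           }))
    }),
    conserved = lapply(config$conserved, function(g) {
      list(name = g$name, kind = g$kind, length = g$length,
           divergence = g$divergence,
           placements = lapply(seq_len(nrow(g$placements)), function(i) {
             as.list(g$placements[i, ])
           }))
    }))
  yaml::write_yaml(as_plain, path)
  invisible(config)
}

#' @rdname write_community_config
#' @export
read_community_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tiers <- lapply(raw$tiers, function(t) {
    tier_config(t$id, t$kind, lapply(t$species, function(s) {
      species_spec(s$name, unlist(s$lineage) %||% character(),
                   s$n_seqs, unlist(s$length), s$gc)
    }))
  })
  conserved <- lapply(raw$conserved, function(g) {
    conserved_gene(g$name, g$kind, g$length, g$divergence,
                   dplyr::bind_rows(lapply(g$placements, as_tibble)))
  })
  community_config(tiers, conserved)
}
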