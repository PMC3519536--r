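#' Preprocessing parameters
#'
#' Controls 3' adapter trimming and the four read filters (length, mean
#' quality, adapter-only, polyA-only). Thresholds default to values typical
#' for small-RNA libraries: inserts of 16-35 nt, mean Phred >= 20, and a
#' read counted as polyA when >= 90% of its bases are A.
#'
#' @param adapter_3p 3' adapter sequence (required for trimming).
#' @param min_overlap Minimum adapter/read overlap in nt.
#' @param max_adapter_mismatch_rate Maximum mismatch fraction over the
#'   adapter/read overlap.
#' @param min_length,max_length Kept insert length range in nt.
#' @param min_mean_quality Minimum mean Phred score.
#' @param polyA_fraction A-content at or above which a read is polyA-only.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter_3p, min_overlap = 5,
                              max_adapter_mismatch_rate = 0.1,
                              min_length = 16, max_length = 35,
                              min_mean_quality = 20, polyA_fraction = 0.9) {
  if (!is.character(adapter_3p) || !nzchar(adapter_3p)) {
    abort("`adapter_3p` must be a non-empty sequence")
  }
  if (min_length > max_length) abort("min_length must not exceed max_length")
  if (min_overlap < 1) abort("min_overlap must be at least 1")
  if (max_adapter_mismatch_rate < 0 || max_adapter_mismatch_rate > 1) {
    abort("max_adapter_mismatch_rate must lie in [0, 1]")
  }
  if (polyA_fraction < 0 || polyA_fraction > 1) {
    abort("polyA_fraction must lie in [0, 1]")
  }
  structure(list(adapter_3p = toupper(adapter_3p),
                 min_overlap = as.integer(min_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 min_mean_quality = min_mean_quality,
                 polyA_fraction = polyA_fraction),
            class = "preprocess_params")
}

#' Trim the 3' adapter from reads
#'
#' The leftmost alignment of the adapter prefix against the read with
#' overlap >= `min_overlap` and mismatch fraction <=
#' `max_adapter_mismatch_rate` truncates the read at that position
#' (qualities are truncated alongside). Reads trimmed to length zero are
#' flagged `adapter_only`; reads with no acceptable alignment are returned
#' unchanged.
#'
#' @param reads Reads tibble (`read_id`, `seq`, optional `qual`).
#' @param params A [preprocess_params()].
#' @return The reads tibble with trimmed `seq`/`qual` plus logical columns
#'   `trimmed` and `adapter_only`.
#' @export
trim_adapter <- function(reads, params) {
  stopifnot(inherits(params, "preprocess_params"))
  reads <- as_tibble(reads)
  validate_read_seqs(reads)
  pos <- trim_adapter_cpp(toupper(reads$seq), params$adapter_3p,
                          params$min_overlap,
                          params$max_adapter_mismatch_rate)
  hit <- pos >= 0L
  out <- reads
  out$seq[hit] <- substr(reads$seq[hit], 1L, pos[hit])
  if ("qual" %in% names(out)) {
    ok <- hit & !is.na(out$qual)
    out$qual[ok] <- substr(reads$qual[ok], 1L, pos[ok])
  }
  out$trimmed <- hit
  out$adapter_only <- pos == 0L
  out
}

#' Filter reads with full rejection accounting
#'
#' Applies the cleanup filters in a fixed precedence order (first matching
#' reason wins): `adapter_only` (trimmed to empty), `too_short`,
#' `too_long`, `polyA_only` (A fraction >= threshold), `low_quality`
#' (mean Phred below threshold). Counts are conserved:
#' kept + all rejections = input.
#'
#' @param reads Reads tibble, usually the output of [trim_adapter()]; an
#'   `adapter_only` column is honored if present.
#' @param params A [preprocess_params()].
#' @return List with `reads` (kept tibble, helper columns dropped) and
#'   `summary` (one-row tibble of input/kept/per-reason counts).
#' @export
filter_reads <- function(reads, params) {
  stopifnot(inherits(params, "preprocess_params"))
  reads <- as_tibble(reads)
  validate_read_seqs(reads[nzchar(reads$seq), ])
  n <- nrow(reads)
  len <- nchar(reads$seq)
  adapter_only <- if ("adapter_only" %in% names(reads)) {
    reads$adapter_only | len == 0L
  } else {
    len == 0L
  }
  frac_a <- ifelse(len > 0,
                   stringi::stri_count_fixed(reads$seq, "A") / len, 0)
  quals <- if ("qual" %in% names(reads)) mean_phred(reads$qual) else Inf

  reason <- rep(NA_character_, n)
  reason[is.na(reason) & adapter_only] <- "adapter_only"
  reason[is.na(reason) & len < params$min_length] <- "too_short"
  reason[is.na(reason) & len > params$max_length] <- "too_long"
  reason[is.na(reason) & frac_a >= params$polyA_fraction] <- "polyA_only"
  reason[is.na(reason) & quals < params$min_mean_quality] <- "low_quality"

  kept <- reads[is.na(reason), setdiff(names(reads), c("trimmed", "adapter_only"))]
  summary <- tibble(
    input = n, kept = nrow(kept),
    adapter_only = sum(reason == "adapter_only", na.rm = TRUE),
    too_short = sum(reason == "too_short", na.rm = TRUE),
    too_long = sum(reason == "too_long", na.rm = TRUE),
    polyA_only = sum(reason == "polyA_only", na.rm = TRUE),
    low_quality = sum(reason == "low_quality", na.rm = TRUE))
  list(reads = kept, summary = summary)
}

#' Trim and filter in one call
#'
#' @inheritParams filter_reads
#' @return As [filter_reads()].
#' @export
preprocess_reads <- function(reads, params) {
  filter_reads(trim_adapter(reads, params), params)
}

#' Write a preprocessing summary as TSV or JSON
#' @param summary One-row summary tibble from [filter_reads()].
#' @param path Output path.
#' @return The summary, invisibly.
#' @export
write_preprocess_summary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE)
  } else {
    readr::write_tsv(summary, path)
  }
  invisible(summary)
}
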