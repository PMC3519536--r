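#' Tier specification for the map-and-remove cascade
#'
#' An ordered table of (database, category label, mismatch policy). Tiers
#' with policy `"strategy"` use the run's strategy value (0, 1 or 2
#' mismatches); tiers with policy `"fixed0"` always require exact matches —
#' miRNA tiers because mature miRNAs are near-identical across families, and
#' all exogenous tiers to keep cross-species assignment conservative.
#'
#' @param db Character vector of database ids, in search order.
#' @param category Category label per tier (unique).
#' @param policy `"fixed0"` or `"strategy"`, per tier.
#' @return A `tier_spec` tibble.
#' @export
tier_spec <- function(db, category, policy) {
  if (anyDuplicated(category)) abort("tier category labels must be unique")
  if (anyDuplicated(db)) abort("tier database ids must be unique")
  if (!all(policy %in% c("fixed0", "strategy"))) {
    abort("policy must be 'fixed0' or 'strategy'")
  }
  if ("unmapped" %in% category) abort("'unmapped' is reserved")
  structure(tibble(db = db, category = category, policy = policy),
            class = c("tier_spec", class(tibble())))
}

#' The canonical six-tier cascade
#'
#' Host miRNA (exact), host transcripts and host genome (strategy-
#' controlled), then microbiome, exogenous miRNA and the nucleotide
#' collection, all exact.
#'
#' @param mirna,transcripts,genome,microbiome,exo_mirna,nt Database ids.
#' @return A [tier_spec()].
#' @export
default_tier_spec <- function(mirna = "host_mirna",
                              transcripts = "host_transcripts",
                              genome = "host_genome",
                              microbiome = "microbiome",
                              exo_mirna = "exo_mirna", nt = "nt") {
  tier_spec(
    db = c(mirna, transcripts, genome, microbiome, exo_mirna, nt),
    category = c("endogenous_miRNA", "human_transcripts", "human_genome",
                 "microbiome", "exogenous_miRNA", "other"),
    policy = c("fixed0", "strategy", "strategy", "fixed0", "fixed0",
               "fixed0"))
}

#' Run the tiered map-and-remove cascade
#'
#' Reads are screened against the tier databases in order. A read with at
#' least one valid placement in the current tier is assigned that tier's
#' category and removed from the stream — it is never tested against later
#' tiers. Reads surviving every tier are `"unmapped"`. All hits of each
#' assigned read in its winning tier are retained for downstream taxonomy.
#'
#' @param reads Reads tibble (`read_id`, `seq`); lengths may vary — each
#'   tier is searched through per-length seed indexes.
#' @param dbs Named list of [reference_db()] objects.
#' @param tiers A [tier_spec()].
#' @param strategy Mismatch allowance (0, 1 or 2) for strategy-controlled
#'   tiers; fixed-0 tiers ignore it.
#' @return An object of class `rna_classification`: `assignments` (tibble
#'   `read_id`, `category`, `tier`, `n_hits`), `hits` (tibble of retained
#'   placements with their `category`), `counts` (tibble `category`, `n`,
#'   including zero rows and `"unmapped"`), plus `strategy`, `tiers`,
#'   `n_reads`.
#' @export
run_map_and_remove <- function(reads, dbs, tiers, strategy = 0) {
  stopifnot(inherits(tiers, "tier_spec"))
  if (!strategy %in% 0:2) abort("strategy must be 0, 1 or 2")
  reads <- as_tibble(reads)
  for (i in seq_len(nrow(tiers))) {
    db <- dbs[[tiers$db[i]]]
    if (is.null(db) || nrow(db$sequences) == 0L) {
      abort(sprintf("tier '%s' has a missing or empty database ('%s')",
                    tiers$category[i], tiers$db[i]))
    }
  }

  remaining <- reads
  assignment_rows <- list()
  hit_rows <- list()
  for (i in seq_len(nrow(tiers))) {
    if (nrow(remaining) == 0L) break
    db <- dbs[[tiers$db[i]]]
    m <- if (tiers$policy[i] == "strategy") as.integer(strategy) else 0L
    lens <- sort(unique(nchar(remaining$seq)))
    tier_hits <- vector("list", length(lens))
    for (j in seq_along(lens)) {
      sub <- remaining[nchar(remaining$seq) == lens[j], ]
      idx <- build_index(db, lens[j], m)
      tier_hits[[j]] <- find_matches(idx, sub)
    }
    tier_hits <- dplyr::bind_rows(tier_hits)
    if (nrow(tier_hits) == 0L) next
    assigned <- unique(tier_hits$read_id)
    tier_hits$category <- tiers$category[i]
    hit_rows[[i]] <- tier_hits
    assignment_rows[[i]] <- tibble(
      read_id = assigned, category = tiers$category[i], tier = i,
      n_hits = as.integer(table(tier_hits$read_id)[assigned]))
    remaining <- remaining[!remaining$read_id %in% assigned, ]
  }

  assignments <- dplyr::bind_rows(c(
    list(tibble(read_id = character(), category = character(),
                tier = integer(), n_hits = integer())),
    assignment_rows))
  if (nrow(remaining)) {
    assignments <- dplyr::bind_rows(
      assignments,
      tibble(read_id = remaining$read_id, category = "unmapped",
             tier = NA_integer_, n_hits = 0L))
  }
  cats <- c(tiers$category, "unmapped")
  counts <- tibble(
    category = cats,
    n = unname(vapply(cats, function(cc) sum(assignments$category == cc),
                      integer(1))))

  structure(list(assignments = assignments,
                 hits = dplyr::bind_rows(hit_rows),
                 counts = counts, strategy = as.integer(strategy),
                 tiers = tiers, n_reads = nrow(reads)),
            class = "rna_classification")
}

#' @export
print.rna_classification <- function(x, ...) {
  cat(sprintf("<rna_classification> %d reads | strategy %d\n",
              x$n_reads, x$strategy))
  print(category_fractions(x), n = Inf)
  invisible(x)
}

#' Per-category fractions of processed reads
#'
#' @param x An `rna_classification`.
#' @return Tibble with `category`, `n`, `fraction` and `percent` (summing to
#'   100 within rounding), over all processed reads including `"unmapped"`.
#' @export
category_fractions <- function(x) {
  stopifnot(inherits(x, "rna_classification"))
  if (x$n_reads == 0L) {
    abort("category fractions are undefined for zero processed reads")
  }
  dplyr::mutate(x$counts, fraction = .data$n / x$n_reads,
                percent = 100 * .data$fraction)
}

#' @export
tidy.rna_classification <- function(x, ...) {
  x$assignments
}

#' @export
glance.rna_classification <- function(x, ...) {
  unm <- x$counts$n[x$counts$category == "unmapped"]
  tibble(n_reads = x$n_reads, strategy = x$strategy,
         n_tiers = nrow(x$tiers),
         n_mapped = x$n_reads - unm,
         pct_unmapped = if (x$n_reads > 0) 100 * unm / x$n_reads else NA_real_)
}

#' Write a classification table / category summary as TSV or JSON
#' @param x An `rna_classification`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_classification_tsv <- function(x, path) {
  readr::write_tsv(x$assignments, path)
  invisible(x)
}

#' @rdname write_classification_tsv
#' @export
write_category_summary <- function(x, path) {
  fr <- category_fractions(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(strategy = x$strategy, n_reads = x$n_reads,
           categories = fr),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(fr, path)
  }
  invisible(x)
}
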