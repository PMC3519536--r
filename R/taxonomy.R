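#' Taxonomy tree
#'
#' Wraps the simplified taxonomy table (taxid, parent, rank, name) with
#' fast parent/rank/name lookup. The root is its own parent; every parent
#' chain must terminate at the root.
#'
#' @param nodes Tibble with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("taxid", "parent_taxid", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$taxid)) abort("duplicate taxids in taxonomy")
  key <- as.character(nodes$taxid)
  parent <- setNames(nodes$parent_taxid, key)
  if (!all(nodes$parent_taxid %in% nodes$taxid)) {
    abort("taxonomy parent refers to an unknown taxid")
  }
  roots <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(roots) != 1L) abort("taxonomy must have exactly one root")
  # verify chains terminate (no cycles other than the root self-loop)
  for (t in nodes$taxid) {
    seen <- 0L
    cur <- t
    while (cur != roots) {
      cur <- parent[[as.character(cur)]]
      if ((seen <- seen + 1L) > nrow(nodes)) {
        abort("taxonomy contains a cycle")
      }
    }
  }
  structure(list(nodes = nodes, parent = parent,
                 rank = setNames(nodes$rank, key),
                 name = setNames(nodes$name, key),
                 root = roots),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes | ranks: %s\n", nrow(x$nodes),
              paste(unique(x$nodes$rank), collapse = ", ")))
  invisible(x)
}

#' Root-to-node ancestor path
#' @param tree A [taxonomy_tree()].
#' @param taxid A single taxid.
#' @return Integer vector of taxids from the root down to `taxid`.
#' @export
ancestor_path <- function(tree, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(tree$parent)) {
    abort(sprintf("taxid %s not found in taxonomy", key))
  }
  path <- integer()
  cur <- as.integer(taxid)
  repeat {
    path <- c(cur, path)
    if (cur == tree$root) break
    cur <- tree$parent[[as.character(cur)]]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#' @param tree A [taxonomy_tree()].
#' @param taxids Integer vector of taxids.
#' @return The LCA taxid.
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(taxids)
  paths <- lapply(taxids, function(t) ancestor_path(tree, t))
  depth <- min(lengths(paths))
  common <- tree$root
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[[`, integer(1), d)
    if (length(unique(level)) != 1L) break
    common <- level[1]
  }
  common
}

#' Ancestor of a taxon at a named rank
#' @param tree A [taxonomy_tree()].
#' @param taxid A single taxid.
#' @param rank Rank name (e.g. `"phylum"`).
#' @return The taxid of the ancestor at `rank`, or `NA` if the chain lacks
#'   that rank.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  path <- ancestor_path(tree, taxid)
  at <- path[tree$rank[as.character(path)] == rank]
  if (length(at)) at[length(at)] else NA_integer_
}

#' Resolve per-read hits to taxa
#'
#' For each read, hits are filtered to the minimal mismatch count; if all
#' surviving hits point to one taxon the read is assigned to it at that
#' taxon's rank, otherwise to the lowest common ancestor of the surviving
#' taxa. A read's `structural_rna` flag is set when any surviving hit
#' overlaps an annotated rRNA/tRNA feature by at least one base.
#'
#' @param hits Hits tibble from one tier (single database), e.g. the
#'   `hits` element of [run_map_and_remove()] filtered to one category.
#' @param db The [reference_db()] the hits refer to.
#' @param tree A [taxonomy_tree()].
#' @return Tibble of `TaxonAssignment`s: `read_id`, `taxid`, `level`
#'   (the assigned node's rank), `structural_rna`.
#' @export
assign_taxa <- function(hits, db, tree) {
  stopifnot(inherits(db, "reference_db"), inherits(tree, "taxonomy_tree"))
  hits <- as_tibble(hits)
  if (nrow(hits) == 0L) {
    return(tibble(read_id = character(), taxid = integer(),
                  level = character(), structural_rna = logical()))
  }
  if (!all(hits$seq_id %in% db$sequences$seq_id)) {
    abort("hit refers to a sequence absent from the database")
  }
  taxid_of <- setNames(db$sequences$taxid, db$sequences$seq_id)
  if (!all(as.character(taxid_of[unique(hits$seq_id)]) %in%
           names(tree$parent))) {
    abort("hit refers to a taxid absent from the taxonomy")
  }

  # keep only minimal-mismatch hits per read
  best <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$mismatches == min(.data$mismatches)) |>
    dplyr::ungroup()
  best$taxid <- unname(taxid_of[best$seq_id])

  # structural-RNA flag: any surviving hit overlapping a feature by >= 1 base
  flagged <- character()
  if (nrow(db$features)) {
    ov <- dplyr::inner_join(best, db$features, by = "seq_id",
                            suffix = c("", ".f"),
                            relationship = "many-to-many")
    ov <- ov[ov$start < ov$end.f & ov$end > ov$start.f, ]
    flagged <- unique(ov$read_id)
  }

  # LCA per distinct taxon set (memoized)
  sets <- best |>
    dplyr::distinct(.data$read_id, .data$taxid) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(key = paste(sort(unique(.data$taxid)), collapse = ","))
  uniq <- unique(sets$key)
  resolved <- vapply(uniq, function(k) {
    ids <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    if (length(ids) == 1L) ids else lca(tree, ids)
  }, integer(1))
  assigned <- unname(resolved[match(sets$key, uniq)])

  tibble(read_id = sets$read_id,
         taxid = assigned,
         level = unname(tree$rank[as.character(assigned)]),
         structural_rna = sets$read_id %in% flagged)
}

#' Roll taxon assignments up to a fixed rank
#'
#' Each assignment contributes one count to its ancestor at the requested
#' rank; assignments whose lineage lacks that rank are counted as
#' `"unranked"`. If the assignments carry a `sample` column, counts are
#' reported per sample.
#'
#' @param assignments Tibble from [assign_taxa()] (optionally with a
#'   `sample` column).
#' @param tree A [taxonomy_tree()].
#' @param rank Target rank, e.g. `"phylum"`.
#' @return Tibble of counts: (`sample`,) `taxid` (NA for unranked), `name`,
#'   `n`.
#' @export
rollup <- function(assignments, tree, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!rank %in% tree$nodes$rank) {
    abort(sprintf("rank '%s' is not present in the taxonomy", rank))
  }
  assignments <- as_tibble(assignments)
  uniq <- unique(assignments$taxid)
  anc <- vapply(uniq, function(t) ancestor_at_rank(tree, t, rank), integer(1))
  assignments$rollup_taxid <- anc[match(assignments$taxid, uniq)]
  grp <- if ("sample" %in% names(assignments)) {
    c("sample", "rollup_taxid")
  } else {
    "rollup_taxid"
  }
  out <- assignments |>
    dplyr::count(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::rename(taxid = "rollup_taxid")
  out$name <- ifelse(is.na(out$taxid), "unranked",
                     unname(tree$name[as.character(out$taxid)]))
  out[c(setdiff(grp, "rollup_taxid"), "taxid", "name", "n")]
}

#' Mean rollup across samples
#'
#' Computes the per-sample rollup and averages counts across samples with an
#' unweighted arithmetic mean, counting a taxon as zero in samples where it
#' was not observed.
#'
#' @inheritParams rollup
#' @return Tibble `taxid`, `name`, `mean_n`.
#' @export
rollup_mean <- function(assignments, tree, rank) {
  assignments <- as_tibble(assignments)
  if (!"sample" %in% names(assignments)) {
    abort("`assignments` must carry a `sample` column for averaging")
  }
  per <- rollup(assignments, tree, rank)
  n_samples <- length(unique(assignments$sample))
  per |>
    dplyr::group_by(.data$taxid, .data$name) |>
    dplyr::summarise(mean_n = sum(.data$n) / n_samples, .groups = "drop")
}

#' Remove structural-RNA (rRNA/tRNA) assignments
#'
#' Drops every assignment whose read had a minimal-mismatch hit overlapping
#' an annotated rRNA/tRNA feature. Re-running [rollup()] on the result gives
#' the masked (open-bar) analysis; taxa observed only through their
#' conserved structural-RNA genes disappear.
#'
#' @param assignments Tibble from [assign_taxa()].
#' @return The assignments with `structural_rna == TRUE` rows removed.
#' @export
mask_structural_rna <- function(assignments) {
  assignments <- as_tibble(assignments)
  assignments[!assignments$structural_rna, ]
}
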