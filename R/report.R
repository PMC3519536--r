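#' Strategy-comparison table
#'
#' Cross-tabulates category percentages for the same processed read set
#' classified under mismatch strategies 0, 1 and 2. Categories can be
#' grouped into summary rows (e.g. all host tiers as "Endogenous", the
#' microbiome tier as "Bacteria") via a named mapping; unmapped reads are
#' always reported as their own final row. Cells are percentages of
#' processed reads rounded to 2 decimals; a zero cell is rendered 0, never
#' omitted.
#'
#' @param classifications List of `rna_classification` objects for
#'   strategies 0, 1 and 2 (in any order; the strategy is read from each).
#' @param groups Optional named character vector mapping category labels to
#'   row labels; unmentioned categories keep their own label.
#' @return Wide tibble: `category` plus one `strategy_<s>` column per run.
#' @export
strategy_table <- function(classifications, groups = NULL) {
  stopifnot(length(classifications) >= 1)
  n_reads <- vapply(classifications, `[[`, numeric(1), "n_reads")
  if (length(unique(n_reads)) != 1L) {
    abort("all strategies must be run on the same processed read set")
  }
  strategies <- vapply(classifications, `[[`, integer(1), "strategy")
  if (anyDuplicated(strategies)) {
    abort("duplicate strategy values among classifications")
  }
  relabel <- function(category) {
    if (is.null(groups)) return(category)
    out <- unname(groups[category])
    ifelse(is.na(out), category, out)
  }
  rows <- purrr::map2(classifications, strategies, function(cl, s) {
    fr <- category_fractions(cl)
    fr$row <- relabel(fr$category)
    fr |>
      dplyr::group_by(.data$row) |>
      dplyr::summarise(percent = sum(.data$percent), .groups = "drop") |>
      dplyr::mutate(strategy = s)
  })
  # stable row order: tier order of the first classification, unmapped last
  first <- classifications[[1]]
  order_ref <- unique(c(relabel(first$tiers$category), "unmapped"))
  dplyr::bind_rows(rows) |>
    dplyr::mutate(percent = round(.data$percent, 2)) |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "percent",
                       names_prefix = "strategy_", names_sort = TRUE,
                       values_fill = 0) |>
    dplyr::arrange(match(.data$row, order_ref)) |>
    dplyr::rename(category = "row")
}

#' Fold ratio between the mean read counts of two species
#'
#' The ratio of across-sample arithmetic mean read counts, reported with
#' both means and the per-sample counts. Undefined when the denominator
#' mean is zero (no pseudocount fallback is applied).
#'
#' @param counts_a,counts_b Per-sample read counts (equal length).
#' @param species_a,species_b Labels for the pair.
#' @return One-row tibble: labels, means, `ratio`, `n_samples`, and the
#'   per-sample counts as list columns.
#' @export
fold_ratio <- function(counts_a, counts_b, species_a = "A", species_b = "B") {
  if (length(counts_a) != length(counts_b)) {
    abort("per-sample count vectors must have equal length")
  }
  mean_b <- mean(counts_b)
  if (mean_b <= 0) {
    abort(sprintf("fold ratio %s/%s is undefined: mean count of %s is zero",
                  species_a, species_b, species_b))
  }
  mean_a <- mean(counts_a)
  tibble(species_a = species_a, species_b = species_b,
         mean_a = mean_a, mean_b = mean_b, ratio = mean_a / mean_b,
         n_samples = length(counts_a),
         counts_a = list(counts_a), counts_b = list(counts_b))
}

#' Exogenous miRNA count table
#'
#' Database entries with identical mature sequences are collapsed into one
#' row (their names joined with `"; "`), and each row reports per-sample
#' read counts: a read contributes once to every identity group it hits.
#' Hits must come from the exact-match exogenous miRNA tier.
#'
#' @param hits Hits tibble carrying a `sample` column (bind per-sample
#'   classification hits with e.g. `dplyr::bind_rows(.id = "sample")`).
#' @param db The exogenous miRNA [reference_db()].
#' @param samples Optional sample ordering for the columns.
#' @return Tibble: `mirna_group` plus one count column per sample, sorted by
#'   total count.
#' @export
mirna_count_table <- function(hits, db, samples = NULL) {
  stopifnot(inherits(db, "reference_db"))
  hits <- as_tibble(hits)
  if (!"sample" %in% names(hits)) abort("`hits` must carry a `sample` column")
  groups <- db$sequences |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(
      mirna_group = paste(sort(unique(.data$seq_id)), collapse = "; "),
      .groups = "drop")
  group_of <- db$sequences |>
    dplyr::left_join(groups, by = "seq") |>
    dplyr::select("seq_id", "mirna_group")
  samples <- samples %||% sort(unique(hits$sample))
  counted <- hits |>
    dplyr::inner_join(group_of, by = "seq_id") |>
    dplyr::distinct(.data$sample, .data$read_id, .data$mirna_group) |>
    dplyr::count(.data$mirna_group, .data$sample) |>
    dplyr::mutate(sample = factor(.data$sample, levels = samples)) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L, names_expand = TRUE)
  totals <- rowSums(counted[setdiff(names(counted), "mirna_group")])
  counted[order(-totals), ]
}

#' Plot-ready log10 mean counts
#'
#' Emits `log10(count)` for counts >= 1; zero counts are absent rows, never
#' negative infinities.
#'
#' @param rollup_means Tibble from [rollup_mean()] (or any tibble with
#'   `name` and a count column).
#' @param count_col Name of the count column.
#' @return Tibble `name`, `log10_count`.
#' @export
rollup_plot_data <- function(rollup_means, count_col = "mean_n") {
  x <- as_tibble(rollup_means)
  x <- x[x[[count_col]] >= 1, ]
  tibble(name = x$name, log10_count = log10(x[[count_col]]))
}
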