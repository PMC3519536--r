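#' Per-cycle substitution error profile
#'
#' Describes an Illumina-like sequencer: a fixed read length, a substitution
#' probability per sequencing cycle, and a mean Phred quality per cycle used
#' to synthesize FASTQ quality strings. Substitutions are governed solely by
#' `per_cycle_sub_rate`; qualities are cosmetic. No indel model: the
#' downstream cascade is defined purely by mismatch counts.
#'
#' @param read_length Read length in nt.
#' @param per_cycle_sub_rate Substitution probability per cycle; scalar or one
#'   value per cycle, each in \[0, 1\].
#' @param quality_model Mean Phred score per cycle (scalar or per cycle);
#'   defaults to a mild 38 to 31 ramp.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(read_length, per_cycle_sub_rate,
                          quality_model = NULL) {
  stopifnot(read_length >= 1)
  rate <- rep_len(per_cycle_sub_rate, read_length)
  if (any(rate < 0 | rate > 1)) abort("substitution rates must lie in [0, 1]")
  if (is.null(quality_model)) {
    quality_model <- seq(38, 31, length.out = read_length)
  }
  qual <- rep_len(quality_model, read_length)
  structure(list(read_length = as.integer(read_length),
                 per_cycle_sub_rate = rate,
                 quality_model = qual,
                 qual_string = intToUtf8(round(pmin(pmax(qual, 0), 41)) + 33L)),
            class = "error_profile")
}

#' Default Illumina-like profile: substitution rate rising linearly along the
#' read (error accumulates with cycle number), mean rate about 0.55%.
#' @param read_length Read length in nt.
#' @param rate_start,rate_end Substitution rate at the first and last cycle.
#' @return An `error_profile`.
#' @rdname error_profile
#' @export
illumina_profile <- function(read_length = 23, rate_start = 0.002,
                             rate_end = 0.009) {
  error_profile(read_length,
                seq(rate_start, rate_end, length.out = read_length))
}

#' Species entry for a synthetic community
#'
#' @param name Species name (also its taxonomy leaf label).
#' @param lineage Named character vector of ancestor names, e.g.
#'   `c(genus = "G", phylum = "P", kingdom = "K")`; missing ranks are skipped.
#' @param n_seqs Number of sequences to generate.
#' @param length Sequence length, scalar or range `c(min, max)` sampled
#'   uniformly per sequence.
#' @param gc GC content in (0, 1).
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, lineage = character(), n_seqs, length,
                         gc = 0.5) {
  if (any(length <= 0) || n_seqs < 1) {
    abort("species_spec requires positive sequence counts and lengths")
  }
  if (gc <= 0 || gc >= 1) abort("`gc` must lie strictly between 0 and 1")
  structure(list(name = name, lineage = lineage, n_seqs = as.integer(n_seqs),
                 length = length, gc = gc),
            class = "species_spec")
}

#' One tier of a synthetic community
#' @param id Database id the tier will carry.
#' @param kind Tier kind (see [reference_db()]).
#' @param species List of [species_spec()] entries.
#' @return A `tier_config` list.
#' @export
tier_config <- function(id, kind, species) {
  structure(list(id = id, kind = kind, species = species),
            class = "tier_config")
}

#' Conserved structural-RNA gene shared across taxa
#'
#' Emulates rRNA/tRNA genes: one master sequence is copied into several
#' species with independent per-base divergence, and every copy is annotated
#' as a structural-RNA feature. This reproduces the cross-species
#' read mapping that motivates rRNA/tRNA masking.
#'
#' @param name Gene name.
#' @param kind `"rRNA"` or `"tRNA"`.
#' @param length Gene length in nt.
#' @param divergence Per-base substitution probability applied independently
#'   to each copy.
#' @param placements Tibble with columns `tier` and `species` naming where
#'   copies go.
#' @return A `conserved_gene` list.
#' @export
conserved_gene <- function(name, kind = c("rRNA", "tRNA"), length, divergence,
                           placements) {
  kind <- match.arg(kind)
  if (length < 1) abort("conserved gene length must be positive")
  if (divergence < 0 || divergence > 1) abort("divergence must lie in [0, 1]")
  structure(list(name = name, kind = kind, length = as.integer(length),
                 divergence = divergence, placements = as_tibble(placements)),
            class = "conserved_gene")
}

#' Synthetic community configuration
#' @param tiers List of [tier_config()] entries.
#' @param conserved Optional list of [conserved_gene()] entries.
#' @return A `community_config` list.
#' @export
community_config <- function(tiers, conserved = list()) {
  ids <- vapply(tiers, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("tier ids must be unique")
  structure(list(tiers = tiers, conserved = conserved),
            class = "community_config")
}

new_taxonomy_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$taxid <- c(1L)
  env$parent <- c(1L)
  env$rank <- c("root")
  env$name <- c("root")
  env$next_id <- 2L
  env
}

tb_add <- function(env, parent_id, rank, name) {
  hit <- which(env$parent == parent_id & env$rank == rank & env$name == name)
  if (length(hit)) return(env$taxid[hit[1]])
  id <- env$next_id
  env$next_id <- id + 1L
  env$taxid <- c(env$taxid, id)
  env$parent <- c(env$parent, parent_id)
  env$rank <- c(env$rank, rank)
  env$name <- c(env$name, name)
  id
}

#' Generate tiered reference databases and a taxonomy
#'
#' Builds, deterministically for a fixed seed, one [reference_db()] per tier
#' of a [community_config()], together with a taxonomy table
#' (taxid, parent, rank, name) in which every sequence's taxon label
#' resolves. Conserved genes are embedded into a sequence of each placed
#' species (or emitted as a standalone record when no sequence is long
#' enough) and annotated as rRNA/tRNA feature intervals.
#'
#' @param config A [community_config()].
#' @param seed Integer seed.
#' @return List of class `reference_set` with elements `dbs` (named list of
#'   `reference_db`) and `taxonomy` (tibble).
#' @export
generate_reference_set <- function(config, seed) {
  stopifnot(inherits(config, "community_config"))
  set.seed(as.integer(seed))
  tb <- new_taxonomy_builder()
  rank_order <- c("kingdom", "phylum", "genus")

  tier_seqs <- list()
  tier_feats <- list()
  species_taxid <- list()  # per tier: name -> taxid

  for (tier in config$tiers) {
    rows <- list()
    sp_tax <- integer()
    for (sp in tier$species) {
      parent <- 1L
      for (rk in rank_order) {
        if (rk %in% names(sp$lineage)) {
          parent <- tb_add(tb, parent, rk, sp$lineage[[rk]])
        }
      }
      taxid <- tb_add(tb, parent, "species", sp$name)
      sp_tax[[sp$name]] <- taxid
      lens <- if (length(sp$length) == 2L) {
        sample(sp$length[1]:sp$length[2], sp$n_seqs, replace = TRUE)
      } else {
        rep_len(sp$length, sp$n_seqs)
      }
      seqs <- random_dna(sp$n_seqs, lens, sp$gc)
      rows[[sp$name]] <- tibble(
        seq_id = sprintf("%s.%s.%d", tier$id, gsub("\\W+", "_", sp$name),
                         seq_len(sp$n_seqs)),
        seq = seqs, taxid = taxid)
    }
    tier_seqs[[tier$id]] <- dplyr::bind_rows(rows)
    tier_feats[[tier$id]] <- tibble(seq_id = character(), start = integer(),
                                    end = integer(), kind = character())
    species_taxid[[tier$id]] <- sp_tax
  }

  for (gene in config$conserved) {
    master <- random_dna(1, gene$length, 0.5)
    for (i in seq_len(nrow(gene$placements))) {
      tier_id <- gene$placements$tier[i]
      sp_name <- gene$placements$species[i]
      if (is.null(tier_seqs[[tier_id]])) {
        abort(sprintf("conserved gene '%s' placed in unknown tier '%s'",
                      gene$name, tier_id))
      }
      taxid <- species_taxid[[tier_id]][[sp_name]]
      copy <- mutate_bases(master, gene$divergence)$seq
      seqs <- tier_seqs[[tier_id]]
      cand <- which(seqs$taxid == taxid & nchar(seqs$seq) >= gene$length)
      if (length(cand)) {
        j <- cand[1]
        room <- nchar(seqs$seq[j]) - gene$length
        at <- if (room > 0) sample.int(room + 1L, 1L) - 1L else 0L
        substr(seqs$seq[j], at + 1L, at + gene$length) <- copy
        tier_seqs[[tier_id]] <- seqs
        feat <- tibble(seq_id = seqs$seq_id[j], start = at,
                       end = at + gene$length, kind = gene$kind)
      } else {
        sid <- sprintf("%s.%s.%s", tier_id, gsub("\\W+", "_", sp_name),
                       gene$name)
        tier_seqs[[tier_id]] <- dplyr::bind_rows(
          tier_seqs[[tier_id]],
          tibble(seq_id = sid, seq = copy, taxid = taxid))
        feat <- tibble(seq_id = sid, start = 0L, end = gene$length,
                       kind = gene$kind)
      }
      tier_feats[[tier_id]] <- dplyr::bind_rows(tier_feats[[tier_id]], feat)
    }
  }

  dbs <- lapply(config$tiers, function(tier) {
    reference_db(tier$id, tier$kind, tier_seqs[[tier$id]],
                 tier_feats[[tier$id]])
  })
  names(dbs) <- vapply(config$tiers, `[[`, character(1), "id")

  taxonomy <- tibble(taxid = tb$taxid, parent_taxid = tb$parent,
                     rank = tb$rank, name = tb$name)
  structure(list(dbs = dbs, taxonomy = taxonomy), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d databases, %d taxonomy nodes\n",
              length(x$dbs), nrow(x$taxonomy)))
  for (db in x$dbs) print(db)
  invisible(x)
}

#' Mixture specification for read simulation
#'
#' @param components Tibble with columns `db` (database id), `weight`
#'   (non-negative, normalized internally) and optionally `taxid` to restrict
#'   a component to one taxon (`NA` = whole database).
#' @param n_reads Total number of reads to draw (multinomial over weights).
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(components, n_reads) {
  components <- as_tibble(components)
  stopifnot(all(c("db", "weight") %in% names(components)))
  if (!"taxid" %in% names(components)) components$taxid <- NA_integer_
  if (any(components$weight < 0) || sum(components$weight) <= 0) {
    abort("mixture weights must be non-negative and sum to a positive value")
  }
  if (n_reads < 1) abort("n_reads must be positive")
  structure(list(components = components, n_reads = as.integer(n_reads)),
            class = "mixture_spec")
}

#' Simulate error-bearing short reads from a synthetic community
#'
#' Draws reads from the databases of a [generate_reference_set()] result
#' according to a [mixture_spec()]: component read counts are multinomial
#' over normalized weights; within a component, source sequences are chosen
#' proportionally to their number of eligible start positions and starts are
#' uniform. Reads from transcript-kind databases come from the sense strand;
#' genomic kinds (`genome`, `microbiome`, `nt`) from either strand with
#' probability 1/2. Each cycle is then substituted independently at the
#' profile's per-cycle rate (replacement uniform over the 3 alternatives).
#'
#' @param refs A `reference_set` or named list of [reference_db()] objects.
#' @param mixture A [mixture_spec()].
#' @param profile An [error_profile()].
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return List with `reads` (tibble: `read_id`, `seq`, `qual`) and `truth`
#'   (tibble: `read_id`, `db`, `seq_id`, `taxid`, `start`, `end`, `strand`,
#'   `error_pos` list-column of 0-based cycle indices, `n_errors`).
#' @export
simulate_reads <- function(refs, mixture, profile, seed) {
  stopifnot(inherits(mixture, "mixture_spec"),
            inherits(profile, "error_profile"))
  dbs <- if (inherits(refs, "reference_set")) refs$dbs else refs
  set.seed(as.integer(seed))
  L <- profile$read_length
  comp <- mixture$components
  counts <- drop(rmultinom(1, mixture$n_reads,
                           comp$weight / sum(comp$weight)))

  pieces <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    if (counts[i] == 0L) next
    db <- dbs[[comp$db[i]]]
    if (is.null(db)) abort(sprintf("mixture component references unknown database '%s'", comp$db[i]))
    pool <- db$sequences
    if (!is.na(comp$taxid[i])) pool <- pool[pool$taxid == comp$taxid[i], ]
    pool <- pool[nchar(pool$seq) >= L, ]
    if (nrow(pool) == 0L) {
      abort(sprintf("empty source pool for mixture component %d ('%s')",
                    i, comp$db[i]))
    }
    n_pos <- nchar(pool$seq) - L + 1L
    idx <- sample.int(nrow(pool), counts[i], replace = TRUE, prob = n_pos)
    start <- floor(runif(counts[i]) * n_pos[idx])
    strand <- if (is_genome_kind(db)) {
      sample(c("+", "-"), counts[i], replace = TRUE)
    } else {
      rep("+", counts[i])
    }
    window <- substring(pool$seq[idx], start + 1L, start + L)
    window[strand == "-"] <- revcomp(window[strand == "-"])
    pieces[[i]] <- tibble(db = comp$db[i], seq_id = pool$seq_id[idx],
                          taxid = pool$taxid[idx], start = as.integer(start),
                          end = as.integer(start + L), strand = strand,
                          seq0 = window)
  }
  truth <- dplyr::bind_rows(pieces)
  mut <- mutate_bases(truth$seq0, profile$per_cycle_sub_rate)
  read_id <- sprintf("r%07d", seq_len(nrow(truth)))
  reads <- tibble(read_id = read_id, seq = mut$seq,
                  qual = rep(profile$qual_string, nrow(truth)))
  truth <- tibble(read_id = read_id,
                  truth[c("db", "seq_id", "taxid", "start", "end", "strand")],
                  error_pos = mut$positions,
                  n_errors = lengths(mut$positions))
  list(reads = reads, truth = truth)
}
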