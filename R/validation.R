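#' Mapping-completeness check on a simulated transcriptome
#'
#' Generates a random transcriptome, simulates error-bearing reads from it
#' with an Illumina-like per-cycle substitution profile, classifies them
#' against the source transcriptome alone under the 2-mismatch strategy,
#' and reports the mapped percentage. Because the pigeonhole matcher is
#' exhaustive, every read carrying at most `strategy` substitutions is
#' guaranteed to map back; the shortfall from 100% is essentially the
#' binomial tail of reads with more errors than the allowance.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_transcripts Number of transcripts to generate.
#' @param transcript_length Length range `c(min, max)` in nt.
#' @param n_reads Number of simulated reads.
#' @param read_length Read length in nt.
#' @param profile An [error_profile()]; defaults to [illumina_profile()].
#' @param strategy Mismatch allowance for the mapping (default 2).
#' @return One-row tibble: `mapped_percent`, `n_reads`, `n_transcripts`,
#'   `mean_sub_rate`.
#' @export
simulated_mapping_rate <- function(seed, n_transcripts = 2000,
                                   transcript_length = c(500, 2000),
                                   n_reads = 1e5, read_length = 23,
                                   profile = illumina_profile(read_length),
                                   strategy = 2) {
  config <- community_config(list(
    tier_config("host_tx", "transcripts", list(
      species_spec("Homo sapiens synthetic",
                   c(genus = "Homo", phylum = "Chordata",
                     kingdom = "Metazoa"),
                   n_seqs = n_transcripts, length = transcript_length)))))
  refs <- generate_reference_set(config, seed)
  sim <- simulate_reads(refs,
                        mixture_spec(tibble(db = "host_tx", weight = 1),
                                     n_reads),
                        profile, seed + 1)
  cl <- run_map_and_remove(
    sim$reads, refs$dbs,
    tier_spec("host_tx", "endogenous_transcripts", "strategy"),
    strategy = strategy)
  fr <- category_fractions(cl)
  tibble(mapped_percent =
           100 - fr$percent[fr$category == "unmapped"],
         n_reads = n_reads, n_transcripts = n_transcripts,
         mean_sub_rate = mean(profile$per_cycle_sub_rate))
}

#' Negative-control check: false exogenous assignment rate
#'
#' Simulates reads from a single synthetic host genome, then runs the full
#' map-and-remove cascade in which the exogenous tiers are independently
#' generated random genomes sharing no sequence with the host (host tiers
#' first under the given strategy, exogenous tiers exact-match). The
#' percentage of reads ending in any exogenous category measures how often
#' sequencing errors plus chance produce a false foreign assignment — the
#' in-silico analogue of sequencing a sterile single-organism culture.
#'
#' @param seed Integer seed.
#' @param host_mb Host genome size in Mb.
#' @param exogenous_mb Total size of the unrelated exogenous genomes in Mb
#'   (split between a microbiome tier and an nt-collection tier).
#' @param n_reads Number of simulated host reads.
#' @param read_length Read length in nt.
#' @param sub_rate Flat per-cycle substitution rate.
#' @param strategy Mismatch allowance for the host tiers (default 2).
#' @return One-row tibble: `exogenous_percent`, `unmapped_percent`,
#'   `endogenous_percent`, `n_reads`.
#' @export
simulated_false_exogenous_rate <- function(seed, host_mb = 12,
                                           exogenous_mb = 50,
                                           n_reads = 2e5, read_length = 23,
                                           sub_rate = 0.005, strategy = 2) {
  host_len <- round(host_mb * 1e6)
  micro_total <- round(exogenous_mb * 1e6 / 2)
  micro_species <- 4L
  nt_species <- 2L
  config <- community_config(list(
    tier_config("host_genome", "genome", list(
      species_spec("Host synthetic",
                   c(genus = "Homo", phylum = "Chordata",
                     kingdom = "Metazoa"),
                   n_seqs = 1, length = host_len))),
    tier_config("microbiome", "microbiome", lapply(
      seq_len(micro_species), function(i) {
        species_spec(sprintf("Bacterium synthetic %d", i),
                     c(genus = sprintf("Bactogenus%d", i),
                       phylum = sprintf("Bactophylum%d", (i + 1) %/% 2),
                       kingdom = "Bacteria"),
                     n_seqs = 1, length = round(micro_total / micro_species))
      })),
    tier_config("nt", "nt", lapply(seq_len(nt_species), function(i) {
      species_spec(sprintf("Other synthetic %d", i),
                   c(genus = sprintf("Altogenus%d", i),
                     phylum = "Altophylum", kingdom = "Fungi"),
                   n_seqs = 1,
                   length = round((exogenous_mb * 1e6 - micro_total) /
                                    nt_species))
    }))))
  refs <- generate_reference_set(config, seed)
  profile <- error_profile(read_length, sub_rate)
  sim <- simulate_reads(refs,
                        mixture_spec(tibble(db = "host_genome", weight = 1),
                                     n_reads),
                        profile, seed + 1)
  tiers <- tier_spec(db = c("host_genome", "microbiome", "nt"),
                     category = c("human_genome", "microbiome", "other"),
                     policy = c("strategy", "fixed0", "fixed0"))
  cl <- run_map_and_remove(sim$reads, refs$dbs, tiers, strategy = strategy)
  fr <- category_fractions(cl)
  pct <- setNames(fr$percent, fr$category)
  tibble(exogenous_percent = pct[["microbiome"]] + pct[["other"]],
         unmapped_percent = pct[["unmapped"]],
         endogenous_percent = pct[["human_genome"]],
         n_reads = n_reads)
}
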