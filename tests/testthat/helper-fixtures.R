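# Small synthetic communities shared across tests. Everything is generated
# in code under fixed seeds; no fixture files.

library(tibble)

# A miniature plasma-like community: host transcripts + host genome,
# a two-phylum microbiome sharing a conserved rRNA gene, and a small
# "nt" catch-all tier with a fungus and a plant.
tiny_community <- function(seed = 101) {
  config <- community_config(
    tiers = list(
      tier_config("host_tx", "transcripts", list(
        species_spec("Homo synthetic",
                     c(genus = "Homo", phylum = "Chordata",
                       kingdom = "Metazoa"),
                     n_seqs = 30, length = c(300, 800)))),
      tier_config("host_genome", "genome", list(
        species_spec("Homo synthetic",
                     c(genus = "Homo", phylum = "Chordata",
                       kingdom = "Metazoa"),
                     n_seqs = 2, length = 20000))),
      tier_config("microbiome", "microbiome", list(
        species_spec("Bacterium one",
                     c(genus = "Bactus", phylum = "PhylumA",
                       kingdom = "Bacteria"),
                     n_seqs = 3, length = 5000),
        species_spec("Bacterium two",
                     c(genus = "Bactus", phylum = "PhylumA",
                       kingdom = "Bacteria"),
                     n_seqs = 3, length = 5000),
        species_spec("Bacterium three",
                     c(genus = "Coccus", phylum = "PhylumB",
                       kingdom = "Bacteria"),
                     n_seqs = 3, length = 5000))),
      tier_config("nt", "nt", list(
        species_spec("Fungus one",
                     c(genus = "Fungillus", phylum = "Ascomycota",
                       kingdom = "Fungi"),
                     n_seqs = 3, length = 5000),
        species_spec("Plant one",
                     c(genus = "Planta", phylum = "Streptophyta",
                       kingdom = "Viridiplantae"),
                     n_seqs = 3, length = 5000)))),
    conserved = list(
      conserved_gene("ssu_rrna", "rRNA", length = 600, divergence = 0.02,
                     placements = tibble(
                       tier = c("microbiome", "microbiome", "microbiome"),
                       species = c("Bacterium one", "Bacterium two",
                                   "Bacterium three")))))
  generate_reference_set(config, seed)
}

tiny_tiers <- function() {
  tier_spec(db = c("host_tx", "host_genome", "microbiome", "nt"),
            category = c("human_transcripts", "human_genome", "microbiome",
                         "other"),
            policy = c("strategy", "strategy", "fixed0", "fixed0"))
}

# Reads at a fixed length drawn from given databases with zero error.
clean_reads <- function(refs, weights, n, L = 23, seed = 7) {
  simulate_reads(refs,
                 mixture_spec(tibble(db = names(weights),
                                     weight = unname(weights)), n),
                 error_profile(L, 0), seed)
}

random_reads_tbl <- function(n, L, seed = NULL, prefix = "rr") {
  if (!is.null(seed)) set.seed(seed)
  tibble(read_id = sprintf("%s%04d", prefix, seq_len(n)),
         seq = random_dna(n, L))
}
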