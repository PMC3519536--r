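# Reference-set generation and Illumina-like read simulation.

test_that("generation is deterministic and validates its configuration", {
  cfg <- community_config(list(
    tier_config("t", "transcripts", list(
      species_spec("sp", c(kingdom = "K"), 1, 1000, gc = 0.5)))))
  a <- generate_reference_set(cfg, 3)
  b <- generate_reference_set(cfg, 3)
  expect_identical(a$dbs$t$sequences, b$dbs$t$sequences)
  expect_identical(a$taxonomy, b$taxonomy)

  expect_error(species_spec("x", c(), 1, 100, gc = 1.2), "gc")
  expect_error(species_spec("x", c(), 1, 0), "positive")
})

test_that("conserved genes are annotated and near-identical across taxa", {
  cfg <- community_config(
    tiers = list(tier_config("m", "microbiome", list(
      species_spec("A", c(genus = "G1", phylum = "P", kingdom = "B"), 1, 2000),
      species_spec("B", c(genus = "G2", phylum = "P", kingdom = "B"), 1, 2000)))),
    conserved = list(conserved_gene(
      "rrn", "rRNA", length = 600, divergence = 0.02,
      placements = tibble(tier = c("m", "m"), species = c("A", "B")))))
  refs <- generate_reference_set(cfg, 21)
  feats <- refs$dbs$m$features
  expect_equal(nrow(feats), 2L)
  expect_true(all(feats$kind == "rRNA"))

  # recover the two copies and compare base by base
  seqs <- refs$dbs$m$sequences
  copies <- vapply(seq_len(2), function(i) {
    s <- seqs$seq[seqs$seq_id == feats$seq_id[i]]
    substr(s, feats$start[i] + 1L, feats$end[i])
  }, character(1))
  identity <- mean(strsplit(copies[1], "")[[1]] == strsplit(copies[2], "")[[1]])
  expect_gte(identity, 0.95)
})

test_that("taxonomy rolls two species under one shared phylum node", {
  cfg <- community_config(list(tier_config("m", "microbiome", list(
    species_spec("A", c(genus = "G1", phylum = "P", kingdom = "B"), 1, 500),
    species_spec("B", c(genus = "G2", phylum = "P", kingdom = "B"), 1, 500)))))
  refs <- generate_reference_set(cfg, 4)
  tax <- refs$taxonomy
  expect_equal(sum(tax$rank == "phylum"), 1L)
  tree <- taxonomy_tree(tax)
  sp <- tax$taxid[tax$rank == "species"]
  phyla <- vapply(sp, function(t) ancestor_at_rank(tree, t, "phylum"),
                  integer(1))
  expect_equal(length(unique(phyla)), 1L)
})

test_that("zero-error reads are exact source substrings and truth is faithful", {
  refs <- tiny_community()
  sim <- clean_reads(refs, c(host_tx = 0.6, microbiome = 0.4), 300)
  expect_equal(nrow(sim$reads), 300L)
  expect_true(all(sim$truth$n_errors == 0L))
  expect_true(all(lengths(sim$truth$error_pos) == 0L))

  seqs <- dplyr::bind_rows(lapply(refs$dbs, function(d) d$sequences))
  src <- setNames(seqs$seq, seqs$seq_id)
  windows <- substring(src[sim$truth$seq_id], sim$truth$start + 1L,
                       sim$truth$end)
  windows[sim$truth$strand == "-"] <-
    revcomp(windows[sim$truth$strand == "-"])
  expect_identical(unname(windows), sim$reads$seq)
})

test_that("transcript reads are sense-strand; genome reads use both strands", {
  refs <- tiny_community()
  sim <- clean_reads(refs, c(host_tx = 0.5, host_genome = 0.5), 2000,
                     seed = 8)
  tx <- sim$truth[sim$truth$db == "host_tx", ]
  ge <- sim$truth[sim$truth$db == "host_genome", ]
  expect_true(all(tx$strand == "+"))
  # both strands present, roughly balanced (binomial 5-sigma bound)
  n_minus <- sum(ge$strand == "-")
  expect_gt(n_minus, nrow(ge) / 2 - 5 * sqrt(nrow(ge) / 4))
  expect_lt(n_minus, nrow(ge) / 2 + 5 * sqrt(nrow(ge) / 4))
})

test_that("error statistics follow the binomial per-cycle model", {
  refs <- tiny_community()
  n <- 20000
  sim <- simulate_reads(refs,
                        mixture_spec(tibble(db = "host_tx", weight = 1), n),
                        error_profile(23, 0.01), 31)
  # mean errors per read ~ Binomial(23, 0.01): 3-sigma band around 0.23
  mean_err <- mean(sim$truth$n_errors)
  se <- sqrt(23 * 0.01 * 0.99 / n)
  expect_lt(abs(mean_err - 0.23), 3 * se)
  # distribution of per-read error counts vs the binomial law
  obs <- c(sum(sim$truth$n_errors == 0), sum(sim$truth$n_errors == 1),
           sum(sim$truth$n_errors >= 2))
  p <- c(dbinom(0, 23, 0.01), dbinom(1, 23, 0.01),
         1 - pbinom(1, 23, 0.01))
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
  # substituted positions are distinct, in range, and truly substituted
  expect_true(all(vapply(sim$truth$error_pos,
                         function(p) !anyDuplicated(p) && all(p < 23),
                         logical(1))))
})

test_that("per-cycle mismatch rates match the profile (chi-square, n = 1e5)", {
  refs <- tiny_community()
  n <- 1e5
  rates <- seq(0.002, 0.012, length.out = 23)
  sim <- simulate_reads(refs,
                        mixture_spec(tibble(db = "host_tx", weight = 1), n),
                        error_profile(23, rates), 33)
  per_cycle <- tabulate(unlist(sim$truth$error_pos) + 1L, nbins = 23)
  x2 <- sum((per_cycle - n * rates)^2 / (n * rates * (1 - rates)))
  expect_gt(pchisq(x2, df = 23, lower.tail = FALSE), 0.01)
})

test_that("mixture draws are multinomial and conserve read counts", {
  refs <- tiny_community()
  n <- 10000
  sim <- clean_reads(refs, c(host_tx = 0.9, microbiome = 0.1), n, seed = 12)
  counts <- table(sim$truth$db)
  expect_equal(sum(counts), n)
  sd_host <- sqrt(n * 0.9 * 0.1)
  expect_lt(abs(counts[["host_tx"]] - 9000), 3 * sd_host)
  expect_error(
    simulate_reads(refs,
                   mixture_spec(tibble(db = "none", weight = 1), 10),
                   error_profile(23, 0), 1),
    "unknown database")
})

test_that("identical seed and config give byte-identical FASTQ output", {
  refs <- tiny_community()
  mix <- mixture_spec(tibble(db = "host_tx", weight = 1), 200)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(simulate_reads(refs, mix, illumina_profile(23), 5)$reads, f1)
  write_reads_fastq(simulate_reads(refs, mix, illumina_profile(23), 5)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("error profiles validate their invariants", {
  expect_error(error_profile(23, 1.5), "\\[0, 1\\]")
  p <- error_profile(23, 0.01)
  expect_length(p$per_cycle_sub_rate, 23)
  expect_equal(nchar(p$qual_string), 23)
  expect_error(mixture_spec(tibble(db = "a", weight = -1), 10), "non-negative")
  expect_error(mixture_spec(tibble(db = "a", weight = 0), 10), "positive")
})
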