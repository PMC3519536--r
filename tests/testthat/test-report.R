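# Summary artifacts: strategy tables, fold ratios, miRNA count tables.

test_that("an all-endogenous sample reports 100% in every strategy column", {
  refs <- tiny_community()
  sim <- clean_reads(refs, c(host_tx = 1), 300, seed = 51)
  cls <- lapply(0:2, function(s) {
    run_map_and_remove(sim$reads, refs$dbs, tiny_tiers(), s)
  })
  tbl <- strategy_table(cls, groups = c(human_transcripts = "Endogenous",
                                        human_genome = "Endogenous",
                                        microbiome = "Bacteria",
                                        other = "Other"))
  endo <- tbl[tbl$category == "Endogenous", ]
  expect_equal(unlist(endo[, c("strategy_0", "strategy_1", "strategy_2")],
                      use.names = FALSE),
               c(100, 100, 100))
  # empty categories render as 0, never dropped
  expect_true(all(c("Bacteria", "Other", "unmapped") %in% tbl$category))
  expect_equal(tbl$strategy_0[tbl$category == "Bacteria"], 0)
  # columns sum to 100 within rounding
  for (cc in c("strategy_0", "strategy_1", "strategy_2")) {
    expect_equal(sum(tbl[[cc]]), 100, tolerance = 0.02)
  }
})

test_that("exogenous cells are non-increasing across strategies", {
  refs <- tiny_community()
  sim <- simulate_reads(refs,
                        mixture_spec(tibble(db = c("host_tx", "microbiome",
                                                   "nt"),
                                            weight = c(0.6, 0.25, 0.15)),
                                     1500),
                        error_profile(23, 0.02), 53)
  cls <- lapply(0:2, function(s) {
    run_map_and_remove(sim$reads, refs$dbs, tiny_tiers(), s)
  })
  tbl <- strategy_table(cls)
  for (cat in c("microbiome", "other")) {
    v <- unlist(tbl[tbl$category == cat,
                    c("strategy_0", "strategy_1", "strategy_2")])
    expect_true(all(diff(v) <= 0))
  }
})

test_that("strategy tables reject inconsistent read sets", {
  refs <- tiny_community()
  s1 <- clean_reads(refs, c(host_tx = 1), 100, seed = 55)
  s2 <- clean_reads(refs, c(host_tx = 1), 120, seed = 56)
  a <- run_map_and_remove(s1$reads, refs$dbs, tiny_tiers(), 0)
  b <- run_map_and_remove(s2$reads, refs$dbs, tiny_tiers(), 1)
  expect_error(strategy_table(list(a, b)), "same processed read set")
})

test_that("fold ratios are arithmetic on across-sample means", {
  fr <- fold_ratio(c(600, 700, 680), c(12, 9, 9), "corn", "rice")
  expect_equal(fr$ratio, 660 / 10)
  expect_equal(fold_ratio(c(5, 5), c(5, 5))$ratio, 1)
  expect_error(fold_ratio(c(1, 2), c(0, 0), "a", "b"), "undefined")
  expect_error(fold_ratio(1:3, 1:2), "equal length")
})

test_that("a 66:1 two-species design is recovered within sampling error", {
  # corn and rice transcript pools, disjoint random sequences, no errors
  cfg <- community_config(list(
    tier_config("plants", "transcripts", list(
      species_spec("Zea synthetic", c(genus = "Zea", phylum = "Streptophyta",
                                      kingdom = "Viridiplantae"), 20,
                   c(500, 900)),
      species_spec("Oryza synthetic", c(genus = "Oryza",
                                        phylum = "Streptophyta",
                                        kingdom = "Viridiplantae"), 20,
                   c(500, 900))))))
  refs <- generate_reference_set(cfg, 61)
  tree <- taxonomy_tree(refs$taxonomy)
  corn_tax <- refs$taxonomy$taxid[refs$taxonomy$name == "Zea synthetic"]
  rice_tax <- refs$taxonomy$taxid[refs$taxonomy$name == "Oryza synthetic"]
  n_per_sample <- 20000
  samples <- lapply(1:3, function(s) {
    sim <- simulate_reads(refs, mixture_spec(
      tibble(db = "plants", taxid = c(corn_tax, rice_tax),
             weight = c(66, 1)), n_per_sample),
      error_profile(23, 0), 70 + s)
    cl <- run_map_and_remove(sim$reads, refs$dbs,
                             tier_spec("plants", "plants", "fixed0"), 0)
    a <- assign_taxa(cl$hits, refs$dbs$plants, tree)
    a$sample <- sprintf("S%d", s)
    a
  })
  counts <- rollup(dplyr::bind_rows(samples), tree, "genus")
  corn <- counts$n[counts$name == "Zea"]
  rice <- counts$n[counts$name == "Oryza"]
  fr <- fold_ratio(corn, rice, "corn", "rice")
  # 3-SE band from multinomial sampling variance (delta method)
  p_rice <- 1 / 67
  mean_rice <- n_per_sample * p_rice
  mean_corn <- n_per_sample * (1 - p_rice)
  var_rice <- n_per_sample * p_rice * (1 - p_rice)
  var_corn <- var_rice
  se_ratio <- 66 * sqrt(var_corn / (3 * mean_corn^2) +
                          var_rice / (3 * mean_rice^2))
  expect_lt(abs(fr$ratio - 66), 3 * se_ratio)
})

test_that("identical mature sequences collapse into one miRNA row", {
  mir <- random_dna(2, 22)
  db <- reference_db("exo_mirna", "exo_miRNA", tibble(
    seq_id = c("tca-miR-263a", "dpu-miR-263a", "bma-miR-228"),
    seq = c(mir[1], mir[1], mir[2]),
    taxid = c(4L, 5L, 6L)))
  hits <- tibble(
    sample = c("A", "A", "A", "B", "B"),
    read_id = c("r1", "r1", "r2", "r3", "r4"),
    db = "exo_mirna",
    seq_id = c("tca-miR-263a", "dpu-miR-263a", "bma-miR-228",
               "tca-miR-263a", "bma-miR-228"),
    start = 0L, end = 22L, strand = "+", mismatches = 0L)
  tbl <- mirna_count_table(hits, db, samples = c("A", "B"))
  expect_equal(nrow(tbl), 2L)
  grp <- tbl[tbl$mirna_group == "dpu-miR-263a; tca-miR-263a", ]
  expect_equal(grp$A, 1L)  # r1 counts once despite hitting both names
  expect_equal(grp$B, 1L)
  expect_equal(tbl$A[tbl$mirna_group == "bma-miR-228"], 1L)
})

test_that("plot data emits log10 counts and drops zeros", {
  x <- tibble(taxid = 1:3, name = c("a", "b", "c"), mean_n = c(100, 1, 0))
  pd <- rollup_plot_data(x)
  expect_equal(pd$log10_count, c(2, 0))
  expect_false("c" %in% pd$name)
})

test_that("plot functions return ggplot objects", {
  refs <- tiny_community()
  sim <- clean_reads(refs, c(host_tx = 0.7, microbiome = 0.3), 200, seed = 57)
  cl <- run_map_and_remove(sim$reads, refs$dbs, tiny_tiers(), 0)
  expect_s3_class(plot_category_fractions(cl), "ggplot")
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
  tree <- taxonomy_tree(refs$taxonomy)
  a <- assign_taxa(cl$hits[cl$hits$category == "microbiome", ],
                   refs$dbs$microbiome, tree)
  a$sample <- "S1"
  m <- rollup_mean(a, tree, "phylum")
  expect_s3_class(plot_rollup(m, m), "ggplot")
  cls <- lapply(0:1, function(s) run_map_and_remove(sim$reads, refs$dbs,
                                                    tiny_tiers(), s))
  expect_s3_class(plot_strategy_table(strategy_table(cls)), "ggplot")
})
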