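# Taxon assignment (best-hit LCA), rank rollups, structural-RNA masking.

toy_tree <- function() {
  taxonomy_tree(tibble(
    taxid = 1:8,
    parent_taxid = c(1L, 1L, 2L, 3L, 3L, 2L, 6L, 1L),
    rank = c("root", "kingdom", "genus", "species", "species", "genus",
             "species", "kingdom"),
    name = c("root", "Bacteria", "Bactus", "B. one", "B. two", "Coccus",
             "C. three", "Fungi")))
}

test_that("tree construction validates parent chains and the root", {
  expect_error(taxonomy_tree(tibble(taxid = c(1L, 2L),
                                    parent_taxid = c(1L, 3L),
                                    rank = c("root", "species"),
                                    name = c("r", "s"))),
               "unknown taxid")
  expect_error(taxonomy_tree(tibble(taxid = c(1L, 2L),
                                    parent_taxid = c(1L, 2L),
                                    rank = c("root", "root"),
                                    name = c("r", "r2"))),
               "exactly one root")
  expect_error(taxonomy_tree(tibble(taxid = c(1L, 2L, 3L),
                                    parent_taxid = c(1L, 3L, 2L),
                                    rank = c("root", "g", "g"),
                                    name = c("r", "a", "b"))),
               "cycle")
})

test_that("single-species hit sets resolve to the species at species level", {
  tree <- toy_tree()
  db <- reference_db("m", "microbiome", tibble(
    seq_id = c("s1", "s2"), seq = c(strrep("ACGT", 20), strrep("GGCA", 20)),
    taxid = c(4L, 4L)))
  hits <- tibble(read_id = c("r1", "r1"), db = "m",
                 seq_id = c("s1", "s2"), start = 0L, end = 23L,
                 strand = "+", mismatches = c(0L, 0L))
  a <- assign_taxa(hits, db, tree)
  expect_equal(a$taxid, 4L)
  expect_equal(a$level, "species")
})

test_that("two species in one genus resolve to the genus LCA", {
  tree <- toy_tree()
  db <- reference_db("m", "microbiome", tibble(
    seq_id = c("s1", "s2"), seq = c(strrep("ACGT", 20), strrep("GGCA", 20)),
    taxid = c(4L, 5L)))
  hits <- tibble(read_id = "r1", db = "m", seq_id = c("s1", "s2"),
                 start = 0L, end = 23L, strand = "+", mismatches = 0L)
  a <- assign_taxa(hits, db, tree)
  expect_equal(a$taxid, 3L)
  expect_equal(a$level, "genus")
})

test_that("minimal-mismatch hits win before the LCA is taken", {
  tree <- toy_tree()
  db <- reference_db("m", "microbiome", tibble(
    seq_id = c("s1", "s2"), seq = c(strrep("ACGT", 20), strrep("GGCA", 20)),
    taxid = c(4L, 7L)))
  hits <- tibble(read_id = "r1", db = "m", seq_id = c("s1", "s2"),
                 start = 0L, end = 23L, strand = "+",
                 mismatches = c(0L, 1L))
  a <- assign_taxa(hits, db, tree)
  expect_equal(a$taxid, 4L)  # the 1-mismatch hit is discarded
})

test_that("conserved-gene reads match a brute-force LCA oracle", {
  refs <- tiny_community()
  tree <- taxonomy_tree(refs$taxonomy)
  sim <- clean_reads(refs, c(microbiome = 1), 500, seed = 41)
  cl <- run_map_and_remove(sim$reads, refs$dbs["microbiome"],
                           tier_spec("microbiome", "microbiome", "fixed0"), 0)
  a <- assign_taxa(cl$hits, refs$dbs$microbiome, tree)
  taxid_of <- setNames(refs$dbs$microbiome$sequences$taxid,
                       refs$dbs$microbiome$sequences$seq_id)
  for (i in seq_len(nrow(a))) {
    h <- cl$hits[cl$hits$read_id == a$read_id[i], ]
    h <- h[h$mismatches == min(h$mismatches), ]
    expect_equal(a$taxid[i],
                 oracle_lca(refs$taxonomy, unname(taxid_of[h$seq_id])))
  }
  # reads from the shared rRNA gene do land above species level
  expect_true(any(a$level != "species"))
  expect_true(any(a$structural_rna))
})

test_that("rollups are additive, rank-aware and conserve totals", {
  tree <- toy_tree()
  tree2 <- taxonomy_tree(tibble(
    taxid = 1:5, parent_taxid = c(1L, 1L, 2L, 3L, 3L),
    rank = c("root", "phylum", "genus", "species", "species"),
    name = c("root", "P", "G", "s1", "s2")))
  a <- tibble(read_id = sprintf("r%d", 1:10),
              taxid = c(rep(4L, 2), rep(5L, 3), rep(3L, 5)),
              level = c(rep("species", 5), rep("genus", 5)),
              structural_rna = FALSE)
  ph <- rollup(a, tree2, "phylum")
  expect_equal(sum(ph$n), 10L)
  expect_equal(ph$n[ph$name == "P"], 10L)  # genus-level counts join their phylum
  sp <- rollup(a, tree2, "species")
  expect_equal(sp$n[sp$name == "unranked"], 5L)  # genus rows lack a species
  expect_equal(sum(sp$n), 10L)
  expect_error(rollup(a, tree2, "kingdom"), "not present")
})

test_that("mean rollup across samples is the arithmetic mean with zeros", {
  tree <- toy_tree()
  a <- dplyr::bind_rows(lapply(1:9, function(s) {
    n4 <- s          # species 4 grows across samples
    n7 <- ifelse(s <= 3, 2L, 0L)  # species 7 absent from samples 4..9
    tibble(sample = sprintf("S%d", s),
           read_id = sprintf("S%d_r%d", s, seq_len(n4 + n7)),
           taxid = c(rep(4L, n4), rep(7L, n7)),
           level = "species", structural_rna = FALSE)
  }))
  m <- rollup_mean(a, tree, "genus")
  expect_equal(m$mean_n[m$name == "Bactus"], mean(1:9))
  expect_equal(m$mean_n[m$name == "Coccus"], mean(c(2, 2, 2, rep(0, 6))))
})

test_that("masking removes exactly the structural-RNA reads", {
  a <- tibble(read_id = sprintf("r%d", 1:6), taxid = 4L, level = "species",
              structural_rna = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(mask_structural_rna(a)), 3L)
  expect_equal(nrow(mask_structural_rna(a[a$structural_rna, ])), 0L)
  expect_identical(mask_structural_rna(a[!a$structural_rna, ]),
                   a[!a$structural_rna, ])
})

test_that("a phylum seen only through its conserved rRNA gene vanishes when masked", {
  # species D's only sequence IS the rRNA copy (gene embeds into the whole
  # 600 bp record); species E has ordinary genes besides its copy
  cfg <- community_config(
    tiers = list(tier_config("m", "microbiome", list(
      species_spec("D", c(genus = "Dg", phylum = "Dphylum",
                          kingdom = "Bacteria"), 1, 600),
      species_spec("E", c(genus = "Eg", phylum = "Ephylum",
                          kingdom = "Bacteria"), 2, 4000)))),
    conserved = list(conserved_gene(
      "rrn", "rRNA", length = 600, divergence = 0.02,
      placements = tibble(tier = "m", species = c("D", "E")))))
  refs <- generate_reference_set(cfg, 77)
  tree <- taxonomy_tree(refs$taxonomy)
  d_tax <- refs$taxonomy$taxid[refs$taxonomy$name == "D"]
  sim <- clean_reads(refs, c(m = 1), 800, seed = 78)
  cl <- run_map_and_remove(sim$reads, refs$dbs,
                           tier_spec("m", "microbiome", "fixed0"), 0)
  a <- assign_taxa(cl$hits, refs$dbs$m, tree)
  unmasked <- rollup(a, tree, "phylum")
  masked <- rollup(mask_structural_rna(a), tree, "phylum")
  expect_true("Dphylum" %in% unmasked$name)
  expect_false("Dphylum" %in% masked$name)
  expect_true("Ephylum" %in% masked$name)
  # masked counts never exceed unmasked counts, taxon by taxon
  j <- dplyr::left_join(unmasked, masked, by = c("taxid", "name"),
                        suffix = c("_all", "_masked"))
  j$n_masked[is.na(j$n_masked)] <- 0L
  expect_true(all(j$n_masked <= j$n_all))
})

test_that("assignments referencing unknown taxa raise data errors", {
  tree <- toy_tree()
  db <- reference_db("m", "microbiome", tibble(
    seq_id = "s1", seq = strrep("ACGT", 20), taxid = 99L))
  hits <- tibble(read_id = "r1", db = "m", seq_id = "s1", start = 0L,
                 end = 23L, strand = "+", mismatches = 0L)
  expect_error(assign_taxa(hits, db, tree), "absent from the taxonomy")
})
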