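acfg <- align_config(matrix = BL62)

test_that("conservation table scores families by median pairwise stats", {
  fam13 <- ortholog_family("f1", setNames(rep("MKVLWRE", 13),
                                          paste0("g", 1:13)))
  fam2 <- ortholog_family("f2", c(ga = "MW", gb = "MF"))
  tab <- conservation_table(list(fam13, fam2), acfg)
  expect_equal(tab$family_id, c("f1", "f2"))
  expect_equal(tab$median_identity_pct, c(100, 50))
  expect_equal(tab$median_similarity_pct, c(100, 100))
  expect_equal(tab$n_pairs, c(78L, 1L))
  expect_equal(nrow(conservation_table(list(), acfg)), 0L)
})

test_that("conservation table is invariant to genome order within families", {
  set.seed(19)
  members <- setNames(vapply(1:5, function(i) random_protein(30), ""),
                      paste0("g", 1:5))
  t1 <- conservation_table(list(ortholog_family("f", members)), acfg)
  t2 <- conservation_table(list(ortholog_family("f", rev(members))), acfg)
  expect_equal(t1$median_identity_pct, t2$median_identity_pct)
  expect_equal(t1$median_similarity_pct, t2$median_similarity_pct)
})

test_that("quartile threshold uses linear interpolation on a seeded sample", {
  rec <- data.frame(median_similarity_pct = c(60, 70, 80, 90))
  cfg <- conservation_config(annotated_sample_size = 10, quantile = 0.25)
  expect_message(th <- quartile_threshold(rec, cfg), "using all")
  expect_equal(th, 67.5)

  rec_eq <- data.frame(median_similarity_pct = rep(83.2, 6))
  expect_message(expect_equal(quartile_threshold(rec_eq, cfg), 83.2))

  expect_error(quartile_threshold(
    data.frame(median_similarity_pct = c(1, 2, 3)), cfg), "at least 4")

  # sampling is seeded and reproducible
  set.seed(99)
  big <- data.frame(median_similarity_pct = runif(500, 50, 100))
  cfg2 <- conservation_config(annotated_sample_size = 100, seed = 7)
  expect_identical(quartile_threshold(big, cfg2),
                   quartile_threshold(big, cfg2))
})

test_that("fraction_exceeding is strict and monotone in the threshold", {
  rec <- data.frame(median_similarity_pct = c(95, 50))
  expect_equal(fraction_exceeding(rec, 67.5), 0.5)
  expect_equal(fraction_exceeding(rec, 99), 0)
  expect_equal(fraction_exceeding(rec, 95), 0)      # strict inequality
  expect_equal(fraction_exceeding(rec, 95, strict = FALSE), 0.5)
  expect_error(fraction_exceeding(rec[0, , drop = FALSE], 50), "no ORF")

  set.seed(31)
  recs <- data.frame(median_similarity_pct = runif(40, 40, 100))
  ths <- seq(30, 100, by = 5)
  fr <- vapply(ths, function(t) fraction_exceeding(recs, t), 1)
  expect_true(all(diff(fr) <= 0))
})

test_that("similarity excess compares records to the nearest null bin", {
  curve <- data.frame(bin = c(0L, 5L, 10L),
                      median_identity_pct = c(100, 95, 90),
                      median_similarity_pct = c(100, 97, 93),
                      n = c(10L, 10L, 10L))
  rec <- data.frame(median_identity_pct = c(100, 95, 89.7, 80),
                    median_similarity_pct = c(100, 97, 95, 96))
  ex <- similarity_excess(rec, curve)
  expect_equal(ex[1], 0)     # (100,100) vs bin 0
  expect_equal(ex[2], 0)     # equals the curve
  expect_equal(ex[3], 2)     # bin 10 via rounding
  expect_equal(ex[4], 3)     # edge: nearest bin is 10
  expect_error(similarity_excess(rec, curve[0, ]), "empty")
})

test_that("reciprocal best hit recovers trivial and engineered cases", {
  p <- list(gA = c(x = "MKVLWREHD"), gB = c(y = "MKVLWREHD"))
  fams <- rbh_single_copy_families(p, acfg)
  expect_length(fams, 1)
  expect_equal(unname(fams[[1]]$members), rep("MKVLWREHD", 2))
  expect_error(rbh_single_copy_families(list(gA = c(x = "MK"),
                                             gB = character(0)), acfg),
               "empty protein set")

  # a duplicated gene in gA bridges two otherwise-clean families: dropped
  p2 <- list(gA = c(x1 = "MKKKKKWWWW", x2 = "MLLLLLFFFF"),
             gB = c(y = "MKKKKKWWWW"),
             gC = c(z = "MLLLLLFFFF"))
  expect_length(rbh_single_copy_families(p2, acfg), 0)
})

test_that("RBH recovers families on a small simulated clade", {
  cfg <- clade_config(n_genomes = 5, n_genes = 25, gene_length_codons = 120,
                      orf_fraction = 0, substitutions_per_gene_per_branch = 15,
                      rejection_prob = 0.5, seed = 42)
  clade <- simulate_clade(cfg)
  prots <- lapply(clade$genomes, genome_proteins)
  names(prots) <- vapply(clade$genomes, function(g) g$genome_id, "")
  fams <- rbh_single_copy_families(prots, acfg)
  # each recovered family should consist of one gene id shared by all genomes
  ids <- vapply(fams, function(f) {
    parts <- strsplit(f$family_id, "|", fixed = TRUE)[[1]]
    if (length(unique(parts)) == 1L) parts[1] else NA_character_
  }, "")
  expect_gte(sum(!is.na(ids)), ceiling(0.95 * cfg$n_genes))
  expect_false(anyDuplicated(ids[!is.na(ids)]) > 0)
})

test_that("orthogroup import resolves ids and enforces single copy", {
  prots <- list(gA = c(a1 = "MKVLW", a2 = "MPPPP"),
                gB = c(b1 = "MKVLW", b2 = "MPPPP"),
                gC = c(c1 = "MKVLW", c2 = "MPPPP"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tgA\tgB\tgC",
               "OG1\ta1\tb1\tc1",
               "OG2\ta2\tb2\t",          # missing in gC
               "OG3\ta1, a2\tb2\tc2"),   # paralogous cell
             f)
  fams <- read_orthogroups(f, prots)
  expect_length(fams, 1)
  expect_equal(fams[[1]]$family_id, "OG1")
  expect_equal(unname(fams[[1]]$members), rep("MKVLW", 3))
  # with a lower coverage requirement the two-genome families are kept
  # (OG3 keeps gB/gC; the paralogous gA cell is excluded)
  fams2 <- read_orthogroups(f, prots, n_genomes_required = 2)
  expect_length(fams2, 3)
  og3 <- fams2[[3]]
  expect_setequal(names(og3$members), c("gB", "gC"))
})
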