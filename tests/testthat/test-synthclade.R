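usage <- enterobacterial_codon_usage()
acfg <- align_config(matrix = BL62)

test_that("the synthetic usage profile is a valid stop-free distribution", {
  expect_length(usage, 61)
  expect_equal(sum(usage), 1, tolerance = 1e-12)
  expect_true(all(usage > 0))
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(usage)))
})

test_that("ancestor simulation implants intact, findable antisense ORFs", {
  cfg <- clade_config(n_genomes = 2, n_genes = 20, gene_length_codons = 120,
                      orf_fraction = 1, seed = 3)
  anc <- simulate_ancestor(usage, cfg)
  expect_equal(nrow(anc$truth$orfs), 20L)
  found <- find_embedded_antisense_orfs(anc$genome, min_codons = cfg$min_codons)
  # every truth ORF is recovered at its stop anchor (the reported ORF may
  # extend past the truth start via an upstream in-frame initiator)
  fanchor <- paste(found$contig_id, found$strand,
                   ifelse(found$strand == "+", found$end, found$start))
  tanchor <- paste(anc$truth$orfs$contig_id, anc$truth$orfs$strand,
                   anc$truth$orfs$stop_anchor)
  expect_true(all(tanchor %in% fanchor))
  # truth proteins are suffixes of the found proteins (shared stop)
  m <- match(tanchor, fanchor)
  for (k in seq_along(m)) {
    tp <- anc$truth$orfs$protein[k]
    fp <- found$protein[m[k]]
    expect_identical(substring(fp, nchar(fp) - nchar(tp) + 2L),
                     substring(tp, 2L))
  }
  # host genes remain translatable without internal stops
  prots <- genome_proteins(anc$genome)
  expect_length(prots, 20L)
  expect_false(any(grepl("\\*", prots)))
})

test_that("no ORFs are implanted at orf_fraction 0 and bytes are reproducible", {
  cfg <- clade_config(n_genomes = 2, n_genes = 10, gene_length_codons = 100,
                      orf_fraction = 0, seed = 5)
  a1 <- simulate_ancestor(usage, cfg)
  a2 <- simulate_ancestor(usage, cfg)
  expect_equal(nrow(a1$truth$orfs), 0L)
  expect_identical(a1$genome$contigs, a2$genome$contigs)

  clade1 <- simulate_clade(cfg)
  clade2 <- simulate_clade(cfg)
  expect_identical(lapply(clade1$genomes, `[[`, "contigs"),
                   lapply(clade2$genomes, `[[`, "contigs"))
})

test_that("zero substitutions reproduce the ancestor at every tip", {
  cfg <- clade_config(n_genomes = 3, n_genes = 6, gene_length_codons = 80,
                      orf_fraction = 0.5, selected_fraction = 0.5,
                      substitutions_per_gene_per_branch = 0, seed = 7)
  clade <- simulate_clade(cfg)
  for (g in clade$genomes) {
    expect_identical(unname(g$contigs), unname(clade$ancestor$contigs))
  }
})

test_that("substitution counts per branch are respected", {
  cfg <- clade_config(n_genomes = 2, n_genes = 4, gene_length_codons = 90,
                      orf_fraction = 0, substitutions_per_gene_per_branch = 12,
                      rejection_prob = 0, seed = 11)
  clade <- simulate_clade(cfg)
  anc <- strsplit(clade$ancestor$contigs[["chr"]], "")[[1]]
  for (g in clade$genomes) {
    tip <- strsplit(g$contigs[["chr"]], "")[[1]]
    diffs <- sum(anc != tip)
    # <= 12 per gene (repeat hits can collide), and > 0
    expect_lte(diffs, 12 * 4)
    expect_gte(diffs, 4)
    # substitutions only within gene spans
    inside <- logical(length(anc))
    f <- g$features
    for (i in seq_len(nrow(f))) inside[f$start[i]:f$end[i]] <- TRUE
    expect_true(all(inside[anc != tip]))
  }
})

test_that("purifying selection raises protein conservation above neutral", {
  base <- list(n_genomes = 4, n_genes = 12, gene_length_codons = 100,
               orf_fraction = 0, substitutions_per_gene_per_branch = 20,
               seed = 13)
  cl_neutral <- simulate_clade(do.call(clade_config,
                                       c(base, rejection_prob = 0)))
  cl_purify <- simulate_clade(do.call(clade_config,
                                      c(base, rejection_prob = 0.9)))
  sim_of <- function(clade) {
    fams <- families_from_feature_ids(clade$genomes)
    mean(conservation_table(fams, acfg)$median_similarity_pct)
  }
  expect_gt(sim_of(cl_purify), sim_of(cl_neutral))
})

test_that("antisense-selected ORFs show positive similarity excess vs neutral", {
  cfg <- clade_config(n_genomes = 5, n_genes = 40, gene_length_codons = 150,
                      orf_fraction = 0.8, selected_fraction = 0.5,
                      substitutions_per_gene_per_branch = 10,
                      rejection_prob = 0.95, seed = 17)
  clade <- simulate_clade(cfg)
  fams <- orf_families_by_anchor(clade$genomes, min_codons = cfg$min_codons,
                                 n_genomes_required = cfg$n_genomes)
  expect_gt(length(fams), 5)
  tab <- conservation_table(fams, acfg)
  # null curve at matching scale
  sim_cfg <- simulation_config(n_sequences = 15, n_codons = 50, n_rounds = 25,
                               mutations_per_round = 4, frame = "antisense",
                               seed = 17)
  null_anti <- trajectory(generate_sequences(usage, sim_cfg), sim_cfg, acfg)
  tab$excess <- similarity_excess(tab, null_anti)
  # map family anchors to truth regimes
  anchor <- sub("^orf:", "", vapply(fams, function(f) f$family_id, ""))
  truth_key <- paste(clade$truth$orfs$contig_id, clade$truth$orfs$strand,
                     clade$truth$orfs$stop_anchor, sep = ":")
  regime <- clade$truth$orfs$regime[match(anchor, truth_key)]
  expect_true(any(regime == "antisense_selected", na.rm = TRUE))
  expect_true(any(regime == "neutral", na.rm = TRUE))
  sel <- tab$excess[which(regime == "antisense_selected")]
  neu <- tab$excess[which(regime == "neutral")]
  expect_gt(mean(sel), mean(neu))
})

test_that("a clade round-trips through the FASTA/GFF3 writers", {
  cfg <- clade_config(n_genomes = 3, n_genes = 5, gene_length_codons = 80,
                      orf_fraction = 0.4, seed = 19)
  clade <- simulate_clade(cfg)
  dir <- withr::local_tempdir()
  paths <- write_clade(clade, dir)
  expect_equal(nrow(paths), 3L)
  for (i in seq_len(nrow(paths))) {
    g <- clade$genomes[[i]]
    expect_identical(read_fasta(paths$fasta[i]), g$contigs)
    back <- read_features(paths$gff3[i], "gff3")
    expect_equal(back$start, g$features$start)
    expect_equal(back$end, g$features$end)
    expect_equal(back$strand, g$features$strand)
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("a user-supplied bifurcating topology is honored", {
  # ((t1,t2),(t3,t4)); tips 1..4, root 5, internal 6/7; zero-length internal
  # edges make t1/t2 identical and t3/t4 identical, but the pairs differ
  tr <- list(edge = rbind(c(5L, 6L), c(6L, 1L), c(6L, 2L),
                          c(5L, 7L), c(7L, 3L), c(7L, 4L)),
             edge.length = c(30, 0, 0, 30, 0, 0),
             tip.label = paste0("t", 1:4), Nnode = 3L)
  cfg <- clade_config(n_genomes = 4, n_genes = 4, gene_length_codons = 80,
                      orf_fraction = 0, rejection_prob = 0, tree = tr,
                      seed = 23)
  clade <- simulate_clade(cfg)
  seqs <- vapply(clade$genomes, function(g) g$contigs[["chr"]], "")
  expect_identical(seqs[[1]], seqs[[2]])
  expect_identical(seqs[[3]], seqs[[4]])
  expect_false(identical(seqs[[1]], seqs[[3]]))
})
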