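test_that("read_fasta normalizes case, U->T, ids and multi-line records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT"))

  writeLines(c(">c1 desc", "AC", "GT", ">c2", "TT"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT", c2 = "TT"))

  writeLines(c(">r1", "acgu"), f)
  expect_identical(read_fasta(f), c(r1 = "ACGT"))
})

test_that("read_fasta rejects sequence before header and warns on empty file", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">c1", "AA"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(character(0), f)
  expect_warning(res <- read_fasta(f), "empty")
  expect_length(res, 0)
})

test_that("FASTA round-trips through write_fasta", {
  seqs <- c(a = strrep("ACGT", 50), b = "TTG", c = "")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 13)
  expect_identical(read_fasta(f), seqs)
})

test_that("GFF3 reading maps fields and rejects bad records individually", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\t.\tCDS\t7\t15\t.\t-\t.\tID=g1",
               "c1\t.\ttRNA\t20\t95\t.\t+\t.\tID=t1",
               "c1\t.\tgene\t1\t30\t.\t+\t.\tID=x1"), f)
  fs <- read_features(f, "gff3")
  expect_equal(fs$feature_id, c("g1", "t1", "x1"))
  expect_equal(fs[fs$feature_id == "g1", ]$start, 7)
  expect_equal(fs[fs$feature_id == "g1", ]$end, 15)
  expect_equal(fs[fs$feature_id == "g1", ]$strand, "-")
  expect_equal(fs$kind, c("CDS", "tRNA", "other"))

  writeLines(c("##gff-version 3",
               "c1\t.\tCDS\t50\t15\t.\t-\t.\tID=bad",
               "c1\t.\tCDS\t7\t15\t.\t-\t.\tID=g1"), f)
  expect_warning(fs <- read_features(f, "gff3"), "rejected")
  expect_equal(fs$feature_id, "g1")
})

test_that("feature round-trip: read_features(write_gff3(fs)) == fs", {
  fs <- gene_features(c("g1", "g2", "g3"), c("c1", "c1", "c2"),
                      c(7L, 100L, 1L), c(15L, 220L, 9L),
                      c("-", "+", "+"), c("CDS", "rRNA", "other"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fs, f)
  back <- read_features(f, "gff3")
  expect_equal(back[order(back$feature_id), ], fs[order(fs$feature_id), ],
               ignore_attr = TRUE)
})

test_that("NCBI feature-table dialect maps the documented columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("# feature", "class", "genomic_accession", "start",
                     "end", "strand", "locus_tag", sep = "\t"),
               paste("CDS", "with_protein", "NC_1", "10", "51", "+", "b0001",
                     sep = "\t"),
               paste("tRNA", "tRNA", "NC_1", "60", "135", "-", "b0002",
                     sep = "\t"),
               paste("ncRNA", "ncRNA", "NC_1", "140", "160", "+", "b0003",
                     sep = "\t")), f)
  fs <- read_features(f, "ncbi_feature_table")
  expect_equal(fs$kind, c("CDS", "tRNA", "other"))
  expect_equal(fs$feature_id, c("b0001", "b0002", "b0003"))
  expect_equal(fs$start, c(10L, 60L, 140L))
})

test_that("genome invariants: spans within contigs, out-of-frame CDS flagged", {
  expect_error(asorf_genome("g", c(c1 = "ACGTACGT"),
                            gene_features("f1", "c1", 3, 12, "+", "CDS")),
               "beyond contig")
  expect_warning(g <- asorf_genome("g", c(c1 = strrep("ACGT", 10)),
                                   gene_features("f1", "c1", 1, 10, "+", "CDS")),
                 "divisible by 3")
  expect_false(g$features$frame_ok)
})

test_that("reverse_complement is an involution and rejects bad symbols", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("AAAN"), "NTTT")
  expect_error(reverse_complement("ACGR"), "'R'")
  set.seed(7)
  for (k in 1:25) {
    s <- random_dna(sample(0:80, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(nchar(reverse_complement(s)), nchar(s))
  }
})

test_that("translate follows table 11 with N->X and stop handling", {
  expect_identical(translate("ATGAAATAA", strip_terminal_stop = TRUE), "MK")
  expect_identical(translate("ATGTGAAAA", strip_terminal_stop = TRUE), "M*K")
  expect_identical(translate("ATGNNN", strip_terminal_stop = FALSE), "MX")
  expect_error(translate("ATGA"), "divisible by 3")
  expect_error(translate("ATGAXG"), "'X'")
})

test_that("translate agrees with Biostrings on random sequences, both strands", {
  gc11 <- Biostrings::getGeneticCode("11")
  set.seed(11)
  for (k in 1:20) {
    s <- random_dna(300)
    expect_identical(
      translate(s, strip_terminal_stop = FALSE),
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         genetic.code = gc11,
                                         no.init.codon = TRUE)))
    rc <- reverse_complement(s)
    expect_identical(
      translate(rc, strip_terminal_stop = FALSE),
      as.character(Biostrings::translate(
        Biostrings::reverseComplement(Biostrings::DNAString(s)),
        genetic.code = gc11, no.init.codon = TRUE)))
  }
})

test_that("read_matrix parses BLOSUM62 with the documented spot values", {
  m <- blosum62()
  expect_equal(m["A", "A"], 4)
  expect_equal(m["C", "C"], 9)
  expect_equal(m["W", "W"], 11)
  expect_equal(m["W", "F"], 1)
  expect_equal(m["R", "S"], -1)
  expect_true(all(m == t(m)))
  expect_error(matrix_score(m, "A", "J"), "'J'")
})

test_that("parsed BLOSUM62 matches the Biostrings copy on canonical residues", {
  bl <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  m <- blosum62()
  expect_equal(unname(m[AA20, AA20]), unname(bl[AA20, AA20]))
})

test_that("read_matrix rejects asymmetric matrices", {
  f <- withr::local_tempfile()
  writeLines(c("   A  R", "A  4 -1", "R -2  5"), f)
  expect_error(read_matrix(f), "[Aa]symmetric")
})
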