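# Independent oracles and small fixture builders shared across tests.

BL62 <- asorf::blosum62()
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# --- exhaustive global-alignment oracle -------------------------------------
# Enumerates every global alignment as a move sequence (diag / up / left) and
# scores it column-run by column-run: a gap run of length L costs
# go + L * ge unless it is a leading/trailing run and end gaps are free.
# Exponential; only for very short sequences.
oracle_best_alignment_score <- function(a, b, mat = BL62, go = 10, ge = 0.5,
                                        free_end_gaps = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  score_moves <- function(moves) {
    r <- rle(moves)
    i <- 0L; j <- 0L; s <- 0
    for (k in seq_along(r$values)) {
      L <- r$lengths[k]
      if (r$values[k] == 1L) {
        for (t in seq_len(L)) {
          i <- i + 1L; j <- j + 1L
          s <- s + mat[ca[i], cb[j]]
        }
      } else {
        if (r$values[k] == 2L) i <- i + L else j <- j + L
        end_run <- free_end_gaps && (k == 1L || k == length(r$values))
        if (!end_run) s <- s - (go + ge * L)
      }
    }
    s
  }
  rec <- function(i, j, moves) {
    if (i > na && j > nb) {
      s <- score_moves(moves)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, c(moves, 1L))
    if (i <= na) rec(i + 1L, j, c(moves, 2L))
    if (j <= nb) rec(i, j + 1L, c(moves, 3L))
  }
  rec(1L, 1L, integer(0))
  best
}

# --- brute-force embedded antisense ORF oracle ------------------------------
# Six-frame scan over the whole contig with Biostrings translation, keeping
# every start sharing a stop, then a containment filter against
# opposite-strand host CDS spans, then longest-per-stop. Independent of the
# package's span-restricted scan.
oracle_embedded_orfs <- function(genome, min_codons = 2L,
                                 starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  gc11 <- Biostrings::getGeneticCode("11")
  hosts <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  rows <- list()
  for (ct in names(genome$contigs)) {
    fwd <- genome$contigs[[ct]]
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      for (fr in 0:2) {
        open_starts <- integer(0)
        i <- fr + 1L
        while (i + 2L <= n) {
          cod <- substr(s, i, i + 2L)
          if (cod %in% stops) {
            for (st in open_starts) {
              if ((i - st) / 3 >= min_codons) {
                if (strand == "+") { g1 <- st; g2 <- i + 2L }
                else { g1 <- n - (i + 2L) + 1L; g2 <- n - st + 1L }
                containing <- which(hosts$contig_id == ct &
                                      hosts$strand != strand &
                                      hosts$start <= g1 & hosts$end >= g2)
                for (h in containing) {
                  nt <- substr(s, st, i + 2L)
                  prot <- as.character(Biostrings::translate(
                    Biostrings::DNAString(nt), genetic.code = gc11))
                  rows[[length(rows) + 1L]] <- data.frame(
                    contig_id = ct, start = g1, end = g2, strand = strand,
                    protein = sub("\\*$", "", prot),
                    stop_key = paste(ct, strand,
                                     if (strand == "+") g2 else g1,
                                     hosts$feature_id[h]),
                    len = i + 2L - st + 1L, stringsAsFactors = FALSE)
                }
              }
            }
            open_starts <- integer(0)
          } else if (cod %in% starts) {
            open_starts <- c(open_starts, i)
          }
          i <- i + 3L
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  # longest contained ORF per (stop codon, host), then distinct genomic spans
  keep <- unlist(lapply(split(seq_len(nrow(orfs)), orfs$stop_key),
                        function(ix) ix[which.max(orfs$len[ix])]))
  orfs <- orfs[sort(keep), c("contig_id", "start", "end", "strand", "protein")]
  orfs <- orfs[!duplicated(paste(orfs$contig_id, orfs$start, orfs$end,
                                 orfs$strand)), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

orf_key <- function(df) {
  sort(paste(df$contig_id, df$start, df$end, df$strand, df$protein))
}

# random annotated genome: CDS spans of random strand/length, may overlap
random_annotated_genome <- function(id = "rg", contig_len = 600L,
                                    n_cds = 2L) {
  contig <- random_dna(contig_len)
  start <- integer(n_cds); end <- integer(n_cds)
  for (i in seq_len(n_cds)) {
    len <- 3L * sample(30:80, 1L)
    start[i] <- sample.int(contig_len - len, 1L)
    end[i] <- start[i] + len - 1L
  }
  feats <- gene_features(sprintf("cds%02d", seq_len(n_cds)), "c1", start, end,
                         sample(c("+", "-"), n_cds, TRUE), rep("CDS", n_cds))
  asorf_genome(id, c(c1 = contig), feats)
}

# --- toy SAM writer ----------------------------------------------------------
write_toy_sam <- function(path, contig_lengths, reads) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   contig_lengths))
  body <- character(0)
  if (nrow(reads)) {
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    reads$qname, reads$flag, reads$rname, reads$pos,
                    reads$cigar, reads$seq)
  }
  writeLines(c(hdr, body), path)
  path
}

toy_reads <- function(qname, flag, rname, pos, len) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = paste0(len, "M"),
             seq = vapply(len, function(l) strrep("A", l), ""),
             stringsAsFactors = FALSE)
}

# small usage table over a handful of codons
toy_usage <- function() {
  u <- c(ATG = 0.3, AAA = 0.25, GAA = 0.2, CTG = 0.15, GCT = 0.1)
  u / sum(u)
}
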