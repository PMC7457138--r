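# Sequence and annotation IO: FASTA, GFF3, NCBI feature tables, genetic codes
# and substitution matrices. All user-facing coordinates are 1-based inclusive,
# matching GFF3.

VALID_KINDS <- c("CDS", "rRNA", "tRNA", "other")

#' Construct a gene feature table
#'
#' Builds the canonical feature `data.frame` used throughout the package. All
#' coordinates are 1-based inclusive genomic positions; `start <= end`
#' regardless of strand.
#'
#' @param feature_id character, unique feature identifiers.
#' @param contig_id character, contig each feature lies on.
#' @param start,end integer, 1-based inclusive span (start <= end).
#' @param strand character, `"+"` or `"-"`.
#' @param kind character, one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"other"`.
#' @return A `data.frame` with the five columns above.
#' @export
gene_features <- function(feature_id, contig_id, start, end, strand, kind) {
  start <- as.integer(start); end <- as.integer(end)
  n <- length(feature_id)
  stopifnot(length(start) == n, length(end) == n)
  # scalar contig/strand/kind recycle across features
  if (length(contig_id) == 1L) contig_id <- rep(contig_id, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(kind) == 1L) kind <- rep(kind, n)
  stopifnot(length(contig_id) == n, length(strand) == n, length(kind) == n)
  if (any(start < 1L)) stop("feature start must be >= 1")
  if (any(start > end)) stop("feature start must be <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(kind %in% VALID_KINDS)) {
    stop("kind must be one of: ", paste(VALID_KINDS, collapse = ", "))
  }
  data.frame(feature_id = as.character(feature_id),
             contig_id = as.character(contig_id),
             start = start, end = end,
             strand = as.character(strand), kind = as.character(kind),
             stringsAsFactors = FALSE)
}

#' Construct an annotated genome
#'
#' Bundles contig sequences with a feature table and validates the invariants:
#' unique contig ids, nucleotide alphabet `A/C/G/T/N`, and every feature span
#' within its contig. Host CDS spans whose length is not divisible by 3 are
#' kept (the antisense ORF scan works on raw nucleotides) but flagged in the
#' `frame_ok` column so annotation errors do not abort a genome-wide run.
#'
#' @param genome_id character scalar.
#' @param contigs named character vector of nucleotide sequences.
#' @param features feature table as built by [gene_features()]; may be empty.
#' @return An object of class `asorf_genome`: a list with elements
#'   `genome_id`, `contigs`, `features`.
#' @export
asorf_genome <- function(genome_id, contigs, features = gene_features(
                           character(), character(), integer(), integer(),
                           character(), character())) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must be uniquely named")
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    sym <- unique(strsplit(gsub("[ACGTN]", "", contigs[bad][1]), "")[[1]])[1]
    stop("contig '", names(contigs)[bad][1],
         "' contains non-ACGTN symbol: '", sym, "'")
  }
  if (nrow(features)) {
    if (!all(features$contig_id %in% names(contigs))) {
      stop("feature contig_id not present in contigs: ",
           setdiff(features$contig_id, names(contigs))[1])
    }
    clen <- nchar(contigs)[features$contig_id]
    if (any(features$end > clen)) {
      bad <- which(features$end > clen)[1]
      stop("feature '", features$feature_id[bad],
           "' extends beyond contig '", features$contig_id[bad], "'")
    }
    features$frame_ok <- !(features$kind == "CDS" &
                             (features$end - features$start + 1L) %% 3L != 0L)
    if (any(!features$frame_ok)) {
      warning(sum(!features$frame_ok),
              " CDS feature(s) with span not divisible by 3 (flagged)")
    }
  } else {
    features$frame_ok <- logical(0)
  }
  structure(list(genome_id = as.character(genome_id),
                 contigs = contigs, features = features),
            class = "asorf_genome")
}

#' @export
print.asorf_genome <- function(x, ...) {
  cat("asorf_genome '", x$genome_id, "': ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " nt, ", nrow(x$features), " feature(s)\n",
      sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased, `U` is converted to `T`, and record ids are the
#' first whitespace-delimited token of the header. A sequence line appearing
#' before any header is a parse error reporting the offending line number; an
#' empty file yields an empty result with a warning.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence line before any header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene features from GFF3 or an NCBI assembly feature table
#'
#' GFF3 is parsed with `rtracklayer`; records whose start exceeds their end
#' are rejected individually with a warning rather than aborting the file.
#' The NCBI dialect expects the tab-separated `*_feature_table.txt` layout
#' (columns `feature`, `genomic_accession`, `start`, `end`, `strand`,
#' `locus_tag`, ...). Feature kinds outside CDS/rRNA/tRNA are retained as
#' `"other"`.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"ncbi_feature_table"`.
#' @return Feature table as from [gene_features()].
#' @export
read_features <- function(path, dialect = c("gff3", "ncbi_feature_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    ok <- vapply(fields, function(f) {
      length(f) >= 8 && suppressWarnings(!is.na(as.integer(f[4])) &&
                                           !is.na(as.integer(f[5])) &&
                                           as.integer(f[4]) <= as.integer(f[5]))
    }, logical(1))
    if (any(!ok)) {
      warning("rejected ", sum(!ok), " malformed GFF3 record(s) (start > end ",
              "or missing columns)")
      tmp <- tempfile(fileext = ".gff3")
      writeLines(c(lines[!body & startsWith(lines, "#")],
                   lines[body][ok]), tmp)
      on.exit(unlink(tmp))
      path <- tmp
    }
    gr <- rtracklayer::import(path, format = "gff3")
    if (!length(gr)) {
      return(gene_features(character(), character(), integer(), integer(),
                           character(), character()))
    }
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
    if (anyNA(ids)) ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
    kind <- as.character(md$type)
    kind[!kind %in% VALID_KINDS] <- "other"
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) {
      warning("features with unspecified strand treated as '+'")
      strand[strand == "*"] <- "+"
    }
    gene_features(ids, as.character(GenomicRanges::seqnames(gr)),
                  BiocGenerics::start(gr), BiocGenerics::end(gr), strand, kind)
  } else {
    hdr <- readLines(path, n = 1L)
    tab <- read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
    cols <- strsplit(sub("^#\\s*", "", hdr), "\t")[[1]]
    if (ncol(tab) != length(cols)) stop("malformed NCBI feature table header")
    names(tab) <- cols
    need <- c("feature", "genomic_accession", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("NCBI feature table missing columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    bad <- tab$start > tab$end
    if (any(bad)) {
      warning("rejected ", sum(bad), " feature-table record(s) with start > end")
      tab <- tab[!bad, , drop = FALSE]
    }
    ids <- if ("locus_tag" %in% names(tab)) tab$locus_tag else rep(NA, nrow(tab))
    miss <- is.na(ids) | !nzchar(ids)
    ids[miss] <- paste0("feature_", which(miss))
    kind <- tab$feature
    kind[!kind %in% VALID_KINDS] <- "other"
    gene_features(ids, tab$genomic_accession, tab$start, tab$end,
                  tab$strand, kind)
  }
}

#' Write a feature table as GFF3
#'
#' @param features feature table from [gene_features()].
#' @param path output path.
#' @param source value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "asorf") {
  lines <- c("##gff-version 3",
             if (nrow(features)) sprintf(
               "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
               features$contig_id, source, features$kind,
               features$start, features$end, features$strand,
               features$feature_id))
  writeLines(lines, path)
  invisible(path)
}

#' Genetic code table
#'
#' Returns the codon-to-amino-acid map for an NCBI translation table (default
#' 11, the bacterial/archaeal/plant-plastid code: stops TAA/TAG/TGA). Start
#' codons default to the common bacterial initiators ATG/GTG/TTG.
#'
#' @param table_id NCBI genetic code table number.
#' @param start_codons initiator codon set.
#' @return A list of class `asorf_codon_table` with `table_id`, `codons`
#'   (named character vector of 64 amino acids, stops as `"*"`), and
#'   `start_codons`.
#' @export
codon_table <- function(table_id = 11L, start_codons = c("ATG", "GTG", "TTG")) {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(code) == 64L)
  structure(list(table_id = as.integer(table_id),
                 codons = setNames(as.character(code), names(code)),
                 start_codons = start_codons),
            class = "asorf_codon_table")
}

# byte lookup A/C/G/T -> 0..3 (else NA), shared by translate()
.base_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
})

# amino acids ordered by codon index b1*16 + b2*4 + b3 (A<C<G<T)
.aa_by_index <- function(table) {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  dim(codons) <- NULL
  idx <- sapply(strsplit(codons, ""), function(x) {
    .base_lut[utf8ToInt(x[1]) + 1L] * 16L +
      .base_lut[utf8ToInt(x[2]) + 1L] * 4L + .base_lut[utf8ToInt(x[3]) + 1L]
  })
  out <- character(64L)
  out[idx + 1L] <- unname(table$codons[codons])
  out
}

#' Translate a nucleotide sequence
#'
#' Codons containing `N` translate to `X`; internal stops are rendered `*`;
#' a terminal stop is removed iff `strip_terminal_stop`. With
#' `initiator_to_met`, a leading initiator codon (from `table$start_codons`)
#' is rendered `M`, the convention for proteins defined by their start codon;
#' the default is literal codon translation. Length must be divisible by 3.
#'
#' @param seq nucleotide string over `A/C/G/T/N`.
#' @param table genetic code from [codon_table()].
#' @param strip_terminal_stop drop a trailing `*`?
#' @param initiator_to_met render a leading initiator codon as `M`?
#' @return Amino-acid string.
#' @export
translate <- function(seq, table = codon_table(), strip_terminal_stop = TRUE,
                      initiator_to_met = FALSE) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " not divisible by 3")
  if (n == 0L) return("")
  bytes <- utf8ToInt(seq)
  idx <- .base_lut[bytes + 1L]
  if (anyNA(idx)) {
    off <- intToUtf8(bytes[is.na(idx)][1])
    if (off != "N") stop("invalid nucleotide symbol: '", off, "'")
  }
  dim(idx) <- c(3L, n %/% 3L)
  cidx <- idx[1L, ] * 16L + idx[2L, ] * 4L + idx[3L, ] + 1L
  aa <- .aa_by_index(table)[cidx]
  aa[is.na(cidx)] <- "X"  # any codon containing N
  if (initiator_to_met && substr(seq, 1L, 3L) %in% table$start_codons) {
    aa[1L] <- "M"
  }
  if (strip_terminal_stop && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Reverse complement
#'
#' Strict alphabet `A/C/G/T/N`; an involution
#' (`reverse_complement(reverse_complement(s)) == s`).
#'
#' @param seq nucleotide string (vectorized).
#' @return Reverse-complemented string(s).
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    sym <- substring(gsub("[ACGTN]", "", seq[bad][1]), 1, 1)
    stop("invalid nucleotide symbol: '", sym, "'")
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  if (length(seq) == 1L && is.null(names(seq))) out <- unname(out)
  out
}

#' Read an NCBI/EMBOSS-format substitution matrix
#'
#' Parses the standard text layout (comment lines starting `#`, a header row
#' of residues, one labelled row per residue). The matrix must be symmetric.
#'
#' @param path path to the matrix file (e.g. BLOSUM62).
#' @return Numeric matrix with residue dimnames and a `"name"` attribute.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no matrix content in ", path)
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(alphabet)
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(rows) != n) stop("matrix has ", length(rows), " rows for ",
                              n, " alphabet symbols")
  m <- matrix(NA_real_, n, n, dimnames = list(alphabet, alphabet))
  for (r in rows) {
    if (length(r) != n + 1L) stop("malformed matrix row: ", r[1])
    m[r[1], ] <- as.numeric(r[-1])
  }
  if (anyNA(m)) stop("matrix rows do not cover the alphabet")
  if (!isTRUE(all.equal(m, t(m)))) {
    bad <- which(m != t(m), arr.ind = TRUE)[1, ]
    stop("asymmetric matrix entry: ", alphabet[bad[1]], "/", alphabet[bad[2]])
  }
  attr(m, "name") <- sub("\\.[^.]*$", "", basename(path))
  m
}

#' The BLOSUM62 substitution matrix
#'
#' Reads the standard NCBI-format BLOSUM62 file shipped with the package.
#'
#' @return Substitution matrix as from [read_matrix()].
#' @export
blosum62 <- function() {
  read_matrix(system.file("extdata", "BLOSUM62", package = "asorf",
                          mustWork = TRUE))
}

#' Look up a substitution score
#'
#' @param matrix substitution matrix from [read_matrix()].
#' @param a,b single residues.
#' @return Numeric score; error naming the residue if absent.
#' @export
matrix_score <- function(matrix, a, b) {
  for (r in c(a, b)) {
    if (!r %in% rownames(matrix)) stop("residue not in matrix: '", r, "'")
  }
  matrix[a, b]
}

#' Extract CDS nucleotide sequences of a genome
#'
#' Returns each in-frame CDS on its own (sense) strand, 5'->3'.
#'
#' @param genome an [asorf_genome()].
#' @return Named character vector (names = feature ids).
#' @export
genome_cds_seqs <- function(genome) {
  feats <- genome$features
  feats <- feats[feats$kind == "CDS" & feats$frame_ok, , drop = FALSE]
  if (!nrow(feats)) return(setNames(character(0), character(0)))
  out <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    s <- substr(genome$contigs[[feats$contig_id[i]]], feats$start[i], feats$end[i])
    if (feats$strand[i] == "-") s <- reverse_complement(s)
    out[i] <- s
  }
  setNames(out, feats$feature_id)
}

#' Extract and translate CDS features of a genome
#'
#' Returns the protein for every CDS whose span length is divisible by 3,
#' translated on its own strand with the terminal stop stripped and a leading
#' initiator codon rendered as M.
#'
#' @param genome an [asorf_genome()].
#' @param table genetic code.
#' @return Named character vector of proteins (names = feature ids).
#' @export
genome_proteins <- function(genome, table = codon_table()) {
  feats <- genome$features
  feats <- feats[feats$kind == "CDS" & feats$frame_ok, , drop = FALSE]
  if (!nrow(feats)) return(setNames(character(0), character(0)))
  out <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    s <- substr(genome$contigs[[feats$contig_id[i]]], feats$start[i], feats$end[i])
    if (feats$strand[i] == "-") s <- reverse_complement(s)
    out[i] <- translate(s, table, strip_terminal_stop = TRUE,
                        initiator_to_met = TRUE)
  }
  setNames(out, feats$feature_id)
}
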