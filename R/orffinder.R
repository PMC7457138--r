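# Enumeration of ORFs, and of ORFs fully embedded in antisense to annotated
# CDS features. An ORF runs from an initiator codon to the first in-frame stop
# (stop included in the span); by default only the longest ORF per stop is
# reported so nested in-frame sub-ORFs are not counted as distinct candidates.

#' Find ORFs on one strand of a sequence
#'
#' Scans all three frames of `seq` (as given, 5'->3') for spans running from
#' an initiator codon to the first in-frame stop codon. `min_codons` counts
#' the start codon but not the stop. With `longest_only` (default), only the
#' 5'-most initiator per stop is reported.
#'
#' @param seq nucleotide string.
#' @param table genetic code from [codon_table()].
#' @param min_codons minimum ORF length in codons (start included, stop
#'   excluded); must be >= 2.
#' @param start_codons initiator codon set (default from `table`).
#' @param longest_only report only the longest ORF per stop codon?
#' @return `data.frame` with columns `start`, `end` (1-based inclusive on
#'   `seq`, stop codon included), `frame` (0/1/2) and `protein` (terminal
#'   stop stripped).
#' @export
find_orfs <- function(seq, table = codon_table(), min_codons = 20L,
                      start_codons = table$start_codons,
                      longest_only = TRUE) {
  if (min_codons < 2L) stop("min_codons must be >= 2 (start + stop)")
  n <- nchar(seq)
  out <- list()
  stops <- names(table$codons)[table$codons == "*"]
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    cod_start <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, cod_start, cod_start + 2L)
    is_stop <- codons %in% stops
    is_start <- codons %in% start_codons
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (si in stop_idx) {
      starts_in <- which(is_start[seq_len(si - 1L)] &
                           seq_len(si - 1L) > prev_stop)
      if (length(starts_in)) {
        keep <- if (longest_only) starts_in[1L] else starts_in
        for (st in keep) {
          n_cod <- si - st  # codons incl. start, excl. stop
          if (n_cod >= min_codons) {
            nt_from <- cod_start[st]
            nt_to <- cod_start[si] + 2L
            prot <- translate(substr(seq, nt_from, nt_to), table,
                              strip_terminal_stop = TRUE,
                              initiator_to_met = TRUE)
            out[[length(out) + 1L]] <-
              data.frame(start = nt_from, end = nt_to, frame = frame,
                         protein = prot, stringsAsFactors = FALSE)
          }
        }
      }
      prev_stop <- si
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Find ORFs fully embedded in antisense to annotated genes
#'
#' For each host CDS, the reverse complement of the host span is scanned in
#' all three frames; every ORF found is, by construction, fully contained in
#' the host span and on the opposite strand. ORFs contained in multiple
#' overlapping host genes are reported once per distinct genomic span, with
#' all host ids listed (comma-separated, first = primary).
#'
#' @param genome an [asorf_genome()] with at least one CDS feature.
#' @param table genetic code.
#' @param min_codons,start_codons,longest_only see [find_orfs()].
#' @return `data.frame` of ORF records: `orf_id`, `host_gene_id`, `contig_id`,
#'   `start`, `end` (1-based inclusive genomic span including the stop codon),
#'   `strand` (opposite of host), `frame_offset` (0/1/2 relative to the host
#'   gene start), `nt_seq` (ORF strand, 5'->3'), `protein`.
#' @export
find_embedded_antisense_orfs <- function(genome, table = codon_table(),
                                         min_codons = 20L,
                                         start_codons = table$start_codons,
                                         longest_only = TRUE) {
  stopifnot(inherits(genome, "asorf_genome"))
  hosts <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  if (!nrow(hosts)) stop("genome has no CDS features")
  recs <- list()
  for (i in seq_len(nrow(hosts))) {
    h <- hosts[i, ]
    span <- substr(genome$contigs[[h$contig_id]], h$start, h$end)
    host_seq <- if (h$strand == "+") span else reverse_complement(span)
    anti <- reverse_complement(host_seq)
    orfs <- find_orfs(anti, table, min_codons, start_codons, longest_only)
    if (!nrow(orfs)) next
    L <- nchar(host_seq)
    # map antisense-scan positions (p1 <= p2 on the ORF strand) to genomic
    if (h$strand == "+") {
      gstart <- h$end - orfs$end + 1L
      gend <- h$end - orfs$start + 1L
      ostrand <- "-"
    } else {
      # host on '-': its antisense is the contig's forward strand
      gstart <- h$start + orfs$start - 1L
      gend <- h$start + orfs$end - 1L
      ostrand <- "+"
    }
    # frame of the ORF start relative to the host gene start, on the host span
    p_host <- L - orfs$end + 1L  # host-seq coordinate of the ORF's 3'-most nt
    recs[[length(recs) + 1L]] <- data.frame(
      host_gene_id = h$feature_id, contig_id = h$contig_id,
      start = gstart, end = gend, strand = ostrand,
      frame_offset = (p_host - 1L) %% 3L,
      nt_seq = substring(anti, orfs$start, orfs$end),
      protein = orfs$protein, stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    return(data.frame(orf_id = character(), host_gene_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame_offset = integer(), nt_seq = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, recs)
  # deduplicate identical genomic spans arising from overlapping hosts
  key <- paste(res$contig_id, res$start, res$end, res$strand)
  if (anyDuplicated(key)) {
    hosts_by_key <- tapply(res$host_gene_id, key, function(x)
      paste(unique(x), collapse = ","))
    res <- res[!duplicated(key), , drop = FALSE]
    res$host_gene_id <- unname(hosts_by_key[paste(res$contig_id, res$start,
                                                  res$end, res$strand)])
  }
  res <- res[order(res$contig_id, res$start, res$end), , drop = FALSE]
  res <- cbind(orf_id = sprintf("orf_%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write an ORF catalog as GFF3 and protein FASTA
#'
#' @param orfs ORF table from [find_embedded_antisense_orfs()].
#' @param gff3_path,fasta_path output paths (either may be `NULL`).
#' @param min_codons value recorded in the output header.
#' @return Invisibly, the paths written.
#' @export
write_orf_catalog <- function(orfs, gff3_path = NULL, fasta_path = NULL,
                              min_codons = NA) {
  if (!is.null(gff3_path)) {
    lines <- c("##gff-version 3",
               sprintf("#min_codons=%s", min_codons),
               if (nrow(orfs)) sprintf(
                 "%s\tasorf\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;host=%s",
                 orfs$contig_id, orfs$start, orfs$end, orfs$strand,
                 orfs$orf_id, orfs$host_gene_id))
    writeLines(lines, gff3_path)
  }
  if (!is.null(fasta_path)) {
    write_fasta(setNames(orfs$protein, orfs$orf_id), fasta_path)
  }
  invisible(c(gff3 = gff3_path, fasta = fasta_path))
}
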