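# Strand-specific ribosome-profiling coverage: per-site reads-per-million
# (RPM) tracks computed from aligned reads after removing reads that touch
# rRNA/tRNA annotations.

#' Strand-specific per-site RPM coverage from aligned reads
#'
#' Primary alignments are read from a SAM (or BAM) file; reads overlapping
#' any feature of an excluded kind by >= 1 nt (either strand) are removed;
#' each retained read increments depth at every reference position it covers,
#' on the strand it mapped to. RPM = site depth / denominator x 1e6, where
#' the denominator is the count of retained mapped reads (`post_exclusion`,
#' default) or of all mapped reads (`pre_exclusion`). A zero denominator
#' yields all-zero tracks with a warning.
#'
#' @param sam_path SAM or BAM file; coordinate order not required.
#' @param genome an [asorf_genome()] whose contigs cover the alignment
#'   references.
#' @param exclude_kinds feature kinds whose overlapping reads are removed.
#' @param denominator `"post_exclusion"` or `"pre_exclusion"`.
#' @return An object of class `asorf_coverage`: list with `tracks` (per
#'   contig, a list of numeric RPM vectors `plus` and `minus` over
#'   `[1, contig length]`), `denominator`, `n_total_mapped`, `n_excluded`.
#' @export
compute_rpm <- function(sam_path, genome, exclude_kinds = c("rRNA", "tRNA"),
                        denominator = c("post_exclusion", "pre_exclusion")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(genome, "asorf_genome"))
  bam <- if (grepl("\\.bam$", sam_path, ignore.case = TRUE)) sam_path else
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  refs <- GenomeInfoDb::seqlevels(gal)
  unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gal))),
                     names(genome$contigs))
  if (length(unknown)) {
    stop("alignment reference absent from genome: ", unknown[1])
  }
  n_total <- length(gal)
  excl_feats <- genome$features[genome$features$kind %in% exclude_kinds, ,
                                drop = FALSE]
  if (nrow(excl_feats) && n_total) {
    excl <- GenomicRanges::GRanges(
      excl_feats$contig_id,
      IRanges::IRanges(excl_feats$start, excl_feats$end))
    GenomeInfoDb::seqlevels(excl) <- GenomeInfoDb::seqlevels(gal)
    hit <- IRanges::overlapsAny(gal, excl, ignore.strand = TRUE)
    retained <- gal[!hit]
  } else {
    retained <- gal
  }
  n_excl <- n_total - length(retained)
  denom <- if (denominator == "post_exclusion") length(retained) else n_total
  # pad coverage to full contig lengths
  sl <- nchar(genome$contigs)
  tracks <- lapply(names(genome$contigs), function(ct) {
    out <- list(plus = numeric(sl[[ct]]), minus = numeric(sl[[ct]]))
    if (denom == 0L) return(out)
    for (str in c("+", "-")) {
      sel <- retained[as.character(GenomeInfoDb::seqnames(retained)) == ct &
                        as.character(BiocGenerics::strand(retained)) == str]
      depth <- numeric(sl[[ct]])
      if (length(sel)) {
        cov <- GenomicAlignments::coverage(sel)[[ct]]
        v <- as.numeric(cov)
        depth[seq_along(v)] <- v
      }
      out[[if (str == "+") "plus" else "minus"]] <- depth / denom * 1e6
    }
    out
  })
  names(tracks) <- names(genome$contigs)
  if (denom == 0L && n_total > 0L) {
    warning("no reads retained after exclusion; RPM tracks are all zero")
  }
  message("compute_rpm: ", n_total, " mapped reads, ", n_excl,
          " removed by ", paste(exclude_kinds, collapse = "/"),
          " overlap, denominator ", denom)
  structure(list(tracks = tracks, denominator = denom,
                 n_total_mapped = n_total, n_excluded = n_excl),
            class = "asorf_coverage")
}

#' @export
print.asorf_coverage <- function(x, ...) {
  cat("asorf_coverage: ", length(x$tracks), " contig(s), denominator ",
      x$denominator, " (", x$n_excluded, " reads excluded)\n", sep = "")
  invisible(x)
}

#' Write coverage tracks as bedGraph, one file per strand
#'
#' bedGraph uses 0-based half-open intervals; zero-valued runs are omitted.
#'
#' @param cov an `asorf_coverage`.
#' @param prefix output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph <- function(cov, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (str in names(paths)) {
    con <- file(paths[[str]], "w")
    for (ct in names(cov$tracks)) {
      v <- cov$tracks[[ct]][[str]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths  # 0-based
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%g", ct, starts[keep], ends[keep],
                           r$values[keep]), con)
      }
    }
    close(con)
  }
  invisible(paths)
}
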