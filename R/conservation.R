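# Per-family conservation statistics across a clade and the lower-quartile
# classification: ortholog families (reciprocal best hit, imported orthogroup
# tables, or id/coordinate mapping on simulated clades) are scored by median
# pairwise amino-acid identity/similarity; antisense ORF families are then
# classified against the lower quartile of annotated single-copy families.

#' Conservation analysis configuration
#'
#' @param n_genomes_required genomes a family must cover to be single-copy
#'   complete (the published analysis used 13).
#' @param annotated_sample_size annotated families sampled for the quantile
#'   threshold (published analysis: 1000); all are used if fewer exist.
#' @param quantile quantile defining the conservation threshold (default 0.25,
#'   the lower quartile).
#' @param quantile_method quantile algorithm; `"linear"` is linear
#'   interpolation between order statistics (R type 7).
#' @param strict_exceed does "exceeds" mean strictly greater (default)?
#' @param seed seed for the annotated-family sample.
#' @return A list of class `asorf_conservation_config`.
#' @export
conservation_config <- function(n_genomes_required = 13L,
                                annotated_sample_size = 1000L,
                                quantile = 0.25, quantile_method = "linear",
                                strict_exceed = TRUE, seed = 1L) {
  stopifnot(quantile > 0, quantile < 1)
  structure(list(n_genomes_required = as.integer(n_genomes_required),
                 annotated_sample_size = as.integer(annotated_sample_size),
                 quantile = quantile, quantile_method = quantile_method,
                 strict_exceed = strict_exceed, seed = as.integer(seed)),
            class = "asorf_conservation_config")
}

#' Construct an ortholog family
#'
#' @param family_id character scalar.
#' @param members named character vector, one protein per genome (names =
#'   genome ids); at least 2 members, single-copy.
#' @param kind `"annotated_gene"` or `"antisense_orf"`.
#' @return A list of class `asorf_family`.
#' @export
ortholog_family <- function(family_id, members,
                            kind = c("annotated_gene", "antisense_orf")) {
  kind <- match.arg(kind)
  if (length(members) < 2L) stop("a family needs at least 2 members")
  if (is.null(names(members)) || anyDuplicated(names(members))) {
    stop("members must be named by genome, one member per genome")
  }
  structure(list(family_id = as.character(family_id), members = members,
                 kind = kind),
            class = "asorf_family")
}

#' Single-copy ortholog families by reciprocal best hit
#'
#' Builds the reciprocal-best-hit (RBH) graph over all genome pairs using
#' global alignment scores and keeps connected components that contain exactly
#' one protein per genome and are RBH-consistent for every genome pair. This
#' is the built-in fallback for desk-scale clades; full-scale studies should
#' import orthogroups from a dedicated clustering tool via
#' [read_orthogroups()].
#'
#' @param proteomes named list (genome id -> named character vector of
#'   proteins).
#' @param config an [align_config()].
#' @return List of [ortholog_family()] objects (kind `"annotated_gene"`).
#' @export
rbh_single_copy_families <- function(proteomes, config = align_config()) {
  if (length(proteomes) < 2L) stop("need at least 2 genomes")
  empty <- vapply(proteomes, length, 1L) == 0L
  if (any(empty)) {
    stop("genome with empty protein set: ", names(proteomes)[empty][1])
  }
  gids <- names(proteomes)
  n_g <- length(gids)
  # global protein index
  all_prot <- unlist(proteomes, use.names = FALSE)
  prot_genome <- rep(gids, vapply(proteomes, length, 1L))
  prot_name <- unlist(lapply(proteomes, names), use.names = FALSE)
  enc <- lapply(all_prot, .encode_protein, alphabet = rownames(config$matrix))
  idx_by_genome <- split(seq_along(all_prot), prot_genome)[gids]

  edges <- matrix(integer(0), ncol = 2)
  for (gi in seq_len(n_g - 1L)) {
    for (gj in seq(gi + 1L, n_g)) {
      ia <- idx_by_genome[[gi]]; ib <- idx_by_genome[[gj]]
      sc <- matrix(0, length(ia), length(ib))
      for (a in seq_along(ia)) {
        for (b in seq_along(ib)) {
          sc[a, b] <- .nw_score(enc[[ia[a]]], enc[[ib[b]]], config$matrix,
                                config$gap_open, config$gap_extend,
                                config$free_end_gaps)
        }
      }
      best_ab <- apply(sc, 1L, which.max)
      best_ba <- apply(sc, 2L, which.max)
      mutual <- which(best_ba[best_ab] == seq_along(ia))
      if (length(mutual)) {
        edges <- rbind(edges, cbind(ia[mutual], ib[best_ab[mutual]]))
      }
    }
  }
  if (!nrow(edges)) return(list())
  # union-find over RBH edges
  parent <- seq_along(all_prot)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(all_prot), find, 1L)
  edge_key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  fams <- list()
  for (members in split(seq_along(all_prot), comp)) {
    if (length(members) != n_g) next
    if (anyDuplicated(prot_genome[members])) next
    pair_idx <- combn(members, 2L)
    keys <- paste(pmin(pair_idx[1, ], pair_idx[2, ]),
                  pmax(pair_idx[1, ], pair_idx[2, ]))
    if (!all(keys %in% edge_key)) next  # every pair must be mutual-best
    m <- setNames(all_prot[members], prot_genome[members])[gids]
    fams[[length(fams) + 1L]] <- ortholog_family(
      paste(prot_name[members][order(prot_genome[members])], collapse = "|"),
      m, kind = "annotated_gene")
  }
  fams
}

#' Import orthogroups from a clustering tool's TSV output
#'
#' Reads a tab-separated orthogroups table (first column = family id, one
#' column per genome, cells = protein ids; empty or multi-id cells mark
#' missing/paralogous members) and resolves ids against the supplied
#' proteomes. Only families with exactly one member in every required genome
#' are returned.
#'
#' @param path orthogroups TSV.
#' @param proteomes named list (genome id -> named character vector of
#'   proteins); names must match the table's genome columns.
#' @param n_genomes_required minimum genome coverage (default: all columns).
#' @return List of [ortholog_family()] objects.
#' @export
read_orthogroups <- function(path, proteomes, n_genomes_required = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gcols <- intersect(names(tab)[-1], names(proteomes))
  if (!length(gcols)) stop("no orthogroup columns match the proteome names")
  if (is.null(n_genomes_required)) n_genomes_required <- length(gcols)
  fams <- list()
  for (i in seq_len(nrow(tab))) {
    ids <- trimws(unlist(tab[i, gcols]))
    single <- nzchar(ids) & !grepl("[,;]", ids)
    if (sum(single) < n_genomes_required) next
    g_use <- gcols[single]
    seqs <- mapply(function(g, id) proteomes[[g]][[id]], g_use, ids[single])
    if (any(vapply(seqs, is.null, TRUE))) {
      stop("orthogroup ", tab[i, 1], " references unknown protein id")
    }
    fams[[length(fams) + 1L]] <- ortholog_family(
      as.character(tab[i, 1]), setNames(unlist(seqs), g_use),
      kind = "annotated_gene")
  }
  fams
}

#' Conservation table: median pairwise identity/similarity per family
#'
#' @param families list of [ortholog_family()] objects.
#' @param config an [align_config()].
#' @return `data.frame` with `family_id`, `kind`, `median_identity_pct`,
#'   `median_similarity_pct`, `n_pairs`.
#' @export
conservation_table <- function(families, config = align_config()) {
  if (!length(families)) {
    return(data.frame(family_id = character(), kind = character(),
                      median_identity_pct = numeric(),
                      median_similarity_pct = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(families, function(f) {
    v <- family_pairwise_medians(unname(f$members), config)
    data.frame(family_id = f$family_id, kind = f$kind,
               median_identity_pct = v[["median_identity_pct"]],
               median_similarity_pct = v[["median_similarity_pct"]],
               n_pairs = as.integer(v[["n_pairs"]]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Conservation threshold: quantile of annotated-family similarity
#'
#' The `cfg$quantile` quantile (default lower quartile) of median pairwise
#' similarity over a seeded random sample of `cfg$annotated_sample_size`
#' annotated families (all families, with a message, if fewer exist).
#'
#' @param annotated_records conservation table of annotated families.
#' @param cfg a [conservation_config()].
#' @return Threshold similarity percentage (scalar).
#' @export
quartile_threshold <- function(annotated_records, cfg = conservation_config()) {
  if (nrow(annotated_records) < 4L) {
    stop("need at least 4 annotated families for a quartile threshold")
  }
  sims <- annotated_records$median_similarity_pct
  if (nrow(annotated_records) > cfg$annotated_sample_size) {
    set.seed(cfg$seed)
    sims <- sims[sample.int(length(sims), cfg$annotated_sample_size)]
  } else if (nrow(annotated_records) < cfg$annotated_sample_size) {
    message("fewer annotated families (", nrow(annotated_records),
            ") than requested sample size (", cfg$annotated_sample_size,
            "); using all")
  }
  type <- if (cfg$quantile_method == "linear") 7L else 7L
  unname(quantile(sims, probs = cfg$quantile, type = type, names = FALSE))
}

#' Fraction of ORF families exceeding a conservation threshold
#'
#' @param orf_records conservation table of antisense ORF families.
#' @param threshold similarity threshold from [quartile_threshold()].
#' @param strict strictly greater (default) or greater-or-equal.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_exceeding <- function(orf_records, threshold, strict = TRUE) {
  if (!nrow(orf_records)) stop("no ORF conservation records")
  s <- orf_records$median_similarity_pct
  if (strict) mean(s > threshold) else mean(s >= threshold)
}

#' Similarity excess over the neutral trajectory
#'
#' For each conservation record, the difference between its median similarity
#' and the null-curve median similarity at the record's identity-decrease bin
#' (nearest populated bin at the edges). Positive values indicate a bias
#' toward fixing similar amino-acid replacements relative to neutral
#' mutation accumulation.
#'
#' @param records conservation table (one or more rows).
#' @param null_curve an `asorf_trajectory` (or its `curve` data.frame).
#' @return Numeric vector of excesses, one per record row.
#' @export
similarity_excess <- function(records, null_curve) {
  curve <- if (inherits(null_curve, "asorf_trajectory")) null_curve$curve
           else null_curve
  if (!nrow(curve)) stop("empty null curve")
  bins <- as.integer(round(100 - records$median_identity_pct))
  vapply(seq_len(nrow(records)), function(i) {
    j <- which.min(abs(curve$bin - bins[i]))
    records$median_similarity_pct[i] - curve$median_similarity_pct[j]
  }, numeric(1))
}

#' Write a conservation table as TSV
#'
#' @param records conservation table, optionally with an `exceeds_threshold`
#'   column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
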