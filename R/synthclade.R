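# Synthetic clade generator: an ancestral genome of codon-usage-sampled genes,
# a subset carrying fully embedded antisense ORFs, evolved down a star (or
# user-supplied) topology under per-gene substitution counts with rejection
# sampling emulating purifying selection (sense frame for host genes,
# additionally antisense frame for "selected" ORFs). Ground truth regimes are
# recorded for parameter-recovery tests.

#' Representative enterobacterial codon usage (synthetic)
#'
#' A smooth, synthetic codon-usage profile built from approximate bacterial
#' amino-acid composition and a geometric within-family codon bias. It is NOT
#' a measured codon-usage table; it reproduces the qualitative features that
#' matter for the simulations (non-uniform amino-acid composition, unequal
#' synonymous codon use, no stop codons). For real analyses derive usage from
#' a genome with [codon_usage_from_cds()].
#'
#' @param table genetic code.
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
enterobacterial_codon_usage <- function(table = codon_table()) {
  aa_freq <- c(A = 9.5, R = 5.5, N = 3.9, D = 5.2, C = 1.2, Q = 4.4, E = 5.8,
               G = 7.4, H = 2.2, I = 6.0, L = 10.5, K = 4.7, M = 2.8, F = 3.9,
               P = 4.4, S = 5.8, T = 5.4, W = 1.5, Y = 2.9, V = 7.1)
  codons <- names(table$codons)[table$codons != "*"]
  aas <- table$codons[codons]
  w <- numeric(length(codons))
  for (aa in unique(aas)) {
    fam <- which(aas == aa)
    fam <- fam[order(codons[fam])]
    w[fam] <- aa_freq[[aa]] * 0.6^(seq_along(fam) - 1L)
  }
  usage <- w / sum(w)
  names(usage) <- codons
  attr(usage, "source") <- "synthetic representative enterobacterial profile"
  usage
}

#' Clade simulation configuration
#'
#' @param n_genomes genomes in the clade (default 13).
#' @param n_genes annotated genes per genome (default 200).
#' @param gene_length_codons gene length excluding the stop codon (default
#'   333).
#' @param orf_fraction share of genes hosting an embedded antisense ORF.
#' @param selected_fraction share of those ORFs under antisense
#'   similarity-biased selection.
#' @param substitutions_per_gene_per_branch accepted substitutions applied to
#'   every gene on every branch.
#' @param rejection_prob probability of rejecting a proposed substitution
#'   whose amino-acid replacement scores <= 0 (sense frame for all host
#'   genes; additionally antisense frame inside selected ORF spans).
#' @param orf_codons_range inclusive range of implanted ORF lengths in codons
#'   (start included, stop excluded).
#' @param min_codons minimum ORF length used when validating implants.
#' @param tree `"star"` (independent branches from the ancestor) or a
#'   `phylo`-style list (`edge`, `edge.length`, `tip.label`, `Nnode`) whose
#'   edge lengths are per-gene substitution counts.
#' @param seed master seed.
#' @return A list of class `asorf_clade_config`.
#' @export
clade_config <- function(n_genomes = 13L, n_genes = 200L,
                         gene_length_codons = 333L, orf_fraction = 0.3,
                         selected_fraction = 0.3,
                         substitutions_per_gene_per_branch = 25L,
                         rejection_prob = 0.9, orf_codons_range = c(20L, 50L),
                         min_codons = 20L, tree = "star", seed = 1L) {
  stopifnot(n_genomes >= 2L, n_genes >= 1L, gene_length_codons >= 10L,
            orf_fraction >= 0, orf_fraction <= 1,
            selected_fraction >= 0, selected_fraction <= 1,
            substitutions_per_gene_per_branch >= 0L,
            rejection_prob >= 0, rejection_prob <= 1,
            orf_codons_range[1] >= 2L,
            orf_codons_range[2] <= gene_length_codons - 3L)
  structure(list(n_genomes = as.integer(n_genomes),
                 n_genes = as.integer(n_genes),
                 gene_length_codons = as.integer(gene_length_codons),
                 orf_fraction = orf_fraction,
                 selected_fraction = selected_fraction,
                 substitutions_per_gene_per_branch =
                   as.integer(substitutions_per_gene_per_branch),
                 rejection_prob = rejection_prob,
                 orf_codons_range = as.integer(orf_codons_range),
                 min_codons = as.integer(min_codons),
                 tree = tree, seed = as.integer(seed)),
            class = "asorf_clade_config")
}

.comp_lut <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement of a character vector of bases
.rc_chars <- function(x) rev(unname(.comp_lut[x]))

#' Simulate an ancestral annotated genome with implanted antisense ORFs
#'
#' Genes are drawn codon-wise from `usage` (plus a stop codon) and placed on
#' random strands along one contig, separated by short random spacers. For
#' `orf_fraction` of genes an interior, codon-aligned window is overwritten
#' with the reverse complement of a constructed ORF (initiator, non-stop
#' codons, stop), rejection-sampled until the host sense frame stays free of
#' stop codons; so every truth ORF is fully embedded, antisense, and intact
#' in the ancestor.
#'
#' @param usage codon usage (see [enterobacterial_codon_usage()]).
#' @param cfg a [clade_config()].
#' @param max_tries rejection budget per ORF implant.
#' @return A list with `genome` ([asorf_genome()]) and `truth` (list with
#'   `genes` and `orfs` data.frames).
#' @export
simulate_ancestor <- function(usage, cfg = clade_config(), max_tries = 10000L) {
  set.seed(cfg$seed)
  table <- codon_table()
  stops <- names(table$codons)[table$codons == "*"]
  n <- cfg$n_genes
  L <- cfg$gene_length_codons
  gene_len <- 3L * (L + 1L)  # incl. stop codon
  spacer <- 30L

  orf_genes <- sort(sample.int(n, round(cfg$orf_fraction * n)))
  n_sel <- round(cfg$selected_fraction * length(orf_genes))
  selected <- if (length(orf_genes)) sort(sample(orf_genes, n_sel)) else integer(0)

  genes <- vector("list", n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  orf_rows <- list()

  for (i in seq_len(n)) {
    cod <- sample(names(usage), L, replace = TRUE, prob = usage)
    cod <- c(cod, sample(stops, 1L))
    if (i %in% orf_genes) {
      Lo <- sample(seq(cfg$orf_codons_range[1], cfg$orf_codons_range[2]), 1L)
      win_cod <- Lo + 1L  # host codons covered by the implant (incl. ORF stop)
      if (win_cod > L - 2L) stop("ORF too long for gene; increase gene_length_codons")
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        o_cod <- c(sample(table$start_codons, 1L),
                   sample(names(usage), Lo - 1L, replace = TRUE, prob = usage),
                   sample(stops, 1L))
        orf_nt <- paste(o_cod, collapse = "")
        w_nt <- reverse_complement(orf_nt)
        starts <- seq(1L, nchar(w_nt), by = 3L)
        w_cod <- substring(w_nt, starts, starts + 2L)
        if (!any(w_cod %in% stops)) { ok <- TRUE; break }
      }
      if (!ok) stop("ORF implant rejection budget exhausted; ",
                    "increase gene_length_codons or max_tries")
      w <- sample(seq(2L, L - win_cod), 1L)  # first host codon of the window
      cod[w:(w + win_cod - 1L)] <- w_cod
      a <- 3L * (w - 1L) + 1L          # window start, gene nt coords
      b <- 3L * (w + win_cod - 1L)     # window end
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        gene_index = i, sense_from = a, sense_to = b, orf_nt = orf_nt,
        protein = translate(orf_nt, table, initiator_to_met = TRUE),
        regime = if (i %in% selected) "antisense_selected" else "neutral",
        stringsAsFactors = FALSE)
    }
    genes[[i]] <- paste(cod, collapse = "")
  }

  # lay genes along one contig
  bases <- c("A", "C", "G", "T")
  pieces <- character(2L * n + 1L)
  gstart <- integer(n); gend <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    sp <- paste(sample(bases, spacer, replace = TRUE), collapse = "")
    pieces[2L * i - 1L] <- sp
    pos <- pos + spacer
    gstart[i] <- pos + 1L
    gend[i] <- pos + gene_len
    pieces[2L * i] <- if (strands[i] == "+") genes[[i]] else
      reverse_complement(genes[[i]])
    pos <- pos + gene_len
  }
  pieces[2L * n + 1L] <- paste(sample(bases, spacer, replace = TRUE),
                               collapse = "")
  contig <- paste(pieces, collapse = "")

  feats <- gene_features(sprintf("g%03d", seq_len(n)), "chr", gstart, gend,
                         strands, rep("CDS", n))
  genome <- asorf_genome("ancestor", c(chr = contig), feats)

  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(gene_index = integer(), sense_from = integer(),
               sense_to = integer(), orf_nt = character(),
               protein = character(), regime = character(),
               stringsAsFactors = FALSE)
  if (nrow(orfs)) {
    # genomic span and strand of each truth ORF
    gi <- orfs$gene_index
    plus <- strands[gi] == "+"
    orfs$contig_id <- "chr"
    orfs$start <- ifelse(plus, gstart[gi] + orfs$sense_from - 1L,
                         gend[gi] - orfs$sense_to + 1L)
    orfs$end <- ifelse(plus, gstart[gi] + orfs$sense_to - 1L,
                       gend[gi] - orfs$sense_from + 1L)
    orfs$strand <- ifelse(plus, "-", "+")
    # the ORF's stop codon sits at the low-coordinate edge for '-' ORFs and
    # the high-coordinate edge for '+' ORFs; this anchor survives in-frame
    # start-codon turnover during evolution
    orfs$stop_anchor <- ifelse(orfs$strand == "+", orfs$end, orfs$start)
    orfs$host_gene_id <- sprintf("g%03d", gi)
  }
  truth <- list(
    genes = data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                       strand = strands, start = gstart, end = gend,
                       host_regime = "sense_purifying",
                       has_orf = seq_len(n) %in% orf_genes,
                       stringsAsFactors = FALSE),
    orfs = orfs)
  list(genome = genome, truth = truth)
}

# evolve one gene's sense sequence (character vector) by n_sub accepted
# substitutions under the rejection rules; orf window in gene nt coords or NULL
.evolve_gene <- function(s, n_sub, orf_from, orf_to, orf_selected,
                         rejection_prob, matrix, aa_by_index) {
  len <- length(s)
  accepted <- 0L
  tries <- 0L
  max_tries <- max(1000L, 200L * n_sub)
  bases <- c("A", "C", "G", "T")
  codon_aa <- function(c1, c2, c3) {
    i <- .base_lut[utf8ToInt(c1) + 1L] * 16L +
      .base_lut[utf8ToInt(c2) + 1L] * 4L + .base_lut[utf8ToInt(c3) + 1L] + 1L
    aa_by_index[i]
  }
  while (accepted < n_sub) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("substitution rejection budget exhausted (rejection_prob too high?)")
    }
    p <- sample.int(len, 1L)
    old <- s[p]
    new <- sample(bases[bases != old], 1L)
    ci <- (p - 1L) %/% 3L
    cpos <- 3L * ci + 1L
    cod <- s[cpos:(cpos + 2L)]
    aa_old <- codon_aa(cod[1], cod[2], cod[3])
    cod[p - cpos + 1L] <- new
    aa_new <- codon_aa(cod[1], cod[2], cod[3])
    if (matrix[aa_old, aa_new] <= 0 && runif(1L) < rejection_prob) next
    if (orf_selected && !is.null(orf_from) && p >= orf_from && p <= orf_to) {
      q <- orf_to - p + 1L  # position on the ORF strand
      cj <- (q - 1L) %/% 3L
      gpos <- (orf_to - 3L * cj - 2L):(orf_to - 3L * cj)
      wcod <- s[gpos]
      acod <- .rc_chars(wcod)
      a_old <- codon_aa(acod[1], acod[2], acod[3])
      wcod[p - gpos[1L] + 1L] <- new
      acod2 <- .rc_chars(wcod)
      a_new <- codon_aa(acod2[1], acod2[2], acod2[3])
      if (matrix[a_old, a_new] <= 0 && runif(1L) < rejection_prob) next
    }
    s[p] <- new
    accepted <- accepted + 1L
  }
  s
}

# star topology as an edge list: root node 0 -> tips 1..n
.clade_edges <- function(cfg) {
  if (identical(cfg$tree, "star")) {
    list(edge = cbind(rep(0L, cfg$n_genomes), seq_len(cfg$n_genomes)),
         length = rep(cfg$substitutions_per_gene_per_branch, cfg$n_genomes),
         tips = seq_len(cfg$n_genomes),
         tip_label = sprintf("g%02d", seq_len(cfg$n_genomes)),
         root = 0L)
  } else {
    tr <- cfg$tree
    stopifnot(is.list(tr), !is.null(tr$edge), !is.null(tr$edge.length))
    ntip <- length(tr$tip.label)
    if (ntip != cfg$n_genomes) stop("tree tip count != n_genomes")
    list(edge = tr$edge, length = round(tr$edge.length),
         tips = seq_len(ntip), tip_label = tr$tip.label, root = ntip + 1L)
  }
}

#' Evolve a clade of genomes from a simulated ancestor
#'
#' Each branch applies its per-gene substitution count. A proposed
#' substitution is rejected with probability `rejection_prob` when its sense
#' amino-acid replacement scores <= 0 (purifying selection on every host
#' gene), and -- additionally, inside antisense-selected ORF spans -- when its
#' antisense-frame replacement scores <= 0. Rejected proposals are redrawn so
#' the per-branch substitution count is always met. With
#' `rejection_prob = 0` evolution is strictly neutral.
#'
#' @param ancestor,truth output of [simulate_ancestor()].
#' @param cfg a [clade_config()].
#' @param matrix substitution matrix used by the rejection rules.
#' @return List of [asorf_genome()] objects, one per tip.
#' @export
evolve_clade <- function(ancestor, truth, cfg = clade_config(),
                         matrix = blosum62()) {
  set.seed(cfg$seed + 1L)
  aa_by_index <- .aa_by_index(codon_table())
  tree <- .clade_edges(cfg)
  feats <- ancestor$features
  n <- nrow(feats)
  # ancestor gene sense sequences as character vectors
  anc_genes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- substr(ancestor$contigs[["chr"]], feats$start[i], feats$end[i])
    if (feats$strand[i] == "-") s <- reverse_complement(s)
    anc_genes[[i]] <- strsplit(s, "")[[1]]
  }
  orf_map <- vector("list", n)
  if (nrow(truth$orfs)) {
    for (k in seq_len(nrow(truth$orfs))) {
      o <- truth$orfs[k, ]
      orf_map[[o$gene_index]] <- list(from = o$sense_from, to = o$sense_to,
                                      selected = o$regime == "antisense_selected")
    }
  }
  # depth-first evolution along the tree
  node_genes <- list()
  node_genes[[as.character(tree$root)]] <- anc_genes
  genomes <- vector("list", length(tree$tips))
  # iterate edges until every parent's sequences are resolved (handles any
  # edge ordering in user-supplied topologies)
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    progressed <- FALSE
    for (e in remaining) {
      pk <- as.character(tree$edge[e, 1])
      if (is.null(node_genes[[pk]])) next
      child <- tree$edge[e, 2]
      g <- node_genes[[pk]]
      for (i in seq_len(n)) {
        om <- orf_map[[i]]
        g[[i]] <- .evolve_gene(g[[i]], tree$length[e],
                               if (is.null(om)) NULL else om$from,
                               if (is.null(om)) NULL else om$to,
                               !is.null(om) && om$selected,
                               cfg$rejection_prob, matrix, aa_by_index)
      }
      node_genes[[as.character(child)]] <- g
      remaining <- setdiff(remaining, e)
      progressed <- TRUE
      if (child %in% tree$tips) {
        contig <- strsplit(ancestor$contigs[["chr"]], "")[[1]]
        for (i in seq_len(n)) {
          gi <- g[[i]]
          if (feats$strand[i] == "-") gi <- .rc_chars(gi)
          contig[feats$start[i]:feats$end[i]] <- gi
        }
        genomes[[child]] <- asorf_genome(
          tree$tip_label[child], c(chr = paste(contig, collapse = "")),
          feats[, c("feature_id", "contig_id", "start", "end", "strand",
                    "kind")])
      }
    }
    if (!progressed) stop("tree has unreachable edges")
  }
  genomes
}

#' Simulate a full clade with ground truth
#'
#' Convenience wrapper: [simulate_ancestor()] + [evolve_clade()].
#'
#' @param cfg a [clade_config()].
#' @param usage codon usage.
#' @param matrix substitution matrix for the selection rules.
#' @return List with `ancestor`, `truth`, `genomes`.
#' @export
simulate_clade <- function(cfg = clade_config(),
                           usage = enterobacterial_codon_usage(),
                           matrix = blosum62()) {
  anc <- simulate_ancestor(usage, cfg)
  genomes <- evolve_clade(anc$genome, anc$truth, cfg, matrix)
  list(ancestor = anc$genome, truth = anc$truth, genomes = genomes)
}

#' Write a simulated clade to FASTA + GFF3 files
#'
#' @param clade output of [simulate_clade()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a data.frame of written paths.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(clade$genomes, function(g) {
    fa <- file.path(dir, paste0(g$genome_id, ".fna"))
    gff <- file.path(dir, paste0(g$genome_id, ".gff3"))
    write_fasta(g$contigs, fa)
    write_gff3(g$features, gff)
    data.frame(genome_id = g$genome_id, fasta = fa, gff3 = gff,
               stringsAsFactors = FALSE)
  })
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(clade$truth, truth_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, rows))
}
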