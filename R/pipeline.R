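# Orchestration of the conservation analysis: ortholog families and their
# conservation statistics for annotated genes and embedded antisense ORFs,
# sense/antisense neutral trajectories from the clade's own codon usage, the
# lower-quartile threshold, and the exceedance summary. Plain TSV/JSON
# outputs; figures are deliberately left to plotting consumers.

#' Single-copy families by shared feature id
#'
#' Annotated families on clades whose genomes share feature ids (e.g.
#' simulated clades): one family per feature id that is unique within, and
#' present in, every genome.
#'
#' @param genomes list of [asorf_genome()] objects.
#' @param table genetic code.
#' @return List of [ortholog_family()] objects.
#' @export
families_from_feature_ids <- function(genomes, table = codon_table()) {
  prots <- lapply(genomes, genome_proteins, table = table)
  names(prots) <- vapply(genomes, function(g) g$genome_id, "")
  common <- Reduce(intersect, lapply(prots, names))
  common <- common[vapply(common, function(id)
    all(vapply(prots, function(p) sum(names(p) == id) == 1L, TRUE)), TRUE)]
  lapply(common, function(id) {
    ortholog_family(id, vapply(prots, `[[`, "", id), kind = "annotated_gene")
  })
}

#' Single-copy antisense ORF families by stop-codon anchor
#'
#' Runs [find_embedded_antisense_orfs()] on every genome and groups ORFs by
#' the genomic position of their stop codon (strand-aware): in-frame start
#' codons can appear or vanish under mutation, but homologous embedded ORFs
#' keep their stop anchor when coordinates are comparable across genomes
#' (substitution-only evolution). Families present exactly once per genome in
#' at least `n_genomes_required` genomes are returned.
#'
#' @param genomes list of [asorf_genome()] objects with comparable
#'   coordinates.
#' @param table genetic code.
#' @param min_codons,start_codons ORF scan parameters.
#' @param n_genomes_required genomes a family must cover (default: all).
#' @return List of [ortholog_family()] objects (kind `"antisense_orf"`).
#' @export
orf_families_by_anchor <- function(genomes, table = codon_table(),
                                   min_codons = 20L,
                                   start_codons = table$start_codons,
                                   n_genomes_required = length(genomes)) {
  per_genome <- lapply(genomes, function(g) {
    orfs <- find_embedded_antisense_orfs(g, table, min_codons, start_codons)
    orfs$anchor <- paste(orfs$contig_id, orfs$strand,
                         ifelse(orfs$strand == "+", orfs$end, orfs$start))
    orfs
  })
  gids <- vapply(genomes, function(g) g$genome_id, "")
  names(per_genome) <- gids
  anchors <- table(unlist(lapply(per_genome, function(o) unique(o$anchor))))
  anchors <- names(anchors)[anchors >= n_genomes_required]
  fams <- list()
  for (a in anchors) {
    members <- character(0)
    ok <- TRUE
    for (g in gids) {
      hit <- which(per_genome[[g]]$anchor == a)
      if (length(hit) > 1L) { ok <- FALSE; break }  # not single-copy
      if (length(hit) == 1L) members[g] <- per_genome[[g]]$protein[hit]
    }
    if (ok && length(members) >= n_genomes_required) {
      fams[[length(fams) + 1L]] <- ortholog_family(
        paste0("orf:", gsub(" ", ":", a)), members, kind = "antisense_orf")
    }
  }
  fams
}

#' Run the clade conservation analysis
#'
#' Executes the full analysis behind the conservation figures: annotated
#' single-copy families and their conservation table; embedded antisense ORF
#' discovery, families, and conservation table; sense and antisense neutral
#' mutation trajectories from the codon usage of one genome; the
#' lower-quartile threshold from the annotated families; and the fraction of
#' ORF families exceeding it, plus per-family similarity excess over the
#' antisense null curve.
#'
#' @param genomes list of [asorf_genome()] objects (>= 2), or `NULL` to
#'   simulate a clade from `clade_cfg`.
#' @param clade_cfg a [clade_config()], used when `genomes` is `NULL`.
#' @param align_cfg an [align_config()].
#' @param cons_cfg a [conservation_config()]; `n_genomes_required` defaults to
#'   the genome count.
#' @param sim_cfg a [simulation_config()] for the null trajectories (frame is
#'   overridden internally; both frames are computed).
#' @param min_codons minimum ORF length in codons.
#' @param family_method `"feature_id"` (shared ids, e.g. simulated clades),
#'   `"rbh"` (reciprocal best hit) or `"orthogroups"` (import TSV from an
#'   external clustering tool via `orthogroups_path`).
#' @param orthogroups_path orthogroups TSV for `family_method="orthogroups"`.
#' @param usage codon usage for the null model; default: derived from the
#'   CDS of `genomes[[usage_genome]]`.
#' @param usage_genome index of the genome supplying codon usage.
#' @param out_dir if non-`NULL`, TSV/JSON outputs are written there.
#' @return A list of class `asorf_analysis`: `annotated_table`, `orf_table`,
#'   `null_sense`, `null_antisense`, `threshold`, `summary`, `manifest`.
#' @export
run_conservation_analysis <- function(genomes = NULL, clade_cfg = NULL,
                     align_cfg = align_config(),
                     cons_cfg = NULL,
                     sim_cfg = simulation_config(),
                     min_codons = 20L,
                     family_method = c("feature_id", "rbh", "orthogroups"),
                     orthogroups_path = NULL,
                     usage = NULL, usage_genome = 1L, out_dir = NULL) {
  family_method <- match.arg(family_method)
  manifest <- list(run_id = sprintf("asorf-run-%d", sim_cfg$seed),
                   package_version = as.character(packageVersion("asorf")),
                   r_version = R.version.string,
                   family_method = family_method,
                   min_codons = min_codons,
                   align = align_cfg[c("gap_open", "gap_extend",
                                       "free_end_gaps")],
                   sim = unclass(sim_cfg), stage = "init")
  stage <- function(name, expr) {
    manifest$stage <<- name
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) .write_manifest(manifest, out_dir)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(genomes)) {
    if (is.null(clade_cfg)) stop("supply genomes or a clade_config")
    clade <- stage("simulate_clade", simulate_clade(clade_cfg))
    genomes <- clade$genomes
    manifest$clade <- unclass(clade_cfg)[setdiff(names(unclass(clade_cfg)),
                                                 "tree")]
  }
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  gids <- vapply(genomes, function(g) g$genome_id, "")
  manifest$genomes <- gids
  stage("check_annotations", for (g in genomes) {
    if (!any(g$features$kind == "CDS")) {
      stop("genome '", g$genome_id, "' has no CDS annotations")
    }
  })
  if (is.null(cons_cfg)) {
    cons_cfg <- conservation_config(n_genomes_required = length(genomes))
  }
  manifest$conservation <- unclass(cons_cfg)

  ann_fams <- stage("annotated_families", switch(
    family_method,
    feature_id = families_from_feature_ids(genomes),
    rbh = {
      prots <- lapply(genomes, genome_proteins)
      names(prots) <- gids
      rbh_single_copy_families(prots, align_cfg)
    },
    orthogroups = {
      if (is.null(orthogroups_path)) stop("orthogroups_path is required")
      prots <- lapply(genomes, genome_proteins)
      names(prots) <- gids
      read_orthogroups(orthogroups_path, prots,
                       cons_cfg$n_genomes_required)
    }))
  if (!length(ann_fams)) stop("no single-copy annotated families found")
  manifest$n_annotated_families_total <- length(ann_fams)
  # threshold sample drawn before alignment to bound compute at full scale
  if (length(ann_fams) > cons_cfg$annotated_sample_size) {
    set.seed(cons_cfg$seed)
    ann_fams <- ann_fams[sort(sample.int(length(ann_fams),
                                         cons_cfg$annotated_sample_size))]
  }
  ann_tab <- stage("annotated_conservation", conservation_table(ann_fams,
                                                                align_cfg))

  orf_fams <- stage("orf_families", orf_families_by_anchor(
    genomes, min_codons = min_codons,
    n_genomes_required = cons_cfg$n_genomes_required))
  orf_tab <- stage("orf_conservation", conservation_table(orf_fams,
                                                          align_cfg))

  if (is.null(usage)) {
    usage <- stage("codon_usage",
                   codon_usage_from_cds(genome_cds_seqs(genomes[[usage_genome]])))
    manifest$usage_genome <- gids[usage_genome]
  }
  null_sense <- stage("null_sense", {
    cfg <- sim_cfg; cfg$frame <- "sense"
    trajectory(generate_sequences(usage, cfg), cfg, align_cfg)
  })
  null_antisense <- stage("null_antisense", {
    cfg <- sim_cfg; cfg$frame <- "antisense"
    trajectory(generate_sequences(usage, cfg), cfg, align_cfg)
  })

  threshold <- stage("threshold", quartile_threshold(ann_tab, cons_cfg))
  frac <- if (nrow(orf_tab)) {
    fraction_exceeding(orf_tab, threshold, cons_cfg$strict_exceed)
  } else NA_real_
  if (nrow(orf_tab)) {
    orf_tab$exceeds_threshold <- if (cons_cfg$strict_exceed)
      orf_tab$median_similarity_pct > threshold else
        orf_tab$median_similarity_pct >= threshold
    orf_tab$similarity_excess <- similarity_excess(orf_tab, null_antisense)
  }
  ann_tab$similarity_excess <- similarity_excess(ann_tab, null_sense)

  summary <- list(
    n_genomes = length(genomes),
    n_annotated_families_total = manifest$n_annotated_families_total,
    n_annotated_families_scored = nrow(ann_tab),
    n_orf_families = nrow(orf_tab),
    threshold_similarity_pct = threshold,
    quantile = cons_cfg$quantile,
    fraction_exceeding = frac,
    median_annotated_similarity_pct = median(ann_tab$median_similarity_pct),
    median_orf_similarity_pct = if (nrow(orf_tab))
      median(orf_tab$median_similarity_pct) else NA_real_,
    family_method = family_method)
  manifest$stage <- "done"

  res <- structure(list(annotated_table = ann_tab, orf_table = orf_tab,
                        null_sense = null_sense,
                        null_antisense = null_antisense,
                        threshold = threshold, summary = summary,
                        manifest = manifest),
                   class = "asorf_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

.write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write the analysis outputs of [run_conservation_analysis()] as TSV/JSON
#'
#' @param res an `asorf_analysis` result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotated = file.path(dir, "annotated_conservation.tsv"),
    orf = file.path(dir, "orf_conservation.tsv"),
    sense = file.path(dir, "null_curve_sense.tsv"),
    antisense = file.path(dir, "null_curve_antisense.tsv"),
    summary = file.path(dir, "summary.json"),
    manifest = file.path(dir, "manifest.json"))
  write_conservation_tsv(res$annotated_table, paths["annotated"])
  write_conservation_tsv(res$orf_table, paths["orf"])
  write_trajectory_tsv(res$null_sense, curve_path = paths["sense"])
  write_trajectory_tsv(res$null_antisense, curve_path = paths["antisense"])
  jsonlite::write_json(res$summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_manifest(res$manifest, dir)
  invisible(paths)
}

#' @export
print.asorf_analysis <- function(x, ...) {
  s <- x$summary
  cat("asorf conservation analysis:\n",
      "  genomes: ", s$n_genomes, "\n",
      "  annotated families scored: ", s$n_annotated_families_scored,
      " (of ", s$n_annotated_families_total, ")\n",
      "  antisense ORF families: ", s$n_orf_families, "\n",
      "  lower-quartile similarity threshold: ",
      sprintf("%.1f%%", s$threshold_similarity_pct), "\n",
      "  ORF families exceeding threshold: ",
      sprintf("%.1f%%", 100 * s$fraction_exceeding), "\n", sep = "")
  invisible(x)
}
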