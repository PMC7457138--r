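# Mutation-accumulation null model: random coding sequences drawn from a
# codon-usage table accumulate rounds of point substitutions; originals and
# mutants are translated (sense frame, or frame 0 of the reverse complement
# for the antisense control) and aligned, giving the neutral identity ->
# similarity trajectory against which observed conservation is compared.

#' Codon usage from coding sequences
#'
#' Pools codon counts over all CDS, removes stop codons (the sampling
#' distribution must not truncate simulated proteins) and renormalizes.
#'
#' @param cds_list character vector of CDS nucleotide sequences, each with
#'   length divisible by 3.
#' @param table genetic code from [codon_table()].
#' @return Named numeric vector of relative codon frequencies summing to 1,
#'   with a `"source"` attribute.
#' @export
codon_usage_from_cds <- function(cds_list, table = codon_table()) {
  if (!length(cds_list)) stop("no coding sequences supplied")
  bad <- nchar(cds_list) %% 3L != 0L
  if (any(bad)) stop("CDS length not divisible by 3 at index ", which(bad)[1])
  codons <- unlist(lapply(cds_list, function(s) {
    st <- seq(1L, nchar(s), by = 3L)
    substring(s, st, st + 2L)
  }))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  stops <- names(table$codons)[table$codons == "*"]
  codons <- codons[!codons %in% stops]
  if (!length(codons)) stop("no non-stop codons in input")
  tab <- table(factor(codons, levels = sort(names(table$codons))))
  tab <- tab[tab > 0]
  usage <- as.numeric(tab) / sum(tab)
  names(usage) <- names(tab)
  attr(usage, "source") <- sprintf("pooled from %d CDS", length(cds_list))
  usage
}

#' Simulation configuration for the null model
#'
#' Defaults follow the published control: 50 sequences of 333 codons, mutated
#' through 70 rounds of 10 point substitutions each.
#'
#' @param n_sequences number of independent starting sequences.
#' @param n_codons sequence length in codons.
#' @param n_rounds mutation rounds.
#' @param mutations_per_round substitutions applied per round.
#' @param frame `"sense"` or `"antisense"` (frame 0 of the reverse
#'   complement, no further frame shift).
#' @param seed master seed; per-sequence streams use `seed + sequence index`.
#' @param distinct_positions if `TRUE`, the positions hit within one round are
#'   distinct; default `FALSE` (independent draws may collide).
#' @param allow_same_base if `TRUE` a substitution may redraw the original
#'   base; default `FALSE` (the base always changes).
#' @return A list of class `asorf_sim_config`.
#' @export
simulation_config <- function(n_sequences = 50L, n_codons = 333L,
                              n_rounds = 70L, mutations_per_round = 10L,
                              frame = c("sense", "antisense"), seed = 1L,
                              distinct_positions = FALSE,
                              allow_same_base = FALSE) {
  frame <- match.arg(frame)
  stopifnot(n_sequences >= 1L, n_codons >= 1L, n_rounds >= 0L,
            mutations_per_round >= 0L)
  structure(list(n_sequences = as.integer(n_sequences),
                 n_codons = as.integer(n_codons),
                 n_rounds = as.integer(n_rounds),
                 mutations_per_round = as.integer(mutations_per_round),
                 frame = frame, seed = as.integer(seed),
                 distinct_positions = distinct_positions,
                 allow_same_base = allow_same_base),
            class = "asorf_sim_config")
}

#' Generate random coding sequences from a codon-usage table
#'
#' Codons are drawn i.i.d. from `usage`; since stop codons are excluded from
#' the usage table, sequences carry no in-frame sense stops.
#'
#' @param usage codon usage from [codon_usage_from_cds()].
#' @param cfg a [simulation_config()].
#' @return Character vector of `cfg$n_sequences` sequences, each
#'   `3 * cfg$n_codons` nt.
#' @export
generate_sequences <- function(usage, cfg = simulation_config()) {
  stopifnot(abs(sum(usage) - 1) < 1e-9, all(usage >= 0))
  set.seed(cfg$seed)
  vapply(seq_len(cfg$n_sequences), function(i) {
    paste(sample(names(usage), cfg$n_codons, replace = TRUE, prob = usage),
          collapse = "")
  }, character(1))
}

#' Apply rounds of random point substitutions
#'
#' Each round draws `mutations_per_round` positions uniformly at random and
#' replaces the base at each with a uniformly chosen different base (see
#' [simulation_config()] for the two sampling variants). Positions may recur
#' across rounds; sequence length is preserved (substitutions only, no
#' indels, so reading frames stay intact).
#'
#' @param seq nucleotide string.
#' @param cfg a [simulation_config()].
#' @param seed seed for this sequence's mutation stream (default
#'   `cfg$seed`).
#' @return Character vector of `cfg$n_rounds` sequences, element r being the
#'   sequence after r rounds.
#' @export
mutate_rounds <- function(seq, cfg = simulation_config(), seed = cfg$seed) {
  if (!nzchar(seq)) stop("cannot mutate an empty sequence")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  out <- character(cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    if (cfg$mutations_per_round > 0L) {
      pos <- sample.int(n, cfg$mutations_per_round,
                        replace = !cfg$distinct_positions)
      for (p in pos) {
        s[p] <- if (cfg$allow_same_base) sample(bases, 1L)
                else sample(setdiff(bases, s[p]), 1L)
      }
    }
    out[r] <- paste(s, collapse = "")
  }
  out
}

#' Identity-similarity trajectory of the null model
#'
#' For every starting sequence and every mutation round, the original and the
#' mutant are translated -- in the sense frame, or as frame 0 of their reverse
#' complements when `cfg$frame == "antisense"` -- and globally aligned.
#' Observations are binned by integer percent decrease in identity
#' (`round(100 - identity_pct)`) and per-bin medians reported. Internal stop
#' codons arising from mutation are translated as `*` and scored through the
#' matrix's `*` entries, keeping alignment lengths comparable. Round 0
#' (original vs itself) is included, so bin 0 is always populated.
#'
#' @param originals sequences from [generate_sequences()].
#' @param cfg a [simulation_config()]; per-sequence mutation streams are
#'   seeded `cfg$seed + i` for sequence i.
#' @param config an [align_config()].
#' @param table genetic code.
#' @return A list of class `asorf_trajectory`: `curve` (data.frame `bin`,
#'   `median_identity_pct`, `median_similarity_pct`, `n`), `observations`
#'   (data.frame `frame`, `seq_index`, `round`, `identity_pct`,
#'   `similarity_pct`) and `frame`.
#' @export
trajectory <- function(originals, cfg = simulation_config(),
                       config = align_config(), table = codon_table()) {
  stopifnot(length(originals) >= 1L)
  prot <- function(s) {
    if (cfg$frame == "antisense") s <- reverse_complement(s)
    translate(s, table, strip_terminal_stop = FALSE)
  }
  obs <- vector("list", length(originals))
  for (i in seq_along(originals)) {
    ref <- prot(originals[i])
    muts <- mutate_rounds(originals[i], cfg, seed = cfg$seed + i)
    idp <- numeric(cfg$n_rounds + 1L)
    simp <- numeric(cfg$n_rounds + 1L)
    idp[1L] <- 100; simp[1L] <- 100  # round 0: original vs itself
    for (r in seq_len(cfg$n_rounds)) {
      v <- identity_similarity(ref, prot(muts[r]), config)
      idp[r + 1L] <- v[["identity_pct"]]
      simp[r + 1L] <- v[["similarity_pct"]]
    }
    obs[[i]] <- data.frame(frame = cfg$frame, seq_index = i,
                           round = 0:cfg$n_rounds, identity_pct = idp,
                           similarity_pct = simp, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)
  structure(list(curve = .bin_trajectory(obs), observations = obs,
                 frame = cfg$frame),
            class = "asorf_trajectory")
}

.bin_trajectory <- function(obs) {
  bin <- as.integer(round(100 - obs$identity_pct))
  agg_id <- tapply(obs$identity_pct, bin, median)
  agg_sim <- tapply(obs$similarity_pct, bin, median)
  agg_n <- tapply(obs$identity_pct, bin, length)
  data.frame(bin = as.integer(names(agg_id)),
             median_identity_pct = as.numeric(agg_id),
             median_similarity_pct = as.numeric(agg_sim),
             n = as.integer(agg_n), row.names = NULL)
}

#' @export
print.asorf_trajectory <- function(x, ...) {
  cat("asorf_trajectory (", x$frame, " frame): ", nrow(x$observations),
      " observations in ", nrow(x$curve), " identity-decrease bins\n",
      sep = "")
  invisible(x)
}

#' Write trajectory tables as TSV
#'
#' @param traj an `asorf_trajectory`.
#' @param curve_path,observations_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_trajectory_tsv <- function(traj, curve_path = NULL,
                                 observations_path = NULL) {
  if (!is.null(curve_path)) {
    write.table(traj$curve, curve_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(observations_path)) {
    write.table(traj$observations, observations_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(curve = curve_path, observations = observations_path))
}
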