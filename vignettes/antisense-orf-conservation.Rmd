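---
title: "Methods: conservation analysis of embedded antisense ORFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation analysis of embedded antisense ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `asorf`, the
assumptions behind them, the parameters that matter, and the choices made
where the design was genuinely open.

## The question

An ORF encoded antiparallel to — and fully inside — an annotated bacterial
gene is constrained twice over: most of its nucleotides also encode the host
("mother") gene's protein. If such an ORF is itself a functional gene, its
protein sequence should be conserved across related genomes *beyond* what is
explained by conservation of the host gene alone, and the substitutions that
do fix should be biased toward biochemically similar amino acids. The package
quantifies both signals:

1. the **conservation level** of an ORF family relative to annotated gene
   families (lower-quartile classification), and
2. the **similarity excess** of a family over a neutral
   mutation-accumulation trajectory in the matching reading frame.

## ORF discovery

For every annotated CDS, the reverse complement of the host span is scanned in
all three frames. An ORF runs from an initiator codon to the first in-frame
stop; the stop codon is part of the reported genomic span. Conventions:

* **Genetic code**: NCBI translation table 11. Initiator set defaults to
  ATG/GTG/TTG — the common bacterial initiators; the rarer ones (ATT, ATC,
  ATA, CTG) are excluded by default because they would inflate the candidate
  set with weak starts. Configurable via `start_codons`.
* **Minimum length** (`min_codons`): 20 codons counting the initiator and not
  the stop, the conventional floor for small-protein candidates. The value is
  an explicit knob, recorded in output headers, because candidate counts are
  extremely sensitive to it.
* **Longest-per-stop**: when several in-frame initiators share one stop, only
  the 5'-most (longest) ORF is reported by default, so nested sub-ORFs are not
  counted as separate candidates (`longest_only = FALSE` reports all).
* **Full embedding is strict**: an ORF must lie inside the host span including
  its stop codon; ORFs crossing the host boundary are discarded, not
  truncated. ORFs contained in several overlapping hosts are reported once per
  distinct genomic span with all hosts listed.
* **Initiator translation**: ORF and CDS proteins render a leading initiator
  codon as M (the annotation convention); `translate()` itself is literal
  unless asked otherwise. This matters when comparing GTG/TTG-initiated
  homologs.
* Host CDS spans not divisible by 3 are flagged (`frame_ok = FALSE`) rather
  than fatal: the antisense scan works on raw nucleotides, and one malformed
  annotation should not abort a genome-wide run. Only `N` is tolerated among
  ambiguity codes (codons containing it translate to `X`); other IUPAC codes
  are rejected because the analysis needs unambiguous codons.
* Only features of kind `CDS` are treated as host genes; whether pseudogenes
  or other annotated features should host ORFs is annotation-dependent, and a
  caller can relabel kinds before the scan if needed.

## Pairwise alignment and conservation statistics

Protein pairs are aligned by global Needleman–Wunsch with affine gaps
(Gotoh's three-state recursion, implemented in C++). The cost conventions
replicate the widely used needle/needleall defaults:

* a gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$ with
  defaults $10$ and $0.5$ (a 1-residue gap costs 10.5);
* end gaps are free by default (`free_end_gaps = TRUE`), appropriate when
  comparing homologs whose annotated boundaries differ slightly; a flag turns
  end-gap penalties on;
* **percent identity** = identical residue columns / alignment length
  (gap columns count in the length);
* **percent similarity** = columns whose substitution-matrix score is
  strictly positive / alignment length. Identities with non-positive
  self-score (e.g. `X:X` = −1 under BLOSUM62) are identical but not similar.
* `*` (stop) is retained and scored through the matrix's `*` row, so ORF
  homologs that acquired an internal stop stay alignable at full length.

Traceback ties break in a fixed order (diagonal > up > left). Because
co-optimal alignments can differ in identity even at equal score, the
argument pair is ordered canonically before alignment, making score,
identity and similarity exactly symmetric in the inputs. On unrelated random
sequences different optimal-alignment implementations may still report
slightly different percentages; on homologous pairs the optimum is in
practice unique (the test suite checks both regimes against an independent
reference aligner and an exhaustive-enumeration oracle).

A family of $n$ single-copy orthologs is summarized by the **median** of the
$n(n-1)/2$ pairwise identities and similarities (even counts: mean of the
central two). Medians are robust to the occasional degenerate pair and make
family records comparable across family sizes.

### Ortholog families

Three routes produce single-copy families:

* `read_orthogroups()` imports the orthogroups TSV of an external clustering
  tool — the intended route for full-scale analyses of real genomes;
* `rbh_single_copy_families()` is a built-in reciprocal-best-hit fallback for
  desk-scale data: components of the RBH graph are kept only if they contain
  exactly one protein per genome *and* every genome pair in the component is
  mutually best — a deliberately conservative filter, since false merges bias
  conservation downward;
* on simulated clades, annotated families map by shared feature id and ORF
  families by the genomic position of their stop codon ("stop anchor"),
  which survives in-frame start-codon turnover; both are exact under
  substitution-only evolution. The route used is recorded in the run
  metadata.

### Threshold and classification

The conservation threshold is the lower quartile (configurable `quantile`)
of median pairwise similarity over annotated single-copy families, computed
by linear interpolation between order statistics (R quantile type 7, the
default of mainstream numerical stacks; the method is recorded in the run
metadata). When more annotated families exist than `annotated_sample_size`
(default 1000), a seeded random sample is used — sampling noise moves the
threshold, so full-scale reproductions should consider using all families.
"Exceeds" is a strict inequality by default (`strict_exceed`).

## The neutral trajectory (null model)

The null model asks: as random point mutations accumulate in a coding
sequence, how does percent similarity fall as a function of percent identity?

* `generate_sequences()` draws codons i.i.d. from a codon-usage table
  (stops excluded, so the sense frame is stop-free); defaults are 50
  sequences of 333 codons.
* `mutate_rounds()` applies 70 rounds of 10 point substitutions: a uniformly
  random position is replaced by a uniformly chosen *different* base.
  Substitution-only is deliberate — indels would frameshift the fixed-frame
  translations and destroy the comparison; the smoothness of the resulting
  curves depends on frame preservation. Within a round, positions are drawn
  independently (collisions allowed); `distinct_positions` and
  `allow_same_base` expose the alternative conventions.
* Original and mutant are translated in the **sense** frame, or — for the
  antisense control — as **frame 0 of their reverse complements**, with no
  further frame shift: the antisense frame choice has little effect on the
  identity–similarity relation, so the direct reverse complement is used.
  Internal stops arising from mutation are translated as `*` and aligned
  (not truncated), keeping alignment lengths comparable.
* Observations are binned by `round(100 − identity_pct)` (integer percent
  decrease in identity); per-bin medians form the `TrajectoryCurve`. Round 0
  (original vs itself) is included, so bin 0 exists and equals (100, 100).
  Empty bins are omitted; `similarity_excess()` uses the nearest populated
  bin at the edges.
* **Seeding**: one master seed; the mutation stream of sequence $i$ is seeded
  `seed + i`, so runs are bitwise reproducible and per-sequence streams are
  independent of execution order.

A conservation record's similarity excess is its median similarity minus the
null-curve similarity at its identity bin; positive values indicate a bias
toward fixing similar replacements relative to neutral expectation. Annotated
families are compared against the sense curve, antisense ORF families against
the antisense curve.

## Ribosome-profiling coverage

`compute_rpm()` computes strand-specific per-site coverage in reads per
million from aligned reads (SAM/BAM; primary alignments only). Reads
overlapping any rRNA/tRNA feature by at least one nucleotide — on either
strand — are removed first, because rRNA/tRNA fragments dominate
ribosome-profiling libraries and would otherwise set the scale. Each retained
read increments depth at every reference position of its aligned blocks on
the strand it mapped to ("full-read" coverage, not 5′-end or P-site
assignment). The denominator is the count of retained mapped reads
(`post_exclusion`, default) or of all mapped reads (`pre_exclusion`); the
choice is exposed because "total mapped reads" is ambiguous in common usage,
and post-exclusion is the variant under which tracks from libraries with
different rRNA contamination are comparable. A zero denominator yields
all-zero tracks with a warning. No MAPQ filter is applied by default. Tracks
are raw RPM; any display smoothing is left to plotting consumers.

## The synthetic clade generator

The generator provides ground truth for end-to-end tests and parameter
recovery. It emulates:

* a clade of `n_genomes` (default 13) genomes descending from one ancestor by
  independent branches (star topology by default; any topology given as a
  `phylo`-style edge list with per-branch substitution counts is honored);
* `n_genes` (default 200) annotated genes of `gene_length_codons` (default
  333, matching the null model) sampled from a codon-usage table, on random
  strands, separated by short random spacers on one contig;
* an `orf_fraction` (default 0.3) of genes carrying one implanted, fully
  embedded antisense ORF of 20–50 codons, constructed directly
  (initiator + non-stop codons + stop, reverse-complemented into a
  codon-aligned interior window) and rejection-sampled until the host's sense
  frame stays stop-free — so every truth ORF is intact in the ancestor by
  construction;
* per-branch evolution by `substitutions_per_gene_per_branch` accepted
  substitutions per gene (default 25): a proposal whose **sense** amino-acid
  replacement scores ≤ 0 is rejected with probability `rejection_prob`
  (default 0.9) — purifying selection on every host gene; inside the spans of
  a `selected_fraction` of ORFs, proposals whose **antisense** replacement
  scores ≤ 0 are additionally rejected with the same probability. Rejected
  proposals are redrawn, so branch lengths are met exactly;
  `rejection_prob = 0` gives strictly neutral evolution.

Selection as rejection of dissimilar replacements is the simplest mechanism
that produces a similarity bias of the kind the analysis is designed to
detect; it is not a full codon model (no transition/transversion bias, no
rate heterogeneity, no indels, no gene gain/loss or recombination). The
default branch length was chosen so that a star clade's pairwise divergence
(two branches, ≈5% nucleotide) yields annotated-family amino-acid identities
in the high 80s–90s, the range typical of an enterobacterial clade; the
default codon usage is a synthetic representative enterobacterial profile
(documented as synthetic — derive usage from a real genome with
`codon_usage_from_cds()` for real analyses).

What passing tests on synthetic clades do **not** show about real data:
real ortholog families vary in length and divergence, annotations contain
errors, orthology calls are noisy, genomes differ in codon usage, and real
embedded ORFs are not implanted at codon-aligned interior windows. The
synthetic results validate the machinery and the direction of the signals,
not the magnitude of any real-genome quantity.

### A note on chance ORFs

At these gene lengths and codon usages, antisense ORFs of ≥ 20 codons arise
by chance in large numbers, and many of their stop anchors are conserved
across the whole simulated clade — as passengers of host-gene conservation.
In parameter-recovery analyses these non-implanted families are treated as
neutral ground truth, which they are: only implanted, flagged ORFs evolve
under antisense selection. Their abundance mirrors the situation in real
genomes, where candidate sets are dominated by ORFs whose conservation merely
reflects the mother gene.

## Problem sizes used by the test suite

Unit tests run on deliberately small instances (genes of 80–150 codons,
clades of 2–5 genomes, trajectories of 4–20 sequences). The study-scale
checks run the null model at its full default size (50 × 333 codons, 70 × 10
substitutions, both frames, bitwise-reproducibility included) and parameter
recovery on 13-genome, 200-gene clades across selected fractions
{0, 0.3, 0.6, 1}; these sizes keep the complete suite within a coffee break
on one CPU while exercising the defaults end to end. `scripts/acceptance.R`
re-runs both at the same scale.

## Known limitations

* The RBH fallback is quadratic in proteome size; it is meant for desk-scale
  clades, not full proteomes — import orthogroups from a dedicated tool at
  scale.
* ORF families on real (non-simulated) genomes cannot use stop anchors
  (coordinates are not comparable across assemblies); cluster ORF proteins
  with the external tool and import, as for annotated genes.
* The null model fixes sequence length at 333 codons; very short ORF families
  have noisier identity/similarity estimates than the curve they are compared
  to, an effect the similarity-excess statistic does not correct for.
* `find_orfs` reports ORFs relative to the supplied initiator set; organisms
  using rare initiators need `start_codons` adjusted.
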