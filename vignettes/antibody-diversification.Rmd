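---
title: "Quantifying antibody diversification: clonal-resampling SHM spectra and switch-junction scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Germinal-center B cells diversify antibodies through two mutagenic DNA
repair programmes. Somatic hypermutation (SHM) introduces point mutations
into the rearranged heavy-chain variable region: AID deaminates cytosines
preferentially in WRC motifs (and, read on the other strand, GYW), and
error-prone mismatch repair recruits polymerase eta, which mutates A:T
pairs preferentially at WA/TW motifs. Class-switch recombination (CSR)
joins double-strand breaks between switch regions; how the two ends are
joined — bluntly, through short microhomologies, or with untemplated
insertions — reports on the end-resection machinery available to the cell.

`shmspectra` implements the computations needed to read both signals out
of amplicon sequencing data: UMI-collapsed repertoire reconstruction,
hotspot-aware mutation-spectrum estimation with clonal resampling, and
exact junction decomposition with the accompanying statistics. A
synthetic-data generator with recorded ground truth stands in for the
sequencing data, so every stage is testable end to end.

## The spectrum statistic

A naive mutation frequency over all sequenced molecules is biased in two
ways. First, clonally related B cells inherit mutations from their common
ancestor, so one mutational event can be counted dozens of times; clones
are recognisable by their shared CDR3 sequence. Second, raw per-subtype
counts confound mutability with target availability: a sequence with few
WA/TW sites cannot show many polymerase-eta mutations no matter how active
the pathway is.

The package addresses both with a resampling statistic. For iteration
$t = 1, \dots, T$ (default $T = 1000$) one sequence is drawn uniformly
from every CDR3 clone. For subtype $s$ (one of `GC_AID_HOT`, `GC_OTHER`,
`AT_POL_HOT`, `AT_OTHER`) with $S_s$ eligible germline sites and $N_s^{(t)}$
mutations observed in the $n$ sampled sequences, the normalised frequency
is

$$ f_s^{(t)} = \frac{N_s^{(t)}}{S_s \, n}. $$

The denominator is the potential maximum number of subtype-$s$ mutations
in the sampled set — each sequence can mutate each site at most once under
the substitution-only model — so $f_s \in [0,1]$ and subtypes of different
abundance become comparable. Iterations are aggregated as the arithmetic
mean with an SD and a 2.5–97.5 percentile interval that exposes the
resampling spread. A positional profile accumulates per-position incidence
over iterations and rescales within each subtype to a maximum of 1.

Sampling one sequence per clone is the sole de-duplication step: two
independent clones hitting the same hotspot are legitimately counted
twice, so no cross-clone collapsing of identical events is performed. When
every clone has size one the procedure degenerates to the plain normalised
frequency with zero resampling variance, which is what makes parameter
recovery against the simulator exact to binomial error.

Genotype contrasts build, per subtype, a 2x2 table of rounded mean mutated
site-opportunities against remaining opportunities and apply Pearson's
chi-square with Yates' continuity correction. The construction of the
table from the resampled means is a documented package choice: it is
explicit, reproducible, and reduces to the observed counts when clone
sizes are one. Whether subtypes should be tested separately or pooled is
exposed as an option (`pooled = TRUE`); separate tests are the default.

## Site classification

`classify_sites()` assigns every germline position exactly one subtype
from the germline context (IUPAC: W = A/T, R = A/G, Y = C/T):

* C in `WRC` or G in `GYW` → `GC_AID_HOT`;
* other G/C → `GC_OTHER`;
* A preceded by W (`WA`) or T followed by W (`TW`) → `AT_POL_HOT`;
* other A/T → `AT_OTHER`.

Context positions outside the sequence never match, so terminal bases can
only be `_OTHER`. Because WRC/GYW and WA/TW are mutual reverse
complements, the total hotspot counts of a sequence and its reverse
complement agree — a property the tests exercise. Subtypes are always
assigned from the *germline* mask, not the mutated sequence: hotspots are
a property of the target site, not of the product.

## Junction scoring

`score_junction()` decomposes a junction against the donor and acceptor
references by exact matching: the longest junction prefix occurring
contiguously in the donor and the longest suffix occurring in the
acceptor. With prefix length $p$, suffix length $q$ and junction length
$L$, the signed score is $p + q - L$: positive values are microhomologies
(shared bases written once), zero is a blunt joint, negative values are
untemplated insertions. Both anchors being maximal encodes the tie-break
rule — prefer the longest microhomology, then the shortest insertion —
which is the conservative convention for microhomology-biased repair
calls; junctions that genuinely contain both a microhomology and an
adjacent insertion therefore resolve to the maximal-overlap reading.
Junctions whose anchors fall below `anchor_min` (default 10 bases) are
reported unresolved and excluded from distributions rather than guessed.

Exact matching replaces pairwise alignment deliberately: it is
deterministic, verifiable against brute-force enumeration of every
decomposition (the test suite does exactly that), and equivalent on
junctions without sequencing error. A mismatch-tolerant mode is out of
scope.

Cohort distributions of signed scores are compared with the
Kruskal-Wallis test (tie-corrected) followed by Dunn's pairwise
post-tests; the Dunn statistic is implemented in the package since no
installed library provides it. Pairwise p-values are unadjusted by
default, with `p.adjust` methods available by argument. For very small
cohorts `exact = TRUE` replaces the chi-square approximation with full
enumeration over group assignments. Insertion frequencies (junctions with
negative scores over all resolved junctions) are compared with two-sided
Fisher exact tests; a zero margin yields p = 1 by convention.

## What the simulator emulates

The generator produces every input the pipeline consumes, with recorded
truth:

* **Germline.** A random 294-base V reference (the span of the murine VH
  readout locus commonly used for SHM analysis) with FR/CDR annotations
  and the per-site subtype mask. The terminal 15-base window labelled
  `CDR3` is the clone-tag interval.
* **Repertoire.** Clones receive a distinct random CDR3 tag — exact
  clonal truth without modelling V(D)J junction biology — and a founder
  mutation set drawn at the profile rates scaled by `inherited_fraction`
  (default 0.2), shared by all members; members add private mutations at
  the full rates at sites not already mutated. No site mutates twice in a
  molecule (no back-mutation), matching the normalisation bound.
  Substitutions favour transitions 2:1 over each transversion by default.
  Clone sizes default to 1 + geometric(0.5), i.e. mean two members.
* **Genotype profiles.** `WT-like` uses per-site rates
  (`mu_gc_hot` 0.020, `mu_gc_other` 0.005, `mu_at_hot` 0.015,
  `mu_at_other` 0.003); `DA-like` halves A:T mutagenesis to an
  intermediate level and raises G:C; `KO-like` nearly abolishes A:T and
  concentrates G:C further. These reproduce the qualitative phenotype
  contrast between repair-proficient and nuclease-compromised B cells;
  the WT values double as recovery targets for validation.
* **Reads.** Each molecule gets a distinct UMI (length 8) prepended to
  read 1; mates overlap in the middle; substitution errors are i.i.d. at
  the configured rate in molecule-derived bases, with UMIs error-free to
  match the exact-UMI collapse. Depth defaults to 3 reads per molecule.
  Depth and UMI length are package choices; typical amplicon protocols
  vary widely, and both are configurable.
* **Junctions.** Outcomes are drawn from a blunt/microhomology/insertion
  mixture. Microhomologies are engineered by copying the donor k-mer at a
  fixed per-length breakpoint into a dedicated acceptor slot, with flank
  bases set to stop extension; insertions draw bases that match neither
  reference continuation. Every emitted junction is verified by direct
  substring checks to have an unambiguous breakpoint context, so truth
  recovery by the scorer is exact. Microhomology junctions consequently
  cluster at one donor breakpoint per length — a simplification
  reminiscent of, but cruder than, real switch-region break clustering.
* **CSR.** Per-animal switched fractions are Binomial(`n_cells`,
  `p_switch`)/`n_cells`; relative efficiencies rescale to the reference
  (WT) mean defined as 100%.

What the simulator does *not* model, and what passing tests therefore do
not certify on real data: indels, quality-dependent or context-dependent
sequencing error, PCR duplicates and chimeras, UMI collisions or UMI
sequencing errors, biological V(D)J recombination and selection, and
junction-scoring under sequencing noise. The consensus stage also assumes
equal-length inserts per UMI family (unequal lengths reject the family),
which holds by construction here but not necessarily for real libraries.

## Numerical and design choices

* **Coordinates** are 1-based and inclusive everywhere, in code and in
  reports.
* **Pair merging** scans all overlaps of at least `min_overlap` (default
  20) bases, keeps the mismatch-count argmin (ties to the longer
  overlap), rejects pairs above `max_mismatch_frac` (default 0.1), and
  resolves disagreements by base quality with read 1 winning ties. The
  original study's assembler parameters are unpublished; these are
  package decisions, not reconstructions.
* **Consensus ties** become `N`, and `N` positions are skipped by the
  mutation caller — a tie is never turned into a mutation. UMI collapse
  is exact-match only (no within-edit-distance merging), with
  `min_family_size` defaulting to 1.
* **Clonality** is exact CDR3 nucleotide identity; clone ids are assigned
  in lexicographic CDR3 order so they are stable under input order. The
  IMGT clonotype and CDR3-anchor conventions are not reimplemented;
  on real data this may split or merge borderline clonotypes.
* **Rejections** always carry a reason code; stage reports satisfy
  passed + rejected = input.
* **Determinism.** Every stochastic function takes a seed; the pipeline
  derives per-stage, per-genotype seeds from one top-level seed, and two
  runs with the same configuration are byte-identical.
* **Chi-square degeneracy**: contrasts with a zero expected cell are
  reported as not computable rather than silently dropped or forced.
* **Undefined frequencies**: a subtype with zero eligible sites is
  reported as missing (`NA`), never as 0.

## Problem sizes used in the shipped analyses

The analysis scripts and validation suite run at desk scale, chosen so the
statistical assertions have power while the whole suite stays fast:
150 clones per genotype (about 300 molecules) for the worked pipeline,
1000 molecules for rate-recovery checks, 2000 molecules for exact
truth-recovery checks, 1000 resampling iterations (matching the analysis
convention), 40 junctions per cohort (the study's cohorts were of
comparable size, n > 22), and 400 replicates for type-I-error
calibration. Raw sequencing data of the original study are external to
the package; all quantitative claims shipped here are about the synthetic
generative model and the estimators themselves.

## Worked example

```{r, eval = FALSE}
library(shmspectra)

germline <- make_germline(length = 294, gc_fraction = 0.5, seed = 17)
profile <- default_profiles()[["WT-like"]]
sim <- simulate_repertoire(germline, profile, n_clones = 150, seed = 18)
reads <- simulate_reads(sim$sequences, reads_per_molecule = 3,
                        error_rate = 0.001, seed = 19)
col <- collapse_reads(reads$reads)
ann <- annotate_repertoire(col$consensus, germline)
grp <- group_clones(ann$sequences)
spec <- aggregate_spectrum(
  list(sequences = grp$sequences, mutations = ann$mutations),
  germline, spectrum_config(n_iterations = 1000, seed = 20))
spec$summary
```

The same flow, staged and with all outputs on disk, is available as
`run_pipeline()` or as the numbered scripts under `analysis/`.

## Known limitations

Substitution-only calling means any indel-bearing molecule is rejected
whole. The junction scorer requires exact anchors and will return
unresolved on noisy junctions rather than align around errors. The
contingency construction from resampled means is one defensible choice
among several; with very few clones the rounding step can matter. The
exact Kruskal-Wallis option enumerates all group assignments and is only
feasible for tiny cohorts.
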