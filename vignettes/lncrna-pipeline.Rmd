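---
title: "Identifying and characterizing lncRNAs with lncfeather"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing lncRNAs with lncfeather}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfeather)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts of at least 200 nt with no
protein-coding capacity. Identifying them from a strand-specific RNA-seq
assembly is a filtering problem: the assembler emits tens of thousands of
transcript fragments ("isotigs"), most of which are fragments of annotated
genes, assembly noise, or weakly expressed artifacts. `lncfeather`
implements the complete cascade from raw isotigs to a characterized,
classified lncRNA catalog, modeled on the embryonic skin study design it
emulates: six libraries covering two dorsal skin regions (anterior, AD;
posterior, PD) at three embryonic incubation days (E8, E9, E12).

The stages are:

1. **Discovery** — remove unstranded isotigs; remove isotigs with
   same-strand exonic overlap with annotated genes; single-linkage merge
   the remainder into raw transcripts; remove transcripts shorter than
   200 nt (mature length) or below 1 FPKM in every library; label
   known/novel against a non-coding catalog.
2. **Coding-potential consensus** — intersect three filters: a CPC-style
   score < −0.5, a PLEK-style score < −0.5, and the absence of a protein
   domain hit at E < 10⁻⁴.
3. **Positional classification** — lincRNA / intronic lncRNA / lncNAT,
   with precedence lncNAT > intronic > lincRNA.
4. **Characterization** — length, exon count, mean conservation,
   transposable-element (TE) overlap, expression summaries, Jensen-Shannon
   (JS) tissue specificity.
5. **Co-expression clustering** — WPGMA on z-scaled profiles, tree cut.
6. **Differential expression** — pooled AD-vs-PD and stage comparisons
   with an empirical noise-dominance probability, call at q > 0.7.
7. **Enrichment and candidate selection** — per-cluster Fisher/BH term
   enrichment, and the three-criterion candidate rule (selected cluster ∧
   regional DE ∧ cross-species same-chromosome similarity).

## Coordinate and boundary conventions

All internal coordinates are 0-based, half-open; GTF converts at the
boundary (1-based inclusive), BED/bedGraph pass through. A single internal
convention prevents off-by-one drift between stages. Strand `"."` is a
first-class unknown (`"*"`), never coerced to `"+"`, because the first
discovery filter is defined by it.

Threshold boundaries are fixed once and used everywhere:

| parameter | default | boundary rule |
|---|---|---|
| minimum mature length | 200 bp | remove iff length < 200 |
| expression floor | 1 FPKM | keep iff max over libraries ≥ 1 |
| CPC-style cutoff | −0.5 | noncoding iff score < −0.5 |
| PLEK-style cutoff | −0.5 | noncoding iff score < −0.5 |
| domain E-value | 10⁻⁴ | excluded iff E < 10⁻⁴ |
| expressed (clustering) | 1 FPKM | expressed iff > 1 in ≥ 1 library |
| tree cut | 0.69 | merge iff height ≤ 0.69 |
| DE call | 0.7 | called iff q > 0.7 |
| enrichment | 0.01 / 0.05 | significant iff p < 0.01 and FDR < 0.05 |

The exact-cutoff direction for a score of exactly −0.5 is not dictated by
the "less than" phrasing alone; it is fixed to the coding side here for
determinism. Mature length is the sum of exon lengths, not the genomic
span, because transcript lengths are compared against mRNA transcript
lengths.

## Why the annotation filter is strand-aware and exon-level

Antisense lncRNAs (lncNATs) overlap coding exons by definition, and
intronic lncRNAs sit inside gene spans. A strand-blind or gene-span-level
annotation filter would delete both classes before classification could
see them. The only reading of "overlaps annotated genes" consistent with a
downstream catalog that contains intronic and antisense classes is
same-strand, exon-level overlap (≥ 1 bp), and that is what
`partition_by_annotation()` implements.

`classify_positional()` accepts intronic containment on either strand (the
class definition is strand-silent); the generator's
`intronic_same_strand` switch exposes both conventions. Transcripts that
straddle a gene boundary without exonic overlap match no definition; they
fall back to intronic when the majority of their exonic bases lie inside a
gene span, else lincRNA. That fallback is an artifact decision for
geometric completeness — the planted geometry never produces such cases.

## The JS specificity score

The tissue-specificity score of a profile is computed from the
per-condition mean FPKM vector `p` (normalized to sum 1): for condition
`t` with unit vector `e_t`,

`score_t = 1 − sqrt(JSD(p, e_t))`,

with base-2 Jensen-Shannon divergence, and the transcript score is the
maximum over conditions. It is 1 exactly when expression is confined to
one condition, and `NA` (excluded, not zero) for an all-zero profile.
Whether the probability vector should be per-library or per-condition-mean
is a genuine choice; per-condition-mean is the default because the
conditions (region, stage) are what the maximum is taken over, and
`per_library = TRUE` exposes the alternative.

## WPGMA and the 0.69 cut

Profiles are z-scaled per transcript (population divisor `n` by default;
`sample_sd = TRUE` for `n − 1`) and clustered by WPGMA: the distance from
a merged node to any other node is the plain average of its two children's
distances. The distance metric is 1 − Pearson correlation between scaled
profiles, the standard choice for expression heatmaps — the 0.69 cut is
interpreted on that scale, and Euclidean distance is available as an
option. Minimum-distance ties are broken by the first minimal pair in node
creation order, which makes merge order and labels deterministic; random
continuous data has no ties, so the cross-check against
`hclust(method = "mcquitty")` in the test suite is tie-free. Zero-variance
profiles cannot be correlated; they are placed at distance 1 from
everything and 0 from each other, with a warning at the z-scaling step.

Because the cut scale of a correlation-distance tree depends on the data,
recovering any particular cluster count on real data is not a contract;
what is contracted (and tested) is that a cut strictly between the
within-cluster and between-cluster merge heights recovers a planted
partition exactly.

## The noise-dominance q

For a pooled comparison the signal per transcript is
`M = log2((mean_a + c)/(mean_b + c))` and `D = |mean_a − mean_b|`, with
pseudocount `c = 0.5` guarding the ratio. The noise cloud is every
transcript's (M, D) computed between replicate libraries of the same
condition — the same pooling that justifies treating the AD libraries as
AD replicates. The probability of differential expression is the fraction
of the noise cloud strictly dominated by the signal
(`|M0| < |M|` and `D0 < D`), and transcripts with q > 0.7 are called.
This dominance form is a deliberately simple, exactly enumerable
probability; `deg_call(external_q = ...)` accepts a table from any
dedicated differential-expression engine when one is preferred.

## What the synthetic generator emulates

`synthetic_config()` describes a desk-scale study with known ground truth:
a multi-chromosome genome with non-overlapping, stranded, multi-exon
coding genes; planted lincRNAs (intergenic), intronic lncRNAs (strictly
inside one intron), lncNATs (antisense over a coding exon); coding
fragments (same-strand exon overlap), unstranded isotigs, sub-200-nt
decoys and sub-1-FPKM decoys; TE intervals and a conservation track as
non-overlapping grid windows covering configurable fractions; and a
mutated second-species homolog catalog with a chromosome homology map.
The generator and the classifier are written against the same geometric
predicates and cross-validated, so planted classes are recoverable with
zero errors at noise zero.

Expression is `scale × template` with multiplicative log-normal noise of
configurable coefficient of variation (CV; unit mean, so noise never
shifts means). Log-normal noise is chosen because it is positive-valued
and one parameter controls the difficulty of DE recovery. Cluster
templates are region-balanced stage patterns — cluster *k* is high at
stage *k* in both regions — which keeps two invariants simultaneously:
planted AD-vs-PD fold changes are exactly `2^de_log2fc` on top of any
template, and distinct templates sit at correlation distance 1.5 from each
other, so any cut in (0, 1.5) — including the default 0.69 — recovers the
planted partition at noise zero. The six-library design (2 regions × 3
stages) supports at most three such mutually separated region-balanced
templates, which is why `n_clusters` is capped at 3. mRNA expression
scales are drawn higher (2³–2⁸) than lncRNA scales (2^1.2^–2⁵), mirroring
the expression gap between coding and non-coding transcripts.

What the generator does **not** emulate: read-level sampling noise,
assembly fragmentation and chimeras, isoform complexity, realistic
genome composition, library-size effects, or the correlation structure of
real transcriptomes. Passing planted-truth tests therefore demonstrates
the correctness of the pipeline's logic under its own definitions, not
performance on real libraries.

Problem sizes are deliberately modest — the bundled study uses 3
chromosomes of 0.5 Mb with 45 coding genes and 96 isotigs, the DE
recovery study 200 transcripts, and oracle suites run 100 randomized
trials per operation — chosen so the whole validation runs in minutes on
one core while still exercising every code path.

## Numerical and degenerate-input choices

* All-zero expression profiles give `NA` JS scores and are excluded from
  group means; conservation means ignore unscored bases and are `NA` when
  no exonic base is scored.
* A transcript id on two chromosomes is a hard error everywhere — the
  pipeline assumes unique ids; overlapping bedGraph intervals with
  conflicting scores are rejected.
* Missing coding scores raise errors listing the offending ids rather than
  silently keeping or dropping transcripts.
* An empty coding annotation classifies everything lincRNA with a warning
  (not an error): a catalog without a reference is still a catalog.
* Degenerate pipeline configurations (e.g. a length threshold that removes
  everything) produce empty stage outputs and a complete manifest, never a
  crash.
* Cross-species similarity uses an exact 11-mer seed, window length 50 nt
  and identity 0.8 by default; these are artifact defaults for the
  geometry of "shared similar sequences", not estimates of any published
  procedure, and are exposed as arguments.

## Known limitations

* Coding-potential scores are consumed as tables; the built-in
  `naive_orf_score()` is plumbing for running the pipeline without
  external classifiers, not a trained model.
* The q probability is a dominance count, not a kernel-density odds; with
  very few replicate pairs its resolution is limited by the noise-cloud
  size.
* The cross-species search is ungapped; diverged homologs with indels are
  found only if an ungapped 50-nt window still clears the identity bar.
* Enrichment operates on a user-supplied gene-to-term map; no ontology
  graph propagation is performed.
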