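---
title: "Identifying floral-scent-related lncRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying floral-scent-related lncRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`lncscent` re-implements, as a tested and reusable pipeline, a workflow for
discovering long non-coding RNAs (lncRNAs) associated with floral volatile
emission in rose. The pipeline has six analysis stages, each its own module:

1. **Volatile quantification** — GC-MS peak areas are converted to emission
   rates (µg·g⁻¹·h⁻¹) against a spiked internal standard (ethyl caprate),
   aggregated into the three floral-scent classes (terpenoids,
   phenylpropanoids/benzenoids, fatty-acid derivatives), and compared
   between developmental stages.
2. **lncRNA identification** — a five-filter cascade over assembled
   transcript models: housekeeping-ncRNA removal, an exon-count floor, a
   protein-alignment filter, a length/ORF filter, and a protein-domain plus
   coding-potential gate. Transcripts matching annotated lncRNA genes are
   split off before the novel-lncRNA filters.
3. **Positional classification** — each lncRNA is assigned one of four
   classes relative to protein-coding genes (lincRNA, antisense,
   sense-overlapping, sense-intronic), with strand tallies and feature
   histograms.
4. **Target prediction** — cis candidates by genomic distance (100 kb
   window), trans candidates by expression correlation (Pearson r > 0.95,
   more than five samples).
5. **Differential expression** — stage-wise contrasts (EF→SF, SF→LF) with a
   fold-change/FDR gate, a minimum-expression floor, and "core" lncRNAs
   defined as those differential in both contrasts, with up–down / down–up
   temporal patterns. ΔΔCt and fold-change concordance utilities support
   qPCR validation.
6. **Co-expression network** — an unsigned weighted network (soft threshold
   β = 6), topological overlap, average-linkage clustering with a
   simplified dynamic branch cut, module eigengenes with eigengene-based
   merging, and module–trait correlation against individual volatile
   compounds with top-3 module selection.

Everything is exercisable without external data through a seeded
synthetic-data generator (`simulate_bundle()`) that emits every input the
pipeline consumes together with a ground-truth manifest.

# Coordinate conventions

All genomic intervals are Bioconductor `GRanges` (1-based, closed). Every
overlap, containment and distance decision is delegated to
`IRanges`/`GenomicRanges` machinery, so boundary semantics are inherited
from that well-tested stack rather than hand-written arithmetic: abutting
exons do not overlap, and `GenomicRanges::distance()` measures the gap
between closest interval edges (0 for overlapping intervals), which makes
the 100 kb co-location window inclusive at the boundary. GTF and GFF3 I/O
go through `rtracklayer`, FASTA through `Biostrings`.

# The identification cascade

Filter constants live in one object, `filter_criteria()`:

| parameter | default | rule |
|---|---|---|
| `min_length_nt` | 200 | keep at length ≥ 200 |
| `max_orf_aa` | 100 | keep at longest ORF < 100 aa (exclusive) |
| `min_exons` | 2 | keep at exon count ≥ 2 |
| `coding_hit_max_p` | 1e-10 | exclude only at p strictly below |
| `coding_hit_min_identity_pct` | 90 | exclude only at identity strictly above |
| `coding_hit_min_coverage_pct` | 80 | exclude only at coverage strictly above |
| `pfam_evalue_max` | 1e-5 | exclude at E ≤ threshold |
| `cpc_score_max` | 0 | keep at score strictly below |

A protein hit excludes a transcript only when **all three** alignment
inequalities hold strictly; a hit at identity exactly 90% does not exclude.
The length rule keeps transcripts of exactly 200 nt: the conventional
definition of a lncRNA ("longer than 200 nt") is ambiguous at the boundary
and the inclusive reading is adopted once and logged here.

Hit-table coverage is consumed as a precomputed column and documented as
query coverage; the standard BLAST tabular format has no coverage column,
so the reader requires it explicitly.

## ORF definition

`longest_orf()` scans the three forward frames (the assembly is
strand-specific, so transcript sequences are sense-strand); a `six_frame`
flag exists for non-stranded inputs. An ORF is an ATG followed by in-frame
codons up to the first in-frame stop; its length counts the codons from
the ATG through the codon before the stop, and open-ended ATG runs without
a stop are not ORFs. This is the stricter of the possible readings of a
"longest consecutive codon chain" and, unlike open-ended definitions, is
directly testable: the finder is verified against an exhaustive
enumeration oracle on random sequences in the test suite and the
acceptance script. Ties are broken toward the smallest start position,
then the smallest frame. Codons containing N never match ATG or a stop.

## Coding-potential gate

External evidence takes precedence: transcripts with a Pfam-domain hit at
E ≤ 1e-5 are removed outright, and an external coding-potential score
table (negative = non-coding) is used when supplied. When no external
score is available the built-in heuristic scores a transcript as

```
score = 2 * (orf_coverage - 0.5) + (testcode - 0.95)
```

where `orf_coverage = 3 * aa_length / length` and `testcode` is the
classic Fickett position/composition statistic computed from lookup
tables. The heuristic is a documented surrogate for an SVM-based
coding-potential classifier, not a reimplementation of one; its role in
testing is to separate planted coding-like sequences (ORF covering most of
the transcript) from ORF-poor lncRNAs, which the test suite checks
directly.

# Positional classification

The four classes are assigned with explicit precedence, since exon-level
evidence is stronger than containment:

1. **antisense** — ≥ 1 bp overlap between a lncRNA exon and a coding exon
   on the opposite strand;
2. **sense_overlapping** — the same overlap on the same strand;
3. **sense_intronic** — the lncRNA span lies wholly inside a coding-gene
   span with no exonic overlap on either strand. Containment, not strand,
   drives this class: intronic lncRNAs occur on both strands;
4. **lincRNA** — everything else.

The partner gene is the one providing the triggering overlap (closest span
midpoint on ties); lincRNAs have no partner. Feature histograms use the
conventional printed bins (length: <300 through >1000 nt in 100-nt steps;
exons: 1–10 and >10; ORF length for the coding set up to ≥1000 aa); bins
are left-closed and right-open, with lengths of exactly 1000 falling in
">1000".

# Target prediction

Co-location pairs a lncRNA with every protein-coding gene whose genomic
gap is at most 100 kb (strand-ignored, boundary inclusive, overlap = 0).
The anchor is the closest interval edge; the window is a parameter
(`target_params()`).

Co-expression uses signed Pearson correlation with threshold r > 0.95 by
default, following the literal "greater than" rule: perfectly
anti-correlated pairs are *not* emitted. Because negative regulation is
biologically plausible, an `absolute` flag admits |r| > threshold instead;
it is off by default and the choice is surfaced in the output. The
more-than-five-samples precondition is enforced with an explicit error,
and constant expression vectors (undefined correlation) are skipped with a
warning rather than silently producing NA pairs.

# Differential expression

Fold changes are pseudocounted ratios of stage means,
`log2((mean_b + 0.01)/(mean_a + 0.01))`; tests run on `log2(FPKM + 0.01)`.
The assembler-level count model of the original tool chain is out of
scope, so the test is a per-transcript linear-model contrast. The default
is limma's moderated t (empirical-Bayes variance shrinkage): with three
replicates per stage, an unmoderated Welch t has only 2–4 effective
degrees of freedom, and its attainable p-values frequently cannot clear a
Benjamini–Hochberg threshold even for a true four-fold change — variance
moderation is the field-standard remedy at this design size and is what
the package's planted-truth recovery tests are run against.
`method = "welch"` retains the plain Welch t for users who want a
dependency-free test; it is cross-checked against `stats::t.test()` in the
suite.

Adjustment is BH across all transcripts in the matrix, per contrast. A
transcript is `up` at `log2fc ≥ 1` and `p_adj < 0.05` (boundary
inclusive), `down` symmetrically. The expression floor excludes a
transcript only when its stage-mean expression is below 0.5 in **all**
stages. Core lncRNAs are those differential in both successive contrasts;
`up_down` and `down_up` label the two rise-and-fall patterns and any other
combination is `other`.

# Co-expression network

`network_params()` carries the standard unsigned WGCNA-style setup: power
6, minimum module size 6, deep split 4, merge threshold 0.15. Adjacency is
`|cor|^6` with a zero diagonal; the topological overlap is

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),   l_ij = Σ_u a_iu a_uj
```

with unit diagonal, verified against a double-loop oracle and the
two-node closed form (TOM = adjacency) in the tests.

**Dynamic branch cutting** is implemented as a documented simplified
variant, not a port of the reference algorithm: average-linkage clustering
of `1 − TOM`, a static cut at height 0.99 to define main branches, then a
recut within each branch at `0.99 − 0.05 × deep_split`. Sub-branches of at
least `min_module_size` members become modules; a branch none of whose
sub-branches stands alone becomes one module if it is large enough;
everything else is grey. The variant is accepted via planted-truth
recovery (adjusted Rand index against planted memberships), not
bit-equivalence with the reference implementation.

Module eigengenes are the first principal component of the standardized
member × sample matrix, unit-variance, oriented so the mean member
correlation is positive (tie toward the first member). Two merge-like
thresholds exist in the parameter set (`me_diss_thresh = 0.15`,
`merge_cut_height = 0.1`) because both appear in common WGCNA
configurations without a clear division of labor; here the eigengene
dissimilarity threshold 0.15 governs merging and `merge_cut_height` is an
alias that only takes over when explicitly enabled. Merging is iterative
(closest pair first, eigengenes recomputed each step), never increases the
module count, and is a fixed point on its own output.

Module–trait correlation ranks modules per compound by |r| (the sign is
reported but not used for ranking, since ranked module tables are
conventionally printed unsigned); the top three modules per compound are
reported and grey is never ranked.

# The synthetic-data generator

`simulate_bundle()` emits a complete, deterministic fixture bundle from a
`sim_config()`. The defaults define the emulated study: one chromosome,
150 multi-exon coding genes, 150 lncRNAs split 60/30/20/40 across
lincRNA/antisense/sense-overlapping/sense-intronic (half of them present
in the annotation as lncRNA-biotype genes), 30 housekeeping ncRNA genes
with matching overlapping transcripts, 100 single-exon noise transcripts,
and 20 coding-like decoys; a 3-stage × 3-replicate × 4-cultivar design (36
samples, comfortably above the 15-sample network floor); 13 planted
co-expression modules of 6–8 lncRNAs; 9 up–down, 9 down–up and 20
single-transition differential patterns at 4-fold with log2-noise SD 0.25,
six of the single-transition plants below the 0.5 expression floor; and 19
scent compounds linked to modules at r = 0.9 plus two non-scent compounds.
These sizes keep the full suite and the acceptance script in the tens of
seconds while leaving every recovery statistic estimable.

Key constructions:

* **lncRNA sequences** come from `plant_orf_free_sequence()`, which
  rejection-samples uniform sequences until the longest ORF — checked with
  the same finder the identification module uses — is under 100 aa.
* **Coding and decoy sequences** carry a planted ORF drawn from non-stop
  codons. Coding ORFs cover 80–90% of the transcript (a realistic CDS
  density for short mRNAs); decoys are short transcripts with a 99-aa ORF
  so that they clear the length/ORF filter and fall only at the hit-table
  or domain/coding-potential gate, exercising each gate in isolation.
* **Positional classes** are realized geometrically: antisense and
  sense-overlapping lncRNAs straddle the first coding exon of their host
  gene (≥ 50 bp exonic overlap) on the appropriate strand; sense-intronic
  lncRNAs sit wholly inside a widened first intron; lincRNAs, noise,
  housekeeping genes and decoys are placed in intergenic gaps with
  kilobase margins.
* **Expression** is log-normal around stage-specific means (multiplicative
  noise, matching FPKM-scale heteroscedasticity) for stage-patterned and
  background transcripts. Module members instead follow
  `loading × eigen-trajectory + Gaussian noise` on the linear scale, with
  orthonormalized random trajectories; linked volatile vectors are
  `r × trajectory + √(1−r²) × noise` mapped affinely to positive emission
  rates, which preserves the planted Pearson correlation.
* **GC-MS peak areas** are back-computed through the exact inverse of the
  emission-rate formula (internal standard: 0.865 µg·µL⁻¹, 10 µL, 3 g
  sample, 40 min extraction), so quantification round-trips to floating
  point accuracy.
* **The Ct table** encodes sequencing-derived fold changes for ten
  differential lncRNAs with 0.5 log2-units of qPCR noise, giving the
  concordance regression something realistic to estimate.

The generator uses a single seeded RNG stream with a fixed generation
order: identical configurations (including seed) produce byte-identical
bundles. Per-artifact stream isolation — where editing one count leaves
unrelated artifacts unchanged — is not provided; R has no cheap
counter-based sub-stream mechanism and the determinism contract only
requires same-config identity.

## What the generator does not emulate

Passing the recovery suite shows the pipeline's logic is correct under the
planted model, not that it reproduces any particular real-data result. The
generator has single-isoform genes, no splice complexity, no sequence
homology between transcripts, no mapping/assembly artifacts, uniform base
composition outside planted ORFs, Gaussian module structure instead of
realistic co-expression topology, and an external coding-potential score
table with category-consistent signs (a synthetic stand-in for a real
classifier's output). Real data will be noisier at every stage; thresholds
were therefore kept as user-facing parameters rather than constants.

# Numerical choices and degenerate inputs

* Correlation matrices with constant rows: those correlations are set to 0
  in the network (with a warning) and produce no pairs in target
  prediction.
* Degenerate tests: replicate vectors with zero variance in both groups
  give t = 0 / p = 1 when the means agree, p = 0 when they differ.
* Zero-total stages in volatile aggregation are flagged (`defined =
  FALSE`) instead of emitting NaN shares.
* Histogram proportions and class shares are validated to sum to 1 (resp.
  100%) to 1e-12/1e-9.
* Eigengene sign is fixed by the mean-member-correlation rule so module
  trait signs are reproducible.
* The TOM oracle tolerance is 1e-12; emission round-trip tolerance 1e-9
  relative.

# Problem sizes used in the tests

The suite runs the full bundle (450 transcripts, 36 samples) once and
shares it across test files; recovery sweeps use 50 seeds × 200
transcripts (differential expression) and 50 seeds × 91 transcripts
(module-trait links); the ORF finder is checked against exhaustive
enumeration on 1000 random sequences of 30–3000 nt and the classifier
against brute force on 500 random geometries. These sizes were chosen so a
complete run stays fast on one CPU while every statistic has enough
resolution to detect a real defect.

# Known limitations

* The dynamic-cut variant is simplified; on dendrograms with nested
  modules of very different tightness it will split less adaptively than
  the reference algorithm.
* The built-in coding-potential heuristic is deliberately simple; for real
  data an external classifier's score table should be supplied.
* Differential expression models log-FPKM, not counts; with real count
  data a negative-binomial tool is preferable.
* Co-location treats all gene-lncRNA gaps equally up to the window; no
  orientation or promoter-proximity weighting is applied.
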