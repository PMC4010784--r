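---
title: "srnablocks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnablocks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnablocks)
```

# Scope

`srnablocks` implements a complete survey pipeline for plant small-RNA
sequencing: unique-tag preprocessing, a hierarchical alignment triage against
structural-RNA and organellar decoys, proximity-based block quantification
with multi-mapper weighting, two-proportion differential expression,
hairpin-criteria discovery of novel miRNA loci, and functional classification
of differentially expressed blocks.  Because real tissue-survey libraries of
this design are typically not deposited, the package treats a synthetic-data
generator with planted ground truth as a first-class module: every stage of
the pipeline is validated against loci the generator planted.

# Preprocessing

Reads are collapsed to unique tags with abundance counts; reads containing
non-ACGT characters (including N) are dropped and logged rather than
corrected.  Size selection keeps 17–35 nt inclusive.

Error correction is a frequency-clustering rule: tags are visited in
increasing abundance order and compared against strictly more abundant tags
of the *same length*; a child within the substitution budget (default 1) is
merged into its best parent — minimal Hamming distance, then maximal current
abundance, then lexicographically smallest sequence.  Passes iterate to a
fixpoint, and total abundance is conserved exactly.  Same-length-only merging
is deliberate: 3′ length variants (isomiRs) are biology, not sequencing
error, and must not be folded together.  One level of merging per pass (with
iteration) is a defined, testable stand-in for published frequency-clustering
correctors whose exact hierarchies are not restated here.  At a 1% per-base
error rate on 21-nt reads roughly 90% of error reads carry exactly one
substitution, which bounds what single-mismatch correction can recover — the
recovery property in the test suite sits exactly at that bound.

# Alignment and triage

The aligner is substitution-only (no indels), which matches practice for
17–35 nt queries, and reports *all* placements on both strands.  Internally
it seeds by pigeonhole chunking — a placement with at most *m* substitutions
must contain an error-free chunk of length `floor(L/(m+1))` — and verifies
candidates with 2-bit-packed XOR/popcount Hamming counts.  The index-free
design keeps the contract simple: every reported placement is reproducible
by direct string comparison (reverse complement for minus-strand hits), and
the test suite holds the implementation to a naive full-scan oracle.

The triage cascade is fixed: (1) tRNA/rDNA at up to 3 mismatches, removed;
(2) nuclear genome, perfect matches only — the only category quantified
downstream; (3) nuclear genome at a relaxed budget, reported only;
(4) chloroplast, then (5) mitochondrion; the remainder is unmapped.  The
relaxed budget defaults to 3 (the procedural description; a narrative
passage elsewhere says two) and is exposed as `relaxed_mismatch`.  The
original study used a quality-aware aligner whose threshold semantics
(`t = 30`) cannot be reconstructed from the text; a plain mismatch budget is
used instead and the divergence is accepted.

# Blocks and weighted counts

Perfect genome placements from all libraries are pooled and merged into
strand-agnostic blocks: two placements share a block iff they are connected
by a chain of placements with consecutive gaps of at most `gap` nt.  The gap
is not stated in the source methodology; the default is 100 nt and the
acceptance suite treats it as a free parameter.  Increasing the gap can only
decrease the number of blocks (tested property).

A tag aligned to *k* genome-perfect loci contributes `abundance/k` to each
containing block.  Uniform 1/k weighting is the canonical over-counting
correction; it reproduces the stated goal (no inflation of repeat-derived
counts) and conserves the grand total exactly — block counts sum to the
genome-perfect abundance to 1e−9 on every run, which the suite asserts.
Per-strand and per-length tallies are retained for classification.  RPM
scaling (`1e6 × count / library total`) is used only for reporting and the
low-expression filter, never for the test statistic.

# Differential expression

Each block is tested with a pooled two-proportion z-test ("difference in
proportion"): with `p1 = x1/n1`, `p2 = x2/n2`, and pooled `p`, the statistic
is `z = (p1 − p2)/sqrt(p(1−p)(1/n1 + 1/n2))`.  The library totals `n` are
the genome-perfect weighted totals; this is the test's internal
normalisation, so counts enter raw — weighted (real-valued) counts are used
directly, since rounding would break conservation.  `z²` is algebraically
the Pearson chi-square statistic of the corresponding 2×2 table without
continuity correction; the acceptance suite verifies this identity to 1e−9
over 10,000 random tables.

A block is tested only when its expression is *strictly* greater than
20 RPM in at least one library.  Within a comparison, p-values are
Bonferroni-corrected over the number of tested blocks; a call requires a
corrected p below 0.05 *and* a fold change of at least 2 in either
direction.  Fold changes are computed on RPM; with a zero denominator the
fold is infinite and passes the cutoff (presence/absence is the strongest
signal, and the prefilter guarantees the numerator is expressed).  Whether
the original fold change used RPM or raw counts is unstated — with pooled
(unreplicated) libraries of equal totals they coincide — so RPM is stated
and totals are exposed for audit.  The six standard contrasts (far-red vs
dark per tissue; convex vs concave hook under each light) ship as a preset.

# miRNA discovery

Tags with at most 20 genome-perfect placements enter candidacy, one
candidate per placement; lengths are unrestricted at candidacy and final
calls are limited to 20–22 nt keys.  For each candidate a 170-nt
strand-specific window is extracted.  "Around the key sequence" is
unspecified in the source; the window is centred on the placement midpoint
and shifted inward at contig edges (candidates on contigs shorter than the
window are rejected, not errored).

Windows are folded by a pluggable backend.  The built-in baseline is a
Nussinov-style dynamic program over nested structures (minimum loop 3) with
per-pair energies GC = −3, AU = −2, GU = −1 kcal/mol, minimising total pair
energy.  This scale is *not* thermodynamically calibrated; the published
−40 kcal/mol gate is kept as the default for the baseline too (the planted
hairpins and the constructed test fixtures are built against it), and is
configurable per backend.  A thermodynamic folder can be passed as a
function returning `list(structure=, delta_g=)`.

The goodness criteria on the folded window are:

* **(i)** strictly more than 75% of the key bases are paired —
  16/21 passes (76.2%), 15/21 fails (71.4%);
* **(ii)** the star span (minimum to maximum window positions paired with
  key bases) is at most 1.5× the key length;
* **(iii)** the key span and star span are separated by at least 20 nt,
  *and* no position within 10 nt of the key ends pairs into the star span —
  the source states this criterion in both forms, and the stricter
  conjunction satisfies either reading;
* **(dG)** folding energy at most the −40 kcal/mol gate.

The suite includes four constructed 170-nt windows, each failing exactly one
criterion under the baseline folder, proving the criteria are evaluated
independently.  Passing candidates overlapping annotated repeats
(`repeat_region`, `transposable_element`) by ≥1 nt are removed; survivors
are classified known/novel by an ungapped sliding alignment against a
mature reference set (known iff ≤2 substitutions over the full shorter
length and length difference ≤2 nt).

At pipeline scale a candidacy floor on summed tag abundance
(`min_candidate_abundance`, default 5 reads) keeps the folding workload
proportional to genuinely expressed sequences; the API default is 1 (no
floor), matching the bare contract.

# Block annotation

For each annotated block: the **key sequence** is the member tag with
maximal abundance summed over libraries (exact ties go to the
lexicographically smallest sequence, making the choice order-invariant);
the 20–24 nt size histogram is computed from weighted abundances (other
lengths count toward the total); the strand bias is the majority-strand
fraction of weighted abundance; the key's most 5′ placement in the block is
hairpin-evaluated; and the key is searched against known matures with local
alignment (match +5, mismatch −4, gap −10).  An external similarity-search
binary's analytic E-values are replaced by a seeded empirical p-value —
mononucleotide shuffles of the query, add-one estimator
`(1 + #{shuffle ≥ observed})/(n + 1)` — applied at the same 0.01 cutoff.

Classification: *miRNA-like* iff the dominant length is 20–22 nt, strand
bias ≥ 0.9 and the hairpin passes; otherwise *siRNA-TE* iff ≥50% of block
abundance overlaps transposon annotation; otherwise *siRNA-gene* by the
same rule on genes; otherwise unclassified.  The 0.9 and 50% thresholds are
implementation choices (the original classification was by inspection) and
are exposed in the configuration.  TE takes precedence over gene when both
overlap, reflecting the heterochromatic-siRNA prior for double-stranded
23–24 nt blocks.

# The synthetic world

The generator emulates the eight-library tissue survey: four tissues
(cotyledon, hypocotyl, hook concave, hook convex) × dark/far-red.  On a
uniform-ACGT background chromosome it plants miRNA hairpin loci
(mature + ≥20 nt loop + mutated reverse complement, built to satisfy the
goodness criteria and *verified against the package's own evaluator before
the genome is accepted*), 1–3 kb transposon siRNA clusters (annotated as TE
and repeat), and gene-overlapping siRNA clusters.  tRNA/rDNA decoys and
plastid contigs are separate reference records.  Planted loci are spaced
> the default block gap, so truth loci map 1:1 onto blocks.

Abundances are log-normal(μ = 4, σ = 1.5) per locus — heavy-tailed, as in
real sRNA libraries.  Per library, reads are drawn multinomially: miRNA loci
emit the mature with 3′ isomiR jitter (80% exact, 10% each ±1 nt where the
20–22 nt range allows), siRNA loci emit 23–24 nt reads (3:1 in favour of
24 nt) uniformly over both strands, decoys emit sense fragments sized so
that 25–55% of each library maps to decoys (cotyledon highest, mirroring
the published range), and a junk component (8%) is unmappable.  Per-base
substitution errors default to 0.5%.  Depths default to 50,000 reads per
library — a deliberate desk-scale stand-in for the 8–15 million reads of a
real survey.

Two knobs are worth calling out:

* **21:24 tilting.** Each library's miRNA-class weights are rescaled so the
  expected 21-nt:24-nt abundance ratio matches the published tissue profile
  (cotyledon 2:1; hypocotyl 0.81/0.67; dark hook 0.71/0.75; far-red hook
  0.98/1.07).  Planted fold changes shift the realised ratio afterwards —
  which is exactly the biology the ratio shift represents.
* **Exact fold changes.** A planted fold multiplies the locus' expected
  proportion exactly; the *other* genomic loci absorb the renormalisation.
  Planted-DE loci are pinned at the median lognormal weight, because a free
  heavy-tailed draw can make a 4-fold boost infeasible (the boosted mass
  would exceed the genome share) and pinning fixes the planted expression
  scale well above the 20 RPM filter.

What the generator does **not** emulate: adapter contamination, indel
errors, quality-score structure, base-composition bias, multi-locus miRNA
families sharing one mature sequence, and cis-NAT siRNA geometry.  A green
test therefore establishes algorithmic correctness on an idealised world,
not performance on real libraries.

`simulate_locus_counts()` draws per-locus multinomial counts from the same
mixture model without synthesising read strings; replicated statistical
experiments (the type-I-error study) use it because the DIP statistic
depends on counts only.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is converted on
  read/write.
* `x1 = x2 = 0` is undefined for the DIP test and raises an error; the RPM
  prefilter guarantees it never occurs in the pipeline.
* Tags longer than 64 nt are rejected by the aligner (packed verification);
  the size filter caps lengths at 35 nt long before.
* Structure traceback prefers pairing the 5′-most base when optima tie; the
  criteria flags of the shipped fixtures are invariant to this choice
  because their optimal pair *sets* are forced.
* The block builder merges at separation ≤ gap (boundary inclusive), and
  `gap = 0` still merges bookended intervals.
* Seeds: every stochastic stage derives an independent 31-bit stream from
  the master seed and a stage tag, so stages can be re-run in isolation and
  whole runs are bit-reproducible (tested).

# Known limitations

The baseline folder maximises pair energy without stacking, so its
structures over-pair relative to thermodynamic folders; specificity comes
from criteria (i)–(iii) jointly rather than from ΔG.  The empirical
similarity p-value saturates at `1/(n_shuffles+1)`, so ranking below ~0.001
requires raising `n_shuffles`.  The DIP test models pooled libraries; with
biological replicates a dispersion-aware model would be required, which is
deliberately out of scope.  Per-module shell subcommands beyond
`all`/`simulate`/`preprocess` are exposed as R functions rather than CLI
verbs.
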