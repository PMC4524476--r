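---
title: "Coverage-based scaffold classification: model, filters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based scaffold classification: model, filters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adratio)
```

## The average-depth ratio model

A male mammal carries one X and one Y chromosome, a female two X and no
Y; autosomes are diploid in both. When short reads of one male and one
female are mapped against a male-derived assembly, the per-scaffold
average read depth carries that ploidy signal. The statistic is

$$\mathrm{AD} = \frac{\bar d_{\mathrm{female}}}{\bar d_{\mathrm{male}}
\cdot \mathrm{norm}}, \qquad
\mathrm{norm} = \frac{N_{\mathrm{female}}}{N_{\mathrm{male}}},$$

where $\bar d$ is the average depth over usable positions of the
scaffold and $N$ the total number of mapped reads (mapping quality
$\ge 20$) of each individual. The normalization standardizes the two
genomes to the same genome-wide coverage, so the expectation is 0 for
Y-linked, 1 for autosomal and 2 for X-linked scaffolds regardless of the
two libraries' absolute sequencing effort. Multiplying both read totals
by any constant leaves every ratio unchanged (this scale invariance is
tested).

The statistic is robust because it needs no gene annotation and covers
intergenic scaffolds, which similarity searches with known sex-linked
genes cannot reach. Its main failure modes are mismapping (female
autosomal/X reads landing on Y scaffolds pull the ratio above 0),
collapsed repeats (excess depth), and pseudoautosomal or recently
diverged X–Y segments, which behave autosomally.

### Average depth, masking and the depth cap

`average_depth()` sums depths over positions whose reference base is a
plain A/C/G/T and whose depth does not exceed a cap (default 50 reads),
then divides by the number of such positions. Zero-depth positions count
in the denominator — omitting them would inflate averages, since depth
tables in the `samtools depth` dialect simply omit uncovered positions.

Two conventions deserve explicit statement:

* **Ambiguity.** Any non-ACGT reference character is treated as
  ambiguous, a conservative superset of masking only N; an `N-only` mode
  is available in `scan_reference()`.
* **Cap denominator.** The published description of the depth cap is
  ambiguous about whether a capped position stays in the denominator.
  The default (`cap_mode = "trim"`) removes capped positions from both
  numerator and denominator, which is an unbiased trimmed mean; keeping
  them in the denominator (the literal reading,
  `cap_mode = "denominator_keeps_capped"`) implicitly scores them as
  depth 0 and systematically deflates averages of repeat-rich scaffolds.
  Both modes are implemented; results in this package use the trimmed
  mean unless stated.

The cap is applied per individual independently: each sex's average is a
property of that individual's mapping alone.

### Classification thresholds

`ad_thresholds()` holds the policy constants: Y when $\mathrm{AD} \le
0.3$ (inclusive — the relaxed cutoff absorbs mismapping on true Y
scaffolds), autosomal when $0.7 < \mathrm{AD} < 1.3$, X-linked when
$1.7 < \mathrm{AD} < 2.3$ (both strict, as the intervals are
conventionally printed), otherwise unassigned. Threshold comparisons are
exact, with no epsilon: the thresholds are policy constants, not
estimates, and an epsilon would only blur the stated rule. Scaffolds
shorter than 1 kb are excluded before classification, as are scaffolds
with no usable positions or no mapped reads in either sex; an upstream
low-mapping-quality exclusion list can be supplied as `exclude_ids`
(that criterion is computed from BAM files, upstream of this package's
inputs). A scaffold with female reads but zero male average depth has an
undefined ratio and is reported unassigned, never Y: zero male depth
contradicts Y-linkage on a male-derived assembly.

### Histogram

`ad_histogram()` bins ratios into left-closed, right-open intervals of
width 0.02 (`[0, 0.02)`, `[0.02, 0.04)`, …) and also reports the
combined scaffold length per bin. Because bin boundaries like 0.06 are
not exactly representable in floating point, a quotient within $10^{-9}$
of an integer is snapped onto it, keeping the left-closed convention
stable; ratios themselves are never rounded.

## Similarity-hit filtering

`select_candidates()` implements the three-rule extraction from a
tabular similarity search (BLAST `-outfmt 6` dialect), per query exon:
the best hit is the lowest E value (ties: higher bit score, then
lexicographically smaller scaffold id — a total order, so the result is
independent of input row order); other scaffolds are retained when their
identity is at least 95 % of the best hit's **relative** identity and
their alignment length is within 5 % of the best hit's. The 95 % rule is
stated relative to the best scaffold; because the underlying sentence
also admits an absolute reading, `similarity_mode = "absolute"`
thresholds at 95 % identity outright. Only the best hit per scaffold
enters the comparison, so a scaffold cannot be retained on a secondary
local alignment.

`confirm_candidates()` then realigns the query against each retained
hit-delimited scaffold subsequence with a global Needleman–Wunsch
aligner (match +1, mismatch −1, gap −2, linear; traceback ties prefer
diagonal, then up, then left) and keeps scaffolds with identity
$\ge 80\,\%$ (inclusive). Identity is matches over alignment columns
after stripping terminal gap columns: the query is a local fragment, so
terminal overhangs carry no signal. The scoring scheme is fixed and
documented rather than configurable — the original interactive aligner's
defaults are not reproducible bit-exactly, and a fixed scheme keeps the
decision rule deterministic. The aligner's scores are verified in the
test suite against an exhaustive enumeration over all monotone match
sets between the two sequences.

Per-gene aggregation over multiple exons is reported as the union of
per-exon candidate sets, without claiming a specific published
aggregation rule (none is stated for the gene-level tables this mirrors).

## Strict alignment column filters

Before phylogenetic analysis of concatenated Y-scaffold consensus
sequences, two column filters apply:

1. **Gaps/ambiguity** (`drop_ambiguous_gap_columns()`): any column in
   which any row holds `-` or a non-ACGT character is removed.
2. **Private adjacent differences** (`drop_singleton_runs()`): a
   *singleton column* is one where exactly one row differs from the
   unanimous state of all other rows. Every maximal run of at least
   `min_run` (default 2) consecutive singleton columns attributable to
   the *same* row is removed — multiple adjacent private differences in
   one individual are far more likely consensus or alignment artefacts
   than independent substitutions. Isolated singletons and adjacent
   singletons in different rows are kept. "Multiple … adjacent" is
   formalized as strictly consecutive runs of length ≥ 2; a looser
   windowed notion would need evidence the data cannot provide.

Columns where the non-focal rows disagree among themselves are not
singleton columns and are never removed by filter 2. With only two rows
a difference is not attributable to one individual, so no column is a
singleton column there. `filter_alignment()` applies filter 1 once and
filter 2 repeatedly until no removable run remains: deleting a run can
make two singletons of another row newly adjacent, and the same
artefact argument applies to them; iteration to the fixed point is also
what makes the whole filter idempotent. The single-pass semantics of
`drop_singleton_runs()` itself is preserved and checked against a
brute-force scanner.

## Repeat-annotation summaries

`coverage_fraction()` reports covered base pairs as the size of the
union of annotation intervals (overlaps counted once), per repeat class
and overall; a base annotated under two classes counts once overall and
once per class, so the overall fraction is bounded below by the largest
class fraction and above by the class sum. `microsatellite_filter()`
keeps simple repeats with $\lfloor \mathrm{span} / |\mathrm{motif}|
\rfloor \ge 15$ whole units — partial motif copies do not count.

## The simulator

`simulate_truth_set()` emulates the study design the method targets: one
male and one female sequenced at similar depth (~12×) and mapped against
an assembly of autosomal, X- and Y-scaffolds. Per-position depths are
independent Poisson draws with ploidy-driven means — autosomal:
$c_{\mathrm{sex}}$ in both sexes; X: $c_m/2$ in the male,
$c_f$ in the female; Y: $c_m/2$ in the male and
$c_f \cdot \mathrm{mismap}$ in the female. Defaults: 100 scaffolds per
class, lengths uniform on 1–50 kb, $c_f = c_m = 12$, mismapping rate
0.01, ambiguous-base rate 0.01 laid out as geometric runs of mean length
20 bp (N-runs in assemblies are gap fills and masked repeats, not
isolated bases). Read length (101 bp) and insert size (400 bp) are
carried as metadata only.

Read totals are derived from the depth sums of the **autosomal**
compartment. In a real whole-genome dataset the total mapped read count
is overwhelmingly autosomal (sex chromosomes are a few percent of a
mammalian genome), so the female/male read-total ratio estimates the
coverage ratio; the simulated assembly deliberately over-represents sex
chromosomes to exercise the classifier, and deriving totals from the
whole simulated assembly would import that artificial class imbalance
into the normalization factor.

What the simulator does *not* model — and what passing tests therefore
do not show about real data: read-length autocorrelation of depth
(adjacent positions share reads, so real averages have fewer effective
degrees of freedom), locus-specific mismapping concentrated on repeats
and X-transposed regions (simulated mismapping is uniform), collapsed
ampliconic repeats with extreme depth, GC-dependent coverage bias, and
mapping-quality structure. The simulator validates the *computation* —
masks, caps, normalization, thresholds, exclusions — under a model
where the expected ratios are known exactly, not the biological error
rates of the approach.

Hit tables (`simulate_hit_table()`) plant, per query, a best hit and
decoys straddling the 95 %/5 % rules, returning the expected retained
set; alignments (`simulate_alignment()`) plant gap/ambiguity columns and
same-row singleton runs, separated by constant buffer columns so the
planted removable fraction is recovered exactly, plus kept features
(an isolated singleton and a mixed-row adjacent pair) when space
allows. All generators are fully reproducible from their seed.

## Problem sizes and test design

The validation suite runs the full recovery experiment at 100 scaffolds
per class (about 7.6 Mb of simulated genome per sex) with and without
mismapping — large enough that the autosomal and X means are estimated
to within well under 1 % — and checks: exact agreement of the sparse
average-depth computation with a full-vector recomputation on random
small scaffolds; exhaustive-enumeration agreement of the aligner on all
sequence pairs up to length 8 over 200 seeded trials; idempotence of the
alignment filter on random 5×50 alignments and exact recovery of a
planted 30 % removable fraction; order-independence and best-hit
retention of the candidate filter; and conservation laws
(label partition, histogram count/length totals, coverage invariance
under interval splitting). The bundled table of 20 published, in vitro
validated Y-scaffold AD-ratios (all ≤ 0.3, including an SRY-bearing
scaffold at 0.075) is classified as a worked example; all 20 receive the
Y label.

## Known limitations

* The AD-ratio cannot separate Y-linked from X-linked sequence in
  pseudoautosomal or recently diverged strata, and underestimates total
  Y content when repetitive Y sequence is collapsed or unassembled.
* The low-mapping-quality scaffold exclusion of the original workflow is
  an upstream BAM-level criterion; here it is an input list, not a
  computation.
* The read-total quality cutoff ("quality ≥ 20") can be read as mapping
  or base quality; the package accepts precomputed totals and leaves
  that choice to the caller.
* Scaffolds with ratios exactly on the autosomal/X interval boundaries
  are unassigned; the printed inequalities are strict and the package
  follows them.
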