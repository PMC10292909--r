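---
title: "Methods: SV simulation, benchmarking, and rate estimation for MA experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV simulation, benchmarking, and rate estimation for MA experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masv)
```

# Scope and model

`masv` implements the computational core of structural-variant (SV) analysis
in bacterial mutation-accumulation (MA) experiments: simulating genomes with
known SVs to benchmark detection pipelines, filtering candidate calls from
evolved MA lines, and converting surviving counts into per-genome,
per-cell-division mutation rates with exact Poisson confidence intervals.
The defaults throughout describe the study design this package models: an
*E. coli* K-12 MG1655-sized chromosome (~4.6 Mbp, reference NC_000913.3),
67 wild-type (WT) and 37 mismatch-repair-deficient (ΔmutS) lines bottlenecked
through ~160 single-colony transfers, and log₂(CFU) ≈ 28 (WT) or 27 (ΔmutS)
cell divisions per transfer, giving T = 4,480 and 4,320 divisions per line.

The mutation-rate model is the standard MA estimator

$$\mu = \frac{m}{\sum_{i=1}^{n} N_i \, T}$$

with `m` events over `n` lines, `N_i` analyzed sites per line, and `T`
divisions per line. For SV rates the genome is the unit of observation
(`N ≡ 1`), so `rate_per_genome(m, n, T) = m/(nT)`; `rate_per_site()` uses the
summed-sites denominator for base-substitution work. Both return exact
(Garwood) Poisson intervals:

$$\left[\tfrac{1}{2}\chi^2_{\alpha/2}(2m),\;
  \tfrac{1}{2}\chi^2_{1-\alpha/2}(2m+2)\right] / \text{denominator},$$

with the lower bound 0 when `m = 0` (upper bound then `-ln(α/2)`/denominator
≈ 3.689/denominator). The exact interval was chosen over the normal
approximation because MA counts per stratum are small (single digits for
deletion classes); the chi-square construction reproduces the published
intervals for the counts this package targets to three significant figures,
and its coverage is conservative (≥ 95 % at every rate, verified by
enumeration over the Poisson pmf in the test suite). Reported rates are
rounded to 3 significant figures; objects keep full precision.

Two published rate values deliberately do *not* reproduce from their printed
counts and the stated denominators (the WT IS-mediated rate, where
70/(67×4480) rounds to 2.33e-4 rather than the printed 2.32e-4, and the
ΔmutS total SV rate, where 82/(37×4320) gives 5.13e-4 rather than 5.26e-4);
the original per-line division totals behind those figures are not
recoverable, so the package computes the arithmetic consequence of the
printed inputs and does not force agreement. Tests assert only the
reproducible values.

# Coordinates and record model

All internal coordinates are 1-based inclusive, matching VCF; BED export is
0-based half-open and composes back to identity. An SV record has a type in
{INS, DEL, DUP, INV}, a start (for insertions, the base immediately left of
the insertion point, so `end == start`), a length (inserted length for INS,
affected span otherwise), an optional inserted sequence, and an `imprecise`
flag mirroring the INFO/IMPRECISE key long-read callers emit. The chromosome
is treated as linear although the real molecule is circular: no simulated or
parsed SV may span the origin, which matches how reference-based callers
report coordinates. VCF records of other types (BND, CNV) are read, tallied,
and excluded with a warning, since the analysis covers exactly four types.

# The genome simulator

`plan_svs()` draws per-type SV counts, lengths from a three-bucket mixture
(70 % in 50–1,000 bp, 20 % in 1,001–5,000 bp, 10 % in 5,001–10,000 bp), and
start positions uniformly along the chromosome, rejecting placements closer
than `min_gap_bp` (default 2 × the 100 bp flank) to an existing SV; 1,000
failed attempts for one SV abort with the achieved count rather than
silently under-delivering. The 10 kb cap on the top bucket is a deliberate
resolution of an internal inconsistency in the source design (which states
both an overall 50–10,000 bp range and a top bucket nominally reaching
100 kb); the cap keeps every drawn length inside the stated overall range
and is config-overridable.

`apply_svs()` performs all edits simultaneously on original coordinates via
`Biostrings::replaceAt`: DEL removes the span, INS inserts its payload after
the anchor base, DUP appends one extra tandem copy after the span, INV
reverse-complements the span in place. Truth coordinates are reported on the
*original* reference — the frame a caller benchmarked against that reference
sees. Insertion payloads default to uniform random A/C/G/T; passing an
`is_library` draws a family consensus instead, emulating IS-mediated
insertion. The test suite verifies reconstruction: independently re-applying
the emitted truth with naive string splicing reproduces the mutated genome
byte-for-byte across randomized configurations.

Breakpoint-flanking noise emulates the small variants that confound
short-read SV detection near junctions: each ±100 bp flank of each junction
independently receives one substitution with probability 0.001 and one indel
(1–20 bp, insertion or deletion) with probability 0.0005, never more than
one indel per flank and never inside another SV's span. The probabilities
are interpreted *per flank* — the only reading consistent with the
at-most-one-indel-per-flank rule — rather than as per-genome totals, which
the source description leaves ambiguous.

# Benchmarking

A call validates a truth record when three conditions hold: identical type;
start within ±30 bp (inclusive); length within 30 % of the *truth* length
(inclusive). Assignment is one-to-one — each unmatched call is exactly one
false positive — using a greedy pass over eligible pairs ordered by smallest
start difference, then smallest relative length difference, then earlier
call position. Greedy was preferred to optimal bipartite matching because
the matching rule is defined per record, not as a global objective; the test
suite compares greedy against exhaustive maximum matching on thousands of
small random instances, asserting equality whenever eligibility is
conflict-free and `greedy ≤ optimal` otherwise. How double-eligibility was
resolved in the original analyses is unstated; the tie-break here is this
package's convention.

# The filter cascade

Real MA candidate lists pass through, in default order: ancestor subtraction
(calls matching any ancestor call under the benchmark tolerances are
removed), imprecise-call removal, and a recurrence filter that single-links
calls across lines under the same tolerances and removes every cluster
touching ≥ 3 distinct lines — recurrent candidates are systematic artifacts
of the reference or caller, not independent mutations. Tolerant (rather than
exact-coordinate) recurrence comparison is a package choice: long-read
callers jitter breakpoints, and single-linkage keeps the rule conservative.
Platform merging keeps the long-read record as representative when a
short-read call matches it, concatenating provenance; long-read breakpoints
are the more reliable. Sanger-style validation is deliberately *strict*
(< 100 bp start difference, < 30 % length difference), whereas benchmarking
is inclusive (≤) — both as printed in the protocols they implement. Each
filter is idempotent and only removes or merges, never fabricates.

# IS-element attribution

No operational attribution rule is published for the analyses this package
models (they inherit junction evidence from a short-read pipeline), so
`classify_sv()` defines a self-contained, reproducible one: an insertion is
IS-mediated when its payload matches a family consensus at ≥ 0.90 ungapped
identity over ≥ 0.80 of the consensus length, sliding on both strands; a
span SV is IS-mediated when it covers ≥ 0.80 of an annotated reference copy.
Ungapped comparison suffices because bacterial IS copies are short
(~0.7–1.5 kb) and near-exact; `align_fun` is a hook for plugging in a gapped
aligner if needed. Payload-less insertions fall back to breakpoint proximity
(≤ 10 bp of a copy edge) and are flagged low-confidence. Family activity
summaries keep zero-count families, and `copy_number_correlation()` reports
both Pearson and Spearman statistics, since the published correlation figure
does not name its statistic.

# The synthetic MA generator

`generate_experiment()` produces what the cascade and estimators assume:
per-line true SV counts ~ Poisson(rate × T) at uniform positions with an
insertion-dominated type mixture (60/30/5/5 over INS/DEL/DUP/INV, matching
the qualitative spectrum of bacterial MA lines); ancestor variants injected
identically into every descendant line (the biological situation motivating
ancestor subtraction); shared false positives injected into 5 lines
(modelling reference artifacts, the rationale for the ≥ 3-line filter); and
a caller model with 2 % false negatives, 0.2 expected random false positives
per line, rounded-Normal breakpoint jitter (SD 5 bp, truncated at ±3 SD so
tolerance guarantees are provable), ±5 % length noise, and 5 % imprecise
flags. Jitter truncation means every surviving call stays inside the ±30 bp
tolerance whenever SD ≤ 10, which the suite asserts.

What the generator does *not* emulate: read-level sequencing error,
alignment ambiguity in repeats, caller-specific biases (e.g. the poor
insertion precision of long-read callers), selection or lineage death, and
clustered/nested SVs. Passing recovery tests therefore demonstrates the
correctness of the filtering and estimation arithmetic under the stated
statistical model, not the performance of any sequencing pipeline on real
data.

`run_recovery()` applies the cascade, benchmarks surviving calls per line
against that line's truth, and feeds the summed true positives to
`rate_per_genome`. Imprecise calls are *kept* for rate counting by default
(an imprecise breakpoint still witnesses a real event); dropping them mimics
the pre-validation triage and biases the estimate down by roughly the
imprecise fraction.

# Problem sizes and numerical choices

The test suite runs on genomes of 15–60 kb with up to a dozen SVs per trial
(100 reconstruction trials), 1,000 matcher fuzz instances of ≤ 8×8, and 200
synthetic MA experiments of 50 lines × 4,000 divisions at a true rate of
3×10⁻⁴ — sizes at which every property is exercised in a couple of minutes
on one CPU. The acceptance script uses the same sizes. Other conventions:
SV tables are plain data.frames validated by invariant checks; ties in
family attribution break by higher identity then lexicographic name;
chi-square uniformity tests pool bins with expected counts < 1; ratios with
zero denominators are reported as `NA`, never infinity; and every stochastic
entry point takes an explicit integer seed and is reproducible from it.

# Known limitations

* The genome is linear; origin-spanning SVs are out of scope.
* Recurrence clustering's length tolerance is measured relative to the
  earlier record in a pair, which makes single-linkage very slightly
  asymmetric at the tolerance boundary.
* The greedy matcher can fall below the optimal assignment on adversarial
  double-eligibility patterns (bounded and measured in tests, not observed
  to matter at MA densities).
* IS attribution without payloads (proximity evidence) cannot distinguish
  the mediating family when two families' copies adjoin the breakpoint.
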