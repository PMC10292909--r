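# masv

Structural-variant (SV) simulation, benchmarking, and mutation-rate
estimation for bacterial mutation-accumulation (MA) experiments.

## The problem

MA experiments propagate many parallel lines of a microbe through repeated
single-colony bottlenecks, so genetic drift — not selection — decides which
spontaneous mutations survive. Sequencing the evolved lines then yields
nearly unbiased mutation rates and spectra. Large-scale structural variants
(insertions, deletions, tandem duplications, inversions, most of them
mediated by insertion-sequence (IS) elements) are the hardest class to
measure: callers disagree on breakpoints, false positives are common, and
candidate lists must be filtered against the ancestor, recurrent artifacts,
and imprecise calls before any rate can be trusted.

`masv` implements that computational core for *E. coli*-scale genomes:

* **svsim** — implant known SVs into a reference genome (uniform
  breakpoints; a 70/20/10 length mixture over 50–1,000 / 1,001–5,000 /
  5,001–10,000 bp; BPS/indel noise confined to ±100 bp of each breakpoint)
  and emit the mutated FASTA plus a truth set on original coordinates.
* **benchmark** — match calls to truth one-to-one under the field's
  three-condition rule (same type; start within ±30 bp; length within 30 %
  of the truth length) and compute
  sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
  F1 = 2·sens·prec/(sens+prec).
* **ma_filter** — the candidate cascade: ancestor subtraction, imprecise-call
  removal, removal of SVs recurring in ≥ 3 lines, short/long-read platform
  merging, and strict (<100 bp, <30 %) Sanger-style validation.
* **rates** — the MA estimator μ = m / (Σᵢ Nᵢ · T) with N ≡ 1 for per-genome
  rates and T = transfers × log₂(CFU) cell divisions per line, with exact
  (Garwood) Poisson 95 % CIs from chi-square quantiles.
* **is_elements** — classify SVs as IS-mediated (sequence identity for
  insertions, copy overlap for span SVs), summarize per-family activity, and
  correlate activity with reference copy number.
* **synthetic_ma** — generate complete mock MA experiments (Poisson SV
  counts per line, ancestor-inherited variants, caller jitter/FN/FP model,
  shared artifacts) for end-to-end testing with known ground truth.

## Worked example

```r
library(masv)

# per-genome SV rate of 67 wild-type lines, 4,480 divisions each, 83 SVs
rate_per_genome(83, 67, 4480)
#> <rate_estimate> m=83 over 3.0016e+05: rate 0.000277 (95% CI 0.00022-0.000343)

# i.e. 2.77e-4 SVs per genome per cell division; the CI is the exact
# Poisson interval on the count, divided by n_lines * T.

# simulate a genome with 20 deletions and benchmark a jittered call set
set.seed(42)
ref <- reference_genome("demo",
  paste(sample(c("A", "C", "G", "T"), 200000, TRUE), collapse = ""))
cfg <- sim_config(n_per_type = c(DEL = 20),
                  length_buckets = data.frame(lo = 50L, hi = 2000L,
                                              weight = 1),
                  seed = 42)
sim <- simulate_genome(ref, cfg)
sim
#> <sim_result> 20 SVs, 1 flanking small variants; mutated genome 176874 bp (seed 42)

calls <- sv_records("demo", sim$truth$start + sample(-10:10, 20, TRUE),
                    "DEL", sim$truth$length, source = "caller")
benchmark_calls(sim$truth, calls, by_type = FALSE)
#>   stratum tp fp fn sensitivity precision f1
#> 1 overall 20  0  0           1         1  1
```

Every call sits within ±10 bp of its truth record, inside the ±30 bp
tolerance, so all 20 are true positives. The mutated genome is 176,874 bp —
the 200,000 bp reference minus 23,128 deleted bases, plus one 2 bp
breakpoint-flanking indel drawn by the noise model.

A command-line wrapper with subcommands (`simulate-genome`, `simulate-ma`,
`evaluate`, `filter-lines`, `estimate-rates`, `classify-is`, `demo`) ships
in `inst/scripts/masv`; see `?masv_cli`.

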