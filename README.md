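# p53triplex

Screening promoters for co-occurring p53 response elements and
intramolecular triplex-forming sequences, with the companion
binding-assay analyses.

## The problem

p53 binds its consensus response element (CON) — two copies of the
degenerate half-site 5'-RRRCWWGYYY-3' (R = A/G, W = A/T, Y = C/T)
separated by a short spacer — through its core domain, and binds non-B
DNA structures through its basic C-terminal domain. One such structure
is the intramolecular triplex (H-DNA): at a mirror-repeated
homopurine·homopyrimidine tract, half of one strand folds back into the
major groove of the remaining duplex, forming T.A.*T* / C.G.*C*
(pyrimidine motif) or C.G.*G* / T.A.*A* (purine motif) base triplets.
Promoters carrying *both* features are candidates for a dual p53
recognition mode.

This package is for genomics researchers who want to run that screen on
their own sequences, and for biochemists quantifying protein–DNA
binding curves. It provides:

* **Promoter windows** — strand-aware extraction of `[-5000, +2000)`
  TSS-anchored windows from FASTA + BED6/TSV inputs.
* **CON scanning** — half-site mismatch profiles, pairing under spacer
  (`s ≤ 20` bp by default, classic `0–13` available) and a shared
  mismatch budget (`≤ 1` over the 20 bp site).
* **Triplex scanning** — homopurine/homopyrimidine tract detection and
  exact mirror-repeat fold scoring: +1 per canonical triplet, −2 per
  stem mismatch, loop 4–12 nt, so a pure poly(A) tract of length *n*
  scores `floor((n − 4)/2)`; the screen threshold (score ≥ 18) is first
  reached at *n* = 40, coherent with requiring a poly(A/T) run > 40 bp.
* **The joint screen** — candidate filtering, signed CON–triplex
  distances, distance histograms, position profiles and TSV/BED reports.
* **Binding assays** — saturation-curve fitting of
  `B([P]) = Bmax·[P]/(Kd + [P])` (hyperbolic) and
  `B([P]) = Bmax·[P]^n/(Kd^n + [P]^n)` (Hill) via multi-start
  Levenberg–Marquardt, returning a classed fit object with
  `print/summary/coef/predict/residuals/plot/simulate` methods; EMSA
  fraction-bound, competition relative-affinity and salt-series
  containers.
* **Synthetic data** — motif-free background with planted CON sites,
  tracts and decoys plus an independent truth table, and simulated noisy
  binding curves, so the whole pipeline is testable offline.

## Worked example

```r
library(p53triplex)

## fit a simulated ELISA saturation curve (0.1-90 nM, 3 replicates)
cv <- generate_binding_curve(kd = 0.75, noise_sd = 0.03, replicates = 3,
                             seed = 1, probe = "TAT")
fit_hyperbolic(cv)
#> <kd_fit> hyperbolic model (probe TAT)
#>   Kd   = 0.758 nM (stderr 0.029)
#>   Bmax = 1.007
#>   residual sum of squares = 0.02547
```

The fitted Kd (0.758 nM) recovers the generating constant (0.75 nM)
within its standard error; Bmax ≈ 1 is the saturating response.

```r
## generate a 100-promoter synthetic set (7 qualifying + decoys) and screen it
specs <- promoter_spec_set(n = 100, n_qualifying = 7, seed = 42)
out <- generate_promoter_set(specs, "demo")
regions <- extract_windows(read_fasta(out$fasta),
                           read_tss_table(out$tss_bed, "bed6"))
scr <- screen_promoters(regions)
summary(scr)
#> Promoters screened:             100
#>   with >= 1 CON site:           70
#>   with passing triplex:         37 (37 distinct loci)
#>   joint candidates:             7
#> Candidates: G001_qualifying, ..., G007_qualifying

distance_histogram(scr)
#>   bin_start bin_end count
#> 1      2500    3000     7
```

Exactly the 7 planted qualifying promoters pass — the decoys (CON-only,
CON + (dA)20, CON + (AT)34, tract-only, mirror-A/G tract with a short
run) are all rejected — and every candidate's CON lies ~2.5–3 kb
downstream of its triplex, the geometry the generator plants.
`write_candidate_report(scr, "candidates.tsv")` writes the per-gene
table (positions TSS-relative and 1-based genomic, sorted by run length
then score).

A thin command-line front end with `extract-windows`, `scan-con`,
`scan-triplex`, `screen`, `fit-kd` and `simulate-*` subcommands is at
`inst/scripts/p53triplex-cli.R`.

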