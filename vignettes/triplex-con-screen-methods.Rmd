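---
title: "Methods: screening promoters for co-occurring p53 response elements and triplex-forming sequences"
author: "p53triplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening promoters for co-occurring p53 response elements and triplex-forming sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53triplex)
```

## The biological question

The tumour suppressor p53 is best known as a sequence-specific transcription
factor binding its consensus response element (CON): two copies of the
degenerate 10-mer 5'-RRRCWWGYYY-3' separated by a short spacer. Its basic
C-terminal DNA binding domain additionally recognises non-B DNA structures.
One such structure is the intramolecular triplex (H-DNA): at a mirror-repeated
homopurine·homopyrimidine tract under negative superhelical stress, half of
one strand can fold back into the major groove of the remaining duplex,
forming base triplets — T.A.*T* and C.G.*C* in the pyrimidine motif, C.G.*G*
and T.A.*A* in the purine motif. Promoters that carry *both* a CON and a
strong triplex-forming tract are candidates for a dual recognition mode, so
the package implements a genome-scale co-occurrence screen over TSS-anchored
promoter windows, together with the quantitative binding-assay analyses
(saturation Kd fitting, EMSA fraction-bound and competition summaries) used
to characterise protein–triplex binding in vitro.

Because a matched genome/annotation download is deliberately out of scope,
the package ships a synthetic-data generator that plants known features into
verified motif-free background, giving an exact truth table against which
every pipeline stage is validated end to end.

## Promoter windows

Windows cover the half-open relative interval `[-upstream, +downstream)`
around each TSS — by default `[-5000, +2000)`, 7000 nt, with the TSS base at
relative position 0 counting as downstream. We chose the half-open reading
(the inclusive alternative differs by one base) because it composes exactly
with BED arithmetic. Minus-strand windows take the genomic slice
`[t - downstream + 1, t + upstream + 1)` and reverse-complement it, so all
downstream analysis works in transcription orientation. Internal coordinates
are 0-based half-open throughout; human-facing TSV reports are 1-based
inclusive. `N` bases are allowed and match no motif class.

## CON scanning

A half-site match at an offset is scored by counting positions violating
their class (positions 1–3 purine, 4 = C, 5–6 = A/T, 7 = G, 8–10
pyrimidine); all ten positions weigh equally, since no position weighting is
part of the site definition used here. Full sites are ordered pairs of
half-sites with spacer `s` (end of the first 10-mer to the start of the
second) in `[0, 20]` — the stringent "< 21 bp" screen setting; the classic
0–13 bp definition is one parameter away — and a *combined* mismatch budget
of 1 by default. We read "a maximum of 1 mismatch" as a budget over the full
20 bp site, the stricter of the two possible readings; the per-half reading
is available by scanning half-sites at `max_mm = 1` and pairing with
`max_total_mismatches = 2`. A useful structural fact, asserted as a property
test: RRRCWWGYYY is its own reverse complement, so a single-strand scan finds
every site on either strand at the same locus. Overlapping sites are all
reported; collapsing is left to consumers.

## Triplex detection and the stand-in scoring scheme

Detection proceeds in two stages. First, maximal homopurine (A/G) tracts of
at least 15 nt containing at most one non-conforming base are located by a
greedy left-to-right merge of conforming runs (pyrimidine tracts are found
symmetrically and reported as purine tracts on the complementary strand);
tract ends always conform, and after emitting a tract the scan resumes after
the first interruption consumed so overlapping tracts sharing a suffix are
both found. Second, every fold of the tract's purine-strand view is scored:
an innermost stem pair `(i, j)` leaving a loop of 4–12 nt is extended
outward; at depth `d` the triplet formed by the duplex base at `i - d` and
the fold-back third-strand base derived from `j + d` is canonical iff the
two tract bases are identical purines (the mirror-repeat criterion), worth
+1, else a stem mismatch at −2. Insertions in the stems are not modelled:
the hits of interest are uninterrupted A/T tracts, for which gaps only lose
score. Ties are broken by shorter loop, then leftmost first stem; the
pyrimidine motif label is reported, since the purine-motif fold of the same
geometry scores identically under mirror identity and duplicate hits would
be noise.

The +1/−2/loop-4–12 scheme is this package's own calibrated stand-in for
triplex-potential scoring, not a re-implementation of any published
scorer's internals. The calibration argument: a pure poly(A) tract of
length *n* folds with a minimal 4 nt loop into two stems of
`floor((n - 4)/2)` triplets, so the screen's score threshold of 18 is first
reached at *n* = 40 — exactly where the companion filter "poly(A/T) run
longer than 40 bp" starts to pass. The two printed thresholds are thus
mutually consistent under this scheme, which is the property the screen
depends on; identity to any external default scheme is not claimed. The
scorer is verified against exhaustive enumeration of every
(innermost pair, loop, stem length) on hundreds of random tracts.

```{r thresholds}
vapply(c(20, 39, 40, 50), function(n) score_fold(strrep("A", n))$score,
       numeric(1))
```

## The joint screen

A promoter passes when it has at least one CON site, its best fold scores at
least 18, and that hit's longest poly(A)/poly(T) run exceeds 40 nt. The best
hit is chosen by score, then run length, then position; per-hit score
thresholding with promoter-best reporting resolves the ambiguity of whether
the threshold applies per hit or per promoter. CON–triplex distances are
midpoint-to-midpoint (symmetric and robust to feature length; start-to-start
is available by flag), signed positive when the CON lies downstream of the
triplex. Distance histograms use half-open bins `[k·w, (k+1)·w)` so bin
edges are deterministic and counts conserve pairs. Enrichment statistics
against external databases are out of scope; the report is descriptive.

## Binding-assay analyses

Saturation curves (response vs protein concentration over a 0.1–90 nM
assay range) are fitted by unweighted least squares on pooled replicates —
matching common plate-reader practice, since no weighting scheme is implied
by replicate measurement alone — with the hyperbolic model
\(B([P]) = B_{max}[P]/(K_d + [P])\) or the Hill model
\(B([P]) = B_{max}[P]^n/(K_d^n + [P]^n)\), \(n \in (0, 6]\). The two models
are reported side by side; no automatic selection is attempted. The
optimiser is Levenberg–Marquardt (`minpack.lm::nlsLM`) with three Kd starts
(grid minimum, geometric mean, maximum); the best converged start wins and
failure of all starts is a hard error. `stderr_Kd` comes from the curvature
at the optimum. Blank subtraction is the caller's responsibility; a constant
offset can optionally be co-estimated. EMSA percent bound derives from
depletion of the free-DNA band relative to the no-protein lane (clamped to
[0, 100]); the competition relative-affinity index is the mean relative
complex-band intensity over non-zero competitor amounts, so lower means a
stronger competitor.

```{r kd}
cv <- generate_binding_curve(kd = 0.75, noise_sd = 0.03, replicates = 3,
                             seed = 1, probe = "TAT")
fit_hyperbolic(cv)
```

## What the synthetic generator emulates — and what it does not

`generate_background()` draws i.i.d. bases at a chosen GC content
(default 0.5) and locally redraws until the sequence contains no half-site
within 1 mismatch, no 15+ nt tract with at most one interruption, and no
10+ nt poly(A)/poly(T) run — bounds strictly tighter than the scanners'
reporting minima, so background contributes exactly zero hits.
`plant_features()` substitutes (never inserts) CON sites, poly(A)/poly(T)
tracts, mirror A/G tracts and alternating (AT)m decoys; planted tracts are
shielded by two guard bases of the opposite class on each side so neither
the run nor the tract can extend into background, and junction windows are
re-verified and locally redrawn. Truth flags are computed from the planted
parameters alone via the closed-form `floor((n - loop_min)/2)` fold score —
independent of the scanner code, so the end-to-end exactness tests are not
circular. One global seed fans out to per-promoter seeds as
`(seed · 1009 + 7919 · i) mod (2^31 − 1)`, giving reproducible yet
independent streams. The default validation set is 100 promoters with 7
qualifying and systematic decoys (CON-only, CON + (dA)20, CON + (AT)34,
tract-only, CON + mirror-A/G-50, pure background), a size at which the whole
round trip (files included) runs in seconds while exercising both strands
and every decoy class.

The generator emulates *composition*, not genomic context: real promoters
have CpG islands, repeats, nucleosome-shaped base composition and many
near-threshold motifs, and real triplex formation depends on superhelical
energy the sequence alone cannot encode. Passing the planted-truth tests
therefore demonstrates correctness of the scanning arithmetic under the
stated definitions — not that the screen's genome-wide yield on a real
annotation would be reproduced. Simulated ELISA curves use Gaussian noise
(sd 0.03 on a unit Bmax, 12-point log grid, 3 replicates), a reasonable
plate-reader model but not a claim about the real assay's error structure.

## Numerical choices and limitations

Degenerate inputs fail loudly: constant responses, too-few concentrations,
tracts shorter than `loop_min + 2`, zero reference band intensity. The
fold scorer is exact but quadratic in tract length; tracts beyond a few
hundred nt (far beyond promoter reality) would be slow. Scores of the
stand-in scheme are comparable only within this package. The screen reports
both promoter-level and locus-level triplex counts, since "sequences
carrying a hit" admits both readings. Validation problem sizes (50
simulations per Kd constant; 200 random tracts for the oracle; 20 seeds of
the 100-promoter set) were chosen as the smallest sets that exercise every
code path with stable statistics.
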