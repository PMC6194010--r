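---
title: "Methods: from gas curves to 13C-labeled OTUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gas curves to 13C-labeled OTUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorosip)
```

`chlorosip` implements the analysis chain of a DNA stable-isotope
probing (SIP) experiment on a trace-gas sink: first-order gas-consumption
kinetics, pulse-amendment carbon budgeting, amplicon OTU processing, the
multi-criterion caller that decides which OTUs assimilated the
¹³C-labeled substrate, and diversity summaries. This vignette explains
the models, the defaults and the numerical decisions, and what the
synthetic-data tests do and do not demonstrate.

## First-order kinetics

A microbially consumed headspace gas with consumption proportional to
its concentration follows $c(t) = c_0 e^{-kt}$. We estimate $k$
(h⁻¹) by ordinary least squares of $\ln c$ on $t$ rather than by
nonlinear least squares: the log-linear model is exact for first-order
decay, its single assumption (homoscedastic multiplicative error) is
transparent, and it has no initialization or convergence concerns.
Under multiplicative lognormal measurement error — the natural error
model for gas-chromatographic quantification — log-linear OLS is also
exactly unbiased in the noise-free limit, which is why the synthetic
generator uses that noise model.

Numerical decisions:

* Points at or below the detection limit are **excluded, not imputed**.
  Imputing the floor (or half of it) biases the slope when the curve
  runs into the instrument floor; exclusion only costs degrees of
  freedom. At least 3 usable points are required.
* A constant series has zero variance in $\ln c$; the fit then reports
  $k = 0$ exactly, flags itself degenerate and sets $r^2$ to `NA`
  instead of returning the numerically meaningless ratio 0/0.
* `classify_sink()` calls a vessel biotic when
  $k_\mathrm{substrate} \ge k_\min$ **and**
  $k_\mathrm{substrate} > r \cdot k_\mathrm{KCN}$, with defaults
  $k_\min = 0.05$ h⁻¹ and $r = 3$. The experimental literature
  compares controls qualitatively (no consumption under cyanide, none
  under anoxia); the two numeric knobs make that comparison explicit
  and are deliberately conservative: a killed control must be at least
  threefold slower before biology is credited.
* `chamber_net_flux()` judges decline/rise on the OLS slope divided by
  the series mean, with tolerance 10⁻³ h⁻¹; an unspiked chamber whose
  values never reach 1 ppb reports "no net emission" without any slope
  test.

Replicate vessels are fitted independently; pooling replicate points
into one regression would understate between-vessel variance.

## Carbon budget

The amendment design (`amendment_schedules()`) mirrors an
eight-treatment SIP setup: four ¹³C treatments and their unlabeled
mirrors plus an unamended control, 18 mM carbon per pulse per substrate
(36 mM for dual-substrate treatments), 5 pulses over 23 days, DNA
harvested after pulse 3. Mineralized percentage is
$100 \cdot \mathrm{^{13}CO_2} / \mathrm{added}$; assimilated is its
complement, so the two always sum to 100. An optional loss term
(e.g. carbonate precipitation) turns the assimilated figure into an
explicit upper bound. Headline values can be rounded to the nearest
10 % on request, but comparisons and stored values are never rounded
internally — rounding first would create threshold artifacts.
Henry's-law partitioning and isotope fractionation are out of scope.

## Amplicon processing

Length filters are marker-aware: 16S keeps the closed interval
420–460 nt (the boundaries survive, by negation of the strict
discard inequalities); functional genes keep reads within 20 nt of the
expected amplicon length (cmuA 422, mxaF/xoxF 430). The
global-singleton rule removes a unique sequence only when its total
count across **all** libraries is one; a sequence occurring once in two
different libraries is kept in both.

One transparent clustering algorithm — abundance-greedy centroid
clustering — serves all markers, in place of the mixed toolchains
(Mothur, USEARCH) such studies typically combine; one algorithm keeps
desk-scale behavior reproducible and testable. Determinism is
guaranteed by a total order: sequences are visited by decreasing total
abundance with lexicographic record-id tie-break, so permuting the
input cannot change membership. Pairwise identity is the fraction of
identical aligned columns from a global alignment with terminal gaps
excluded (ends-free), scored +1/−1/−2 for match/mismatch/gap; the
amplicon literature rarely defines "identity" precisely, and this
matches common tool semantics. IUPAC ambiguity codes (and inosine)
match any compatible base. For equal-length sequences the optimal
alignment under this scoring is gap-free (a gap pair costs −4 against
−1 for a mismatch), so the implementation uses a direct column
comparison there and Biostrings' ends-free alignment otherwise.

`cutoff_scan()` implements iterative cutoff selection: cluster at each
cutoff of a descending list and select the **highest** cutoff whose OTU
count changes by at most `stability_delta` (default 0) at the next
step; a curve that never stabilizes returns the lowest cutoff with a
`stabilized = FALSE` flag rather than guessing. Preclustering distance
is substitution-only on equal lengths (alignment-based otherwise); the
"2 nucleotide differences" convention predates explicit indel handling.
Chimera removal and taxonomy assignment require external reference
databases and are accepted as externally produced flags/labels
(`summarize_by_taxon()` takes a taxonomy map as input).

## The labeling caller

For each ¹³C treatment and its paired ¹²C control the caller pools
replicate libraries by summing counts (duplicate microcosm gradient
fractions are conventionally pooled before sequencing anyway), computes
relative abundances for the four fraction libraries, and applies:

| criterion | test | comparison |
|---|---|---|
| 1 | relAb(H,¹³C) > relAb(H,¹²C) | strict |
| 2 | relAb(H,¹³C) > relAb(L,¹³C) | strict |
| 3 | relAb(H,¹³C) ≥ 0.5 % | inclusive |
| 4 | relAb(H,¹³C) − relAb(L,¹³C) ≥ 0.3 % | inclusive |

plus LP ≥ 5 %, where LP renormalizes relAb(H,¹³C) over the
criterion-passing candidate set. Strict-versus-inclusive follows the
protocol wording exactly ("higher than" vs "at least"). All
comparisons run on exact count ratios, never on rounded percentages.

Two genuinely open design points, and the choices made:

* **LP denominator.** "Relative frequency of a labeled OTU in a
  specific heavy fraction" admits two readings. Against the whole
  library, the 5 % rule would dominate the 0.5 % abundance floor and
  make criterion 3 redundant; renormalizing over the candidate set
  keeps both thresholds meaningful and matches stacked-percentage
  presentations of labeled communities. The whole-library variant
  remains available via `lp_denominator = "library"`.
* **The 0.3 % margin** is described as accounting for per-OTU abundance
  variance, but no variance model accompanies it; it is implemented as
  a plain constant threshold, configurable in
  `labeling_thresholds()`.

Useful consequences, verified as property tests: calls are invariant to
per-library depth scaling; increasing an OTU's heavy-fraction count can
never flip that OTU from labeled to unlabeled (its own abundance, gap
and LP all move monotonically in its favor); and LP sums to 100 over
each library's candidate set.

## Diversity

`diversity_summary()` reports observed richness, Shannon entropy in
nats (the Mothur convention; base configurable) and Simpson diversity
as the inverse Simpson index $1/\sum p_i^2$ — the "effective number of
phylotypes" reading — with Gini–Simpson ($1-\sum p_i^2$) behind a
flag. Index arithmetic is delegated to vegan. No rarefaction or
coverage correction is applied; fraction libraries being compared are
generated (and, in practice, sequenced) at comparable depth.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the study's data: exponential
dissipation with multiplicative lognormal GC noise; pulse-wise
cumulative CO₂ whose increments (not totals) carry noise, preserving
monotonicity; and H/L-fraction count tables in which planted labeled
OTUs are enriched `enrichment_factor`-fold in the heavy fraction of
¹³C treatments while ¹²C-control heavy fractions mirror light
fractions, with multinomial sampling at fixed depth. Defaults encode
the study conditions: duplicate microcosms, 3 planted labeled OTUs of
20 at 5 % base abundance, 10-fold enrichment, mineralized fraction
0.2, 5 % gas noise over 12 samplings. Per-library read depth is not
reported in such studies; 10⁵ is used as a realistic MiSeq-scale
default. All draws descend from one integer seed through the
documented splitting scheme in `split_seed()`.

Deliberately **not** modeled: sequencing error beyond length jitter,
chimeras, PCR and primer bias, compositional correlation between OTUs
(multinomial sampling is the simplest model consistent with
proportion-based criteria), partial ¹³C incorporation and gradient
density smearing, and between-replicate biological variance beyond
multinomial noise. Passing the recovery suites therefore shows that
the chain is *correct* — criteria implemented as stated, estimators
unbiased under the stated noise — not that it is robust to every
artifact of real gradient sequencing data; on real data the 0.3 %
margin and the ¹²C control carry that burden.

## Problem sizes and runtime

The validation suites run at desk scale by design: rate-constant
recovery over $k \in \{0.1, 0.5, 1, 3, 7\}$ h⁻¹ with 200 noisy
replicates each (12 points per curve, sampled over two e-folding times
so that the design matrix is equally informative at every rate);
caller-versus-oracle agreement on 1000 random tables of up to 10 OTUs;
planted-truth recovery on 100 datasets of 20 OTUs at depth 10⁵;
clustering fixtures of a few hundred reads. These sizes give stable
statistics (binomial SE on a 1000-table agreement rate is ~0.3 %)
while keeping the whole suite in seconds.

## Known limitations

* The greedy centroid clusterer is quadratic in unique sequences per
  centroid comparison; it targets desk-scale validation and moderate
  libraries, not million-read production runs.
* `classify_sink()`'s $k_\min$ and ratio are conventions, not
  estimates; with noisy controls a formal test on the two slopes would
  be preferable.
* Quantitative SIP (density-shift estimation, isotope-incorporation
  percentages) is out of scope; the caller is deliberately the
  threshold protocol, no more.
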