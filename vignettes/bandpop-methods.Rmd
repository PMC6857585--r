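---
title: "Models and methods behind bandpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bandpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandpop)
```

`bandpop` analyses dominant-marker data: binary accession × band matrices in
which heterozygotes and dominant homozygotes are indistinguishable, as is
standard for SSR bands scored on gels in polyploids where allele dosage
cannot be called. This vignette documents the statistical conventions the
package commits to, the reasoning where a convention had to be chosen, the
design of the synthetic-data generator, and what the test suite does and
does not establish.

## The data model

A `band_matrix` holds values in {0, 1, NA} with every band assigned to
exactly one primer and every primer to a class label (EST-SSR / G-SSR).
Band frequency is computed over scored accessions only: missing cells are
excluded from both numerator and denominator. A band is *polymorphic* when
its frequency lies strictly between 0.05 and 0.95; the boundaries are
deliberately non-polymorphic so that the rule is deterministic at the edge.

## Marker informativeness conventions

For a dominant band with phenotype frequency $p$:

* **PIC** uses the raw phenotype frequency: $\mathrm{PIC} = 1 - p^2 - (1-p)^2
  = 2p(1-p)$, bounded by 0.5.
* **H** (Nei's gene diversity) and **I** (Shannon index) use Hardy–Weinberg
  allele frequencies $\hat q = \sqrt{1-p}$ (null allele), $\hat p = 1-\hat
  q$: $H = 2\hat p\hat q$, $I = -\hat p\ln\hat p - \hat q\ln\hat q$.
* Per-primer PIC, H and I are **averaged over the primer's polymorphic bands
  only**; MI = PIC × NPB; Rp sums $I_b = 1 - 2|0.5-p|$ over the polymorphic
  bands.

This mixed convention is the only one consistent with published per-primer
tables of this kind: a primer with a single polymorphic band at frequency
2/25 yields PIC 0.147 but H 0.078 and I 0.171 — values that can only
coexist if PIC is phenotype-based while H and I are HWE-allele-based, and
only if monomorphic bands are excluded from the averages. The test suite
verifies this reconstruction from an exact-frequency fixture. Note the
consequence: H peaks at band frequency 0.75 (where $\hat p = \hat q = 0.5$),
not at 0.5 like PIC.

The class contrast of PIC between EST-SSR and G-SSR primers uses a
two-sided Wilcoxon rank-sum test: exact when both classes have at most 8
primers and no ties, otherwise the normal approximation with midrank ties
and **no continuity correction** (the asymptotic convention of the major
commercial statistics packages, which dominant-marker studies typically
report). The variant used is recorded in the result object.

Panel-level Pearson correlations are computed across primers as the units,
pairwise-complete, with zero-variance metrics reported as `NA` rather
than 0. Correlations of per-band statistics over individual bands are a
different quantity (PIC and I correlate only weakly across bands because
their maxima sit at different frequencies); `bandpop` reports the
primer-level version.

## Similarity, trees, ordination

Dice similarity $GS = 2a/(2a+b+c)$ is computed over pairwise-complete
positions; two all-absent profiles are defined identical ($GS = 1$), the
least surprising completion of the 0/0 case. Distance is $1 - GS$, a
semimetric in [0, 1].

UPGMA uses average linkage with the usual size-weighted update. Tie-breaking
is delegated to the (deterministic, platform-stable) agglomeration order of
`stats::hclust`; with continuous similarities ties have probability zero and
the tests verify equality with a brute-force $O(n^3)$ reference. Node depths
follow the ultrametric convention of half the merge distance, so the
cophenetic distance between two leaves equals their merge distance. Clade
cutting at mean similarity $s$ keeps together exactly the leaves whose
cophenetic distance is below $1 - s$.

Bootstrap supports resample bands (columns) with replacement and count, for
each internal **unrooted split** of the original tree, the percentage of
replicate trees containing it. Splits rather than rooted clades, because the
UPGMA root is an artifact of ultrametricity.

PCoA double-centres $-\tfrac12 d^2$ and eigendecomposes. Because $1 -
\mathrm{Dice}$ need not be Euclidean, negative eigenvalues can occur; they
are reported but excluded from the percent-variance denominator, and no
Cailliez/Lingoes correction is applied by default (both available via
`correction =`), matching the uncorrected axes that the field's standard
tools report.

## AMOVA and group statistics

AMOVA is the non-hierarchical (two-level) form on squared Euclidean
distances between band vectors: $SS_{total} = \frac1N\sum_{i<j} d^2_{ij}$,
$SS_{within} = \sum_g \frac1{n_g}\sum_{i<j \in g} d^2_{ij}$, with the
among-groups variance component $V_a = (MS_{among} - MS_{within})/n_0$,
$n_0 = (N - \sum n_g^2/N)/(k-1)$. PhiPT $= V_a/(V_a+V_w)$ with negative
$V_a$ estimates reported as-is but floored at zero inside PhiPT and the
percentage split, standard AMOVA practice that avoids negative-PhiPT
artifacts. The permutation test shuffles accession group labels and uses the
+1-corrected p-value $(\#\{\Phi^* \ge \Phi\}+1)/(B+1)$, so p is never
exactly zero. The permutation statistic is the *unfloored*
variance-component ratio: flooring both the observed and permuted values
would create an atom of p-values at 1 under the null (any dataset with a
negative $V_a$ estimate would tie with every permutation), whereas the raw
ratio keeps null p-values approximately uniform — a property the test suite
checks by simulation. By default AMOVA runs on polymorphic bands (switchable),
since monomorphic bands contribute nothing to any distance.

Per-group indices transform within-group band frequencies to HWE allele
frequencies, then: $N_e = 1/(\hat p^2 + \hat q^2)$, $H_e = 2\hat p\hat q$,
$uH_e = H_e \cdot 2n/(2n-1)$, with means ± standard errors over bands.
$N_a$ follows an explicit phenotype-segregation rule — 2 iff the band
segregates within the group, else 1. Published $N_a$/$N_e$ values from
binary data depend on unstated tool-internal conventions and cannot be
reproduced exactly from any simple rule; `bandpop` therefore documents its
own rule and treats such printed values as non-binding, while the $uH_e/H_e
= 2n/(2n-1)$ identity is exact and is asserted in the tests.

Nei's group distance uses the 1972 uncorrected formulation on the HWE allele
frequencies, with the $J$ terms averaged arithmetically over bands — the
common default when a study names "Nei's genetic distance" without a
variant.

## The admixture model

The sampler treats each band as a haploid biallelic locus: $z_{ib} \sim
\mathrm{Cat}(q_i)$, $x_{ib}\mid z \sim \mathrm{Bern}(f_{z b})$, with
conjugate updates $f_{kb}\mid z \sim \mathrm{Beta}(1+\text{ones},
1+\text{zeros})$ and $q_i \mid z \sim \mathrm{Dir}(\alpha + \text{counts})$.
This is a deliberate simplification of the recessive-allele dominant model:
it is conjugate, fast, and standard for band matrices, but it interprets
band frequencies as haploid allele frequencies, so admixture proportions are
estimates of band-profile ancestry rather than of diploid genome fractions.
The Dirichlet concentration is fixed at $\alpha = 1$ (no hyperprior update),
removing a tuning loop; it is configurable.

$\ln P(D)$ is the usual proxy: mean per-sweep mixture log-likelihood minus
half its variance over kept sweeps. Evanno's $\Delta K = |L''(K)|/s_K$ is
computed from the per-K means over runs, undefined at the endpoints of the
scanned range; a zero run-to-run standard deviation flags $\Delta K$ as
infinite and removes that K from the argmax with a warning, rather than
silently electing it.

Default sampler sizes are 2,000 burn-in + 10,000 sweeps thinned by 10 —
desk-scale settings; studies typically run 50,000/100,000, available via the
arguments. Run-to-run label alignment for reporting uses greedy matching of
membership columns by correlation; it relabels only and never changes
$\ln P(D)$. Within-chain label switching is not corrected; with structured
data it is rare at these chain lengths, and the validation test uses
label-invariant co-assignment probabilities precisely so that it does not
depend on this.

## Landscape tests

Geographic distances are haversine on a 6371.0 km sphere (the cross-check
against the spherical law of cosines agrees within 0.5%). Environmental
distances are absolute differences of one variable. The Mantel statistic is
the Pearson correlation of upper-triangle entries, tested by jointly
permuting rows/columns of the second matrix (999 permutations by default,
+1-corrected p). The default tail is **upper**: isolation-by-distance
hypotheses are directional. A two-sided option exists. Group scopes smaller
than 4 accessions are reported as unavailable rather than tested — with
3 accessions a Mantel test has 3 distances and 6 permutations, and no
sensible null.

## The synthetic-data generator

`simulate_bands()` draws, per band, an ancestral frequency $\pi_b \sim
\mathrm{Beta}(1.2, 1.8)$ (wide, slightly rare-skewed, spanning near-fixed to
balanced bands), then group frequencies from the Balding–Nichols
parameterization $\mathrm{Beta}(\pi(1-F)/F,\,(1-\pi)(1-F)/F)$ so that a
single interpretable knob $F$ sets the expected differentiation, then
Bernoulli band presences (haploid coding by default; a dominant-diploid
coding, presence iff at least one dominant allele under HWE, via
`coding = "dominant"`). Optional layers: Dirichlet admixture of group
frequencies, a latitude-coupled logit drift producing isolation by distance,
per-group environmental means with Gaussian noise, and uniform missingness.

Defaults emulate the motivating study design: 3 groups of 13/9/3
accessions, 35 primers (30 EST-SSR / 5 G-SSR) with 4–11 bands each
(≈260 bands), $F = 0.2$, coordinates and environmental means chosen once to
resemble western-China collection sites (Xinjiang vs. the eastern
Qinghai-Tibet Plateau: latitude 44°/32°/36°, altitudes 1.2/3.4/2.9 km,
annual precipitation 300/700/550 mm).

What the generator does **not** emulate: linkage between bands of one
primer, coalescent genealogies, mutation processes, scoring error
correlated within gels, and the empirical size distribution of real primer
panels. Tests passing on synthetic data therefore establish the estimators'
statistical behaviour under the stated model, not robustness to those
real-data features.

## Numerical and testing choices

* Exact-frequency fixtures (`band_matrix_from_frequencies()`) place
  presences deterministically, so published per-primer rows can be
  reproduced bit-for-bit from their inverted band frequencies.
* Permutation p-values always carry the +1 correction; permutation and
  sampler randomness is fully seed-controlled, and the pipeline derives
  per-stage substreams from one master seed by fixed offsets so that
  toggling a stage does not shift another's draws.
* Sums of squares are validated against an independent deviation-based
  computation; UPGMA against a brute-force reference; the Gibbs sampler
  against exhaustive enumeration of all latent configurations on a 3 × 4
  instance; Mantel's type-I error by simulation (200 independent pairs,
  n = 15, 199 permutations); and ΔK recovery on a 3-population simulation
  at $F = 0.35$ with 10 accessions per group, ≈120 bands, scanned over
  K = 2–5 with 3 runs of 1,500 sweeps — problem sizes chosen so the full
  suite runs comfortably on one CPU.
* The `cut_clades` threshold semantics, the strict 5–95% polymorphism
  boundaries, and the all-absent Dice convention are all edge cases with
  dedicated tests, because each was a genuinely open reading.

## Known limitations

* $N_a$/$N_e$ follow the package's documented rule, not any specific
  legacy tool's internal convention.
* The admixture model ignores dominance when interpreting band
  frequencies (see above); for strongly dominant-diploid data the
  `coding = "dominant"` generator option exists to probe the consequences.
* CLUMPP-style multi-run consensus is reduced to greedy column matching.
* Mantel tests are marginal only: no partial Mantel or multiple-matrix
  regression, so geography/environment confounding cannot be separated.
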