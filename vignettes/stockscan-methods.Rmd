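---
title: "Selection scans, directional introgression and isolation analysis with stockscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans, directional introgression and isolation analysis with stockscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stockscan` implements a population-genomic workflow for coastal fish stocks
sampled at several sites along a latitudinal/thermal gradient: windowed
genome scans for positive selection, classification of positively selected
regions (PSRs), a shared-haplotype statistic that infers the *direction* of
introgression across a stock boundary, and an isolation-by-distance /
isolation-by-environment (IBD/IBE) regression with a multicollinearity-robust
variance decomposition. A seeded simulator generates phased haplotype panels
with planted sweeps, planted introgression tracts and a sea-surface-
temperature (SST) driven geography, so every stage can be exercised and
validated end to end without external data.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the simulation-based validation does and does not show.

## The haplotype panel and the simulator

All genetic statistics operate on a `haplotype_panel`: phased biallelic
diploid haplotypes (0/1 alleles), SNP positions per chromosome, and a
sample-to-site-to-stock assignment. Panels can be read from a phased VCF
plus a sample map, or simulated.

The simulator (`sim_config()` + `simulate_panel()`) is deliberately a
*calibratable mechanism*, not a demographic reconstruction:

- **Between-stock differentiation** follows a Balding–Nichols law: each
  SNP's ancestral frequency $p$ is drawn from a minor-allele-filtered
  neutral spectrum (density $\propto 1/p$ on $[0.05, 0.95]$, mirroring the
  usual MAF $\ge 0.05$ filter applied to resequencing panels), and each
  stock's frequency from $\mathrm{Beta}(p\theta, (1-p)\theta)$ with
  $\theta = (1-F)/F$. The `divergence` parameter $F$ *is* the expected
  per-SNP Fst; with the default $F = 0.05$ the realized genome-wide
  Weir–Cockerham estimate is within sampling error of 0.05.
- **Linkage and haplotype sharing** come from a founder-mosaic model: each
  stock owns a founder pool (default 100 haplotypes) whose per-SNP allele
  counts are set to match the stock frequency, and every sampled haplotype
  walks along the founders with a per-bp switch probability
  (`mosaic_switch_rate`, default $10^{-5}$, i.e. ~100 kb founder blocks).
  Sites within a stock share the pool, so cross-site haplotype sharing is
  common within stocks and essentially absent between stocks.
- **Sweeps** are planted post hoc: one carrier haplotype is copied over a
  tract into a fraction `carrier_freq` of the stock's haplotypes — 1.0 for
  a completed ("nearly fixed", NF) sweep, 0.5–0.9 for a partial, recent
  ("RS") sweep.
- **Introgression** replaces, in a fraction of recipient-site individuals,
  one haplotype over an exponential-length tract (truncated to a stated
  region) with a copy of a donor-stock haplotype. By default the donor
  haplotype is first made locally common in the donor stock
  (`donor_carrier_freq = 0.5` across the region): introgressed haplotypes
  that are detectable by frequency-based direction inference are, by the
  very logic of that inference, common where they came from and rare where
  they arrived. Setting `donor_carrier_freq = 0` transfers an arbitrary
  donor haplotype instead.

All randomness flows from one seed in a fixed draw order, so identical
configurations are bit-identical. What the simulator does *not* model:
bottlenecks and growth, selection acting during the simulation, missing or
erroneous genotypes, and recombination-eroded sweep edges (planted tracts
have sharp boundaries). Passing recovery tests on these panels shows the
statistics respond to the signals they target at realistic magnitudes; it
does not certify behaviour under demographic confounding.

## The selection scan

The genome is divided into 25 kb windows sliding by 5 kb (`make_windows()`;
coordinates are 0-based half-open internally and 1-based inclusive in all
emitted files; trailing windows are truncated and flagged, and excluded from
percentile thresholds by default since a 5 kb stub cannot satisfy overlap
rules and adds quantile noise). Per window, for a high-latitude stock A vs
a southern stock B:

- **Fst** — the weighted Weir–Cockerham (1984) estimator,
  $\sum_s a_s / \sum_s (a_s + b_s + c_s)$ over the window's SNPs; slightly
  negative values are retained.
- **pi and Pi** — per-bp nucleotide diversity per stock (unbiased per-site
  heterozygosity $2p(1-p)\,n/(n-1)$ summed and divided by the window span),
  and the oriented log-ratio $\Pi = \log_2(\pi_B/\pi_A)$, positive when
  diversity is depleted in A. Windows where one stock has $\pi = 0$ — the
  NF signal itself — are kept in range with a half-count floor (half the
  smallest nonzero window $\pi$); both-zero windows are NA.
- **Rsb** — per SNP, the log-ratio of site-EHH integrals
  $\ln(\mathrm{iES}_A/\mathrm{iES}_B)$. EHHS at a flanking SNP is the
  probability that two random haplotypes are identical from the core to
  that SNP, estimated without replacement; profiles are truncated below
  0.05 (no max-gap rule, since the simulator produces evenly spaced SNPs)
  and integrated trapezoidally over bp. Standardization is robust —
  $(x - \mathrm{median})/(\mathrm{IQR}/1.349)$ — rather than moment-based,
  because sweep windows make the mean/sd non-resistant; per-SNP values are
  averaged per window.
- **Tajima's D** per stock from the classical constants, and the
  **composite selection score** (CSS): each of Fst, Pi, Rsb is converted to
  fractional ranks $r_i = \mathrm{rank}_i/(n+1)$, probit-transformed, and
  averaged. CSS is therefore invariant to monotone transforms of its
  inputs; the exact weighting of published CSS variants differs between
  implementations, and the rank–probit–mean form is the documented choice
  here.

## PSR classification

Outlier sets are the strict top 5% of Fst and, for the signed indices Pi
and Rsb, the top and bottom 5% (one set per direction, attributing the
window to a stock). Two-tailed 5% per direction is the natural reading that
produces five sets; a window with directional evidence for both stocks at
once is contradictory and is dropped with a count.

A window in $\ge 2$ consistent sets becomes part of a PSR:

| evidence | class |
|---|---|
| Pi + Fst | NF (nearly fixed) |
| Pi + Rsb | RS (recently selected) |
| Fst + Rsb, no Pi | UD (undetermined) |

Windows in **all three** sets carry both the NF and the RS combination. We
resolve them by the near-fixation evidence itself: NF when the focal stock
retains less than a quarter of the comparator's window diversity
(`nf_pi_bits = 2`), RS otherwise. The rationale is empirical as well as
conceptual: a partial sweep at carrier frequency ~0.7 shifts window Fst far
above a neutral 95th percentile, so *any* rule that sends all-three windows
to NF absorbs genuine recent sweeps into the NF class, while diversity
depletion separates completed from partial sweeps cleanly (planted NF
windows sit at $\Pi > 3$, planted RS windows near $\Pi \approx 1$). Forcing
the alternative behaviours is supported via `all_three = "NF"`/`"RS"`.

Same-class adjacent windows merge into PSR intervals; classes never merge.
Genes overlapping a PSR by $\ge 1$ bp inherit its stock-by-class category
(a gene can hold several categories), with exact interval-intersection
overlap lengths. Summaries include per-category counts and lengths, a
Kolmogorov–Smirnov test of PSR midpoint uniformity along the cumulative
genome coordinate, and one-way ANOVA with least-significant-difference
pairwise t-tests (pooled mean square) of per-PSR mean CSS and Tajima's D;
categories with fewer than two PSRs are excluded and reported.

## Direction of introgression from shared haplotypes

Shared-haplotype (IBD) segments are consumed in the common detector layout
(sample1, hap1, sample2, hap2, chrom, start, end, score); for synthetic
panels a naive exact-identity detector is provided. Same-site pairs are
always filtered.

Per 25 kb/5 kb window and per stock, cSHF counts cross-site individual
pairs of that stock sharing a segment whose *overlap with the window*
exceeds 10 kb (at most one event per pair per window — counting at the
individual level matches a normalization whose maximum, 1, means "shared by
all individuals of the group"); tSHF is the stock's total cross-site pair
count (a constant per stock — the per-window alternative reading would make
nSHF a ratio of two window-varying counts and lose the 0–1 interpretation);
nSHF = cSHF/tSHF. The direction statistic is
$\mathrm{rSHF} = \log_2(\mathrm{nSHF}_A / \mathrm{nSHF}_B)$, defined only
where both sides are positive (one-sided windows are censored and flagged
rather than given infinite values, and censored windows are excluded from
correlations with a reported count). $|\mathrm{rSHF}| > 2.5$ calls an
asymmetric window; the focal-pair flag marks windows overlapped by a
segment shared between the two boundary sites.

Whether the boundary sites themselves contribute to their stocks'
cSHF/tSHF background is configurable (`include_focal_sites`); the default
excludes them — the boundary sites are the tested signal — but designs with
only two sites per stock must include them or the background pair count is
empty.

Group differences in nSHF are tested three ways (one-way ANOVA,
Kruskal–Wallis, and the Alexander–Govern approximation, implemented from
its normalizing transformation), and rSHF is correlated against the
selection indices (Pearson, Spearman, OLS $R^2$).

The validation experiment plants one-directional introgression and checks
that windows with rSHF > 2.5 dominate; the *symmetric* control introgresses
the same region in both directions — the natural null for direction
inference, under which both stocks' nSHF rise together and no asymmetric
windows should be called. (A control with two separate one-per-direction
regions conflates direction inference with the heavy-tailed variance of
summed exponential tract lengths.)

## Isolation by distance and environment

Pairwise linearised genetic distance $F_{st}/(1-F_{st})$ is regressed on
three geographic distances — great-circle (haversine, mean radius
6371.0088 km), latitudinal ($|\Delta\mathrm{lat}| \times$ 111.195 km/deg,
the mean-radius meridian constant), and a raster coastline distance — and
three SST summaries (differences in annual max, min, mean).

The coastline distance follows a diagonal-grid model: the polyline section
between the vertices nearest to the two sites (snap radius 50 km) is
rasterized onto 0.1 km cells, every cell crossed with positive length
counts once (supercover-style; corner touches have measure zero), and the
distance is $n_{\text{cells}} \times 0.1\sqrt{2}$. A straight axis-aligned
10 km path therefore measures 14.142 km, and halving the cell size changes
smooth-curve lengths by well under 5%.

SST summaries drop the five values with the largest absolute deviation
from the series median before taking max/min/mean — a guard against
recording spikes; the count is configurable since "first five outliers" is
a convention, not a statistic.

Because the geographic and thermal predictors are strongly collinear (VIFs
far above 10 are typical), single-predictor OLS fits are complemented by:

- **regularized regression** (elastic net via coordinate descent; LASSO at
  `l1_ratio = 1`; $\lambda = 0$ is solved exactly by least squares as the
  unpenalised limit; $\lambda$ by seeded 5-fold CV when unspecified), and
- **a weighted-MLR decomposition** (`mlr_decomposition()`): per predictor
  the validity coefficient $r(x_j, y)$, structure coefficient
  $r(x_j, \hat y) = \mathrm{validity}/\sqrt{R^2}$, unique coefficient
  ($R^2$ drop on removal), commonality coefficient
  ($\mathrm{validity}^2 - \mathrm{unique}$), general dominance (average
  incremental $R^2$ over subset sizes, computed from the $2^p - 1$
  all-subset $R^2$ values; equal to the average over all $p!$ orderings),
  and Johnson's relative weights (SVD orthogonal approximation). The
  identities structure = validity$/\sqrt{R^2}$, unique + commonality =
  validity$^2$, $\sum$ dominance = $\sum$ relative weights = $R^2$ hold to
  $10^{-8}$ and are tested on random collinear designs. The all-subsets
  scan refuses $p > 12$.
- **bootstrap percentile CIs** (case resampling of site pairs, default
  5000 replicates, seeded; degenerate resamples are redrawn and counted).
  Site-pair rows are not independent observations; the procedure treats
  them as exchangeable cases, which matches the standard practice this
  workflow reproduces — a Mantel-style permutation would be the stricter
  alternative and is intentionally out of scope here.

The geography generator places sites along a synthetic bending coastline,
builds monthly SST as latitudinal gradient + seasonal sinusoid +
site-idiosyncratic winter offset + noise, and draws genetic distance as
`intercept + slope * dSST_min + noise`. The winter offset (default sd
0.8 °C) matters: without it the SST minimum and mean differ only by noise
and no decomposition can tell them apart; with it, winter minima carry
site-level information — as they do in real coastal seas, where local
cold-current regimes vary between sites.

## Validation scales and numerical choices

The test suite validates every estimator against independent brute-force
oracles (variance components computed term by term, pair enumeration for
Tajima's D and EHHS, rank-sum recomputation for Kruskal–Wallis, all-
orderings general dominance) at tolerance $10^{-10}$ on exhaustive small
instances, and runs parameter-recovery experiments at desk scale: panels of
2–4 chromosomes of 2–5 Mb, 1 SNP/kb, 20 diploids per site, 20–25 seeded
replicates per experiment. These sizes keep each experiment in single-digit
minutes while leaving the planted effects (carrier frequencies 0.7/1.0,
introgression fraction 0.3 with 200 kb tracts, IBE noise at a quarter of
the signal) at magnitudes a real study would consider strong but not
extreme. Ties in outlier percentiles are handled by strict exceedance of
the type-7 quantile, so an all-equal index yields an empty outlier set
rather than an arbitrary 5%.

`scripts/acceptance.R` re-runs the full pipeline on a 104-diploid, 8-site,
3-stock cohort with one NF sweep, one RS sweep and one directional
introgression event, and writes the resulting headline quantities (mean
pairwise Fst, PSR counts per class, asymmetric window counts, the nSHF
ratio, rSHF–Rsb correlations, and the IBE decomposition) as JSON.

## Known limitations

- Sweep and introgression planting have sharp tract edges; real sweeps
  decay by recombination, which mildly inflates recovery rates here.
- The naive shared-segment detector requires exact identity and is meant
  for synthetic panels; real data should come through a dedicated IBD
  detector whose output table is ingested directly.
- Cross-stock ancestry sharing is absent by construction, so focal-pair
  windows in simulations arise only from planted introgression; in real
  data the focal window set is far larger and rSHF correspondingly
  noisier.
- Missing genotypes are not represented in the panel container; VCF
  records containing them are dropped on load.
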