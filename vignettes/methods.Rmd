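---
title: "Methods: small-world efficiency, feature integration and prediction in a two-group MRI cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world efficiency, feature integration and prediction in a two-group MRI cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`asdconnectome` implements a multiparametric analysis chain for two-group
(ASD versus typically developing) brain MRI studies: graph-theoretic
small-world efficiency of functional and structural covariance networks,
quantitative resting-state features, PCA-guided mRMR feature integration,
classification, phenotype prediction, and the accompanying group
statistics. Because raw imaging data is outside the package's scope, a
synthetic-cohort generator produces data with the statistical structure
the analysis assumes, so that every stage can be exercised, calibrated
and tested end to end. This vignette records the models, the defaults and
the design decisions.

## Connectivity networks and efficiency

Functional networks are built per subject as the Pearson correlation
matrix of ROI time courses (112 bilateral ROIs by default). Structural
covariance networks are built per *group*: the correlation, across the
subjects of one group, of regional cortical thickness (148 regions) or
supratentorial-normalized regional volumes. Matrices are binarized at a
target sparsity $s$ by keeping the $\lfloor s\,n(n-1)/2 \rfloor$ largest
**positive** weights (ties broken by lower row then column index).
Negative correlations never become edges; this is the standard convention
for binarized small-world analysis, and since thresholding is
rank-based, applying a Fisher transform first would change nothing.

On the binary graph $G$ with BFS distances $d_{ij}$,

$$E_{glob}(G) = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
  E_{loc}(G) = \frac{1}{n} \sum_i E_{glob}(G_i),$$

where $G_i$ is the subgraph induced by the neighbours of $i$ (nodes of
degree < 2 contribute 0) and $1/\infty = 0$, so disconnected pairs
contribute nothing and $E_{glob}$ stays monotone under edge additions.
These are the Latora–Marchiori definitions; note some libraries (igraph
among them) implement a *local* efficiency variant that routes paths
through the rest of the graph, which differs from the neighbour-subgraph
definition used here. Relative efficiencies divide by the mean of the
same metric over degree-matched random graphs produced by
Maslov–Sneppen double edge swaps (default $10\times$ the edge count of
accepted swaps, proposals rejected if they would create self-loops or
multi-edges). "Total" efficiency is reported as the sum
$E_{loc} + E_{glob}$ at each sparsity; the term is ambiguous in parts of
the literature, and the sum convention is a deliberate, labelled choice.

The default sparsity grid is $0.05$–$0.50$ in steps of $0.05$: below
$0.05$ the 148-node graphs fragment; above $0.50$ every binarized network
approaches the complete graph and all efficiencies saturate.

Group comparison comes in two modes. Subject-level functional profiles
are compared with two-sample t-tests per sparsity (pooled variance by
default, Welch behind a flag). Group-level structural networks have no
subject-level replicates, so uncertainty is estimated by a subject
bootstrap: resample subjects within group, rebuild the covariance matrix
and its profile ($B = 100$ by default), and summarize the bootstrap
distribution of the group difference by its 95% percentile interval and a
doubled, add-one-corrected one-sided tail probability. The percentile
bootstrap at these sizes is approximately, not exactly, calibrated: in
the package's own null-calibration test (200 replicate cohorts with no
planted difference) the accepted rejection-rate band is 1–11% around the
nominal 5%.

## The synthetic cohort

The generator emulates exactly the structure the analysis consumes, with
dimensions matching the motivating study (148 cortical regions, 112 ROIs
with 180 time points at TR = 2 s, 45 subcortical and 70 white-matter
volume regions; ages uniform on 8–20, ~24% female in both groups).

**Volumes and thickness.** Group effects are multiplicative on regional
means (`1 + effect` in the ASD group). Defaults plant effects of the
size and sign pattern reported for school-age cohorts: gray-matter
increments of 5–10%, white-matter decrements of 3.5–5%, enlarged caudate,
thickness increments of about 4% in 9 homotopic pairs. Regional noise is
multiplicative with CV 10% (volumes) and 5% (thickness); a common
head-size factor (SD 8%) multiplies all volumes and the supratentorial
volume, so supratentorial normalization removes it.

**Thickness covariance.** The subject-level latent for region $r$ is

$$\ell_r = \sqrt{\rho_s}\, u_r + \sqrt{\rho_g}\, f + \sqrt{1 - \rho_s -
\rho_g}\, \varepsilon_r,$$

where $u$ is an AR(1) field along the region index within each
hemisphere (correlation $0.97^{|r - r'|}$) and $f$ is a global factor.
The *spatial* share $\rho_s$ makes the thresholded covariance network
banded (lattice-like, low relative global efficiency); the *global*
share pushes ranking among distant pairs toward noise (random-like,
relative efficiency near 1). Defaults plant a stronger spatial share in
the ASD group (0.65/0.05 versus 0.30/0.15 spatial/global), so the ASD
structural network has persistently lower relative global efficiency
across the sparsity grid. A block-factor (modular) construction was
considered and rejected: clique-modular graphs lose their efficiency
deficit once between-block edges enter, at sparsity ≈ 0.15, whereas the
banded field sustains the planted difference across the whole grid —
and distance-dependent covariance is also the more realistic picture for
cortical thickness.

**Time series.** Every elementary signal is white Gaussian noise
band-limited to 0.005–0.1 Hz (frequency-domain masking) and standardized,
matching the band-pass of standard resting-state preprocessing. An ROI
in seed network $m$ follows
$x_i = \sqrt{c_m}\, g_m + \sqrt{c_h}\, h_p + \sqrt{1 - c_m - c_h}\,
e_i$ with a network-shared signal $g_m$, a homotopic-pair-shared signal
$h_p$ and private noise, so within-network correlations are $\approx
c_m$ and homotopic correlations $\approx c_h$ by construction. Four
bilateral networks (caudate, IFG pars opercularis, IFG pars
triangularis, DMN core) have configurable per-group couplings; defaults
give the ASD group weaker seed-network and homotopic coupling. Because
the bilateral networks contain homotopic pairs, the homotopic (VMHC)
summaries legitimately inherit part of any planted network difference —
visible in the feature-selection behaviour below. One consequence of
band-limiting: a 180-point series has only ≈ 35 independent frequency
bins, so null correlations are noticeably wider than $1/\sqrt{T-3}$;
null-distribution tests therefore use white-noise fixtures.

**Phenotypes.** Each clinical score (ADOS subscales, ADI-R, IQ, SRS,
VABS subdomains) is a linear function of *standardized realized imaging
features* plus Gaussian noise, truncated and rounded to a plausible
integer range. A single coupling $\beta$ with residual SD $\sigma$
yields a theoretical feature–score correlation $\beta/\sqrt{\beta^2 +
\sigma^2}$. Default signs mirror the reported correlation structure
(ADOS and IQ negative against caudate/IFG connectivity, VABS
socialization positive). Clinical instruments specific to the ASD group
are missing for controls, exercising pairwise deletion downstream.

What the generator does *not* emulate: site/scanner effects, motion,
voxel-level spatial structure, non-Gaussian score distributions, and
age/sex effects on the imaging measures. Passing tests demonstrate the
pipeline's statistical machinery is correct and calibrated on data
satisfying its assumptions — not that real multi-site cohort data
satisfies them.

## Quantitative features and integration

Seed maps correlate each non-seed ROI with the mean time course over the
(bilateral) seed set and standardize with Fisher's transform,
$z = \operatorname{atanh}(r)\sqrt{T-3}$, so the conventional threshold
2.3 has its one-sided normal reading; $r$ is clipped to
$\pm(1 - 10^{-12})$ before `atanh` so degenerate simulations stay
finite. Each map yields $N$ (count of regions with $z > 2.3$, strict,
positive tail only) and $Z$ (their mean). Since the package operates on
ROI data, $N$ counts regions; voxel-level cluster correction is out of
scope by design. VMHC applies the same summary to homotopic pair
correlations. fALFF is the fraction of spectral amplitude in
0.01–0.08 Hz over all positive frequencies of the demeaned series; a
flat spectrum gives ≈ 0.28 at TR = 2 s.

The canonical feature table has exactly 22 columns: 9 normalized
subcortical volumes, 8 seed N/Z summaries, 3 fALFF means, 2 VMHC
summaries. Integration: variance-normalize (population convention),
eigendecompose the feature covariance (equivalently, correlation-matrix
PCA), take the minimal $k$ capturing 95% (or 99%) of variance, then run
greedy mRMR to select $k$ features. Mutual information uses plug-in
estimates on a three-bin $\mu \pm \sigma$ discretization (the mRMR
method's published convention; it also makes selection affine-invariant).
The difference criterion (MID), relevance minus mean redundancy, is the
default; the quotient form (MIQ) is available behind a switch.

## Models and evaluation

Two representative learners are implemented, the two reported as winners
in the motivating study's sweep. The **random tree** considers
$\lceil\sqrt{d}\rceil$ randomly drawn features per node, splits at the
best midpoint by information gain, and grows to purity; zero-gain splits
are admissible (XOR-type interaction structure has no first-split gain),
and if the drawn features admit no split all features are consulted, so
any consistent training set is memorized. Leaves store class frequencies
as probabilities, from which margin curves (sorted $p_{true} -
\max p_{other}$ with cumulative counts) are drawn. The **instance-based
regressor** is a Gaussian-kernel weighted mean over training points on
standardized features, with the bandwidth chosen per query so the
effective neighbour count $\sum_i w_i / \max_i w_i$ matches a blend
parameter (default 5) — a fully specified analogue of entropic
memory-based (K*-style) regression; exact K* transformation
probabilities were considered and set aside as under-determined.
Evaluation protocols: full-dataset, stratified shuffled k-fold (2–10),
and percentage split (10–90%); all are pure functions of the seed.
Cross-validated prediction of a noisy score is attenuated relative to
the theoretical coupling (kernel smoothing plus regression dilution): a
planted theoretical $r = 0.9$ recovers around the high 0.8s held-out,
which is what the acceptance band encodes; the noise-free limit with a
near-interpolating blend gives slope ≈ 1.

## Group statistics

Regional volumes are normalized as `raw / supratentorial * 1000`;
thickness is compared in raw mm (the published thickness tables are in
mm, so no normalization is applied there). Percentage change is
$(V_2 - V_1)/V_1 \times 100$ with $V_1$ the control mean. Regional
tests are two-sample t-tests (pooled by default) with a Bonferroni
factor of 8 (4 lobes × 2 hemispheres). Feature–phenotype correlations
use Pearson tests with pairwise deletion and a category-structured
Bonferroni factor: 5 categories × the category's sub-domain count (ADOS
10, IQ 3, ADI-R 5, SRS 7, VABS 15). The package ships the published
regional group-mean tables (`reference_group_means()`); re-deriving the
printed percentage changes from the printed means reproduces every cell
to one unit in the last printed digit — the residual up to ~0.001 is
exactly what rounding the means to 3 decimals propagates into the
quotient.

## Numerical and reproducibility choices

* Graph primitives (BFS distances, both efficiencies, edge swaps) are
  compiled (Rcpp); the swap draws from R's RNG so `set.seed()` governs
  everything. Tests verify exact agreement with brute-force
  Floyd–Warshall and induced-subgraph oracles, and with igraph's global
  efficiency.
* Thresholding with fewer positive weights than requested keeps all
  positive edges and records the realized sparsity (with a warning);
  a sparsity yielding zero edges is an error.
* `efficiency_profile` records per-sparsity thresholding failures in an
  `errors` attribute instead of aborting the sweep.
* The pipeline derives one seed per stage by hashing the stage name with
  the master seed, so stage outputs are reproducible independently of
  stage order; re-running an identical configuration is byte-identical.
* Problem sizes in the shipped tests and acceptance script are chosen to
  keep a full run on a single CPU within minutes: e.g. 50 subjects/group
  with $B = 100$ bootstrap replicates and 10 nulls per sparsity for the
  planted-efficiency check, 200 null replicate cohorts (60 regions,
  20/group, $B = 100$) for type-I calibration, 20 seeded replicates for
  the feature-selection recovery rate, and 300 subjects for phenotype
  recovery.

## Known limitations

* The region-level $N$ is a stand-in for the voxel counts of map-based
  software; absolute magnitudes are not comparable to voxel counts.
* The bootstrap comparison of group-level structural networks is
  approximate (see calibration band above); with very small groups
  (< ~15/group) it becomes unreliable.
* Published cross-validated accuracies and component counts from real
  cohorts are data-dependent and are not reproduction targets; the
  package guarantees the rules (thresholding, selection, protocols),
  not the numbers they produce on any particular sample.
* The single random tree is a deliberately simple reference classifier;
  it is noisy at small n, which the calibration tests reflect.
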