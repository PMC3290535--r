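---
title: "Methods: the nucleofit nucleosome-positioning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nucleofit nucleosome-positioning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleofit)
```

# The generative picture

A nucleosome protects ~147 bp of DNA.  Sequencing the ends of
nucleosome-derived fragments yields forward-strand 5' positions piling
up upstream of the dyad and reverse-strand positions downstream, offset
by the fragment length.  `nucleofit` works entirely on these stranded
5' coordinates (0-based throughout; a reverse read's 5' end is
`chromEnd - 1` of its BED record).

Within one candidate region carrying `n_f` forward and `n_r` reverse
reads, positions are modelled as i.i.d. draws from a bidirectional
K-component mixture.  Component `k` has dyad `mu_k`, mean fragment
length `delta_k`, strand scales `sigma_fk`, `sigma_rk`, and a weight
`w_k` shared by both strands (a fragment contributes either end with
probability 1/2).  The component density is a location-scale Student t
with 4 degrees of freedom: heavy-tailed enough that stray reads do not
drag the location estimate, while keeping a finite variance
(`2 sigma^2`).  Forward and reverse variances are deliberately not tied,
because mappability and library biases routinely make the two strand
peaks unequally sharp.

Three priors complete the model:

* **Spacing (GMRF chain).** The ordered dyads pay
  `rho_s * (mu_k - mu_{k-1} - delta0)^2` per adjacent pair.  Defaults
  `delta0 = 200` bp and `rho_s = 1/(2 * 25^2)` bp^-2 make the implied
  spacing sd 25 bp, i.e. spacings of roughly 150-250 bp at two sds —
  tight enough to exploit the nucleosome repeat, loose enough to admit
  closely spaced alternative positioning and short linkers.  We use the
  unnormalized pairwise form with free boundaries (the first and last
  dyads feel only one pair term); a single dyad contributes nothing.
* **Fragment length.** `delta_k ~ N(xi, s0^2/kappa)` with
  `s0 = deltaPriorScale = 50` bp.  MNase libraries are tightly size
  selected, so the MNase preset uses `xi = 150`, `kappa = 16` (prior sd
  12.5 bp); sonication gives variable fragments, so that preset uses
  `xi = 200`, `kappa = 4` (prior sd 25 bp).
* **Read-position precision.** `1/sigma^2 ~ Gamma(alphaPrec,
  betaPrec)`, prior mean variance `betaPrec/(alphaPrec - 1)`: 400 bp^2
  (MNase) and 2500 bp^2 (sonicated).  `alphaPrec > 1` is required so
  the variance MAP below is well defined.

# Preprocessing

**Duplicate capping.**  Per-(strand, position) multiplicities are
pooled; the cap is their empirical quantile (type 1: smallest count
whose cdf reaches the level, hence an integer >= 1) at `dupQuantile` —
0.999 for MNase, where genuine pile-ups at well-positioned fragment
ends are expected, 0.99 for sonicated data.  Capping is idempotent:
values at or below the cap are untouched and the capped distribution
has the same type-1 quantile.

**Segmentation.**  A `windowWidth = 150` bp window slides in
`windowStep = 10` bp steps; forward reads are counted in the left
half-window and reverse reads in the right one (both halves closed
intervals, reads within `centerExclusion` bp of the center excluded —
0 by default, i.e. disabled), and windows with at least `minReads = 2`
reads per strand are merged left-to-right into disjoint regions.
Regions are trimmed to their read span and dropped when shorter than
`minRegionLength = 100` bp (too short to host a nucleosome).  Regions
longer than `maxRegionLength = 1200` bp (~6 repeats, bounding the
mixture size) are cut at the widest read gap whose midpoint lies in the
central third — the restriction guarantees geometric shrinkage, hence
termination — with the cut rounded up to an integer so the two
half-open children partition the reads exactly.  If every central cut
would starve a strand below `minReads`, the region is kept whole with a
warning.

# Fitting

**EM with latent scale weights.**  The t density is the scale mixture
`t4 = integral N(mu, sigma^2/u) dGamma(u; 2, 2)`, so the E-step yields
responsibilities `z_ik` and weights `u_ik = 5/(4 + d_ik^2)` (`d` the
standardized residual), and every M-step update is in closed form with
effective weights `z * u`.  Should all component densities underflow
for a read, it receives uniform responsibilities and a warning — with
t4 tails this requires absurd configurations, but the guard keeps the
iteration finite.

**Center update.**  Stationarity of the penalized expected complete
log posterior in all centers jointly is a symmetric tridiagonal linear
system: the diagonal carries each component's data precision plus
`2 rho_s` per neighbor, the off-diagonals `-2 rho_s`, and the
right-hand side the strand-recentered weighted read sums plus spacing
terms.  It is solved exactly by the Thomas algorithm (and checked
against a dense solve in the tests).  If the update reorders centers,
components are relabeled to restore sorted order — a pure relabeling
that leaves the objective unchanged.

**Fragment length and variances.**  `delta_k` is the exact MAP under
its Normal prior: a precision-weighted blend of the data's
forward/reverse offset estimate (curvature `(P_f + P_r)/4`, with `P`
the summed `z*u/sigma^2` weights) with `xi` at prior precision
`kappa/s0^2`.  As `kappa -> 0` this is the pure data estimate; as
`kappa -> infinity` it is `xi` exactly.  The variance MAP under the
Gamma precision prior is `(2 betaPrec + weighted SSE)/(sum z +
2 alphaPrec - 2)` — the exact stationary point of the penalized
objective in the precision parameterization.  Both are then projected
onto their configured boxes (`deltaBounds = (80, 250)` bp,
`sigmaBounds = (5, 150)` bp); because each 1-D objective is concave,
projection is still the constrained maximizer, so the tracked MAP
objective (likelihood plus all log-priors) is nondecreasing across
iterations — asserted to within 1e-8 in the tests.

**Initialization and stopping.**  Centers start at evenly spaced
quantiles of the pooled strand-recentered reads (forward `+ xi/2`,
reverse `- xi/2`), `delta = xi`, variances from the pooled spread,
weights uniform.  The default fit is therefore deterministic given the
data; a `restarts` knob adds seeded jittered starts keeping the best
objective.  Iteration stops when the relative objective change drops
below `tol = 1e-6` or after `maxIter = 500` iterations.

**Choosing K.**  Candidate K values span `expected +/- kMargin` with
`expected = max(1, round(length/delta0))` and `kMargin = 2`, capped at
the thinner strand's read count.  The winner maximizes the
log-likelihood penalized by the spatial log-prior of its centers; BIC
would ignore exactly the spacing information that distinguishes a
genuine neighbor from an overfit duplicate, whereas a spurious
component inserted mid-array pays a large spacing penalty.  Ties go to
the smaller K; all tie-breaks in the package resolve toward smaller K,
then leftmost center.

**Post-fit screening.**  Components with weight below `0.05/K`,
`delta` outside `deltaBounds`, or a scale outside `sigmaBounds` are
dropped; adjacent centers closer than `mergeDistance = 60` bp merge
(the heavier member keeps its shape, weights add, closest pair first);
weights renormalize.

# Scoring, FDR, and the low-density filter

Core reads are counted inside the central `coreQuantile = 0.90` t4
contour of each strand density (`+/- 2.13 sigma` around the strand
center); the enrichment score is `(n_f + n_r)/(sigma_f + sigma_r)` —
reads per bp, so diffuse fits score lower.  With a control sample the
same intervals are counted in the control and the depth-normalized
ratio `(n_f + n_r)/(n_f^c + n_r^c + 1) * N_ctrl/N_chip` is reported,
and an empirical FDR is estimated by running the identical pipeline on
the control and comparing score tail counts, made monotone by a
running maximum from high scores down.

The low-density filter compares each call with its neighbors within
`nbRadius = 500` bp, ignoring neighbors beyond a nucleosome-free gap
(adjacent-dyad distance minus 147 bp) longer than `nbGapThreshold =
250` bp.  Under a shared local read density, a neighbor observed with
`N` core reads at width `s_nb` predicts the reference's count as
Poisson with a Gamma(N, s_nb)-distributed rate times `s_ref` — i.e.
negative binomial with mean `N * s_ref/s_nb` and size `N`.  A call
whose count falls below the `nbAlpha = 0.01` quantile for any neighbor
is flagged, in a single pass against the unflagged set so removal is
order-independent.

A deliberate scope note: the benchmarking harness evaluates *unfiltered*
scored calls.  An ROC sweep already thresholds along the score, and the
low-density flag is strongly score-correlated, so pre-filtering would
double-count the evidence and bias AUC; the filter also, by
construction, sacrifices some genuine low-coverage calls to suppress
false ones, which is the right trade for a reported call set but not
for a detection benchmark.

# Downstream classification

A binding-site summit with no dyad within `noneDist = 1000` bp is
`NoNuc`; with a dyad within `monoDist = 50` bp (inside nucleosomal
DNA) it is `monomodal`; all other sites are `bimodal`.  We read
"bimodal" as the residual class — no additional flanking-distance
requirement — since typical sites between phased nucleosomes fall 50 bp
to 1 kb from the nearest dyad.  Genes with several sites take the most
informative label, strict precedence `bimodal > monomodal > NoNuc`.
Before classification, weak calls can be removed with the low-density
filter plus a score cutoff at the elbow of the sorted-score curve,
computed as the point of maximum distance to the chord — a standard
parameter-free knee rule (`scoreElbow()`).  Occupancy profiles place a
Gaussian kernel (sd 30 bp, peak height score/max-score) at each dyad in
anchor-relative coordinates; summit-to-dyad histograms truncate at 100
bp with reference marks at +/- 73 bp (half the core).

# Evaluation harness

Subsampling draws `floor(fraction * n)` reads without replacement from
the pooled strands, seeded.  A reference dyad is *detected* if any
prediction lies within `detectDist` (50 bp MNase / 100 bp sonicated —
looser for sonication's broader signal); true-positive labels are
assigned one-to-one by greedy matching in increasing distance so a
single prediction cannot detect two references.  ROC curves sweep score
thresholds and are truncated at specificity 0.8 (sensitivity without
specificity being worthless), giving a maximum area of 0.2 and a chance
level of 0.02; the truncation point is interpolated linearly.  When a
prediction set has no false positives the ROC is degenerate — the
package reports the curve's limit, `0.2 * max sensitivity`, rather than
erroring, so depth-sweep comparisons remain defined at saturation.

# The simulator, and what passing tests mean

`simulateDataset()` draws from exactly the fitted model: dyads from the
causal chain (each spacing `delta0 +` Gaussian noise of sd
`1/sqrt(2 rho_s)`, rejection-resampled into `spacingBounds = (150,
250)`), per-nucleosome `delta` and `sigma` from their truncated priors,
and reads as rounded t4 draws at `mu -/+ delta/2`, with between-array
gaps wider than `maxRegionLength` so segmentation cannot merge arrays.
Defaults (150 reads per strand per nucleosome, sonicated preset) mirror
a well-covered sonicated ChIP-seq experiment around binding sites.

Because the simulator and the model agree, recovery tests certify the
*inference machinery* — segmentation, EM, model selection, scoring —
not robustness to real-data pathologies.  The simulator deliberately
omits mappability gaps, GC and amplification bias, copy-number
variation, cell-population heterogeneity beyond the spacing prior, and
background (non-nucleosomal) reads; performance on real data will be
worse than on these fixtures, which is why the duplicate cap, control
normalization and low-density filter exist at all.

Problem sizes in the shipped tests were chosen to make the checks
statistically meaningful at interactive runtimes: 100 single-array
regions (K 1-4) for parameter recovery, 50 seeded regions for EM
monotonicity, 10 seeds by 3 subsample fractions (5 arrays each) for the
depth sweep, and 50 replicates for the K = 3 selection rate.

# Known limitations

* Single-end reads only; paired-end fragment midpoints would carry more
  information and are not modelled.
* MAP point estimates, no posterior uncertainty on dyad positions.
* No mappability-aware imputation of unmappable-region reads.
* The NB low-density threshold treats a neighbor's count as fixed
  evidence for a per-bp rate; with very wide, poorly fitted reference
  peaks it can flag genuine nucleosomes (see the scope note above).
* Chromosomes are processed independently; the spacing prior never
  couples across candidate regions, so nucleosomes split across a
  region boundary can be double-called at most `mergeDistance` apart.
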