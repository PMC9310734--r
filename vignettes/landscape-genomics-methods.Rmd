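---
title: "Methods: genotype-likelihood population genetics and landscape resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genetics and landscape resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landpop)
```

# Scope and model overview

`landpop` implements a complete analysis chain for landscape population
genomics of low-coverage reduced-representation (e.g., RADseq) data:

1. **Genotype-likelihood estimators** (no genotype calling): site frequency
   spectra (SFS) by EM, nucleotide diversity θπ, per-individual
   heterozygosity, inbreeding coefficients, pairwise genetic distances,
   genotype-posterior covariance PCA, two-dimensional SFS and Hudson FST.
2. **Niche suitability modelling**: a penalized presence/background
   classifier with AUC/TSS evaluation, fourfold spatial-block
   cross-validation, multivariate environmental similarity surfaces (MESS)
   and multi-epoch habitat stability.
3. **Resistance surfaces and least-cost distances**: terrain ruggedness
   (TRI), occurrence-quantile cost tiers, one-minus-suitability and
   one-minus-stability costs, a 16-direction geodesic transition graph and
   shortest-path distances between sampling localities.
4. **Matrix inference**: Mantel permutation tests, multiple matrix
   regression with randomization (MMRR), and generalized dissimilarity
   modelling (GDM) with monotone I-splines and permutation-based backward
   elimination, relating pairwise FST to isolation by distance (IBD),
   terrain resistance (IBR_Terrain), habitat resistance (IBR_Habitat),
   historical climatic instability (IBI) and environmental distance (IBE).
5. A **synthetic-data module** that generates landscapes, occurrences,
   locality layouts and genotype likelihoods with recorded ground truth, so
   that every stage above is testable without external downloads.

# Genotype-likelihood machinery

## Allele-frequency likelihoods and the SFS EM

For a biallelic site with genotype likelihoods $L_i(g)$, $g \in \{0,1,2\}$
copies of the derived (or minor) allele in diploid $i$, the likelihood of a
total derived count $d$ among $2N$ chromosomes is computed by a
dynamic-programming convolution over individuals with combinatorial weights
$\binom{2}{g}$ and a final normalization by $\binom{2N}{d}$. This makes the
vector exact for fully certain genotypes (each configuration weighted by
the hypergeometric probability of assigning $d$ alleles to individuals) and
exactly uniform for all-missing sites. The SFS is the maximizer of
$\prod_s \sum_d \phi_d L_s(d)$ over the probability simplex, obtained by EM;
on certain genotypes the EM converges in one step to the empirical
histogram. The log-likelihood trace is retained and asserted non-decreasing
in the test suite. Default tolerance is `1e-8` on the probability-scale
spectrum with a 500-iteration cap; both are arguments.

θπ uses the class-weight identity
$\theta_\pi = \sum_i i\,(n-i)\,\eta_i / \binom{n}{2}$, which applies
unchanged to folded spectra because $i(n-i)$ is symmetric under
$i \mapsto n-i$; folding sums classes $d$ and $2N-d$ after estimation.
θπ comparisons between localities are made on the intersection of
per-locality *variable* sites (sites whose maximum-likelihood allele count
is polymorphic); a comparison over all intersected sites is available by
supplying the site list directly.

## Inbreeding

Each individual's deviation from Hardy-Weinberg equilibrium is modelled by
the prior $(q^2 + fpq,\; 2pq(1-f),\; p^2 + fpq)$. We estimate $(f_i, p_s)$
by an exact EM on the latent identity-by-descent indicator: with
probability $f$ the individual carries two copies of a single allele draw.
The M-step for $p$ weights an IBD individual as one independent allele draw
and a non-IBD individual as two, which makes the update an exact EM M-step
and guarantees a monotone log-likelihood (asserted at every iteration).
Because $f = 0$ is a fixed point of the EM map, "neutral" starting values
are $f = 0.01$ with $p$ initialized from likelihood-weighted dosages.
Estimation runs in two stages — a short first run producing starting values
and a deeper second run capped at 1,500 iterations — matching the two-run
convention of genotype-likelihood inbreeding estimation.

## Two-dimensional SFS and FST

The joint SFS of two populations is estimated by EM over the outer-product
class space of the per-population allele-frequency likelihood vectors. The
E- and M-steps are evaluated in matrix form (`sites x classes` products),
never materializing per-site outer products, so 50,000 sites with 20+20
diploids run in seconds. The EM is initialized from the normalized
cross-product of the likelihood matrices (equivalent to one E-step from a
flat prior), which roughly halves the iterations to convergence without
changing the fixed point.

FST is the Hudson/Bhatia ratio of sums: per class $(d_1, d_2)$ with sample
frequencies $p_k = d_k / n_k$,
$$\alpha = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad \beta : \alpha + \beta = p_1(1-p_2) + p_2(1-p_1),$$
weighted by expected class counts and summed before the ratio. Hudson's
estimator is the default for its robustness to unequal sample sizes; a
Reynolds-style ANOVA estimator is available via `method = "reynolds"`.
Negative pairwise estimates are clamped to zero in matrix output (the raw
values are kept in an attribute) because the downstream normalization
$F_{ST}/(1-F_{ST})$ and GDM response require $[0, 1)$.

## Genetic distances and PCA

Pairwise genetic distance is the posterior expectation of $|g - h| / 2$
over shared covered sites (uniform genotype prior unless site frequencies
are supplied); a 0/1 mismatch kernel is available. The covariance PCA uses
expected dosages under an HWE prior at frequencies from a single
uniform-prior pass, standardized by $2\hat p(1-\hat p)$, with sites of
$\hat p \notin (0.01, 0.99)$ excluded; iterative individual-allele-frequency
refinement is deliberately out of scope.

# Niche modelling

The suitability model is an L1-penalized logistic presence/background
classifier on standardized linear and quadratic terms of the four
bioclimatic layers — the penalized-GLM formulation equivalent to
maximum-entropy niche modelling with linear+quadratic features. Ten
replicate fits on random 80/20 presence splits against 10,000 background
points are averaged; the optimizer iteration cap is 500. The classifier
probability is the suitability output (the output scale of the surrogate
model is a package decision; it satisfies the required $[0,1]$ contract).
The L1 weight defaults to 0.001 on standardized features and is fitted at
the end of a short warm-start path for numerical stability on separable
data.

AUC is the Mann-Whitney rank statistic with ties counted one half; TSS is
maximized over all observed score thresholds. Spatial-block
cross-validation splits the bounding box into a fixed 2 x 2 grid of
contiguous blocks (boundary points go south/west) with fold roles rotating.
MESS follows the piecewise percentile definition with "strictly below"
percentages and is negative exactly when a cell is outside the reference
range in some variable. Habitat stability is the cellwise arithmetic mean
of per-epoch suitability; circulation-model replicates per epoch are
averaged, with a config-level exclusion list for models flagged by MESS.

# Resistance and least-cost distances

TRI uses the sum-of-squared-differences form over the 8-neighbourhood
(mean-absolute-difference variant by flag). Analysis areas are restricted
to the convex hull of occurrences buffered by 0.4 degrees, and to the
occurrence elevation range with a +-100 m margin; the margin is read as
"100 m beyond the lowest and highest occurrence elevation" (an explicit
flag drops the lower restriction, which is the default for the stability
surface, since glacial elevation zones may have shifted downward).

Terrain cost tiers follow occurrence TRI quantiles: cost 1 for the central
70% ([q15, q85]), 2 and 4 for the adjacent 5% bands, 8 for the outermost
occupied bands, 16 outside the occupied range, with boundary ties resolved
to the cheaper tier (closed central intervals). Linear-interpolation
(type 7) quantiles are used.

The transition graph connects passable cells by the 8 queen and 8 knight
moves. Edge weight is the haversine distance between cell centers (Earth
radius 6371 km) times the arithmetic mean resistance of the two cells,
floored at `1e-6`: an accumulated-cost integral along the path. A
mean-conductance (harmonic) composition is available by flag; the two
differ only at strongly heterogeneous edges. Least-cost distances are
Dijkstra shortest paths between the passable cells nearest to locality
centroids (snap radius two cell diagonals, reported per locality;
unreachable pairs are infinite and flagged).

# Matrix statistics

Mantel tests correlate lower triangles, optionally after dividing each
matrix by its off-diagonal mean (a pure rescaling that leaves r unchanged
but matches the convention of comparing matrices on a common scale);
significance is one-tailed for positive association by default (the
standard direction for isolation-by-distance; two-sided by flag) with
$p = (1 + \#\{r_\pi \ge r\})/(1 + n_\pi)$ under joint row/column
permutation, or exhaustive enumeration for $n \le 7$. MMRR z-scores the
unfolded triangles, fits OLS, and recomputes t and F statistics under
permutations of the response; raw-scale coefficients are also reported.

GDM models dissimilarity as $1 - \exp(-\eta)$, $\eta$ a non-negative
combination of order-2 I-splines (three per predictor, knots at the
0/50/100 percentiles of each predictor's distances), fitted by iteratively
re-weighted non-negative least squares on the binomial-deviance objective
with step-halving; non-negativity guarantees monotone fitted relationships.
The FST response enters untransformed (already in $[0,1)$); the normalized
form is reserved for Mantel/MMRR. Backward elimination measures each
predictor's unique contribution as the mean drop in percent deviance
explained when that predictor's matrix is row/column permuted, removes the
least-contributing predictor while any retained predictor is
non-significant, and records the full per-round history.

# The synthetic-data generator

The generator defines the study conditions for all tests:

* **Landscape**: elevation is seeded spectral noise with a fixed $1/f^2$
  power law; `roughness` in $[0,1]$ scales the relief amplitude around a
  2000 m plateau (0 = flat, 1 = 0-4000 m). The spectral exponent is a
  separate argument; amplitude, not exponent, is the intended "roughness"
  control because a zero exponent would produce white noise — the roughest
  possible surface — rather than a flat one. Four bioclimatic layers are
  deterministic functions of elevation and smooth gradients plus seeded
  noise (temperature with a 6.5 K/km lapse rate, a diurnal-range layer, a
  precipitation layer with a west-east gradient, a seasonality layer with a
  south-north gradient). Past epochs shift temperature additively (-1.5 K
  mid-epoch, -4.5 K glacial, within the range of reconstructed glacial
  cooling) and scale precipitation multiplicatively (0.95, 0.8).
* **Occurrences** are sampled proportional to a recorded Gaussian niche on
  the temperature and precipitation layers, with sub-cell jitter.
* **Localities** follow the sampling design of comparable field studies:
  five to six localities, about 13 individuals each scattered over ~1 km,
  exactly one pair closer than 12 km and all other pairs beyond 20 km.
* **Genotypes**: ancestral frequencies uniform on (0.05, 0.95); population
  frequencies Balding-Nichols around them (or, for landscape-coupled runs,
  logit-normal with covariance $\sigma^2 e^{-d/\lambda}$ in the terrain
  least-cost distance $d$, so that differentiation grows with resistance);
  genotypes with per-individual inbreeding; Poisson depth (default 8,
  within the 5-17x range typical of the data the pipeline targets; not
  asserted anywhere); binomial read counts with error 0.01; likelihoods
  normalized beagle-style with uniform triples at zero depth. The default
  divergence scale `divergenceSigma = 1.5` produces pairwise FST spanning
  roughly 0.05-0.3 on the default landscape, inside the 0.02-0.66 span
  reported for comparable RADseq studies of montane plants.

What the generator does *not* emulate: linkage disequilibrium (sites are
independent), coalescent genealogies, read-level artifacts (mapping bias,
indels, allele-specific error), spatially autocorrelated sampling within
localities, and niche truncation by biotic interactions. Passing tests
therefore demonstrate correctness of the estimators and the inferential
cascade under the stated generative model, not robustness to those
real-data complications.

# Numerical choices

* EM tolerances: `1e-8` (1D SFS), `1e-6` (2D SFS, inbreeding) on the
  maximum absolute parameter change; caps 500 / 200 / 200+1500 iterations.
  Analyses in the test suite that only need the FST functional of the 2D
  SFS use `1e-5`, which changes estimates by $<10^{-4}$.
* The DP convolution rescales when values exceed `1e250`; beagle
  normalization (max 1 per triple) keeps row scales bounded below.
* `lsqnonneg` failures inside the GDM IRLS fall back to the previous
  iterate; deviance increases trigger step-halving, so the objective is
  non-increasing.
* Zero geographic distances under the log transform are replaced by half
  the smallest positive distance (warned).
* Negative FST clamped to zero for matrices; raw values logged.
* Boundary points in rasters and CV blocks resolve south/west; tier
  boundaries resolve to the cheaper tier.

# Pipeline problem sizes

The packaged demo configuration (`pipelineConfig()` defaults scaled in the
examples: a 24-48 cell grid, 5 localities x 8-13 diploids, 1,500-5,000
sites, 199-999 Mantel permutations, 49-199 GDM permutations) completes in
seconds to a few minutes on one CPU; the full-size defaults (10,000 Mantel
and MMRR permutations, 500 GDM permutations) are the framework's standard
settings and scale linearly. These sizes were chosen so that the complete
validation chain — simulation, estimation, resistance modelling and matrix
inference — runs routinely as part of the test suite.

# Known limitations

* Rasters are WGS84 lon/lat Esri ASCII grids; projected grids and GeoTIFF
  are not read (no georeferenced-TIFF reader is available to the package).
* The Mantel/MMRR permutation tests assume exchangeable localities; they
  inherit the known liberality of matrix permutation tests under strong
  autocorrelation of predictors.
* MMRR requires at least five localities (ten pairs); with the minimum
  design the permutation distribution is coarse.
* GDM importance p-values are permutation proportions under refitting;
  with few pairs a spuriously fitted noise predictor can appear
  significant, which is why elimination decisions are driven by the
  importance ranking with the p-values as the stopping rule.
* The niche-model surrogate restricts features to linear+quadratic terms;
  hinge/threshold/product features of the maximum-entropy feature hierarchy
  are out of scope.
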