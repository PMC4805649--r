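---
title: "Methods: flowering-time association mapping, QTL calling and selection scans"
author: "ftqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flowering-time association mapping, QTL calling and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ftqtl` analyses multi-environment flowering-time trials in panels of
inbred crop lines that divide into growth-habit sub-populations (spring
vs winter sowing types, with semi-winter material in between).  Two
questions drive the design: *where in the genome does flowering time
map*, and *how much of that architecture was shaped by the artificial
selection that separated the growth habits*.  This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic cohorts do and do not establish.

## Phenotype model and heritability

The plot-level trait is days from sowing until a fixed fraction of a
plot has opened its first flower.  The package treats the two-way layout
as fixed effects and fits

```
value ~ environment + line + environment:line
```

with `aov()`, reporting the sequential decomposition (exact and
order-free on balanced data; a warning flags type-I sums of squares on
unbalanced data).  With a single replication everywhere, the interaction
and plot error cannot be separated, so the model drops the interaction
and flags the pooled residual.

Variance components come from the random-model expected mean squares —
`sigma2_e = MS_res`, `sigma2_ge = (MS_GxE - MS_res)/b`,
`sigma2_g = (MS_G - MS_GxE)/(n b)` — even though the `aov` fit is a
fixed-effects fit.  That mixed usage (fixed-effect test statistics,
random-model component extraction) is deliberate: it is how
multi-environment trials in this field conventionally report both the F
tests and an entry-mean heritability

\[ H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/n + \sigma^2_e/(nb)} . \]

Two numerical conventions matter.  Negative component estimates truncate
to zero (with a warning), keeping \(H^2\) in \([0, 1]\).  For unbalanced
replication (the motivating trials grew 1–3 replications depending on
site-year) the effective `b` is the harmonic mean of the per-environment
mean replication counts; because the original analysis never states the
constant it used, `b` is also exposed as an argument of
`variance_components()` and `heritability()` rather than hard-coded.

## Structure covariates

Marker thinning (`thin_markers()`) keeps, per chromosome, markers with
MAF strictly above 0.05 whose distance to the preceding map marker
strictly exceeds the genome-wide mean adjacent-marker distance.  The
wording "distance to adjacent SNPs" admits two readings; the
left-neighbour walk is the default because it reproduces the boundary
behaviour we take as definitional (equally spaced markers at exactly the
mean gap thin to one marker per chromosome), and a both-neighbours
variant sits behind `method = "neighbors"`.

Kinship defaults to the centred-and-scaled cross-product
\(K = ZZ'/m\) with `Z` the column-standardised dosage matrix — the
VanRaden-type estimator — with a mean-IBS similarity option, because the
original tooling names no estimator.  PCA scores are singular vectors of
the centred dosage matrix scaled by singular values, five components by
default, signs fixed so each component's largest-magnitude loading is
positive.  The Q matrix is *not* estimated by admixture MCMC: the
association algebra only needs a membership covariate, and the upstream
choice of k = 2 sub-populations is taken as given.  Q comes either from
the growth-habit labels (one-hot) or from k-means on the leading PCs
with memberships proportional to inverse centroid distance; one column
is dropped in regressions to avoid collinearity with the intercept.
Missing dosages are mean-imputed inside kinship and PCA only; they never
feed allele-frequency estimates.

## Association models

Six models are supported, distinguished by their covariates: `naive`,
`Q`, `PCA` (ordinary least squares per marker) and `K`, `Q+K`, `PCA+K`
(mixed model).  The phenotype entering a scan is the per-line mean over
replications within one environment — the replicate handling is not
stated by the motivating analysis, and line means are the standard
choice that keeps the model per-line.

The mixed model is \(y = X\beta + u + e\) with
\(u \sim N(0, \sigma^2_g K)\).  The variance ratio
\(\lambda = \sigma^2_g/\sigma^2_e\) is profiled by REML as a single 1-D
optimisation over \(\log\lambda \in [-14, 14]\) in the eigenbasis of K
(eigenvalues clamped at zero; a kinship with eigenvalues below `-1e-8`
is rejected).  Each marker is then tested by generalised least squares
with the covariance fixed — the population-parameters-previously-
determined (EMMAX/P3D) scheme.  Re-estimating \(\lambda\) per marker
would cost three orders of magnitude more at array scale and changes
p-values negligibly at these panel sizes; with `lambda` supplied the
scan is exact GLS, which the tests exploit against a brute-force
\((X'V^{-1}X)^{-1}X'V^{-1}y\) oracle.  When K is a multiple of the
identity the weights are constant and the scan reduces to ordinary least
squares exactly; per-marker p-values come from the Wald t test with
`n - p - 1` degrees of freedom and `r2_marker` is the partial R² of the
marker on the whitened data.  Markers with missing calls lose those
lines in the GLM scans; the mixed scan mean-imputes instead, because
dropping lines per marker would invalidate the shared eigenbasis.

Model diagnosis follows the usual QQ logic: expected quantiles
\(-\log_{10}((i - 0.5)/m)\) against ordered observed values, plus the
median-based genomic inflation factor.  On confounded two-population
nulls the Q+K model's inflation factor sits nearer 1 than the naive
model's — the package's acceptance tests check exactly this ranking.

## Significance threshold and QTL calling

P-values of all environments are pooled and passed through the
Benjamini–Hochberg step-up procedure at `q = 0.10`; the reported
threshold `p*` is the largest raw p-value whose adjusted value stays at
or below `q`, and SNPs are significant at raw `p < p*` (strict).  The
motivating write-up invokes "Bonferroni" while reporting an FDR, which
is contradictory; BH is implemented because an FDR level and the
magnitude of the published threshold are only consistent with step-up
FDR control, not with a Bonferroni bound.  Pooling across environments
(rather than per-environment thresholds) follows the stated
"across all environments" usage; the threshold is then applied within
each environment.

Significant SNPs merge into QTLs by single-linkage chaining with a
1.5 Mb gap — the distance at which LD in this species decays to
\(r^2 \approx 0.1\), taken as a parameter, not re-estimated.  Chaining
(rather than fixed 1.5 Mb tiles) is what produces the variable-width
loci seen in practice, including multi-megabase loci from runs of
significant SNPs and zero-width single-SNP loci.  A cluster is kept iff
it has ≥ 2 member SNPs or its single SNP is significant in ≥ 2
environments; other singletons are reported as unassigned.  The lead SNP
maximises \(-\log_{10} p\) over environments, ties broken by smaller
position (the tie-break is this package's choice).  A locus's
environment list uses *any-member* significance, matching how
multi-environment loci are tabulated in the field.  Candidate genes
attach on ≥ 1 bp interval overlap; interval algebra goes through
`IRanges`.

## Selection scan

Per-SNP differentiation between the spring and winter sub-populations
(semi-winter lines are excluded — their habit is not cleanly assignable)
uses the Weir–Cockerham (1984) single-locus estimator
\(\theta = a/(a + b + c)\) computed from per-population allele counts and
heterozygote frequencies; a Hudson-style estimator is available.  The
motivating procedure invokes a Bayesian pure-drift model without giving
formulas; Weir–Cockerham is implemented instead as the standard
moment estimator with identical downstream windowing — a deliberate
substitution, documented here.  Negative single-locus estimates clamp to
zero by default (windows average clamped values; raw averaging sits
behind `clamp = FALSE`), and a marker needs ≥ 2 callable lines per
sub-population.

Windows of 0.5 Mb slide by 50 kb, anchored at bp 1 of each chromosome
(the anchor is unstated upstream; position 1 is the reproducible
choice), and a window with fewer than two markers carrying an estimate
is set to zero rather than dropped.  "Above the 10th percentile" in the
source text is read as the *top decile* of window means — the
alternative reading (above the 10th percentile from below, i.e. 90% of
windows) contradicts the stated arithmetic that the selected regions
cover about one tenth of the genome — and the fraction is a parameter
(`top_fraction`).  Qualifying windows merge when overlapping or
book-ended; regions are therefore disjoint per chromosome.  Overlap of
QTLs and genes with regions counts ≥ 1 bp intersection, reported in both
directions (items hit, regions hit).

## Synthetic cohorts: what they emulate, and what they do not

`simulate_genotypes()` places markers uniformly per chromosome, draws
per-marker sub-population allele frequencies from the Balding–Nichols
model \( \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F) \) — window-level F
inside planted sweeps, background F elsewhere — and draws inbred-line
dosages as \(2 \times \mathrm{Bernoulli}(p_{pop})\) (fully homozygous;
`het_rate` adds dosage-1 calls).  `simulate_phenotypes()` builds
records as environment mean + QTL term + polygenic line term +
line-by-environment interaction + plot noise.  `var_g` is the *total*
genetic variance: the realised variance of planted QTL terms is
subtracted and the remainder realised as a single Gaussian line effect,
so ANOVA recovery targets stay meaningful without simulating hundreds of
small loci.

Generator defaults mirror the motivating study's structure: 448 lines
(106 spring / 153 winter / 189 semi-winter), 19 chromosomes of 63 Mb
(~1.2 Gb), 20,342 markers, environment means 163.4 / 159.8 / 154.6 /
164.8 days, and variance components `var_g = 36`, `var_ge = 32`,
`var_e = 12.3` days² — the values the expected-mean-square identities
return when applied to the published mean squares (539, 108, 12.3) with
`n = 4` and `b = 3`.  Replication defaults to a balanced `b = 3`
because the exact ANOVA decomposition assumes balance; the unbalanced
1/2/3/3 pattern of the real trials is supported via the `replications`
vector.  The background divergence defaults to `F_ST = 0.05`, a
realistic genome-wide level for crop sub-populations of this kind.
Planted QTLs may pin the causal marker's ancestral frequency (`maf`),
since a uniformly drawn frequency occasionally lands near monomorphism
and a power property stated "at MAF 0.3" is otherwise testing nothing,
and may carry `n_tags` co-significant neighbours built as flip-noise
copies of the causal column (`tag_flip = 0.05`, giving \(r^2 \approx
0.8\)).

The generator deliberately omits: linkage disequilibrium between
ordinary markers (markers are independent given frequencies — QTL
merging is exercised through planted tags, not recombination), allele
ascertainment of array design, genotyping error, and any real gene
annotation (the acceptance script's 1,520-gene table is synthetic and
labelled as such).  Passing tests therefore certify the statistical
machinery — calibration of the FDR rule, equivalence of the mixed model
with explicit GLS, recovery of planted effects — on data whose
assumptions are known to hold; they do not certify behaviour under real
LD structure or array artefacts.

## Problem sizes and numerical conventions

The test suite runs its simulation-based properties at 100–400 lines,
400–2,500 markers and 5–10 seeds per property; the acceptance script
runs the full default scale (448 × 20,342 × 4 environments) in well
under a minute.  The selection-scan recovery property plants three 4 Mb
sweeps on a 100 Mb five-chromosome genome — sized so the elevated
windows slightly exceed one decile of all windows, which makes the
strict top-decile cut fall inside the elevated population and the called
regions cover close to one tenth of the genome, the regime the method's
own genome-fraction arithmetic presumes.

Remaining conventions: chromosome ordering is the natural sort `A01..
A10`, `C01..C09`, then other names lexicographically; all internal
coordinates are 1-based inclusive, with BED converted at the boundary
(so QTL names match the published naming convention); `filter_maf()`
excludes strictly below the threshold while thinning requires strictly
above; monomorphic markers are excluded from kinship with a warning; a
marker collinear with the covariates yields a missing p-value rather
than an error; and all generator randomness derives from a single
integer seed, with the phenotype layer using a fixed offset of that seed
so genotypes are reproducible independently of whether phenotypes are
drawn.

## Known limitations

EMS-based components are method-of-moments, not REML, by design (the
heritability formula is defined in EMS terms).  The P3D approximation
slightly understates per-marker uncertainty when a marker explains a
large variance fraction.  The Q matrix from k-means is a proxy for
admixture proportions and carries no uncertainty.  F_ST windows use
marker counts with valid estimates, so sparsely genotyped regions are
zeroed rather than interpolated.  And because simulated markers are
LD-free, the distribution of locus *widths* in synthetic runs is
narrower than in real panels.
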