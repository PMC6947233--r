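---
title: "Methods: genotype and haplotype divergence scans in divscan"
author: "divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype and haplotype divergence scans in divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`divscan` analyses a single cohort that is splitting into two
subpopulations under divergent selection — the motivating case is a sport
horse breed in which breeders specialize towards either show jumping (SJ)
or other disciplines (NS), with the split defined by the estimated breeding
value (EBV) for the focal discipline. The pipeline runs: marker quality
control; population-structure inference on an LD-pruned panel (principal
coordinates, K-means/BIC cluster counting, discriminant analysis of
principal components); two selection scans on the full post-QC panel (a
per-SNP fixation-index scan at genotype level and a cross-population
extended-haplotype-homozygosity scan at haplotype level); and
candidate-region construction that requires the two scans to agree, with
gene and QTL annotation. A forward Wright–Fisher simulator with planted
sweeps provides ground-truthed data for every stage.

# Cohort definition

Samples carry an EBV on a scale whose tested-population mean is 100.
`assign_groups()` labels a sample SJ when its EBV is strictly above the
threshold (default 100) and NS otherwise. A value exactly at the threshold
goes to NS: the strict reading of "above" leaves the boundary to the other
group, and assigning it deterministically keeps the partition total.
Missing EBVs yield `unassigned` with a warning rather than an error, so a
partially scored cohort still loads.

`blood_fraction()` scores the expected genome fraction inherited from a
flagged ancestral group (e.g. Thoroughbred) over a pedigree truncated at
`generations` meioses (default 4). Every ancestral path contributes
`(1/2)^d` at the *first* flagged ancestor it meets at depth `d`. Stopping
at the first flagged ancestor is a deliberate choice: if descent continued
past a flagged individual, a fully flagged pedigree would sum to one per
generation and the result would leave `[0, 1]`. Unknown parents contribute
zero, so incomplete pedigrees under-, never over-estimate the fraction.

# Quality control

Filters run in a fixed order — call rate, minor allele frequency,
Hardy–Weinberg — and each marker is attributed to the first filter it
fails, so the attrition table sums exactly.

* **Call rate** (default minimum 0.90): markers genotyped in strictly
  fewer than 90% of samples are removed; the boundary is retained.
* **MAF** (default minimum 0.01): the alt-allele frequency is computed
  from called genotypes only; markers with `min(p, 1-p)` strictly below
  the floor are removed, as are markers with no calls at all.
* **Hardy–Weinberg** (default p < 1e-4): the exact conditional test, not
  the chi-squared approximation — the exact test is stable at the low
  genotype counts where the approximation fails, and it is what standard
  genotype-QC tooling applies by default. The test sums the probabilities
  of all heterozygote configurations no more probable than the observed
  one, conditional on the allele counts. It is applied to the whole cohort
  rather than within groups, matching the default invocation of standard
  QC tools. This has a consequence worth knowing: when the two
  subpopulations are strongly diverged, pooling them induces a Wahlund
  heterozygote deficit proportional to the marker's F_ST, so the very most
  differentiated markers can fail HWE and leave the panel before the scans
  see them. At the modest divergence typical of a recently splitting breed
  the effect is negligible; in deeply diverged simulations it trims the
  extreme F_ST tail.

**LD pruning** (windows of 50 SNPs advanced by 5, r² ceiling 0.5) is
applied only ahead of the structure analyses; the selection scans use the
full post-QC panel, because pruning would remove exactly the locally
correlated markers that carry a sweep signal. Within an offending pair the
member with the lower MAF is removed (tie: the marker later in map order).
The rule is deterministic and keeps the more informative marker; the
window/step scheme never crosses chromosome boundaries. Squared
correlations use pairwise-complete samples; a constant column contributes
r² = 0, and a pair with fewer than two complete observations is skipped.

# Population structure

`ibs_similarity()` computes allele-sharing identity by state,
`s = 1 - sum |g_i - g_j| / (2 m)` over markers called in both samples.
`pcoa()` converts similarities to squared Euclidean distances
`D2 = 2 (1 - s)`, double-centres (`B = -J D2 J / 2`), and
eigendecomposes. The scale factor 2 is arbitrary (it cancels in variance
fractions); what matters is that the transform is monotone in
allele-sharing distance. Negative eigenvalues — possible because
allele-sharing dissimilarities need not be exactly Euclidean — are dropped
rather than shifted, and are excluded from the variance-explained
denominator; shifting (adding a constant to all off-diagonal
dissimilarities) would silently distort the retained axes.

`find_clusters_bic()` runs K-means (multiple restarts under a caller seed)
on the top principal components and scores
`BIC(K) = n log(WSS_K / n) + K log(n)`. Two practical notes. First, the
criterion only resists splitting unstructured noise when many PCs are
retained — with a handful of PCs, K-means can always carve noise into
lower-WSS pieces faster than the `log(n)` penalty accrues. The default
therefore retains `min(100, n - 2)` components, mirroring the established
practice of keeping most PCs at the clustering step. Second, in any
finite-population split-drift cohort the expected within-group kinship is
about `T/(2N)`, i.e. twice the between-group F_ST, so genealogical family
clusters are always about as prominent as the two-population split and the
BIC argmin tends to drift above 2 on such data; the full BIC table is
returned precisely so the flat tail is visible. On cohorts whose members
are exchangeable within groups the argmin lands cleanly on the generative
K.

`dapc_fit()` performs PCA on the centred (column-mean-imputed) dosages and
builds `g - 1` discriminant axes maximizing the between/within variance
ratio on the retained PCs. Membership posteriors use Gaussian
class-conditional densities with the pooled within-group covariance on the
discriminant axes and class-proportion priors; they sum to one by
construction. `dapc_crossvalidate()` repeats stratified 90/10 splits
(default 30 replicates, seeded) and reports, per candidate PC count, the
mean held-out assignment rate and `RMSE = sqrt(mean((1 - rate)^2))`; the
chosen count maximizes the mean rate with ties broken by lower RMSE.
Retaining `n_pcs` requires `n - g` within-group degrees of freedom, so the
fit refuses `n_pcs > n - g`.

# The genotype-level scan

`nei_fst()` implements the fixation index in its unweighted two-population
form: with `pbar = (p1 + p2)/2`,
`F_ST = (H_T - H_S) / H_T`, `H_T = 2 pbar (1 - pbar)`,
`H_S = (2 p1 (1-p1) + 2 p2 (1-p2)) / 2`. The unweighted mean is
appropriate for near-equal group sizes and makes the statistic
algebraically equal to `(p1 - p2)^2 / (2 H_T)`, hence non-negative; the
clamping of negative values required by some estimators can only trigger
through floating-point rounding here. Markers monomorphic in both groups
return 0. No small-sample bias correction is applied. Markers uncalled in
an entire group are excluded from the scan and from the outlier-threshold
denominator.

Significance is empirical: `empirical_threshold()` returns the k-th
largest value with `k = ceiling(f n)` for tail fraction `f` (default
0.001), and the significant set is everything at or above it, ties
included. Values are interpreted qualitatively by `classify_wright()`
(below 0.05 little, 0.05–0.15 moderate, 0.15–0.25 large, above 0.25 very
large differentiation).

# The haplotype-level scan

Input haplotypes are phased upstream (the package consumes `|`-separated
GT fields and never phases). `filter_haplotypes()` first drops haplotype
rows whose missing fraction exceeds a tolerance (default 0: any missing
call), then drops markers still missing in a surviving row, leaving a
complete matrix.

The decay statistic is the *site* (allele-agnostic) extended haplotype
homozygosity: at flank marker x,
`EHHS(x) = pairs identical over [core..x] / pairs identical at the core`.
This form conditions on core-site homozygosity rather than splitting by
core allele, which keeps every core usable including near-monomorphic
ones. It equals 1 at the core and is non-increasing outward. The decay is
truncated when it falls below `cutoff` (default 0.05, the conventional
floor below which the integral tail is noise), when an inter-marker gap
exceeds `max_gap_bp` (default 200 kb, guarding against integrating across
assembly gaps), or at `max_extend_bp` from the core (default 2.5 Mb). The
extension cap follows the convention of haplotype-scan tools that bound
the integration support; 2.5 Mb sits at the expected haplotype scale of a
sweep lasting tens of generations (`1/(T r)` is 2 Mb at T = 50 and
r = 1e-8 per bp) and an order of magnitude above typical background
sharing. Cores whose decay is still above the cutoff at a chromosome end
have an under-estimated integral on that side; they are flagged and, by
default, excluded from standardization (configurable via
`exclude_chrom_end`). The implementation detects these cores exactly,
before walking, from suffix/prefix identity partitions — EHHS is
non-increasing, so a walk reaches the boundary if and only if the boundary
EHHS is still at or above the cutoff.

`integrate_ies()` integrates EHHS against physical distance (trapezoid
rule) over both flanks; no genetic map is assumed. The cross-population
score at a core is `ln(iES_A / iES_B)`; with the reference labelling
`pop_a = "NS"`, `pop_b = "SJ"`, positive scores point to longer haplotypes
(putative selection) in NS and negative in SJ. Scores are standardized
genome-wide without allele-frequency binning, transformed to a two-sided
`-log10` p-value via the Gaussian CDF
(`p = -log10(1 - 2 |Phi(z) - 0.5|)`, computed in log space and capped at
300 to guard overflow), and adjusted by Benjamini–Hochberg step-up FDR
(default level 0.05). A fixed `|z| >= 4` flag is also reported as an
alternative significance rule, but BH-FDR is the primary call.

# Candidate regions and annotation

Each scan-significant SNP expands to a ±250 kb window (clamped at
position 1); touching or overlapping windows on a chromosome, within a
direction, merge. Coordinates are 1-based inclusive internally; BED export
converts to 0-based half-open. Region length in kb is
`round((end - start)/1000)`, matching how published region tables report
lengths. A region is *concordant* when it contains at least one
F_ST-significant SNP; the highest such F_ST is attached. Gene annotation
intersects regions with `gene` features from a GFF3 (any overlap,
inclusive bounds) and tallies biotypes; malformed GFF3 lines are skipped
with a warning unless strict mode is requested. Term enrichment is
database-agnostic: the caller supplies the term-to-gene map, fold
enrichment is `(k/n)/(K/N)` and the p-value the hypergeometric upper tail,
reported raw by default (an optional BH column is available) because
over-representation reports conventionally print raw p-values.

# The synthetic cohort generator

`simulate_divergence()` is a forward Wright–Fisher simulator chosen over a
coalescent because it gives direct control of the split and of selection:
an ancestral pool (default 500 diploids — larger than either subgroup,
because two recently specialized subgroups descend from a base population
with many more breeding animals) with site frequencies from Beta(2, 2)
(the common-variant spectrum a genotyping array ascertains) runs a 100
generation burn-in of random mating with recombination to build LD and a
genealogy, splits into two populations (default 190 diploids each, the
cohort scale the package targets), and drifts independently for T
generations (default 50). Recombination is a Poisson process at 1e-8 per
bp per generation (1 cM/Mb); chromosomes (default 5 × 2,000 SNPs over
25 Mb) assort independently; mating excludes selfing.

A sweep is planted as *single-origin standing variation*: one origin
haplotype is chosen, and every carrier receives an identity-by-descent
copy of the origin's segment around the site, eroded by recombination with
exponential segment lengths whose rate is the allele age times the
recombination rate. The age is not a free parameter: it is the neutral
expectation `E[age | freq f] = -4N f ln(f)/(1 - f)` computed from the
configuration. Selection is genic (fitness 1, 1+s, 1+2s) in the target
population only; an allele lost to drift is retried up to a cap and
reported if still lost. Genotype missingness is applied at a configurable
rate; haplotypes stay complete, as after statistical phasing. Pseudo-EBVs
are drawn per group from N(125, 13.4) and N(77, 11.3), giving the bimodal
distribution that motivates the threshold split. Everything derives from
one seed; identical configurations are bit-identical.

What the generator does **not** emulate: migration and bottlenecks; the
real stallion-centred pedigree (a handful of sires with many offspring),
which concentrates relatedness far more than random mating; array
ascertainment against the reference genome; and genotyping error beyond
uniform missingness. Passing tests on this generator therefore demonstrate
the correctness and calibration of the statistics, not the power of the
scans on any particular real cohort.

# Power at desk scale, and two honest limitations

Two observations from the package's own calibration runs deserve emphasis.

First, between two descendant populations of size N split T generations
ago, the expectation of the per-SNP fixation index is approximately
`(1 - λ^T) / (1 + λ^T)` with `λ = 1 - 1/(2N)` — the total heterozygosity
in the denominator drifts down together with the subpopulation terms. The
familiar closed form `1 - λ^T` describes one population's fixation
relative to the *ancestor*, which is roughly twice as large; comparing a
two-population scan mean against it will appear to "fail" by a factor of
about two even when the simulation and the statistic are both correct.

Second, at census sizes of a few hundred diploids the locus-to-locus
drift noise of `ln(iES_A/iES_B)` is large (standard deviation near 0.45
in the default null), because integrated haplotype homozygosity is
dominated by the minority of haplotype pairs with recent coalescence.
Since the standardized score measures a sweep *against* that noise, no
planted sweep at s = 0.1 over 50 generations — not even a forced
young-origin complete sweep — clears the Benjamini–Hochberg threshold
across ~10,000 cores in such cohorts. The scan still localizes the sweep
(the most extreme scores concentrate at the locus with the correct sign,
and the genotype-level F_ST scan flags it), but FDR-significant
*discoveries* at this scale require either larger cohorts, longer
selection, or stronger selection than that regime provides. This is a
property of the method at small N, not of the implementation; the
brute-force oracles in the test suite pin the statistics themselves to
their definitions.

# Numerical conventions

Positions are 1-based inclusive; BED export converts. The missing-genotype
sentinel is `NA`, never 0. Dosages count the alternate allele (PLINK A1 is
taken as alternate on input), making frequency statistics invariant to
allele labelling. Quantile thresholds use nearest-rank top-k with ties
included. The exact HWE p-value compares configuration probabilities with
a `1 + 1e-10` relative tolerance so ties are included despite rounding.
K-means and cross-validation consume explicit seeds; the pipeline threads
a single seed through every stochastic stage, and rerunning a
configuration reproduces every output byte for byte.

# Problem sizes used in the shipped checks

The test suite exercises the full pipeline at two scales: small cohorts
(tens of diploids, hundreds of markers) for unit and property tests, and
20-seed calibration batches of 200 diploids per population with 5 × 2,000
SNPs — the scale the package treats as its reference study condition —
for the null-calibration and sweep-recovery suites. The acceptance script
reruns the same computations at 6 seeds per batch and writes every
quantity it computes to JSON.
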