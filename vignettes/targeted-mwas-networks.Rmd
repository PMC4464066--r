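---
title: "Methods: targeted MWAS and correlation networks in tmwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted MWAS and correlation networks in tmwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmwas)
```

# The problem and the model

Untargeted high-resolution LC/MS profiling of plasma yields thousands of
m/z features — ions characterized by mass-to-charge ratio and retention
time, quantified per sample — most without a confirmed identity. A
*targeted* metabolome-wide association scan turns one trusted measurement
into a lens on all the others: given the per-sample profile $x$ of an
anchor metabolite (either one of the table's own features or an external
assay of the same samples), the scan computes for every feature $y_j$

$$r_j = \mathrm{cor}(x, y_j), \qquad
  t_j = r_j\sqrt{\frac{n_j-2}{1-r_j^2}}, \qquad
  p_j = 2\,P\!\left(T_{n_j-2} > |t_j|\right),$$

with $n_j$ the number of complete sample pairs, followed by
Benjamini–Hochberg step-up adjustment $q_{(i)} = \min_{j \ge i}
p_{(j)}\,m/j$ over the $m$ features with defined p-values. Features with
$q < \alpha$ form the significant set. The implied assumptions are the
usual ones for correlation inference: approximately bivariate-normal
log-intensities per pair, independent samples, and a monotone (Spearman)
or linear (Pearson) association. Heavy-tailed ion intensities are the norm
in electrospray data, which is why the scan log10-transforms intensities
before Pearson correlation by default (zeros are treated as missing —
a zero ion count carries no usable magnitude); Spearman ranks are
invariant to the transform.

Two-sided p-values from the $t$ transform are used for both coefficient
types; for Spearman this is the standard large-sample approximation with
midranks at ties. A coefficient of exactly $\pm 1$ is assigned $p = 0$ and
flagged by construction (it can only arise from degenerate or duplicated
profiles).

## Self-exclusion

A targeted scan against a metabolite always rediscovers the metabolite
itself: its monoisotopic ion, its $^{13}$C isotopologues (+1.0033548 Th
per substitution) and its electrospray adducts ([M+H]$^+$, [M+Na]$^+$,
[M−H$_2$O]$^+$, [M+2Na−H]$^+$; the Na-for-H replacement adds
21.9819442 Th) all share the underlying abundance and correlate near 1.
These self-correlations are informative for identification but drown the
biology in a Manhattan plot, so `run_targeted_mwas()` removes, before
scanning, every feature within the ppm tolerance of any registered form of
the target mass. The exclusion list is reported in the fit so nothing is
silently dropped.

## Multiple testing

BH is applied per target, not pooled across targets: each anchor asks a
separate metabolome-wide question, and pooling would let a strongly
correlated anchor subsidize the error budget of an unrelated one.
Features with fewer than `min_pairs` (default 10) complete pairs get an
undefined coefficient and are excluded from the adjustment, shrinking $m$
accordingly — reporting them with fabricated q-values would understate the
multiplicity actually tested.

# Mass arithmetic

All tolerance decisions use the signed relative deviation
$\mathrm{ppm} = 10^6\,(m_{\mathrm{obs}} - m_{\mathrm{ref}})/m_{\mathrm{ref}}$
with a default tolerance of 10 ppm, the conventional annotation window for
Orbitrap-class accuracy. Retention-time windows default to 30 s — tight
enough to separate an early-eluting small polar metabolite (~50 s on a
short C18 gradient) from the lipid region (> 350 s), loose enough to
absorb ordinary run-to-run drift. Adduct transforms are exact
monoisotopic arithmetic over a registry built from CODATA/IUPAC masses
(proton 1.0072765 Th, H$_2$O 18.0105646 Th), so a transform followed by
its inverse returns the input bit-for-bit.

Cross-study overlap uses greedy one-to-one nearest-|ppm| pairing:
candidate pairs within tolerance are accepted in order of increasing
absolute ppm error, each feature pairing at most once. Greedy matching is
transparent, symmetric in its accepted pair set, and guarantees the
accounting identity $|A| = \text{common} + A_{\text{only}}$; a globally
optimal assignment would differ only in pathological near-tie clusters
that a 10 ppm window rarely produces. Whether retention time participates
is the caller's choice — chromatography rarely aligns across laboratories,
so the default compares masses only.

# Quality control

`qc_filter()` keeps features with median CV below 50%, median technical-
replicate profile correlation above 0.7, and missingness below 30%, all
strict comparisons against the conventional thresholds for triplicate
injection workflows. The replicate correlation pairs the $k$-th injection
of each biological sample across samples; with singleton groups the
criterion is unevaluable and is skipped with a flag rather than failing
the feature — a feature should not be discarded for lack of evidence
against it. The same logic covers constant features, whose correlation is
undefined.

# Association networks

`build_association_network()` expands breadth-first around seed features:
wave 1 tests every seed against all other features; edges need both
$|r| > r_{\min}$ and $q < q_{\max}$ (BH within the wave, i.e. over the
tests actually performed in that expansion step); accepted neighbours
become depth-1 nodes. Wave 2 repeats from the depth-1 frontier against all
not-yet-recruited features. Depth is capped at 2: deeper waves lose the
seed-centred interpretation and recruit half the table. Within-wave
adjustment is the default because each wave asks a homogeneous family of
questions; a pooled variant (`q_adjust = "pooled"`) is available for users
who prefer one error budget across the whole construction. Spearman is
the network default (robust to the heavy tails that dominate weak
correlations); the scan's default stays Pearson.

A recruitment cap (default 500 nodes) aborts constructions whose
thresholds would swallow the table, with advice to tighten $r_{\min}$ —
inverting, plotting, or reading such a network is meaningless.

## Stringency sweeps

`stringency_sweep()` runs one expansion at the loosest threshold and
derives stricter networks by filtering edges to $|r|$ above each
threshold, keeping seeds plus nodes incident to a surviving edge. This
makes the edge sets nested by construction, which is the point of a
sweep: the same data examined at increasing confidence. Re-running the
full expansion per threshold cannot guarantee nestedness, because the
within-wave BH family changes with the recruited frontier. A consequence
worth knowing: at high stringency a secondary cluster may persist while
its link to the seed drops below threshold, leaving it visibly detached —
that is a faithful description of the data, not an artifact.

## Partial correlations

In partial mode the recruited node set is re-estimated jointly. The
sample correlation matrix of $k$ nodes over $n$ complete observations is
shrunk toward the identity, $R^* = (1-\lambda) R$ off the diagonal, with
the analytic intensity

$$\lambda^* = \frac{\sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij})}
                   {\sum_{i \ne j} r_{ij}^2}$$

clipped to $[0,1]$, where $\widehat{\mathrm{Var}}(r_{ij}) =
\frac{n}{(n-1)^3} \sum_k (w_{kij} - \bar w_{ij})^2$ is the unbiased
empirical variance of the standardized cross-products
$w_{kij} = x_{ki} x_{kj}$. If every off-diagonal sample correlation is
exactly zero the ratio is undefined and $\lambda = 1$ (full shrinkage to
the identity) by convention — there is nothing to preserve. Any
$\lambda > 0$ makes $R^*$ positive definite even when features outnumber
samples, so the inversion to partial correlations
$P_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$, $\Omega = R^{*-1}$,
is always well posed; a numerically singular input without shrinkage
falls back to the Moore–Penrose pseudoinverse only on request. Partial
correlations are computed on the recruited subgraph, not all measured
features: conditioning a seed-centred neighbourhood on tens of thousands
of irrelevant features is neither feasible (a $40000^2$ inversion) nor
meaningful for the question the network asks. Edge p-values in partial
mode reuse the $t$ transform with the complete-case $n$; this is an
approximation (the effective degrees of freedom after conditioning on
$k-2$ others are smaller), acceptable because thresholds, not exact
partial p-values, carry the decision.

Shrinkage requires complete data. The default uses complete-case rows;
half-minimum imputation (each missing cell replaced by half the feature's
smallest observed positive intensity, the usual proxy for
below-detection-limit censoring) is available but off by default, since it
fabricates rank and magnitude information.

## Cross-study pattern similarity

`pattern_similarity()` asks, for each feature of a matched cross-study
set, whether its correlation profile is conserved: its off-diagonal row in
study A is Pearson-correlated with the same row in study B over the $k-1$
shared partners, and the feature is selected when the coefficient is
positive with two-sided $p < \alpha$. Requiring positivity is deliberate —
an inverted correlation pattern is evidence against conservation, not for
it — and halves the null selection rate to about $\alpha/2$ per feature,
a property the test suite verifies by simulation.

# Visualization

Three Manhattan plot types share $y = -\log_{10} p$ and the colour code
(blue positive, red negative correlation) and differ in the x-axis:
type 1 plots m/z (the mass-domain overview), type 2 retention time (which
exposes chromatographic co-behaviour, e.g. a significant band in the lipid
region), type 3 mean log10 intensity (which separates, for instance, a
$^{12}$C/$^{13}$C pair by abundance). The dashed significance line is
drawn at the largest p-value with $q < \alpha$ — the realized BH cutoff —
and omitted when nothing is significant, never fabricated from the
nominal level. Network layouts are force-directed with a caller-supplied
seed, so a layout is reproducible by construction; renderers return a
machine-readable spec (threshold value, layout coordinates) so contracts
can be tested without parsing vector graphics.

# The synthetic-data generator

`simulate_feature_table()` exists so that every claim above can be tested
against known truth without any external download. It emulates the
statistical skeleton of a cohort-scale HRM experiment:

* log10 intensities are multivariate normal — correlations are planted on
  the log scale, consistent with the scan's default transform — realized
  per module through the Cholesky factor of the (parent + members) block,
  reusing the parent's innovations so the planted correlation with the
  parent is exact;
* modules can hang off the anchor or off an earlier member (`parent`),
  directly or through the member's anchor-orthogonal residual
  (`parent_link = "residual"`), which plants a secondary cluster exactly
  uncorrelated with the anchor — the structure a depth-2 network should
  find and a depth-1 network should not;
* companion ions copy a parent with an exact adduct/isotope mass shift and
  signal-proportional noise (default scale 0.05, noise 5%), giving the
  ~0.99 parent–companion correlation characteristic of $^{12}$C/$^{13}$C
  pairs;
* unspecified masses are drawn uniformly but rejected within 20 ppm of
  the anchor's ion family, so self-exclusion removes exactly what was
  planted; missingness is completely at random at a configured rate.

Defaults mirror the cohort scale the package targets: 50 samples, one
anchor, late-eluting modules (360–480 s) against an early anchor.
`choline_casestudy_fixture()` pins the anchor at m/z 104.1062 (51 s) with
a $^{13}$C companion and an eight-feature phosphocholine-like module at
known adduct masses, planted at $r = 0.6$.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: chromatographic peak shape and drift,
intensity-dependent (non-MCAR) missingness, batch and injection-order
effects, ion suppression, correlated null features from shared noise
sources, and heteroscedastic mass error. Results on simulated tables
validate the machinery, not the biology.

# Numerical and design choices

* **Raw vs log intensities.** The scan's Pearson mode log10-transforms by
  default; reported intensity summaries are log-scale. A flag
  (`log_transform = FALSE`) preserves raw-scale analysis; Spearman is
  unaffected.
* **Missing data.** Pairwise-complete deletion with `min_pairs = 10`;
  below that a correlation at $n = 50$-scale cohorts is too unstable to
  interpret, and the feature is flagged undefined rather than guessed.
* **Tie-breaks.** Feature display ids collide when two features round to
  the same "m/z_rt" string; an ordinal suffix disambiguates. Matching
  returns candidates ordered by |ppm| and resolution takes the closest.
* **Degenerate inputs.** Constant profiles yield undefined correlations
  (reported `NA`, excluded from BH); an all-missing replicate group stays
  missing after averaging; an empty network writes valid GML with zero
  node blocks.
* **Determinism.** Every stochastic operation takes an explicit integer
  seed; replicate seeds inside simulation studies are drawn once from the
  master seed. Manifests record the seed, all options and input MD5
  hashes; two runs with identical options produce manifests identical up
  to timestamps.
* **Provenance format.** The run manifest is JSON rather than an R
  serialization: the reproducibility contract (options + inputs + seed →
  outputs) is language-neutral, and JSON keeps it greppable and parseable
  outside R.

# Problem sizes

The test suite and the acceptance script size their simulations to what
the claims need, not more: the false-discovery-rate study uses 500
replicates of 50 samples × 1050 features (1000 null, 50 planted at
$r = 0.6$) and completes in well under a minute on one CPU; the power and
bias study uses 200 replicates at $r = 0.7$; oracle equivalences
(partial-correlation closed form, brute-force BH) use 1000 and 50 random
instances respectively. At these sizes the Monte Carlo error of the FDP
estimate is about 0.0015, an order of magnitude below the 0.05 criterion
it is compared against.

# Known limitations

Charge states above one and isotope-pattern deconvolution are out of
scope: the adduct registry assumes singly charged species, which covers
small-molecule plasma profiling but not intact peptides. The scan is
marginal correlation — no covariate adjustment or regression MWAS. The
partial-correlation p-values are approximate as noted. Database lookup
(Metlin, HMDB) is intentionally absent: the package computes the mass
arithmetic and tolerance logic, and leaves identity claims to MS/MS and
curated resources. Networks are reported as constructed; no community
detection or enrichment is attempted.
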