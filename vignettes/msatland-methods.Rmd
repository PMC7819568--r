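---
title: "Methods and design notes for msatland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for msatland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msatland` implements a multi-scale population and landscape genetics
workflow for codominant microsatellite data: diversity and differentiation
statistics at the regional scale, isolation-by-distance (IBD) and
isolation-by-resistance (IBR) inference by matrix regression over
hypothesis-driven resistance surfaces, and fine-scale kinship spatial
autocorrelation for detecting philopatry. This vignette records the models,
the estimator dialects, the numerical choices, and the reasoning behind the
design decisions that were genuinely open.

## Data model

A `genotype_table` holds diploid allele-size calls (base pairs) for `n`
individuals at `L` microsatellite loci, each locus carrying its repeat-unit
length, plus a site id per individual. Missingness is all-or-nothing per
individual-locus pair: GenAlEx-style inputs encode a missing genotype as
`0,0` (blank and `NA` are also accepted on read), and a lone missing allele
is rejected rather than half-imputed, because both the Bruvo matching and
the allele-frequency machinery assume complete diploid calls and
fragment-analysis pipelines essentially never emit half-calls. Allele sizes
are stored losslessly in base pairs; conversion to repeat units happens
only inside the distance computation.

Distance matrices are the currency between stages. Every `dist_matrix` is
labelled, symmetric, zero-diagonal, and carries a units tag (`bruvo`, `km`,
or `resistance`); label mismatches between stages are errors, never
silently reordered.

## Diversity and differentiation

Observed heterozygosity is the fraction of heterozygotes among genotyped
individuals; expected heterozygosity uses the unbiased estimator
$\hat H_e = \frac{2n}{2n-1}\,(1-\sum_a p_a^2)$, and the inbreeding
coefficient is $F_{IS} = 1 - H_o/H_e$ (undefined at monomorphic cells,
reported as `NA`). Because "mean $F_{IS}$" is ambiguous, both aggregates —
the mean over all site-by-locus cells and the mean of site means — are
emitted under distinct labels.

Differentiation uses the $G_{ST}$ family. Per locus, $H_S$ is the mean
within-site expected heterozygosity, $H_T$ the expected heterozygosity of
the mean allele frequencies, $G_{ST} = (H_T - H_S)/H_T$, and Hedrick's
standardized index is

$$G'_{ST} = G_{ST}\,\frac{k - 1 + H_S}{(k-1)(1 - H_S)},$$

with $k$ subpopulations. The default estimator dialect applies the Nei &
Chesser small-sample corrections (harmonic-mean sample size $\tilde n$;
$\hat H_S = H_S\,2\tilde n/(2\tilde n - 1)$ and
$\hat H_T = H_T + \hat H_S/(2\tilde n k)$), which is what GenAlEx-style
tools report; `corrected = FALSE` switches to the uncorrected Nei (1973)
estimators so results can be checked against hand-computable textbook
values. Multilocus values are ratios of sums over loci, standardized with
the mean $\hat H_S$. Negative pairwise $G'_{ST}$ estimates are reported as
computed and annotated "interpret as 0" — truncation would bias
resampling distributions.

Pairwise significance is dual-reported, because "bootstrapping over loci
for N permutations" conflates two procedures: (i) a percentile 95% CI from
resampling loci with replacement (significant when the CI excludes 0), and
(ii) optionally a permutation p-value from shuffling individuals between
the two sites. Both are named explicitly in the output.

The Hardy-Weinberg test is the conditional exact test on the genotype
array given allele counts, ordering tables by their conditional (Levene)
probability, with equal-probability tables included in the tail
(Guo-Thompson ordering). Full enumeration is used for at most 3 alleles
and 30 individuals; otherwise Monte Carlo shuffling of the gene array with
the add-one correction. Linkage disequilibrium is tested with a composite
genotypic statistic — the sum of squared covariances between allele
dosages at the two loci — against a null built by permuting one locus's
genotypes across individuals; it requires no phase information. Bonferroni
is the only multiple-testing correction provided. All resampling flows
from a single seeded generator per call.

## Bruvo distance

The per-allele distance under stepwise mutation is
$d(x, y) = 1 - 2^{-|x-y|}$ with $x, y$ in repeat units
(`size / repeat_length`, kept as real numbers so sub-repeat variants
survive). The diploid locus distance is the minimum over the two perfect
matchings of the mean of the two allele distances — at ploidy 2 the
explicit minimum replaces any assignment-problem machinery. Individual
distances average per-locus values over the loci where *both* individuals
are genotyped (whole-locus pairwise deletion with per-pair
renormalization); this differs deliberately from genome-addition/loss
treatments of missing data, which address ploidy differences that do not
arise here. Pairs sharing zero loci are flagged, not imputed. Site-level
genetic distance is the mean over all cross-site individual pairs.

## Landscape distances

Geographic distances are haversine great-circle distances on a sphere of
radius 6371.0088 km.

Resistance surfaces are built from a categorical land-cover raster by
grouping classes into five cover groups (developed, cultivated,
forest/shrub, grassland, other; the NLCD code mapping is configurable) and
assigning a low resistance to the permeable groups of a named hypothesis
and a high resistance to everything else. Five hypotheses are provided:
semi-natural cover permeable (A); woody-substrate cover — developed,
cultivated, forest — permeable (B); and each of those three covers
permeable alone (Set C). Crossing them with four (low, high) value pairs
(0.1/0.9, 0.1/0.5, 0.3/0.9, 0.3/0.5) probes nonlinearity and yields the
20-surface suite; with the two IBD models this gives the 22-model suite.
Nodata cells get the high value rather than acting as barriers, so data
gaps cannot disconnect the landscape graph. Surfaces are aggregated by
non-overlapping block means ("210 m" from 30 m input means factor 7 — the
squared-unit phrasing in common usage denotes the cell edge); blocks are
anchored at the top-left corner.

Resistance distance is the effective resistance of the raster viewed as an
electrical network: nodes are cells, edges join 8-neighbors, edge
conductance is the arithmetic mean of the two cell conductances divided by
the center distance in cell units (1 rook, $\sqrt2$ diagonal; the
resistance-mean alternative is available behind a flag for sensitivity
analysis). Effective resistance — not commute time, which differs only by
a constant factor (twice the total edge weight) and therefore cannot
change matrix-regression inference — is computed from the graph Laplacian
via one sparse linear solve per sampling point against a grounded
reference node. Points snap to the center of the containing cell, with
boundary ties going to the lower-index cell.

The raster is indexed row-major from the top-left; external coordinates
are geographic. For synthetic data the package uses a local equirectangular
mapping between the metric raster grid and lon/lat around a fixed
reference point; at study scales (tens of km) the projection error is
orders of magnitude below the 210 m cell size. Real rasters should be
supplied in a metric projection by the caller — the package deliberately
contains no reprojection engine.

## Matrix regression (MRDM)

`mrdm()` unfolds strict lower triangles, fits OLS with an intercept, and
reports $R^2$ and $F = (R^2/q)/((1-R^2)/(n-q-1))$ over $n$ site pairs and
$q$ predictors. Inference permutes rows and columns of the **response**
matrix simultaneously (the convention of the MRM family; residual- or
predictor-permutation variants are deliberately not implemented),
recomputing $F$ each time:

$$p = \frac{1 + \#\{F_{perm} \ge F_{obs}\}}{n_{perm} + 1},$$

with ties counted toward the tail and the add-one correction guaranteeing
$p > 0$ (tools that report $\#\{\ge\}/n_{perm}$ can return 0; the
difference is $O(1/n_{perm})$). Per-coefficient p-values use $|t|$
analogously. Predictors are z-standardized over the unfolded vector by
default so coefficients are comparable across units (km vs resistance);
raw coefficients are available. With a single predictor the permutation p
agrees with a plain Mantel test up to Monte Carlo error, which is asserted
in the test suite.

`run_model_suite()` fits the two IBD models — all sites, and the subset of
sites more than 1 km apart, formed by keeping only the two end sites of
each within-region transect — plus one IBR model per surface, and returns
the table sorted by $F$. Every value variant is labelled with its
hypothesis and (low, high) pair so any row is locatable.

## Kinship autocorrelation

Pairwise kinship uses the Loiselle estimator,

$$F_{ij} = \frac{\sum_l \sum_a \left[(p_{ila}-\bar p_{la})
(p_{jla}-\bar p_{la}) + \frac{\bar p_{la}(1-\bar p_{la})}{n_l - 1}\right]}
{\sum_l \sum_a \bar p_{la}(1-\bar p_{la})},$$

with allelic states $p_{ila} \in \{0, \tfrac12, 1\}$ and reference
frequencies $\bar p_{la}$ pooled over the **whole filtered dataset** —
kinship relative to the total sample is what makes "elevated relatedness
at short distance" interpretable. The small-sample term uses
$1/(n_l - 1)$; the $1/(2n_l - 1)$ dialect found elsewhere in the
literature is available behind a flag, and both are cross-checked against
a direct formula transcription in the tests. Loci missing in either
individual drop out of both sums for that pair.

Pairs are binned by great-circle distance into classes
(0-250, 250-500, 500-750, 750-1000 m by default, each interval
$(lo, hi]$), with distance-0 pairs (same plot) in the first class and
everything beyond the last edge pooled into a far class reported at a
nominal 25 km. The within-plot pairs are additionally reported as a
separate labelled `within_site` row, since they are of independent
interest and also members of class 1. Standard errors come from
delete-one-locus jackknifing; the null envelope permutes the
genotype-to-location assignment (kinship values are fixed; only the
pair-to-class map changes), reporting the 2.5/97.5 percentiles and a
two-tailed rank-based p — a relatedness *deficit* is as reportable as an
excess.

## Synthetic data generator

The simulator is forward-time — philopatry and resistance-dependent
migration are most naturally expressed forward, and desk-scale sizes keep
it fast. One deme of `deme_size` diploids per region; founders draw from a
shared triangular allele pool over 8-20 repeat units (configurable; a
single-allele pool gives the no-variation limit). Each generation, every
offspring slot picks a source deme by backward migration — total
emigration probability `migration_total`, spread across regions
proportionally to $\exp(-\lambda R_{ij})$ with $R$ the effective
resistance between region anchors on the generating surface — then two
distinct parents (no selfing; sexes are not modelled, matching female-only
sampling), one allele from each with stepwise $\pm 1$ mutation at rate
`mu`, reflecting at 5 and 40 repeat units to stop unbounded drift.
Offspring of non-migrants keep the first parent's natal subsite
(transect collection point) with probability `philopatry`, otherwise — and
always for migrants — they draw a uniform subsite. The final generation is
sampled without replacement per collection point. Integer allele
arithmetic and a single master seed (with deterministic per-stage child
seeds) make every output reproducible bit for bit.

Default parameters: 10 loci with dinucleotide repeats, `mu = 0.005`
(microsatellite mutation rates are commonly 1e-4 to 1e-2 per generation),
`deme_size = 40`, 60 generations, `migration_total = 0.05`, and
`lambda = 5` per effective-resistance unit. Transect regions place 5
collection points at 0-1200 m in 300 m steps, matching the nested design
the fine-scale analysis assumes.

What the generator emulates: hierarchical sampling (regions, transects,
plots), stepwise mutation, drift, resistance-governed migration, and
matriline-like subsite fidelity. What it does not: null alleles and
scoring error, sex-biased dispersal, selection, overlapping generations,
and demographic change. Passing tests therefore demonstrate that the
estimators and their inference machinery behave correctly under the
model's own assumptions — not that any particular field system satisfies
those assumptions.

## The recovery benchmark

Validating the 22-model suite needs a scenario where the generating
hypothesis is genuinely identifiable, which constrains the design more
than intuition suggests. Three properties matter. First, on a two-level
conductance raster the effective resistances between points span only
~0.1-0.3 units (the permeable background shunts every corridor), so the
migration decay must e-fold well inside that span — the benchmark uses
`lambda = 50`; with a gentler decay, migration is nearly uniform and *no*
surface is recoverable. Second, corridor topology must decouple the
competing hypotheses: the benchmark places twelve regions in three
spatially interleaved rows, each row internally chained by corridors of a
*single* woody cover (cultivated, developed, forest respectively) with no
between-row corridors. Under the generating hypothesis B all rows are
internally connected; each single-cover hypothesis mispredicts two of the
three rows; hypothesis A (semi-natural permeable) sees the grassland
background as permeable everywhere and degenerates to a smooth
distance-like predictor; and geographic distance cannot reproduce the
row-block structure because within- and between-row separations overlap.
Third, drift noise with 10 loci is substantial, so the benchmark uses
demes of 50 run for 150 generations at `migration_total = 0.25`, placing
within-row pairs near migration-drift equilibrium while rows stay
differentiated. Recovery is scored at the hypothesis level (the top-ranked
model's hypothesis equals the generating one): the four (low, high) value
variants of one hypothesis yield near-collinear resistance matrices, so
the variant label within the winning hypothesis is not an identifiable
quantity and is not scored.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path with stable statistics: oracle
comparisons on up to 12 individuals / 6-node graphs at 1e-10 to 1e-12
tolerances; permutation-calibration checks at 200 replicates of 199
permutations; envelope coverage at 100 replicates; hypothesis recovery at
50 replicates of the benchmark above; philopatry detection at 20
replicates with `philopatry = 1`. The shipped pipeline defaults are the
full-scale analysis settings (10,000 MRDM and autocorrelation
permutations, 9,999 pairwise resamples, 20% missing-data threshold,
250/500/750/1000 m classes with a 25 km far class, factor-7 aggregation).

Other numerical conventions: HWE probability ties use a relative 1e-9
tolerance when accumulating the tail; permutation ties count toward the
tail everywhere (conservative); monomorphic loci contribute nothing to
kinship sums and are skipped (flagged) in differentiation when $H_T = 0$;
$F$-statistics of pairs where a site has fewer than 2 individuals carry a
`low_n` flag; the Laplacian solve grounds the last sampling point's node
and solves one sparse system per remaining point.

## Known limitations

No Weir & Cockerham theta, AMOVA, rarefied allelic richness, or effective
population size estimation; no sibship reconstruction (an explicit
exclusion list stands in for it — whether a deposited dataset already
flags siblings cannot be decided from the data, so the pipeline never
guesses); no null-allele modelling; no least-cost-path distances or
raster reprojection; no polyploid Bruvo variants; no commonality analysis
or surface optimization on top of the MRDM suite. Bayesian clustering
(STRUCTURE-family) is deliberately out of scope — published tools cover
it, and its outputs feed none of the quantities computed here.
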