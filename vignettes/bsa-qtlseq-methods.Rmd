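---
title: "Methods: delta(SNP index) bulked-segregant scans with bsascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta(SNP index) bulked-segregant scans with bsascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The method

Bulked-segregant analysis by whole-genome sequencing (QTL-seq / BSA-seq)
maps quantitative trait loci without genotyping a full mapping population.
From an F2 between two inbred parents, the individuals with the most
extreme phenotypes are pooled into a *high* and a *low* bulk (here 20
plants each, the design used for grain-elongation mapping in rice), and
each pool is shotgun-sequenced. At every SNP distinguishing the parents,
the **SNP index** of a bulk is the fraction of its reads carrying the
*donor* allele — the allele from the parent that raises the trait; an
index of 0.5 is the expectation for an unselected locus, 1 means the bulk
is fixed for the donor segment. The statistic of interest is

$$\Delta(\text{SNP index}) = \text{index}_{\text{high}} -
\text{index}_{\text{low}},$$

which is centred at 0 genome-wide and departs from 0 near a locus under
divergent selection between the bulks.

`bsascan` implements the full chain: per-SNP indices and filters
(`compute_snp_index()`, `filter_by_depth()`, `filter_low_index_both()`),
sliding-window smoothing (`sliding_windows()`), a Monte-Carlo null
distribution with per-depth confidence bounds and empirical p-values
(`null_delta_distribution()`, `ci_table()`, `empirical_p()`), region
calling (`call_regions()`), and downstream single-marker validation
statistics (`single_marker()`, `joint_pve()`, `bulk_allele_frequency()`,
`ge_ratio()`). A complete F2 simulator (`simulate_bsa_experiment()`)
provides calibrated synthetic experiments.

## The null model and its confidence bounds

Even with no QTL anywhere, delta fluctuates for two reasons: the bulks are
finite random samples of F2 individuals (bulk-composition noise), and each
bulk is sequenced to finite depth (binomial read-sampling noise). The null
simulation reproduces exactly this two-stage process for a bulk of $B$
individuals sequenced to depth $d$:

1. draw the summed donor dosage of the bulk as Binomial($2B$, ½) — the sum
   of $B$ independent F2 dosages, each Binomial(2, ½) — and divide by $2B$
   to get the bulk allele frequency $p$;
2. draw the donor read count as Binomial($d$, $p$) and divide by $d$.

Delta is the difference of two such independent indices, so by the law of
total variance

$$\operatorname{Var}(\Delta) = 2\left(\frac{1}{8B} +
\frac{E[p(1-p)]}{d}\right),$$

which the test suite checks against the simulation (s.d. 0.171 at
$d = 29$, $B = 20$; 0.112 in the $d \to \infty$ limit). Confidence bounds
are empirical quantiles of the simulated delta: the default two-sided
convention takes the $1 - (1-L)/2$ quantile as the upper bound at level
$L$, which at depth 29 and bulk size 20 gives upper bounds of about 0.34
and 0.45 at the 95% and 99% levels — consistent, to the published
precision, with the 0.33/0.43 pair reported for the rice
grain-elongation scan at that depth. A one-sided convention is available
(`ci_table(..., two_sided = FALSE)`).

Per-SNP empirical p-values use the add-one correction
$p = (1 + \#\{|\Delta_0| \ge |\Delta|\})/(n_{\text{sims}} + 1)$, so the
smallest attainable p is $1/(n_{\text{sims}}+1)$, never 0. Note that at
depth $d$ the null delta is supported on multiples of $1/d$; quantiles and
p-values inherit that granularity.

The low-index data filter is *not* applied inside the null simulation by
default; `null_delta_distribution(..., low_index_filter = 0.3)` enables it
for sensitivity analysis.

## Filters

* **Depth**: a SNP is kept when both bulks reach `min_depth` reads
  (default 29, the high-confidence cutoff of the motivating study). The
  joint both-bulk rule is the conservative choice that keeps the two
  indices comparable; `rule = "either"` and `rule = "sum"` are provided
  because pipelines differ in how they word this cutoff. Note that with
  bulks sequenced to ~22x, a per-bulk cutoff of 29 is very aggressive
  (it keeps <1% of SNPs under a Poisson depth model); the simulation
  studies below therefore run with `min_depth = 10`, and users should set
  the cutoff relative to their realized depth.
* **Low index in both bulks**: SNPs with index < 0.3 in *both* bulks are
  removed as likely sequencing/alignment artifacts (a genuine segregating
  SNP should show the donor allele in at least one bulk). The inequality
  is strict, so a SNP at exactly 0.30 survives.
* **Undefined records**: zero-depth draws yield undefined indices; they
  are flagged `NA` and excluded downstream rather than imputed.

Both filters commute, and every filter reports its record counts via
messages so a chromosome-wise accounting table can be assembled from a
run's log.

## Windows and region calling

Windows of 2 Mb advance in 10 kb steps along each chromosome (defaults;
both configurable). Window means are unweighted arithmetic means over
member SNPs in the closed interval $[s, s + w - 1]$, 1-based, matching
VCF coordinates; BED output converts to 0-based half-open. Two layout
choices deserve note:

* only windows that fit entirely on the chromosome are emitted, so every
  window has the same true width — trailing partial windows would carry
  very few SNPs and emit noisy, incomparable means;
* windows with fewer than `min_snps = 3` defined SNPs report no means,
  guarding against single-SNP spikes.

A window is *significant* when |mean delta| exceeds the null bound at the
window's read depth (rounded mean across member SNPs and bulks, nearest
simulated depth) **and** its mean per-SNP empirical p-value is below 0.05.
"Average p below threshold" is implemented as the mean of per-SNP
p-values, the reading that matches per-SNP nulls; the p-value of the mean
delta would require a separate window-level null for every window size
and SNP count and is not what the per-depth bounds describe.

Significant windows of the same delta sign merge into regions. Because
consecutive window starts overlap by 99.5% under the defaults, a literal
"gap of at most 2 windows" rule would split one physical signal into
bp-adjacent fragments; the merge rule therefore joins significant windows
whose genomic extents overlap, plus `max_gap_windows` (default 2) extra
step positions. For non-overlapping tiling windows this reduces exactly
to the simple gap rule. A sign change always splits. Region bounds are
the outermost member-window bounds, and the donor parent is assigned from
the delta sign (positive delta = high bulk enriched for the donor
allele). No genome-wide multiple-testing correction is applied beyond the
per-window bound — the convention of the QTL-seq literature — so isolated
false windows are possible and the null false-region rate is a property
the simulation suite measures rather than controls.

## The F2 simulator

The generator reproduces the statistical structure the scan assumes, with
defaults set to the motivating study's design:

| Parameter | Default | Meaning |
|---|---|---|
| `n_individuals` | 178 | phenotyped F2 lines |
| `bulk_size` | 20 | plants per extreme bulk |
| `depth_mean`, `depth_model` | 22, Poisson | per-bulk read depth (between the two bulks' reported 21.25x/23.16x averages) |
| `sequencing_error` | 0.001 | symmetric per-read allele flip |
| `cm_per_mb` | 4 | rice-scale recombination rate |
| `heritability` | — | fraction of phenotypic variance that is genetic |

Meiosis follows the Haldane model: crossover counts per gamete are
Poisson with mean equal to the genetic length in Morgans, crossover
positions are uniform, the telomeric phase is a fair coin, and there is no
interference — so the recombination fraction satisfies
$r = (1 - e^{-2m})/2$, which the test suite verifies at $m = 0.5$.
Phenotypes are additive + dominance ($-a$, $d$, $+a$ for dosage 0/1/2)
plus Gaussian noise scaled so the *realized* genetic variance fraction
equals the requested heritability; a polygenic background is represented
by the noise term only. Bulks take the exact phenotypic extremes with a
deterministic index tie-break. Pooling is idealized — exactly equal DNA
per plant — and read sampling is binomial at the bulk allele frequency
after the symmetric error flip $p' = p(1-e) + (1-p)e$.

One root seed drives everything; meiosis, phenotype noise, read sampling
and the null simulation each use an independent derived substream, so any
stage can be re-run alone and identical seeds give byte-identical outputs
(the pipeline writes seeds and parameters into every artifact header).

What the generator does **not** emulate: read-level errors and mapping
bias, indels and multiallelic sites, uneven pooling, library-level
overdispersion beyond binomial sampling, segregation distortion, and
crossover interference. Passing tests therefore demonstrate the
statistical machinery is correct under the stated model, not that real
data meet the model; with real data, the low-index filter and depth
cutoff carry the burden of removing artifact SNPs.

## Marker-trait statistics

Single-marker analysis regresses the phenotype on dosage coded
$(-1, 0, +1)$ by ordinary least squares: PVE $= 100R^2$, LOD
$= -(n/2)\log_{10}(1 - R^2)$ (equivalently $(n/2)\log_{10}(RSS_0/RSS_1)$,
the identity the tests verify to $10^{-10}$), additive effect = the slope,
i.e. half the homozygote difference, and donor = the parent whose allele
has a positive slope. A 2-df genotype-class model is available via
`model = "genotype"` since published single-marker tables rarely state the
coding. Missing genotypes are dropped listwise per marker; the joint PVE
of several markers is the $100R^2$ of the multiple regression with
listwise deletion, with collinear columns dropped and reported. The LOD-3
reporting threshold is a convention, exposed as `lod_threshold`.

The grain-elongation ratio is computed per replicate as mean cooked
length / mean milled length (default design: 3 replicates x 10 grains),
reported as the mean and s.d. across replicates; it is scale-invariant in
the length units.

## Validation study sizes

The shipped test and acceptance studies use: null bounds from 1e5
replicates at depth 29; calibration on 25 replicate no-QTL genomes of 10 x
4 Mb chromosomes with SNPs every 100 kb, judged against cluster-robust
standard errors across replicates (linked SNPs are correlated, so a
binomial s.e. over SNPs would be anti-conservative); and parameter
recovery over 100 replicate experiments on a 31 Mb chromosome (SNPs every
50 kb, QTL at 6.7 Mb, $a = 1$, $h^2 = 0.8$), where a single called region
containing the true position is required in at least 90% of replicates.
These sizes give stable Monte-Carlo estimates at interactive runtimes.

## Known limitations

* Confidence bounds are per-depth lookups at the window's rounded mean
  depth; when the two bulks' depths differ strongly, the single-depth
  null slightly understates the read-sampling variance (convexity of
  $1/d$).
* Region boundaries are window-grid quantities (multiples of the step
  size) and inherit the smoothing scale: a 2 Mb window cannot resolve
  loci much closer than the window width, and a strong QTL's region
  extends as far as linkage keeps window means above the bound.
* The empirical p floor is $1/(n_{\text{sims}}+1)$; raise `n_sims` if you
  need smaller p-values than that.
* `joint_pve()` is a descriptive $R^2$, not a variance-component
  estimate; with linked markers it double-counts shared signal exactly as
  a multiple regression does.
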