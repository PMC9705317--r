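---
title: "Methods: models, estimators and design choices in minpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in minpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`minpop` implements a population-genomic workflow for structured mosquito
cohorts: cohort simulation, QC, PCA-based structure inference with outlier
and mislabel handling, diversity statistics over four-fold degenerate sites,
windowed Hudson F~ST~ scans with selection-signal detection, and
per-population allele-frequency reports for insecticide-resistance genes.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the design decisions taken where the methodology
was genuinely open.

## The cohort simulator

### Divergence model

The generator uses the Balding–Nichols model. For each variant site an
ancestral allele frequency $p$ is drawn uniformly on $[0.05, 0.95]$; each
population $k$ draws its own frequency

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F_k}{F_k},\;(1-p)\,\frac{1-F_k}{F_k}\right),$$

which has mean $p$ and variance $p(1-p)F_k$, and diploid genotypes are
independent binomial draws from $p_k$. The appeal of this model is that the
divergence parameter is the recovery target in closed form: for two
populations the expected Hudson F~ST~ is $(F_i + F_j)/2$, so estimator
consistency can be tested against a known truth without a coalescent
simulator. A coalescent model was deliberately avoided: it would add a heavy
dependency and slow the generator by orders of magnitude while testing
nothing extra about the estimators downstream.

The uniform ancestral band $[0.05, 0.95]$ avoids degenerate monomorphic
draws while still letting population-level fixation arise through drift at
high $F$. Sites that come out monomorphic across all samples are retained —
they exercise the invariant-site census.

**Consequence of one $F$ per population.** A per-population $F$ vector
cannot realise an arbitrary pairwise differentiation matrix. The default
$F = (0.003, 0.003, 0.055, 0.055)$ for the TD/PV/RK1/RK2-analogue
populations reproduces the study's headline scale — TD–PV ≈ 0.003 and
RK2-versus-others ≈ 0.03 — but forces RK1–RK2 ≈ 0.055 rather than ≈ 0.03.
This is a known constraint of the model, accepted because the quantities the
pipeline is validated against (the low TD–PV contrast and the ~0.03
RK2 contrasts) are the ones the model can hit simultaneously.

### Planted features

* **Sweeps**: inside a configured interval the target population's $F$ is
  replaced by `f_sweep` (which must exceed every background $F$). This
  modifies marginal differentiation only; hitchhiking linkage disequilibrium
  is a declared non-goal, and windows/thresholds — not haplotype structure —
  are what the detector consumes.
* **Isolated outliers**: each outlier is drawn from its *own* private
  population with divergence `outlier_f` (default 0.3). Drawing each from a
  separate population makes them mutually isolated, matching the intended
  phenotype of single samples that belong to no cluster and dominate
  individual principal components. The default 0.3 is a free choice of this
  package: no quantitative description of how distinct such outliers are in
  real data was available, so the value was fixed once at "unambiguously
  separate but same species" scale.
* **Mislabelled group**: `n_mislabeled` samples are drawn genetically from
  `mislabel_from` (default the RK2-analogue) but recorded with the
  collection site and province of `mislabel_as` (default the PV-analogue).
  They are extra draws on top of the per-population sizes, so the default
  cohort totals 302 = 283 assignable + 9 mislabelled + 10 outliers.
* **Multiallelic sites**: a configured fraction (default 0.134) of
  segregating sites is converted by re-assigning chromosomes that carry the
  alternate allele across two (or, for a 0.056 sub-fraction, three) distinct
  alternate alleles, conserving total allele count. Splitting an existing
  draw, rather than layering a second mutation model, keeps site frequency
  structure intact.
* **Missing genotypes** are planted per genotype call at `missing_rate`
  (default 0.01).

Collection metadata mirrors the study design: five sites in three provinces,
with the two Ratanakiri-analogue populations sharing the same two collection
sites — so recorded metadata genuinely cannot distinguish them, which is
what makes cluster-versus-label consistency checks meaningful.

### What the generator does not emulate

No linkage disequilibrium, recombination, demographic history, or
sequencing-read error; coverage summaries in the metadata are synthetic
numbers drawn to pass QC. Passing tests therefore demonstrate that the
estimators and decision rules behave correctly under the statistical
structure they assume — not that they are robust to LD, batch effects, or
real sequencing artefacts.

### Seeding

One global integer seed; every stochastic operation derives a substream from
a deterministic hash of `(seed, operation name, contig index)`, so whole
cohorts are bit-reproducible and per-stage reruns are stable. All hashes
stay below $2^{31}$.

## QC and the site census

Samples fail QC when median coverage is below 10× or breadth-at-1× is below
80%; both thresholds are inclusive at the boundary, consistent with
exclusion rules phrased as "less than". The site census counts distinct
alleles among non-missing calls — 1 invariant, 2/3/4 bi-/tri-/quadriallelic
— ignoring missing calls rather than dropping sites, because the downstream
statistics are computed from the same allele counts; a site is unclassified
only when fully missing. Accessibility masks are treated as an *input*
(defaulting to all-true): upstream site filters are pipeline-specific and
not re-derived here.

## Population structure

PCA uses alternate-allele dosages (0/1/2) at up to 100,000 biallelic,
non-singleton autosomal SNPs, with missing dosages imputed to the site mean
before per-site centring (mean imputation avoids biased centring and is
standard for genotype PCA). The decomposition is an eigendecomposition of
the sample-by-sample cross-product of the centred dosage matrix; component
signs are arbitrary and all comparisons are made up to sign. Restricting the
same operation to a named contig (e.g. an X-linked one) needs no separate
code path — pass the contig as the autosome set.

### Outlier exclusion

The iterative rule: run PCA; on each of the top 10 components flag samples
whose score lies more than 6 MADs from the per-component median; exclude;
repeat to a fixed point (cap 20 iterations). Two details are this package's
own design, fixed where the qualitative description ("isolated outliers
along single components") left the rule open:

* **Threshold 6 MADs on 10 components.** Robust and scale-free; at cohort
  sizes of a few hundred, 6 scaled MADs is far enough into the tail that no
  inlier is flagged by chance, while a private-population outlier lies tens
  to hundreds of MADs out on the component it dominates.
* **Isolation guard.** A genuine population of, say, 28 samples also sits
  many MADs from the median along the component that separates it — a plain
  MAD rule would amputate real clusters. Flags on a component are therefore
  accepted only when the flagged set is small (≤ 5% of current samples,
  `max_flag_frac`); larger flagged sets are read as population structure and
  ignored. The guard encodes "isolated … not part of any cluster" as a
  testable criterion.

### Cluster assignment and mislabel flagging

After outlier removal, samples are clustered by single linkage on the top
two principal components, cutting the dendrogram at `linkage_cutoff` (0.15)
times the maximum pairwise distance. Each cluster takes the majority
recorded province of its members; a sample is flagged
`excluded_anomalous` when its recorded province differs from its cluster's
majority *and* its recorded province is the majority label of a different
cluster. The second condition matters: when two weakly diverged populations
merge into a single cluster on two components (the expected picture when a
third axis is needed to separate them), the minority's label is not the
signature of a mix-up — but nine "Preah Vihear" samples sitting inside a
Ratanakiri-majority cluster is. Flagging whole groups by inspection is not
testable; this automated vote is, and it reproduces the intended behaviour
on simulated cohorts with planted mislabels.

Cluster population names are cluster ids (`cluster_1`, … by size), not
province labels: sympatric populations share provinces, so labels cannot key
populations.

### SNP thinning

For external model-based structure tools, biallelic SNPs with minor-allele
frequency strictly above 1% are thinned to exactly 50,000 per contig by
evenly spaced rank selection — deterministic, order-preserving, and exact
when supply exceeds the target.

## Diversity statistics

Four-fold degenerate sites are derived from the reference and CDS
annotation: for every codon (reverse-complemented on minus-strand features,
phase-adjusted), the third position is flagged when all four substitutions
leave the amino acid unchanged. Every complete-codon position of a CDS
counts as *covered*; a position flagged in one frame but covered as a first
or second codon position in another frame is vetoed, so overlapping frames
must agree. Incomplete terminal codons are ignored; features that run off
the contig are skipped with a warning.

π is computed per site as the mean pairwise difference among sampled
chromosomes, $1 - \sum_a \binom{c_a}{2} / \binom{n}{2}$ — multiallelic
sites contribute all alleles — and divided by the accessible-site count.
θ~W~ is $S / a_n / L$ counting any segregating site once. Tajima's D uses
the standard constants and requires a uniform chromosome count, enforced by
restricting to sites fully called in the downsampled sample set; $S = 0$
returns `NA`, never 0. Populations are downsampled without replacement to a
common size (default: the smallest population) before any of these are
computed, so unequal sample sizes cannot masquerade as diversity
differences.

Confidence intervals are percentile bootstrap over individuals, 100
replicates, 2.5/97.5 percentiles, flagged unreliable when the statistic is
undefined on more than 20% of replicates. A known limitation: resampling
individuals with replacement duplicates genotypes, which biases π and θ~W~
slightly downward (duplicated pairs contribute no differences), so the
percentile interval tracks the bootstrap distribution rather than
guaranteeing to bracket the point estimate. For mean-like statistics the
interval is calibrated; for π under strong drift the point can sit at or
just above the upper bound. The plain percentile form is kept because it is
the procedure the workflow specifies; users wanting strict containment
should recentre (basic bootstrap) at their own judgement.

## Divergence and selection scans

Hudson's F~ST~ estimator in the two-population parameterisation

$$\hat N = (\hat p_1-\hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{n_1-1} - \frac{\hat p_2(1-\hat p_2)}{n_2-1},
\qquad \hat D = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1)$$

is accumulated per site and combined within windows as a ratio of sums,
which avoids the small-window bias of averaging per-site ratios. Only
biallelic sites with at least two called chromosomes in each population
enter; sites monomorphic for the same allele in both populations have zero
denominator and are excluded. Windows are either positional (20 kb, tiling
half-open intervals, empty windows omitted) or SNP-count blocks (1000
usable SNPs, non-overlapping, final partial block dropped). Non-overlapping
rather than stepped SNP windows were chosen for independence of window
values; the window size is exposed if users want otherwise.

Genome and contig averages are means over window values. Selection signals
are maximal runs of consecutive windows above `threshold_mult` (2×) times
the genome-wide mean for that population pair, kept when the run has at
least `min_run` (5) windows; each signal is summarised by its peak window
and ranked by peak F~ST~ (ties broken by contig then position, making the
ranking total). Runs must be strictly consecutive by default — one
below-threshold window splits a run — with a `max_gap` parameter exposed
for users who prefer tolerance. Genes whose span overlaps
peak ± 100 kb (inclusive) are attached with signed distance from the peak.
Scans cover contigs of at least 2 Mb: short contigs make window statistics
noisy and contribute little genome.

## Insecticide-resistance report

Gene coordinates are configuration input (BED or YAML), not hardcoded —
the analysis is annotation-agnostic and testable on synthetic annotations.
Within each region, every alternate allele of every variant gets a
per-population frequency over non-missing chromosomes (multiallelic
variants decomposed into one record per alternate); records are kept when
the frequency strictly exceeds 2% in at least one population with called
chromosomes. The threshold applies at the allele level; consequence
annotation and copy-number variation are out of scope.

## Orchestration

`run_pipeline()` executes stages in dependency order from one YAML
configuration whose parameter defaults equal the analysis constants above;
unknown keys are rejected so typos cannot silently revert to defaults.
Populations entering the per-population analyses are clusters of at least
`min_cluster_size` (5) assigned samples: single-linkage occasionally splits
off one or two peripheral samples as their own cluster, and population
statistics on such splinters are meaningless.
Every exclusion decision is logged with a reason, and a JSON manifest
records the seed, the full parameter snapshot and an MD5 checksum per
output file; identical configuration and seed reproduce identical
checksums.

## Problem sizes

The shipped tests exercise the estimators at sizes chosen to make
statistical assertions sharp but quick: oracle equivalence on matrices up
to 200 sites × 20 samples; estimator recovery at 100,000 sites; the
end-to-end structure test at the full study configuration (302 samples,
100,000 sites, 4 contigs of 3 Mb); sweep detection at 60,000 sites with
two planted sweeps. The acceptance script repeats the structure run once
and the F~ST~ recovery over 10 replicate cohorts.
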