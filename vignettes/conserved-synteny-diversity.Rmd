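---
title: "Windowed diversity across conserved synteny: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed diversity across conserved synteny: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntpi)
```

# The question and the pipeline

Two bird species that diverged tens of millions of years ago have long since
finished sorting their ancestral polymorphism, so any correlation between
their genome-wide diversity landscapes cannot be inherited variation. If the
correlation is real, it points at conserved *processes*: a stable karyotype, a
conserved recombination landscape, and the diversity-reducing effect of
selection at linked sites, whose local strength depends on the density of
selection targets and on recombination.

`syntpi` implements the analysis end to end:

1. **Synteny** — tile the reference genome into fixed 200 kb windows and lift
   each window into the other genome through a UCSC chain; retain a window
   only when more than 80% of its bases remap into a single collinear run
   whose span is 180–220 kb.
2. **Diversity** — per population, estimate window nucleotide diversity
   ($\pi$) from VCF genotypes, counting only sites where *every* individual
   has depth $\ge 4$; drop windows with fewer than 10 000 qualifying sites;
   average the two populations per species.
3. **Shared polymorphism** — count sites variable in at least one population
   of each species at homologous (lifted) positions, as a lineage-sorting
   audit.
4. **Covariates** — per window: coding-sequence density, intergenic GC,
   repeat density, gene-length-weighted $d_S$ (excluding genes with
   $d_S = 0$ or $d_S > 2$, window averages $> 0.3$ set missing),
   recombination rate, chromosome length; $\sqrt{\cdot}$ transforms for CDS
   density and $d_S$, $\log_{10}(x + 1)$ for recombination.
5. **Statistics** — Spearman correlation of window diversity between species
   (with and without CDS masking); OLS of one species' diversity on the
   other's plus chromosome length; the five-predictor OLS; a
   principal-component regression (PCR); and diversity~recombination fits in
   the top and bottom deciles of CDS density or GC.

# The diversity estimator

The source studies name no estimator formula, so the package uses the
standard windowed estimator: for each qualifying variable site with $n$
called allele copies and alternate frequency $\hat p$, the unbiased per-site
heterozygosity $2 \hat p (1 - \hat p)\, n/(n-1)$, summed and divided by the
number of qualifying sites (variable *plus* monomorphic). This equals the
mean pairwise difference per site over all haplotype pairs, and is therefore
independent of phasing — a property the test suite checks by brute-force
pair enumeration. The $n/(n-1)$ correction can be disabled
(`unbiased = FALSE`) to reproduce toolchains that omit it.

Because variant-only VCFs cannot supply the qualifying-site denominator, the
module accepts a per-window accessible-site count (the generator emits one);
variant records that fail the coverage filter are subtracted from it. Sites
with missing genotypes stay in as long as depth passes, with missing alleles
simply excluded from the allele counts; this follows the published filtering,
which conditions on coverage, not call rate.

The low-site filter is applied **per population** (a window must reach
10 000 qualifying sites in both populations), the stricter of the two
readings of the published filter. The published outlier removal was a manual
call on one window; the reproducible surrogate here flags windows whose
species-average $\pi$ exceeds $Q_3 + 10\,\mathrm{IQR}$ and removes them only
when `removeOutliers = TRUE`.

# Lift-over semantics

Chains are parsed strictly (block arithmetic must tile the declared spans;
negative-strand targets are normalised to forward coordinates). Lifting is
defined per base: a base maps through the highest-scoring chain whose
aligned blocks cover it (ties by input order); gap bases are unlifted. The
bases of a window lifted through one chain form a *collinear run*; "one
window in the other genome" is interpreted as one such run, since a chain is
by construction a collinear alignment block. The retained-window span is
measured from the first to the last lifted base (so target-side insertions
inflate it — that is what the 220 kb ceiling is for); the lifted-base count,
not the span, feeds the remap fraction. The remap threshold is strict
(`> 0.80`), the size bounds inclusive, following the published wording
("more than 80%", "less than 180 kb or greater than 220 kb" excluded).
Windows whose mapped bases pass the threshold only when several runs are
summed are classed `rejected_split`; a strict target-tiling interpretation
was considered and rejected because it makes retention depend on an
arbitrary tiling origin in the target genome.

All interval containers are `GRanges` (1-based, closed), the platform
convention; 0-based half-open coordinates appear only in the file formats
that define them (chain, BED, output TSVs). Keeping the platform convention
internally avoids a second, package-private coordinate system.

# The synthetic two-species generator

The generator produces everything the pipeline consumes — chain files,
per-population VCFs, GFF3/BED annotation, covariate TSVs — with known truth
per window. It is windowed and coalescent-free: per window,

* landscapes (recombination $r$, CDS density $d$, repeat density, mutation
  scale) are drawn through a Gaussian copula with a shared latent component,
  `s * z + (1 - s) * independent`, so the sharing coefficient `s` tunes
  cross-species landscape similarity;
* linked selection reduces diversity by
  $B = \exp(-k\, d / (r + 0.1))$ — stronger where targets are dense and
  recombination low;
* expected diversity is $E[\pi] = 4 N_e \mu \cdot m_w \cdot B \cdot e^\eta$
  with a per-window mutation scale $m_w$ and log-normal noise
  $\eta \sim N(0, \sigma^2)$, independent between species;
* the segregating-site count is $S \sim
  \text{Poisson}(E[\pi] \cdot L \cdot a_n)$ with Watterson's
  $a_n = \sum_{i<n} 1/i$, site frequencies follow the neutral SFS
  ($P(i) \propto 1/i$), genotypes are random assortments of the allele
  copies, and depths are Poisson. With these choices realised window $\pi$
  is an unbiased estimator of $E[\pi]$, which the tests verify.

Defaults are calibrated to the study system: $4 N_e \mu = 0.004$ (species A,
flycatcher-like) and $0.0012$ (species B, crow-like); 15 diploids in each of
two populations per species; mean depth 20; CDS density Beta-distributed
with mean 0.02 (the reported per-window scale, range reaching ~0.15);
recombination log-normal with median ≈1.2 cM/Mb and $\sigma_{\log} = 1$,
spanning roughly 0.1–10 cM/Mb as avian linkage maps do; GC coupled to CDS
density (correlation ≈0.3, matching the reported predictor collinearity);
linked-selection strength $k = 2$, landscape sharing $s = 0.8$, noise
$\sigma = 0.3$. Under these settings the five-predictor model explains
roughly 30% of diversity variance, the scale observed in the real data. The
default genome is five chromosomes of 60/36/24/18/12 Mb (750 windows):
avian-style chromosome-size skew so the chromosome-length covariate is a
real covariate.

Chains are block-identity with small benign indels (50–500 bp) in ~30% of
windows. With probability `rearrangementRate` a window's chain is instead
perturbed to *fail* a specific filter — split across two spare target
chromosomes (`rejected_split`), inflated by a 30 kb target insertion
(`rejected_size`), or gapped by a 50 kb reference deletion
(`rejected_low_remap`) — and with probability `lowSiteRate` a window gets a
sub-threshold accessible-site budget (4 000–9 000 sites), exercising the
10 000-site filter. The truth table records the intended verdict for every
window; the filter-bookkeeping test demands exact agreement.

Two populations per species are resamples of one panmictic pool; that alone
reproduces the high published within-species between-population window
correlations (r ≈ 0.96–0.99). What the generator does **not** emulate:
linkage disequilibrium within windows, gene conversion and GC-biased
substitution, sequencing error, population structure, shared ancestral
polymorphism (so the shared-site audit has a purely coincidental
expectation). Passing tests therefore demonstrate correctness of the
*pipeline machinery and statistical recovery*, not realism of any particular
biological parameter.

# Regression and PCR choices

OLS uses `stats::lm` with classical inference; rank-deficient designs are an
error naming the collinear columns rather than a silent drop. PCR
standardises predictors (correlation-matrix PCA — the predictors have
incommensurate units), orients every component so its largest-magnitude
loading is positive, and reports per-PC response shares as squared
correlations with the orthogonal scores; these sum exactly to the full OLS
$R^2$, an identity the tests check to $10^{-10}$. The sign of each PC's
association with the response is reported separately from the loading
orientation. Numerically zero-variance PCs (duplicated predictors) are kept
with zero share and flagged not-retained.

Decile strata take `floor(0.1 n)` complete-case windows (ties broken by
genome coordinate), which reproduces the published degrees of freedom
($F_{1,247}$ from 2 490 complete cases). p-values are classical and
uncorrected, as in the source analysis. For the chromosome-length model the
length enters untransformed by default (`logLength = TRUE` available); the
source does not state which was used.

# Problem sizes and numerical points

The test suite and the acceptance script choose desk-scale problem sizes:
brute-force oracles run on ≤10 kb chains and ≤8 samples; the
filter-bookkeeping run uses a 100-window genome with elevated defect rates;
correlation-recovery runs 20 replicate genomes of 3 000 windows on the
in-memory variant layer (sufficient statistics per site — identical in
distribution to the VCF path, which is itself validated against the
in-memory path on smaller genomes); effect-sign recovery runs 200
replicates at the default 750-window scale, where the per-replicate power
for the CDS-density sign is ≈99%.

Degenerate inputs are defined, not accidental: zero qualifying sites gives a
missing $\pi$ (never 0); an empty lift gives verdict `unmapped`; a constant
stratifier or predictor is an error; `E[\pi] = 0` emits no variants. The
recombination floor $\epsilon = 0.1$ cM/Mb keeps $B$ finite in
recombination deserts. All generator draws descend from one mandatory seed;
identical seeds give byte-identical output files.

# Known limitations

* Lift-over is run-based; sub-window inversions are not modelled (an
  inversion inside one chain still forms one run).
* The accessible-site count is a per-window scalar, so masks are assumed to
  overlap accessible bases proportionally; windows where that matters most
  (low accessibility) are the ones the 10 000-site filter removes.
* The shared-polymorphism audit matches positions (optionally alleles); it
  does not classify CpG context.
* The generator's two populations per species are exchangeable replicates;
  real population structure would lower the within-species correlation and
  with it the power of the species average.
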