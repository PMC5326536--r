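# syntpi

Cross-species windowed nucleotide diversity in regions of conserved synteny.

Closely related species stop sharing polymorphism once lineage sorting is
complete, yet their genome-wide *landscapes* of genetic diversity can stay
correlated if the processes that shape diversity — recombination-rate
variation, the density of targets of selection, local mutation rate — are
themselves conserved. `syntpi` is an R package for asking that question with
two resequenced populations per species and a pairwise genome alignment:

* **Conserved-synteny mapping.** Non-overlapping 200 kb windows of the
  reference genome are lifted into the second genome through a UCSC chain
  file. A window is retained when more than 80% of its bases remap into one
  collinear target run whose span is between 180 kb and 220 kb; windows that
  split across runs, inflate/shrink, or fail to remap are rejected with an
  explicit verdict.
* **Windowed diversity.** Per population, nucleotide diversity per window,

  π = Σ<sub>variable sites</sub> 2·p̂(1−p̂)·n/(n−1) / (qualifying sites),

  counting only sites where *every* individual has read depth ≥ 4.
  Windows with fewer than 10 000 qualifying sites are dropped; the two
  population values are averaged per species; extreme-π windows are flagged
  as outliers (Q3 + 10·IQR).
* **Trans-species polymorphism audit.** Sites variable in at least one
  population of each species, compared at homologous (lifted) positions —
  after complete lineage sorting only coincidental double hits are expected.
* **Covariates and models.** Per-window CDS density, intergenic GC, repeat
  density, gene-length-weighted dS (excluding dS = 0 and dS > 2; window
  means > 0.3 set missing), recombination rate, chromosome length; √ and
  log10(x+1) transforms; Spearman correlation of window π between species
  (± CDS masking), OLS (π<sub>B</sub> ~ π<sub>A</sub> + chromosome length;
  the five-predictor model y = β₀ + β₁x₁ + … + β₅x₅ + ε), principal-component
  regression, and diversity~recombination fits within the top/bottom 10% of
  windows by CDS density or GC.
* **A calibrated two-species simulator.** Chain files, per-population VCFs,
  GFF3/BED annotation and covariate TSVs with known per-window truth, built
  on a shared linked-selection landscape: B = exp(−k·d/(r+0.1)),
  E[π] = 4Nₑμ·B·e^η, segregating sites via the Watterson correspondence and
  the neutral SFS. Every pipeline stage can be tested against the generator's
  recorded ground truth.

## Worked example

Simulate a small two-species dataset (300 windows across four chromosomes)
and run the full pipeline on the emitted files:

```r
library(syntpi)

cfg <- simulationConfig(seed = 7, chromLengths = c(2.4e7, 1.6e7, 1.2e7, 8e6))
sim <- simulateDataset(cfg, dir = "example")

inputs <- list(
  chain = sim$files$chain, aSizes = sim$files$aSizes, bSizes = sim$files$bSizes,
  vcfA = c(sim$files$vcfA1, sim$files$vcfA2),
  vcfB = c(sim$files$vcfB1, sim$files$vcfB2),
  genesA = sim$files$genesA, genesB = sim$files$genesB,
  repeatsA = sim$files$repeatsA, rec = sim$files$rec, gc = sim$files$gc,
  ds = sim$files$ds, accessible = sim$files$accessible)

res <- runPipeline(inputs, outDir = "example/out", seed = 7)
res$map
#> SyntenyMap with 300 reference windows
#> verdict
#> rejected_low_remap      rejected_size     rejected_split           retained
#>                  2                  2                  2                294
```

Six windows carry simulated rearrangements and are rejected by the retention
filters — each with the verdict the generator's truth table predicted. The
headline quantities:

```r
res$summary$piMeanA; res$summary$piMeanB
#> 0.00415 / 0.00127          # designed theta: 0.004 and 0.0012
res$summary$rho; res$summary$rhoMasked
#> 0.341 / 0.341              # cross-species window correlation, ± CDS mask
res$summary$sharedPolyFraction
#> 0.0104                     # shared variable sites: coincidental level
res$models$table2
#> Linear model [five-predictor model]: n = 289, R2 = 0.2185, F(5,283) = 15.82
#>                  estimate          se       t         p
#> recRate        0.00018547  0.00031418  0.5903   0.55545
#> cdsDensity    -0.00146478  0.00125737 -1.1650   0.24502
#> ds             0.02156265  0.00249096  8.6564 3.754e-16 ***
#> ...
```

At this small scale the mutation-rate proxy (dS) carries most of the signal;
the recombination and CDS-density effects have the designed signs but need
more windows for individual significance — the acceptance suite shows they
are recovered in ≥95% of 200 replicates at the default 750-window scale.
`res$models$pcr` prints the per-PC loadings, predictor-variance shares and
per-PC response shares (which sum exactly to the OLS R²), and
`res$sharedPoly` the coverage-filtered and unfiltered audits.

See the methods vignette (`vignettes/conserved-synteny-diversity.Rmd`) for
the model, estimator and design choices, and what the simulation does and
does not emulate.

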