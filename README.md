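# spliceKinetics

RNA splicing in vivo is hard to quantify from short reads because every
genomic position mixes precursor RNA, intermediates and isoforms.
`spliceKinetics` implements a bond-level alternative for 4sU metabolic
labeling time series (TT-seq + RNA-seq): it estimates synthesis rates and
half-lives of the three *phosphodiester bonds* that characterize one
splicing event — the donor bond (exon|intron), the acceptor bond
(intron|exon) and the exon–exon junction bond — and derives the splicing
yield, the fraction of precursor converted to spliced product.

For a bond with synthesis rate α and first-order decay rate β, a 4sU
pulse of length t gives a labeled concentration (α/β)(1 − e^{−tβ}), so a
TT-seq sample with depth factor F and cross-contamination χ has expected
counts

    E = F (α/β) (1 + e^{−tβ}(χ − 1))        (TT-seq, labeling time t)
    E = F α/β                                (RNA-seq, steady state)

Counts are negative binomial with a dispersion θ shared across the data
set; F, χ and θ are calibrated from labeled/unlabeled spike-ins under
the GLM E_ij = F_j p_ij w_ij (w = 1 labeled, χ_j unlabeled). Per bond,
(α, β) maximize the NB likelihood over all samples (BFGS, 10 random
starts, medians across runs); half-life = ln2/β. Alternative models — a
transcription-delay model for donor bonds and a coupled
precursor→product model for junction bonds — plus a full-design
simulator, splicing-yield tables, and lasso models of sequence effects
(single nucleotides around donor/acceptor/branchpoint, octamers in four
intronic regions, PWM matching against RNA-binding-protein motifs) round
out the toolkit. See the methods vignette
(`vignettes/bond-kinetics-methods.Rmd`) for models, assumptions and
numerical choices.

## Worked example

Simulate the full 28-sample design (TT-seq and RNA-seq at 2–60 min, two
replicates), calibrate factors from simulated spike-ins, and fit the
first-order model:

```r
library(spliceKinetics)

cfg    <- simulationConfig(n_bonds = 200, model = "first_order", seed = 42)
truth  <- sampleGroundTruth(cfg)
counts <- simulateBondCounts(truth, cfg)

sp  <- simulateSpikeIns(cfg)
fit <- fitSpikeInModel(sp$counts, sp$labeled, cfg$design)
fit
#> SpikeInFit: 28 samples, 14 TT-seq / 14 RNA-seq
#>   dispersion theta = 26.58, logLik = -1161
#>   TT-seq cross-contamination chi: median 0.0456 (range 0.0302-0.0646)

rates <- fitFirstOrder(counts, cfg$design, fit, seed = 42)
rates
#> RateEstimates (first_order model): 200 bonds; 174 ok, 26 below count threshold, 0 failed
#>   half-life (min): median 31.5, IQR 7.74-199
```

The spike-in fit recovers the simulated contamination (truth χ = 0.05)
and dispersion (truth θ = 20) from eight spike-ins; 26 bonds fall under
the 100-read coverage filter and are skipped. Half-lives are absolute
(minutes); synthesis rates are on the spike-in normalization scale, so
only their ratios (e.g. splicing yield) are meaningful across runs.
Against the known truth:

```r
tab <- rateTable(rates); ok <- tab$status == "ok"
median(tab$half_life[ok] / (log(2) / truth$beta[ok]))
#> [1] 1.011
```

i.e. half-life recovery is unbiased to ~1% on well-covered bonds.
`discoverIntrons()` / `countBondReads()` produce the per-intron donor /
acceptor / junction counts from BAM or SAM alignments,
`yieldTable()` aggregates junction and acceptor synthesis rates into
per-site yields, and `fitSingleNtModel()` / `fitOctamerModel()` regress
log half-life on sequence context. `runPipeline()` (or the thin CLI in
`inst/scripts/splicekinetics.R`) chains simulate/count → normalize →
fit → yield with a manifest and resumable stages.

## Acceptance script

`scripts/acceptance.R` re-runs the package's estimator-validation
studies from scratch: it simulates spike-ins and fits the normalization
model, simulates ≥1000 donor bonds under the delay model and ≥1000
junction bonds under the coupled model and fits each with the
first-order model (reporting the median ratio of the estimated half-life
to the model-implied half-life), and runs matched-model recovery at
10–99-read coverage and at half-lives of 0.5 min / 3 days (reporting
median relative errors in percent). Run it from the repository root
against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` and problem size `n`
per quantity and finishes in about 3 minutes on one CPU.
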