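---
title: "Phosphodiester-bond kinetics from 4sU labeling time series: models and methods"
author: "spliceKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphodiester-bond kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceKinetics)
```

# The problem and the modeling idea

Short-read RNA-seq signal at any genomic position mixes precursor RNAs,
partially spliced intermediates and multiple isoforms, which makes rates
of "splicing of an intron" ambiguous. This package instead models the
metabolism of single phosphodiester bonds, which are unambiguous
molecular species: the **donor bond** between the last exonic and first
intronic base (cleaved by the first transesterification, after the intron
has been transcribed at least to the branchpoint), the **acceptor bond**
between the last intronic and first exonic base (cleaved once both
transesterification steps complete), and the **junction bond** joining
two exons (created by successful splicing, destroyed by degradation of
the mature RNA).

The data are a metabolic-labeling time series: cells are exposed to
4-thiouracil (4sU) for t ∈ {2, 5, 10, 15, 20, 30, 60} minutes; labeled
RNA is purified after fragmentation (TT-seq) and sequenced alongside
total RNA-seq, two replicates each (28 samples). Reads are classified
per intron into donor-supporting (an aligned block covering both bases
flanking the donor bond), acceptor-supporting, and junction-supporting
(split reads whose skipped interval equals the intron exactly).

# First-order bond kinetics

Each bond obeys dc/dt = α − βc with synthesis rate α (normalized
counts/min) and decay rate β (1/min). At steady state c = α/β. All RNA
made during the pulse is labeled, so

* labeled: c_lab(t) = (α/β)(1 − e^{−tβ})
* unlabeled: c_unl(t) = (α/β) e^{−tβ}

A TT-seq library contains the labeled molecules plus a fraction χ of
the unlabeled ones (cross-contamination), an RNA-seq library the steady
state, giving expected counts

* TT-seq: E = F (α/β)(1 + e^{−tβ}(χ − 1))
* RNA-seq: E = F α/β

with per-sample depth factor F. The bond half-life is ln(2)/β; for
donor/acceptor bonds it measures splice-site cleavage, for junction
bonds mature-RNA decay. Counts are negative binomial with dispersion θ
shared across the whole data set. Per bond, (α, β) maximize the NB
log-likelihood over all 28 samples (BFGS on log parameters, analytic
gradient); bonds with fewer than 100 total raw reads are excluded — the
package's own simulations (see the acceptance criteria) show errors grow
rapidly below that coverage.

**Multi-start policy.** Each bond is fitted from 10 random
initializations (α log-uniform 0.01–1000, half-life log-uniform
0.1–10^4 min) and the reported rates are element-wise medians across
runs. Two numerical hazards motivated refinements: (i) the likelihood
has a degenerate plateau where α and β diverge jointly (TT-seq
expectations collapse to χ × steady state); runs more than 0.5 log-lik
units worse than the best run are excluded from the median, otherwise
the median can mix distinct modes; (ii) for the coupled model (below)
the product curve is exactly invariant under swapping the two rates with
α rescaled, so every run is first canonicalized to the physical branch
β_spl ≥ β_deg (splicing is the fast step).

# Spike-in normalization

Labeled and unlabeled synthetic spike-ins added at constant amounts
before purification calibrate F, χ and θ. The expectation of spike i in
sample j is E_ij = F_j p_ij w_ij with w = 1 for labeled and w = χ_j for
unlabeled spike-ins (χ_j ≡ 1 for RNA-seq). We deliberately weight the
*unlabeled* spikes by χ: cross-contamination means unlabeled RNA leaking
into the purified fraction, and this convention is the one consistent
with the kinetic model's χ-mixture. Extraction probabilities are shared
as: one p per labeled spike across all samples; one TT-seq and one
RNA-seq p per unlabeled spike.

Two exact scale degeneracies require constraints: F·c, p/c (fixed by
pinning the geometric mean of labeled-spike p, default 0.5), and — for
the unlabeled block — p^tt·c, χ/c, which the model as stated leaves
free; we fix it by equating the geometric means of the unlabeled TT-seq
and RNA-seq extraction probabilities. Without the second constraint χ
is only identified up to a constant. θ is profiled on the same
objective, alternating with the (F, χ, p) fit until the objective is
stable to 1e-10 relative.

# Alternative kinetic models

**Delay model (donor bonds).** Transcribing the intron to the
branchpoint takes a fixed time τ during which the donor bond cannot be
cleaved; cleavage then proceeds at rate λ. Each bond lives τ plus an
Exp(λ) time, so the labeled concentration is α[min(t, τ) +
1{t>τ}(1 − e^{−λ(t−τ)})/λ], the steady state α(τ + 1/λ), and the bond
half-life (median lifetime) τ + ln2/λ. An earlier variant that set the
labeled curve to zero during the delay was rejected: bonds synthesized
during the pulse are labeled and observable even while uncleavable, and
only the accumulation form reproduces the documented behavior that a
first-order fit *underestimates* τ + ln2/λ (median ratio ≈ 0.84–0.93 in
this package's simulations). τ and λ are only weakly separable from
these data; the delay fit is provided for completeness and for the
simulation studies.

**Coupled model (junction bonds).** Precursor bonds are synthesized at
α and converted by splicing at β_spl; the junction bond then decays at
β_deg. The labeled product is the standard two-exponential catenary
solution (with the confluent series limit when the rates coincide
within 1e-8). A first-order fit to such data recovers approximately
ln2/β_spl + ln2/β_deg, typically overestimating.

# Splicing yield

The yield of an acceptor site is η = Σ α_junction / α_acceptor over all
junctions using the site, with junction synthesis rates from the coupled
model and the acceptor rate from the first-order model (the first-order
model systematically underestimates junction synthesis and the acceptor
kinetics involve no transcription delay). η is deliberately not capped
at 1: truncation would bias comparisons, and estimation error legitimately
produces values above 1. Junctions whose coupled fit failed are excluded
from the sum and the site is flagged incomplete.

# Sequence-effect models

Responses are log half-lives (or log yield, floored at a configurable
epsilon, default 0.01). The single-nucleotide model one-hot encodes the
20 nt on each side of the donor site, acceptor site and branchpoint
relative to the consensus (modal base per position; ties break toward
the canonical GT/AG/branchpoint-A where defined, else alphabetically),
runs a lasso at the one-standard-error penalty (10-fold CV; folds are
assigned by a hash of the intron id and the run seed, so they are
reproducible and survive subsetting), drops positions whose three
substitution coefficients are all exactly zero, and refits the survivors
plus three GC covariates (whole intron, donor window, acceptor window)
by ordinary least squares. GC covariates are mean-centered so a pure
consensus sequence predicts exactly the intercept. Rows containing N are
excluded. Reported metrics are in-sample variance explained and the
multiplicative median error median(exp(|log(y/ŷ)|)).

The octamer model counts 8-mers with up to two mismatches (overlapping
offsets all count) in four intronic regions — 15–100 nt downstream of
the donor, 100 nt upstream of the branchpoint, branchpoint to 5 nt
upstream of the acceptor, and 5–100 nt upstream of the acceptor — each
cropped to the intron. log2(count + 1) covariates enter a per-region
lasso (5-fold CV), and the selected octamers join the single-nucleotide
features, per-region GC, log intron length and the first-intron flag in
a joint lasso (10-fold CV). The variance ledger reports joint,
per-group individual (group alone, OLS) and drop-one variance explained;
all values are in-sample. Scanning all 65,536 octamers at two mismatches
is genome-scale compute, so the API takes an explicit candidate universe
(default: all 8-mers observed exactly in the supplied regions).

PWM matching scores an octamer against a motif as the ratio of the best
alignment probability to the best achievable probability (so consensus
matches score 1 and uniform columns are neutral); octamers shorter than
the PWM are padded with Ns (neutral, column-maximum factors; one extra N
on the right when the length difference is odd). Per PWM the top 5% of
matches are kept, then matches below 0.9 are removed.

# The simulator: what it emulates and what it does not

The generator reproduces the full 28-sample design, NB count noise with
a shared dispersion, per-sample depth factors and cross-contamination,
spike-in tables under the normalization expectation (with truth drawn to
satisfy both identifiability constraints), and ground-truth rates drawn
log-uniformly. Stated-world defaults, chosen once: F_j = 1, χ_j = 0.05
for TT-seq samples (a few percent contamination is typical for a
streptavidin purification), θ = 20 (biological-replicate level
overdispersion, CV² = 0.05), α log-uniform 0.1–100 counts/min, half-life
log-uniform 1–1000 min, τ log-uniform 0.1–10 min, splicing half-time
1–30 min, product half-life 30–1000 min. "Total coverage" of a bond is
its expected raw count summed over samples, controlled by rescaling α.

The simulator does **not** emulate read-level artifacts: alignment
errors, positional/fragment-length biases, duplicate reads, or the
correlation of counts between neighboring bonds of one transcript. A
green recovery test therefore establishes correctness of the estimator
under the stated noise model, not robustness to alignment pathologies.
Error summaries are reported both as |est − true|/true and in the
multiplicative currency exp(|log(est/true)|) − 1; the latter treats
k-fold under- and overestimation symmetrically and is the package's
preferred metric for half-life errors.

# Numerical choices and degenerate inputs

* NB log-likelihood is written via `lgamma`, so exact (non-integer)
  expected counts can serve as a continuous noiseless limit in
  round-trip tests; for integer counts it equals `dnbinom`.
* Optimizer: BFGS, relative tolerance 1e-12, up to 1000 iterations; all
  rates on log scale, χ on logit scale. Failed bonds are retried with
  fresh initializations up to 3 extra rounds, then flagged `failed`.
* Expectation means are floored at 1e-12; parameter magnitudes are
  bounded at e^{±50} to keep the objective finite.
* Counting: mapping quality must equal 255 (the unique-alignment score
  of the upstream aligner) and secondary alignments are dropped; both
  are configurable. Mates of a fragment are evaluated independently and
  pooled per (intron, class). A read whose single block spans the whole
  intron starts in the upstream exon in transcript orientation and is
  counted as donor only, keeping the three classes disjoint per read.
* Strand is assigned from the library protocol; the default
  `rf` (first read reverse-complement of the transcript) matches
  dUTP-class kits. Fixtures that use unpaired reads with `fr` make the
  alignment strand the fragment strand.
* Ties in the major-isoform choice break lexicographically by isoform
  id; singleton groups yield NA relative uncertainty with a warning.

# Known limitations

* τ/λ of the delay model and (for slow product decay) β_deg of the
  coupled model are weakly identified by a 2–60 min labeling window;
  estimates outside roughly 1 min–3 days of half-life are unreliable,
  and the acceptance criteria quantify this.
* The variance-ledger R² values are in-sample; with many octamer
  covariates they are optimistic relative to cross-validated values.
* The spike-in model identifies χ only up to the stated geometric-mean
  convention for unlabeled extraction probabilities; if labeled and
  unlabeled spike-ins truly differ in capture efficiency, χ absorbs the
  average difference.
* `runPipeline` covers the simulated and TSV-driven paths end to end;
  alignment inputs are processed per file without parallelism.
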