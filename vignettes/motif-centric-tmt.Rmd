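---
title: "Motif-centric TMT phosphoproteomics: models, filters, and the synthetic experiment"
author: "motifboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-centric TMT phosphoproteomics: models, filters, and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifboost)
```

## The problem and the design

Phosphotyrosine sites make up roughly 0.05% of the human phosphoproteome
(pS:pT:pY ≈ 90:10:0.05), and many kinase substrates sit below the MS1
detection limit of a shotgun phosphoproteomics run. The motif-centric
boosting design attacks this with isobaric labeling: peptides from the
study sample are phosphorylated *in vitro* by a chosen kinase
("back-phosphorylation"), so that every peptide carrying that kinase's
sequence motif becomes a phosphopeptide. This motif-centric material is
labeled with one or two TMT channels and mixed with the endogenous sample
channels. Because isobarically labeled peptides co-elute as a single MS1
peak, the abundant motif-centric material lifts low-abundance endogenous
phosphopeptides over the detection and identification thresholds, while
MS3 reporter ions still quantify each channel separately.

Three analysis products fall out of the channel structure:

1. **Acceptance-criteria filtering.** Boosting has a cost: reporter ions
   are sampled from a finite ion budget, so an overwhelming boost channel
   starves the sample channels. Records are kept only when the *boost
   ratio* (boost-channel signal over the mean sample-channel signal) is
   strictly below 100, the summed sample-channel intensity is strictly
   above 2^40, at least two valid reporter values exist in one duplicate
   set, and (for class-1 sites) the localization probability exceeds 0.75.
2. **Group A/B classification.** With an inhibitor arm, a direct substrate
   of the assay kinase should go *down* under inhibition
   (treated-vs-control t-test) *and* come back *up* in the motif-centric
   channel (boost-vs-treated t-test). Down-regulated sites with a
   significant positive motif contrast are group B — inferred direct
   substrates; the remaining down-regulated sites are group A.
3. **Stoichiometry.** If the *in vitro* reaction drives every copy of a
   site to completion, the boost channel is the "100% phosphorylated"
   reference, and the endogenous/boost intensity ratio estimates the
   site's phosphorylation stoichiometry directly.

## Kinase motif models

Kinase specificity is represented as a position-specific log2-odds matrix
over positions −7..+7 (15-mer windows, the logo convention), an acceptor
set, and a logistic calibration mapping score to a match probability. The
shipped defaults encode textbook consensi — CK2 with D/E at +1..+3
(strongest +3), PKA with R/K at −3/−2, the four Pro-directed kinases
sharing P at +1 but differing in their secondary positions (CDK1 K/R at
+3, ERK2 P at −2, p38a with a mild pT acceptor preference), and distinct
acidic-context SRC/EGFR pY models. Strong preferences carry weight ±2,
weak ones ±1 to ±1.5. These magnitudes are calibration, not measurement:
the published analyses score substrate preference with a model learned
from large *in vitro* kinase-substrate surveys, which is not reproduced
here. The matrices are a transparent PWM stand-in, shipped as editable
JSON (`inst/extdata/kinase_models.json`), and every analysis accepts
user-supplied matrices.

Two calibration choices matter downstream:

* **Match slope.** `match_probability` is
  `plogis((score − midpoint) × slope)` with midpoint at half the maximal
  attainable score and slope 3. The slope keeps the background (zero
  score) match probability below 0.1%, so non-substrates acquire
  essentially no back-phosphorylation — if background conversion were
  ~1%, low-stoichiometry null sites would show a spurious positive motif
  ratio and contaminate group B.
* **Consensus sharpening γ.** Planted consensus windows are sampled from
  `p ∝ background × 2^(γ·logodds)` with γ = 4. With γ = 1 the ±2 weights
  give windows that frequently lack the consensus residues entirely,
  which contradicts what "a substrate of this kinase" means in the
  planted-truth sense; γ = 4 makes ≥95% of a model's own windows
  assignable back to it while keeping the flanks variable.

The acceptor gate returns a −∞ score (match probability exactly 0) when
the center residue is outside the kinase's acceptor set, and padding
positions contribute nothing — a window truncated at a tryptic peptide
boundary is uninformative there, not penalized. This is precisely the
mechanism behind the protein-level rule for basophilic kinases: a PKA
site whose required arginine lies N-terminal of the peptide boundary
scores at background when the reaction is run on peptides, so basophilic
motif-centric material must be produced at the protein level and digested
afterwards.

## The synthetic experiment

The generator is first-class, tested code; its defaults *are* the study
conditions, and every draw flows from one integer master seed through a
fixed multiplicative-hash substream scheme (`derive_seed`), so runs are
reproducible across platforms at the level of stored values.

**Sites.** Either from a generated proteome (i.i.d. residues at roughly
human composition, Poisson lengths, full tryptic digestion with up to two
missed cleavages and KP suppression — configurable off, since the
original protocol states only full tryptic digestion) via
`phosphosite_universe()`, or directly via `synthetic_site_table()`, which
plants a configurable number of consensus windows per kinase among
background windows whose center residues follow the 90:10:0.05 pS:pT:pY
target.

**Ground truth.** Each site is classed by its best motif match and its
endogenous stoichiometry drawn from a per-class Beta prior: acidophilic
Beta(2,8), Pro-directed/basophilic Beta(1.5,12), tyrosine Beta(1,40),
matching the observed ordering acidophilic > Pro-directed > tyrosine.
Unassigned sites use Beta(1.2,15), placed between the Pro-directed and
tyrosine means — the class is a mixture and nothing stronger is known
about it. A site is a *direct substrate* of a kinase when its
protein-context match probability is at least 0.5 (the logistic
midpoint). Direct substrates of the inhibited kinase have their
stoichiometry multiplied by `inhibitor_effect` (default 0.5) in the
treated condition.

**Back-phosphorylation.** The converted fraction is
`efficiency × match_probability × (1 − stoichiometry)`, so the motif
channel's total phospho fraction can never exceed 1. The published
stoichiometry analysis assumes 100% reaction efficiency; `efficiency` is
the knob that relaxes this, and under-efficiency translates directly into
stoichiometry overestimation, as expected.

**Acquisition.** True channel abundance is
`intensity_scale × loading × phospho fraction`. A site is detected when
its summed abundance exceeds the MS1 threshold, then identified with a
logistic probability in log2 summed abundance (identification is
spectrum-based in reality and is modeled only as a probability).
Reporter ions are sampled per channel as independent Poisson draws with
rates `ion_budget × channel share` — jointly identical to drawing a
Poisson total (budget default 5×10^4, the reporter-scan AGC target) and
splitting it multinomially — then rescaled to abundance units. Channels
that sampled at least one ion receive an additive lognormal noise floor
(log2 mean 35, sd 1); channels with zero sampled ions are recorded as 0,
i.e. missing, which is what makes the valid-channel criterion operative.
Localization probability is drawn independently of abundance with a
configurable fraction (0.9) above the class-1 cutoff, deliberately
leaving sites below 0.75 to exercise that filter. No co-isolation
interference term is modeled (SPS-MS3 is assumed to have removed it, and
its residual magnitude is not quantified); only singly-phosphorylated
site records are emitted.

**Calibration.** `intensity_scale = 2^40` per stoichiometry-loading unit
puts a typical detected site at the paper-relevant 25-unit loading in the
log2 41–45 band, so the "greater than 40" intensity criterion separates
signal from the 2^35 noise floor rather than being vacuous; the MS1
threshold 2^43 makes unboosted pY sites (stoichiometry mostly below
0.05) largely undetectable while boosted ones are recovered — the
boosting mechanism — and, at a 5-unit sample loading, reproduces the
rise-then-fall of quantifiable pY sites across boost loadings
{5, 25, 125}: too little carrier fails detection, too much fails the
boost-ratio criterion and starves the sample channels of the fixed ion
budget.

## Statistical choices

* **Tests.** Equal-variance two-sided Student t-tests (the default of the
  downstream statistics environment used in the original workflow), with
  a Welch variant by flag. Observations are duplicate channels ×
  replicate injections, pooled; the pooling is configurable because the
  original report does not state its scheme. Raw p < 0.05 is the default
  decision rule, matching the published captions; BH q-values are emitted
  alongside for stricter use. Degenerate rows are resolved explicitly:
  zero pooled variance with equal means gives t = 0, p = 1; with unequal
  means, ±∞ and p = 0; fewer than two observations in a group flags the
  result undefined rather than erroring.
* **Classification.** `down` requires significance *and* a negative
  ratio; the fold-change floor defaults to 0 (significance-only) since no
  fold-change cutoff is published. Group B additionally requires a
  significant, strictly positive motif contrast; A and B partition the
  down set by construction.
* **Stoichiometry.** Per duplicate set, endogenous/boost; the per-site
  estimate is the median over sets. Values above 1 (measurement noise or
  incomplete conversion of the reference) are clipped to 1 and flagged,
  never silently; a missing boost signal flags the estimate undefined.
* **Boost ratio.** Mean of boost channels over the mean of the designated
  denominator channels — the published single-boost pY design divides the
  131 signal by the average of 127 and 129, which the `ChannelDesign`
  expresses via `denominator_channels`; the default denominator is all
  sample channels, generalizing both published designs as means on both
  sides.
* **Notch.** The signal/noise threshold is the deepest interior minimum
  of a Gaussian-kernel density (Silverman's rule) between the two tallest
  modes; unimodal densities return no threshold. The estimator is
  translation-equivariant and, on a bimodal mixture with modes at 35 and
  43, lands within one log2 unit of the analytic component-density
  crossing.
* **Strictness.** All criterion inequalities are strict ("greater than",
  "less than"), and missing intensities are encoded as 0 and treated as
  invalid for counting — both matching the published wording and the
  MaxQuant table convention.

## What the simulation does and does not establish

The generator reproduces the *statistical structure* the analysis relies
on: class-dependent stoichiometry, motif-coupled back-phosphorylation,
detection driven by summed MS1 abundance, and budget-limited reporter
sampling. Passing tests therefore show that the filters, classification,
and stoichiometry estimators are correct *given that structure*. They do
not certify behaviour on real data, which additionally contains
co-isolation interference, TMT isotope impurities, peptide-level
identification artifacts, multiply-phosphorylated peptides,
non-lognormal noise, and incomplete *in vitro* conversion. The headline
counts of the original datasets (thousands of pY sites, specific group
sizes) derive from instrument-scale acquisitions and are not desk-scale
reproducible; the package's own checks are accordingly property-based.

Problem sizes in the test-suite and in `scripts/acceptance.R` — 10,000
records for the filter-agreement check, 1,000–2,000 sites per simulated
experiment, 500 windows per motif-recovery check — were chosen as the
smallest sizes at which the binomial/multinomial sampling error is far
from each property's margin.

## Known limitations

* Motif matrices are consensus stand-ins; absolute match probabilities
  are calibrated, not learned.
* Identification is a logistic in abundance; no spectrum-level effects.
* One boost kinase per simulated experiment (multi-kinase pooling is
  analyzed by running per-kinase experiments and overlapping site sets,
  as in the multi-kinase comparison workflow).
* Stoichiometry inherits the complete-conversion assumption; with
  `efficiency < 1` estimates are biased upward by exactly the reciprocal
  of the achieved conversion.
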