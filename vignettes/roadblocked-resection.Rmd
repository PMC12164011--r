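---
title: "Quantifying roadblocked DNA end resection: models, estimators and the forward simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying roadblocked DNA end resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectquant)
```

## The measurement problem

After a site-specific double-strand break (DSB), the 5' strands on both
sides of the break are degraded, leaving 3' single-stranded DNA (ssDNA)
tails. A DNA-bound protein roadblock — here catalytically dead Cas9
(dCas9) targeted between the break and a region of interest — can halt
the resection machinery and thereby confine the ssDNA, and with it
ssDNA-directed mutagenesis, to the break-proximal side of its binding
site. `resectquant` implements the quantitative chain needed to measure
that attenuation from three orthogonal assays (ssDNA-specific qPCR,
live-cell RPA fluorescence, and a canavanine-resistance mutation
reporter), together with a forward stochastic simulator that generates
every input those analyses consume, so the whole chain is testable
without wet-lab data.

## The ssDNA-specific qPCR model

SphI cuts double-stranded DNA but not ssDNA. Digesting genomic DNA with
SphI before qPCR therefore destroys amplicons not yet reached by
resection, while resected (single-stranded) amplicons survive with one
strand — half the template of intact dsDNA. With DSB formation frequency
$f$, per-site resection efficiency $r$ (fraction of DSB-bearing molecules
whose tract passed the site) and digestion efficiency $e$, the expected
amplicon yield relative to intact dsDNA is

$$ y_{\mathrm{mock}} = 1 - \tfrac{fr}{2}, \qquad
   y_{\mathrm{dig}} = (1 - fr)(1 - e) + \tfrac{fr}{2}. $$

The half-weighting of ssDNA is the only choice under which the assay's
design predictions (50% yield irrespective of digestion for a fully
resected amplicon; 0% digested / 100% mock for a fully protected one)
and the estimator below are simultaneously exact. Whether denatured
ssDNA amplifies at exactly half efficiency in a real thermocycler is not
observable from our inputs; the package adopts the weighting as a model
assumption.

The observable is the fold-difference $D = y_{\mathrm{dig}} /
y_{\mathrm{mock}}$ of ACT1-normalized quantities. Inverting the forward
model gives the digestion-corrected resection estimator

$$ r = \frac{2\,(D - 1 + e)}{f\,(D - 1 + 2e)}, $$

which reduces to the classical form $2D/(f(D+1))$ at $e = 1$. Both
identities are enforced by property tests: exact inversion of the forward
model to $10^{-12}$ over a parameter grid, and the $e = 1$ reduction as a
closed-form identity.

Auxiliary parameters come from controls on the same plate: $e = 1 - D$
on a no-DSB (glucose) control, per SphI amplicon; $f = 1 - D$ from a
cleavage-spanning amplicon on undigested samples, per strain. $D$ is
oriented digested-over-mock; this orientation is forced by requiring
those two control identities to hold simultaneously.

Two normalizations make strains comparable: each site's $r$ is divided
by $r$ at SphI-1 (the most break-proximal site, which no roadblock can
shield), and that ratio is divided by the matching ratio in the DSB
reference strain (roadblock targeted to an unrelated locus), removing
the distance dependence of natural resection. The blocking efficiency is
one minus the doubly normalized value. Estimates are kept unclamped for
all ratio arithmetic (silently clamping noisy values into $[0,1]$ before
dividing would bias the ratios); clamped views are provided alongside.

Replicate Ct values are averaged on the cycle scale before
quantification, matching the duplicate-well workflow; quantities are
never averaged. Quantification uses per-amplicon standard curves fitted
to 10-fold dilution series by least squares.

## The forward simulator

`simulate_population()` draws, per cell: a Bernoulli($f$) break; a
per-direction resection speed $v \cdot m$ with $m \sim
\Gamma(k, k)$ (mean 1, shape $k$ controlling tract-length dispersion);
and a walk along the telomeric roadblock sites in distance order, where
an arriving machine is halted with the site's blocking probability for
an exponential dwell (the roadblock's residence time) and then resumes.
Sites act independently — the property that makes the blocking
efficiency of dual targeting the complement of the product of
single-site pass-throughs. The centromeric tract is capped by a natural
barrier. Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| `f_true` | 0.5 | DSB induction plateaus near 48% at 4 h |
| `induction_hours` | 4 | the qPCR assay's induction window |
| `resection_speed` | 4000 bp/h | resection reaches ~50 kb in 12 h when unrepairable |
| `tract_shape` | 4 | moderate tract-length dispersion (CV 0.5) |
| `residence_minutes` | 206 | measured dCas9 residence on matched targets in human cells; a borrowed figure, deliberately exposed as a free parameter |
| `digestion_efficiency` | 0.98 | a well-behaved SphI digest |
| `ct_noise_sd` | 0.15 cycles | typical duplicate-well technical noise |
| `seq_depth` | 50,000 | the amplicon pools' printed coverage range |
| `deamination_rate` | 2e-3 per exposed C | gives order-1 mutations per fully exposed reporter |
| `kill_prob_dsb` | 0.4 | DSB induction roughly halves survival |

`simulate_ct_plate()` maps each population's realized ssDNA fractions
through the forward signal model, converts quantities to Ct via the
configured standard curve, and adds Gaussian per-well noise — so with
the noise at zero, `analyze_experiment()` recovers the population's
empirical resection bookkeeping exactly (to float tolerance), which is
the package's strongest end-to-end correctness check.

What the simulator deliberately does not model: DSB repair (the
measurement window is treated as repair-free, consistent with the
observation that a recombination-deficient background reproduces the
wild-type resection pattern; viability loss is modelled as a simple kill
probability), RPA-to-Rad51 exchange on ssDNA (the fluorescence proxy is
linear in ssDNA), chromatin, sequence-dependent Cas binding, and repair
pathway choice. Passing tests therefore certify the estimator chain and
its statistical behaviour under the stated noise model, not the
biological completeness of the generative process.

## Measurement replication

The blocking efficiencies this assay family reports are means over
biological replicates (three to six per strain in the source
experiments). A single simulated run at the default conditions carries a
standard deviation near 5 percentage points on the dual-targeting
blocking estimate — Ct noise propagated through a small fold-difference
is the dominant term — so the package's tests and the acceptance script
measure blocking as the mean over **6** independently simulated
biological replicates, each a fresh population and plate. With that
replication the recovered dual-targeting blocking (configured
$1 - 0.47 \times 0.53 = 75.09\%$) has SD ≈ 1.9 pp and lies within
±0.05 of the configured value in 99 of 100 seeded runs.

```{r pipeline, eval = FALSE}
layout <- default_layout()
cfg <- sim_config(n_cells = 10000, block_probs = c(sg1 = 0.53, sg2 = 0.47),
                  residence_minutes = 1e9, seed = 1L)
pop <- simulate_population(cfg, layout)
# ... simulate_ct_plate() over test / reference / glucose populations,
# then analyze_experiment(); see README for the full worked example
```

## Imaging quantification

The fluorescence module mirrors the stated workflow: the most focused of
the 7 z-slices is the one with the highest total intensity (ties to the
lowest index); background is removed by grayscale morphological opening
with a 5-pixel disc (a deliberate stand-in for ImageJ's sliding
paraboloid — correctness is asserted by spot-preservation properties,
not bit-equality with any external program); particles are segmented by
Otsu thresholding with 8-connectivity and a 4-pixel minimum area (the
source workflow does not state a threshold policy; these are
config-overridable decisions, not inferences); and the per-sample
statistic is the mean raw integrated density over all particles on the
focused slice. The population statistic

$$ \mathrm{relative\ I} = \frac{I - \bar I_{NC}}{\bar I_{DSB} - \bar I_{NC}} $$

is affine-invariant in the intensities, pinned to 0 at the
negative-control mean and 1 at the DSB-reference mean. The simulator's
image renderer attenuates in-plane signal away from the focal slice
(light spreading along z) — without that attenuation a sum-intensity
focus criterion has nothing to find.

## Mutagenesis readout

Bisulfite deaminates cytosines on exposed ssDNA. Resection from the
break exposes the non-sense strand of the CAN1 reporter, so its
deamination is read on the sense strand as G>A; transcription-coupled
exposure of the sense strand would instead yield C>T. The simulator
exposes this as the `exposed_strand` switch, and `classify_spectrum()`
reports the sense-strand substitution tally plus the G>A/C>T ratio. The
reporter's reference sequence is synthetic (a fixed position hash; no
real gene sequence ships with the package). Colony arithmetic follows
the plate algebra: density from colonies, dilution and volume; mutation
frequency as Can-R density over viable density; normalization by $f$;
and the cross-strain comparison in percent of the DSB reference strain.
Per-position relative frequencies divide treated by untreated
non-reference frequencies, excluding (and listing) positions whose
untreated frequency is zero; the ratio is depth-invariant by
construction. "Mutation frequency" at a position is total non-reference
frequency; substitution-type-specific views are available through the
spectrum tally.

## Numerical choices and degenerate inputs

* `estimate_resection()` raises an error when $|D - 1 + 2e| < 10^{-9}$
  rather than returning an unbounded estimate, and refuses $f = 0$
  (resection is undefined without breaks). Within
  `analyze_experiment()`, a strain whose measured $f$ is at zero is
  flagged with `NA` estimates instead of aborting the whole plate.
* Out-of-range estimates ($r$, $e$, $f$, blocking) are preserved raw and
  additionally exposed clamped; downstream ratios always use raw values.
* When digestion controls disagree across SphI amplicons by more than
  0.05, a warning is emitted; each amplicon keeps its own $e$.
* Standard-curve fits flag non-negative slopes; quantification flags
  extrapolation beyond the dilution series but permits it.
* Within-sample normalization errors when SphI-1's estimate is
  non-positive; such samples are meant to be excluded upstream.

## Problem sizes

The shipped tests and the acceptance script run populations of
2,500–40,000 cells, plates with duplicate wells, 100-seed recovery
sweeps at 6 biological replicates each, rendered fields of 160–256 px
with 30–60 cells, and 1.8-kb reporter pileups at 50,000x depth. These
sizes give binomial/technical standard errors comfortably inside every
asserted tolerance while keeping a full run in tens of seconds.

## Known limitations

Blocking probabilities are free inputs, not predictions — the package
cannot say how well a given guide RNA will block, only quantify it. The
residence-time default is a cross-organism borrowing. The image renderer
draws cells as uniform discs (no DIC channel, no cell-size effects). The
mutation model ignores mismatch repair and treats inactivating positions
as a fixed fraction of deaminatable sites. None of these limit the
estimator chain, which is exercised against the simulator's exact
bookkeeping.
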