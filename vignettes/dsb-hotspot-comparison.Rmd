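---
title: "Comparing meiotic DSB hotspots and recombination intermediates between two conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing meiotic DSB hotspots and recombination intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbquant)
```

# The problem

Meiotic recombination starts with programmed DNA double-strand breaks
(DSBs) made by the Spo11/Rec12 transesterase.  Breaks cluster at hotspots,
in fission yeast up to several hundred fold above the cold-region
background.  When two induction protocols for synchronous meiosis are to
be compared — an ATP-analog-sensitive kinase allele at 25°C against the
classical temperature-sensitive allele at 34°C — the question is whether
the genome-wide DSB landscape and the downstream recombination
intermediates (Holliday junctions, crossover DNA, recombinant spores) are
the same under both.

`dsbquant` packages the quantitative machinery of that comparison:

* tiling-array ChIP (IP:WCE) normalization, cross-array calibration and
  hotspot integration, with Southern-blot anchoring to percent DNA
  breakage;
* differential calling of per-hotspot signals between conditions by the
  95% prediction interval of an ordinary least-squares comparison, with
  replicate intersection and de novo detection;
* densitometry of 1D gel lanes (percent DNA broken, crossover DNA
  frequency) and of 2D gels (Holliday-junction frequency,
  intersister:interhomolog ratio, HJ:novel-species time courses);
* recombination-genetics statistics (Haldane map function, t-tests from
  summary statistics, contingency chi-square).

Real array data of this kind live in public repositories; the package
instead ships a synthetic-data module that generates all inputs with
planted ground truth, so every downstream stage is testable end to end
with known right answers.

# The array model

## Signal

A scenario (`build_scenario()`, `scenario_preset()`) consists of a
multi-chromosome genome tiled by probes at regular spacing, and a set of
non-overlapping hotspot intervals.  Each hotspot has a true enrichment
fold $I \ge 1$ over background; the probe-level IP:WCE ratio is

$$ r(x) \;=\; b \, \Big( 1 + \sum_h (I_h - 1)\, k_h(x) \Big), $$

where $b$ is the arbitrary background level and $k_h$ is a Gaussian kernel
centred on the hotspot with SD one quarter of the interval width
(truncated at 3 SD), emulating a cluster of distinct break sites within
the interval; a rectangular kernel is available for exact-identity tests.
With all noise switched off the simulated probe ratio equals this planted
enrichment exactly.

## Noise, replicates and conditions

Three noise terms act on the log10 scale:

* **probe noise** (`probe_sigma`, default 0.03): independent log-normal
  noise on each channel of each probe;
* **replicate noise** (`replicate_sigma`, default 0.03): a per-hotspot,
  per-array Gaussian deviation of the kernel amplitude;
* **condition deviation** (`condition_sigma`, default 0.12): a
  per-hotspot deviation of condition A relative to B, drawn uniformly on
  $\pm\sqrt{3}\,\sigma$ and *fixed across replicate inductions*.

The last point is the structural choice that matters.  Replicate
inductions of the same condition correlate near $r = 0.98$, while
cross-condition comparisons of the same hotspots correlate near
$r = 0.8$; if the condition-level scatter were re-drawn per induction it
would be impossible to have both, because replicate arrays would carry
the same scatter.  Modelling the cross-condition deviation as a stable,
sub-threshold per-hotspot property reproduces both correlation regimes
and matches the observation that modest condition differences inside the
prediction interval are themselves reproducible.  The uniform (bounded)
law, rather than a Gaussian, keeps those deviations strictly inside the
95% prediction interval, so unchanged hotspots do not generate spurious
reproducible calls; with Gaussian tails the planted "unchanged" class
would not actually be unchanged.

Planted effects multiply the hotspot amplitude in condition A: the default
emulation plants, among 288 hotspots, 11 increased 4–5×, 6 decreased to
1/10–1/5, and one de novo hotspot (amplitude zero in condition B).  The
effect ranges sit at the strong end of what the prediction-interval rule
can detect: at the calibrated $r \approx 0.8$ noise level the 95% PI
spans about 2.6-fold, so only effects of roughly 4-fold and above are
*reproducibly* outside it — which is precisely the regime the
differential caller is meant to recover.  Differential hotspots are
planted among the hotspots intense enough that a 10-fold reduction still
leaves breakage measurable above threshold.

Each array also receives a log-scale **gain** below 1 (drawn in
$[1/1.28, 1/1.12]$ for non-reference arrays), compressing its log ratios.
This is what cross-array scaling must undo, and makes the fitted scale
factors land in the 1.1–1.3 band that such calibrations typically
require.

## Desk scale

The default genome is three chromosomes totalling 2.4 Mb at 300 bp probe
spacing (~8,000 probes) carrying the full 288 hotspots;
`genome_spec(scale = "full")` gives the 12.57 Mb, ~44,000-probe version.
At desk scale the hotspot density is five times higher than on the full
genome, which interacts with median normalization: the genome median sits
at an upper quantile of the background noise when a large fraction of
probes carries kernel signal, biasing integrated values downward.
Hotspot widths are therefore drawn from 0.9–1.8 kb (rather than the
2–3 kb typical of real hotspots), keeping kernel-covered probes near 40%
and the median bias at the few-percent level.  This is a deliberate
desk-scale artefact: on the full-scale genome the bias is negligible.

# The array pipeline

1. **Normalization** (`normalize_profile()`): per-probe IP/WCE, divided
   by the genome median, so the background ratio is 1 and the log10 ratio
   is 0.
2. **Cross-array scaling** (`fit_scale_factor()`): the reference profile
   is the array with the highest mean log ratio over six reference
   hotspots (intense hotspots known to be broken equally in both
   conditions — in the emulation their condition deviation is planted at
   zero, mirroring reference sites validated by direct Southern blot).
   Every other array's log ratios are multiplied by the through-origin
   least-squares factor $c = \sum r_k s_k / \sum s_k^2$ over the six
   reference means.  A factor outside $[1.0, 1.5]$ triggers a warning.
3. **Integration** (`integrate_hotspots()`): the integrated value of a
   hotspot is $\sum \max(\text{ratio} - 1, 0) \times \text{probe width}$
   over probes whose midpoint falls in the interval, after scaling —
   i.e. above-baseline enrichment mass in units of bp × fold.  The exact
   statistic behind an "integrated array value" is rarely specified in
   this literature; this choice is proportional to enriched DNA mass and
   insensitive to interval padding, because background probes contribute
   zero.
4. **Calibration** (`calibrate_breakage()`): a through-origin
   least-squares line maps integrated signal to percent DNA broken using
   ~25 Southern-blot calibration pairs; zero signal means zero breakage,
   hence no intercept.  The calibration anchors must be hotspots broken
   equally in both conditions — anchoring one condition's arrays to
   breakage values measured in the other at *differential* hotspots tilts
   the slope badly (the emulation draws its anchors from the unchanged
   class for exactly this reason).  Hotspots above 0.3% breakage count as
   bona fide hotspots.

# Differential calling

`fit_comparison()` regresses condition-A on condition-B integrated
signals, by default on the log10 scale (signals span two orders of
magnitude and the scatter is multiplicative; a linear-scale flag is
provided).  The two-sided 95% prediction interval for a new observation,

$$ \hat y(x) \pm t_{0.975,\,n-2}\; s \sqrt{1 + \tfrac1n +
   \tfrac{(x - \bar x)^2}{S_{xx}}}, $$

classifies each hotspot: above the upper limit `increased`, below the
lower limit `decreased`, otherwise `unchanged`; a point exactly on a
limit is inside.  No multiplicity correction is applied — with 288
hotspots about 14 points are expected outside a 95% interval by chance,
and the error control comes instead from **replication**:
`intersect_reproducible()` keeps only hotspots called in the same
direction in *every* provided comparison (here, two independent
induction pairs).  Because the per-pair noise is independent, the chance
of the same null hotspot escaping in the same direction twice is ~0.06%,
so the reproducible set is essentially free of false calls while the
planted strong effects are recovered with sensitivity 1.

Hotspots below half the breakage threshold in either condition are
excluded from the regression (their log signal is dominated by clipped
background noise) and routed to `detect_de_novo()`: de novo in A means
above threshold in A and below *half* the threshold in B.  The
half-threshold guard band is an invented but necessary hysteresis — with
a single cutoff, a hotspot fluctuating around the threshold would flicker
in and out of the de novo set.

# Gel densitometry

1D lanes are simulated as sums of Gaussian bands at mobility
$1.05 - 0.45\log_{10}(\text{size in kb})$ — the constants are arbitrary,
only monotonicity in log size matters — with band areas following a
phenomenological break-and-repair kinetic model (`gel_kinetics()`): the
broken fraction rises linearly from onset to peak and falls back to zero
by the repair end; in `rad50S` mode repair is disabled and the broken
fraction is non-decreasing.  `quantify_lane()` subtracts a linear
baseline interpolated between window-edge intensities (areas clipped at
zero) and reports each band as a fraction of the *whole lane* signal —
"percent of total DNA" has the total lane as denominator, including the
parental band.  Crossover DNA is $2 \times$ the R2 recombinant-fragment
fraction (`crossover_frequency()`), because partial digestion can
contribute to the other recombinant fragment, and is averaged over
replicate lanes.

2D gels are grids of bivariate Gaussian spots (linear species, Y-arc
novel species, intersister HJ, and the two interhomolog HJ spots that
arise from heterozygous restriction-site polymorphisms) over a uniform
baseline.  `quantify_2d_spots()` subtracts a local-median background
(median pixel intensity in a frame around each window) and reports spot
fractions, HJ frequency, and the IS:IH ratio
$\mathrm{IS}/(\mathrm{IH}_{small} + \mathrm{IH}_{large})$ — reported as
`NA`, not infinity, when no IH signal is present.  The `mbs1-25C` preset
plants 2.1% of total DNA as HJs at IS:IH = 3:1 with HJ:NS = 1.3; the
time-course preset plants HJ:NS = 1.3, 1.7, 2.6 at 7, 8, 9 h (the novel
species, a putative single-end-invasion precursor, decays faster than
HJs).  Simulation noise defaults (SD 1 intensity unit per pixel against a
total of $10^6$) put quantification error at 1–2%, the regime of clean
phosphorimager quantification.

# Genetics

`haldane()`/`haldane_R()` implement $d = -50\ln(1-2R)$ and its inverse
(no interference).  `ttest_from_summary()` computes
$t = |\bar y - \bar x| / \sqrt{\mathrm{SEM}_x^2 + \mathrm{SEM}_y^2}$; the
default degrees of freedom are $n_x + n_y - 2$, with Welch–Satterthwaite
as an option.  For the packaged cross summaries (1200 ± 110, n = 3
against 3650 ± 1100, n = 6 recombinants per $10^6$ viable spores) the
pooled-count rule gives $t = 2.216$, $p = 0.062$; Welch gives
$p = 0.076$.  Both routes are exposed because the convention behind a
p-value quoted for such crosses (raw replicate values vs summaries,
pooled vs Welch df) usually cannot be reconstructed from the summaries —
the pooled-count rule, which reproduces the conventionally quoted
$p \approx 0.06$ within rounding, is the default.  `chisq_2x2()` is a Pearson
chi-square without continuity correction by default (flag available).
`simulate_cross()` draws recombinants binomially at the planted
recombinant fraction.

# Numerical choices and degenerate inputs

* All randomness flows through seeds passed explicitly per call
  (`withr::with_seed`); no global RNG state is consumed, and identical
  seeds give bitwise-identical outputs, including byte-identical pipeline
  output files.
* Probes belong to an interval when their midpoint is inside (0-based
  half-open coordinates throughout; BED files are converted on read).
* Band/spot windows span ±6 SD, so noiseless planted fractions are
  recovered to well below $10^{-6}$ relative error; negative
  background-subtracted areas are clipped at zero.
* Degenerate inputs error early and specifically: non-positive WCE
  (naming the probe), overlapping intervals, empty interval sets,
  all-zero reference signal, $R \ge 0.5$ in the map function, both SEMs
  zero with unequal means, zero-margin contingency tables.
* Ties: a point exactly on a PI limit is inside; reference-profile ties
  break by input order.

# Problem sizes

The shipped analyses and tests run at desk scale: 8,000 probes, 288
hotspots, four arrays, 200 × 200 2D grids, 1,000-replicate
prediction-interval coverage simulations, 200-seed binomial checks.  On
one CPU the full analysis sequence takes a few seconds and the test suite
under half a minute.

# What passing tests do and do not show

The generator emulates the *statistical structure* of the study data —
hotspot intensity spread, replicate and cross-condition correlation,
planted effect classes, gel band/spot geometry, binomial cross sampling —
not its biology or its instrumentation.  There is no scanner PSF, no dye
bias, no hybridization chemistry, no lane warping, no partial-digestion
artefacts; kinetics are phenomenological ramps, not mechanistic models.
Recovery of planted truth therefore validates the *analysis pipeline*
(normalization, scaling, integration, calibration, interval-based
calling, densitometry arithmetic, statistics), and says nothing about
whether real arrays satisfy the model's assumptions.  The background
level of cold regions is set to 1 arbitrary unit; nothing downstream
depends on its absolute value.

# Known limitations

* The prediction-interval rule controls errors only through replication;
  with a single comparison it is a raw 95% interval with the expected 5%
  false-call rate.
* The reproducibility rule is all-comparisons intersection; weaker
  "majority" rules are not implemented.
* Integration assumes non-overlapping intervals each containing at least
  one probe; intervals without probes are reported `NA` with a warning,
  not imputed.
* The de novo rule compares calibrated breakage tables only; it does not
  scan for unannotated peaks (hotspot intervals are inputs, not
  discovered).
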