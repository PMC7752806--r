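---
title: "Eyeblink conditioning under partial reinforcement: models and methods"
author: "blinkcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eyeblink conditioning under partial reinforcement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkcr)
```

## The scientific problem

Delay eyeblink classical conditioning pairs a tone conditioned stimulus (CS)
with a corneal air-puff unconditional stimulus (US) that co-terminates with
the tone. As learning proceeds, subjects begin to blink *before* the puff
arrives: a conditioned response (CR). Under a 50% partial reinforcement
schedule (only half of CS presentations are reinforced, the rest are CS-
trials), acquisition is degraded in typical subjects, which accentuates
group differences: anxiety-prone and PTSD-symptomatic groups tend to acquire
CRs faster and to a higher asymptote under exactly these suboptimal
conditions. `blinkcr` implements the full analysis chain for such a study --
protocol generation, EMG simulation, CR detection, blockwise scoring,
questionnaire scoring, mixed repeated-measures ANCOVA, and behavioural
subtyping by hierarchical clustering -- so that every stage is testable
end-to-end without access to any participant data.

## Conditioning protocol

A session is a sequence of trials with a 3,000-ms EMG sampling window each.
The CS is a 500-ms, 1200-Hz tone at 82 dB; on CS+ trials a 50-ms air puff
co-terminates with it, so the US starts 450 ms after CS onset. Week 1
consists of 3 US-alone exposures (UR calibration only) followed by 60
acquisition trials (30 CS+, 30 CS-); Week 2 has 30 acquisition trials and no
US-alone exposures. Trial order is pseudorandom under the constraint that no
more than 3 same-type trials occur in succession; the generator uses
rejection sampling (shuffle the trial-type multiset, reject any ordering
with a longer run), which is exactly uniform over admissible orderings. The
inter-trial interval is uniform on 15-30 s and is recorded for realism but
feeds no downstream computation. The run-length constraint is applied to the
acquisition block only; the three US-alone exposures precede it and are
excluded from all CR statistics.

CS onset is placed 1,000 ms into the trace (the protocol leaves this
unstated); that leaves a full 250-ms pre-stimulus baseline window with
margin, and more than 1.5 s of post-stimulus tail.

## Synthetic EMG and latent learning profiles

The generator emulates the *post-preprocessing* envelope of periocular EMG
rather than raw muscle potentials. A trial's trace is:

* band-limited (1-30 Hz) Gaussian baseline noise with envelope-scale SD
  `sigma_b = 0.05`;
* a UR burst on every trial with a US, beginning 25-60 ms after US onset;
* iff the trial expresses a CR, a CR burst whose peak lies 120-400 ms after
  CS onset (inside the 80-450 ms scoring window);
* spontaneous blinks at a Poisson rate of 0.05 per trial, placed outside the
  CR window by default (configurable inside it to stress false-positive
  handling).

Bursts are Gaussian envelopes with width (SD) uniform on 30-60 ms and
log-normal peak amplitudes (CR median 0.8 = 4x the detection threshold,
UR median 1.2). A `raw` mode multiplies the envelopes by a 15-Hz carrier to
mimic band-passed oscillatory EMG; the detector then has to do its own
rectification and smoothing. The band-pass is implemented as a zero-phase
order-2 high-pass at 1 Hz cascaded with an order-4 low-pass at 30 Hz: the
steeper low side keeps more than 95% of broadband-noise power inside the
band, and the gentle high side keeps `filtfilt` numerically stable at the
very low normalised corner frequency.

Each subject carries a latent learning profile. Within a week the per-block
CR probability follows saturating growth
$p(t) = p_0 + (p_\infty - p_0)\,(1 - e^{-r t})$ with $t$ the block number;
Week 2 starts at `retention` times the Week-1 final value and approaches the
same asymptote (held constant if retention overshoots it, so the curve never
decreases within a week). The default profiles are stand-ins chosen to
reproduce the qualitative phenotypes -- HIGH responds at a high rate from
the first block and plateaus near 65%, MID rises gradually toward ~45%,
LOW stays near 15% -- not measured values, and all of them are configurable:

```{r profiles}
sapply(default_profiles(), function(p)
  round(100 * c(cr_probability(p, 1, 1:6), cr_probability(p, 2, 1:3))))
```

Cohort structure mirrors a 54-veteran sample: groups PTSD-/mTBI- (8),
PTSD-/mTBI+ (21), PTSD+/mTBI- (12), PTSD+/mTBI+ (13), with questionnaire
totals drawn from truncated normals matching each group's published
mean/SD and decomposed into item responses by random increments under the
per-item maxima (only totals and cluster sums are analysed downstream, so
item-level realism is not needed). PCL-5 draws are additionally truncated on
the diagnostic side of the 33-point cut-off so generated group labels and
scored flags agree. Latent profiles are assigned conditional on PTSD status
(about 71% of HIGH learners PTSD+), mirroring the published subtype
composition. Each subject derives a deterministic child seed from the master
seed, so enlarging a cohort never reshuffles existing subjects.

What the generator does *not* emulate: motor-unit physiology, electrode
artifacts (pops, movement), alpha/startle responses, habituation of the UR,
or item-level questionnaire responses with realistic inter-item structure.
Passing closed-loop tests therefore demonstrates that the analysis machinery
is correct and calibrated, not that the detector would meet the same
operating characteristics on noisy clinical recordings.

## CR detection

The detector reproduces a three-criterion peak-counting rule on the smoothed
rectified envelope. Candidate peaks are local envelope maxima in the
half-open window `[CS onset + 80 ms, US onset)`; on CS- trials the window
ends at the *virtual* US onset (CS onset + 450 ms) so both trial types are
scored over identical windows. A candidate counts as an eyeblink only if

1. its amplitude exceeds the fixed unitless threshold 0.2,
2. its amplitude exceeds the 250-ms pre-CS baseline mean plus 2 baseline
   SDs, and
3. both waveform slopes measured 25 ms on either side of the peak
   (`slope_fwd` rising, `|slope_bwd|` falling) reach `min_slope`.

The first two criteria are conjunctive by design: failing either rejects the
peak. A CR is present when at least one candidate passes; the reported event
is the earliest passing candidate, with ties broken to the earliest sample.
The UR is scored with the same criteria in `[US onset + 20, US onset + 500]`
ms, reporting the passing peak's amplitude minus baseline as the UR
magnitude.

`min_slope` deserves its own paragraph, because the slope criterion is only
qualitative in the source protocol ("steep enough to resemble a blink") and
its default here is a genuine calibration. Measured across the 25 ms
adjacent to the peak -- where a smooth envelope is flattest -- a Gaussian
burst of width $w$ and amplitude $A$ has slope
$A\,(1 - e^{-312.5/w^2})/25$ per ms, only $\sim 0.0033 A$ at $w = 60$ ms.
Baseline noise additionally displaces the detected local maximum a few ms
off the true peak, which flattens whichever measured slope faces the true
peak; empirically this produces near-peak slopes as low as ~0.0006 on
clearly genuine bursts. The default `min_slope = 0.0005` therefore sits
below both effects while still rejecting slow drifts by a wide margin (a
0.3-amplitude rise over 800 ms has slope 0.000375). At these defaults the
closed-loop hit rate is ~0.98 and the false-positive rate on blink-free CS-
trials is ~0. Anyone changing the envelope scaling or smoothing should
recalibrate this parameter.

Peaks are detected on the smoothed envelope (moving average, 12-ms
half-width), never on the raw band-passed signal, where a single blink
fragments into many carrier-frequency maxima.

## Blockwise scoring

CR calls are aggregated in blocks of 10 consecutive acquisition trials (the
60/6 and 30/3 trial counts force this block size), pooling CS+ and CS-
trials; both are scored over identical windows, and a `cs_plus_only` switch
exists for sensitivity analyses. The learning series is the concatenation
`[w1b1..w1b6, w2b1..w2b3]`; subjects missing either session are excluded
and reported.

## Questionnaire scoring

PCL-5: 20 items (0-4), total 0-80, DSM-5 clusters B (items 1-5), C (6-7),
D (8-14), E (15-20), provisional PTSD at total >= 33. PHQ-8: 8 items (0-3);
aggregate severity bands None (0-4), Mild (5-9), Moderate (10-14),
Moderately Severe (15-20), Severe (>20) with >= 10 flagged clinically
significant; symptom scoring requires depressed mood or anhedonia at
"More Than Half the Days" (coded >= 2) plus at least 5 of 8 symptoms at
that frequency. AMBI: 16 items (0-2), total 0-32, behavioural inhibition
above 15.5. The concussion screen is reduced to a single swappable
predicate: head-injury event with alteration of consciousness and any loss
of consciousness no longer than 30 minutes (the conventional mild bound);
structured screening interviews are richer than this, and the predicate is
documented as an approximation.

## Mixed repeated-measures ANCOVA

The inferential model is the classical univariate mixed design: Training
Block as the repeated factor, PTSD and mTBI as crossed between-subject
factors (sum-to-zero coding, Type III sums of squares), and mean-centered
age as a between-subject covariate. Between effects are tested against the
between-subject error (df $n - 5$ with the covariate; 49 at $n = 54$);
within effects against the block-by-subject error stratum (df
$(k-1)(n-5)$; 245 for the six-block week). Sphericity is assessed with
Mauchly's test on the orthonormal-contrast covariance of the between-model
residuals, $W = \det S / (\mathrm{tr}\,S/(k-1))^{k-1}$ with the standard
chi-square approximation, and the Greenhouse-Geisser estimate
$\hat\varepsilon = (\mathrm{tr}\,S)^2 / ((k-1)\,\mathrm{tr}\,S^2)$,
clipped to $[1/(k-1), 1]$, shrinks the within-effect degrees of freedom
whenever Mauchly rejects at 0.05 (policy configurable to `always` or
`never`). Partial $\eta^2$ is reported per effect as
$SS_{\text{effect}}/(SS_{\text{effect}} + SS_{\text{error}})$ within its
stratum. The implementation is validated to ~1e-8 against both a balanced
cell-means decomposition computed from scratch and the multivariate-model
route in `car::Anova`.

Design choices worth flagging. Type III with sum coding matches the
reporting conventions of mainstream statistics packages for this design;
Type II is not offered because no spec-relevant quantity needs it. The
covariate enters the between model only (the `block:age` row of the
standard decomposition is reported, but age does not reduce the within
error further); this is what reproduces the published df structure. At toy
scale ($n_e < k - 1$) the contrast covariance is singular, so sphericity
statistics are skipped with a warning and uncorrected df are used rather
than failing the whole analysis. Post-hoc group comparisons use
pooled-variance Student t-tests (reproducing integer published df such as
32 and 18) with Bonferroni correction; Helmert contrasts over the ordered
learning profiles test Low against the mean of Mid and High, then Mid
against High, on the pooled one-way error term.

One caveat the test suite encodes: the common claim that the GG-corrected
p-value always exceeds the uncorrected one is false deep in the null region
(shrinking both df of an F tail lowers the probability when F is small,
e.g. $P(F_{5,245} > 1) = 0.42$ vs $P(F_{1,49} > 1) = 0.32$). The inflation
property holds wherever the effect is near significance, and that is where
the suite asserts it.

## Behavioural subtyping

Learning series are clustered with complete-linkage agglomeration on
squared Euclidean distances, computed on raw CR percentages (all columns
share units; no standardisation). The number of clusters for the all-blocks
analysis is chosen by majority rule over a panel of ten internal validity
indices -- Calinski-Harabasz, mean silhouette, Dunn, point-biserial and
Ratkowsky-Lance (maximised), Davies-Bouldin, C-index and McClain-Rao
(minimised), Ball-Hall and Hartigan (largest change between successive k)
-- over k in 2-8, with ties broken toward smaller k. The full vote table is
part of the output so the selection is auditable. The Week-2-only analysis
specifies a three-group solution a priori, mirroring the design where the
reduced-input analysis fixes k = 3 for comparability with the first.
Clusters are named HIGH/MID/LOW by descending grand-mean CR%.

A structural finding from the closed-loop simulations is worth recording
honestly: with the default curve shapes, the three latent profiles are
*ordered* along a single learning-curve gradient, and the majority of this
ten-index panel prefers the two-cluster split (HIGH vs the rest) over the
three-cluster one in most seeds, even on noise-free planted centroids. The
original 30-index panel this emulates produced only a plurality (11/30) for
three groups; with a 10-index subsample the plurality winner shifts. Users
who need the three-group structure should either use the Week-2 forced
three-group mode or extend the index panel. Well-separated, non-ordered
cluster structures (the planted-partition tests) are recovered with
adjusted Rand >= 0.8 in >= 90% of seeds.

## Problem sizes and numerical choices

The test suite runs the closed loops at sizes chosen to finish in minutes
while keeping binomial/Monte-Carlo error well inside the asserted bands:
1,000 seeds for protocol checks; 100-300 simulated trials for detector
operating characteristics; 2,000 replicates for type-I calibration of
Mauchly and the ANCOVA (n = 40, k = 6); 1,000 replicates of the
detection-free simulate-score-ANCOVA chain (n = 24); all 4-7-subject random
instances against the brute-force linkage oracle; and 10 full 54-subject
cohorts for the end-to-end subtyping loop. Statistical calibration of the
full chain uses the generator's detection-free mode (planted CR draws stand
in for detector calls); the detector's own error rates are characterised
separately, and at a ~98% hit / ~0% false-positive operating point they
perturb block percentages by far less than the binomial noise of 10-trial
blocks.

Seeds: every public generator takes an explicit seed and restores the
caller's RNG state; per-subject child seeds are derived by a fixed offset
so cohorts are extensible. Windows are half-open `[start, end)` throughout;
peak ties break to the earliest sample; the moving-average smoother
truncates symmetrically at trace edges.

## Known limitations

Simulated EMG is an envelope-level idealisation; detector operating points
on real recordings will differ and `min_slope` in particular must be
re-calibrated against hand-scored trials. The mTBI screen predicate is a
deliberate simplification. The ANCOVA assumes complete data (no mixed-model
handling of missing sessions; incomplete subjects are excluded and listed).
The index panel implements 10 of the 30 indices of the reference procedure;
see the subtyping note above for the consequence.
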