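# blinkcr

Analysis pipeline for delay eyeblink classical conditioning studies run
under a 50% partial reinforcement schedule, aimed at researchers studying
learning biases in PTSD, mild TBI and behaviourally inhibited populations.
The package covers the full chain from protocol to inference:

* **Protocol** — pseudorandom conditioning schedules (Week 1: 3 US-alone +
  60 acquisition trials, 30 CS+/30 CS−; Week 2: 30 trials) with no more
  than 3 same-type trials in succession, sampled uniformly over admissible
  orderings.
* **Synthetic cohort** — subjects with latent learning profiles
  (HIGH/MID/LOW saturating-growth CR-probability curves
  `p(t) = p₀ + (p∞ − p₀)(1 − e^(−rt))`), PTSD/mTBI group structure,
  item-level PCL-5/PHQ-8/AMBI responses, and per-trial band-limited
  (1–30 Hz) EMG with Gaussian-envelope blink bursts.
* **CR detection** — a three-criterion peak detector on the smoothed
  rectified envelope: amplitude > 0.2 (unitless), amplitude > 250-ms
  baseline mean + 2 SD, and forward/backward waveform slopes ±25 ms around
  the peak both ≥ `min_slope`; CRs scored in the half-open window
  [CS + 80 ms, US onset).
* **Scoring** — blockwise CR percentages (blocks of 10 trials; 6 Week-1 +
  3 Week-2 blocks per subject).
* **Questionnaires** — PCL-5 (clusters B/C/D/E, PTSD cut-off ≥ 33), PHQ-8
  (severity bands and symptom scoring), AMBI (BI above 15.5), and a
  concussion-screen predicate for mTBI.
* **Inference** — mixed repeated-measures ANCOVA (PTSD × mTBI × Block with
  age covariate; Type III SS, sum coding) with Mauchly's sphericity test
  `W = det S/(tr S/(k−1))^(k−1)`, Greenhouse–Geisser
  `ε̂ = (tr S)²/((k−1)·tr S²)`, partial η², Bonferroni post-hocs, pooled
  t-tests and Helmert contrasts.
* **Subtyping** — complete-linkage hierarchical clustering on squared
  Euclidean distances between learning series, cluster count chosen by
  majority rule over ten internal validity indices, clusters labelled
  HIGH/MID/LOW by mean CR%, and profile-wise symptom comparisons.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
54-subject cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_detect_score.R
Rscript analysis/03_score_questionnaires.R
Rscript analysis/04_fit_ancova.R
Rscript analysis/05_subtype.R
```

Stage 2 reports, for the default seed:

```
Scored 5022 trials over 54 subjects: 1445 CRs, 2571 URs detected.
Mean CR% by block (pooled over subjects):
w1b1 w1b2 w1b3 w1b4 w1b5 w1b6 w2b1 w2b2 w2b3
20.9 28.0 31.9 28.5 33.7 34.3 28.1 31.9 30.4
```

i.e. CR expression rises over Week-1 training and is retained a week later.
Stage 4 fits the 2 × 2 × 6 mixed ANCOVA and prints, among other rows:

```
Mauchly: W = 0.747, chi-sq(14) = 13.73, p = 0.470; sphericity retained
 effect df_num df_den    F     p partial_eta_sq
   ptsd      1     49 4.44 0.040           0.08
  block      5    245 7.69 0.000           0.14
```

a significant acquisition effect over blocks and a PTSD main effect (the
synthetic PTSD+ group is enriched in fast-learning profiles, so it expresses
more CRs — the direction the paradigm is designed to detect). Stage 5
clusters the learning series; with the default cohort the ten-index
majority vote is printed in full, together with the three-group Week-2
solution and its cluster mean CR% (`HIGH 56.7, MID 40.0, LOW 17.1` for this
seed) and per-profile PTSD/MDD/BI proportions.

The same pipeline is available as one call:

```r
library(blinkcr)
run <- run_study(run_config(seed = 101, outdir = "results/run101"))
```

which streams EMG subject-by-subject (traces are discarded after detection)
and writes every table plus a manifest with the seed and a config hash.

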