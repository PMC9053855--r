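# sinpipe

An R package re-implementing the analysis chain of a human intracranial
(iEEG) speech-in-noise experiment in which electrical stimulation of the
planum temporale (PT) improved the perceived quality and intelligibility
of speech in background noise. The original data are single-patient
clinical recordings that were never deposited, so sinpipe pairs every
analysis stage with a synthetic-data generator whose ground truth is known
by construction — the whole chain is testable, end to end, on any machine.

## What it computes

* **Behavior** — keyword intelligibility (percent of sentence keywords
  repeated, BKB-SIN style) and mean opinion score (MOS, 1–5), compared
  between stimulation and sham arms with two-sided Wilcoxon rank-sum
  tests (exhaustive permutation distribution for small arms, normal
  approximation with tie correction otherwise).
* **Preprocessing** — resampling to 512 Hz, 1 Hz high-pass, 60–240 Hz
  notch chain (all zero-phase); high-gamma envelope as the average of
  eight 70–150 Hz band envelopes (analytic-signal magnitude), resampled
  to 100 Hz; sound-responsive site selection by t test with
  Benjamini–Hochberg FDR at q = 0.01.
* **STRFs** — spectrotemporal receptive fields by normalized reverse
  correlation, `w = (X'X + λI)⁻¹X'y` with a soft-threshold sparseness
  operator, (λ, s) chosen by blocked cross-validation; best frequency and
  latency as the center of gravity of the excitatory kernel region. The
  stimulus representation is a 128-band constant-Q cochlear spectrogram
  reduced to 16 bands.
* **CCEP graphs** — trial-averaged corticocortical evoked potentials,
  0–20 ms artifact blanking, baseline Z-normalization (−500 to −5 ms),
  N1 statistic max|Z| in [20, 30) ms, adjacency binarized at Z ≥ 12,
  directed graph with force-directed layout and minimal-hop shortest
  paths between anatomic groups (HG, PT, STG).
* **Discriminability** — silence-gated time-averaged responses per sound,
  Euclidean dissimilarity, 2-D multidimensional scaling minimizing
  Kruskal stress-1 (SMACOF majorization), and per-region speech vs
  nonspeech t scores.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
bundle (seed 1):

```sh
Rscript analysis/01_simulate.R 1      # generate all inputs + ground truth
Rscript analysis/02_strf.R 1
Rscript analysis/03_ccep_graph.R
Rscript analysis/04_discriminability.R 1
Rscript analysis/05_behavior.R
```

which prints, among other lines:

```
mean kernel correlation: 1.000 (min 0.999)
best-frequency rank correlation: 1.000
mean |latency error|: 0.40 ms
excitatory bandwidth: broadband 7.8 vs narrowband 2.2 bands

edges at Z >= 12: 100; matches ground truth: TRUE
edge set identical for every cutoff in [5, 15]: TRUE
shortest HG -> STG: 1-5-9 (regions HG-PT-STG)
shortest PT -> STG: 5-9 (regions PT-STG)
N1 in STG: PT stim 19.75 vs HG stim 1.92 (t test p = 1e-45)

HG: mean t = 0.37 ... PT: mean t = 3.52 ... STG: mean t = 10.57
MOS: stim 3.25 vs sham 2.38, rank-sum p = 5.8e-06 (n = 24/arm)
intelligibility: stim 90.3% vs sham 37.5%, p = 2.8e-08
```

Reading it: the STRF estimator recovers all 20 planted kernels nearly
exactly at 10 dB SNR, and recovers broadband (PT-like) kernels broader
than narrowband (HG-like) ones. The CCEP stage rebuilds the planted
three-region connectivity motif exactly and robustly over the whole
cutoff band, and information flow from primary cortex (HG) to the
superior temporal gyrus (STG) passes through the PT while PT → STG is
direct. Speech/nonspeech separability rises strictly from HG to PT to
STG, and the behavioral stage detects the planted stimulation benefit in
both quality and intelligibility. Tables land under `results/`.

Equivalently, `run_pipeline(pipeline_config(seed = 1))` runs all stages
in one call and returns the summary as a list.

## Layout

```
R/                   package code (generators + all analysis stages)
analysis/            numbered narrative drivers over the package
scripts/acceptance.R headline measurements as JSON
tests/testthat/      unit, property, and end-to-end recovery tests
vignettes/           methods vignette (models, parameters, limitations)
```
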