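# motifrhythm

Rhythm analysis of annotated birdsong motifs, built around the question of
how zebra finch tutees copy the *temporal* structure — not just the
spectral one — of their tutor's song.

Zebra finch motifs are quasi-isochronous: element onsets approximately
follow a metronome-like grid whose rate is individual. Starting from
element-onset annotations (Praat TextGrid interval tiers or a long-format
CSV), the package:

* computes, per analysis sequence of inter-onset intervals
  `d_1 … d_m`, the three standard rhythm parameters

  - **IOI beat** `= 1 / mean(d)` (Hz),
  - **adjusted CV** `= (1 + 1/(4m)) · sd(d)/mean(d)`,
  - **nPVI** `= 100/(m−1) · Σ |d_k − d_{k+1}| / ((d_k + d_{k+1})/2)`
    (0 for perfect isochrony);

* classifies each tutee motif against its tutor's element-label sequence
  into the subsets *everything*, *all-shared*, *part-shared* and
  *not-shared* (beginning-anchored in-order matching, minimum three
  intervals per unit);

* compares the parameters across subsets with Welch's t tests, Bonferroni
  correction and Cohen's d, and correlates tutor and tutee mean beats per
  nest;

* runs a null simulation — random sequences resampled i.i.d. from the
  empirical interval pool — to check that parameter-vs-length trends in
  the real subsets are a property of the data, not of the metrics;

* generates complete synthetic nests (17 tutors with 1–4 tutee sons each,
  10 motifs per bird, bimodal intra/inter-syllable intervals, per-bird
  beats ~ N(17.1, 3.7²) Hz, tutees slightly slower than their tutors)
  with ground truth, so the whole pipeline is testable and parameter
  recovery can be verified without any recordings.

See `vignettes/motif-rhythm-methods.Rmd` for the model, the tunable
parameters and the design decisions.

## Worked example

```r
library(motifrhythm)

corpus <- generate_corpus(generator_config(seed = 42))
corpus
#> Synthetic corpus: 17 nests, 17 tutors, 36 tutees, 530 motifs
#>   seed: 42
#>   tutee strategies: full_copy=10, improvise=11, partial_copy=15

fit <- rhythm_analysis(corpus$motifs)
fit
#> Motif rhythm analysis
#>   analysis units: TUTOR=170, EVERYTHING=360, ALL_SHARED=100, PART_SHARED=150, NOT_SHARED=160
#>   intervals (tutor + everything): n = 5260, range 0.009-0.290 s, mean 0.057 s
#>   IOI beat: mean 18.5 Hz (sd 4.1), range 6.2-38.0 Hz
#>   adjusted CV: mean 0.60 (sd 0.15)
#>   nest-level tutor-tutee beat correlation: r = 0.96 (p = 5.1e-10, 17 nests)
```

Reading the output: every tutor motif is one `TUTOR` unit and every tutee
motif one `EVERYTHING` unit; the shared/not-shared counts depend on how
much each simulated tutee copied. The corpus realises ~5000 intervals in
the configured 0.009–0.29 s support with a mean near 0.06 s, bird-level
beats around 17 Hz, and a strong per-nest tutor–tutee beat correlation —
tutees inherit their tempo from their tutor (here by construction; on
real data this is the finding under test).

```r
fit$length_correlations
#>    parameter         r     p   n
#>  ioi_beat_hz -0.015559 0.634 940
#>       cv_adj  0.000502 0.988 940
#>         npvi  0.045623 0.162 940
```

`summary(fit)` prints the full Welch/Bonferroni comparison table, and
`plot(fit)` draws the IOI distribution, the per-nest beat scatter with
the identity line, and per-group boxplots. `run_pipeline(motifs, out_dir,
seed)` writes the whole report bundle (`units.csv`, `metrics.csv`,
`comparisons.csv`, `correlations.csv`, `nullsim.csv`, `summary.json`,
optional plots) deterministically; `inst/cli/motifrhythm.R` wraps the
same functions as a small command line tool.

Real annotations come in via `read_textgrids("dir/", tier = "elements")`
or `read_motifs("motifs.csv")`; `inst/extdata/` holds small synthetic
examples of both formats.

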