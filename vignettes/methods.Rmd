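---
title: "Methods: Fourier detection of 24-hour rhythmicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier detection of 24-hour rhythmicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythm24)
library(dplyr)
```

## The model and its assumptions

rhythm24 scores diurnal (24-hour) rhythmicity of expression profiles
sampled on an **equally spaced grid**. The reference design is twelve
samples taken every 4 hours over two consecutive days (48 h). An
expression profile $E_0, \dots, E_{N-1}$ is transformed with the
discrete Fourier transform

$$\hat{E}_k = \sum_{n=0}^{N-1} E_n \, e^{-2\pi i k n / N},$$

and folded into one power per non-negative frequency index:

$$P(T_k) = \begin{cases}
  |\hat{E}_k|^2 / N^2 & k = 0 \text{ or } k = N/2,\\[2pt]
  (|\hat{E}_k|^2 + |\hat{E}_{N-k}|^2) / N^2 & 0 < k < N/2.
\end{cases}$$

With this normalisation the powers satisfy Parseval's identity: they
sum to the mean squared expression, the DC term is the squared mean,
and the non-DC terms sum to the population variance. The 12-point /
48-hour design resolves the periods 48, 24, 16, 12, 9.6 and 8 h
(frequency indices 1–6; index 6 is the Nyquist limit), and places the
24-h component at $k = 2$:

```{r}
period_grid(12, 48)
```

Key assumptions: the grid is equally spaced with no missing points;
the 24-h period lies exactly on the Fourier grid ($N \Delta t / 24$
integer); profiles are non-negative expression values; replicates, if
present, are collapsed (mean by default) before scoring.

## Scores

* **RP24** — the relative power of the 24-h component,
  $P(24) / \sum_{T \ne T_0, 24} P(T)$: how much of the non-DC,
  non-24-h variance budget the 24-h component commands. It is scale
  free (invariant to multiplying the profile by a constant).
* **F24** — $P(24)$ divided by its mean over random permutations of
  the time points: the fold enrichment of 24-h power over what this
  profile's values produce in random order.
* **Phase** — $-12 \cdot \mathrm{Arg}(\hat{E}_{k_{24}})/\pi \bmod 24$,
  the peak time of the fitted 24-h cosine in Zeitgeber hours.
* **p-value** — permutation test. Shuffling time points holds the
  variance fixed, so the permutation ranks of $P(24)$, RP24 and F24
  coincide; the implementation permutes once per profile and shares
  the null set between F24 and the p-value. The add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$
  is used, so the smallest attainable p is $1/(n_{\text{perm}}+1)$ and
  ties count against the observed statistic (conservative).
* **q-value** — Benjamini–Hochberg across transcripts, within each
  condition.

```{r}
v <- 3 * cos(2 * pi * (seq(0, 44, 4) - 5) / 24) + 10
spec <- power_spectrum(dft(v), 48)
c(rp24 = rp24(spec), phase = phase24(v, 4))
```

## Spike ("staccato") screen

A profile with two equal spikes half a period apart concentrates all
its variance in even frequency indices: every odd coefficient is
exactly zero and RP24 is exactly 2/3 — high enough to masquerade as
rhythmic. Three statistics flag this shape:

* **SP**, the log ratio of even to odd non-DC power (`spectral_parity`);
* **PVEC**, the circular dispersion (1 − mean resultant length) of the
  arguments of the even coefficients after aligning them by the
  estimated spike position. For an ideal two-spike profile PVEC is
  exactly 0 at *any* spike position; this alignment is why the naive
  variance of raw arguments is not used. Profiles with fewer than two
  even coefficients above numerical dust (for example a pure cosine)
  return `NA` and are never flagged.
* the fraction of non-DC variance carried by even indices
  (`spike_variance_fraction`).

The screen flags a profile when SP ≥ 2, PVEC ≤ 0.15 and the even
variance fraction ≥ 0.75. These cutoffs were fixed in a single
calibration run on simulated smooth-rhythmic, noise-only and two-spike
profiles (no false positives, full recovery of spikes) and are frozen;
they are exposed in `rhythm_thresholds()` for users with different
data regimes.

## Classification across two conditions

`classify_transcripts()` compares a reference condition (e.g. young)
with a second condition (e.g. old):

1. spike-flagged in either condition → `staccato_filtered`;
2. any decision-relevant q-value in the open band (0.05, 0.075) →
   `indeterminate` (rhythmic means q ≤ 0.05, arrhythmic q ≥ 0.075;
   the gap is refused rather than forced);
3. rhythmic and detectable in both → `RLC` (robust life cycler); the
   full 1.5 max/min fold is required in at least one condition, the
   other may pass at a relaxed 1.4, and the median expression floor
   (1 unit) applies in both;
4. rhythmic and detectable only in the first → `ELC`, only in the
   second → `LLC`;
5. otherwise `NR`. Detectability (fold ≥ 1.5, median ≥ 1) is part of
   the rhythmic call: a significant but flat or barely expressed
   profile is treated as not cycling.

## Phase geometry

Phases live on a 24-h circle drawn as a clock face: ZT0 at the top,
time running clockwise, so $\theta = \pi/2 - \pi \cdot \text{phase}/12$.
The radial coordinate maps RP24 through the logistic
$r = \mathrm{RP24}/(1 + \mathrm{RP24})$ (noise-free $\infty \mapsto 1$).
Phase differences are the shortest signed arc in $(-12, 12]$ hours;
the exact half-turn tie is reported as +12 (a delay) by convention.
`dot_and_arrow()` builds the between-condition arrow table and
`circular_histogram()` / `circular_median()` summarise phase
populations; both plot via `ggplot2::autoplot()`.

## Promoters and motif enrichment

`extract_promoters()` assembles, for each annotated transcript, up to
6000 nt upstream of the TSS (clipped at the contig edge), a 20-N
linker, and the first intron in transcript order, reported on the
sense strand (segments are reverse-complemented individually for
minus-strand transcripts so the order upstream → linker → intron is
preserved). The linker prevents motif hits from spanning the junction.
Motif occurrence tables from an external scanner are thresholded at
p ≤ 5e-5 per occurrence and collapsed to presence/absence
(`load_fimo()`); enrichment of a motif in a transcript cluster is the
upper-tail hypergeometric probability with BH correction across motifs
(`motif_enrichment()`), and `motif_effect_tests()` compares RP24 and
expression between motif-present and motif-absent transcripts with
Welch's t-test.

## Simulator

`simulate_sinusoid()` draws
$E_n = A \cos(2\pi t_n / 24 + \varphi) + B + \varepsilon_n$ with
$\varepsilon_n \sim \mathcal{N}(0, A^2/\mathrm{SNR})$.
`simulate_dataset()` plants ELC/RLC/LLC/NR/staccato classes with
baseline $B \sim U(2, 20)$ and amplitude $A = 0.5B$ (max/min fold ≈ 3,
comfortably detectable), using the same noise scale for the
non-rhythmic profiles. The simulator uses the package's own 12-point /
48-hour design so its output feeds straight into
`score_rhythmicity()`; it is a tool for validating the pipeline's
operating characteristics, not a generative model of RNA-seq counts
(no overdispersion, no heteroscedastic library-size effects).

```{r}
sim <- simulate_dataset(n_elc = 5, n_rlc = 5, n_llc = 5, n_nr = 5,
                        n_staccato = 5, snr = 10, seed = 1)
scores <- score_rhythmicity(sim$expression, n_perm = 200, seed = 1)
classify_transcripts(scores) |>
  inner_join(sim$truth, by = "transcript_id") |>
  count(planted = class.y, called = class.x)
```

`phase_recovery_experiment()` measures the mean absolute circular
error of the phase estimate across an SNR grid; recovery is exact in
the noise-free limit and degrades monotonically as noise grows.

## Numerical conventions

* Package tolerance is $10^{-9}$ (relative).
* Ratio scores whose denominator is floating-point dust relative to
  the signal (noise-free sinusoids) return `Inf`, not a huge finite
  number; an all-zero spectrum returns `NA`.
* `ks_compare()` accepts `Inf` scores by capping them just above the
  finite maximum — the KS statistic depends only on ranks, so any cap
  beyond the maximum is equivalent.
* Per-profile permutation seeds are derived from one master seed after
  sorting profiles by (condition, transcript), so results are
  independent of input row order and reproducible end to end.

## Limitations

* Periods off the Fourier grid (e.g. 20-h rhythms in this design) leak
  across neighbouring frequencies and are not modelled.
* The permutation null assumes exchangeable time points under the null
  hypothesis; strong autocorrelated trends violate this.
* Asymptotic KS p-values are used (`exact = FALSE`); for very small
  score sets the exact test would differ.
* The q-value band boundaries and detectability floors are thresholds
  with defaults chosen for two-day, 4-h-resolution expression designs;
  they are parameters of `rhythm_thresholds()`, not laws.
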