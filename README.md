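# rhythm24

Fourier-based detection, classification and visualisation of diurnal
(24-hour) rhythmicity in expression time series sampled on an equally
spaced grid — the reference design being twelve samples every 4 hours
over two days, as in two-condition (e.g. young vs. old) transcriptome
ageing studies.

## The scientific problem

Given a transcript's expression profile `E_0 … E_(N-1)`, how much of
its variation is a 24-hour rhythm rather than noise or a sharp
artefact? rhythm24 answers with the discrete Fourier transform

    Ê_k = Σ_n E_n · exp(−2πikn/N)

folded into one power per period, `P(T_k) = |Ê_k|²/N²` at k = 0 and
k = N/2 and `(|Ê_k|² + |Ê_{N−k}|²)/N²` in between, which satisfies
Parseval's identity (the non-DC powers sum to the profile variance).
For 12 points over 48 h the resolvable periods are 48, 24, 16, 12,
9.6 and 8 h, with the 24-h component at k = 2. Three scores follow:

* **RP24** = P(24) / Σ of all other non-DC powers — the share of the
  variance budget held by the 24-h component (scale free);
* **F24** = P(24) / mean of P(24) over random permutations of the
  time points — fold enrichment over the profile's own shuffled null;
* **phase** = −12·Arg(Ê_k24)/π mod 24 — the peak time in ZT hours.

Significance is a permutation test (shuffling fixes the variance, so
P(24), RP24 and F24 rank permutations identically), followed by
Benjamini–Hochberg correction within condition. A spectral-parity
screen removes "staccato" spike artefacts — two equal spikes 24 h
apart have *zero* odd Fourier coefficients and RP24 = 2/3 exactly, so
they fool a naive rhythmicity cut. Transcripts are then classified
across two conditions as early (ELC), robust (RLC) or late life
cyclers (LLC), non-rhythmic (NR), `staccato_filtered`, or
`indeterminate` when a q-value falls in the refused band between the
rhythmic (q ≤ 0.05) and arrhythmic (q ≥ 0.075) cutoffs.

The package also ships circular-phase geometry (clock-face
dot-and-arrow plots, circular histograms and medians), promoter
extraction (≤ 6 kb upstream + 20-N linker + first intron, strand
aware) with hypergeometric motif enrichment, a planted-truth
simulator, and a thin command-line interface.

## Worked example

```r
library(rhythm24)

sim <- simulate_dataset(n_elc = 2, n_rlc = 2, n_llc = 2, n_nr = 2,
                        n_staccato = 2, snr = 10, seed = 1)
scores <- score_rhythmicity(sim$expression, n_perm = 500, seed = 1)
tidy(scores)
#> # A tibble: 20 × 13
#>    transcript_id condition     rp24    f24  phase p_value q_value max_min_fold
#>  1 tx00001       old        0.0838  0.424  10.2   0.677   0.752           1.40
#>  3 tx00003       old       34.4     5.30   15.3   0.00200 0.00665         5.83
#>  9 tx00009       old        0.677   2.07    3.97  0.0439  0.0732         27.2
#> 11 tx00001       young     27.8     5.37    7.36  0.00200 0.00499         3.43
#> ...                        (plus median_expr, sp, pvec, spike_frac, staccato)

glance(scores)
#> # A tibble: 1 × 6
#>   n_transcripts n_conditions n_perm  seed p_resolution n_staccato_flagged
#> 1            10            2    500     1      0.00200                  4

classify_transcripts(scores)
#> # A tibble: 10 × 2
#>    transcript_id class
#>  1 tx00001       ELC
#>  2 tx00002       ELC
#>  3 tx00003       RLC
#>  4 tx00004       RLC
#>  5 tx00005       LLC
#>  6 tx00006       LLC
#>  7 tx00007       NR
#>  8 tx00008       NR
#>  9 tx00009       staccato_filtered
#> 10 tx00010       staccato_filtered
```

All ten planted labels are recovered. Downstream:

```r
arrows <- dot_and_arrow(scores)          # young -> old phase shifts
ggplot2::autoplot(arrows)                # clock-face plot, ZT0 up

ks_compare(tidy(scores)$rp24[tidy(scores)$condition == "young"],
           tidy(scores)$rp24[tidy(scores)$condition == "old"])
```

Real data enters through `read_expression_matrix()`, a wide TSV with
columns named like `young_ZT0`, `young_ZT4_r2`, `old_ZT44` (replicates
are collapsed). A scriptable front end with `simulate`, `score` and
`classify` subcommands lives at `inst/cli/rhythm24-cli.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) records the model,
every threshold and its rationale, the numerical conventions
(Inf/NA sentinels, dust tolerances, circular tie-breaking) and the
simulator's limitations.
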