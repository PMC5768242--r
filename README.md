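# dirlfp

Directional local field potentials (LFPs) for deep-brain-stimulation (DBS)
contact programming.

Directional STN-DBS leads carry six segmented contacts per hemisphere
(two levels × three 120°-spaced segments), and the monopolar contact review
needed to choose among them takes roughly 20 minutes per contact — about
4 hours per patient. Beta-band (13–35 Hz) LFP activity recorded from the same
contacts is spatially concentrated near the dorsolateral motor STN, where
stimulation is most effective, so the contacts that see the most beta are
strong candidates to screen first. `dirlfp` turns that observation into a
reproducible analysis pipeline for clinical neurophysiologists and
methodologists working on LFP-guided programming.

## What it computes

For each hemisphere, every segmented contact *c* gets a **normalized beta**
value

```
beta_c = ∫_peak-band P_c(f) df / ∫_13..35 P_c(f) df
```

from a Welch PSD (1-s Hann windows, 50 % overlap), where the peak band
(peak ± 3 Hz) comes from a single hemisphere-level spectral peak detected
≥ 3 dB above a fitted 1/f background; when no clear peak exists the low-beta
band (13–20 Hz) is the numerator. The ratio lies in [0, 1] and cancels any
channel gain. Contacts are scored clinically from the monopolar review
(**efficacy** = % rigidity improvement per mA; **therapeutic window** =
side-effect minus effect threshold, mA) and the package quantifies how often
the top-k beta-ranked contacts contain the clinically best one, against the
analytic random baseline k/6 (0.17 per contact), plus per-hemisphere Spearman
correlations, one-sample and paired t tests, and a screening-time estimate.
A synthetic cohort generator with a common beta source driving both signal
and clinical response makes the whole pipeline testable without patient data.

## Worked example

```r
library(dirlfp)

cfg    <- sim_config(n_hemispheres = 19, fs = 250, duration_s = 100, seed = 20)
cohort <- generate_cohort(cfg)   # recordings + monopolar reviews + truth
fit    <- beta_screening(cohort) # the central analysis
fit
#> LFP-guided contact screening: 19 hemisphere(s) analyzed, 0 excluded
#>   P(best-efficacy contact in top-k beta): k=1: 0.42, k=2: 0.68 (random: 0.17, 0.33)
#>   P(widest-TW contact in top-k beta):     k=1: 0.37, k=2: 0.68
#>   beta-efficacy Spearman rho: mean 0.37 (t(18) = 3.95, p = 0.000947)

round(coef(fit), 2)              # screening curves, one column per strategy
#>      efficacy_all tw_all random efficacy_peak_only tw_peak_only
#> [1,]         0.42   0.37   0.17               0.36         0.45
#> [2,]         0.68   0.68   0.33               0.82         0.73
#> [3,]         0.84   0.89   0.50               0.91         1.00
#> [4,]         0.95   0.89   0.67               1.00         1.00
#> [5,]         1.00   1.00   0.83               1.00         1.00
#> [6,]         1.00   1.00   1.00               1.00         1.00
```

Reading: screening only the two highest-beta contacts already contains the
best-efficacy contact in 68 % of these synthetic hemispheres (82 % among the
hemispheres with a clear beta peak), versus 33 % for untargeted screening of
two contacts. `summary(fit)` adds the top-2 vs rest paired comparisons and
the exclusion/tie log; `plot(fit)` draws both curve panels.

Recommending a screening order for a new recording:

```r
rec <- predict(fit, new_recording)   # or recommend_contacts(new_recording)
rec
#> Recommended screening order (highest normalized beta first):
#>    5 > 2 > 6 > 7 > 3 > 4
#> Screen first: 5, 2
#> Beta peak at 21.0 Hz (high beta), band 18.0-24.0 Hz, 13.0 dB above 1/f
#> Evidence (normalized beta):
#>  contact value fallback
#>        5 0.784    FALSE
#>        2 0.638    FALSE
#>        ...
#> Estimated review time, both sides: full 240 min vs LFP-guided 80 min (20 min/contact)
```

`analyze_cohort(cohort_dir, out_dir)` runs the same analysis end to end from
files on disk (TSV or EDF recordings plus a review table) and writes a
deterministic bundle of tables, figures and a log. A thin command-line
wrapper with `simulate`, `analyze` and `recommend` subcommands lives at
`inst/scripts/dirlfp.R`.

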