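---
title: "Directional LFP beta activity as a guide for DBS contact screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional LFP beta activity as a guide for DBS contact screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirlfp)
```

## The problem

Directional deep-brain-stimulation leads replace the two middle ring contacts
of a conventional electrode with three 120°-spaced segments each, so a single
subthalamic (STN) lead offers six steerable contacts per hemisphere. The
monopolar review — testing the effect and side-effect thresholds of every
contact — is the gold standard for choosing the chronic stimulation contact,
but at roughly 20 minutes per contact a full bilateral review of 12 segmented
contacts approaches 4 hours. Beta-band (13–35 Hz) local field potential (LFP)
activity recorded from the same contacts is spatially focused on the
dorsolateral motor STN, the region where stimulation works best, which makes
it a candidate physiological shortcut: screen only the contacts that see the
most beta.

`dirlfp` implements that idea as a reusable analysis: a per-contact
normalized beta statistic, clinical scoring of the monopolar review, top-k
screening curves against an analytic random baseline, and the group
statistics that quantify the association. Because no patient recordings are
publicly deposited, the package ships a synthetic cohort generator with the
same statistical structure, and every pipeline stage is validated against it.

## The normalized beta statistic

For each hemisphere the six segmented-contact signals are turned into Welch
power spectral densities: 1-s Hann windows (1 Hz resolution — enough to
separate low beta, ≤ 20 Hz, from high beta), 50 % overlap, per-segment mean
removal, and one-sided density scaling such that the integral of the PSD over
$[0, f_s/2]$ equals the signal variance (Parseval; verified in the tests to
within 5 % on white noise with ≥ 60 windows).

A hemisphere-level beta peak is then detected **once**, on the contact with
the largest raw 13–35 Hz power: a linear fit to the log-log spectrum over
5–45 Hz (excluding 13–35 Hz) estimates the 1/f background, and the largest
local maximum of the background-subtracted spectrum inside 13–35 Hz counts as
a peak if it rises at least 3 dB above the fit. The peak band is the peak
frequency ± 3 Hz, clipped to 13–35 Hz. Using one common band for all six
contacts is deliberate: the analysis ranks contacts against each other, and
per-contact band choices would confound band selection with power.

The statistic for contact $c$ is

$$\beta_c \;=\; \frac{\int_{\text{peak band}} P_c(f)\,df}
                     {\int_{13}^{35} P_c(f)\,df},$$

integrated by the trapezoid rule on the PSD grid. When no peak qualifies, the
numerator band falls back to low beta (13–20 Hz) and the value is flagged.
Because the numerator band is a subset of the denominator band,
$\beta_c \in [0,1]$, and any overall channel gain cancels — the statistic
measures spectral *shape*, not amplitude, so it is robust to per-contact
impedance differences. "Beta activity" could equally be read as an amplitude
rather than a power ratio; both are implemented
(`statistic = "power"|"amplitude"`), power is the default, and the contact
*ranking* is identical under either since the square root is monotone.

## Clinical scoring and inclusion filters

From the monopolar review of each contact:

* **Clinical efficacy** = 100 × (baseline − on-stim rigidity)/baseline ÷
  current, in %/mA. The denominator is by default the recorded test current;
  `current_basis = "threshold"` uses the effect threshold instead (the source
  data leave this ambiguous, so both are exposed).
* **Therapeutic window (TW)** = side-effect threshold − effect threshold, in
  mA — the standard monopolar-review definition. Side-effect thresholds never
  reached are capped at the maximum tested current (default 5 mA, logged);
  negative windows are clipped to 0 and flagged.

Hemispheres enter the analysis only if baseline upper-limb rigidity is ≥ 2
points (enough signal to measure improvement) and the efficacy range across
the six contacts exceeds `min_range` (no contrast between contacts means the
comparison is meaningless). The numeric range threshold is not established in
the literature; the default of 5 %/mA is exposed in the interface and every
exclusion is logged with its reason.

## Screening curves and statistics

For each hemisphere the contacts are ranked by normalized beta (ties broken
deterministically by lower contact id, and logged — ties have measure zero on
real spectra, and determinism matters more than unbiasedness for a reporting
tool). The **LFP strategy curve** gives, for k = 1…6, the fraction of
hemispheres whose clinically best contact (max efficacy, or max TW — analyzed
separately) lies among the top-k beta contacts. The **random baseline** is
analytic: screening in random order finds the best contact after k of 6
contacts with probability exactly k/6 — the 0.17-per-contact increment — so
no Monte-Carlo noise enters the comparison.

Group-level evidence uses three statistics implemented from first principles
(and cross-checked in the tests against `stats::cor` and `stats::t.test`,
including all 720 orderings at n = 6): per-hemisphere Spearman correlation
between beta and efficacy (mid-ranks for ties), a one-sample t test of the
correlations against zero, and a paired t test comparing the mean metric of
the two highest-beta contacts against the remaining four. All p-values are
two-sided and no multiplicity correction is applied, matching standard
reporting for this design. A degenerate paired sample in which every
difference is zero is reported as t = 0, p = 1 rather than an error.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` emulate the statistical structure the
analysis assumes, not the biophysics:

* A **beta source** sits at a continuous angle (uniform) and level
  (2 + Beta(2.2, 1.2), i.e. dorsally weighted, since beta sources concentrate
  in the dorsolateral motor STN).
* Each contact records an independent 1/f background
  ($10 f^{-1.5} + 0.02\ \mu V^2/\mathrm{Hz}$ by default) plus a **shared**
  narrowband oscillation (white noise through a Gaussian frequency window,
  SD 1 Hz — a broadband peak like real LFPs, not a sine) scaled by
  $\exp(-0.006\,\Delta\theta)\exp(-0.7\,\Delta L)$ in angular (degrees) and
  level distance. Sharing one oscillation makes aligned contacts on adjacent
  levels correlated, reproducing the characteristic motif of a dominant
  contact plus its aligned partner.
* With probability 12/19 a hemisphere has a clear peak (3 µV RMS at the
  source, ~10–14 dB above background at the best contact, frequency
  15–30 Hz); otherwise it carries a weak low-beta residual (20 % amplitude,
  ≈ −14 dB in power, 14–19 Hz) that stays clearly below the 3 dB prominence
  criterion, so the low-beta fallback path is exercised while a faint
  directional gradient remains — mirroring the observation that no-peak
  hemispheres still show the beta–efficacy relationship.
* **Clinical coupling**: expected efficacy = 15 + 20 × proximity %/mA with
  Gaussian noise (SD 8 %/mA), improvement truncated to [−50, 100] %; effect
  threshold falls and TW rises with the same proximity signal; thresholds are
  recorded at 0.01 mA resolution and side-effect thresholds beyond 5 mA
  become "not reached". Rigidity on stimulation is stored as a continuous
  (session-averaged) score so contact-level contrasts are not quantized away.
  Setting `coupling = 0` severs the clinical–electrophysiological link and is
  the null condition used for calibration tests.
* Each hemisphere draws from its own seed substream, so cohorts are
  bit-reproducible and parallel-safe.

What the generator does **not** emulate: volume conduction and realistic
current spread, stun-effect drift, artifacts beyond stationary noise,
non-rigidity outcomes, and inter-rater variability of the clinical scores.
Passing tests therefore demonstrate that the pipeline recovers the structure
it assumes — not that the clinical effect sizes of any specific patient
cohort will be reproduced.

## Numerical choices and degenerate inputs

* Welch scaling conserves power; DC is excluded by per-segment demeaning.
* Band integrals interpolate the PSD linearly at band edges, so bands need
  not align with the frequency grid.
* The 1/f fit needs ≥ 3 positive PSD points in 5–45 Hz outside the beta
  band; an all-zero spectrum reports "no peak" and the fallback band, and a
  zero 13–35 Hz integral is an error (the ratio is undefined).
* All-equal beta values rank contacts (2,3,4,5,6,7) with a warning; an
  all-tied Spearman input returns flagged `NA` rather than a number.
* With literally zero background noise, all six channels are scalar
  multiples of the shared oscillation and the gain-invariant statistic ties
  at 1 by construction — spatial discrimination requires (arbitrarily little)
  background, which the defaults provide.

## Problem sizes used in validation

The shipped tests run the estimator oracles at 100 random signals/spectra,
the statistic oracles over all 720 permutations plus 2 000 null draws, the
recovery analysis at 500 hemispheres (fs = 150 Hz, 100 s — detection accuracy
at these sizes is indistinguishable from the 1 kHz default, and the top-1
recovery rate under high coupling/low noise is ≥ 95 %, with residual misses
confined to near-tie source geometries), the null calibration at 500
six-hemisphere cohorts with `coupling = 0`, and the qualitative end-to-end
reproduction on a 19-hemisphere cohort with 12 peak-bearing hemispheres.
`scripts/acceptance.R` re-runs the cohort analysis and recovery from scratch
at the same sizes.

## Known limitations

* Orientation is abstract: segments are labelled 0/120/240° and never mapped
  to anatomical directions; orientation calibration is out of scope.
* Ring contacts (1 and 8) are carried in the lead model but not analyzed —
  the screening question concerns the six segments.
* The EDF reader/writer covers plain 16-bit EDF with a common sampling rate;
  EDF+ annotations are not supported.
* Artifact handling is limited to NaN rejection; recordings are assumed
  monopolar and stationary.
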