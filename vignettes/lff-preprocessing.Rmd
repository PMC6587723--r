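---
title: "Low-frequency fluctuation measures and the cost of detrending"
author: "lffpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-frequency fluctuation measures and the cost of detrending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lffpipe)
```

## The scientific question

Resting-state fMRI quantifies spontaneous brain activity through the
amplitude of low-frequency fluctuations of the BOLD signal.  For a voxel
time course of length $N$ sampled at repetition time $TR$, with one-sided
DFT magnitudes $a_i$ at frequencies $f_i$:

* **ALFF** is the sum of $a_i$ over the low-frequency band
  ($0.01 \le f_i \le 0.1$ Hz by default),
* **fALFF** divides ALFF by the sum of $a_i$ over all frequencies up to
  Nyquist ($f_i > 0$, DC excluded),
* **hfALFF** divides ALFF by the sum over $f_i \ge 0.01$ Hz only, so that
  frequencies below the band's lower edge cannot enter the normalisation.

Because non-neural signals — scanner drift, respiration, cardiac
pulsation, head motion — contaminate these measures, they are usually
preceded by nuisance regression.  `lffpipe` implements the full
evaluation machinery for the question *which* nuisance regressors help:
four regressor blocks (polynomial trends `Detr`; six WM and six CSF
regressors, each the mean plus five principal components of tissue
voxel time courses; the six realignment parameters `RP`), all
$2^4 = 16$ on/off combinations, QR orthogonalisation of every
non-detrending block against the polynomials, phase-randomised surrogate
controls, exploratory (lag-one CCA) detrending, and group-level
one-sample $t$, percent-change and test–retest-variance statistics on
standardised, smoothed maps.

The group-level figure of merit is the voxelwise one-sample $t$ across
subjects (mean over subjects divided by its standard error), averaged
over a grey-matter mask: a *consistency* statistic — successful nuisance
removal lowers between-subject variance relative to the mean amplitude.

## Design of the synthetic study

No scanner data ship with the package.  Instead, `simulation_config()` /
`generate_group()` produce a multi-subject, multi-session 4D study with
known ground truth.  The default conditions are 20 subjects x 2 sessions,
$N = 128$ time points at $TR = 2$ s (a four-minute run; Nyquist 0.25 Hz)
on a 16 x 16 x 10 grid of 3 mm voxels holding three nested tissue
compartments (CSF core, WM shell, GM rind).  A brain voxel time course is

$$y_v(t) = g_v\,\bigl[B + a_v s_v(t) + w_\tau P_v d_s(t)
  + P_{jv} S_s u_{js}(t) + \kappa_{j\tau} Q_v p_{js}(t)
  + m\,E_v r_s(t) + \varepsilon_v(t)\bigr]$$

with $g_v$ a smooth multiplicative bias field, $B$ a constant baseline,
$s_v$ voxelwise band-limited GM fluctuations with a group-stable
amplitude map $a_v$, $d_s$ a subject-level polynomial scanner drift with
per-tissue weight $w_\tau$ (CSF weighted 5x: pulsatile partial-volume
drift), $u_{js}$ shared slow GM fluctuations (0.004–0.04 Hz, 1/f), $p_{js}$
shared narrowband physiological components (respiratory at
$0.07 \pm 0.01$ Hz, aliased cardiac at $0.19 \pm 0.01$ Hz) with
per-tissue, vessel-profile-modulated coupling, $r_s$ a motion signal
derived from mean-reverting head-position wander (the *measured*
realignment parameters add estimation noise on top of the true motion),
and white thermal noise $\varepsilon$.  $P_v,\,Q_v$ are smooth spatial
profiles and $E_v$ an edge-weighted profile; a common lognormal
"drift severity" $S_s$ scales a subject's polynomial and slow drift
together.

Several of these choices were forced by analysis of what a group $t$ on
*standardised* maps can see, and are worth recording:

* **Spectral magnitudes add nonlinearly.**  $\lvert Z_{sig}+Z_{nui}\rvert$
  grows linearly with the nuisance only where the nuisance *dominates its
  bins*; a weak broadband contaminant is suppressed quadratically.
  Physiological components are therefore narrowband and strong rather
  than broadband and weak.
* **Standardisation cancels spatially flat effects.**  Dividing each map
  by its in-brain mean removes any contamination that scales all voxels
  alike; only spatially structured contamination (the profiles
  $P_v, Q_v, E_v$, tissue weights) survives into the group statistics.
* **Surrogate immunity requires time-locked structure.**  Phase-randomised
  surrogates preserve amplitude spectra, so they remove spectrally
  concentrated subspaces almost as well as the real regressors; only
  genuinely time-locked shared components (physio, motion) produce real
  effects that surrogates cannot mimic.  With the defaults the mean
  absolute surrogate-induced $t$ change is about a tenth of the real one.
* **Head position mean-reverts.**  A random-walk motion model is mostly
  trend; because the tissue and RP blocks are orthogonalised against the
  polynomials, that trend would be left for the detrending block to claim,
  inflating every detrending effect.  An AR(1) wander (coefficient 0.97)
  removes the artefact.

## What the default study reproduces

On the default group the pipeline comparison reproduces, qualitatively,
the canonical direction-of-effect pattern for this analysis family:

* full nuisance regression (Detr+WM+CSF+RP) clearly **raises** the
  GM-mean ALFF $t$ relative to no regression;
* adding polynomial detrending on top of WM+CSF+RP **raises** the
  hfALFF $t$;
* the same addition leaves the fALFF $t$ essentially unchanged to
  slightly **lowered**;
* full regression **reduces** GM-mean test–retest variance across
  sessions;
* phase-randomised surrogate regression changes $t$ values by an order
  of magnitude less than real regression.

The fALFF point deserves honesty.  The mechanism is real and
measurable in the simulation: a drift's sub-0.01 Hz mass co-varies with
its in-band leakage inside fALFF's denominator, partially cancelling —
in a controlled run with a strong pure-linear drift, removing it
benefits hfALFF roughly 3.5x more than fALFF.  But in a stationary
additive Gaussian model the net fALFF effect of detrending is bounded
near zero from above: removal of *any* subject-varying component weakly
dominates the injection cost.  The default conditions therefore sit
where the measured fALFF detrending effect is tiny (about $-1\%$ at the
default seed) and its sign is not stable across realisations — which is
also what the field's empirical reports suggest at well-behaved sites,
where the effect ranges from a few percent negative to indistinguishable
from zero.  The package's tests assert the pattern at the default
configuration and the accompanying analysis makes the fragility
explicit rather than hiding it.

## Numerical conventions

* DC is excluded from every numerator and denominator: it encodes the
  baseline, not fluctuation, and keeping it would break the
  multiplicative-gain invariance that makes fALFF "intrinsically
  bias-field corrected".
* Band edges are closed ($0.01 \le f \le 0.1$); for even $N$ the Nyquist
  bin enters once; magnitudes are unnormalised one-sided moduli without
  doubling (any fixed convention cancels in the ratios and only rescales
  ALFF before standardisation).
* Plain FFT, no window, no padding.  Spectra agree with a
  direct-summation DFT to $10^{-9}$ relative.
* Least squares uses QR; the explicit normal equations are kept only as
  a test oracle.  The Fourier-domain formulation
  $\hat{Y} = (I - X(X^{H}X)^{-1}X^{H})\,Y$ with the unitary DFT matrix
  reproduces time-domain residuals to $10^{-8}$ and is exposed as
  `regress_fourier()` — nuisance regression is a linear transform of the
  Fourier components in which frequencies mix.
* Phase randomisation draws one Hermitian-symmetric phase vector per
  repetition, shared by all regressors (DC and the even-$N$ Nyquist bin
  stay real), so surrogates are exactly real, preserve each amplitude
  spectrum, and preserve all inter-regressor correlations.
* Exploratory detrending reduces the pooled non-GM voxels to
  $d = \lceil 0.05\,N \rceil$ principal components, runs a CCA between
  the reduced series and its lag-one shift, ranks variates by empirical
  lag-one autocorrelation, and returns the top four, never
  orthogonalised against (nor orthogonalising) the other blocks.  The
  "5%" is interpreted as 5% of the number of time points.
* Standardisation divides by the in-brain mean (exactly 1 afterwards);
  smoothing is a separable Gaussian, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
  per axis in voxel units, with reflecting boundaries, applied after
  standardisation.
* Maps use unbiased ($n-1$) variances; zero-SD voxels yield missing
  values, never infinite $t$; the provided Bonferroni threshold is plain
  Bonferroni over in-mask voxels, not a random-field-theory family-wise
  error bound.
* Tissue masks from probability maps use threshold 0.9 and one
  6-connected erosion by default; the synthetic generator's binary masks
  are used at threshold 0.5 without erosion (the default grid's WM shell
  is one voxel thin along z).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_subjects = 6, n_sessions = 2,
                         grid_dims = c(10, 10, 10), rng_seed = 7)
res <- run_experiment(cfg, measures = c("alff", "falff"))
subset(res$summary, pipeline %in% c("none", "wm+csf+rp", "detr+wm+csf+rp"))
res$marginal
```

`run_experiment()` executes all sixteen pipelines over every subject and
session, reusing each data set's regressor blocks, and returns (and
optionally writes as TSV/NIfTI) the per-pipeline GM-mean $t$, its percent
change against the no-regression pipeline, test–retest variances, the
marginal-effect table (for each block, the mean change over the eight
pipeline pairs differing only in that block), and, on request, the
surrogate control for every pipeline.

## Problem sizes

The default study (20 x 2 data sets of 16 x 16 x 10 x 128 values, 16
pipelines x 3 measures, 25 surrogate repetitions for each of the 15
non-empty pipelines) completes in a few minutes on one core; the unit
test suite uses smaller grids (8–12 voxels per axis, 16–256 time points)
chosen so every oracle comparison still exercises non-trivial cases
(odd-length spectra, eroded masks, rank-deficient designs).

## Known limitations

* The generator is stationary and Gaussian; real drifts are neither, and
  effects that depend on non-stationarity (e.g. stronger detrending
  penalties) will be underestimated.
* Tissue geometry is nested boxes, not anatomy; partial-volume mixing
  between compartments is absent, so tissue-regressor specificity is
  optimistic.
* The exploratory-detrending variant estimates trends from WM/CSF only;
  GM-specific slow fluctuations are invisible to it by construction.
* Session effects are limited to realisation noise, drift-coefficient
  jitter and physiological amplitude jitter; no hardware upgrades,
  repositioning or registration error across sessions.
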