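# lffpipe

Low-frequency fluctuation analysis for resting-state fMRI, with the full
nuisance-regression machinery needed to study how preprocessing choices
change its group statistics.

## What it is for

Resting-state BOLD analyses summarise spontaneous brain activity by the
amplitude of low-frequency fluctuations of each voxel's time course.
With one-sided DFT magnitudes *a<sub>i</sub>* at frequencies
*f<sub>i</sub>*:

- **ALFF** = Σ *a<sub>i</sub>* over 0.01 ≤ *f<sub>i</sub>* ≤ 0.1 Hz;
- **fALFF** = ALFF / Σ *a<sub>i</sub>* over all 0 < *f<sub>i</sub>* ≤ Nyquist;
- **hfALFF** = ALFF / Σ *a<sub>i</sub>* over 0.01 Hz ≤ *f<sub>i</sub>* ≤ Nyquist
  (very slow frequencies excluded from the normalisation).

These measures are sensitive to scanner drift, physiology and head
motion, so they are normally preceded by nuisance regression.  `lffpipe`
implements the evaluation framework for deciding *which* regressors
help:

- the four nuisance blocks — polynomial trends (constant/linear/quadratic),
  six WM and six CSF regressors (tissue mean + five principal
  components), and the six realignment parameters — with QR
  orthogonalisation of every non-detrending block against the trends;
- all 2⁴ = 16 block combinations (`enumerate_pipelines()`), executed per
  subject by `apply_pipeline()` / `run_experiment()`;
- least squares in the time domain and, equivalently, on the Fourier
  coefficients (`regress_fourier()`), which makes explicit that nuisance
  regression mixes frequency components;
- phase-randomised surrogate regressors (amplitude spectra and
  inter-regressor correlations preserved exactly) as a control for
  "more regressors help by chance";
- exploratory detrending: lag-one CCA on PCA-reduced non-GM time
  courses, trends ranked by autocorrelation;
- voxelwise ALFF/fALFF/hfALFF maps with subject-wise standardisation and
  Gaussian smoothing, bias-field application/removal, group one-sample
  and paired *t* maps, percent change against the no-regression
  pipeline, GM-masked summaries, and test–retest variance across
  sessions;
- a synthetic multi-subject BOLD generator (`simulation_config()`,
  `generate_group()`) with ground truth — band-limited GM signal,
  tissue-weighted polynomial drift, shared slow fluctuations, narrowband
  respiratory/cardiac components, motion coupling, bias fields — so the
  whole pipeline is testable without scanner data;
- NIfTI-1/TSV/JSON input and output for real data
  (`compute_fluctuation_map()` accepts any 4D array plus masks and a
  6-column realignment TSV).

## Worked example

```r
library(lffpipe)
cfg <- simulation_config(n_subjects = 6, n_sessions = 2,
                         grid_dims = c(10, 10, 10), rng_seed = 7)
res <- run_experiment(cfg, measures = c("alff", "falff"))
subset(res$summary, pipeline %in% c("none", "wm+csf+rp", "detr+wm+csf+rp"))
```

```
       pipeline measure gm_mean_t pct_change_vs_none retest_var_pct_change
           none    alff     38.99              0.000                  0.00
           none   falff     95.16              0.000                  0.00
      wm+csf+rp    alff     39.41              7.537                 19.69
      wm+csf+rp   falff    141.44             65.302                -27.41
 detr+wm+csf+rp    alff     40.13              9.217                 12.70
 detr+wm+csf+rp   falff    150.87             76.423                -28.39
```

`gm_mean_t` is the grey-matter mean of the voxelwise one-sample *t*
across subjects — a consistency measure: removing nuisance variance
raises it.  Here tissue + motion regression raises the fALFF *t* by 65%
over no regression, adding polynomial detrending brings ALFF to +9.2%,
and full regression reduces fALFF test–retest variance across the two
sessions by 28%.  `res$marginal` additionally reports, for each block,
the mean *t* change over the eight pipeline pairs that differ only in
that block.

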