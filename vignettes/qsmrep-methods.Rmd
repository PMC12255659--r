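---
title: "Measuring test-retest repeatability of quantitative susceptibility maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring test-retest repeatability of quantitative susceptibility maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(qsmrep)
```

## The problem

Quantitative susceptibility mapping (QSM) reconstructs tissue magnetic
susceptibility ($\chi$, in ppm) from MRI phase. Before a susceptibility
value can be used as a biomarker, one must know how well it is reproduced
when the same subject is scanned again: the test-retest repeatability.
`qsmrep` implements the full statistical battery for a repeated-measures
QSM study — several scans per subject across sessions, several subjects,
possibly several reconstruction methods — together with a physics-based
simulator so that every statistic can be validated against known ground
truth.

Susceptibility is a *signed* quantity with tissue means close to zero,
which breaks some standard repeatability metrics (the coefficient of
variation in particular) and motivates a structural-similarity variant
(XSIM) tuned for signed data. The package treats these pitfalls
explicitly: unstable CVs are flagged rather than silently reported, and
XSIM uses a small covariance stabiliser suited to data centred on zero.

## The variance model

All ROI-level statistics operate on the long table of per-ROI mean
susceptibilities $\chi_{s,r}$ for subject $s$ and repetition $r$. The
implied hierarchical model is

$$\chi_{s,r} = \mu + b_s + w_{s,r}, \qquad
  b_s \sim N(0, \sigma_b^2), \quad w_{s,r} \sim N(0, \sigma_w^2),$$

with three nested scales of variation:

* $\sigma_r$ — **within-region** SD: voxel-scale heterogeneity inside an
  ROI of a single map (population divisor $N_v$);
* $\sigma_w$ — **within-subject** SD: variation of the ROI mean across a
  subject's repetitions (population divisor $N_r$ per subject, pooled
  across subjects by root-mean-square);
* $\sigma_b$ — **between-subject** SD: variation of subject-level means
  across subjects (population divisor $N_s$).

In real neck data the ordering is typically
$\sigma_r > \sigma_b > \sigma_w$, and the simulator reproduces it by
construction.

Derived quantities:

* $CV = \sigma_w / \bar{\chi}_r$, flagged unstable when
  $|\bar{\chi}_r| < 2\sigma_w/\sqrt{N_r}$, because division by a mean near
  zero is meaningless for signed data (|CV| > 1 occurs in practice);
* $RC = 1.96\sqrt{2\sigma_w^2}$, the smallest difference between two
  repeated measurements detectable at 95% confidence, also the minimum
  detectable effect size;
* $ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$, the one-way
  random-effects intraclass correlation. The estimate comes from the
  one-way ANOVA mean squares: $\hat{\sigma}_b^2 = (MSB - MSW)/N_r$ and
  $ICC(1,1) = (MSB - MSW)/(MSB + (N_r - 1) MSW)$. The one-way model is the
  right choice when repetitions are exchangeable acquisitions with no
  systematic order effect.

Two conventions deserve a note. First, the *descriptive* statistics
$\sigma_r, \sigma_w, \sigma_b$ use population ($1/N$) divisors, so the
pooled $\sigma_w$ carries a finite-sample factor $\sqrt{(N_r-1)/N_r}$
relative to the generating SD; the *inferential* path (`icc_oneway()`)
uses standard unbiased mean squares, and $\sqrt{MSW}$ is the estimator
that recovers a simulated $\sigma_w$ without bias. Both are reported.
Second, a raw $ICC(1,1)$ can be negative in finite samples; the
population quantity is a variance ratio, so the clamped-to-$[0,1]$ value
is used for classification while the raw value is kept alongside.

ICC classification follows the widely used reliability bands: poor below
0.5, moderate in $[0.5, 0.75)$, good in $[0.75, 0.9)$, excellent at 0.9
and above. The lower edge of each band is inclusive; the literature the
thresholds come from does not fix the boundary convention, and a
half-open band is the least surprising reading.

## Confidence intervals

The 95% interval on the ICC is a subject-level percentile bootstrap:
subjects are resampled with replacement, each keeping its full repetition
vector, the ICC is recomputed per resample (1000 by default), and the
2.5/97.5 percentiles are taken. Resamples that draw a single unique
subject carry no between-subject information and are redrawn (the count
is returned). The percentile interval was chosen because it is the
simplest method consistent with "bootstrap with 1000 repetitions"; a
known limitation is that, with only 10 subjects and a downward-biased,
left-skewed ICC estimator, the percentile interval under-covers — the
package's own acceptance checks measure coverage around 82–86% for a
true ICC of 0.8 rather than the nominal 95%. Users who need calibrated
intervals at small $N_s$ should treat the bootstrap CI as descriptive.
For the SD interval plots, analytic $\chi^2$ intervals are the default
and a bootstrap is available, since the reporting convention cannot be
pinned down from the literature.

## Repeated-measures ANOVA across methods

`rm_anova()` tests for a reconstruction-method effect on within-subject
data: $F = MS_{cond} / MS_{cond \times subj}$ with
$(k-1, (k-1)(n-1))$ degrees of freedom. Sphericity (equal variances of
all pairwise condition differences) is checked with Mauchly's $W$,
computed from the eigenvalues of the covariance of orthonormal condition
contrasts with the standard $\chi^2$ approximation plus its second-order
series term. When sphericity is rejected, the conservative *lower-bound*
correction $\varepsilon = 1/(k-1)$ multiplies both degrees of freedom.
The corrected p-value is floored at the uncorrected one: for $F < 1$,
shrinking the degrees of freedom can otherwise *lower* the p-value, and a
correction meant to be conservative should never strengthen the
evidence. Greenhouse–Geisser and Huynh–Feldt estimates are deliberately
not implemented — the lower bound is the correction this battery
standardises on.

Method comparisons are made on subject-level means (repetitions averaged
first): using all repetitions as independent observations would
pseudo-replicate, shrinking p-values by roughly $\sqrt{N_r}$. A
`replicates = "stack"` mode exists for sensitivity analyses. Pairwise
method differences (reported in ppb) use paired two-sided t-tests,
uncorrected for multiplicity by default — per-pair significance is the
reporting convention in this field — with Bonferroni available by flag.
The significance flag marks pairs that are *not* significant, matching
the highlight convention of published method-comparison tables.

## Voxel-wise metrics

NRMSE between two co-registered maps is
$\lVert test - ref \rVert_2 / \lVert ref \rVert_2$ over the mask, using
the chronologically earlier scan as the reference (NRMSE is asymmetric;
the pairing convention is documented and configurable). XSIM is a
Gaussian-windowed structural-similarity index with stabilisers
$C_1 = (k_1 L)^2$, $C_2 = (k_2 L)^2$; the defaults $k_1 = 0.01$,
$k_2 = 0.001$, $L = 1$ ppm, window $\sigma = 1.5$ voxels (truncated at
$\pm 3\sigma$) use a much smaller $C_2$ than photographic SSIM because
signed susceptibility values cluster near zero and a large stabiliser
would wash out covariance structure. All four constants are exposed in
the configuration. At mask borders, window weights are renormalised over
in-mask voxels (windows are *clipped to the mask*), so voxels outside an
ROI never leak into its score. Which repetition pairs enter the summary
is not standardised in the literature; all $\binom{N_r}{2}$ unordered
pairs are used by default, and a subset can be supplied.

## The synthetic cohort

The simulator is first-class, tested code, not a fixture. A
`phantom_spec()` places non-overlapping ellipsoidal ROIs on a uniform
background; the default phantom has six neck-like ROIs with means from
-0.1 to +0.3 ppm (muscle- and artery-like diamagnetic, fat- and
vein-like paramagnetic, two weakly paramagnetic glands/cartilage), so
the overall mean is near zero as in tissue. No anatomical fidelity is
claimed. `sample_cohort()` draws, per ROI: one offset per subject
($\sigma_b$), one offset per repetition ($\sigma_w$), and iid voxel
noise per repetition; voxel-scale texture is drawn *once per subject*
and reused across that subject's repetitions, which keeps
$\sigma_r > \sigma_w$ — anatomy does not change between scans,
measurement noise does.

Defaults are the study design this battery targets: 10 subjects, 2
sessions, 3 scans per session ($N_r = 6$), $\sigma_b = 10$ ppb,
$\sigma_w = 5$ ppb (true ICC 0.8), voxel noise 5 ppb, texture SDs
20–50 ppb. The multi-echo branch uses a four-echo 3 T protocol (TEs
4.61/9.22/13.83/18.44 ms, 1.25 mm isotropic). Offsets are additive at
the ROI level — the minimal model consistent with analysing ROI means;
no claim is made about voxel-level covariance of real repetition error.

`simulate_roi_table()` draws the same hierarchical model directly at the
table level, skipping volume rendering. Calibration studies that need
hundreds of cohorts (parameter recovery, bootstrap coverage, ANOVA
type-I rates) run at table level; the volumetric path is exercised on
small grids (10–16 voxels per side in the tests, 32 by default, 64 in
the physics checks). These sizes are chosen so the full validation suite
runs in well under a minute while each ROI still contains hundreds of
voxels.

What the generator does **not** emulate: streaking artefacts,
background-field residuals, registration error, coil combination, fat
chemical shift, motion — i.e. the structured, spatially correlated error
sources of real acquisitions. Passing recovery tests therefore
demonstrates that the *statistics* are computed correctly, not that any
real scanner achieves these repeatability numbers.

## Dipole physics

The susceptibility-to-field step is the k-space unit dipole
$D(k) = 1/3 - (k \cdot \hat{b})^2/|k|^2$ with $D(0) = 0$ (the mean
susceptibility shifts no field), applied by FFT with circular boundary
conditions; a `pad = TRUE` flag doubles the grid to suppress wrap-around
when fields near the volume edge matter. Two closed-form inversions are
provided to emulate "different reconstruction methods": truncated
k-space division (TKD, kernel values below $\delta$ replaced by
$\mathrm{sign}(D)\,\delta$) and Tikhonov regularisation
($\hat{\chi}_k = D F_k/(D^2 + \lambda)$). Both set the unrecoverable DC
term to zero, so reconstructed maps are compared after demeaning. These
single-step operators are stand-ins for the iterative and learned
inversions used on real data — they are enough to give two methods with
genuinely different regularisation bias, which is all the
method-comparison machinery needs. A noiseless TKD round trip does *not*
approach zero error as $\delta \to 0$: the phantom keeps a measurable
fraction of its spectral energy near the zero cone of $D$, where the
inversion is blind; the error floor (~0.38 NRMSE for the smooth default
phantom at $64^3$) is the ill-posedness of the problem, not a numerical
artefact.

The multi-echo branch converts the field to Hz via the proton
gyromagnetic ratio, builds complex signal per echo with constant
per-tissue magnitude and complex Gaussian noise at the stated SNR, and
fits the field back by weighted linear least squares on temporally
unwrapped phase. Spatial unwrapping is out of scope, so susceptibility
amplitudes must keep inter-echo phase increments below half a cycle; a
violation triggers a warning naming the maximal offending frequency.
The linear fit replaces a nonlinear complex fit deliberately: at the
simulated SNRs the two coincide, and the linear path is exactly
invertible, which gives the round-trip test a machine-precision target.

## Degenerate inputs and numerical choices

* Zero-variance cohorts: NRMSE 0, XSIM 1, ICC 1 with interval [1, 1];
  no NaNs.
* Exactly zero ROI mean: CV reported `NA` with the unstable flag, not an
  exception.
* Zero interaction variance in RM-ANOVA: flagged degenerate; F and p
  reported at their limits (0/1 or Inf/0).
* Singular contrast covariance in Mauchly's test (identical conditions):
  $W = 0$, $p = 0$, flagged — judged against the variance scale of the
  data, not of the contrasts.
* Sum-of-squares identities hold to $10^{-9}$ relative tolerance and are
  asserted in the tests.
* All simulation entry points take explicit integer seeds; identical
  spec + seed reproduces cohorts, bootstrap intervals and pipeline output
  files byte-for-byte (NIfTI included). Units are ppm everywhere inside
  the package; human-facing difference tables convert to ppb.

## A worked run

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 7, grid_shape = c(32, 32, 32))
qsm_simulate(cfg, "cohort")           # 60 NIfTI maps + labels + manifest
analysis <- qsm_analyze("cohort", "analysis")
comparison <- qsm_compare(analysis, "compare")
analysis$records                      # per ROI x method repeatability
comparison$pairwise$vein$diff_ppb     # method-difference matrix, ppb
```

The same three stages are scriptable from a shell through
`inst/cli/qsmrep.R` (`simulate`, `analyze`, `compare`, each taking
`--config`, `--seed`, `--out`, `--log-level`). The statistics modules
also accept a plain CSV of ROI means (columns `subject`, `repetition`,
`method`, `roi`, `chi_ppm`), so real study tables can be analysed
without the simulator.
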