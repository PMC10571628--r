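---
title: "Interstitial free water: model, estimation and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interstitial free water: model, estimation and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifwtools)
```

## The signal model

The package treats each diffusion-weighted voxel as a two-compartment
mixture: an anisotropic tissue compartment described by a symmetric
positive-semidefinite tensor $D$ (mm$^2$/s), and an isotropic free-water
compartment with fixed diffusivity $d_{free}$,

$$ S_i = S_0 \left[ (1-f)\, e^{-b_i\, g_i^\top D\, g_i} + f\, e^{-b_i d_{free}} \right], $$

where $b_i$ and $g_i$ are the b-value and unit gradient direction of
volume $i$ and $f$ is the free-water *signal* fraction. $d_{free}$ defaults
to $3.0\times10^{-3}$ mm$^2$/s, the diffusivity of free water at body
temperature, and is deliberately fixed: letting it float makes the model
unidentifiable against the tissue tensor at these b-values.

The default acquisition, `paper_scheme()`, is a 44-volume multi-shell
protocol (5 volumes at $b=0$ and 3/6/30 directions at $b = 200/500/1000$
s/mm$^2$, TE = 109 ms, 2 mm isotropic voxels). Shells above 1000 s/mm$^2$
are excluded by `select_shells()` because non-Gaussian (kurtosis) effects
there violate the mono-exponential compartment model. Direction sets are
generated once by electrostatic-repulsion minimization over antipodal
pairs; the procedure is deterministic, so the scheme is reproducible
bit-for-bit.

## Fitting

`fit_voxel()` minimizes the Gaussian least-squares cost over
$(f, S_0, L)$ with $D = LL^\top$ (Cholesky factor, guaranteeing positive
semidefiniteness), $f$ box-constrained to $[0,1]$ and $S_0 > 0$, using
Levenberg-Marquardt. Initialization is deterministic, so repeated fits are
bit-identical:

* $S_0$: mean $b=0$ signal;
* $f$: the two-point estimate comparing the mean attenuation of the
  highest shell against an assumed tissue diffusivity
  (`lambda_init`, default $0.7\times10^{-3}$ mm$^2$/s);
* $D$: weighted linear least squares on the log of the
  free-water-corrected attenuations.

Numerical choices worth knowing:

* Signals $\le 0$ are floored at $10^{-6} \times S_0$ before fitting; the
  number of floored entries is recorded per voxel.
* After fitting, tensor eigenvalues are clamped to $[0, d_{free}]$;
  diffusivities above free water are physically meaningless here.
* When the tissue compartment is itself free-water-like (a pure CSF
  voxel), the model has a degenerate ridge: any mixture of a
  $d_{free}$-isotropic "tissue" and the free-water term fits equally
  well. The tie is broken toward $f = 1$ — a pure free-water fit is
  attempted, and if it matches the optimized cost the voxel is reported
  as $f = 1$ with a `degenerate` flag rather than an arbitrary interior
  point.
* All-zero or non-finite signals yield a missing-coded voxel
  (`converged = FALSE`, `f_fw = NA`), never a silent zero.

No spatial regularization is applied. With four b-values the voxelwise
problem is well conditioned, and regularization would couple voxels and
obscure the per-voxel validation against ground truth.

## T2 compensation

The fit measures a signal fraction. Because CSF-like free water has a far
longer T2 than cortical tissue, the free-water compartment contributes
disproportionately to the signal at TE = 109 ms, so the signal fraction
overestimates the volume fraction. Under compartmental mono-exponential
weighting with $w_x = e^{-TE/T2_x}$,

$$ f_{app} = \frac{f\, w_{free}}{f\, w_{free} + (1-f)\, w_{tissue}}, $$

which `t2_correct()` inverts in closed form:
$f = f_{app} k / (1 - f_{app} + f_{app} k)$ with
$k = w_{tissue}/w_{free}$. The inversion fixes 0 and 1, is strictly
increasing, and reduces the fraction whenever $T2_{free} > T2_{tissue}$ —
the direction of the bias it is designed to remove. Defaults are
$T2_{tissue} = 90$ ms and $T2_{free} = 2000$ ms, typical 3T values for
cortical gray matter and CSF; both are plain arguments, and every
command-line run logs the constants it used. A single fixed tissue T2 is
an approximation — voxelwise relaxometry would require a multi-echo
acquisition that this data does not include — and the plasma contribution
to the free-water signal is assumed negligible.

## From free water to interstitial free water

`compute_ifw()` subtracts the CSF fractional-volume map voxelwise and
projects negatives to zero:

$$ iFW = \min(\max(FW_{corrected} - CSFv,\ 0),\ 1). $$

The upper clip at 1 only enforces the fraction contract; it can bind only
on invalid inputs. The CSFv map is an *input*: it must already live on the
diffusion grid (affines equal within $10^{-3}$), and the package refuses
to resample — registration quality is an upstream responsibility that
silent interpolation would hide. Fraction maps read from disk may carry
float noise; values within $10^{-2}$ outside $[0,1]$ are clipped with a
warning, anything further is an error.

## ROI aggregation

`roi_mean()` is an arithmetic mean over the voxels of one of eight
cortical lobes (OFC, LPFC, MPFC, LTC, MTC, SMC, PC, OCC), with
missing-coded voxels excluded from numerator and count, and empty lobes
missing-coded rather than zero-filled. The packaged parcel-to-lobe table
groups bilateral Desikan-Killiany `aparc+aseg` labels into the eight
lobes. It is a plausible reconstruction of such a grouping — published
lobe compositions vary, and the exact grouping used by any given study
should be supplied as an edited TSV. All labeled voxels contribute,
regardless of their CSFv: the CSF contribution has already been removed
voxelwise, and further exclusion rules would make ROI means depend on an
arbitrary threshold.

## Synthetic data: what it does and does not emulate

`simulate_voxel()` extends the fitting model with a third compartment and
per-compartment T2 weighting:

$$ S_i = S_0 \left[ w_t (1 - f_{int} - f_{csf})\, e^{-b g^\top D g}
      + w_f (f_{int} + f_{csf})\, e^{-b d_{free}} \right]. $$

Interstitial water and CSF share $d_{free}$ and $T2_{free}$ — they are the
same physical fluid in different places — so the fitter can only see their
sum, and the pipeline's job is to split it using the CSFv map. By
construction the ground-truth iFW equals $f_{int}$, which is what makes
end-to-end identifiability testable: on a noiseless grid of
$f_{int}, f_{csf} \in \{0, \dots, 0.5\}$ the full pipeline recovers
$f_{int}$ to better than $10^{-2}$.

Noise is Rician (the magnitude-MRI standard): independent Gaussian noise
of standard deviation $\sigma = S_{b=0}/\mathrm{SNR}$ on the real and
imaginary channels, then the magnitude. A Gaussian option exists for
debugging. Realizations are seeded and reproducible, and the generators
restore the caller's RNG state.

What the phantom does **not** emulate: cortical geometry and
partial-volume mixing across voxel faces, motion and eddy artifacts,
spatially varying $S_0$ or coil profiles, and exchange between
compartments. Passing phantom tests therefore validates the estimator and
its algebra, not robustness to acquisition artifacts.

`simulate_cohort()` generates the longitudinal ROI tables: three groups
(HC/CHR-NP/CHR-P, default 96/127/33 subjects — converters are the small
group, as in realistic high-risk cohorts), a common timepoint schedule
(default 0/1/2 years, approximating baseline plus yearly follow-ups),
subject-level Gaussian random intercepts, group-specific baseline offsets
and annual slopes, and Gaussian residuals. The default measure scale
emulates cortical iFW: baseline mean 0.15, CHR baseline offset +0.01,
slopes 0 / 0.001 / 0.005 per year for HC / CHR-NP / CHR-P, residual sd
0.02 and random-intercept sd 0.03 — values chosen once to put group
effects at the edge of detectability at these sample sizes, which is the
regime where the statistics are worth testing. Ages are uniform on 12-35
years (the inclusion window of such cohorts), sex is Bernoulli(0.5), ICV
log-normal around $1.5\times10^6$ mm$^3$; covariate effects default to
zero so the null design is exactly null.

## Longitudinal statistics

`fit_lme()` fits, by REML via `lme4`,

```
value ~ group * timepoint_years + age + sex + icv + (1 | subject_id)
```

with treatment contrasts referenced to HC. Because time is measured from
baseline, the `group` main effect is the baseline difference and the
`group:time` interaction is the difference in rates of change. Omnibus
tests are Type-III F with Satterthwaite denominator degrees of freedom
(`lmerTest`); the denominator-df method is an approximation, and no claim
is made of matching any particular software's df to the digit. Numeric
covariates are z-scored internally (ICV is of order $10^6$), which leaves
the group and time tests unchanged while conditioning the model matrix.
Rows with missing model variables are dropped with a message; singular
random-effect fits are flagged in the result.

Post hoc contrasts (`posthoc_pairwise()`) are Tukey-adjusted pairwise
differences of estimated marginal means *at time 0* (group effect) or of
marginal slopes (interaction), via `emmeans` with Satterthwaite df,
reported as CHR-NP − HC, CHR-P − HC and CHR-P − CHR-NP.
`longitudinal_analysis()` assembles the per-lobe table, adjusts each
effect family across the eight lobes by Benjamini-Hochberg FDR (the
conventional reading of "FDR correction"), and computes post hocs for
lobes whose FDR-adjusted omnibus test is significant.

Rates of change for correlation analyses are per-subject OLS slopes
(subjects with $\ge 2$ distinct timepoints). Spearman correlations use
tie-corrected ranks with a two-sided large-sample p-value; two independent
correlations are compared by Fisher's z,
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

## Validation design and problem sizes

Every stage is tested against an oracle that is independent of the code
path it checks: the fitter against an exhaustive grid search over $f$
(step $10^{-3}$) with a per-$f$ linearized tensor fit; the T2 inversion
against the forward weighting (round trip exact to $10^{-12}$); the BH
adjustment against a hand evaluation of the step-up definition; slopes
against closed-form OLS; Fisher's z against the formula. Statistical
calibration is checked by simulation: 200 null cohorts at 30/40/10
subjects and two timepoints give interaction p-values consistent with
uniformity (Kolmogorov-Smirnov), 500 smaller null cohorts bound the
empirical size at $1.5\times$ nominal, and 200 replicates at the full
96/127/33 design give essentially complete power for a slope difference
of 1.5 residual-sd per year. These sizes keep the whole suite around a
minute of compute while leaving the Monte-Carlo error well below the
margins being tested.

## Known limitations

* **Per-voxel dispersion at realistic SNR.** At Rician SNR 30 on the
  44-volume scheme, the free-water fraction estimate at $f = 0.3$ has
  negligible bias (≈ 0.01 after T2 handling) but a standard deviation of
  about 0.08. This is intrinsic to the estimation problem — the exhaustive
  grid-search oracle shows the same dispersion, and it grows with tissue
  mean diffusivity as the tissue compartment approaches $d_{free}$ — not
  an optimizer artifact. Per-voxel iFW should therefore be read through
  ROI averages, which is how the measure is designed to be used.
* Gaussian least squares on Rician magnitudes slightly biases very
  low-SNR (high-b, high-f) voxels upward; a Rician likelihood is out of
  scope.
* The T2 compensation uses one fixed tissue T2 for all voxels.
* The parcel-to-lobe lookup is a reconstruction; studies should supply
  their own.
* The cohort simulator draws covariates independently of group, so it
  cannot probe confounding between covariates and group membership.
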