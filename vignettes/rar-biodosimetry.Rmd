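---
title: "Quantifying the radio-adaptive response from biomarker calibration curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the radio-adaptive response from biomarker calibration curves}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rardose)
```

## The problem and the model

A radio-adaptive response (RAR) is the reduced biological effect of a large
"challenge" radiation dose in an organism previously given a small acute
"priming" dose. The study design rardose supports is a seven-group rat
experiment with thermal neutrons: an unexposed control, three acute groups
(5, 10 and 50 mSv), a challenge-only control (50 mSv), and two combined
groups given a priming dose (5 or 10 mSv) fourteen days before the 50 mSv
challenge. Eleven blood and liver biomarkers are read per animal:
antioxidant enzymes (GSH, CAT, SOD), lipid peroxidation (MDA), free-radical
EPR intensity, comet-assay DNA-damage metrics (TM, DNA-in-tail percentage,
TL, OTM), hemoglobin and red-cell distribution width.

The analysis is inverse dosimetry. The four acute groups (0, 5, 10, 50 mSv)
define a per-marker *calibration curve* — a dose-response function
$g$ fitted to the four (dose, group-mean) points. Reading a combined
group's mean through the inverted curve gives its **RAR equivalent dose**,

$$D_{RAR} = g^{-1}(N_{p+c}),$$

the single acute dose that would have produced the same reading. Adaptation
is then quantified by the dimensionless **RAR factor**

$$f_{RAR} = 1 - \frac{D_{RAR} - D_p}{D_{p+c}},$$

where $D_p$ is the priming dose and $D_{p+c} = D_p + D_c$ the accumulated
dose (55 or 60 mSv here). When the combined group reads like the priming
dose alone, $f_{RAR} = 1$ (full adaptation); larger $D_{RAR}$ means weaker
adaptation. The package also computes the classical Yonezawa-scheme
difference fraction $\delta = 1 - N_{p+c}/N_c$ against the challenge-only
group, which needs no calibration curve but carries no dose units.

Two modelling points deserve emphasis:

* **The accumulated dose is the arithmetic sum** $D_p + D_c$. This is the
  only reading under which the reference per-marker doses and factors are
  mutually consistent (e.g. $D_{RAR} = 40.9$ mSv at 10+50 gives
  $1 - 30.9/60 = 0.485 \to 0.49$).
* **Neither $f_{RAR}$ nor $\delta$ is clamped.** The formula can leave
  $[0, 1]$ on noisy or inconsistent inputs; rardose reports the raw value
  with an `in_unit_interval` flag. Clamping would destroy invertibility and
  hide data problems. Note that the two anchor interpretations are not
  perfectly symmetric: a completely unadapted animal
  ($D_{RAR} = D_{p+c}$) yields $f_{RAR} = D_p/D_{p+c}$, not 0; the formula
  is implemented verbatim and the anchors are not reinterpreted.

## Calibration families and fit diagnostics

Three families cover the eleven markers (family per marker is
configuration, defaulting to the reference assignments in
`default_marker_families()`):

| family       | model                         | markers (default)          |
|--------------|-------------------------------|----------------------------|
| linear       | $y = ax + b$                  | SOD, EPR, DNA, Hb, RDW     |
| exponential  | $y = A e^{R_0 x} + y_0$       | GSH, CAT, TM, OTM, MCV, CA |
| quadratic    | $y = c_0 + B_1 x + B_2 x^2$   | MDA, TL                    |

Linear and quadratic fits are ordinary least squares (`stats::lm`). The
exponential fit is Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with convergence declared at a relative
residual-sum-of-squares change below $10^{-10}$ within 500 iterations.
Initialization is deterministic and derivative-free: place $y_0$ one
percent of the response range beyond the plateau-side extreme (below the
minimum for decays, above the maximum for rise-to-plateau curves), then
read $R_0$ and $A$ off a log-linear regression of
$\log|y - y_0|$ on dose. Because a shallow curve whose range is comparable
to the replicate noise can leave that start on a singular gradient, the
fitter also tries a small fixed grid of fallback starts (four $y_0$
placements crossed with the log-linear slope and two rate scales, all
deterministic functions of the data) and keeps the convergent fit with the
lowest residual sum of squares.

The fit diagnostics follow a deliberately mixed convention, because only
this combination reproduces the reference diagnostic pattern:

* linear fits report the *signed* Pearson correlation between dose and
  response (so decreasing markers like SOD and Hb carry negative R), with
  the two-sided correlation-t probability
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom
  (`correlation_pvalue(-0.994, 4)` prints 0.006);
* exponential fits report the non-negative correlation between observed
  and fitted responses and a categorical convergence status (no numeric p
  is defined for the nonlinear fit);
* quadratic fits report the observed-vs-fitted correlation and the overall
  regression F-test probability.

Fits use the unweighted group means of the four acute groups, not
per-animal readings: the analysis calibrates four group points per marker,
and a `weight` column on `dose_points()` is available where per-animal
precision differs.

## Inversion: branch selection and guard rails

Inversion is analytic per family. The two non-trivial cases:

* **Exponential**: $x = \log((y - y_0)/A)/R_0$, defined only when
  $(y - y_0)/A > 0$, i.e. the reading lies on the curve's side of its
  asymptote. Readings beyond the asymptote raise a domain error — they are
  unreachable at any dose.
* **Quadratic**: both roots of $B_2 x^2 + B_1 x + (c_0 - y) = 0$ are
  computed. If the vertex $-B_1/(2B_2)$ falls inside the fitted dose
  domain the model is flagged non-monotone and only the *data-bearing
  branch* — the lower-dose side of the vertex, where the doses live — is
  invertible; the off-branch root is reported in `branch_note`. With the
  default constants this matters for MDA (vertex near 39.6 mSv) and TL
  (near 49.6 mSv). When both roots are on the branch, the one inside the
  dose domain wins, ties broken toward the smaller dose. Branch selection
  is tested against a brute-force grid search of
  $\arg\min_x |g(x) - y|$ at 1 mGy resolution.

Extrapolation beyond the fitted domain is permitted up to twice the upper
dose bound, flagged via `in_domain = FALSE`; beyond that cap the inversion
raises rather than extrapolating silently. The cap is generous by design —
the reference analysis never needed more than 40.9 mSv against a 50 mSv
domain — and exists to keep synthetic or corrupted inputs from producing
absurd doses quietly. Negative inverted doses are returned unclamped with
a `negative-dose` note.

One marker's failure does not void the panel: `run_rar_pipeline()` records
a calibration or inversion failure as an `NA` row annotated with the error
message, and the across-marker aggregates are computed over the markers
that succeeded (the aggregate rows record how many that is).

## The synthetic study generator

`generate_study()` produces the full seven-group, eleven-marker study with
known ground truth. Its defaults *are* the reference conditions and are
not tuning knobs:

* generating curves: the published per-marker constants
  (`reference_models()`), dose domain 0–50 mSv;
* 5 animals per group; replicate noise multiplicative Gaussian with
  coefficient of variation 0.05, truncated at zero by rejection — the
  reference error bars are SDs of five replicates whose magnitude roughly
  tracks the mean, and a constant CV is the simplest faithful model of
  that (the true per-marker CVs are not recoverable from published
  figures, so this is configuration, not a claim);
* adaptation: each combined group's mean sits on its generating curve at
  the *effective dose* $D_p + (1 - f^\*) D_{p+c}$ implied by a true factor
  $f^\*$, defaulting to the published per-marker factors. The pipeline's
  recovered factor therefore has an exact target; combined groups use the
  same CV as acute groups (nothing distinguishes them);
* the challenge-only group sits at the challenge dose.

A combined group's effective dose must lie on the data-bearing branch of a
non-monotone quadratic curve; configurations that push it to or past the
vertex are rejected. Acute groups may sit at or past the vertex — the
default TL and MDA curves themselves do at 50 mSv — because their means
enter fitting, not inversion.

What the generator deliberately does **not** emulate: biological kinetics
(repair dynamics, the 14-day interval and 24-hour readout are carried as
design metadata, not modelled), inter-animal correlation, assay-specific
error structure (counting error in EPR, comet-scoring variation), or
fluctuating markers with no dose response (HCT, MCHC pass through
summaries and significance testing but get no calibration). Recovery tests
on synthetic data therefore validate the *estimation machinery*, not the
biology: passing them shows the pipeline inverts what it fits and is
unbiased under the stated noise model, nothing more.

## Numerical and reporting choices

* Group summaries use the sample SD (n − 1 denominator) everywhere; this
  also reproduces the reference across-marker SDs (7.5 mSv at 10+50,
  where an n-denominator would give 7.1).
* Significance against the unexposed control uses the two-sided Welch
  unequal-variance t-test, a robust default for five-animal groups; no
  multiple-testing correction is applied (a documented limitation, kept
  for comparability). In the noiseless limit where both cells are
  constant, the p-value is defined as 1 for equal means and 0 otherwise.
* Rounding happens only at the reporting layer, half away from zero (so
  0.485 prints 0.49), with a $10^{-9}$-scale tolerance absorbing binary
  representation error; computations keep full precision.
* The pipeline is a pure function of (readings, design, configuration,
  seed); identical CLI runs are byte-identical.

## The reference-table reproduction check

`reproduce_reference_table()` feeds the published per-marker RAR
equivalent doses back through the factor formula. Twenty-one of the
twenty-two published cells reproduce at two decimals. The EPR cell at
5+50 mSv does not: its printed dose (19.4 mSv) implies a factor of 0.74,
not the printed 0.92, while a dose of 9.4 mSv would reproduce both the
printed factor and the printed 5+50 average of 10.1 ± 3.4 mSv — a
suspected transcription slip. The package flags the inconsistency and
reports both values; it never silently corrects a published number.

```{r reproduce}
reproduce_reference_table()
```

## Validation problem sizes

The test suite validates each stage at sizes chosen to make the checks
sharp yet quick to run: noiseless four-point designs for exact constant
recovery and forward–invert round trips (tolerance $10^{-6}$ mSv);
40–50-replicate noise studies for standard-error calibration of the
fitters; 500 replicate studies (one marker per family, true factors 0.5,
0.78, 0.91 and 1.0, CV 0.05, n = 5) for end-to-end recovery, requiring the
median recovered factor within ±0.03 of truth; and 2000 null replicates
for the Welch test's type-I error at the 0.05 threshold (±0.02).

## Known limitations

* No uncertainty interval accompanies $D_{RAR}$ or $f_{RAR}$; the
  inversion consumes a group mean. Bootstrap propagation over the
  per-animal option of `invert_dose()` is the natural extension point.
* A marker whose dynamic range is comparable to its replicate noise (CAT:
  a 6% total change over 0–50 mSv) is weakly identified; at the default
  noise level its calibration or inversion fails in a substantial fraction
  of synthetic studies and is flagged rather than estimated. This mirrors
  a real design constraint of shallow biomarkers, not a numerical defect.
* The marker-to-family map is configuration; no model selection is
  performed.
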