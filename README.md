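# rardose

Inverse biodosimetry of the radio-adaptive response (RAR) from biomarker
dose-response calibration curves.

When an animal receives a small acute "priming" dose of radiation before a
larger "challenge" dose, its biomarkers often respond as if it had absorbed
far less than the accumulated total — a radio-adaptive response. rardose
quantifies that effect for a panel of blood and liver biomarkers (antioxidant
enzymes GSH/CAT/SOD, lipid-peroxidation MDA, EPR free-radical intensity,
comet-assay DNA-damage metrics, hemoglobin, red-cell distribution width)
measured in a seven-group rat study of acute thermal-neutron exposure. It is
aimed at radiation-biology and biodosimetry researchers who need the full
chain from per-animal readings to an adaptation report, with a synthetic-data
generator providing ground truth for validation.

## The method

For each marker, a calibration curve `g` (linear `y = ax + b`, exponential
`y = A·exp(R₀x) + y₀`, or quadratic `y = c₀ + B₁x + B₂x²`) is fitted to the
four acute-exposure group means at 0, 5, 10 and 50 mSv. The mean reading
`N_{p+c}` of a primed-plus-challenged group is pushed back through the
inverted curve to get the **RAR equivalent dose**

    D_RAR = g⁻¹(N_{p+c}),

the single acute dose that would produce the same reading. Adaptation is the
dimensionless **RAR factor**

    f_RAR = 1 − (D_RAR − D_p) / D_{p+c},

with `D_p` the priming dose and `D_{p+c} = D_p + D_c` the accumulated dose;
`f_RAR = 1` means the combined group reads like the priming dose alone. The
Yonezawa-scheme difference fraction `δ = 1 − N_{p+c}/N_c` against the
challenge-only group is computed alongside. Values are reported raw (flagged,
never clamped to [0, 1]).

## Worked example

Simulate a study under the reference conditions (7 groups × 11 markers × 5
rats, replicate noise CV 0.05, adaptation strengths at the published
per-marker factors) and analyse it:

```r
library(rardose)
cfg <- synthetic_config(seed = 42)
st  <- generate_study(cfg)
an  <- run_rar_pipeline(st$readings, cfg$design)
print(an$table)
```

```
RAR equivalent dose (RARED, mSv) and RAR factor (RARF) per marker

(5 + 50 mSv)
  marker  RARED   RARF
  GSH      10.8   0.89
  CAT        NA     NA *
  SOD      14.6   0.83
  MDA       6.4   0.97 *
  EPR      18.6   0.75
  TM       10.2   0.91
  DNA       9.5   0.92
  TL       11.8   0.88
  OTM      12.9   0.86
  Hb       23.3   0.67
  RDW      15.9   0.80
  mean     13.4   0.85
  sd        4.9   0.09
...
* CAT (5+50): Inversion failed for marker CAT at 5+50 mSv: Reading 0.0942835 is beyond the exponential asymptote y0 = 0.092154.
  MDA (5+50): alternative root 70.3415 rejected as off-branch
```

Each marker row is an estimated equivalent dose in mSv and its adaptation
factor; the `mean`/`sd` rows are the across-marker aggregates (sample SD).
The annotations are the package surfacing real features of the problem: the
CAT curve's total change over 0–50 mSv (~6%) is comparable to the replicate
noise, so at this noise level its inversion can be unidentifiable and is
flagged rather than guessed; the MDA curve is quadratic with an interior
vertex, so the off-branch root of its inversion is reported. With noiseless
data (`synthetic_config(cv = 0, ...)`) the pipeline recovers every
generating constant and every true adaptation factor to better than 1e-6.

Checking the published summary table against its own factor formula:

```r
reproduce_reference_table()
```

```
Recomputed RARF from published RARED: 21/22 cells match at 2 decimals
  MISMATCH EPR (5+50 mSv): published 0.92, formula gives 0.74 from RARED 19.4 mSv
  (5+50 mSv) mean RARED 11.0 +/- 4.4 mSv; mean RARF 0.89 +/- 0.08
  (10+50 mSv) mean RARED 23.1 +/- 7.5 mSv; mean RARF 0.78 +/- 0.12
```

The flagged EPR cell is a documented internal inconsistency of the published
table (a dose of 9.4 mSv would reproduce both its printed factor and the
printed 5+50 average of 10.1 ± 3.4); rardose reports it, never corrects it.

A command-line shell covers the same pipeline
(`exec/rardose simulate|calibrate|invert|rar|report|reproduce-table7`); runs
with the same seed are byte-identical.

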