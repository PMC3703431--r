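# lesion4d

Currents-based 4D shape regression for ischemic stroke lesion evolution.

Acute stroke imaging yields a handful of snapshots: lesion outlines on
diffusion-weighted MRI (DWI, conventionally read as the infarct core) and
on the perfusion mean-transit-time map (MTT, read as tissue at risk) at a
few timepoints days apart, plus a final T2 lesion a month or more later.
`lesion4d` turns those snapshots into a continuous, smooth, invertible
4D evolution of the lesion surface, imputed to 3-hour intervals, and then
quantifies what the snapshots alone cannot show: where and how fast the
lesion surface contracts and expands, how DWI dynamics relate to the
corresponding MTT areas, and *when* the evolving lesion best matches the
final T2 damage. It is aimed at researchers modelling stroke lesion
dynamics from longitudinal MR segmentations, and at methodologists who
want a tested, self-contained reference implementation of currents-based
longitudinal surface regression.

## The model

A triangulated lesion surface is represented as a **current**: face
barycenters `x_p` carrying area-weighted normals `n_p`, compared through a
Gaussian reproducing-kernel inner product

    <A,B>_W = sum_{p,q} exp(-|x_p^A - x_q^B|^2 / lambda_W^2) (n_p^A . n_q^B)

so no point correspondence is ever needed. The lesion evolves under a
diffeomorphic flow `dchi_t/dt = v_t(chi_t)` whose velocity is a kernel sum
over momenta attached to the baseline face centers,
`v_t(x) = sum_k K_V(x_k(t), x) alpha_k(t)`. The momenta are estimated per
inter-observation interval by gradient descent on

    J = gamma * kinetic_energy(v)  +  || current(chi_{t_i}(S_0)) - current(S_i) ||_W^2

(piecewise-geodesic regression; `gamma = 1e-4`, `lambda_V` = 30% of the
lesion bounding box, `lambda_W` = 5 or 35 mm, time step 3 h). On top of
the fitted scenarios the package computes signed contraction/expansion
speeds (cm/3h), extracts highly dynamic areas by mean ± SD thresholds,
maps them between timepoints and modalities through the fitted
correspondence deformation `phi: DWI(t1) -> MTT(t1)`, and evaluates the
Dice index and symmetric surface distance against the final T2 surface at
every time step:

    dice(t) = 2 |V(S(t)) & V(S_T2)| / (|V(S(t))| + |V(S_T2)|)

with the best-match times `t_dice = argmax dice(t)`,
`t_dsym = argmin d_sym(t)`.

Because no patient MRI accompanies the method, the package ships a
first-class synthetic-lesion generator (`generate_patient()`,
`generate_cohort()`) that reproduces the study conditions — nested
DWI/MTT lesions with > 3 cm³ mismatch, acquisitions near 5 h / 5 d /
10.5 d, lobe-wise anisotropic growth and shrinkage, a T2 surface crossed
at a known time — with exact ground truth for every downstream quantity.

## Worked example

```r
library(lesion4d)

patient <- generate_patient(seed = 7, subdivisions = 1)
patient
#> <synthetic_patient> seed 7: DWI r0 20.0 mm, MTT r0 28.0 mm, mismatch 51.0 cm^3
#>   times 5 / 143 / 239 h, T2 crossed at 191 h (momenta dynamics)

report <- run_patient(patient, regression_config())
report
#> <patient_report>
#>   fit dice: DWI t2 0.998, DWI t3 0.996, MTT t2 0.993, MTT t3 0.994
#>   phi dice: 1.000
#>   T2 concordance: DWI t_dice 191 h (max 0.997), MTT t_dice 5 h (max 0.567)

head(report$kinetics$curves_dwi, 3)
#>   time_hours mean_speed_contracting mean_speed_expanding
#> 1          8           -0.007664701           0.01210858
#> 2         11           -0.007698110           0.01202771
#> 3         14           -0.007731940           0.01194759
```

Reading the output: the fitted evolution scenarios reproduce the observed
surfaces at the second and third timepoints with Dice ≈ 0.99 per modality
(the fit-quality evaluation); the correspondence deformation maps the DWI
baseline onto the MTT baseline with Dice 1.000; the evolving DWI surface
matches the final T2 surface best at 191 h — exactly the generator's
ground-truth crossing time — while the MTT scenario, which recedes from
the T2 shape, matches best at its first timepoint. The kinetics table
gives the mean signed speed (cm/3h, negative = inward) of the highly
contracting and highly expanding DWI areas at each 3-hour step.

`run_patient(..., outdir = "out")` additionally writes the speed and
concordance curves as CSV, a summary JSON, fitted momenta as tabular
arrays with a JSON header, and the labelled baseline mesh as PLY with
per-face scalars. `run_cohort()` repeats the analysis over a cohort and
collects a summary table. Surfaces and masks move through standard
formats: NIfTI for masks (`read_mask()`, `z_subsample()`,
`mask_to_surface()`), ASCII PLY/legacy VTK for meshes (`read_surface()`,
`write_surface()`). A thin command-line front end lives at
`inst/cli/lesion4d.R` (`simulate` and `run` subcommands).

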