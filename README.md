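# alpsdti

Diffusion-tensor MRI analysis of glymphatic function: the perivascular
diffusivity index ("analysis along the perivascular space"), global DTI
parameters, weighted structural-connectome graph measures, and the
accompanying cohort statistics — implemented as a tested, reusable R
pipeline that runs end to end on synthetic diffusion phantoms and
synthetic cohorts.

## Who this is for

Researchers who want a transparent, scriptable implementation of the
perivascular diffusivity index and its surrounding study pipeline —
tensor fitting, deterministic tractography, connectome graph metrics,
Bonferroni-corrected group statistics — with every numerical convention
pinned down and testable without access to patient data.

## The statistic at the core

At the level of the lateral-ventricle body, perivascular spaces of the
deep medullary veins run along the left–right (x) axis, orthogonal to
both the projection fibers (head–foot, z) and association fibers
(anterior–posterior, y). For one selected voxel per fiber region, with
scanner-frame tensor elements D<sub>xx</sub>, D<sub>yy</sub>,
D<sub>zz</sub>:

```
index = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

Diffusivity along x that both fiber regions share — the numerator excess
over the fiber-transverse denominator — is attributed to perivascular
water mobility. Isotropic tissue gives exactly 1. Voxels are selected by
the modal dominant fiber orientation within rectangular ROIs that share
one axial band (see the methods vignette for every convention and
tie-break).

## Worked example

Build the default periventricular phantom (ground-truth index 1.5),
simulate a 32-direction b = 1000 s/mm² acquisition at snr 50, fit
tensors, and measure the index:

```r
library(alpsdti)

ph  <- default_phantom(g = 0.2)          # truth: (0.4 + 0.2) / 0.4 = 1.5
dwi <- simulate_dwi(ph$tensor_field, default_scheme(),
                    S0 = 100, snr = 50, seed = 42)
tf  <- fit_tensor(dwi)
res <- alps_pipeline(tf, ph$roi_spec)
res
#> <alps_bilateral> mean index = 1.4811 over 2 hemisphere(s)
tidy(res)[, c("laterality", "dxx_proj", "dxx_assoc",
              "dyy_proj", "dzz_assoc", "index")]
#> # A tibble: 2 × 6
#>   laterality dxx_proj dxx_assoc dyy_proj dzz_assoc index
#>   <chr>         <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 left          0.584     0.601    0.390     0.418  1.47
#> 2 right         0.582     0.613    0.383     0.416  1.50
```

The four diffusivities (10⁻³ mm²/s) are the raw tensor elements at the
selected projection/association voxels; the bilateral index 1.481 sits
within the noise floor of the true 1.5 (noiseless recovery is exact to
1e-6). Global DTI parameters over an FA-threshold summary mask:

```r
maps <- scalar_maps(tf)
global_summary(maps, fa_mask(maps), provenance = "fa>0.2")
#> # A tibble: 1 × 6
#>      fa    md    ad    rd n_voxels mask
#>   <dbl> <dbl> <dbl> <dbl>    <int> <chr>
#> 1 0.623 0.799  1.46 0.467      144 fa>0.2
```

Generate a synthetic 109-patient / 88-control cohort with the default
imposed correlation structure and build the full statistics report:

```r
co  <- make_cohort(cohort_spec(), seed = 42)
rep <- build_report(co)
rep
#> <alps_stats_report> patients n = 109 , controls n = 88
#> DTI family threshold 0.012 | graph family threshold 0.005
#> 12 significant index correlation(s) at alpha = 0.05
dplyr::filter(rep$fig3_correlations, group == "patient",
              y %in% c("age", "md", "assortativity"))
#> # A tibble: 3 × 7
#>   x     y             group       n      r      p_value significant
#> 1 alps  age           patient   109 -0.202 0.0352       TRUE
#> 2 alps  md            patient   109 -0.498 0.0000000372 TRUE
#> 3 alps  assortativity patient   109  0.320 0.000698     TRUE
```

The report carries the Bonferroni families (α/4 for the four DTI
parameters, presented 0.012; α/9 for the nine graph measures, presented
0.005), per-group correlation tables against the index, and
`tidy()`/`glance()` methods. Tractography and connectome metrics follow
the same pattern (`track()`, `build_matrix()`, `graph_metrics()`), and a
command-line front end chains the stages
(`inst/exec/alpsdti simulate --dir out --seed 7`, then `fit`, `alps`,
`track`, `connect`, `graph`, `stats`).

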