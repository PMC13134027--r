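# osteomap

Deterministic, voxel-based compartmentalization and classification of
skull-involving meningiomas (osteomeningiomas) from binary masks in a common
atlas space.

## The problem

Meningiomas with an osseous (skull) component — whether by invasion,
hyperostosis, or metaplasia — are hard to classify reproducibly from imaging.
Given two already-normalized binary masks per case (a tumor mask and a skull
mask on one 1-mm isotropic reference grid), `osteomap` builds a mutually
exclusive compartment map and assigns a radiological subtype from exact voxel
counts, with no reader judgement in the loop:

- **osseous** compartment: the skull mask itself;
- **juxta-osseous / "dural"** compartment: the band of intracranial voxels
  within a fixed distance *t* (default 5 mm) of the inner table, computed by
  an exact anisotropic Euclidean distance transform — a radiological proximity
  layer, not anatomical dura;
- **intradural** compartment: the remaining intracranial cavity.

With `N_bone`, `N_dura`, `N_intra` the tumor voxel counts per compartment,
the subtype is a pure function of the counts:

| rule | subtype |
|---|---|
| `N_bone > 0, N_dura = 0, N_intra = 0` | POM |
| `N_bone > 0, N_dura > 0, N_intra = 0` | SOM-I |
| all three `> 0` and `N_bone >= N_intra` | SOM-IIA (ties go here) |
| all three `> 0` and `N_intra > N_bone` | SOM-IIB |

`N_bone = 0` (no osseous involvement) and the geometrically anomalous
`N_bone > 0, N_dura = 0, N_intra > 0` pattern are flagged, not forced into a
class. The package also provides the accompanying cohort machinery: thickness
sensitivity analysis (2/3/5 mm layers), voxelwise frequency maps, Dice/Jaccard
inter-rater agreement, and the statistical layer (odds ratios with Woolf
logit intervals, Fisher exact, Kruskal–Wallis, exploratory logistic
regression with separation diagnostics). Seeded phantom generators produce
skulls and lesions with *exact* known per-compartment composition, so the
whole pipeline is testable without patient data.

## Worked example

```r
library(osteomap)

# a 28 mm spherical-shell skull phantom on a 1-mm grid
grid  <- volume_grid(c(28, 28, 28))
skull <- make_skull(grid, shell_geometry(c(13.5, 13.5, 13.5),
                                         outer_r = 11, inner_r = 8.5))
cmap  <- compartment_map_from_skull(skull, layer_spec(thickness_mm = 5))
cmap
#> <compartment_map> 28 x 28 x 28; osseous 3104, juxta-osseous 2352, intradural 160 vox; layer 5 mm

# a lesion with exactly 50 osseous, 20 juxta-osseous, 80 intradural voxels
les <- make_lesion_by_counts(cmap, 50, 20, 80, seed = 7)
cnt <- count_compartment_voxels(les$mask, cmap)
cnt
#> <compartment_counts> bone 50, dura 20, intra 80, other 0 (total 150)
classify_osteomeningioma(cnt)
#> <subtype_call> SOM_IIB     # intradural (80) exceeds osseous (50)

# predefined univariable comparisons on the bundled reference cohort counts
print(univariable_or_table(), digits = 4)
#>        symptom  target  a  b  c   d     or ci_low ci_high
#> 1        edema SOM_IIB 49 19 16  84 13.539  6.379   28.74
#> 2      seizure SOM_IIB 15 53  6  94  4.434  1.623   12.11
#> 3          icp SOM_IIB 21 47  6  94  7.000  2.647   18.51
#> 4 exophthalmos   SOM_I 14 23 16 115  4.375  1.878   10.19
```

The odds ratios read: SOM-IIB tumors have 13.5-fold higher odds of
peritumoral brain edema than all other subtypes combined (95% CI 6.4–28.7),
and analogously for epileptic seizure, raised intracranial pressure, and
(for SOM-I) exophthalmos.

A shell entry point wrapping the same functions is installed at
`inst/exec/osteomap` (`classify`, `sensitivity`, `phantom`, `stats`,
`agreement` subcommands over a YAML run configuration).

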