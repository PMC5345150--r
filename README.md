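# MyoTensor

Structure-tensor and diffusion-tensor mapping of cardiac microstructure in R.

Cardiac diffusion tensor imaging (DTI) infers cardiomyocyte ("cell") and
sheetlet orientations from water diffusion, but the signal is shaped by many
confounds, so DTI orientation measurements need independent validation.
Micrometre-resolution X-ray phase-contrast volumes of the same fixed heart
provide that reference: local image-gradient orientation is summarised per
voxel by a **structure tensor (ST)** built from six 3D quadrature filters,

T = Σₖ ‖qₖ‖ (nₖ nₖᵀ − I/(m−1)),  m = 3,

where ‖qₖ‖ is the magnitude of the k-th complex (lognormal, 2-octave)
quadrature filter response and nₖ the six icosahedral filter directions.
After element-wise Gaussian smoothing and block averaging to the DTI
resolution, the ST eigenvector of least intensity variation (v₃,ST) tracks
the voxel-averaged cell long-axis, the counterpart of the DTI principal
eigenvector (v₁,DT). Helix (HA), transverse (TA) and sheet (SE/SA) angles
are mapped in local cardiac frames from Laplace (harmonic) transmural
coordinates, and agreement between modalities is quantified with
Bland–Altman statistics, AHA 17-segment transmural profiles, and
streamline tractography.

The package is aimed at researchers validating or exploring orientation
reconstructions: it contains the complete processing chain plus a fully
synthetic, parametric myocardial phantom so that every stage is testable
without any acquired data.

## What is included

- `phantomSpec()` / `buildPhantom()` — transmural slab of close-packed
  cuboidal cells in sheetlets three cells deep, linear −88°→+88° helix-angle
  ramp, per-voxel ground-truth orientation triads; `addPoissonNoise()` for
  photon-counting noise (SD = √Sᵢ).
- `simulateDwi()` / `fitDiffusionTensor()` — monoexponential tensor signal
  generation and nonlinear least-squares fitting (log-linear initialised),
  `meanADC()`, `segmentHeart()`, rigid long-axis alignment
  (`longAxisTransform()`, `applyRigid()`).
- `flatDarkCorrect()`, `paganinRetrieve()`, `fbpReconstruct()` —
  single-distance phase retrieval (δ/β = 1000, λ = 6.2×10⁻¹¹ m, z = 0.5 m
  defaults) and parallel-beam filtered back-projection.
- `designBank()`, `computeStructureTensor()`, `smoothTensors()`,
  `downsampleTensors()`, `eigenDecompose()`, `segmentVessels()` — the ST
  chain with the reference parameters (centre frequency π/(3√2), 11³
  kernel, 7³ Gaussian smoothing, 28³ downsampling) and vessel exclusion.
- `laplaceDepth()`, `localFrames()`, `computeAngles()`, `aha17Segment()`,
  `transmuralProfiles()`, `blandAltman()` — angle mapping and agreement.
- `trackStreamlines()`, `writeTrk()` — RK2 eigenvector streamlines with a
  30° angle threshold and 0.5 mm minimum length, TrackVis output.
- `runPhantomValidation()` — the end-to-end phantom experiment;
  `inst/scripts/validate-phantom.R` is a command-line wrapper.

## Worked example

```r
library(MyoTensor)

# ground-truth reference: dyadic voxel averaging of the noiseless phantom
vol <- buildPhantom(phantomSpec())
vol
#> LabelledVolume: 250 x 250 x 28 voxels at 3.60 um; 55.0% intracellular

ref <- voxelAverageReference(vol, 28 * voxelSize(vol), partial = TRUE)
round(apply(ref$angles@ha, 1, mean, na.rm = TRUE), 2)
#> [1] -77.50 -57.48 -38.51 -20.16   0.00  20.17  39.03  57.87  77.26

# full experiment: Poisson noise + structure tensors at the reference
# parameters, angles in the slab frame, agreement with the reference
res <- runPhantomValidation(validationConfig(noiseSeed = 1, sweep = NULL))
round(res$layerTable[c(1, 9), c("haSt", "haStSd", "taSt", "haRef")], 2)
#>   haSt haStSd  taSt  haRef
#> 1 -76.10   0.38 -0.16 -77.50
#> 9  75.96   0.32  0.09  77.26
res$agreement$ha
#> Bland-Altman agreement over 81 voxels: -0.07 deg +/- 5.58 (LoA -5.65 .. 5.51)
```

The first block prints the transmural profile of the voxel-averaged
ground-truth helix angle on the nominal 100 µm grid: −77.5° at the
epicardial face rising to +77.3° at the endocardial face. The second block
runs the measurement chain on the noisy phantom: the reconstructed helix
angle spans −76.1° to +76.0° with sub-degree spread per layer, transverse
angles stay near 0°, and the Bland–Altman comparison against the reference
shows no meaningful bias.

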