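# wmlseg

Simultaneous whole-brain and white-matter-lesion segmentation from
multi-contrast brain MRI with a contrast-adaptive generative model.

## The problem and the model

Automated segmentation of brain MRI in diseases such as multiple sclerosis
faces two coupled problems: white-matter lesions corrupt the intensity
statistics that healthy-brain segmenters rely on, and supervised lesion
segmenters generalize poorly across scanners and pulse sequences because
they bind image appearance to anatomy at training time.  `wmlseg`
implements a generative approach that decouples the two:

- **Anatomy prior.** A deformable probabilistic mesh atlas supplies, for
  every voxel *i* and anatomical label *k*, a prior
  `p(l_i = k | θ_l) = Σ_j α_jk ψ_ji(θ_l)`, where `α_jk` are label
  probabilities at the mesh vertices and `ψ_ji` are piecewise-linear
  (barycentric) interpolation weights that move with the vertex positions
  `θ_l`.  A topology-preserving deformation prior forbids the mesh from
  folding.  A lesion location prior `ρ_i(θ_l) = Σ_j β_j ψ_ji(θ_l)` deforms
  in concert with the anatomy.
- **Appearance model.** Voxel log-intensities are modeled per scan with one
  multivariate Gaussian per tissue class, `N(d_i | μ_k + C φ_i, Σ_k)`,
  where `C φ_i` is a smooth, per-contrast bias field expanded in cosine
  basis functions.  Because `{μ_k, Σ_k, C}` are re-estimated for each scan,
  the model adapts to any combination of pulse sequences (T1w, T2w, FLAIR,
  ...) without retraining.
- **Lesion intensity prior.** The lesion Gaussian `(μ_les, Σ_les)` is tied
  to the white-matter Gaussian by a normal-inverse-Wishart prior
  `N(μ_les | μ_WM, ν⁻¹Σ_les) · IW(Σ_les | κν Σ_WM, ν − N − 2)`, acting as
  `ν` pseudo-voxels with mean `μ_WM` and variance `κ Σ_WM`.  At `ν = 0`
  lesions form an independent intensity class; as `ν → ∞` the model becomes
  a robust outlier detector with `μ_les ≡ μ_WM` and `Σ_les ≡ κ Σ_WM`
  (defaults `ν = 500` per mm³, `κ = 50`).
- **Lesion shape prior.** A variational autoencoder over binary lesion
  masks supplies voxelwise shape factors `f_i(h) ∈ (0,1)` from a
  low-dimensional latent code `h`, so that
  `p(z_i = 1 | h, θ_l) = f_i(h) ρ_i(θ_l)`.

Fitting maximizes the joint posterior of all parameters by generalized-EM
coordinate ascent in a *simplified* model with all `f_i` clamped to 1.
The voxelwise lesion posterior `p(z_i = 1 | d_i, θ̂)` is then estimated by
a blocked Gibbs-style Monte-Carlo chain that alternately samples the shape
code through the encoder/decoder, the lesion Gaussian from its conjugate
conditional, and the lesion map from voxelwise Bernoulli posteriors.
Voxels not brighter than the gray-matter mean in FLAIR/T2-role channels
are excluded as candidates, the posterior is thresholded at a user-facing
`γ` (default 0.5), and remaining voxels take the anatomical label with the
highest posterior weight.

The package also ships a synthetic phantom generator (multi-contrast
brain-like slices with known anatomy, bias fields and WM lesions), an
atlas builder, evaluation metrics (Dice, precision/recall, volumes,
Pearson correlation, leave-one-out threshold tuning), NIfTI I/O and a
command-line interface.

## Worked example

```r
library(wmlseg)

spec  <- phantomSpec()                      # 64x64, T1w/T2w/FLAIR-like
atlas <- makeAtlasFromPhantoms(spec, seed = 3)
shape <- trainShapeModel(generateLesionMaskCorpus(100, spec, seed = 11),
                         spec@dim, epochs = 50, seed = 4)

ph  <- generatePhantom(phantomSpec(lesionRate = 3), seed = 8)
seg <- segmentBrain(ph$image, atlas, shape, fitConfig(seed = 5))
seg
#> SegmentationResult: 4096 labeled voxels; 87 lesion voxels
#>
#> background        csf         gm         wm        dgm     lesion
#>       1600        500        927        981          1         87
diceScore(seg@lesionMask, ph$lesionMask)
#> [1] 1
```

The phantom simulated 87 lesion voxels in white matter; the model
recovers all of them (Dice 1.0 on this easy, well-separated phantom) while
simultaneously labeling the remaining anatomy.  `seg@lesionPosterior`
holds the voxelwise Monte-Carlo lesion posterior and
`seg@fit@objectiveTrace` the (non-decreasing) log-posterior trace of the
generalized-EM fit.

The same pipeline is available from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("scripts/wmlseg-cli.R", package="wmlseg"))')
Rscript $cli make-phantom --seed 8 --out phantom/
Rscript $cli build-atlas  --seed 3 --out atlas/
Rscript $cli train-shape-model --seed 4 --out shape/
Rscript $cli segment --input phantom/t1w.nii.gz,phantom/t2w.nii.gz,phantom/flair.nii.gz \
                     --roles t1w,t2w,flair --atlas atlas/ --shape-model shape/ --out seg/
Rscript $cli evaluate --pred seg/lesion_mask.nii.gz --ref phantom/truth_lesions.nii.gz
```

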