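# quatfit

Batched superimposition of protein structure models onto a reference by
quaternion gradient descent.

## The problem

Molecular dynamics, docking and protein-design pipelines emit thousands to
millions of models of the same system. Downstream analysis — clustering,
per-residue deviation maps, pose ranking — needs every model superimposed
onto one reference: per model, the rigid motion minimizing the RMSD over
corresponding α-carbons. Correspondence is known (models share the
reference's residue numbering), so the task is superimposition, not
alignment.

Classical tools solve each model separately with a closed form (Kabsch SVD
of the cross-covariance, or the equivalent quaternion eigen-problem). At
scale this means one decomposition per model, and residue deletions break
uniform array layouts. `quatfit` instead optimizes one rotation quaternion
per structure for the **whole batch at once** with plain two-phase gradient
descent on the masked CA loss

$$\mathcal{L}_i = \frac{\sum_j m_{ij}\,\lVert R(q_i)(p_{ij}-c_i) - (r_j-c_\mathrm{ref})\rVert^2}{\sum_j m_{ij}},$$

where the binary mask $m_{ij}$ removes residues deleted in model $i$,
$c_i$ is the model's masked CA centroid and $c_\mathrm{ref}$ the reference
selection centroid. Every descent step is elementwise N×L array
arithmetic — no per-model covariance decomposition — and memory is bounded
by the batch size, not the collection size. Insertions relative to the
reference are ignored; deletions cost nothing. The learned transform
$p \mapsto R(q_i)(p - c_i) + c_\mathrm{ref}$ is applied to **all** atoms
and superimposed PDB files are written with non-coordinate columns
byte-identical to the input.

A closed-form Kabsch solver (`kabsch_superimpose()`) ships as the exact
oracle: the package's central invariant is per-structure agreement between
the gradient-descent RMSD and the Kabsch RMSD within 1e-3 Å across
selection sizes, noise levels and deletion fractions.

## Worked example

Synthesize a 60-residue reference, 50 rigidly moved copies with 0.5 Å
per-coordinate noise, and superimpose them:

```r
library(quatfit)

base <- make_backbone(60, seed = 1)
td <- tempfile(); dir.create(td)
write_pdb(base, file.path(td, "ref.pdb"))
pert <- perturb_structures(
  base, synth_spec(n_structures = 50, noise_sigma = 0.5, seed = 2))
for (i in seq_along(pert$structures))
  write_pdb(pert$structures[[i]], file.path(td, sprintf("m%02d.pdb", i)))

s <- run_superposition(
  list.files(td, pattern = "^m.*pdb$", full.names = TRUE),
  reference = file.path(td, "ref.pdb"),
  output_dir = file.path(td, "aligned"),
  seed = 0)
print(s)
#> <superposition_summary>
#>   written: 50, skipped: 0
#>   selection residues: 60
#>   RMSD: mean 0.8569 +/- 0.04464 (sd)

head(s$table[, 1:6], 3)
#>      name      rmsd         qw          qx         qy         qz
#> 1 m01.pdb 0.9658335  0.4153089  0.08359296  0.7362093 -0.5277561
#> 2 m02.pdb 0.8789133  0.1179725 -0.53765319  0.5902209  0.5904666
#> 3 m03.pdb 0.8593781 -0.1067615  0.86853461 -0.3133599  0.3688565
```

The mean RMSD ≈ 0.86 Å is what 0.5 Å per-coordinate noise implies
(σ√3, slightly reduced by the six rigid degrees of freedom the fit
absorbs); with noise-free copies it drops to the 1e-14 Å numerical floor.
Each structure agrees with the closed-form optimum:

```r
frame <- build_reference_frame(parse_pdb(file.path(td, "ref.pdb")))
b <- load_coords(list.files(td, pattern = "^m.*pdb$", full.names = TRUE),
                 frame)
cen <- center_batch(b)
kabsch_superimpose(cen$batch$coords[1, , ], frame$ref_coords,
                   b$mask[1, ])$rmsd
#> [1] 0.9658335
s$table$rmsd[1]
#> [1] 0.9658335
```

Superimposed models land in `aligned/` under their input basenames,
together with `superposition_summary.tsv` (one row per structure: name,
RMSD, quaternion, translation).

### Command line

```sh
inst/cli/quatfit align models/ --reference ref.pdb --output aligned \
    --selection "A:10-120" --batch-size 50000 --seed 0
inst/cli/quatfit synth --output fixtures --residues 100 --structures 1000
```

(After installation the launcher lives at
`system.file("cli", "quatfit", package = "quatfit")`.)

Key functions: `run_superposition()` (full pipeline),
`optimize_quaternions()` (in-memory batches), `kabsch_superimpose()`
(closed-form oracle), `make_backbone()` / `perturb_structures()` /
`write_fixture_set()` (synthetic fixtures with ground-truth manifests),
`quatfit_cli()` (shell interface). The methods vignette
(`vignettes/quaternion-superposition.Rmd`) documents the loss, the
two-phase schedule and its defaults, centering and masking conventions,
and known limitations.

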