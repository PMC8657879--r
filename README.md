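# foldcv

Residue folding degree and secondary-structure collective variables for
protein backbones.

`foldcv` is for structural bioinformaticians and molecular-dynamics
practitioners who want a cheap, bounded, per-residue measure of folded
content — and a collective variable (CV) built on it that tracks the
formation of secondary structure in trajectory segments, through to
potential-of-mean-force (PMF) surfaces and minimum-energy-path barriers.

## The quantity at the core

The backbone N, Cα, C atoms of an *N*-residue stretch form a path graph
whose third iterated line graph has one vertex per backbone dihedral, in
the order ψ₁, ω₁, φ₂, ψ₂, ω₂, φ₃, …, φ_N.  Its adjacency matrix **A** is
symmetric tridiagonal of size 3(N−1), with ones off the diagonal and
cos(dihedral) on the diagonal.  From the spectrum (λⱼ, vⱼ) of **A**, the
subgraph-centrality contributions and the residue folding degree are

    CS_i = Σⱼ v²ⱼᵢ e^λⱼ  =  [exp(A)]_ii ,
    RCS_k = CS(φ_k vertex) + CS(ψ_k vertex) ,

high (≈7) for helical/turn backbones and low (≈3) for extended ones.
Because exp(**A**) decays away from the diagonal, RCS_k is computed from a
small tridiagonal window around the (φ_k, ψ_k) vertices at linear cost
(`rcs_local()`, default 6×6 window, within ~0.2 % of the full
eigendecomposition; the classic 4×4 block is `window = 1`).

The *relative segment folding degree* turns this into a CV: for segment κ
with reference RCS_ref and tolerance RCS_tol, with
x = (RCS_k − RCS_ref)/RCS_tol,

    RCS_k,rel = (1 − x^m) / (1 − x^n)   (m = 2, n = 4  →  1/(1+x²)) ,
    SCS_κ,rel = mean over k ∈ κ of RCS_k,rel ∈ (0, 1] .

With the α-helix reference (RCS_ref = 7.273, RCS_tol = 0.421, the H
category's characteristic mean and s.d., see `ss_reference_stats()`) this
is a helical-content measure; with a reference structure's own values
(`make_reference()`) it measures similarity to any conformation.

## Worked example

Everything below is synthetic and deterministic — an ideal helix, then a
two-state (helix/strand) switching trajectory:

```r
library(foldcv)

ch <- build_backbone(ideal_helix_spec(12))
prof <- rcs_profile(ch)
head(prof, 4)
#>   chain resno resname      rcs
#> 1     A     1     ALA       NA
#> 2     A     2     ALA 7.443887
#> 3     A     3     ALA 7.443887
#> 4     A     4     ALA 7.443887

seg <- segment_definition("core", 2, 11)
scs_rel(prof, make_reference("helicality", seg))
#> [1] 0.8585457

traj <- two_state_cv_trajectory(2000,
  state_a = list(phi = -64.70, psi = -39.56, sd = 8),   # helical state
  state_b = list(phi = -110.89, psi = 122.38, sd = 8),  # extended state
  switch_prob = 0.1, n_res = 12, seed = 7)
pdb <- tempfile(fileext = ".pdb")
write_trajectory_pdb(traj, pdb)

ser <- cv_timeseries(pdb, make_reference("helicality", seg))
g <- build_pmf(ser$scs, bins = 5, kT = thermal_energy(300), range_x = c(0, 1))
g
#> <pmf_grid> 5 x 1 bins, 5 occupied, kT = 0.5962 kcal/mol, max F = 3.256
mep <- minimum_energy_path(g, c(1, 1), c(3, 1))
sprintf("barrier %.2f kcal/mol", mep$barrier)
#> [1] "barrier 2.16 kcal/mol"
```

The RCS of 7.44 sits in the helical band; the segment scores 0.86 against
the ideal-helix reference (geometric idealisation is not the statistical
H-category mean).  The trajectory's CV is bimodal — an extended basin near
SCS ≈ 0.1 and a helical basin near 0.5 under this noise level — and the
minimax path between the basins crosses a 2.16 kcal/mol barrier at 300 K
(kT = 0.596 kcal/mol).

Per-category reference scores of ideal motifs under the helical reference:

```r
ideal_motif_table()$scs_display
#> [1] 1.00 0.74 0.24 0.01 0.01 0.59 0.03 0.01 0.01   # H G I E B T S P C
```

See `vignette("folding-degree-cv")` for the model, parameter and design
discussion, including what the synthetic generators do and do not emulate.

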