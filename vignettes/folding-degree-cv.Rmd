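---
title: "Residue folding degree and secondary-structure collective variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue folding degree and secondary-structure collective variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcv)
```

## The model

Native protein backbones confine their dihedral angles $\psi$, $\omega$ and
$\varphi$ to narrow regions, so a scalar built from those angles can measure
how "folded" a residue is.  `foldcv` implements the *folding degree*, a
weighted subgraph centrality on the backbone dihedral graph.  The backbone
atoms N, C$\alpha$, C of an $N$-residue stretch form a path; its third
iterated line graph has one vertex per consecutive four-atom dihedral, in
the order $\psi_1, \omega_1, \varphi_2, \psi_2, \omega_2, \varphi_3, \dots,
\varphi_N$ — again a path, with $3(N-1)$ vertices.  Its adjacency matrix
$A$ is symmetric tridiagonal with ones off the diagonal and, in place of
the usual zeros, $\cos$ of each vertex's dihedral on the diagonal.  With the
spectrum $(\lambda_j, v_j)$ of $A$, the vertex centralities and the global
folding degree are

$$
CS_i = \sum_j v_{ji}^2\, e^{\lambda_j}
     = \big[e^{A}\big]_{ii},
\qquad
\langle CS \rangle = \frac{1}{3(N-1)} \sum_i CS_i ,
$$

and the *residue folding degree* of residue $k$ sums the centralities of
its $\varphi$ and $\psi$ vertices (positions $3(k-1)$ and $3(k-1)+1$,
1-based):

$$
RCS_k = CS_{3(k-1)} + CS_{3(k-1)+1}.
$$

$RCS$ is high (around 7) for helical and turn conformations and low
(around 3) for extended ones, and depends only on cosines, so it is even
in every angle and invariant under mirroring.

## Full versus local-window evaluation

`rcs_full()` diagonalises the whole $3(N-1)$ matrix.  Because the matrix
exponential of a tridiagonal matrix decays quickly away from the diagonal,
$RCS_k$ is dominated by the dihedrals near residue $k$, and a small window
around the $(\varphi_k, \psi_k)$ pair suffices.  `rcs_local()` therefore
solves one fixed-size tridiagonal eigenproblem per residue — linear cost in
chain length, against the superlinear cost of the full spectral problem.

Two window sizes matter in practice:

* `window = 1` is the classic sliding **4×4 block**
  $(\omega_{k-1}, \varphi_k, \psi_k, \omega_k)$ with
  $RCS_k = CS_2 + CS_3$ of the block.  In our measurements it deviates
  from the full calculation by about 1.5 % at ideal α-helical angles and
  by up to ≈3.5 % in the worst corners of a uniformly random dihedral
  ensemble (the worst cases sit at low-$RCS$ conformations, where the
  absolute error is small).
* `window = 2` (the package default) adds one more shell,
  $(\psi_{k-1}, \omega_{k-1}, \varphi_k, \psi_k, \omega_k, \varphi_{k+1})$,
  a 6×6 block.  Its maximum relative deviation over 100 random 50-residue
  configurations ($\varphi,\psi$ uniform, $\omega = 180^\circ \pm
  10^\circ$) is ≈0.16 %, comfortably below the one-percent level at which
  the approximation is usually quoted, while remaining linear in $N$.

We therefore default to `window = 2` everywhere a profile is computed; the
strict 4×4 block remains available both through `rcs_local(..., window =
1)` and as the vectorised primitive `rcs_block()`, which also generates the
theoretical Ramachandran-like surface `theoretical_surface()` (there only
$\varphi$, $\psi$ and a fixed $\omega$ exist, and the surface is evaluated
with the planar trans value $\omega = 180^\circ$ on a half-open
$[-180, 180)$ grid so the periodic boundary is not duplicated).

```{r}
# the two routes agree well inside a helix
helix <- internal_coords(rep(-64.70, 20), rep(-39.56, 20), rep(180, 20))
range(abs(rcs_local(helix)$rcs - rcs_full(helix)$rcs), na.rm = TRUE)
```

## From structures to profiles

`parse_structure()` reads (multi-model) PDB files through bio3d, keeping
`ATOM` records only, resolving alternate locations by highest occupancy
(ties toward altloc "A") and ordering residues by number and insertion
code.  `compute_dihedrals()` applies the IUPAC sign convention with angles
on $(-180, 180]$ and treats consecutive residues as bonded only when their
C–N distance is at most 2.5 Å — generously above the 1.33 Å peptide bond,
so only genuine gaps split a chain.  No dihedral is evaluated across a
break, hence $\varphi$ is undefined at the start of every contiguous
stretch, $\psi$/$\omega$ at its end, and $RCS$ at both termini.  These
conventions (break cutoff, altloc rule, hetero-residue exclusion) are our
choices; published surveys rarely state theirs.

## The collective variable

To compare a segment $\kappa$ (a consecutive residue range) against a
reference conformation, each residue's $RCS_k$ passes through a rational
switching function of the scaled deviation
$x = (RCS_k - RCS_{\mathrm{ref}})/RCS_{\mathrm{tol}}$:

$$
RCS_{k,\mathrm{rel}} = \frac{1 - x^m}{1 - x^n},
\qquad
SCS_{\kappa,\mathrm{rel}} = \frac{1}{|\kappa|}
  \sum_{k \in \kappa} RCS_{k,\mathrm{rel}} .
$$

With the default even exponents $m = 2 < n = 4$ the function simplifies
exactly to $1/(1+x^2)$ — bounded on $(0, 1]$, equal to 1 at the reference
and to $m/n = 0.5$ one tolerance away; we require even $m < n$ so the
function stays symmetric and bounded for any input.  The default reference
$RCS_{\mathrm{ref}} = 7.273$ and tolerance $RCS_{\mathrm{tol}} = 0.421$
are the characteristic mean and standard deviation of the α-helix (H)
category (`ss_reference_stats()`), which turns the CV into a measure of
helical content: an ideal H motif scores exactly 1.00, the neighbouring
helical categories G and I score 0.74 and 0.24, turns 0.59, and extended
categories essentially 0.

```{r}
ideal_motif_table()[, c("category", "rcs_mean", "scs_display")]
```

`make_reference()` generalises the reference choice: a shared segment mean
from a reference structure (`segment_mean`), the per-residue values of the
reference structure (`per_residue`, which scores exactly 1 on the
reference itself), or the characteristic value of each residue's
secondary-structure category (`category`).  For arbitrary references the
tolerance is a free parameter; we default to 1.0, which in our experience
gives free-energy surfaces with well-separated basins, and keep 0.421 only
for the helicality preset.  In category mode the category's own standard
deviation can be requested with `tol = "sd"`.  `cv_timeseries()` evaluates
segments frame by frame over a multi-model PDB with the block method;
frames in which a segment touches an undefined $RCS$ (chain break,
terminus) are flagged `NA` rather than silently averaged over fewer
residues.

## Free-energy surfaces and paths

`build_pmf()` histograms one or two CV series and converts the occupied
bins to $F = -kT \ln(p / p_{\max})$, so the global minimum is exactly 0;
empty bins are masked, never imputed, and paths may not cross them.
`thermal_energy()` uses the gas constant, $RT$, in kcal mol$^{-1}$ (300 K
→ 0.596).  Default binning is 50 per axis over the observed range — a
display choice, not an estimate.  `minimum_energy_path()` adopts the
minimax criterion on the 8-connected bin graph: among all unmasked paths
it minimises the maximum $F$ encountered, which is the natural barrier
definition on a discretised surface; ties prefer shorter, then
lexicographically earlier paths, and the reported barrier is the peak
above the starting basin.  This is a deliberate, simple substitute for
full node-flooding path analyses; profiles along the path are qualitative
comparators, not replacements for those tools.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage can be tested without
downloads:

* `build_backbone()` places N/C$\alpha$/C atoms sequentially (NeRF-style)
  from prescribed torsions with standard stereochemistry (N–CA 1.458 Å,
  CA–C 1.525 Å, C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA
  121.7°).  Recomputing dihedrals from the built coordinates reproduces
  the prescription to below $10^{-6}$ degrees, which makes the builder
  the round-trip oracle for all dihedral code.
* `random_dihedrals()` draws $\varphi, \psi$ uniformly on $(-180, 180]$
  with $\omega = 180^\circ \pm$ jitter (default 10°) — deliberately
  harsher than native backbones, to stress the local-window
  approximation over the whole torus.
* `two_state_cv_trajectory()` switches between two conformational states
  with a symmetric Markov chain (default switch probability 0.05 per
  frame) and adds wrapped Gaussian angle noise within each state.  It
  reproduces the *bimodal* CV statistics of a folder at equilibrium, but
  none of the kinetic correlation structure, anharmonicity, or
  side-chain physics of real MD — so passing tests demonstrate the
  correctness of the measurement chain, not force-field realism.

All generators are deterministic under a fixed seed.

## Numerical choices and edge cases

* Eigendecomposition (`eigen(symmetric = TRUE)`) is the primary route for
  centralities; the matrix-exponential diagonal serves as the independent
  test oracle (agreement to $10^{-8}$ on random tridiagonals up to
  30×30).
* Terminal residues never get an $RCS$; chains shorter than three
  residues yield all-`NA` profiles rather than errors.
* $\langle CS \rangle$ is reported only by the full method — the block
  method does not produce a consistent set of all vertex centralities.
* At $|x| = 1$ the switching function takes its continuous limit $m/n$;
  for $(2, 4)$ the simplified form $1/(1+x^2)$ has no singularity at all.
* Segment scores refuse partial means: an undefined residue inside a
  segment is an error (library) or a flagged `NA` (time series).
* Problem sizes in the shipped tests (100 random 50-residue
  configurations for the approximation bound, a few hundred frames and
  $2\times10^4$ samples for the free-energy checks) were chosen as the
  smallest ensembles at which the measured quantities stabilise.

## Known limitations

* Only PDB input is supported; mmCIF and structure repair are out of
  scope, as is secondary-structure *assignment* — `parse_labels()`
  consumes DSSP / DSSP 4 / STRIDE output files (or a plain TSV) but never
  re-derives labels from geometry.
* The characteristic category table ships as summary statistics; the
  underlying multi-thousand-structure survey is not reproduced by this
  package.
* The Trp-cage worked example (PDB id `1l2y`, segment means 7.450 for
  residues 2–9 and 3.262 for residues 16–19 of model 1) needs the
  experimental structure, which is not redistributable here.  Download
  `1l2y.pdb` from the PDB and place it under the package's
  `inst/extdata/` (or pass your local copy to `parse_structure()`) to run
  that check; everything else works on synthetic inputs.
* No gradients of the CV are provided, so it can *analyse* trajectories
  but not yet drive biased sampling.
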