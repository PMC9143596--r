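---
title: "Reverse screening of an enzyme sequence space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse screening of an enzyme sequence space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revscreen)
```

## The problem and the approach

Engineering a faster PET-hydrolysing enzyme (PETase, catalytic triad
S160/D206/H237) by brute-force mutagenesis is hopeless: even two sites
saturate to 400 variants, and eight sites scanned combinatorially give
255 libraries before a single saturation grid is built. The *reverse
screening* idea works backwards from cheap physics: dock a model
substrate (a tetrameric PET fragment) into every variant, read off a
binding score, and let the statistics of the resulting *sequence
space* — binding-energy change as a function of mutation count, site
and side-chain chemistry — nominate the few variants worth simulating
and, eventually, expressing.

`revscreen` implements the screening logic as a reusable, tested
pipeline. The physics engines are deliberately *inputs*: docking poses
and scores, MD trajectories, and vacuum/polar energy terms arrive as
files (or as synthetic stand-ins with planted ground truth), while the
package owns everything that turns them into decisions:

1. **Site nomination** — physicochemical conservation over a multiple
   sequence alignment of PET-hydrolases; candidate sites are loop
   residues lining the active site plus weakly conserved non-loop
   residues (score strictly below 6 on the 0–11 scale).
2. **Alanine scanning (ASM)** — each candidate substituted to alanine;
   the binding-score change ΔΔG = ΔG(variant) − ΔG(WT) is thresholded
   at mean − SD to nominate *sites*.
3. **Combinatorial ASM** — all subsets of the nominated sites
   (2⁸ − 1 = 255 for eight sites) establish how many simultaneous
   mutations are useful.
4. **Site saturation (SSM)** — 19 substitutions per site, and a full
   20 × 20 grid over a chosen site pair, summarized by side-chain
   class maps.
5. **Post-hoc validation** — trajectory RMSD/RMSF/distance series and
   MM/PBSA bookkeeping for the shortlisted variants.

## Conservation scoring

Alignment viewers shade conservation by the *set-based* method: each
amino acid either has or lacks each of ten binary physicochemical
properties (hydrophobic, polar, small, tiny, aliphatic, aromatic,
charged, positive, negative, proline). A column's score is the number
of properties whose membership status is uniform across all non-gap
residues; a fully identical column is graded 11 (the `*` rendering).
The exact table is exposed and editable:

```{r}
aa_property_table()[c("I", "L", "V", "D", "K", "E"), ]
```

`{I,L,V}` scores 9 (only *small* splits them), `{D,E}` scores 9,
`{D,K}` — opposite charges — drops to 6. The upstream aligner is not
run here; alignments are inputs (aligned FASTA or Clustal). Gap
handling: gaps are skipped; all-gap columns score 0 and are flagged,
as are columns with more than 50 % gaps (low confidence). Different
viewers differ by ±1 on mixed columns depending on their gap
conventions; fixing one published table makes the score deterministic
and testable, which we value over emulating any particular viewer.

Loop/non-loop region labels and the "lines the active site" flag are
*inputs* (read off the crystal structure), not computed — secondary
structure assignment is out of scope.

## The docking screen

Raw docking output is a set of poses (ligand heavy-atom coordinate
sets with engine scores; typically hundreds of independent runs per
variant). Three rules distil one ΔG per variant:

* **Leader clustering at 2.0 Å RMSD.** Poses are visited in ascending
  energy; each joins the first cluster whose representative is within
  tolerance, else founds a new cluster. Pose RMSD is computed *without*
  superposition — poses share the receptor frame, so rigid differences
  are real. Ties on energy break by pose id for determinism.
* **Geometric acceptance.** A cluster representative is accepted only
  if some ligand heavy atom lies strictly within 4.0 Å of the
  catalytic serine's side-chain oxygen (OG of S160) *and* every
  configured cleft subsite is contacted (≥ 1 ligand atom within 5.0 Å
  of a subsite atom). The subsite residue sets are configuration with
  documented defaults; "distance between substrate and the S160
  hydroxyl" is read as the *minimum* over ligand heavy atoms — the
  permissive interpretation, since the relevant chemistry needs any
  carbonyl carbon near the nucleophile.
* **Lowest accepted energy.** ΔG is the minimum representative energy
  among accepted clusters; if nothing passes, the variant is flagged
  with undefined ΔG and excluded (but counted) downstream.

Site nomination uses the sample standard deviation (n − 1): with 42
variants the difference from the population SD is ~1 %, and sample SD
is the default a statistician reaches for when the 42 ΔΔG values are
treated as draws from the screen's error distribution. Nomination is
strict (`ΔΔG < mean − SD`); a value exactly at the cutoff is not
selected. Both choices are exposed.

Docking engine parameters (search grid, genetic-algorithm budget, run
count) are carried as a provenance block in configs and reports, and
never executed.

## Sequence-space maps

Three summaries mirror the figures practitioners draw:

* **Mutation-count map** — per-r distribution (n, min, quartiles,
  mean) of ΔΔG.
* **Fixed-site map** — matrix (r, site) → aggregate over all size-r
  variants containing that site. Default aggregator **min**, because
  the screening question is "does *any* variant containing this site
  improve binding?".
* **Class maps** — SSM grids aggregated by side-chain class. Default
  aggregator **mean**, because class-level claims are about
  distributions, not champions. Both aggregators (plus median) are
  available everywhere.

The six-class partition (P1 small aliphatic G,A,V,L,I,P; P2 aromatic
F,Y,W; P3 polar uncharged S,T,N,Q,C,M; P4 positive K,R,H; P5 negative
D,E; P6 reserved) is shipped as editable data and echoed into every
map output. Published figure legends rarely pin down edge cases (is C
"special" or polar?), so transparency about the table used beats
guessing: swap in your own partition and the maps recompute.

## Trajectory analysis

Internal units are Å and ps; nm-based formats are converted on
ingestion. The superposition is a standard Kabsch fit: centroid
removal, SVD of the cross-covariance, determinant correction to
guarantee a proper rotation (det = +1), post-fit RMSD. Degenerate
(< 3 atoms, collinear) selections raise errors rather than returning
garbage.

* **RMSD series**: superpose each sampled frame's selection on the
  reference frame (frame 1 — the minimized start — by default), report
  RMSD on the same selection. Whether to use backbone or all heavy
  atoms is the caller's choice via the selection.
* **RMSF**: computed over a trailing window — "last half" by default,
  which for a 100-ns production run is the conventional converged last
  50 ns; absolute-time windows are supported when the frame spacing is
  known. Frames are superposed on the fit selection (α-carbons by
  default) of the window-mean structure in two passes; each residue's
  RMSF is the RMS excursion of its α-carbon (centroid fallback) about
  its window mean. For isotropic per-coordinate noise of SD σ the
  expectation is σ√3 — the closed form the tests pin.
* **Distance series** report per-frame distances from one probe atom
  (e.g. S160 OG) to a set of targets (e.g. the four mid-chain carbonyl
  carbons C1–C4 of the tetrameric substrate) plus the per-frame argmin
  label, which is what reveals substrate *sliding* along the cleft.
  Which atoms are "C1–C4" is a configurable selection; topologies
  differ.
* **Hydrogen bonds** use a standard geometric criterion — donor–
  acceptor heavy-atom distance ≤ 3.5 Å and donor–H–acceptor angle
  ≥ 120° — since no criterion is canonical across tools.

One estimator subtlety is worth recording. When fluctuations are
measured on synthetic trajectories that contain *no* rigid-body
motion, the superposition fit itself absorbs a little noise, with the
largest relative effect at high-leverage chain termini (up to ~19 %
at the quietest terminus in our 50-residue benchmark). That is a
property of any fitted-reference RMSF, not a defect; accordingly the
planted-amplitude recovery benchmark measures with the fit off, and
the fitted estimator is separately required to track the planted
profile at r > 0.99. On real trajectories, where global motion is
genuine, the fit is indispensable and is the default.

## MM/PBSA bookkeeping

The binding free energy is the end-point difference
ΔG = G(complex) − G(protein) − G(ligand), term by term over vacuum
van der Waals, vacuum electrostatics, polar solvation, and apolar
solvation, with entropy omitted. The vdW, electrostatic and polar
terms are *inputs* parsed from engine tables — re-implementing a force
field or a Poisson–Boltzmann solver is explicitly out of scope, and
the dielectric constants (protein 4, water 80) ride along as metadata.
The apolar term is recomputable here:

* **Shrake–Rupley SASA** with a deterministic golden-spiral quadrature
  (960 points per atom by default; quadrature error well under 1 % for
  isolated spheres), probe radius 1.4 Å, and an editable element-based
  radius table.
* **Linear surface-tension model**: E = 0.0226778 · SASA + 3.84982
  (kJ/mol, SASA in Å²), the constants used by the g_mmpbsa lineage of
  tools.

Snapshots are selected equidistantly over the trailing half of the
trajectory, 500 by default, inclusive of both window endpoints — so
for a window whose length is not a multiple of the count, gaps differ
by at most one frame. Summaries report mean ± sample SD per term and
for per-snapshot totals; the mean total equals the sum of term means
exactly before rounding (published tables rounded per component can
disagree with their printed totals by up to 1 kJ/mol, which is the
tolerance the consistency fixture enforces). The "±" in the shipped
reference table is treated as SD over snapshots rather than a
block-averaged error — the table gives no basis for block sizes.

Per-residue decomposition deltas subtract the *average of the
wild-type replica mean profiles* (not pooled snapshots) from the
variant's mean profile: averaging at the profile level weights both
replicas equally regardless of snapshot counts. Negative values are
binding-energy gains.

## Synthetic data: what it emulates, and what it does not

Every input has a generator with planted ground truth, so the entire
pipeline is testable at desk scale without a docking engine, an MD
engine, or downloads:

* **Landscape** — variant → ΔG with per-(site, residue) additive
  effects, sparse pairwise epistasis (site-level, optionally
  residue-specific), and per-variant Gaussian noise keyed to the
  variant label, so scoring is reproducible and independent of query
  order.
* **Pose sets** — well-separated cluster centers with bounded
  within-cluster jitter; the planted partition is exactly recoverable
  at the clustering tolerance.
* **Trajectories** — one α-carbon per residue on a fixed scaffold,
  independent Gaussian displacements with planted per-residue SDs,
  optional rigid drift (which superposition must annihilate).
* **Energy frames** — Gaussian per-term draws per entity, optional
  per-residue decomposition that sums to each snapshot's decomposable
  total by construction.

One global seed fans out to per-generator and per-variant child seeds
through a deterministic string hash (always below 2³¹), so identical
configs give byte-identical outputs.

The default pipeline configuration *is* the study design the package
models: 42 candidate sites (27 loop, 15 non-loop) around the binding
cleft with the triad excluded; eight strong sites whose alanine
substitution is planted at −1.4 kcal/mol; three weak sites at
−0.3 kcal/mol; residue-specific gains at positions 112/119/238 with a
residue-specific synergy on the (112, 238) pair and a +1.0 kcal/mol
crowding penalty on every other simultaneous pair (so the optimum sits
at one or two mutations, as cleft geometry suggests it should); and
0.15 kcal/mol of scoring noise — the repeatability scale of a
clustered best-of-500 docking score, and comfortably below half the
planted effects, the regime in which a mean − SD screen can be
expected to recover all planted sites. These values were fixed once,
as the package's model of a realistic screen.

What the generators deliberately do **not** emulate: physically
realistic conformations or energies, pose-energy/geometry correlation,
anharmonic or correlated residue motion, autocorrelated energy time
series, and force-field detail. Passing tests therefore demonstrate
that the *screening logic* is correct under known ground truth — not
that any particular docking or MD protocol is accurate. The published
per-variant energies themselves are not reproducible without re-running
the original engines, and the package makes no attempt to fake them.

## Numerical choices, degeneracies, tie-breaks

* Exact integer enumeration everywhere (no floating-point counting);
  libraries are ordered by mutation count, then label, and labels
  (`D112M/S238F`, ascending positions) are the primary key across all
  modules.
* Clustering ties on energy break by pose id; equal-energy accepted
  representatives resolve to the lower id.
* Kabsch uses the SVD determinant correction; reflections are never
  returned.
* SASA sphere points come from a golden-section spiral — deterministic,
  no RNG in quadrature.
* Undefined ΔG (no accepted cluster) propagates as `NA`, is excluded
  from maps and thresholds, and is counted separately rather than
  silently dropped.
* Strict inequalities: catalytic distance `< 4.0 Å`, conservation
  `< 6`, nomination `< mean − SD`.

## Problem sizes used by the test-suite benchmarks

Chosen as the smallest sizes at which the closed forms and recovery
claims are sharp: 200 random ≤ 8-pose sets for the clustering oracle,
50 random 10-atom pairs against a 2304-rotation grid for the Kabsch
bound, 50 residues × 10⁴ frames for RMSF recovery (sampling error
≈ 0.7 %, against a 5 % tolerance), 10³ random vectors for the
threshold invariance sweep, and the full 42-site end-to-end screen.

## Known limitations

* No symmetry correction in pose RMSD (symmetric ligands can inflate
  RMSD between chemically identical poses); the metric is an extension
  point.
* No PBC unwrapping beyond what the caller does on ingestion.
* The conservation score is one fixed, documented variant of the
  set-based family; viewers that treat gaps as a 21st residue will
  differ on gapped columns.
* Cross-enzyme identity values depend on the upstream aligner's gap
  placement; the package computes identity on the alignment it is
  given and records the denominator convention (columns with at least
  one non-gap residue).
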