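---
title: "Docking geometry, hybrid templates and PAE-based specificity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking geometry, hybrid templates and PAE-based specificity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpmhc)
```

`tcrpmhc` implements the non-neural-network machinery of a specialized
TCR:pMHC structure-prediction pipeline. The structure predictor itself is
deliberately out of scope: it enters only through the hybrid-template PDB
files and manifest this package writes, and through the interface-PAE
matrices it returns, which this package converts into binding scores. This
vignette explains the models and procedures, the parameters that matter,
the numerical choices, and what the synthetic-data module does and does
not emulate.

## Coordinate frames from internal pseudo-symmetry

Both MHC class I molecules and αβ TCRs carry an approximate internal
2-fold symmetry: the β-sheet floor of the MHC peptide-binding groove is
built from structurally equivalent N- and C-terminal halves, and the TCR
Vα and Vβ domains are structurally homologous. The package exploits this
to attach a reproducible orthonormal frame to each molecule:

1. Select paired core residues — 6+6 β-sheet Cα for the MHC, 13+13
   framework Cα for the TCR (`locate_core_residues()`).
2. Compute the least-squares rigid transform mapping the concatenated
   core set onto itself with the halves interchanged
   (`pseudo_symmetry_transform()`, SVD/Kabsch with determinant
   correction so reflections are never returned).
3. The rotation axis of that transform, signed to point toward the
   peptide (MHC) or toward the CDR3 loops (TCR), is the frame x-axis. The
   z-axis is the unit vector from the first-half to the second-half
   center of mass, Gram–Schmidt-orthogonalized against x, and y = z × x
   completes a right-handed frame. The field's convention fixes only
   x and z; the y = z × x completion is this package's explicit choice.
   The origin is the core center of mass.

Core residues are *located*, not hard-coded: each chain is globally
aligned (BLOSUM62, gap open 10, extend 0.5) against a shipped reference
profile and the reference core indices are mapped through the alignment.
The shipped profile is synthetic — an idealized 48-residue class I
groove-domain sequence and 44-residue TCR V-domain sequences matching the
synthetic-complex generator — because the authoritative core identities
exist only as a figure in the source literature, not as machine-readable
tables. Users with curated core tables can pass their own profile;
everything downstream depends only on the 6+6/13+13 index sets. Only a
class I profile ships; class II needs a user profile.

## The 6-parameter docking chart

The docking geometry is the rigid-body relation between the MHC and TCR
frames. Because both x-axes point toward the typical partner location,
the relation is charted smoothly near the consensus binding mode by six
numbers (`geometry_vector()`):

* `d` — inter-origin distance (Å), positive;
* `torsion` — the four-point dihedral (MHC x-tip, MHC origin, TCR
  origin, TCR x-tip), radians;
* polar/azimuth angles of the MHC→TCR direction in the MHC frame and of
  the TCR→MHC direction in the TCR frame. The polar angle is measured
  from the frame x-axis; the azimuth is `atan2(z, y)` in the frame's
  y–z plane.

`geometry_to_transform()` inverts the chart exactly: the TCR frame is
placed at distance `d` along the stated direction, rotated so the
back-direction constraint holds, then spun about the inter-origin axis
until the torsion matches. Round-trip error is below 1e-6 over the whole
sampled range (the suite sweeps 1,000 random 6-vectors), and the chart is
invariant under any global rigid motion applied to both frames.

The chart has coordinate boundaries where a polar angle reaches 0 or π
(the azimuth degenerates there). Observed TCR:pMHC binding modes sit far
from these boundaries, which is why the chart was chosen; the Gaussian
machinery below assumes the data stay inside.

## Gaussian model and Z score

`fit_geometry_distribution()` fits a mean and covariance to the 6-vectors
of a class-matched set of geometries. Three components are circular
(torsion and the two azimuths); each is unwrapped around its circular
mean before moments are taken, so sets straddling ±π pool correctly. The
covariance is regularized by +1e-6·I — the source procedure is silent on
regularization, but small template sets (the minimum accepted is 7, the
rank requirement for a 6×6 covariance) need it for stable inversion.
`mahalanobis_z()` reports Z = √((v−μ)ᵀΣ⁻¹(v−μ)) with the geometry's
circular components unwrapped against the fitted mean; for
in-distribution samples Z² is χ²(6)-distributed, which the suite checks
at n = 10,000 (mean within 5% of 6, plus a KS check).

## RMSD metrics

* `cdr_rmsd()` superposes the model on the native over the MHC Cα
  (unweighted), then takes a weighted Cα RMSD over the 8 CDR loops with
  no further superposition, each CDR3 residue weighted 3. Weights enter
  the squared sum and are normalized by Σw — stated explicitly because
  the ×3 factor alone does not fix the squared-vs-linear convention. A
  uniform 2 Å displacement of the TCR therefore gives exactly 2.0 Å.
  By default all shared MHC Cα are used for the superposition; pass the
  12-residue core set to restrict it (the source convention is not
  stated at that level of detail).
* `peptide_rmsd()` — same convention over peptide Cα, uniform weights.
* `docking_rmsd()` compares two geometries without sequences: with the
  MHC frame at the identity, each geometry places a TCR frame, 8 generic
  CDR centers of mass are mapped through both, and a weighted point RMSD
  (CDR3 COMs ×3) is taken without superposition. The generic COMs are
  averaged over a structure database in each structure's own TCR frame
  (`compute_generic_cdr_coms()`); a canonical set from the synthetic
  reference complex ships as the default so the metric works without a
  database. It is a true pseudometric (a weighted Euclidean embedding),
  and on perturbed synthetic models it rank-correlates with CDR RMSD
  above 0.9.

## TCRdist and repertoire operations

The sequence distance is an additive weighted mismatch over CDR1, CDR2,
CDR2.5 (weight 1) and CDR3 (weight 3): per-position cost
min(4, 4 − BLOSUM62), gaps 4, CDR3s compared after trimming 3 N-terminal
and 2 C-terminal flank residues and center-gapping the shorter trimmed
loop. These constants follow the measure's established definition (the
pipeline uses it without restating it) and are all exposed as arguments.
One non-conservative CDR3 substitution costs 3 × 4 = 12; three cost 36,
the single-chain template-exclusion threshold.

`redundancy_filter()` drops an entry when some already-kept entry has
*both* fewer than 3 peptide mismatches and paired TCRdist ≤ 120; scanning
in input (deposit-date) order keeps the earlier structure — the source
procedure does not say which member of a redundant pair was dropped, so
this package fixes first-come-wins. Peptides of different length count as
infinitely mismatched, so cross-length pairs are never redundant.

`kde_subsample()` picks up to n = 50 representatives: candidates are
scored once by a Gaussian kernel density over paired TCRdist and accepted
in decreasing density order subject to a minimum distance to everything
already selected. Bandwidth 120 and min_dist 24 are this package's
defaults (one redundancy radius; two non-conservative CDR3 mismatches):
the source defers both to a script, so they are exposed, not hard-coded.
A seeded jitter breaks exact density ties, making the selection
deterministic and permutation-stable up to ties.

## Template engine

In benchmark mode, records too similar to the target are excluded before
selection: pMHC templates at fewer than 3 peptide mismatches, TCR chain
templates at single-chain TCRdist ≤ 36, docking-geometry sources at fewer
than 3 peptide mismatches *or* paired TCRdist ≤ 48. Production mode
applies only the deposit-date cutoff (default 2021-08-05, the template
snapshot date). pMHC templates are ranked by total sequence identity over
MHC plus peptide (global alignment, identities counted over aligned
non-gap positions); TCR chains by ascending single-chain TCRdist — the
source says only "sequence similarity", and TCRdist is adopted for
consistency with the exclusion thresholds. Ties break by earlier deposit
date, then PDB id.

Representative geometries: the pairwise docking-RMSD matrix is
hierarchically clustered and the tree cut at exactly k = 12 clusters;
each cluster contributes its medoid. Single linkage is the default (the
referenced clustering routine's own default), with average/complete
available.

`assemble_hybrid_template()` keeps the TCRα template fixed, superposes
the TCRβ donor onto it over the 13 TCRα core residues (warning above
5 Å residual), computes the hybrid TCR frame from the merged cores, and
rigidly places the pMHC donor so the realized geometry equals the
requested representative; the realized geometry is re-measured from the
assembled coordinates and must agree to 1e-3. `build_run_manifest()`
emits 3 runs × 4 templates: run r uses geometries 4(r−1)+1..4r, and
geometry j is paired with chain-template rank ((j−1) mod 4)+1. The full
chain-template × geometry combinatorics is deliberately not sampled; the
exact pairing is not derivable from the source description, so this
rank-aligned scheme is fixed and documented here. The manifest records
single-sequence mode (no MSA) and per-chain target→template alignment
maps.

## Binding scores

Raw interface PAE (the mean of a predictor's residue-pair aligned-error
estimates over TCR×pMHC pairs, pooled in both directions since PAE is
asymmetric; a `pool = "sum"` switch exists because the two source
descriptions differ — ranks are unaffected at fixed complex size) mixes
binding signal with molecule-intrinsic offsets. The correction is

B[i,j] = (PAE[i,j] − bg[j]) − mean_j(PAE[i,·] − bg[·])

where bg[j] is the mean interface PAE of peptide j against a panel of
irrelevant background TCRs. Column-wise background subtraction removes
pMHC-intrinsic offsets; row centering removes TCR-intrinsic ones, so
every row mean is exactly 0 and adding any per-row constant, or a
per-column constant simultaneously to PAE and background, leaves B
unchanged. Wild-type ranks count strictly better decoys (0 = best; ties
do not count against the wild type, matching a 0–9 rank scale), AUROC is
the midrank Wilcoxon–Mann–Whitney statistic, decoys are the top-9 scored
9-mers of a seed-shuffled 1500-residue artificial antigen (duplicates and
wild-type epitopes excluded — the source is silent on duplicates in the
scan, so uniqueness is enforced), and alanine scans mutate every position
to alanine, with native alanines to glycine.

## What the synthetic data does and does not emulate

`make_synthetic_complex()` builds Cα-only idealized complexes: exactly
C2-symmetric core point sets, β-strand-like 3.8 Å spacing, CDR loops on
the +x side, and the TCR placed by the exact chart inverse — so at zero
noise the recovered geometry equals the generating one to machine
precision, giving the geometry stack a closed-loop oracle. Gaussian
coordinate noise (s.d. in Å) emulates measurement/model error. What it
does not emulate: real secondary-structure geometry, side chains,
insertion codes, missing density, or genuine inter-domain flexibility —
so passing tests demonstrate the correctness of the mathematics, not
robustness to the full messiness of deposited structures.

`make_synthetic_pae()` draws PAE[i,j] = baseline + τᵢ + πⱼ −
β·1[cognate] + ε, mirroring the empirically observed TCR- and
pMHC-intrinsic accuracy offsets, with defaults n = 50 TCRs × 10
peptides, τ s.d. 2, π s.d. 1, β = 3, σ = 1, 50 background TCRs and
baseline 20 error-units; draws are truncated at 4 s.d. so values respect
the non-negativity of real PAE. It does not emulate peptide-similarity
correlations between columns or any structure-derived signal. Under
these defaults the corrected scores put the cognate peptide first for
roughly 90% of TCRs — the per-seed fraction fluctuates by ~5 percentage
points around that value on a 50-row matrix — and separate binders from
decoys with AUROC ≈ 0.99; at β = 0 scores are exactly 0 when σ = 0 and
AUROC ≈ 0.5 otherwise.

`make_synthetic_repertoire()` mutates CDR3 positions around center
sequences with a per-position probability, keeping germline loops tied
to the V gene so repertoires round-trip through the V-gene-based TSV
layout. The shipped V-gene table is synthetic and minimal; full germline
databases are a non-goal.

## Numerical choices and degenerate inputs

* Rotations are fitted by SVD with determinant correction; degenerate
  (collinear/zero-covariance) point sets raise errors rather than
  returning reflections.
* Frame construction fails loudly when the z-axis vanishes after
  orthogonalization (symmetry axis parallel to the half-to-half
  direction).
* Indexing is 0-based half-open everywhere internally; author residue
  numbering appears only at the PDB boundary. Altloc conflicts resolve
  to the highest-occupancy conformer; insertion-coded residues keep
  author order.
* `fit_geometry_distribution()` refuses fewer than 7 samples; Z-score
  computation surfaces singular covariances as errors.
* Distances `d` below 1e-6 Å (coincident origins) are rejected; the
  synthetic generator rejects geometries that place TCR atoms within
  1 Å of the pMHC.
* All stochastic generators take explicit integer seeds, use a local
  RNG stream, and restore the caller's RNG state.

## Problem sizes in the test suite

The suite runs entirely on synthetic data at desk scale: 1,000-vector
chart sweeps, 100-seed noise-recovery runs, 10,000-sample χ² calibration,
10,000 random alternative transforms for superposition optimality,
100-entry databases for the filter checks, and 24-geometry clustering
runs — sizes chosen so every property is exercised with comfortable
statistical margins while the whole suite stays fast. The headline
accuracies of the full pipeline on deposited structures (CDR RMSD
distributions, per-epitope AUROCs) require running a GPU-scale structure
predictor over a curated benchmark and are intentionally outside this
package's test scope.

## Known limitations

* Class II MHC is supported by the data model (`mhc_class = 2`) but no
  class II reference core profile ships.
* The azimuth reference convention of the 6-vector chart is fixed by
  this package; other implementations of the same idea may chart the
  same geometry with different azimuth zeros, so 6-vectors are
  comparable only within one convention (docking RMSD, being built from
  realized frames, is convention-free).
* `single_chain_tcrdist()` compares same-length germline loops
  position-wise and center-gaps length mismatches; it does not
  re-derive IMGT alignments.
* mmCIF, side chains, B-factors and protonation are out of scope.
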