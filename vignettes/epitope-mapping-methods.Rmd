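---
title: "Methods: ortholog-differential epitope mapping and interface geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog-differential epitope mapping and interface geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
library(dplyr)
```

# The problem and the model

A therapeutic antibody binds a cell-surface receptor whose extracellular
domain (ECD) resists direct structural characterization. The mapping
strategy implemented here exploits species selectivity: if the antibody
binds the human ECD and some orthologs but not others, then residues that
are (i) identical across the binding species, (ii) different in every
non-binding species, and (iii) exposed on the antigen surface are the
candidate epitope. Swapping such residues (singly, in small spatial
patches, or as contiguous chimera blocks) from a non-binding ortholog into
the binder — and back — converts binding loss and gain into interval
evidence. An overlapping-peptide array localizes linear epitopes
independently, and a crystal structure of the antibody fragment bound to
the antigen finally quantifies the interface.

The package implements each stage as plain functions over tibbles so the
stages compose with the pipe, plus a structural toolbox over atomic
coordinates.

## Differential conservation

A column of the labelled multiple alignment is *differential* when the
binders (weak binders are grouped with binders, since weak binding still
implies an intact epitope) carry exactly one, ungapped residue and no
non-binder carries that residue. Two asymmetric gap rules follow from the
design goal rather than from symmetry: a gap in any binder disqualifies the
column (a substitution cannot be designed at an indel), while a gap in a
non-binder counts as "dissimilar" (the non-binder genuinely lacks that
epitope residue). Excluded species (for instance an ortholog carrying a
long private insertion) stay in the panel but are ignored by every
analysis. Positions are reported in *mature* numbering (1 = first residue
after signal-peptide cleavage); each species carries its own offset, and
precursor coordinates appear only at I/O boundaries.

## Surface filtering, patches and chimeras

Candidate positions are kept when their relative solvent accessibility
(RSA) on a structural model reaches a threshold, 0.25 by default. The
threshold is a genuinely open choice — no published value exists for this
step — and it is exposed as a parameter; positions missing from the model
are reported separately rather than dropped, because silent loss here would
bias the design toward the crystallized fragment.

Patch mutants group 2–4 substitutions that are close in space:
single-linkage clustering of representative atoms (Cβ, or Cα for glycine)
at a 10 Å cutoff. Single linkage is the right geometry for "close
proximity" chains of residues on a surface; the cutoff is a conventional
side-chain-contact scale, not a fitted constant. Oversized clusters are
split deterministically by ascending mature position into chunks of at most
four, so designs are reproducible; chunks below the minimum size are
reported unpatched, and every input position lands in exactly one patch or
the unpatched list.

Chimeras are maximal runs of differential positions with inter-position
gaps of at most 3, padded symmetrically to a minimum span of 6 and
truncated at the right end to a maximum span of 20 — the span range of
designs that have worked in practice for this family of campaigns. The
donor interval is read through the alignment (cumulative ungapped donor
positions at the reference interval's columns), so reference and donor
intervals round-trip through the alignment by construction.

## Antigenicity consensus

Three windowed predictors annotate the reference sequence: the Emini
surface-accessibility product over a 6-residue window, the
Kolaskar–Tongaonkar 7-residue moving average with its published
whole-protein thresholding rule, and a 7-residue Parker hydrophilicity
moving average. The third predictor stands in for HMM-based linear-epitope
tools whose trained parameters are not tabulated in reusable form; what the
consensus requires is a third concordant signal, not that specific model.
Two normalization choices are the package's own: the Emini product is
divided by `mean(scale)^6` so a uniformly random sequence has expected
score 1.0 (making the published 1.0 threshold meaningful on any input), and
the hydrophilicity threshold is the whole-protein mean window score.
Consensus regions are maximal runs (window-start coordinates) where *every*
profile is positive, ranked by mean normalized excess over threshold —
the ranking rule is documented here because "scored highest across tools"
is otherwise underdetermined.

## Peptide tiling and positivity

Tiles of length 20 at step 5 (overlap 15) cover the precursor; tile *k*
starts at position `5(k−1)+1`, and a truncated terminal tile is added only
when full tiles cannot reach the coverage end. Positivity uses a dual
criterion — signal at least 3× the background mean *and* at least 5
background standard deviations above it — because plate backgrounds vary
both in scale and in dispersion; either criterion alone is fragile, and the
source assays report only "at or near background" without a numeric rule.
Both components are recorded per tile so a reanalysis can change either
threshold.

Localization is interval arithmetic: for each block of mutually overlapping
positive tiles, the intersection (minimal epitope-containing region) and
the union. For `k` consecutive positives the intersection has length
`20 − 5(k−1)` — a closed form the tests check. Non-contiguous positive
blocks are reported separately with a multi-site flag, never merged: a
discontinuous epitope must not be averaged into one interval.

## Evidence integration

The final call intersects all interval-type loss/gain evidence (chimera
losses, reverse-chimera gains, peptide intersections). Pivotal residues are
point-mutant losses plus patch substitutions falling inside a chimera-loss
interval — the set arithmetic that singles out a residue shared between a
patch and a chimera. Retention evidence (a tolerated conservative
substitution) annotates residues but never shrinks the interval: a mild
mutation inside the epitope is still inside the epitope.

One boundary question is genuinely open. With a chimera loss over [74, 92]
and a reverse-chimera gain over [73, 87], strict intersection yields
[74, 87], while privileging the gain-side boundary (the reverse chimera
demonstrates sufficiency of 73–87) yields [73, 87]. Both conventions are
implemented (`boundary_rule = "intersection"` — the default, conservative —
or `"gain"`); the tests exercise both, and conflicting (disjoint) intervals
are rejected with the offending pair named.

## Flow normalization and testing

Binding is normalized as the ratio of the binding-channel median
fluorescence to the display-channel median; a common multiplicative gain
cancels exactly (the tests assert this to machine precision). A construct
whose display median falls to the negative-control floor is a display
failure and is excluded from comparisons rather than scored as a binding
loss.

Many-to-one comparison against wild type is realized as a max-T permutation
test: group labels are permuted, the maximum absolute pooled-variance t
statistic across comparisons forms the null, and each construct's adjusted
p is its observed |t|'s tail probability. This controls the family-wise
error exactly under exchangeability at the replicate counts typical of
these assays (n = 2–3 per construct), where parametric multivariate-t
tabulations are least trustworthy; it is a deliberate substitute for the
classical parametric many-to-one procedure. Binding "loss" additionally
requires the mean ratio to fall below half the wild-type ratio
(`loss_fraction = 0.5`), since a statistically significant but tiny
reduction is not a mapping signal. The two-antibody truth table then
classifies variants: test lost with control retained = epitope disruption;
both lost = fold disruption; test retained with control lost = ambiguous.

The permutation test's calibration is property-based: the acceptance suite
simulates 2,000 null families (reference + 4 constructs, 3 replicates,
499 permutations each) and requires the family-wise rejection rate at a
nominal 0.05 to land inside the binomial 95% confidence band. Power is
checked at a 10-standard-deviation shift in a 9-construct family.

## Interface geometry

Solvent-accessible surface area uses Shrake–Rupley quadrature on a
deterministic golden-spiral point set (960 points per atom by default;
refinement to 4,000 points moves results by under 1% on the test
complexes). Van der Waals radii are element-keyed (C 1.70, N 1.55, O 1.52,
S 1.80 Å), the probe is 1.4 Å, and hydrogens and waters are excluded from
every distance and surface computation — typical deposition resolutions
carry no hydrogens, and excluding them keeps results comparable across
conventions. Unknown elements receive a configurable 1.8 Å default with a
warning. The two-sphere closed form (spherical caps of probe-inflated
spheres) serves as an analytic oracle; the quadrature agrees with it to a
fraction of a percent.

Buried surface area is `SASA(antigen) + SASA(antibody) − SASA(complex)`,
reported in total and per residue; negative per-residue values (quadrature
noise) are clamped to zero with a warning. Burial fraction is ΔSASA over
the free-state residue SASA, with residues above 0.75 flagged as interface
cores. Epitope and paratope are the residues with any heavy-atom pair
within 3.8 Å across the partition — the cutoff is inclusive because the
source convention is "within". RSA normalizes residue SASA by theoretical
Gly-X-Gly maxima (the reference-set id is recorded in every output). One
honesty note on fixtures: a *single* idealized extended conformer of
Gly-Ala-Gly reaches about 88–91% of the tabulated maximum under this radius
set, since the tabulated values are maxima over conformers; the tests
therefore assert a band around full exposure plus the exact monotonicity
property (removing neighbors never decreases SASA) rather than a sharp
100%.

Disulfides are Cys Sγ–Sγ pairs at ≤ 2.3 Å, each Sγ used once with the
nearest partner winning. Hydrogen bonds are donor–acceptor heavy-atom pairs
at ≤ 3.5 Å using per-residue role tables, with no angular criterion — an
angle test would require hydrogens the structures do not have.

Superposition is the closed-form Kabsch solution over corresponding Cα
atoms (by chain map and residue number, or by per-chain global sequence
alignment when numbering differs), with the improper-rotation branch
corrected so the returned matrix is always a proper rotation. Optional
iterative trimming drops pairs deviating more than twice the current RMSD,
refits, and stops when stable, after 5 cycles, or at 50% of the initial
pairs — emulating the "aligned Cα" counts of common structure-comparison
programs without reverse-engineering any one of them. A brute-force
rotation search (Euler-angle grid plus local refinement) is the independent
oracle in the tests. Worth knowing: a single outlier among *n* pairs cannot
exceed `√n` times the RMSD, so the 2× trimming factor only engages for
n ≳ 5 — trimming is meant for chains, not for minimal point sets.

Substitution impact uses a common-atom truncation model: side-chain heavy
atoms in canonical order are retained up to the smaller of the two residue
types' side-chain sizes and deleted beyond it, so X→Ala deletes everything
beyond Cβ and Leu→Ile deletes nothing (equal heavy-atom counts, δ-branch
renamed). Lost contacts are the interface contacts involving deleted atoms.
Clashes are screened by rotating the retained atoms distal to Cβ about the
Cα–Cβ axis through idealized χ1 angles (0°, ±60°, 180°) and flagging any
cross-interface approach below 0.8× the summed van der Waals radii. This is
a screen, not a repacking: it deliberately avoids rotamer-library
optimization.

# Synthetic data: what it emulates, and what it does not

Each generator is seeded, bit-reproducible, and returns its planted ground
truth:

* `gen_ortholog_panel()` plants a divergent interval: binders share a
  consensus, non-binders differ at every planted site and mutate elsewhere
  at a per-site rate (default 0.05, a plausible between-ortholog divergence
  outside a selective region). Columns outside the plant where *all*
  non-binders mutated by chance are repaired so the differential ground
  truth is exactly the planted set — the generator guarantees its own
  truth rather than estimating it. It does not emulate indels, phylogenetic
  correlation between species, or rate variation along the sequence.
* `gen_helix_complex()` builds an ideal α-helix (1.5 Å rise, 100° twist per
  residue) with one Cα and one side-chain centroid pseudo-atom per residue,
  and places probe atoms at an exact distance from designated centroids.
  Ground-truth contacts come from exhaustive pair enumeration and
  ground-truth buried area from 4,000-point SASA. It does not emulate side
  chains, packing, or crystallographic noise.
* `gen_flow_events()` draws two log-normal channels under a common gain —
  strictly positive and right-skewed like cytometer intensities, but with
  no compensation, doublets, or gating structure.
* `gen_peptide_signals()` gives tiles overlapping the planted interval by
  at least `min_overlap` residues (default: the interval length, capped at
  15) a fold-over-background mean, with Gaussian noise. It does not emulate
  plate-position effects or peptide synthesis failures.

Passing tests on these fixtures demonstrates the *arithmetic and
statistical machinery* — recovery of planted truth, oracle agreement,
calibration — not performance on real assay data with its correlated
noise.

# Problem sizes and runtime choices

The test suite and the acceptance script run at deliberately modest sizes:
440-residue precursors with 85 tiles, 100–120-column panels, 20-residue toy
complexes (~45 atoms), 4-point superposition oracles, flow samples of
10⁴–2×10⁴ events, and 2,000 simulated null families at 499 permutations.
These sizes give sub-minute runs while leaving every assertion's
statistical resolution intact (the family-wise calibration, for instance,
has a ±0.0096 binomial band at 2,000 families). Production use on full ECD
panels and complete antibody–antigen complexes only scales the same code;
the SASA quadrature is O(atoms × neighbors × points) and handles
full-size complexes in minutes on one CPU.

# Known limitations

* Deposited crystal structures are not bundled; the structural acceptance
  checks against published interface quantities require the user to supply
  those coordinate files (see `tests/testthat/test-acceptance.R`).
* The progressive consequences of glycans, altloc-rich regions, and
  ligands are handled only to the extent of flagging and exclusion.
* The antigenicity consensus replaces trained linear-epitope predictors
  with a transparent hydrophilicity profile; it is a concordance signal,
  not a reimplementation.
* FCS parsing, compensation and gating are out of scope: flow inputs are
  exported event tables.
* The substitution scan models truncation and rigid χ1 rotation only; it
  cannot predict stabilizing rearrangements.
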