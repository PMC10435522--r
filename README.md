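# epimapr

Epitope mapping of an antibody on a cell-surface antigen, as a tested,
reusable R pipeline. The package covers the four stages of a
chimera-and-crystallography mapping campaign:

1. **Ortholog-differential design** — given a labelled panel of species
   orthologs of the antigen's extracellular domain (binders, weak binders,
   non-binders), find alignment columns where all binders share one residue
   that no non-binder carries, filter them for surface exposure on a
   structural model (relative solvent accessibility, RSA), cluster them into
   patch mutants (2–4 spatially proximal substitutions, single linkage on
   Cβ) and propose contiguous chimera intervals, annotated by a
   three-predictor antigenicity consensus (Emini surface accessibility,
   Kolaskar–Tongaonkar antigenicity, Parker hydrophilicity).
2. **Tiling-peptide localization** — 20-mer peptides at 15-residue overlap
   across the precursor, dual positivity calling against plate background
   (signal ≥ 3× background **and** ≥ 5 sd above it), and interval arithmetic:
   the intersection of positive tiles is the minimal epitope-containing
   region. Chimera, patch, point-mutant and reverse-chimera results are
   integrated by set arithmetic into a final epitope call with pivotal
   residues.
3. **Flow-binding normalization** — binding is normalized to display level
   as MFI(binding antibody)/MFI(display-tag antibody), which cancels
   instrument gain exactly; variants are classified as epitope-disrupted
   versus fold-disrupted using a non-competing control antibody, with
   many-to-one testing against wild type realized as a seeded max-T
   permutation test (a Dunnett-style family-wise control).
4. **Interface geometry** — from antibody–antigen coordinates (PDB/mmCIF):
   Shrake–Rupley solvent-accessible surface area on a deterministic
   golden-spiral quadrature, buried surface area
   `BSA = SASA(A) + SASA(B) − SASA(AB)`, epitope/paratope definition by a
   3.8 Å heavy-atom contact rule, RSA against Gly-X-Gly theoretical maxima,
   disulfide and hydrogen-bond detection, Kabsch superposition with
   iterative trimming, a common-atom-truncation substitution-impact scan,
   and assembly-span measurement.

Every stage has a seeded synthetic-data generator with planted ground truth
and analytic oracles (two-sphere SASA closed form, exhaustive contact
enumeration, brute-force rotation search), so the whole pipeline is testable
without downloads.

## Worked example

The package's worked example reproduces the desk arithmetic of the mapping
campaign: tiling a 440-residue precursor (signal peptide = 23 residues) and
intersecting the two positive 20-mers, then integrating the construct
evidence.

```r
library(epimapr)
library(dplyr)

precursor <- paste0(strrep("G", 90), "NSGDCRSSTCEGLDLLRKISNAQRM", strrep("G", 325))
tiles <- tile_peptides(precursor, length = 20, step = 5, offset = 23)
tiles[19:20, ]
#>    tile start   end mature_start mature_end sequence
#> 1    19    91   110           68         87 NSGDCRSSTCEGLDLLRKIS
#> 2    20    96   115           73         92 RSSTCEGLDLLRKISNAQRM

localize_from_tiles(tiles[19:20, ])
#>   block n_tiles intersection_start intersection_end union_start union_end
#> 1     1       2                 73               87          68        92
```

The two overlapping positives localize the epitope to mature 73–87 (their
15-residue intersection); their union spans 68–92. Adding the construct
evidence — a chimera that loses binding over 74–92, a reverse chimera that
gains binding over 73–87, a 4-substitution patch {15, 62, 66, 80} that loses
binding, a point mutant at 80 that loses binding and one at 83 that retains
it:

```r
ev <- bind_rows(
  evidence("chimera", "loss", 74, 92),
  evidence("reverse_chimera", "gain", 73, 87),
  evidence("peptide_overlap", "loss", 73, 87),
  evidence("patch", "loss", positions = c(15, 62, 66, 80)),
  evidence("point_mutant", "loss", positions = 80),
  evidence("point_mutant", "retention", positions = 83))
integrate_evidence(ev)
#> <epitope_call> interval [74, 87]; pivotal: 80; retention-annotated: 83
```

The strict intersection of the loss/gain intervals is [74, 87]; position 80
is pivotal (a point-mutant loss that is also the only patch substitution
inside the chimera interval), and the retention evidence at 83 annotates but
never shrinks the call. `integrate_evidence(ev, boundary_rule = "gain")`
privileges the reverse-chimera boundary and returns [73, 87]; the choice
between the two conventions is discussed in the methods vignette.

On the structural side, the synthetic helix–probe complex exercises the
interface machinery end to end:

```r
hx <- gen_helix_complex(seed = 1, n_probe_atoms = 5, probe_distance = 3.5)
interface_report(hx$model, antigen_chains = "A", antibody_chains = "B")
#> <interface_report>
#>   epitope:  5 residues
#>   paratope: 5 residues
#>   total BSA: 261.7 A^2
#>   H-bonds: 0; disulfides: 0
```

All five probe contacts (planted at 3.5 Å, inside the 3.8 Å rule) are
recovered, and the buried area at the default 960-point quadrature agrees
with the generator's high-resolution ground truth to well under a percent.

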