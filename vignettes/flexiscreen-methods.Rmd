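---
title: "flexiscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flexiscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexiscreen)
```

## Scope

`flexiscreen` implements a flexibility-guided stability-screening workflow
for proteins: detect highly flexible regions from conformational ensembles
by per-residue RMSF, triage designed point mutants by Rosetta ΔΔG and by the
percent change of region flexibility (ΔRMSF) between mutant and wild-type
ensembles, and characterise the survivors by hydrogen-bond occupancy and
three-state secondary structure. The package consumes ensembles (multi-model
PDB) and score tables; it never runs a molecular-dynamics engine or a design
engine, and it never computes Rosetta energies — ΔΔG values are inputs.

## The flexibility model

For an ensemble of frames sharing one topology, the per-residue RMSF is

$$\mathrm{RMSF}(r) \;=\; \sqrt{\Big\langle\, \overline{|x_a(t) - \langle x_a\rangle_t|^2}^{\,a \in r} \,\Big\rangle_t}$$

the square root of the mean (over frames and over the residue's selected
atoms) squared displacement from each atom's time-average position. For a
multi-atom selection the mean square is averaged over the residue's atoms
*before* the square root. Defaults and why:

* **Atom selection** (`selection`, default `"calpha"`): Cα is the dominant
  convention for per-residue flexibility and keeps RMSF on the Å scale of
  typical region summaries; `backbone`, `heavy` and `all` are selectable
  because the convention is not universal.
* **Superposition** (`superpose = TRUE`): global rigid motion is removed by
  iterative alignment to the evolving average structure (tolerance 1e-4 Å on
  the maximum per-coordinate shift of the average, at most 10 sweeps; a
  non-converged run warns and returns the last iterate). The first reference
  is the raw per-atom average, which makes an already-aligned ensemble an
  exact fixed point. For synthetic ensembles built without rigid-body
  motion, `superpose = FALSE` gives the exact closed-form behaviour
  (RMSF = σ√3 for isotropic per-coordinate sd σ).
* **Superposition algorithm**: Kabsch (SVD of the cross-covariance), with
  the determinant sign corrected so the transformation is always a proper
  rotation. Collinear or coincident fit selections leave the rotation
  undetermined and raise an error rather than silently returning one of the
  minimisers.
* **Centroid frame**: the representative conformation of a trajectory window
  is the frame with minimum RMSD to the window average; ties resolve to the
  earliest frame so the result is deterministic.

## Region calling

The flexibility cutoff is the arithmetic mean of all per-residue RMSF values
pooled over all supplied profiles (e.g. replicate models). Pooling — rather
than averaging per-model cutoffs — is the default because the quantity is
meant to be a protein-wide reference level; a per-model variant is exposed
(`per_model = TRUE`) since the choice is not forced. Flagging is strictly
greater-than: residues exactly at the cutoff are not flexible. Adjacent
flagged residues (consecutive numbering; a gap tolerance is available but
defaults to 0, the strictest reading of "adjacent") merge into regions;
exclusion intervals (for natively floppy termini, e.g. a C-terminal tail)
are applied before merging and are configuration, not hard-coded. Regions
are ranked by mean RMSF with ties broken by the smaller region id; the
published ranking this mirrors contains such a tie, and the tie-break never
affects top-5 membership.

With replicate profiles, a region's `mean_rmsf` is computed on the
across-replicate mean profile and `sd_rmsf` is the spread of the region mean
across replicates — the role the ± plays in replicate simulation studies.
With a single profile the sd is across residues instead; both are defensible
readings and the replicate one is reported by default.

Designability uses the minimum distance over all atom pairs between a
candidate residue and any catalytic residue, with a strict "more than"
threshold (default 15 Å): a residue exactly at the threshold is excluded.

## The design screen

From a design score table (one row per scored position; `-` denotes absence
and is parsed as `NA`, never 0), `select_designs()` keeps at most one call
per position — the substitution with the lowest ΔΔG — and only if
ΔΔG < 0 REU strictly. Rows whose design equals the native residue are
identity designs, not mutants, and are skipped. A ΔΔG tie at a position
resolves to the alphabetically first designed amino acid (determinism);
conflicting duplicate rows are an error rather than a silent choice.

ΔRMSF is defined on region-*mean* RMSF,

$$\Delta\mathrm{RMSF} = 100 \cdot
\frac{\overline{\mathrm{RMSF}}_{\text{mut}} - \overline{\mathrm{RMSF}}_{\text{wt}}}
     {\overline{\mathrm{RMSF}}_{\text{wt}}}\ \%$$

not as the mean of per-residue percent changes: region means are the
quantity the region tables report, and the ratio-of-means is stable when
individual residues have small denominators. The per-residue variant is
available behind `per_residue = TRUE`. Replicates are paired index-wise
(replicate *i* of mutant vs replicate *i* of wild type; all pairs when the
counts differ) and summarised as mean ± SEM over pairs. Stage thresholds
(−10 % at the high-temperature stage, 0 % at the optimum-temperature stage)
are configuration with those defaults; comparisons are strict, so −10.0 %
exactly does not pass, which also makes screening monotone in the threshold.

## Hydrogen bonds

A geometric bond requires donor–acceptor distance ≤ 3.5 Å **and**
D–H⋯A angle ≥ 120°, both inclusive as written. The angle is measured at the
hydrogen (between the H→D and H→A directions), the standard reading of a
"donorH–acceptor" angle. Donors are N/O heavy atoms with a covalently bonded
hydrogen; bonds are inferred by an H-to-heavy distance ≤ 1.2 Å because
MD-derived PDB files rarely carry CONECT records. Occupancy is the
percentage of frames in which a (donor heavy atom, acceptor) pair is bonded;
alternative hydrogens of one donor count once per frame. Intra-residue pairs
are excluded. Strength classes partition occupancies: strong (> 75 %),
medium (75–50], weak (50–25], very weak (25–10]; at or below 10 % a pair is
"unreported" (the conventional reporting floor). Regional summaries count
unique pairs with at least one partner residue inside the region; the other
partner is unrestricted by default because the design shell already limited
neighbours to 10 Å — an optional `neighbor_cutoff` restores a hard
distance restriction when wanted.

## Secondary structure

The three-state assignment is a self-contained simplified DSSP: backbone
hydrogen bonds by the Kabsch–Sander electrostatic energy
(E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond iff
E < −0.5), then the standard pattern rules — two consecutive n-turns define
3₁₀/α/π helices (n = 3, 4, 5), parallel/antiparallel bridge patterns define
strand residues — collapsed to helix {H, G, I}, sheet {E, B} and coil
(everything else, including turns and bends, matching the common
sheet/helix/random-coil reporting convention). Priority at overlaps follows
DSSP: α-helix, then sheet, then 3₁₀/π.

Missing amide hydrogens are synthesized 1.01 Å from N along the previous
residue's O→C direction. This is the original Kabsch–Sander convention and
the one used by reference implementations (we validate against `mdtraj`'s
DSSP); a bisector-based placement was considered and rejected to keep the
assignment aligned with the reference. Chain starts get no synthetic H (there
is no preceding carbonyl to orient it), so they cannot donate — the main
source of single-residue differences from implementations that read explicit
terminal hydrogens. Chain breaks (C–N distance > 2.5 Å or a chain-id change)
restart the pattern search. Degenerate geometries with near-zero interatomic
distances return energy 0 (no bond) instead of ±∞.

Region percentages are per-frame fractions of region residues in each state,
averaged over frames within a replicate, then mean ± sd across replicates;
the three percentages sum to 100 by construction.

## The synthetic-ensemble generator

The generator emulates exactly the statistical features the pipeline
measures, with known ground truth:

* **Base geometry**: an idealised polyalanine backbone (N, H, Cα, C, O)
  built from ideal bond lengths/angles and canonical dihedrals — helix
  (φ = −57°, ψ = −47°), extended strand (φ = −140°, ψ = 135°),
  polyproline-like coil (φ = −75°, ψ = 150°), or concatenated segments.
  A two-strand antiparallel sheet is built by rigidly placing a flipped copy
  of a strand to maximise the inter-strand Kabsch–Sander ladder
  (deterministic smooth optimisation of the rigid placement).
* **Fluctuations**: independent per-atom Gaussian displacements with the
  residue's per-coordinate sd (default 0.3 Å, a realistic ordered-protein
  scale giving RMSF ≈ 0.52 Å; flexible regions are modelled by region-wise
  amplitude factors). Expected RMSF is σ√3 exactly, which makes parameter
  recovery a closed-form test. There are **no dynamics**: frames are i.i.d.
  draws, because every statistic the pipeline computes depends only on the
  marginal conformational distribution. Autocorrelation, anharmonicity,
  concerted motions and actual unfolding at high temperature are *not*
  emulated — passing recovery tests shows the estimators are correct, not
  that MD ensembles behave this simply.
* **Planted hydrogen bonds**: in "on" frames the acceptor O is placed at
  donor–acceptor 2.9 Å with a D–H⋯A angle of 165° (comfortably inside the
  criteria); in "off" frames at 4.5 Å (clearly outside). On-frame counts are
  exact (`round(occ/100 · n_frames)`) by default so occupancy recovery is
  exact; a Bernoulli mode exercises the statistical path. A residue's O can
  carry only one restraint — conflicting restraints are an error.
* **Mutants**: identical specification with the region amplitude multiplied
  by a factor *s* and an independent noise stream, so the expected ΔRMSF is
  100·(s − 1) % by linearity of RMSF in the amplitude.
* **Determinism**: a spec's seed fully determines the output (R's default
  Mersenne-Twister); the caller's RNG state is restored afterwards.
* **Temperature** is only a label: "500 K" vs "313 K" correspond to larger
  vs smaller amplitude profiles chosen by the user, with no physical model.

## Numerical choices and degenerate inputs

* PDB coordinates round-trip at the format's 10⁻³ Å precision; ragged MODEL
  blocks are a topology error naming the counts, malformed ATOM records a
  parse error naming the line. Chain-less files get chain "A".
* Residue numbering is taken verbatim from the PDB (no renumbering), so
  region tables and mutant labels refer to the author's numbering.
* Empty inputs: an empty design table yields an empty call set; an empty
  flagged set yields zero regions; `screen_stage()` of an empty table is an
  empty pass list; a top-k of 0 yields an empty (but successful) report.
* `rank_regions()` requires k ≤ number of regions and is permutation
  invariant in its input order.

## Test problem sizes

The suite validates closed-form recoveries at 2000 frames (σ√3 and ΔRMSF to
within 5 %/2 SEM), occupancy recovery at 100–1000 frames (exact in round
mode, binomial 99 % CI in Bernoulli mode), boundary detection of a planted
region at 1000 frames (±1 residue at 2.5× contrast), oracle equivalence of
the Kabsch RMSD against a rotation-grid brute force on 4-point toys (10⁻³ Å)
and of centroid selection against an exhaustive scan on 50-frame ensembles,
and ≥ 95 % per-residue agreement of the secondary-structure assignment with
`mdtraj`'s DSSP over ideal and perturbed geometries. These sizes were chosen
so each statistical tolerance is comfortably resolved while the whole suite
runs in well under a minute.

## Known limitations

* No mmCIF or binary trajectory formats (DCD/XTC) in this version; convert
  to multi-model PDB first.
* No mass weighting, no covariance/normal-mode analysis of fluctuations, no
  B-factor-based flexibility.
* The hydrogen-bond module is geometric only (no energetic definition
  outside the secondary-structure code) and does not analyse salt bridges or
  hydrophobic contacts.
* Secondary structure is three-state only; solvent accessibility is not
  computed.
* The generator's i.i.d. Gaussian model understates the tails and
  correlations of real conformational ensembles; treat recovered tolerances
  as estimator checks, not as MD realism.
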