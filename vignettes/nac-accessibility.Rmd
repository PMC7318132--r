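---
title: "Profiling P450 site-of-metabolism accessibility with near-attack conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling P450 site-of-metabolism accessibility with near-attack conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacprofiler)
```

## The model

Cytochrome P450 hydroxylation proceeds by hydrogen atom transfer (HAT)
from a substrate C−H bond to the oxo atom of Compound I, the iron(IV)-oxo
porphyrin cation radical. For the abstraction to be geometrically feasible
in a given conformation, the hydrogen must sit within bonding-approach
distance of the oxo atom and roughly along the Fe=O axis. `nacprofiler`
operationalizes this as the **near-attack conformation (NAC) criterion**:

* H–oxo distance within `[dMin, dMax]` = `[2.0, 3.5]` Å, bounds
  **inclusive**, and
* H–oxo–Fe angle strictly **above** `thetaMin` = 120°.

The defaults reflect the geometry of typical HAT transition states for
C−H hydroxylation: shorter than ~2 Å would already be covalent, beyond
3.5 Å no abstraction is initiated, and angles near the Fe=O axis
(180°) are electronically favourable while sideways approaches below
~120° are not. All three values are ordinary arguments of
`nacCriterion()`, in Å and degrees.

A **site of metabolism** (SOM) owns one or more candidate hydrogens: the
stereo-distinct hydrogens on one carbon (6α vs 6β) are *separate sites*,
while a methyl site (18, 19) owns its three equivalent hydrogens. A site is
*accessed* in a frame when at least one of its hydrogens satisfies the
criterion; the site then contributes exactly one **access event** for that
frame, carrying the accessible hydrogen with the smallest H–oxo distance
(ties broken by lowest atom index). Several distinct sites may each record
an event in the same frame.

The per-site **accessibility percentage** divides the site's event count by
the total number of events over the ensemble. With that denominator the
percentages always sum to 100, which is how stacked per-site accessibility
charts are normalized. The caption phrase "snapshots for all the accessed
sites" could also be read as *frames with at least one access*; both
normalizations are implemented (`denominator = "events"` (default) or
`"frames"`), and they differ only when two sites are exposed in the same
frame. No equilibration trimming is applied by default; `skipFrames` drops
leading frames when the input contains a pre-equilibration segment.

## Reactivity and the selectivity synthesis

Intrinsic reactivity is consumed as data: a per-site table of HAT
activation barriers (kcal/mol), plain (`dft`) and dispersion-corrected
(`d3`). The package ships the transcribed testosterone table of 11 sites
(1α/1β, 2α/2β, 6α/6β, 15α/15β, 8, 18, 19) together with the published
recombinant-CYP3A4 turnover rates for the four experimentally observed
sites; the same barrier set is reused for dihydrotestosterone analyses on
the grounds that corresponding sites on the shared steroid scaffold have
closely similar intrinsic reactivity. Quantum-chemical computation of
barriers is out of scope.

Barriers enter the ranking through Boltzmann weights at a configurable
temperature (default 298.15 K, gas constant fixed at
1.987204×10⁻³ kcal mol⁻¹ K⁻¹ for reproducibility), computed after
subtracting the minimum barrier so that arbitrary spreads cannot overflow.
The combined selectivity score is the normalized product

> score_s ∝ accessibility percentage_s × Boltzmann weight_s.

This product rule is an explicit extension of the qualitative
"accessibility gates reactivity" argument: no published quantitative
merging rule exists, so the package picks the simplest one with the right
limiting behaviour (zero accessibility or negligible reactivity both zero
the score, and the score is invariant to rescaling either factor) and
always reports the raw factors alongside. Sites present in the profile but
absent from the barrier table are reported with weight `n/a` and excluded
from the normalization, with a warning — silently dropping them would hide
data mismatches.

## Ensemble flexibility (RMSF)

`ensembleRmsf()` measures per-residue root-mean-square fluctuation across
an ensemble of structures sharing a residue numbering (e.g. a set of
crystal structures of one receptor): one designated atom per residue
(default `"CA"`, the standard choice giving one unambiguous value per
residue), all structures superposed onto the first by the Kabsch algorithm
on the common selected atoms, RMSF = RMS deviation from the ensemble-mean
position. Residues missing from any structure are dropped from fitting and
reporting with a warning, since real crystal sets differ in unresolved
loops. The output flags residues at or above 1.0 Å as flexible.

Two numerical notes. First, superposing on the same atoms being measured
slightly redistributes a single atom's displacement over the whole
ensemble, so closed-form expectations (one atom displaced by ±d/2 giving
RMSF exactly d/2) hold only without fitting; `fit = FALSE` is provided for
that purpose and for pre-aligned ensembles. Second, a rotational fit needs
at least three non-collinear common atoms; below that the function falls
back to centroid (translation-only) alignment.

## Trajectory input

Multi-model PDB is the exchange format: one `MODEL` block per frame, fixed
v3.3 columns, coordinates in Å. Only ATOM/HETATM/MODEL/ENDMDL records are
interpreted. Models are validated up front for identical atom counts and
order (the error names the offending model), and unparseable coordinate
fields are reported with their line number. Alternate locations resolve to
the highest occupancy, ties to the first encountered — crystal inputs need
*a* rule and this is the conventional one. Hydrogens must be present in
the input; the criterion is defined on explicit hydrogen positions and the
package performs no hydrogen building. Atom indices are 1-based throughout,
as is idiomatic in R; PDB serial numbers are preserved for reporting.

Assigning hydrogens to SOM labels is the user's job, via a YAML/JSON site
map of atom selectors with a stereochemical class
(`alpha|beta|methyl|other`). The α/β face labels are chemistry knowledge;
inferring prochirality from coordinates would require substantial extra
machinery (bond perception, CIP rules) for no gain in the analyses the
profiler performs.

## The synthetic generator

`simulateTrajectory()` produces ensembles with known ground truth over a
minimal toy active site (Fe at the origin, oxo at (0, 0, 1.62) Å — a
standard ferryl bond length — dummy substrate carbons, one atom per site
hydrogen). Per frame, one site or the no-access background is drawn from a
categorical distribution; one uniformly chosen hydrogen of the hit site is
placed at a *hit* geometry (distance uniform in 2.1–3.4 Å, angle uniform
in 125°–175°, azimuth uniform — strictly inside the criterion window so
that 3-decimal PDB round-trips cannot flip the classification), and every
other hydrogen at a *miss* geometry (either beyond 4 Å, or at
criterion-range distance but angle ≤ 110°, each with probability one
half — strictly outside the window on at least one dimension). The
closed-form ground truth is `percentage(s) = 100·p_s/Σp` and
`frames-with-access fraction = Σp`. An optional `coaccessProb` lets a frame
expose a second site, which is what makes the events-vs-frames denominator
distinction observable.

What the generator deliberately does **not** emulate: rigid-body substrate
dynamics (hydrogens move independently between frames), force fields,
thermostats, correlated frames, or a protein environment. Passing the
recovery tests therefore demonstrates that the *profiling statistics* are
implemented correctly — not that any MD protocol or binding-mode
prediction is validated. Output of the generator must not be mistaken for
molecular dynamics.

All randomness flows from a single seeded generator consumed in a
documented order (primary site draws, co-access draws, then per-frame
geometry), so a spec reproduces bit-identical coordinates across runs.

## Numerical choices and degenerate inputs

* Distance bounds inclusive, angle strict — "in the range of" vs "above".
* Points closer than 10⁻⁶ Å to an angle vertex raise an error rather than
  returning an arbitrary angle; the same guard rejects a hydrogen sitting
  on the oxo atom.
* `kabschSuperpose()` corrects reflections (rotation determinant always
  +1), so mirror-image point sets keep a positive RMSD; collinear or
  coincident point sets are rejected as having no unique fit.
* Fe–oxo separations outside (1.4, 2.2) Å trigger a warning, not an
  error: a drifting heme is a data-quality signal, and the analysis may
  still be wanted.
* An ensemble with zero access events yields an all-zero profile plus a
  warning rather than an error.
* Profile rows are ordered by descending percentage with lexicographic
  label tie-breaks; all writers are deterministic and atomic (temp file +
  rename), so interrupted runs leave no partial tables.

## Validation problem sizes

The test suite checks classifier-vs-brute-force agreement on 1,000 random
frames, criterion monotonicity and normalization on hundreds of simulated
ensembles, and parameter recovery at 10,000 frames for 10 seeds against
3·σ binomial bounds; the acceptance script repeats the brute-force
comparison and one 10,000-frame recovery at a user-supplied seed. These
sizes give binomial standard errors well under one percentage point for
the recovered percentages while keeping the whole suite comfortably fast
on a laptop.

## Known limitations

* Accessibility is a purely geometric criterion; it ignores electronic
  effects within a frame beyond what the barrier table carries, and the
  frames are treated as an unweighted sample (every frame is one
  snapshot).
* The product rule for combining accessibility with Boltzmann weights is a
  documented modelling choice, not an established observable; treat the
  ranking as a screen, and always inspect the raw factors it reports.
* The barrier fixture is substrate-specific (testosterone sites); analyses
  of other substrates need their own barrier table in the same TSV format.
* No binary trajectory formats (DCD/XTC/TRR) and no topology formats
  (PSF/PRMTOP); convert to multi-model PDB upstream.
* Per-residue RMSF uses one atom per residue; per-atom or heavy-atom RMSF
  is out of scope.
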