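---
title: "Alanine-scanning-guided assessment of antibody-antigen docking poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alanine-scanning-guided assessment of antibody-antigen docking poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abscan)
```

## The problem

When an antibody-antigen complex resists crystallography, a workable
structural model can still be assembled from two cheaper ingredients:
alanine-scanning mutagenesis, which identifies the residues whose side
chains carry the binding energy (hotspots), and data-driven rigid-body
docking, which proposes candidate poses consistent with those hotspots. The
weak link is pose selection -- docking engines return hundreds of poses and
their internal scores alone do not reliably pick the native-like one. The
workflow implemented here is the assessment side of that strategy, developed
around the FGF23-Burosumab system: FGF23 is the phosphate-regulating hormone
whose N-terminal beta-trefoil domain binds the D2/D3 domains of its receptor
FGFR, and Burosumab is the neutralizing therapeutic antibody that blocks
that interaction.

`abscan` implements every computational stage: exposure-based scan design,
binding-curve analysis with hotspot calling, restraint-scenario
construction, interface analysis of poses, receptor-blockage and
scan-concordance scoring, a seven-criterion filter-and-rank step, and
cross-species conservation analysis. Docking itself is out of scope: poses
and their energies are inputs.

## Solvent accessibility and scan design

Surface areas use the classic Shrake-Rupley construction: each heavy atom's
van der Waals sphere (Bondi-type radii; C 1.70, N 1.55, O 1.52, S 1.80 A,
fallback 1.8 A) is inflated by the probe radius (1.4 A, water) and covered
with `n_points` quadrature points; the accessible area is the exposed
fraction times the expanded-sphere area. Two numerical choices matter:

* **Deterministic lattice.** Points come from a golden-angle spiral, not a
  random cloud, so results are bit-reproducible without seeds. The price is
  a small orientation-dependent quadrature error: about 1-2% per atom at the
  default 960 points, under 0.5% at 5000. A seeded Monte-Carlo estimator
  (`monte_carlo_sasa`) with per-atom binomial standard errors serves as an
  independent cross-check; the suite verifies agreement within three
  standard errors and against the closed-form one- and two-sphere cases.
* **Hydrogens** are parsed and flagged but excluded from SASA and contacts
  by default, so files with and without protons give consistent answers.
* **Missing atoms** are tolerated: only atoms present contribute.

Relative solvent accessibility divides a residue's area by a per-type
reference maximum. The default reference is the published theoretical
Gly-X-Gly maxima (Tien et al. 2013); because the phrase "maximum RSA within
the structure" can also be read as normalising by the largest observed area
of each residue type in the structure at hand, that alternative is
implemented as `reference_set = "structure_max"`. The exposure threshold is
20% read *strictly* (a residue at exactly 20.0% is buried), which is the
stricter of the two readings of "more than 20%".

Scan design (`select_scan_positions`) proposes exposed CDR residues plus up
to two exposed framework residues flanking each CDR (the flank width is a
parameter; published scans of this kind include flanking positions, and the
56-position scan this package emulates is reproduced by the suite on a
fixture built to that size). Alanine, glycine and proline are excluded:
mutating A to A is vacuous, and G/P substitutions perturb backbone
conformation rather than side-chain contacts.

## Binding curves, fold changes and censoring

Indirect-ELISA dilution series (three-fold from 9 ug/mL, eight points, in
the emulated design) are fit with a four-parameter logistic,
`signal = bottom + (top-bottom) / (1 + (ec50/x)^hill)`, by
Levenberg-Marquardt least squares; the EC50 is used as the apparent Kd. The
published analysis reports "Kd from ELISA" without naming a model; 4PL/EC50
is the standard choice and is recorded in output metadata. Initialisation is
bottom = min signal, top = max signal, hill = 1, EC50 at the half-range
concentration, with hill bounded to [0.2, 5] -- robust on serial-dilution
designs.

A fit is *converged* only when all of these hold: the optimizer succeeded,
top > bottom, the EC50 lies between one tenth of the lowest and ten times
the highest tested concentration (otherwise no plateau was observed on that
side), the model explains at least 80% of the signal variance, and the
fitted amplitude exceeds both six residual standard deviations and the mean
observed signal. The last two guards exist because a knocked-out mutant's
curve is baseline plus noise, and unconstrained 4PL optimisation will
happily hallucinate a small-amplitude sigmoid out of such noise; for
indirect-ELISA signals, which rise several-fold over background when binding
is real, an amplitude below the mean signal is noise, not dose-response. A
consequence worth knowing: a hypothetical mutant so improved that the curve
is saturated at every tested concentration would also be flagged
non-converged rather than given a fabricated EC50.

Fold changes are `kd_mut / kd_wt` (or `A450_wt / A450_mut` in
single-concentration spot mode, defaulting to the higher of the two spot
concentrations, 1.2 ug/mL). A non-converged mutant fit is *censored* at the
bound (default 100) and reported as ">100", never as a number. Bins follow
the asterisk legend: below 2-fold unmarked, 2-10 `*`, >10-100 `**`, >100 or
censored `***`; 10.0 falls in `*` ("2 to tenfold" read inclusively) and
improvements (fold < 1) are unmarked. Hotspots default to bin `**` and
above, matching a scan in which ~10-fold losses and worse were carried
forward as docking restraints.

Restraint scenarios are built one per labelled epitope hotspot group plus
their union, with the paratope set held constant -- reproducing the
three-scenario design (D2-contacting {52, 124}, D3-contacting {76, 117,
108}, combined) exactly, as the suite checks.

## Interface analysis of a pose

Interface membership is by loss of accessibility: a residue is interfacial
when `SASA(side alone) - SASA(in complex)` is at least 0.1 Angstrom^2 (the
threshold suppresses lattice quadrature noise). Buried surface area uses the
half-sum "interface area" convention,
`(SASA_A + SASA_B - SASA_AB) / 2`, matching the scale on which published
interface areas of this system (about 860-920 A^2) were reported, and the
> 800 A^2 acceptability filter.

The per-region partition divides the *antibody-side* buried area among the
six Chothia CDRs and framework. Published percentages for this system close
to 100 over CDR + framework, which is what the antibody-side convention
produces; a partition over the whole interface would not. CDR boundaries are
the standard Chothia spans (H1 26-32, H2 52-56, H3 95-102, L1 24-34, L2
50-56, L3 89-97, insertion codes included), stored as data and overridable.
Scheme numbering is taken as given; automatic renumbering is deliberately
out of scope -- it is a solved problem in dedicated tools and error-prone to
re-implement.

Cross-molecule contacts are typed geometrically, each atom pair once with
the most specific applicable label: salt bridge (opposite formal charges
within 4.0 A) > hydrogen bond (two N/O atoms within 3.5 A) > attractive
charge (opposite charges within 5.6 A) > nonpolar (two carbons within 4.5
A). Ring-centroid (pi) interactions are folded into the attractive-charge
class; computing ring centroids was judged not worth the geometry for the
analyses this supports.

## The seven-criterion assessment

For each pose the criteria table carries: (1) receptor-blockage grade, (2)
binding energy (input metadata from the docking engine, never recomputed;
absent values stay absent), (3) percent concordance with paratope scanning,
(4) buried surface area, (5) %FWR, (6) %CDR, (7) %H3.

*Blockage* superposes the pose's antigen onto the antigen of a reference
antigen-receptor complex (Kabsch on shared C-alpha atoms -- the reference
superposition atoms are a config value, as the original analysis does not
state them) and measures what fraction of the receptor footprint the
antibody covers. Footprints are matched on residue number and insertion
code, chain-id-agnostic, since the antigen is the same molecule in both
structures. Grades: high at overlap >= 0.5, medium >= 0.2, low below --
invented cut-points, recorded in config, because the original assessment is
qualitative ("strong blockage"). Steric clashes with the superposed receptor
(atom pairs under 2.5 A) are counted and reported but do not enter the
grade; whether the original criterion also counted clashes is not stated, so
both numbers are exposed and only the overlap is graded.

*Concordance* is not defined by a formula in the source analysis; the
default here is balanced agreement, `100 * (TP + TN) / tested`, where a
tested paratope residue is experimentally positive when its bin reaches `*`
and predicted positive when it sits in the pose's antibody-side interface.
The mode is recorded in every report so an alternative (e.g. rank
correlation of dSASA against log-fold) can be distinguished if added.

*Ranking* is filter-then-lexicographic rather than a weighted composite: the
original selection is a qualitative dominance argument, and a documented key
order makes it reproducible. Filters: BSA strictly above 800 A^2, %CDR
within [50, 95], and optionally a minimum blockage grade. Survivors sort by
concordance (desc), blockage (desc), binding energy (asc, absent energies
after present ones), BSA (desc), pose id (asc, the final deterministic
tie-break). The suite checks that the published values of the three
top-scenario poses, with concordance and blockage entered in their stated
order, put pose27 first.

## Cross-species analysis

Ortholog pairs are aligned globally (Needleman-Wunsch with affine gaps,
BLOSUM62, gap open 10 / extend 0.5 -- the source names no parameters, these
are conventional defaults) through Biostrings; an independent hand-written
Gotoh dynamic program, itself validated by exhaustive alignment enumeration
on tiny inputs, cross-checks scores in the suite. Identity is computed over
aligned non-gap columns, and that denominator choice is recorded because
species-identity percentages depend on it; the published per-species
identity values are not reproduced since the domain boundaries behind them
are not stated. Differences are reported in reference (human) numbering;
gap columns are bookkept separately, never as differences. Back-mutation
proposals replace query residues by the reference residue at
epitope-restricted difference positions, with cumulative combination sets
accumulated in a caller-given priority order -- which reproduces the
published four singles (T49N, T76R, Q117H, A159S) and three combinations.

## What the synthetic generators emulate

The generators make every stage testable with ground truth and no external
downloads:

* `make_sphere_pair` -- two single-atom chains; SASA and BSA have
  spherical-cap closed forms, the sharpest oracle available.
* `make_fv_complex` -- a 30-residue antigen "line" against a two-chain mini
  Fv with Chothia-compatible numbering, one C-alpha plus one pseudo
  side-chain atom per residue (large enough for meaningful dSASA, small
  enough for sub-second SASA). Eleven constructed contacts span all six
  CDRs plus two framework flanks, echoing a framework contribution around
  15-20%; a pseudo-receptor chain occupying the same footprint provides the
  blockage reference.
* `make_pose_set` -- near-natives are small rigid perturbations (0.5 A, 5
  degrees); decoys re-dock the antibody back-face-first, the wrong-face
  failure mode that concordance and %CDR are designed to catch.
* `make_elisa_panel` -- 4PL curves on the three-fold-from-9 design with
  gaussian noise (sigma 0.02 by default, a realistic plate-reader scale
  given signals near 2.0).
* `make_ortholog_pair` -- planted differences with forced reference letters.

Each generator draws from its own RNG substream derived from the user seed
and the generator name, so adding a draw in one generator never shifts
another's output; identical seeds give byte-identical fixtures.

These toys are deliberately not protein-like: no secondary structure, no
packing, no chemistry beyond element radii. Passing tests therefore
demonstrate that the *computations* are correct and that the ranking logic
recovers planted structure; they do not demonstrate that the criteria would
pick the right pose for an arbitrary real system, which is an experimental
question the original validation mutants addressed.

## Problem sizes and degenerate inputs

The suite and the acceptance script run the end-to-end recovery at desk
scale: 20 poses per replicate, 20 replicates, 240 lattice points, and a
miniature complex of ~270 atoms; at this scale the toys bury 100-300 A^2,
so the end-to-end runs lower the BSA filter to 50 A^2 while keeping every
other threshold at its default. Curve-fit calibration uses 50 seeded
curves. Degenerate inputs are rejected loudly rather than patched:
superposition requires three non-collinear pairs, empty restraint sets and
panels without a wild type are errors, a pose missing any report is named,
and ranking an empty table is an error while an empty *passed* list (all
poses filtered) is a legitimate result.

## Known limitations

Avidity and bivalent-binding effects in ELISA-derived Kd values are not
modelled; the apparent Kd is the 4PL EC50. Canonical-class assignment,
homology modelling, loop reconstruction, protonation and the docking engine
itself are out of scope. The contact typology is geometric only -- no
angular criteria for hydrogen bonds and no ring geometry. Antigen sub-domain
labels (e.g. "beta8-beta9 hairpin loop") are user-supplied interval
annotations, not computed secondary structure.
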