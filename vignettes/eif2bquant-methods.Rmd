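---
title: "Quantifying eIF2B conformational antagonism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eIF2B conformational antagonism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eif2bquant)
```

## The scientific problem

eIF2B is the decameric guanine nucleotide exchange factor (GEF) that
recycles the translation initiation factor eIF2.  Phosphorylation of
eIF2's alpha subunit converts eIF2 from substrate into inhibitor: the
phosphorylated eIF2alpha N-terminal domain docks at two regulatory sites
between eIF2B's alpha and delta subunits and drives the complex into an
inhibited conformation, triggering the integrated stress response (ISR).
The small molecule ISRIB binds one symmetric pocket at the central
beta/delta-beta'/delta' interface and antagonizes this inhibition
allosterically: the ISRIB-bound conformation and the doubly
eIF2(alphaP)-bound conformation are mutually exclusive.

This package provides the three quantitative layers needed to analyse
that system:

1. **Conformational metrics** between multi-chain coordinate models
   (mmCIF/PDB): displacement and axis rotation of eIF2B-delta helix
   alpha3 (residues 247-267, the helix lining the substrate cleft), and
   the separation of the two half-shells of the ISRIB pocket.
2. **Regression models** for the kinetic and equilibrium assays used to
   measure the antagonism (exponential decays, biphasic BLI traces,
   saturation binding, logistic dose-response).
3. **An equilibrium linkage model** of one ISRIB site coupled to two
   eIF2(alphaP) sites, which doubles as the synthetic-data generator's
   ground truth.

## Structural metrics

### Frames, probes, and superposition

Every metric is a comparison of a *target* entry against a *reference*
entry after least-squares superposition on a *frame* selection.  The
default frame is the four C-terminal (Rossmann-like) domains of the
beta and delta subunits, which move little between states; the probe is
helix delta-alpha3 or the ISRIB-pocket shell.  Superposition uses the
Kabsch SVD solution with a determinant correction so the transform is
always a proper rotation; inputs with fewer than three pairs or a
collinear configuration are refused.  An independent quaternion
(Horn) eigen-decomposition oracle in the test suite checks the RMSD on
random paired clouds to 1e-8.

Because the boundaries of the beta/delta C-terminal domains are not part
of the deposited annotations, the frame ranges are configuration, not
fact: `default_frame_ranges()` ships approximate human-subunit
boundaries (beta 140-330, delta 300-510) and users should calibrate
them so the beta-subunit alignment RMSD between the apo and
doubly-bound entries reproduces its published value (0.7 Angstrom);
`validate_against_targets()` carries that check as a dedicated row.

### Helix axis and rotation

The helix axis estimator smooths each C-alpha with its two sequence
neighbours (suppressing the ~100 degree helical wobble) and takes the
principal component of the smoothed trace, oriented N- to C-terminus.
On ideal 21-residue helices the estimator is accurate to better than
0.5 degrees, and to ~2 degrees under 0.3 Angstrom coordinate noise.
The rotation between two entries is the unsigned angle between their
N->C-oriented axes after frame superposition, in [0, 180] degrees.  The
direction label compares the helix centroid's distance to the
same-protomer beta-subunit C-alpha centroid before and after:
"toward_beta" / "away_from_beta", with changes below 0.05 Angstrom
reported as "n/a".

### Pocket deformation

The ISRIB-pocket metric needs a shell definition even for entries that
lack the ligand, so shell membership (C-alpha atoms within 10 Angstrom
of any ligand atom) is computed once in the designated ligand-bearing
reference entry and transferred to other entries by (role, protomer,
residue number).  The two protomers' half-shells are then treated
asymmetrically: structures are aligned on one unit's shell atoms and
the mean displacement of the *other* unit's shell atoms is reported.
Both alignment orientations are available because the published
analyses do not say which unit anchored the alignment.

### Conventions for missing data and protomers

Cryo-EM models have unmodelled loops, so paired selections keep only
residues resolved in both entries (the n used is reported); selections
resolving less than half of a requested range carry a low-coverage
warning, which the pocket metric escalates to an error.  Published
values do not state which protomer copy was measured, so metrics are
computed for both protomers plus their mean, validation compares the
better-matching value, and a discrepancy flag is raised when the two
copies disagree by more than 1 Angstrom (1.5 degrees for rotations).
Author residue numbering is primary (it matches the human delta
247-267 convention); label numbering is retained and selectable.

## Regression models

The seven assay models are implemented exactly as printed by the
analysis software used in this field (evaluate -> fit round trips are
tested to 1e-6 relative).  Fitting is unweighted nonlinear least
squares via Levenberg-Marquardt (`minpack.lm::nlsLM`) with data-driven
starting values (first/last signal for the plateaus, a log-linearized
rate estimate, half-span crossing for LogIC50) and five deterministic
jittered restarts; the best converged fit wins.  95% confidence
intervals are t-based on the asymptotic standard errors, matching
common practice for reported binding constants; at 2% noise each true
parameter falls in its own 95% CI in >= 90 of 100 simulations for
every model (tested).  Two conventions are worth noting:

* **Biphasic labels.** KFast/KSlow are exchangeable in the likelihood;
  fits are normalized so KFast >= KSlow, with PercentFast mapped to
  100 - PercentFast on swap.
* **Logistic orientation.** As printed, the four-parameter logistic
  runs from Bottom (low X) to Top (high X) when HillSlope is positive;
  a decreasing inhibition curve therefore fits with the plateaus
  mirrored or a negative slope.  The two parameterizations trace the
  identical curve with the same LogIC50, so derived IC50s are
  orientation-independent and Hill slopes should be compared in
  magnitude.
* **4PL X convention.** X is log10(concentration); a flag transforms
  linear-concentration input explicitly rather than guessing.

Derived quantities: half-life = ln(2)/K with the CI propagated from
K's interval, IC50 = 10^LogIC50, and the %Fast-versus-concentration
EC50 obtained by fitting the hyperbolic agonist-response model to the
fast-phase fractions of a series of biphasic dissociation fits.  A
window option restricts fits to an initial time span (dissociation
fits are conventionally taken over the first minutes before slow
processes intrude).

## The linkage model

States are indexed (i, j): i ISRIB molecules (0 or 1) and j
eIF2(alphaP) molecules (0, 1, 2) bound.  Statistical weights follow
the binding polynomial

  w(i, j) = (K_I I)^i B_j(P) g1^(i[j=1]) g2^(i[j=2]),

with B_0 = 1, B_1 = 2 K_P1 P (two equivalent sites), and
B_2 = K_P1 K_P2 c_P P^2.  Populations are normalized weights; GEF
activity is the population-weighted mean of per-state activities with
the ground state fixed at 1.  The model is an *equilibrium* treatment:
the assays it emulates are steady-state or slow-relaxation readouts
and no rate constants for the allosteric coupling have been measured,
so kinetic realism is out of scope.  Time courses of kinase-driven
phosphorylation assume binding equilibrates fast relative to
phosphorylation: [alphaP](t) = total (1 - exp(-k_phos t)), with the
probe signal read off the instantaneous equilibrium.

The default parameter set is illustrative, not fitted (the underlying
experimental curves are not numerically deposited): K_I = 0.1 /nM
(the ~10 nM ISRIB affinity scale), K_P1 = K_P2 = 4 /uM (the ~0.25 uM
inhibition scale), c_P = 20, g1 = 0.5, g2 = 0.01, activities
(ground, I, II, III, IV) = (1, 0.5, 0.05, 0.5, 0.05).  Whether the
doubly-inhibited ISRIB-bound state is merely rare or strictly
forbidden is not established; g2 is therefore a free knob (g2 = 0 is
allowed) rather than a committed choice.  Useful exact properties:
populations sum to 1 to 1e-9 at any input; with g1 = g2 = c_P = 1 the
ISRIB occupancy factorizes to K_I I / (1 + K_I I) exactly; the
apparent Hill slope of a simulated competition curve exceeds 1 only
when two-site binding is effectively cooperative and never
meaningfully exceeds 2 (two sites).  The desensitized-mutant
transform divides both K_P constants by a factor d and leaves K_I
untouched, mirroring regulatory-site mutants that retain wild-type
ISRIB binding; d = 10 right-shifts the apparent IC50 about 10-fold.
By default ligand depletion is ignored (the fluorescent probe is used
far below its K_d); a depletion-aware solver (conservation equations,
bisection on the free concentrations) is available when receptor and
ligand concentrations are comparable.

## Synthetic data: what it emulates and what it does not

`make_decamer_fixture()` builds a ten-chain, two-protomer toy assembly
from ideal alpha-helices: per-role synthetic sequences (so sequence
-based subunit assignment is exercised for real), a delta chain
carrying an "alpha3" helix at residues 247-267, beta/delta "C-terminal
domain" segments used as the frame, and a dummy ligand at the protomer
interface whose 10-Angstrom shell contains beta and delta atoms of
both units.  The geometry is deliberately non-physical - it validates
parsing, assignment, selection, superposition and metric code, not
biology; passing tests say nothing about, e.g., how well the default
frame ranges suit real deposited models.  The random seed draws only a
global rigid placement of the whole assembly, so internal geometry is
seed-invariant and the metric pipeline's invariance under global
motion is tested for free.

`perturb_fixture()` applies rigid motions to chain groups and records
analytically expected metrics: mean displacement as the closed-form
mean of |R(x-c)+c+t-x| over the group's C-alpha atoms, and axis
rotation as the angle between the helix axis and its image under R
(both computed from the injected transform, not by comparing
structures).  `motion_for_metrics()` inverts this: given a target
displacement and rotation it tilts the helix about an in-plane axis
through its centroid and solves for the translation magnitude along
that tilt axis by bisection, so the measured metrics equal the
requested values exactly.  The tilt axis is chosen perpendicular to
the helix axis as the package's estimator defines it; the estimator's
own correctness is established separately against constructed helices
with known axes.  `synthetic_target_suite()` uses this to build one
fixture pair per published structural value (3.2 A / 7.9 deg, 2.8 A /
8.1 deg, 1.1 A / 2.3 deg, 2.4 A, 0.6 A, 0.7 A beta-RMSD, and pocket
separations 2.2 / 0.4 / 0.3 A), giving a download-free end-to-end
check of the measurement pipeline at exactly the magnitudes of
interest.  Reproducing those numbers from the deposited accessions
themselves additionally requires `fetch_structures()` (network) and
real per-subunit reference sequences supplied by the user.

Signal traces are generated as Y = model(X; truth) + N(0, sigma) with
a local seeded RNG (the global RNG state is untouched; same seed,
identical trace).  Simulated assays follow the conventions of the
experiments they mirror: signals are means of three technical
replicates, kinetic grids sample the fast phase densely, titrations
are two-fold dilution series spanning the transition.

## Problem sizes and numerical choices

Test and acceptance workloads are sized for interactive use: 100-draw
Monte-Carlo coverage studies per model (n = 30 points per trace, 2%
noise), 100 random cloud pairs for the superposition oracle, 16-point
titrations for linkage curve fits, and single fixtures of ~700 atoms
for the structural suite; the full no-download validation completes in
well under two minutes.  Tolerances follow the sources of error:
1e-6 for noiseless generative identities, 1e-8 against the
superposition oracle, 1e-9 for population conservation, and +-0.3
Angstrom / +-1.5 degrees when comparing against published
conformational values (printed to one decimal, with frame-range
ambiguity contributing systematic spread).  mmCIF coordinates are
written at the format's conventional three decimals, so write/read
round trips agree to 1e-3 Angstrom.

## Known limitations

* Chain-to-role assignment needs reference sequences; none are bundled
  for the real human subunits, so users must supply them (e.g. from
  their own records) when analysing deposited entries.
* The frame-domain boundaries for real entries are calibration config;
  the shipped defaults are approximate and must be validated via the
  beta-RMSD check before the displacement numbers are quotable.
* The linkage model treats eIF2B as a rigid two-site receptor: no
  decamer assembly equilibria, no explicit kinetics, no fitting of the
  coupling constants to experimental curves.
* Fits are unweighted; heteroscedastic traces (common late in BLI
  dissociations) are the user's responsibility to window.
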