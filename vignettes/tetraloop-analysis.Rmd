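---
title: "Methods: state classification, folding thermodynamics and NMR scoring for UUCG tetraloop ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state classification, folding thermodynamics and NMR scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrafold)
```

# The system and the analysis model

The UUCG tetraloop caps an A-form stem with four loop nucleotides
(U6, U7, C8, G9 in the 14-mer numbering used throughout). Its native
fold is held by four contacts: the trans-wobble G9·U6 pair through
G9(N1H)···U6(O2), two sugar–base hydrogen bonds
U6(2′-OH)···G9(O6) and U7(2′-OH)···G9(N7), and the 7BPh base–phosphate
contact C8(N4H)···U6(pro-R_P). G9 adopts the unusual *syn* glycosidic
conformation. This package implements, as tested reusable code, the
analysis stack used to characterize ensembles of this system: a
rule-based state classifier, the εRMSD folded/unfolded partition with
two-state thermodynamics, and NMR back-calculation with a χ² score.

All criteria operate on heavy atoms only (donor–acceptor distances),
which makes the pipeline independent of protonation and hydrogen naming.

# State classification

`extract_features()` reduces a frame to eight numbers: five monitored
donor–acceptor distances (G9 N1–U6 O2, G9 N2–U6 O2, U6 O2′–G9 O6,
U7 O2′–G9 N7, C8 N4–U6 OP1), the glycosidic torsion χ(G9) over
O4′-C1′-N9-C4, and superposition RMSDs of (a) all heavy atoms of the
four loop residues and (b) all heavy atoms of all residues, each
against the user-supplied reference (the equilibrated starting/native
structure). `classify_frame()` applies the published clustering
criteria — thresholds 3.5 / 3.7 / 4.0 / 4.2 / 5.0 / 5.2 Å for the
distances, 3.0 / 4.6 Å for the two RMSDs, and the *syn* window
[−25°, 115°] — with these documented conventions where the printed
rules are silent:

* **Precedence.** Only two overrides are stated by the source criteria:
  the stem+loop rule (all-atom RMSD > 4.6 Å) overrides everything, and
  the U6+U7+C8-bulge state is carved out of loop-disrupted. We
  evaluate: stem+loop first; then the states ordered from least to most
  disrupted (native, sugar-base(N7) lost, 7BPh lost, both sugar-base
  lost, C8 bulge, G9 bulge *syn*, G9 bulge *anti*, G9 back-in-pocket
  *anti*, U6+U7+C8 bulge); then loop-disrupted; else `unclassified`.
  This honors both printed overrides and resolves the (rare) overlap in
  which a frame satisfies both the C8-bulge and G9-bulge patterns.
* **Strict inequalities.** Printed `<` and `>` are applied strictly;
  equality falls through to later rules. The effect is measure-zero on
  continuous features but makes the decision table unambiguous.
* **Window endpoints.** The *syn* window is closed at −25° and 115°;
  *anti*/high-*anti* is its exact complement, so the two windows
  partition the circle and every χ receives exactly one label.
* **`unclassified`.** The printed criteria do not cover all of feature
  space (for example U7 O2′–G9 N7 > 4 Å with the 7BPh distance between
  3.7 and 5 Å and low loop RMSD). Such frames get an explicit label
  rather than nearest-state imputation, so populations remain
  auditable.

The classifier is a total function: tests check it against an
independently coded decision-table oracle on an exhaustive
threshold-straddling grid (41 472 combinations) and on 10⁵ random
feature vectors.

# εRMSD and the folded indicator

Each base carries a local frame: origin at the centroid of its
six-membered ring, z along the ring normal (right-handed around the
N1→C2→…→C6 cycle), x toward C2 projected into the plane. For every
ordered residue pair the inter-base vector, expressed in the first
base's frame, is scaled by the ellipsoid (a, a, b) = (5, 5, 3) Å and
mapped through the smooth four-component G function with cutoff 2.4
(scaled units), γ = π/2.4; εRMSD is the root-mean-square G difference
over pairs divided by the residue count. Conformers with εRMSD < 0.7
against the native reference count as folded; 0.7 is the published
threshold separating folded from un(mis)folded ensembles.

In-plane axis conventions differ between implementations of this
metric; ours is fixed, documented, and applied identically to both
structures, which is what the metric requires. The test suite pins the
arithmetic with a hand-computed two-ring oracle (1e−9) and the
identity/symmetry/rigid-invariance properties.

# Two-state thermodynamics

`dg_fold()` is the package's central estimator and returns a classed
object with `print`/`summary`/`coef`/`confint` methods. The folded
population p (optionally weighted by user-supplied unbiasing factors;
runs concatenated in order) maps to
ΔG°_fold = −RT ln(p/(1−p)) with R = 0.0019872 kcal mol⁻¹ K⁻¹ and
T = 298 K by default. Errors come from a block bootstrap: 16
contiguous equal blocks over the concatenated series (remainder frames
join the last block, preserving within-block autocorrelation), 1000
resamples, and 2.5/97.5 percentiles of the resampled populations;
the percentile convention is recorded in the object because the source
description ("higher and lower boundaries") does not fix one.
Populations of exactly 0 or 1 make ΔG unbounded; the estimator then
reports the bound with a warning instead of a number, and
`population_to_dG()` raises a classed error.

Calibration (tested): on iid Bernoulli series (n = 16 000) the
bootstrap SE agrees with the analytic binomial SE within 25% averaged
over 50 seeds, and on synthetic two-state ensembles with known p* ∈
{0.1, 0.5, 0.9} (n = 4000, 50 seeded repetitions each) the percentile
interval covers the generating ΔG(p*) in ≥ 90% of runs, pooled over
the three p* values — the stable reading of per-p* coverage at this
repetition count.

# NMR back-calculation and χ²

³J couplings use the Karplus relation J = A cos²(θ+Δ) + B cos(θ+Δ) + C
per frame, averaged with the frame weights. Coefficient sets are
configuration data (`default_karplus_sets()`), shipped with two
literature defaults (sugar H-C-C-H: 9.67/−2.03/0.68 Hz; backbone
H-C-O-P: 15.3/−6.1/1.6 Hz) and a phase offset column standing in for
the proton position on the heavy-atom torsion — the scorer never
hard-codes coefficients, and any consistent offset is self-consistent
between generator and scorer. NOEs are compared as effective distances
r_eff = ⟨r⁻⁶⟩⁻¹ᐟ⁶; ambiguous NOEs sum 2–4 pair contributions inside
the frame average. Comparison in intensity space is out of scope.

The per-class χ² is the mean squared σ-normalized residual; the total
is the weighted arithmetic mean over classes with weights equal to the
class observable counts (63/33/253/27 by default, overridable), which
makes the default total the grand mean squared residual. The published
χ² range on the real NMR dataset is not reproducible here — the exact
experimental table and the original weighting details live outside
this package — so the tests validate the scorer statistically instead:
noiseless self-consistency gives exactly 0, and noise drawn at the
stated σ gives a mean total χ² within 3·√(2/376) of 1 over 20 seeds.

# Synthetic data: what it emulates and what it does not

`build_reference_scaffold()` constructs a deterministic 14-residue
hairpin: idealized planar bases (regular hexagons, fused pentagons for
purines), pentagonal riboses, a short phosphate tail, the loop placed
so every native criterion holds by a comfortable margin (contacts at
2.9 Å, 7BPh at 3.2 Å, χ(G9) = +20°), and twisted stem stacks giving
the εRMSD reference a dense contact set. It is a geometric fixture
emulating the equilibrated starting structure — *not* a model of the
experimental coordinates: sugars are planar (zero pucker amplitude by
construction), bond geometry is idealized, and no energetics are
implied. Any real native structure can be supplied instead wherever a
reference is accepted.

`generate_state_conformer()` perturbs the scaffold with targeted rigid
moves (pulls along contact vectors, pivots about hydrogen-bond atoms,
glycosidic rotation of G9, per-residue scrambling) plus Gaussian
jitter (0.05 Å default), then verifies the frame through the
classifier, retrying up to a bounded number of draws (200) and failing
loudly otherwise. `generate_two_state_ensemble()` mixes jittered-native
and extended conformers by a Bernoulli(p*) draw; extended chains place
residues 13 Å apart so every inter-base vector exceeds the εRMSD
cutoff, making the unfolded εRMSD robustly above threshold. For
large-n statistical calibration the `coordinates = FALSE` switch
returns the identical indicator process without building coordinates;
the coordinate-level contract (ground truth equals `is_folded()` on
every frame) is tested at moderate n. Because the generators sample
feature-space regions rather than physical pathways, passing tests
demonstrate correctness of the *analysis* — not force-field realism,
kinetics, or the conformational preferences of real RNA.

Problem sizes used by the shipped tests — 41 472-point classifier
grid, 10⁵ random vectors, 25 seeds × 11 states, n = 16 000 and
3 × 50 × 4000 bootstrap series, 20 χ² seeds at 376 observables — were
chosen as the smallest sizes at which the statistical assertions are
stable.

# Numerical choices and degenerate inputs

* Torsions follow the IUPAC sign convention (cis = 0°), reported on
  (−180°, 180°]; collinear bonds raise a degenerate-geometry error.
  The signed torsion is invariant under reading the four atoms
  backwards, and the tests assert exactly that identity.
* Superposition uses the closed-form SVD rotation with a determinant
  guard excluding reflections; selections under three atoms are
  rejected as under-determined.
* The pseudorotation phase follows the Altona–Sundaralingam
  convention (ν2 = τ_m cos P); zero amplitude (as in the scaffold's
  deliberately planar sugars) is an error, not a number.
* Block construction assigns remainder frames to the last block;
  resampling is seed-reproducible via an internal RNG scope that never
  leaks into the caller's random state.
* One-decimal reporting uses round-half-away-from-zero
  (`round_half_up()`), the convention under which the reported
  free-energy tables are reproduced; full precision is retained
  internally.

# Interfaces and limitations

Structures enter as (multi-model) PDB through `read_structures()`
(bio3d underneath), with atom-name dialects normalized (O1P/O2P →
OP1/OP2, asterisk primes → apostrophes). `run_pipeline()` composes
classification, εRMSD, thermodynamics and χ² and writes
CSV/JSON reports that embed every threshold used. Binary trajectory
formats, MD/enhanced-sampling execution, metadynamics bias
computation (weights are accepted, not derived), kinetic models,
Leontis–Westhof edge annotation and Karplus coefficient fitting are
out of scope. Modified residues are rejected rather than guessed at
the base-frame stage.
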