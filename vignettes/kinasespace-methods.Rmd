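---
title: "Methods: chemical-space and ring-system analysis of kinase inhibitor libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-space and ring-system analysis of kinase inhibitor libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the analysis

Protein kinase inhibitors (PKIs) are a structurally narrow class: most are
flat, fused-heteroaromatic ATP-site binders whose rings hydrogen-bond to
the kinase hinge region. `kinasespace` implements the comparative
profiling used to characterize that chemical space: descriptor
distributions and drug-likeness rules, mean ± 2 SD design guidelines,
correlation-metric PCA, principal-moments-of-inertia (PMI) shape
analysis, Bemis–Murcko scaffold and graph-framework diversity, and a
ring-system ensemble classification with typed attachment points.

Every stage takes a tibble and returns a tibble, so an analysis is a
dplyr pipeline:

```{r}
library(kinasespace)
mols <- read_molecules("inhibitors.smi", label = "CLINICAL_PKI") |>
  standardize_molecules() |>
  deduplicate_molecules()
desc <- compute_descriptors(mols)
```

## Standardization and molecular identity

Standardization keeps the largest organic fragment (by heavy-atom count;
a fragment is organic when it contains carbon), neutralizes formal
charges where a neutral form exists, and emits canonical SMILES. This
removes counter-ions such as the bromide of tarloxotinib-type salts. The
operation is idempotent: re-standardizing a standardized structure is a
no-op, and the test suite asserts this over seeded libraries.

Two decisions here were genuinely open:

* **Tautomers.** The package does not enumerate tautomers. Molecular
  identity for deduplication is the standard InChIKey, whose
  mobile-hydrogen layer already collapses common tautomers of one parent
  structure; the canonical SMILES keeps the tautomer as written.
  Stereoisomers keep distinct keys and are treated as distinct drugs.
* **Identity is stereo-sensitive** because clinically distinct PKIs can
  differ only in configuration.

## Descriptor panel

Twelve descriptors per molecule: MW (Da), ClogP (Wildman–Crippen atom
contributions), TPSA (Ertl, Å²), HBA, HBD, NRB, NHA, NAR, NCA, FCSP3,
MQN8, MQN10. Conventions that needed fixing:

* **HBA/HBD** use the rule-of-five counting convention (N+O and NH+OH),
  the convention under which the thresholds were originally stated.
* **NRB** counts acyclic single bonds between two non-terminal heavy
  atoms, excluding bonds adjacent to a triple bond (the axis of an
  alkyne adds no conformational freedom).
* **NCA** counts potential tetrahedral stereocenters — sp³ carbons with
  at most one hydrogen whose substituents fall in pairwise distinct
  graph-symmetry classes — whether or not a configuration is assigned,
  because deposited PKI structures frequently omit stereo annotations.
  Nitrogen or sulfur centers are not counted.
* **MQN8/MQN10** are read as components 8 and 10 (1-based) of the
  published 42-component Molecular Quantum Numbers vector, i.e. the
  acyclic nitrogen and acyclic oxygen counts. The choice is a documented
  interpretation; the components are plain atom counts either way.

Rule profiling treats every threshold as a strict inequality (MW > 500
violates; MW = 500 complies). Violation classes 0/1/2/>2 partition the
set exactly.

**Guidelines.** For each descriptor the guideline range is the sample
mean ± `k_sd` sample standard deviations (n−1 denominator; the data are
a sample of PKI space), defaulting to `k_sd = 2`, i.e. 95.4% coverage
under normality. Lower bounds of count descriptors are clamped at zero,
and a rounded presentation form (floor/ceiling integers for counts) is
reported alongside the unrounded bounds.

## PCA

The PCA is correlation-metric: variables are centered and scaled to unit
variance, so the correlation circle is meaningful and a variable's
coordinates on two components are its correlations with them. Component
signs are fixed deterministically (largest-magnitude loading positive)
so that snapshots and cross-run comparisons are stable. Contributions
are `100 · loading²` per component (loadings are orthonormal, so columns
sum to 100%). Class ellipses in the PC1/PC2 plane are Gaussian
chi-square ellipses at the 0.95 quantile (2 df) of the per-class score
mean and covariance; the estimator is a package decision, validated by a
coverage test (95% ± 0.7% on an isotropic Gaussian class at n = 10⁴).
Constant variables are rejected by name rather than silently dropped.

## PMI shape analysis

Conformers are generated with the ETKDG distance-geometry method and
minimized with MMFF94, through RDKit driven as a subprocess; `n_confs`
seeded embeddings are generated per molecule (default 10) and the
lowest-energy conformer is kept. The embedding is deterministic given
(structure, n_confs, seed). OpenBabel's conformer search was rejected
for this stage because it cannot be seeded and violates that contract.

The inertia tensor is mass-weighted about the center of mass, with
explicit hydrogens included (mass-weighted moments require them);
whether to mass-weight was left open by the conventions in the field,
and mass-weighting is the package's documented choice. Sorted
eigenvalues I₁ ≤ I₂ ≤ I₃ give NPR1 = I₁/I₃ and NPR2 = I₂/I₃. All
points lie in the triangle with vertices (0,1) rod, (0.5,0.5) disc,
(1,1) sphere, represented physically by diacetylene, benzene and
adamantane, which `pmi_table()` appends as labelled reference rows. The
computation is verified against a brute-force tensor oracle at 1e-8
relative tolerance and is rotation/translation invariant by
construction.

## Scaffolds and graph frameworks

The Bemis–Murcko scaffold keeps ring atoms and linkers (computed by
iteratively pruning non-ring atoms of heavy degree ≤ 1) plus any atom
attached to that core by a double or triple bond — so the indolin-2-one
carbonyl stays in the scaffold of sunitinib-type inhibitors. Acyclic
molecules have an empty scaffold. The graph framework turns every atom
into carbon and every bond into a single bond; scaffold equality is
string equality of one fixed canonicalizer's output, and both sides of
any comparison are re-canonicalized first.

Macrocycles are molecules whose smallest-set-of-smallest-rings contains
a ring of more than 12 atoms; fused envelopes that are not smallest
rings (naphthalene's 10-ring) do not count.

Diversity statistics report unique scaffold/framework counts with
percentages and the pairwise MACCS/Tanimoto similarity mean and sample
SD within the molecule set (the pair population is within-dataset, a
documented interpretation).

## Ring-system ensembles

Ring atoms are grouped by fusion: rings sharing at least one atom —
ortho-fused, bridged, or spiro — form one system; rings joined by an
acyclic bond are separate. Spiro inclusion is a convention choice
(atom-sharing rather than bond-sharing fusion), made so that "fused"
has a single graph-theoretic definition.

* The **unpositioned** encoding deletes everything outside the system,
  including exocyclic double-bonded atoms, and re-perceives aromaticity:
  stripping the oxindole carbonyl leaves the non-aromatic indoline, not
  indole.
* The **positioned** encoding keeps first-shell context: an atom
  double-bonded to the system is retained unchanged; any other attached
  atom becomes a dummy typed by precedence halogen `[4*]` > aromatic
  `[3*]` > non-aromatic ring `[2*]` > generic `[1*]`. The precedence
  makes the four classes a partition. "Not double bonded" is read as
  "not double-bonded to the system": an acyl carbon bound to the ring by
  a single bond is class 1 regardless of its own C=O. Dummy classes are
  serialized as isotope labels because they survive SMILES/SDF round
  trips bit-exactly.

Bicycle statistics count per occurrence (a molecule with two quinazoline
systems contributes two), rank deterministically (count descending, then
lexicographic key), and report totals, unique counts and singletons.
Prevalence is the molecule-level fraction containing at least one
two-ring system.

## Synthetic libraries and what they do (not) show

`generate_library()` decorates a hand-annotated scaffold pool
(quinazoline, quinoline, indole, oxindole, purine, benzene, and a
13-membered macrocycle, mirroring the bicycles that dominate PKI space)
with substituents chosen to exercise all four attachment classes
(methyl/methoxy/dimethylamino, cyclohexyl, phenyl, halogens). Default
multiplicities plant 65% bicycle prevalence, a singleton bicycle and a
small macrocycle fraction — the regime reported for clinical PKI sets.
All ground truth is recorded from the construction: ring metadata is
hand-annotated in the pool (including oxindole → indoline), MW/HBA/HBD
flags come from atomic arithmetic, and the ClogP flag comes from an
independent Wildman–Crippen implementation (RDKit) with guard bands
(|logP−5| > 0.25, |MW−500| > 0.5 Da, enforced by re-decoration) so that
implementation-level rounding can never flip a planted rule flag.

What passing planted-truth tests shows: the decomposition, encoding,
counting and rule logic are exact on molecules whose answer is known by
construction. What it does not show: coverage of exotic real-PKI
chemistry — charged heterocycles, complex fused macrocycles, tautomeric
ambiguity — which the generator deliberately avoids; conclusions about
real libraries rest on the fixture-based oracle tests plus these
planted recoveries, not on distributional realism.

`generate_descriptor_table()` draws multivariate-normal descriptor
tables with requested moments for the PCA and guideline tests;
`plant_violation_table()` constructs descriptor rows with exact
violation-class counts.

## Numerical choices and problem sizes

Tolerances: inertia oracle 1e-8 relative; PCA eigen-oracle 1e-6 at
n = 10⁴; streaming-similarity vs brute force 1e-12; coverage checks
±0.6–0.7 percentage points at n = 10⁴. Ties in frequency tables break
lexicographically; Butina clustering (leader algorithm on ECFP4,
distance threshold 0.6 by default) is input-order dependent by design
and documented as such; similarity means/SDs are permutation-invariant.
Degenerate inputs error early with named messages (constant PCA
variable, coincident atoms, singleton similarity sets).

The validation suite runs libraries of 100–150 molecules across ten
seeds, 10⁴-row Gaussian tables, and conformer batches of 100 molecules
at 2 embeddings each — sizes chosen so the whole suite completes in a
few minutes while keeping every statistical check at its stated
tolerance.

## Known limitations

* Aromaticity, canonicalization and InChIKeys follow OpenBabel's models;
  other toolkits may perceive borderline heteroaromatics differently.
  Cross-toolkit canonical equality is not claimed — all comparisons
  re-canonicalize both sides with the same engine.
* The standardizer's tautomer handling is identity-level (InChIKey),
  not structural; a preferred-tautomer picker could change a small
  number of scaffold assignments on real data.
* NCA is a graph-symmetry heuristic, not a full CIP analysis; fused-ring
  pseudo-asymmetry can be miscounted.
* The bioactivity filter trusts its caller-supplied kinase flags; no
  target taxonomy is resolved.
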