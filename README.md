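# kinasespace

Chemical-space and scaffold-diversity analysis of protein kinase
inhibitor (PKI) libraries, for computational and medicinal chemists who
need to compare a candidate set against the space of approved and
clinical kinase inhibitors.

Protein kinase inhibitors are a structurally narrow drug class: mostly
flat, fused heteroaromatic cores that hydrogen-bond to the kinase hinge
region. `kinasespace` implements the standard comparative profile of
that space:

* **Standardization & identity** — largest organic fragment, charge
  neutralization, canonical SMILES, InChIKey-based deduplication.
* **Descriptor panel & rules** — MW, Wildman–Crippen ClogP, TPSA (Å²),
  HBA/HBD (N+O / NH+OH), NRB, NHA, NAR, NCA, FCSP3, MQN8/MQN10;
  Lipinski (MW > 500, ClogP > 5, HBA > 10, HBD > 5) and Veber
  (TPSA > 140, NRB > 10) violation profiles; **design guidelines** as
  mean ± 2 SD ranges per descriptor (95.4% coverage under normality).
* **PCA** — correlation-metric PCA of the 10-descriptor panel with
  explained variance, per-variable contributions
  (100·loading²), correlation circle, and 95% chi-square class
  ellipses in the PC1/PC2 plane.
* **PMI shape analysis** — seeded ETKDG conformers minimized with
  MMFF94; mass-weighted principal moments I₁ ≤ I₂ ≤ I₃ and normalized
  ratios NPR1 = I₁/I₃, NPR2 = I₂/I₃ in the rod–disc–sphere triangle
  (diacetylene, benzene, adamantane vertices).
* **Scaffolds** — Bemis–Murcko scaffolds (rings + linkers, exocyclic
  double-bonded atoms retained), graph frameworks (all-carbon,
  all-single-bond skeletons), macrocycle detection (SSSR ring > 12
  atoms), diversity statistics with MACCS/Tanimoto similarity, and
  cross-dataset scaffold matching.
* **Ring-system ensembles** — fused ring systems (atom-shared fusion,
  spiro included) in an *unpositioned* encoding (substituents → H,
  aromaticity re-perceived: oxindole's system becomes indoline) and a
  *positioned* encoding with typed attachment dummies
  (`[1*]` generic, `[2*]` non-aromatic ring, `[3*]` aromatic,
  `[4*]` halogen; double-bonded atoms retained unchanged), with
  occurrence/frequency/singleton statistics for bicycles.
* **Similarity & clustering** — streaming pairwise Tanimoto statistics
  (MACCS or ECFP4) and Butina leader clustering.
* **Dataset construction** — build a kinase-active comparison set from a
  bioactivity table (IC50/Ki/Kd on a kinase target, pChEMBL > 6) with
  exclusion lists, and assemble labelled comparison sets.
* **Synthetic libraries with planted truth** — seeded generators that
  decorate annotated scaffold pools so that every downstream count
  (scaffolds, bicycles in both encodings, singletons, macrocycles,
  prevalence, rule violations) is known by construction.

Chemistry plumbing (parsing, canonical SMILES, InChIKey, logP/TPSA/MW,
fingerprints) runs on OpenBabel (ChemmineOB/`obabel`); ring perception
uses an SSSR computed on the bond graph; conformer embedding drives
RDKit through `python`. Everything else is implemented in the package.

## Worked example

```r
library(kinasespace)
library(dplyr)

mols <- standardize_molecules(c(
  "CC(=O)c1ccccc1",                         # acetophenone
  "COc1cc2ncnc(Nc3ccccc3)c2cc1OC",          # 6,7-dimethoxy-4-anilinoquinazoline
  "O=C1Cc2ccccc2N1",                        # oxindole
  "Cc1ccc2ncncc2c1.[Na+]",                  # methylquinazoline + counter-ion
  "C1CCCCCCCCCCCC1")) |>                    # 13-membered macrocycle
  deduplicate_molecules()

scaffold_table(mols)
#> # A tibble: 5 × 4
#>   molecule_id bm_smiles                 gf_smiles                 is_macrocyclic
#>   <chr>       <chr>                     <chr>                     <lgl>
#> 1 M00001      c1ccccc1                  C1CCCCC1                  FALSE
#> 2 M00002      c1ccc(cc1)Nc1ncnc2c1cccc2 C1CCC(CC1)CC1CCCC2C1CCCC2 FALSE
#> 3 M00003      O=C1Cc2c(N1)cccc2         CC1CC2C(C1)CCCC2          FALSE
#> 4 M00004      c1ccc2c(c1)ncnc2          C1CCC2C(C1)CCCC2          FALSE
#> 5 M00005      C1CCCCCCCCCCCC1           C1CCCCCCCCCCCC1           TRUE
```

The anilinoquinazoline keeps its full ring-and-linker scaffold
(N-phenylquinazolin-4-amine, 17 heavy atoms) while losing both methoxy
side chains; oxindole's scaffold retains the exocyclic carbonyl; the
macrocycle is flagged. Ring-system ensembles add the attachment typing:

```r
rs <- ring_system_table(mols)
rs
#> # A tibble: 6 × 6
#>   molecule_id system_index unpositioned     positioned        n_rings is_bicycle
#>   <chr>              <int> <chr>            <chr>               <int> <lgl>
#> 1 M00001                 1 c1ccccc1         [1*]c1ccccc1            1 FALSE
#> 2 M00002                 1 c1ccc2c(c1)ncnc2 [1*]c1cc2c(cc1[1…       2 TRUE
#> 3 M00002                 2 c1ccccc1         [1*]c1ccccc1            1 FALSE
#> 4 M00003                 1 c1ccc2c(c1)NCC2  O=C1Cc2c(N1)cccc2       2 TRUE
#> 5 M00004                 1 c1ccc2c(c1)ncnc2 [1*]c1ccc2c(c1)c…       2 TRUE
#> 6 M00005                 1 C1CCCCCCCCCCCC1  C1CCCCCCCCCCCC1         1 FALSE
```

Row 4 shows the documented oxindole behavior: the bare (unpositioned)
system re-perceives as non-aromatic indoline (`c1ccc2c(c1)NCC2`), while
the positioned form keeps the ring-bound `=O` unchanged. Bicycle
statistics aggregate occurrences:

```r
f <- bicycle_frequency(rs, "unpositioned")
f
#> # A tibble: 2 × 3
#>   key              count frequency
#>   <chr>            <int>     <dbl>
#> 1 c1ccc2c(c1)ncnc2     2     0.667
#> 2 c1ccc2c(c1)NCC2      1     0.333
frequency_summary(f)
#> # A tibble: 1 × 3
#>   n_total n_unique n_singletons
#>     <int>    <int>        <int>
#> 1       3        2            1
```

Two of the three bicycle occurrences are quinazoline; indoline is a
singleton. Descriptors, rules, guidelines, PCA and PMI chain the same
way: `compute_descriptors(mols) |> rule_profile() |>
violation_distribution()`, `fit_pca(desc)` (with `tidy()`, `glance()`,
`autoplot()`), `pmi_table(mols, n_confs = 10, seed = 42)` and
`plot_pmi_triangle()`. `run_pipeline(mols)` executes all stages and
`write_report_bundle()` emits the tables as CSV/JSON.

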