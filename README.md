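# rxnspace

Exhaustive, mechanism-agnostic enumeration of the reaction space between an
amine and a carboxylic acid, built on bond-order matrices.

Amines and acids are the two most common building blocks in drug discovery,
and they are united almost exclusively by the amide coupling. This package
maps everything else the pair could conceivably form. A molecular system is
encoded as a symmetric integer matrix `B` whose entry `(i, j)` is the bond
order between heavy atoms `i` and `j`; hydrogens are implicit, filling each
atom's remaining total bond order `t` (C = 4, N = 3, O = 2; single-bond
caps `b` = 3, 3, 2), and no atom ever carries a formal charge. A reaction
is the signed difference

```
T = B_product - B_starting_material
```

(positive entries are bonds formed, negative ones bonds broken), and its
**bond edit distance** is `sum(|T|) / 2`, the number of unit bond-order
changes -- a graph-editing cost, not a mechanistic step count: a
Diels-Alder reaction scores 6, a direct C-N cross-coupling scores 1.

For the eight-atom ethylamine + propanoic acid core, the package

* enumerates all **55,964,558** valence-legal product matrices (compiled
  depth-first generator, verified against a brute-force oracle),
* counts degeneracy orbits under the acid-oxygen swap by Burnside's lemma
  and by direct canonical enumeration (the two agree exactly),
* reduces the space to **222,748 unique products** with at least four heavy
  atoms (connected components, canonical-SMILES dedup),
* filters to **80,832 products** with at most 4 rings and at most 6 bond
  edits from the starting materials,
* computes the descriptor panel (HBD, HBA, MW, PSA, FSP3, QED-style
  drug-likeness, LogP, rotatable bonds, rings) and deterministic
  principal-moment-of-inertia shape coordinates (NPR1/NPR2),
* applies the transformation library to substituted drug-like substrates
  (late-stage diversification with octet, strain, aromaticity and
  substituent-loss filters) with matched reaction-center structures, and
* searches enumerated products as substructures of compound libraries,
  with aromaticity-preserving or kekulized matching and chord-diagram data
  export.

The full funnel recomputes from scratch in about a minute on one CPU.

## Worked example

Encode the simple pair on the standard indexing (1 amine beta-C, 2 amine
alpha-C, 3 acid beta-C, 4 acid alpha-C, 5 carboxyl C, 6 N, 7/8 O):

```r
library(rxnspace)

s <- smiles_to_system("CCN.CCC(=O)O", atom_order = c(1, 2, 6, 3, 4, 5, 7, 8))
s
#> <mol_system> CCCCCNOO, 6 bond(s)
#>   C C C C C N O O
#> C 0 1 0 0 0 0 0 0
#> C 1 0 0 0 0 1 0 0
#> C 0 0 0 1 0 0 0 0
#> C 0 0 1 0 1 0 0 0
#> C 0 0 0 1 0 0 2 1
#> N 0 1 0 0 0 0 0 0
#> O 0 0 0 0 2 0 0 0
#> O 0 0 0 0 1 0 0 0
#> SMILES: CCN.CCC(=O)O
```

The amide coupling raises the N6-C5 bond order by one and lowers C5-O8 by
one; applying that transformation to the sp3/sp3 template gives
N-ethylpropanamide (plus the displaced water oxygen), two bond edits away:

```r
tm <- sm_templates()$sp3_sp3
amide <- apply_transformation(tm, amide_transformation())
system_to_smiles(amide, canonical = TRUE)
#> [1] "CCNC(=O)CC.O"
bond_edit_distance(derive_transformation(amide, tm))
#> [1] 2
```

The same machinery runs on any C/N/O atom array. A toy four-atom system:

```r
cen <- product_census(atom_array(c("C", "C", "N", "O")))
nrow(cen)
#> [1] 67
head(cen, 3)
#>     smiles n_heavy_atoms min_bond_edit_distance rings
#> 12 CC(=O)N             4                      5     0
#> 24   CNC=O             4                      5     0
#> 43   NCC=O             4                      5     0
```

Every product row carries its minimal bond edit distance over the four
hybridization templates and its cyclomatic ring count, which drive
`funnel_filter()`. Descriptors and shape coordinates:

```r
compute_descriptors("CCC(=O)NCC")[, c("HBD", "HBA", "MW", "PSA", "LogP")]
#>   HBD HBA      MW  PSA  LogP
#> 1   1   2 101.147 29.1 0.923

compute_npr(c("CCC(=O)NCC", "C1C2CC3CC1CC(C2)C3"))
#>               smiles      NPR1      NPR2 embed_status
#> 1         CCC(=O)NCC 0.1024812 0.9289867           ok
#> 2 C1C2CC3CC1CC(C2)C3 0.9994964 0.9995595           ok
```

The amide is rod-like (NPR1 near 0, NPR2 near 1); adamantane sits at the
sphere vertex. The embedder is deterministic, so shape tables are
byte-identical across reruns.

A thin command-line front end over the same functions lives in
`inst/scripts/rxnspace-cli.R` (subcommands `count`, `census`, `filter`,
`props`, `pmi`, `diversify`, `search`, `fixtures`, `pipeline`).

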