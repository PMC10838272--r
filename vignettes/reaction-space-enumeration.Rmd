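---
title: "Methods: matrix enumeration of amine-acid reaction space"
author: "rxnspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix enumeration of amine-acid reaction space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnspace)
```

## The model

Amines and carboxylic acids are the two most abundant coupling partners in
medicinal chemistry, and they are united almost exclusively by one reaction,
the amide coupling. This package asks the complementary question: what is
*every* product the two partners could conceivably form, independent of
mechanism or present-day feasibility, and what transformation does each
product imply?

The encoding is a bond-electron matrix in the Ugi-Dugundji tradition. A
molecular system over $n$ heavy atoms is a symmetric integer matrix $B$ with
zero diagonal whose entry $B_{ij}$ is the bond order between atoms $i$ and
$j$. Hydrogens are implicit: each element carries two bonding parameters,
$t$ (the maximum total bond order of the neutral atom) and $b$ (the maximum
order of any single bond), and the slack $t_i - \sum_j B_{ij}$ is filled with
hydrogens. The defaults are C $(4,3)$, N $(3,3)$, O $(2,2)$. The oxygen caps
are forced rather than conventional: a neutral octet oxygen cannot carry a
total bond order above two, and a triple-bonded neutral oxygen would imply a
formal charge, which the model excludes everywhere (no charged species, no
radicals, no isotopes, and every structure is treated as a single
stereoisomer).

A *reaction* is the elementwise difference $T = B_{\text{product}} -
B_{\text{SM}}$ between product and starting material on a shared atom
indexing: positive entries are bonds formed, negative entries bonds broken,
and adding $T$ back to the starting material reconstructs the product. The
*bond edit distance* of a transformation is $\tfrac12\sum_{ij}|T_{ij}|$, the
number of unit bond-order changes. It deliberately measures editing effort on
the molecular graph, not mechanism: a Diels-Alder cycloaddition scores 6 in a
single concerted step, while a catalytic C-N cross-coupling scores 1.

The standard system is the eight-atom core of an ethylamine plus propanoic
acid pair, indexed 1 amine $\beta$-C, 2 amine $\alpha$-C, 3 acid $\beta$-C,
4 acid $\alpha$-C, 5 carboxyl C, 6 N, 7 and 8 the two acid oxygens. Four
starting-material templates cover the hybridization combinations of the two
partners; the sp$^2$ variant of a partner is encoded with a double bond
between its $\alpha$ and $\beta$ carbons (`sm_templates()`). That sp$^2$
encoding is a package convention -- the original study's template matrices
were not published in its main text -- and every function that consumes
templates accepts replacements, so alternative encodings can be tested
without touching package code.

## Exhaustive enumeration

`enumerate_matrices()` generates every valence-legal matrix over an atom
array: entries are assigned depth-first in row-major upper-triangle order,
tracking each atom's remaining capacity, so every emitted matrix is valid by
construction and the stream is lexicographically ordered and deterministic.
No connectivity constraint is applied: the all-zero matrix (complete
fragmentation into CH$_4$, NH$_3$, H$_2$O) and partially disconnected
systems are legitimate members of the space. Counting mode
(`count_matrices()`) runs the same recursion without materializing anything
and reports a per-first-entry tally, which doubles as a checkpoint grain: any
bucket can be recomputed independently by pinning the first entry.

For the default eight-atom array the count is 55,964,558 valence-legal
product matrices, computed in about a second by the compiled core and equal
-- exactly -- to the figure reported by the study this package
re-implements. Because products are enumerated independently of any
template, per-template transformation matrices are in bijection with
products, and this number can be read equally as the count of conceivable
transformations.

The generator is verified against `brute_force_enumerate()`, an independent
oracle that expands the full Cartesian grid of upper-triangle entries and
filters it through `validate_matrix()`; the two agree by exact set equality
on every C/N/O multiset of up to five atoms.

## Degeneracy and deduplication

The two acid oxygens are chemically equivalent, and in the unsubstituted
system so are all five carbons. Interchanging degenerate atoms permutes
matrices without changing chemistry, so the package reduces the raw count in
two stages.

**Matrix-level orbits.** `count_orbit_matrices()` counts equivalence classes
under the degeneracy group two independent ways: by Burnside's lemma (the
orbit count is the average number of matrices fixed by each group element,
each fixed-count obtained from a constrained enumeration that ties entries
along the permutation's pair-orbits) and by direct enumeration of
lexicographically minimal representatives. The two routes agree exactly.
Under the oxygen swap the 55,964,558 matrices fall into 29,328,894 orbits.
The reference study prints 23,829,176 for this stage. We were unable to
reproduce that figure under any natural reading: it is not the O-swap orbit
count, not half the total, and not the orbit count under any combination of
oxygen and carbon swaps we tested (those give 14,857,688 and below); no
group of order two can produce the implied mean orbit size of 2.35, and no
larger atom-permutation group is consistent with the measured fixed-point
counts. The package therefore reports its principled orbit count and the
delta against the printed value, rather than tuning toward an
unreproducible number.

**Product-level uniqueness.** `product_census()` produces the set of unique
*products*: connected molecules with at least four heavy atoms (the
threshold is read per connected component -- the full eight-atom system
always has eight atoms, which would make a system-level reading vacuous; we
verified empirically that the component reading reproduces the reference
count and a system-level keying does not). For every sub-multiset of the
atom array the compiled core enumerates connected graphs up to
identical-atom permutation (lexicographically minimal representatives,
exact minimality checked at the leaves), writes each as kekulized SMILES,
and canonicalizes through OpenBabel, which merges the resonance forms of
aromatic rings. Canonicalization is iterated to a fixed point because
OpenBabel's aromaticity perception is input-order sensitive for a few fused
small rings. The census yields 222,748 unique products against the
reference 222,740 (+0.004%): canonical-SMILES dialects differ slightly
between toolkits in which exotic rings they perceive as aromatic, and a
discrepancy of this size is the expected signature of that difference.

## Distance scoring and the structural funnel

Each product is scored with its minimal bond edit distance from the
starting materials: the minimum over the four templates and over all
injective element-preserving placements of the product's atoms onto
template positions. Bonds between placed and unplaced template atoms are
always broken. Two conventions exist for the template atoms the product
does not use:

* `residual = "template"`: unplaced atoms keep their mutual template bonds.
  This is the true minimum over all eight-atom systems containing the
  product (the leftover atoms simply stay as they were).
* `residual = "fragmented"`: bonds among unplaced atoms are also counted as
  broken, i.e. the product is referenced against the product-plus-bare-atoms
  system.

Butane illustrates the difference: loss of NH$_2$ and CO$_2$H followed by
C-C coupling costs 3 edits under the template convention but 6 under the
fragmented one. The package implements both; the default is `"fragmented"`
because it reproduces the reference funnel (80,832 survivors of the
$\leq 4$-ring, $\leq 6$-edit filter against the printed 80,941, $-0.13\%$,
with the same census; the template convention yields 82,368, $+1.8\%$).
Users who want the true minimum-over-systems semantics switch one argument.

Ring count is the cyclomatic number $E - V + C$ of the heavy-atom skeleton,
which equals the cardinality of the smallest set of smallest rings;
`funnel_filter()` removes products with more than 4 rings or more than 6
edits (both thresholds inclusive-keep, configurable). The filter is
idempotent, subset-producing and monotone in both thresholds, and those
properties are tested.

## Descriptors and shape

`compute_descriptors()` assembles the descriptor panel: hydrogen-bond
donors and acceptors, molecular weight, topological polar surface area, the
octanol-water partition coefficient and rotatable-bond counts come from
OpenBabel's implementations; ring count and the fraction of sp$^3$ carbons
are computed from the package's own molecular graph. FSP3 defaults to the
standard definition (sp$^3$ carbons over all carbons); a variant with all
heavy atoms in the denominator is reported alongside as `FSP3_heavy`,
because reaction-center FSP3 shifts quantized in eighths on an eight-atom
core indicate that an all-heavy-atom denominator may better match how the
panel was originally computed. Neither variant is asserted as ground truth.
The drug-likeness column `QED` is a desirability aggregate in the spirit of
the quantitative estimate of drug-likeness: the geometric mean of smooth
unimodal desirability curves over MW, logP, HBA, HBD, PSA, rotatable bonds
and aromatic ring count, with package-default midpoints and widths centred
on typical oral-drug ranges (MW 300, logP 2.5, PSA 70 A$^2$, and so on). It
is bounded in $[0,1]$, but its parameters are this package's own defaults,
not the published fitted set, so values should not be compared numerically
across implementations.

**Shape.** `compute_npr()` embeds each molecule in 3D and reports
normalized principal-moment-of-inertia ratios NPR1 $=I_1/I_3$ and NPR2
$=I_2/I_3$ (moments sorted ascending, hydrogens included, atomic masses
from standard atomic weights). The embedder is a deterministic
distance-geometry scheme built in the package: explicit hydrogens are
added; a target distance matrix is assembled from idealized bond lengths,
law-of-cosines geminal distances at ideal angles (109.5/120/180 degrees by
hybridization), and shortest through-bond paths beyond; classical
multidimensional scaling provides starting coordinates; and a short
weighted stress majorization with bond terms dominant polishes the local
geometry. Determinism was a design requirement -- shape tables must be
byte-identical across reruns and the `seed` argument is recorded for
provenance only -- and the available alternative (OpenBabel's stochastic
builder) cannot guarantee it. The cost of determinism is a single
conformer: flexible chains embed extended, so the NPR cloud of an acyclic
subset is biased toward the rod vertex relative to a Boltzmann ensemble.
The limiting shapes are reproduced correctly (hexatriyne $(0.01, 1.0)$,
benzene $(0.52, 0.52)$, adamantane $(1.0, 1.0)$), and every successful
embedding satisfies the triangle constraints NPR1 $\leq$ NPR2 $\leq 1$,
NPR1 + NPR2 $\geq 1$, the last of which is a theorem for any rigid body and
is asserted over a thousand embedded products in the acceptance suite. An
embedding whose bond-length RMS error exceeds 0.3 angstrom -- the signature
of a geometrically unsatisfiable strained cage -- is reported as
`embed_status = "failed"`, never an error.

## Late-stage diversification

`map_template_atoms()` locates the reaction center in a substituted
amine-acid pair: the primary amine nitrogen with its $\alpha$ and $\beta$
carbons and the carboxyl group with its $\alpha$ and $\beta$ carbons,
requiring the $\alpha$-$\beta$ bond order to match the template's
hybridization (an sp$^3$ template additionally requires an sp$^3$ $\alpha$
carbon, so anilines only match sp$^2$ templates). Multiple chemically
distinct matches are all reported, the first in canonical atom order is
used, and a warning is raised.

`diversify()` applies each transformation matrix of a library to the mapped
atoms only. Because the library was enumerated for the unsubstituted
system, transformations routinely demand valence that a substituted center
no longer has; such octet violations, negative bond orders, cap violations
and sanitization failures are rejection categories, not errors, and the
category counts always partition the library (an invariant under test).
Optional predicates mirror the filters used for drug-like substrates:
strained-motif removal (a shipped, editable SMARTS list -- the reference
never published its pattern set, so ours is a conservative curation of
bridgehead alkenes, in-ring triple bonds and cumulenes, fused cyclopropane
stacks and three-ring exocyclic double bonds; the funnel counts above do
not depend on it), substrate-aromaticity retention, ring retention at the
reacting atoms, and substituent loss. "Lost a significant substituent" is
operationalized as an unmapped heavy atom ending up in a connected
component that retains fewer than two reaction-center atoms -- a
decoration riding away on a single severed center atom or detached outright
-- which leaves the unreacted pair and clean fragmentations of the core
unflagged. The predicate is a package choice (the reference's exact rule is
unpublished) and is configurable.

`generate_reaction_centers()` replays the surviving transformation indices
on the simple eight-atom system, yielding a center structure per product,
order-aligned and deliberately not deduplicated: on a substituted substrate
the $\alpha$ and $\beta$ carbons are not degenerate, so centers that
coincide as molecules are still distinct transformations.

## Substructure search

`substructure_frequencies()` counts occurrences of enumerated products
inside a compound library. Matches are subgraph monomorphisms on the
heavy-atom graph with exact element agreement, computed with igraph's LAD
solver under element-restricted domains and then filtered for bond
compatibility; matches are deduplicated by matched atom set, so the
automorphisms of a symmetric query are not double-counted (a benzene query
matches benzene once, not twelve times). With aromaticity preserved (the
default) an aromatic bond only matches an aromatic bond; in kekulized mode
an aromatic bond also matches a single or double query bond, which is
exactly what lets a saturated C-C-C-C query match along a benzene ring and
why preserved-mode frequencies are bounded above by kekulized-mode
frequencies, pairwise. Aromaticity itself is perceived on the kekulized
graph by a simple Hueckel rule (five- to seven-membered rings, every atom
sp$^2$ or a lone-pair heteroatom, $4k+2$ pi electrons); this matches
toolkit perception on benzenoids, pyridines, pyrroles and furans but makes
no attempt at extended or charged aromatic systems, which cannot occur in
the enumerated space anyway. `group_by_composition()` buckets query totals
into the C / C+N / C+O / C+N+O composition groups, and `chord_export()`
writes the chord-diagram link table: queries arrayed by increasing bond
edit distance (ties broken by canonical SMILES), frequencies banded 1,
2-10, >10. Rendering the diagram is out of scope; the data table is the
deliverable. A bundled 50-molecule drug-like library
(`toy_drug_library()`, ids prefixed `synth_` where structures are
constructed rather than marketed drugs) stands in for licensed drug
databases so that all searches run offline.

## Numerical choices and edge cases

* Matrices are small signed integers (int8 in the compiled census); all
  entries lie in $[-4, 4]$ by construction.
* Empty and single-atom arrays enumerate to exactly one (empty) matrix;
  bond-free molecules ("C.N.O") parse and emit correctly.
* Stream order everywhere is lexicographic on the row-major upper
  triangle; the first-encountered witness matrix represents each unique
  product, making dedup deterministic.
* Sanitization failures in matrix-to-molecule conversion are flagged and
  skipped, never fatal; on the enumerated space the observed failure rate
  is below 1%.
* The toy problem sizes used in the test suite (two- to six-atom arrays,
  200-1000-matrix samples, 50-molecule library) were chosen so the full
  suite, including the complete eight-atom funnel, runs in a couple of
  minutes; the funnel numbers themselves are recomputed from scratch, not
  cached.

## Known limitations

* Charged species, radicals, isotopes and stereochemistry are outside the
  encoding by design; the enumerated space would grow substantially with
  any of them.
* The sp$^2$ template encoding and the strained-motif list are package
  conventions where the reference left details unpublished; both are
  configurable inputs rather than hard-coded behavior.
* The deterministic embedder produces one extended conformer per molecule;
  ensemble shape statistics and energy-based strain estimates are out of
  scope.
* Docking workflows and fingerprint-projection chemical-space maps that
  the surrounding study builds on licensed or visualization-only tooling
  are deliberately not reproduced; the package stops at the tables those
  analyses consume.
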