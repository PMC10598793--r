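---
title: "Ring and acyclic fragment analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring and acyclic fragment analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molfrag)
```

## The fragmentation model

`molfrag` decomposes a molecule into **ring fragments (RFs)** and
**acyclic fragments (AFs)** over the heavy-atom graph:

* An atom is a *ring atom* iff it lies on at least one cycle of the
  molecular graph (equivalently, iff it is incident to a non-bridge edge).
* A *ring system* is a connected component of the subgraph induced by the
  ring atoms. Fused and spiro rings (sharing at least one atom) therefore
  merge into one system, and — a case the rules do not otherwise decide —
  two rings joined by a direct ring-atom–ring-atom bond (biphenyl) also
  form **one** system: RF extraction only ever breaks acyclic–acyclic
  bonds, never ring–ring bonds. This is deliberate and prominent because
  the alternative (splitting at the ring–ring bond) silently changes every
  downstream count.
* **RF rule:** one RF per ring system, consisting of all its ring atoms
  plus every acyclic atom directly bonded to a ring atom of that system,
  with original bond orders. An acyclic atom bonded to ring atoms of *k*
  distinct ring systems is duplicated into all *k* RFs (e.g. the CH~2~ of
  diphenylmethane, or the NH of gefitinib's anilino bridge).
* **AF rule:** the AFs are the connected components of the subgraph
  induced by the acyclic atoms, bond orders preserved within components.

Valences opened by bond breaking are saturated with implicit hydrogens
when the fragment is re-canonicalized, so a ketone oxygen cut from its
ring carbon becomes the water-like fragment `O`. Fragment identity is the
hydrogen-saturated heavy-atom graph: an `N` cut from a secondary and from
a tertiary amine are the same AF. Extraction returns *multisets*
(p-xylene yields `C`, `C`); deduplication is the counting layer's job,
where occurrence is defined as the number of distinct molecules
containing a fragment.

### Normalization policy

Molecules are parsed and canonicalized with OpenBabel (via ChemmineOB).
Before keying, the package strips stereo descriptors and isotope labels —
fragment counts should not distinguish stereoisomers, and dearomatized
database exports must collapse onto the same keys as aromatic notation.
Formal charges are preserved as written; no neutralization pass is
applied, since inventing protonation chemistry would make counts depend
on a model the input never declared. Multi-component records (salts) are
reduced to the largest component by heavy atom count, ties broken by
lexicographic canonical SMILES; counter-ions would otherwise pollute the
AF statistics. Aromaticity perception follows OpenBabel's model: Kekulé
and aromatic input converge to the same canonical key.

## Fragment profiles

RF profiles report the cyclomatic number (`n_rings`), the largest ring
size over a smallest-set-of-smallest-rings decomposition, the number of
acyclic (substituent) atoms and of heteroatoms. AF profiles report
quaternary centers — defined element-agnostically as a carbon with four
heavy-atom *neighbors*, the simplest reading that makes CF~4~ quaternary —
triple bonds, heteroatoms, and terminal atoms (heavy atoms with at most
one heavy neighbor; a lone atom counts as one terminal).

SAscore (1 = easy to 10 = hard synthesis) and NPscore
(natural-product likeness) are *contract-level* here: they are computed
by the published fragment-contribution scorers shipped with RDKit's
Contrib collection, called through a bundled Python helper. A missing
backend raises an explicit configuration error rather than returning
silent zeros.

## Bioactivity enrichment

For each fragment, occurrence percentages are taken relative to the total
number of molecules in each subset, and

$$R_\mathrm{bioactive} = \frac{\%\,\mathrm{active}}{\%\,\mathrm{inactive}},$$

with `0/positive = 0` and `positive/0 = +Inf`. No pseudocounts are added:
subset-exclusive fragments belong at the extremes and are labeled
active/inactive accordingly. The default thresholds are inclusive,
`active` iff $R \ge 4$ and `inactive` iff $R \le 0.25$; the
nonpreferential class is exactly the open complement interval
$(0.25, 4)$ rather than a narrower band around 1 — the complement is the
only parameter-free definition that keeps the partition exhaustive.
Volcano coordinates are $x = \log_2 R$ with subset-exclusive fragments
flagged `left`/`right` for plotting as edge stacks.

## MinHashed atom-pair fingerprints

The similarity screen uses a MinHashed atom-pair fingerprint in the
spirit of MAP4. The shingle grammar is package-defined and pinned in this
document:

* Atom descriptor: element symbol, signed formal charge when non-zero,
  and one of `a` (aromatic), `r` (non-aromatic ring), `-` (acyclic).
* Environment string of radius *r*: the atom descriptor followed by the
  sorted, comma-separated list of `(bond order, child environment)` pairs
  expanded to depth *r* without immediate backtracking. Sorting makes the
  serialization invariant under input atom order.
* Token: `envA|d|envB` for every unordered heavy-atom pair, where *d* is
  the topological distance and `envA <= envB` lexicographically; radii
  {1, 2} (diameters two and four bonds) are both emitted. Distances are
  not capped. A single-atom fragment emits its self-pair token at
  distance 0, so the ubiquitous one-atom AFs (`O`, `N`, `F`, `Cl`) remain
  fingerprintable.

Signatures hold 256 minima of universal hashes
$h_i(x) = (a_i x + b_i) \bmod (2^{31}-1)$ over a 32-bit FNV-1a base hash,
with $(a_i, b_i)$ drawn from a Park–Miller generator seeded by the
signature `seed` — decoupled from R's global RNG so signatures are
reproducible regardless of session state. The estimated Jaccard distance
is one minus the fraction of matching positions; estimates are unbiased
with per-pair standard error $\sqrt{d(1-d)/256} \lesssim 0.031$.
Signatures are only comparable at equal dimensions and seed, which the
API enforces. The triangle inequality is *not* guaranteed at the
estimator level.

The screening contract is a linear scan: a candidate is retained iff its
estimated distance to at least one reference is at most `d_max` (default
0.6). `select_bioactive_like()` composes two screens as a set difference,
so a candidate near both an active and an inactive reference is dropped
and the result is independent of screening order.

## Structural selection defaults

`rf_criteria()` defaults to ≤ 2 rings, largest ring ≤ 7, ≤ 3 heteroatoms,
≤ 3 acyclic atoms; `af_criteria()` to no quaternary center, ≤ 1 triple
bond, ≤ 4 heteroatoms, ≤ 4 terminal atoms; both can require exclusivity
against comparison collections. "Ring size up to seven" is implemented as
*largest* SSSR ring ≤ 7, which under SSSR semantics coincides with
all-rings ≤ 7. Relaxing any bound can only grow the selection (a property
the test suite asserts).

## The synthetic library generator

`generate_library()` emulates small substituted-scaffold libraries: each
molecule is a ring scaffold from `rf_alphabet` with 0–`max_substituents`
substituents from `af_alphabet` attached by single bonds at positions
with free standard valence. Because attachment is only ever a single bond
from a ring atom to the substituent's first atom, the ground truth is
unambiguous *by construction*: the molecule's RF is the scaffold plus one
stub atom per substituent, and its AFs are the substituents themselves. A
separate *bridge mode* joins two scaffolds through a single carbon
linker, exercising the duplication rule with known truth (two RFs each
carrying the linker stub, plus the one-atom AF `C`). Generation is
deterministic per seed, with the RNG state saved and restored around it.

`generate_activity_split()` plants an enrichment ratio ρ: of the *M*
molecules containing the planted fragment, `round(M p)` with
$p = \rho N_a / (\rho N_a + N_i)$ are assigned (at random, seeded) to the
active subset, the rest to the inactive subset, and non-containing
molecules fill the remaining slots. The expected measured
$R_\mathrm{bioactive}$ then equals ρ up to rounding; unattainable
configurations (fragment absent, too few containing molecules, subset
sizes exceeding the library) raise explicit errors.

The generator deliberately does **not** emulate realistic
medicinal-chemistry property distributions, stereochemistry, tautomers,
macrocycles, fused-ring scaffolds built on the fly, or correlated
substituent patterns. Passing tests on generated libraries therefore
demonstrate correctness of the fragmentation/counting/enrichment
machinery under known ground truth — not that real collections have any
particular fragment statistics.

## Numerical and degenerate-case choices

* Ring sizes use an own Horton minimum-cycle-basis implementation
  (shortest-path candidate cycles, sorted by length, kept greedily under
  GF(2) independence up to the cyclomatic number); the installed graph
  library exposes no SSSR primitive.
* `top_fragments()` breaks count ties by lexicographic canonical key, so
  rankings are deterministic.
* `coverage()` treats a molecule with no fragments of the selected kind
  as covered (vacuous truth); this is what makes a fully acyclic molecule
  count as covered by RFs, and it keeps coverage monotone in `max_hac`.
* Empty inputs: an empty molecule stream yields an empty index with
  `n_molecules = 0`; an empty shingle set cannot be fingerprinted and is
  an error; empty reference sets are usage errors for screening.
* Empty SMILES lines raise a *skip* condition distinct from parse errors,
  so batch readers can drop blanks silently while still reporting truly
  unparsable records.

## Validation problem sizes

The test suite validates the fragmenter against an independent
brute-force oracle (hand-rolled per-edge cycle test and BFS components)
on 500+ distinct generated-plus-curated molecules of up to 12 heavy
atoms; enrichment recovery uses a planted ratio of 8 on subsets of
2000/2000 molecules drawn from a 4300-molecule generated library; MinHash
fidelity is measured over 100 random fragment pairs and a 30×10
candidate/reference screen; structural filters are checked against a
50-fragment hand-labeled fixture. These sizes keep the whole suite in the
minutes range on one CPU while leaving each statistical check with ample
resolution. In the similarity screen comparison, candidates were chosen
in three strata (identical to a reference, clear analogue, unrelated)
whose exact distances stay more than three standard errors away from the
0.6 threshold: at 256 permutations the estimator necessarily flips
decisions for candidates within ~0.03 of the threshold, so a boundary
candidate would test the sampling noise, not the implementation.

## Known limitations

* Canonical keys follow OpenBabel's canonicalization dialect; absolute
  fragment counts on large public collections are sensitive to the
  toolkit dialect and version, so published count tables should be
  treated as version-pinned references.
* Whether a direct ring–ring bond should merge ring systems is a genuine
  modeling choice (documented above); pipelines that split biphenyls will
  produce systematically different RF statistics.
* The MinHash screen is a linear scan; sharding is the caller's concern
  for very large candidate sets (indexes are mergeable for this reason).
* SAscore/NPscore require an RDKit-equipped Python at run time.
* Tautomer canonicalization, InChI identity and 2D/3D geometry are out of
  scope.
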