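---
title: "Mining reactions that consume N-nitrosamines: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining reactions that consume N-nitrosamines: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrosaminer)
```

## The problem

N-nitrosamines (NSAs, R2N–N=O) are potentially carcinogenic impurities in
pharmaceuticals. Risk assessment needs to know which reagents and
conditions destroy the N-nitroso group and which leave it intact, and the
evidence for that is scattered across decades of reaction literature.
`nitrosaminer` implements a reaction-mining pipeline for this question: it
curates raw reaction records, tracks atoms across each reaction via
atom–atom maps, decides whether the N-nitroso substructure was consumed,
removes duplicates, and classifies the survivors by substrate class,
reagent class and transformation type into a compact reactivity matrix.

Because real exports of commercial reaction databases are proprietary, the
package also ships a first-class synthetic dataset generator that emulates
such an export — clean template chemistry plus realistic failure modes —
with ground-truth labels, so every stage of the pipeline is testable
end-to-end without any external data.

## Pipeline model

A record enters as a reaction SMILES (`reactants>agents>products`) plus
condition metadata, and passes through six stages, each of which removes
records into an attrition funnel rather than raising errors:

1. **Curation** — every component is parsed into a heavy-atom molecular
   graph, sanitised (valence-checked, aromaticity-normalised) and
   canonicalised. Unparseable records are counted and dropped.
2. **Single-step filter** — records with `step_count > 1` are removed;
   multistep entries conflate several transformations and cannot be
   atom-mapped meaningfully.
3. **Mapping** — a record whose SMILES already carries a full, valid atom
   map is accepted as-is. Otherwise the reaction must pass a heavy-atom
   element balance check (products vs reactants + agents) and is handed to
   a heuristic mapper; unbalanced or unmappable records are attrition.
   This mirrors the observation that mapping failures in practice are
   dominated by unbalanced records.
4. **Consumption filter** — the N-nitrosamine query
   (`[#7;X3]([!#1])([!#1])[#7]=[#8]`) is matched against every reactant;
   the reaction is kept only if some match is *altered*: a bond between
   match atoms broken or changed, a match atom lost from the products, or
   a charge/hydrogen change on a match atom. A match that re-occurs intact
   over the same mapped atoms is a spectator.
5. **Deduplication** — first occurrence kept per canonical key (below).
6. **Classification** — substrate, reagent and transformation labels;
   every record passing stage 5 receives a label (there is a defined
   fallback class), so this stage removes nothing.

## Reaction centers and depth

With a valid mapping, the *reaction center* is the set of atoms and bonds
that change. Depth-0 is exactly the changed atoms plus the endpoints of
changed bonds; depth *d+1* adds every atom bonded to the depth-*d* core on
either side, saturating at the reacting molecules. The default working
depth is 1, which is the shallowest depth at which the environment of the
N–N=O group is visible around the changed atoms; it is configurable.

Two numerical choices matter here:

* **Aromatic bonds are a distinct order (1.5).** Kekulized benzene-like
  six-rings are promoted to the aromatic form at parse time, so a record
  written `C1=CC=CC=C1` and one written `c1ccccc1` produce no spurious
  `order_changed` events. Ring perception is deliberately minimal
  (isolated six-membered C/N rings with alternating single/double bonds);
  fused aromatics must arrive in aromatic SMILES form.
* **Fragment encodings are canonicalised in-package.** A depth-*d* core
  cuts molecules open, and fragments of aromatic rings are ambiguous to
  whole-molecule aromaticity models (a toolkit may kekulize the open
  fragment differently depending on input atom order). Center fragments
  are therefore written in a renumbering-invariant atom order computed by
  Morgan-style rank refinement over (element, aromaticity, charge,
  hydrogen count, degree), with symmetry ties broken by individualisation
  and re-refinement. Whole molecules (dedup keys) are canonicalised with
  OpenBabel, where aromaticity is well defined.

The encoding of a center is `reactant-fragments >> product-fragments`,
each side the sorted `.`-join of its components, maps stripped; the empty
center encodes as `">>"`.

## Consumption semantics

The pipeline's central predicate — "was the N-nitroso group consumed?" —
is not defined formally in the chemistry literature. The package adopts a
match-alteration definition (any broken/changed match bond, lost match
atom, or charge/H change on a match atom) and treats *any* altered match
as consumption when several N-nitroso sites exist, which is the
conservative choice for contaminant tracking. A borderline case worth
knowing about: a pure protonation of the nitroso oxygen would count as
consumption under this definition, because the hydrogen count on a match
atom changes. Tests pin this semantics against an independent brute-force
oracle that re-embeds each reactant match into the products via map
indices and compares the induced subgraphs.

## Atom–atom mapping

The package validates externally supplied maps (bijectivity, element
conservation, orphan indices) and provides a deliberately modest greedy
mapper for records that arrive unmapped: seeds are chosen by matching
neighbour-refined atom signatures between the sides, grown by
element-and-bond-order neighbour matching, and the remainder assigned
element-preservingly. It only attempts reactions with at most two
heavy-atom reactants and two products; anything larger is declined and
becomes attrition. It makes no claim of equivalence to optimisation-based
mappers — its contract is that every mapping it emits passes validation,
and that it is deterministic.

## Deduplication key

Two records are duplicates when starting materials, products and
reagent/conditions agree:

* structure keys: sorted canonical SMILES of each side, so component
  order never matters;
* reagent names: case-folded, whitespace-collapsed, passed through an
  editable synonym file (`reagent_synonyms.yaml`), sorted;
* solvents (case-folded, sorted) and temperature are included by default
  but each sits behind a switch, since condition fields in real exports
  are inconsistently populated;
* temperature is banded into 10 °C bins, with "no temperature" its own
  band — exact float equality would miss near-identical duplicates;
* agents recorded inside the reaction SMILES fold into the condition key.

Hydrogens are excluded from the balance tally because implicit-hydrogen
conventions differ between sources; heavy-atom balance is what the
mapping stage actually requires.

## Classification

**Substrates** are typed by the two substituents on the nitrosamine
nitrogen: aromatic root → aryl; carbonyl root with O/N/C neighbour →
carbamate/urea/amide; amidine-type carbon → guanidine; S(=O)(=O) →
sulfonyl; saturated carbon → alkyl. A substrate carrying both an alkyl/aryl
and an electron-withdrawing substituent takes the electron-poor label
(fixed tie-break: carbamate > urea > guanidine > sulfonyl > amide), since
the activating group dominates reactivity. An oxygen on the β-carbon of an
alkyl substituent sets a `beta_oxy` flag rather than defining its own
class — β-oxygenation modulates reactivity within a class rather than
changing the substituent pattern. Fine labels map to coarse classes
C1–C8 through an editable YAML file; the grouping is configuration, not
chemistry.

**Reagents** are classified into 21 configurable classes by synonym
matching with priorities: reductants, oxidants and organometallics match
before acids and bases, so `Na2S2O4 + NaOH` is an S-based reductant, not a
strong base. Records with no reagent names but a recorded temperature are
"thermal only"; unmatched reagents are "unclassified". The shipped class
list and memberships are reconstructions of the field's usual groupings
and are deliberately editable.

**Transformations** are labelled by precedence-ordered structural rules on
the fate of the matched N–N=O site (first match wins): reduction to
amine/denitrosation; reduction to hydrazine; diazonium formation;
Fischer–Hepp rearrangement; transnitrosation; oxidation to N-nitramine;
then new α C–C bonds, new rings through the site, any other N–N cleavage,
and finally "other". One disjointness choice deserves note: Fischer–Hepp
and transnitrosation products also break the N–N bond while the amine
keeps both substituents, so the denitrosation rule additionally requires
that the nitroso nitrogen leaves carrying nothing but its own oxygen.
Without this the first rule would shadow the later ones; with it, the ten
classes partition cleanly (classification counts in the matrix are
disjoint).

**Streamlining** drops substrate classes with fewer than 10 distinct
substrates or fewer than 3 distinct transformation classes (both
configurable), reporting the number of reactions lost; separately, matrix
*rendering* blanks cells below a display threshold (default 3) without
ever altering stored counts.

## The synthetic generator

The generator emulates the statistical structure of a proprietary
reaction-database export:

* **Clean records** come from a full cross of 6 transformation templates
  (denitrosation, hydrazine reduction, diazonium formation, Fischer–Hepp,
  transnitrosation, N-nitramine oxidation) and 5 substrate classes
  (alkyl-aryl, diaryl, alkyl-carbamate, alkyl-amide, alkyl-urea), with 8
  distinct R-group draws per pair in the default study conditions —
  240 clean reactions. Each template is graph surgery on the mapped
  substrate (+partner) graph, so every clean record is balanced, fully
  mapped, consumes the N-nitroso group, and classifies back to its
  template's label by construction. The class set excludes dialkyl
  because Fischer–Hepp requires an N-aryl ring to migrate into; under the
  Fischer–Hepp template the free substituent of acyl classes is drawn
  from the aryl vocabulary (the class label is unchanged, by the
  electron-poor-wins rule). Template metadata (reagents, solvent,
  temperature, applicable classes) lives in `templates.yaml`; the
  rewrites are code.
* **Noise records** are injected in exact counts, each engineered to fall
  at one specific stage: multistep (`step_count = 2`), unparseable
  (corrupted SMILES), unbalanced (the smallest by-product deleted from a
  by-product-forming template, so the record still parses but fails
  balance), spectator (esterification of a β-hydroxyethyl substituent
  with an acyl chloride — the N–N=O survives mapping but not the
  consumption filter), and duplicates (clones of distinct clean records
  under fresh ids, ordered after their source so first-occurrence dedup
  removes exactly the clones). The default study conditions add
  20/20/20/30/25 of these.
* **Determinism**: the dataset is a pure function of the spec, including
  its seed; record order is shuffled under the same seed.

What the generator does *not* emulate: the long-tailed substrate-frequency
distribution of real exports (class frequencies here are user-set and
near-uniform), multi-product selectivity, condition free-text noise beyond
synonym variation, stereochemistry, and mapping errors from external
mappers. Passing the end-to-end tests therefore demonstrates that the
pipeline's bookkeeping, chemistry rules and invariants are correct on
records whose ground truth is known — not that the shipped taxonomies
capture every real-world reagent spelling or exotic transformation.

## Problem sizes and verification

The test suite validates each module against hand-derived examples
(element tallies, bond-change sets, depth cores), against an independent
consumption oracle, against RDKit (via the system Python) for hydrogen
perception on a fixture set, and end-to-end against generator ground
truth at the default study scale (355 records: 240 clean + 95 noise),
where the attrition funnel and the classification matrix must match
expectation exactly, cell for cell. Depth laws are checked on 50 sampled
reactions with 20 random renumberings each; dedup exactness on 10
regenerated datasets. `scripts/acceptance.R` reruns the full pipeline at
the same scale from a fresh seed and reports the funnel counts, mapping
success rate, oracle agreement and label-recovery fractions it computes.

## Known limitations

* Aromaticity perception beyond isolated benzene-like six-rings is not
  attempted; inputs should use aromatic SMILES for fused systems.
* The greedy mapper declines >2×2-component reactions; real datasets
  need externally supplied maps for such records (the pipeline accepts
  and validates them).
* SMARTS support covers the subset needed for the shipped queries and
  rules (element/aromatic primitives, `X`/`D`/`H`/charge, `;` and element
  `,`-alternation, ring bonds, `~`); recursive SMARTS and boolean `!`/`&`
  expressions beyond `[!#1]` are not supported.
* Stereochemistry is parsed permissively (`/`, `\` read as single bonds)
  and never compared; stereo-only changes are invisible to the center.
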