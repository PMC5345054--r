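---
title: "Aligning taxonomic concepts with RCC-5: model, reasoner and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning taxonomic concepts with RCC-5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcc5align)
```

## The problem

A taxonomic name does not pin down a set of organisms: each published
treatment circumscribes it differently. `rcc5align` works with
*taxonomic concepts* — a name as used in one treatment, written
`tag.name` (e.g. `2012.Scelianoma`) — and with expert *articulations*
that relate concepts from different treatments under the Region
Connection Calculus with five base relations (RCC-5):

| symbol | meaning |
|--------|------------------------------------------|
| `==`   | congruence (same region) |
| `>`    | left properly includes right |
| `<`    | left properly included in right |
| `><`   | overlap (both shared and unshared parts) |
| `!`    | exclusion (disjoint regions) |

For two nonempty regions exactly one base relation holds; an
articulation may assert a disjunction (e.g. `{< ><}`) when the expert
is unsure. Given 2–5 classification hierarchies and a set of
articulations, the package answers three questions:

1. **Consistency** — is there any assignment of nonempty regions to
   all concepts satisfying every hierarchy and articulation?
2. **Maximally Informative Relations (MIR)** — for every
   cross-hierarchy concept pair, which base relations are realizable
   in at least one consistent world?
3. **Merging** — collapsing congruent concepts, what is the inferred
   inclusion/overlap structure of the combined taxonomy?

## The finite world model

Concepts denote unknown nonempty regions constrained by:

* *parenthood*: a child's region lies inside its parent's;
* *sibling disjointness*: children of one parent are pairwise
  disjoint (a global assumption, on by default — see below);
* *coverage*: a parent is exactly the union of its children, unless
  the parent is flagged non-covered (`nc_` in input files), in which
  case it may keep a nonempty unsampled residue;
* *nonemptiness*: every concept denotes a nonempty region.

Only the emptiness pattern of Boolean combinations of regions matters
for RCC-5, so the continuous problem reduces to a finite one.
`build_places()` forms the joint partition of all hierarchies: a
*place* fixes, for each hierarchy, a membership chain ending at a
childless concept, at the residue ("gap") of a non-covered parent, or
outside the hierarchy altogether. A *possible world* is a nonempty set
of occupied places; a concept's region is the union of occupied places
under it. Sibling disjointness, parenthood and coverage hold by
construction; nonemptiness and articulations become constraints on the
occupancy variables. The place count is the product of per-hierarchy
slot counts and is guarded by a configurable cap (default $10^6$).

Switching sibling disjointness off (`sibling_disjoint = FALSE`)
replaces the chain slots by all membership sets consistent with
parenthood and coverage; this grows exponentially in hierarchy size
and is intended for small diagnostic problems only.

## Deciding satisfiability

Encoded over place-occupancy Booleans, every constraint has one of two
shapes:

* **forced-empty places** (negative unit literals): e.g. asserting
  `A == B` empties the places under exactly one of the two; `A ! B`
  empties the places under both;
* **at-least-one clauses** (all positive): nonemptiness of each
  concept, and the zones an asserted relation requires occupied.

For a fixed choice of one disjunct per disjunctive articulation the
formula is monotone: delete the forbidden places and check that every
positive clause retains a live member. If so, occupying *all*
remaining places is a satisfying world; if not, no world exists.
Disjunctive articulations are handled by depth-first search over their
disjuncts with early pruning. This decision procedure is exact — it is
propositional satisfiability specialized to the encoding's structure —
and needs no external solver.

`compute_mir()` probes, for each pair and relation, the problem plus
that single assertion. Each satisfying witness certifies one
realizable relation for *every* pair at once, which removes most
probes; at most five probes per pair remain. The reasoner contains no
randomness, and all outputs follow the canonical concept order
(hierarchy input order, then preorder), so results are deterministic.

As an independent check, the brute-force backend
(`backend = "brute"`) enumerates all $2^{\text{places}}-1$ occupancy
sets as bitmasks and filters them by the same semantics. The test
suite requires exact agreement between the two backends on hundreds of
seeded problems with at most 16 places, and verifies the induced
relation of every world against direct set comparison.

`enumerate_worlds()` reports worlds up to the equivalence "induces the
same relation on every cross pair". We deliberately do not claim this
count matches any notion of counting distinct logical models, which
would additionally distinguish occupancy patterns invisible at the
relation level.

Inconsistency explanations use iterative deletion: each articulation
is dropped if the remainder is still unsatisfiable. The result is a
minimal conflicting set, not necessarily a minimum one.

## Merged graphs

`merged_graph()` collapses concepts linked by singleton `==` MIR rows
into congruence classes (connected components), orders classes by
proper inclusion from singleton `>`/`<` rows plus within-hierarchy
parenthood, transitively reduces that order, and adds undirected
overlap edges from singleton `><` rows. Ambiguous rows (two or more
relations) contribute no edge. Within-hierarchy parent–child edges may
represent equality rather than proper inclusion when a covered parent
has a single child; they are still drawn, matching the convention of
the alignment graphs this output emulates. `count_label_regions()`
then counts, for one name, how many taxonomically distinct regions
carry it across treatments.

## File formats

The alignment dialect is line-oriented: `taxonomy <tag> <title>`
followed by parenthesized parent–child groups (`nc_` marking
non-covered parents), then `articulation <tag1>-<tag2> <title>`
followed by bracketed assertions using the keywords `equals`,
`includes`, `is_included_in`, `overlaps`, `disjoint` or a braced
disjunction. `write_eulerx()` groups articulations by hierarchy pair
in hierarchy order; parsing its output reproduces the problem exactly,
and the round-trip property is tested over seeded synthetic problems
(whose articulation lists are emitted already grouped). MIR tables
export as `left,relation,right` CSV; graphs export as DOT text.

Character matrices read from a NONA/Hennig86-style `.ss` layout
(optional `xread`, a `<n_chars> <n_taxa>` header, one row per taxon)
or from TSV; `'?'` is missing data, `'-'` inapplicable.

## Numerical and counting conventions

* Morphometric ratios and coverage percentages round **half-up** at
  one decimal (`round_half_up()`), not to even; this matches how such
  values are conventionally printed in descriptions.
* `coded_stats()` reports the *range* reading of coding coverage — the
  highest character index at which any selected taxon was assessed
  (`'-'` counts as assessed, `'?'` does not) — because a contiguous
  assessed range is what "coded for the first *k* characters"
  expresses; the strict count of columns with at least one non-missing
  cell is reported alongside (for the bundled fossil rows: range 88 of
  143, 61.5%; strict count 86, because characters 49–50 are missing in
  every row).
* Diagnostic queries are conservative: `'?'` and `'-'` never match a
  state, so a reported "shared only between" combination can only
  shrink when more data arrive.

## The synthetic generator

`synthetic_spec()` / `sample_world()` build ground-truth worlds: a
universe of `universe_size` atoms is recursively partitioned by each
hierarchy — children split their parent's atoms into nonempty blocks,
and with probability `p_gap` a parent keeps a nonempty residue and is
flagged non-covered. This emulates the statistical shape of real
multi-treatment alignments (nested nonempty circumscriptions,
occasional undersampled parents) while guaranteeing by construction
the assumptions the reasoner makes (sibling disjointness,
nonemptiness). It does **not** emulate name-usage drift, synonym
strings or asserted-articulation errors; recovery tests therefore
certify the logic, not robustness to mislabelled input.

Defaults, chosen once for the test conditions: `max_depth = 2`,
`max_children = 3`, `p_gap = 0.15`, `articulation_density = 1`. All
randomness flows from the single spec seed; `emit_problem()` draws a
seeded subset of cross pairs articulated with their true relation, and
`perturb_inconsistent()` injects one articulation contradicting a
fully resolved pair, guaranteeing unsatisfiability.

Problem sizes in the test suite are the package's own choice: oracle
comparisons use universes of 3–4 atoms and 2–3 hierarchies (place
spaces of at most 16 places, where exhaustive enumeration is exact and
fast); recovery runs 100 specs spanning 2–5 hierarchies over universes
of `n_taxonomies + 3` atoms, large enough to exercise every relation
and gap handling while keeping full MIR computation to seconds per
problem.

## Known limitations

* MIR computation is exact but enumerative per pair; alignments far
  larger than the bundled cases (hundreds of concepts per hierarchy)
  would need incremental solving.
* The membership-set mode without sibling disjointness is exponential
  in hierarchy size and capped accordingly.
* Conflict reports are minimal, not minimum.
* The merged graph reflects only singleton MIR rows; partially
  resolved alignments yield conservative (sparser) graphs.
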