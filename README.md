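# rcc5align

Multi-taxonomy alignment of taxonomic concepts under RCC-5, with a
cladistic character-matrix layer.

## What problem this solves

The same taxon name means different things in different publications:
each treatment circumscribes it over its own set of species. For
anyone integrating biodiversity data across revisions — taxonomists
publishing a new treatment, informaticians merging checklists — the
name alone is ambiguous. `rcc5align` represents each usage as a
*taxonomic concept* `tag.name` (e.g. `2012.Scelianoma` = *Scelianoma*
as circumscribed in the 2012 revision) and reasons over expert
*articulations* between concepts in the Region Connection Calculus
with five jointly exhaustive, pairwise disjoint base relations:

```
==  congruence          >   proper inclusion      <   inverse inclusion
><  overlap             !   exclusion
```

Given 2–5 classification hierarchies plus articulations (possibly
disjunctive, e.g. `{< ><}`), the package

* decides **logical consistency** over a finite place-occupancy model
  (sibling disjointness, parent inclusion, and the coverage constraint
  "parent = union of children" — relaxable per concept via the `nc`
  device for undersampled parents), returning a witness world or a
  minimal conflicting articulation set;
* computes the **Maximally Informative Relations (MIR)**: for every
  cross-hierarchy concept pair, the set of base relations realizable
  in at least one consistent world — one table row per pair,
  `sum over i<j of |Ti|·|Tj|` rows in total;
* enumerates the distinct **possible-world relation patterns**;
* builds the **merged graph**: congruence classes ordered by inferred
  proper inclusion (transitively reduced) with overlap edges, and
  counts how many taxonomically distinct regions carry one name;
* reads/writes an Euler/X-dialect alignment text format, MIR CSV and
  DOT graph exports.

A companion layer handles the cladistic character matrix behind such
generic placements: NONA/Hennig86-style `.ss` and TSV input,
coded-coverage statistics, diagnostic character-state combination
queries ("this combination is shared only between ..."), and
morphometric ratio checks. A seeded synthetic-world generator with
known ground-truth relations backs the test suite end to end.

## Worked example

The bundled three-treatment alignment of the weevil genus
*Scelianoma* (2009 original description, 2012 revision, 2017
treatment adding the amber fossil *S. compacta*):

```r
library(rcc5align)
p <- scelianoma_problem()
p
#> Alignment problem: 3 taxonomies (2009, 2012, 2017), 7 concepts, 4 articulations

mir <- compute_mir(p)
head(write_mir_csv(mir), 6)
#> left,relation,right
#> 2009.Scelianoma,==,2012.Scelianoma
#> 2009.Scelianoma,==,2012.Scelianoma_elydimorpha
#> 2009.Scelianoma_elydimorpha,==,2012.Scelianoma
#> 2009.Scelianoma_elydimorpha,==,2012.Scelianoma_elydimorpha
#> 2009.Scelianoma,<,2017.Scelianoma

g <- merged_graph(mir)
g
#> Merged graph: 3 congruence classes (1 with >1 member), 2 inclusion edge(s), 0 overlap edge(s)
count_label_regions(g, "Scelianoma")
#> [1] 2
```

The MIR table has 16 rows (one per cross-taxonomy pair), every
relation fully resolved. The merge shows two distinct regions named
*Scelianoma*: the 2009/2012 circumscription (congruent with each
other and with *S. elydimorpha* under the coverage constraint) is
properly included in the more inclusive 2017 concept that adds the
fossil species.

The fossil coding layer:

```r
s <- coded_stats(fossil_matrix())
s$max_coded_index; s$percent_of_total
#> [1] 88
#> [1] 61.5
diagnostic_match(fossil_matrix(), c("18" = 1, "34" = 1))
#> [1] "Scelianoma_compacta"
```

A command-line wrapper ships in `inst/cli/rcc5align.R`
(`align`, `mir`, `check`, `graph`, `worlds`, `regions`, `matrix`,
`simulate`; exit codes 0 ok / 1 parse error / 2 inconsistent).

See `vignettes/alignment-methods.Rmd` for the model, the
satisfiability procedure, and the design decisions.

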