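---
title: "How gangliosim builds the ganglioside biosynthetic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How gangliosim builds the ganglioside biosynthetic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangliosim)
```

## The model

`gangliosim` treats ganglioside biosynthesis as a string-rewriting system.
A glycan is a rooted tree of residues anchored on ceramide, serialized as
a single-letter identifier read right to left from the reducing end:
`G` (Glc), `L` (Gal), `S` (Neu5Ac), `V` (GalNAc), `T` (ceramide), with
`a`/`b` anomer letters, linkage digits, and brackets around branches that
are not the continuation of the main chain. Each sugar carries a default
anomer (Glc and Gal β; Neu5Ac and GalNAc α), so the abbreviated dialect
drops anomer letters — except GalNAc, which occurs here as the β anomer,
opposite to its default, and therefore always keeps its `b`. GM1a is
`L3Vb4[S3]L4GT`, in full `Lb3Vb4[Sa3]Lb4GbT`.

An enzyme activity is a nucleotide-sugar donor plus one or more acceptor
patterns with a rewrite, in the classical transferase scheme
Ax + B = A + xB. Two rewrite shapes occur: *extension* inserts the new
residue linearly into the chain (x + yB → xyB), and *decoration* creates a
new bracketed branch (x + yB → [x]yB). The ten activities of the default
set (`default_ruleset()`) are classified by how they combine these shapes
with further extendability: extension (activities 1–3, 5, 7, 8),
decoration with extension (4, the GM3/GM4 synthase), decoration (10, the
α2,6-sialyltransferase), termination with extension (9) and termination
(6). `classify_activity()` re-derives the shape from each rewrite and
refuses a rule whose declared category disagrees, so user-edited rule sets
are checked structurally.

The simulator (`expand_network()`) starts from a seed (bare ceramide by
default), and at each iteration offers every structure first formed in the
previous iteration to every active enzyme. All reactions found are kept —
including reactions into structures already known — and the novel products
form the next frontier. Expansion stops when an iteration yields nothing
new, or at `max_iterations` (default 20), in which case the result carries
a `truncated` flag. With the default rule set, the fixed point from
ceramide is reached after 11 productive iterations:

```{r}
glance(expand_network())
```

## Pattern-matching semantics

Acceptor patterns operate on canonical abbreviated identifiers, which are
unambiguous once sibling branches are ordered (lowest linkage written
first, reading right to left) and default anomers dropped. Two anchoring
modes exist, and the choice is load-bearing:

* **Prefix patterns** must match the whole identifier from the
  non-reducing end through the terminal `T`, with `*` standing for one
  bracket-balanced stretch. Prefix anchoring of activity 5
  (`[S3]L4*T → [S8S3]L4*T`) is what encodes the biological assumption that
  GD3 synthesis precedes core extension with GalNAc: once a `Vb4` prefix
  is in place, the pattern can no longer see the `[S3]` branch.
* **Internal patterns** match a literal bracketed branch anywhere in the
  string, brackets aligned character-for-character. Activity 6 carries the
  single internal pattern `[S8S3] → [S8S8S3]`; literal alignment means it
  does not match inside `[S8S8S3]`, which (together with the prefix
  patterns stopping at `S8S3`) caps every sialyl chain at three — no
  product ever contains `S8S8S3` extended further, and the test suite
  asserts the absence of `S8S8S8` across the exhaustive expansion.

Bracketing is semantic, not cosmetic: the decorated `[S3]L4GT` (GM3) and a
hypothetical linear `S3L4GT` are different strings and different trees,
and only the former is producible. Canonicalization therefore never
converts a branch into a chain, even for an only child.

Three acceptor-pattern generalizations beyond the classical minimal table
are part of the default set, each forced by the published product
repertoire: activity 6 also initiates the terminal chain
(`S3*T → S8S3*T`, without which the 0-series GD1/GT1 and the b/c-series
α-variants are unreachable), activity 5 accepts the sialylated
galactocerebroside (`[S3]LT`, giving GM4 → GD4), and activity 7 accepts
the di- and trisialylated lactosylceramides (giving GD2 and GT2). GD4 → GT4
is carried by activity 6's internal pattern, since activity 5 has no
`[S8S3]`-elongating rewrite.

## Counting conventions

Three bookkeeping decisions fix the headline numbers and are asserted by
the oracle test:

* an *iteration* is one synchronous pass over the previous generation's
  novel structures, and `iterations_run` counts passes that produced at
  least one novel structure — the final, unproductive pass that detects
  the fixed point is not counted;
* reactions discovered later into already-known products are retained
  (several structures have two producers, which is why 41 structures sit
  on 49 reactions);
* the seed is excluded from the product count but included as a network
  node (generation 0).

## The independent oracle

`reference_enumeration()` rebuilds the expected wild-type network without
the pattern engine, from the closed-form parameterization of the grammar:
the Gala arm (4 structures), the GlcCer arm with its sialylated and
GalNAc-extended intermediates (9), and the fully extended core family — a
grid over position II branch length 0–3, terminal position IV chain 0–3,
and the optional position III α2,6-Neu5Ac, with α permitted only alongside
a terminal chain, giving 4 × (1 + 3 × 2) = 28 — with the 49 reactions
written out family-by-family and generations assigned by breadth-first
traversal. The equivalence test compares node sets, generation tags and
labelled edges exactly. Because the enumeration is also the sampling pool
for property tests (`sample_ganglioside_identifiers()`), the grammar the
tests draw from is the full reachable set: the grammar is finite, so
"random grammar-valid structures" means uniform draws with replacement
from the 42 canonical identifiers rather than unbounded tree generation.
That is also the main limitation of the property suite: it exercises
exactly the reachable chemistry, so robustness on malformed or
out-of-grammar input is covered separately by the explicit error-path
tests, and nothing here validates the rule set against structures the
model cannot represent (Neu5Gc/KDN variants, O-acetylation, fucosylated
hybrids).

## Nomenclature

The systematic Svennerholm name is assembled from `core_info()`: `"G"`,
the total Neu5Ac count as a letter (A, M, D, T, Q, P, H, S for 0–7; larger
counts are rejected rather than guessed), the core number 4 − n + 1 (n =
backbone residues present; GalCer is core number 4), the series letter
a/b/c when the core is fully extended and position II carries 1–3 sialic
acids, and a trailing `α` for the position III Neu5Ac. Ceramide and GlcCer
fall outside the system (it starts at LacCer/GalCer) and are deliberately
unnameable: `systematic_svennerholm()` returns `NA` and exports render
them by identifier. `parse_ssn()` inverts the name — series letter to the
II branch, α to III, the remainder of the count to the IV chain — and
rejects inconsistent names such as `GM1b` (series b implies two sialic
acids, the letter M allows one), which is precisely why that common name
survives only as a legacy alias handled by `legacy_mapping()`.

Conventions chosen where usage varies, all flagged here rather than
silently assumed: the IUPAC `Gg` subscript is the number of oses in the
linear core (so GM3 renders as `II3Neu5Ac-Gg2Cer`); GM4 is rendered on the
GalCer core with the galactose as position I (`I3Neu5Ac-GalCer`);
super/subscripts are flat by default for bit-stable CSV output, with
`markup = TRUE` switching to `^..^`/`_.._`; the rescinded `GgOse_n_Cer`
descriptor is never emitted; and Linear Code output uses the fixed symbol
map Gal → `A`, Glc → `G`, GalNAc → `GN`, Neu5Ac → `NN` with parenthesized
branches, as an export-only format — no published example pins down every
corner of that dialect, so no importer is offered.

## Knockouts and enzyme inference

A knockout removes a rule and regenerates the network; since rules only
ever add possibilities, knockouts are monotone (nodes and edges of a
deeper knockout set are a subset of a shallower one), which the tests
assert for all ten single knockouts. `infer_required_enzymes()` inverts
the rewrites instead: each rule's replacement is matched against the
target, the pattern restored, the candidate substrate verified by forward
application, and the backward closure searched until ceramide is reached.
Ties (several removable residues) are explored exhaustively; the witness
path returned prefers the lexicographically smallest substrate/enzyme at
each breadth-first level, and the enzyme *set* is path-independent on this
grammar. An underivable target returns an explicit unreachable result
naming the first intermediate with no producing reaction.

## Numerical and engineering choices

There are no tolerances anywhere — the system is exact string rewriting —
so determinism is the only numerical property: node and edge tables are
canonically sorted, rule application is set-semantic (duplicate products
of one rule collapse; identical substrate/enzyme/product triples collapse),
and expansion is invariant under permutation of rule order, which is
tested directly. Exports avoid timestamps so repeated runs are
byte-identical. SBML output is Level 3 Version 1 core with a single
`golgi` compartment (the model has no transport), species for every glycan
plus the four donors and two nucleotides (static ChEBI annotations from a
hard-coded table), one irreversible reaction per edge with all
stoichiometries 1, and reversible bracket escaping in species ids
(`[` → `_l`, `]` → `_r`) so `read_sbml_network()` reconstructs the edge
list exactly; well-formedness and this round trip are what the tests
check, as no schema validator ships with the package.

Problem sizes in the test suite are the natural ones for this model: the
exhaustive 41-structure network everywhere, 500–1000 uniform draws for the
round-trip properties, and full backward inference over every node; the
whole suite is exact-equality throughout.

## Limitations

The model is Boolean in enzyme activity — no kinetics, expression levels,
donor availability or competition; networks are exported to SBML precisely
so rate laws can be added downstream. Lysosomal recycling, glycosidases,
transport compartments, Neu5Gc/KDN sialic acids and O-acetylation are out
of scope, as are 2-D structure drawing and GlycoCT import/export. The
nomenclature engine covers the ganglio and Gala series this grammar
generates; it will refuse, rather than guess at, anything else.
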