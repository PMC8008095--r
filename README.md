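# gangliosim

Rule-based simulation of ganglioside biosynthesis in R.

Gangliosides are sialylated glycosphingolipids — oligosaccharides carrying
one or more N-acetylneuraminic acid (Neu5Ac) residues, linked to ceramide —
that dominate the neuronal cell surface. Their biosynthesis in the
ER/Golgi is a stepwise relay of glycosyltransferases, each transferring one
monosaccharide from a nucleotide-sugar donor to a growing ceramide-linked
acceptor. `gangliosim` models the ten enzyme activities of this pathway as
string-rewrite rules over compact structure identifiers, and generates the
complete biosynthetic reaction network by iterating them to a fixed point.
It is aimed at glycobiologists and systems biologists who want to explore
how congenital enzyme deficiencies (or tumor-associated expression changes)
reshape the ganglioside repertoire, and to hand the resulting networks to
kinetic modelling tools via SBML.

## The model

A glycan is written as a single-letter string read right to left from the
ceramide end: `G` = Glc, `L` = Gal, `S` = Neu5Ac, `V` = GalNAc, `T` =
ceramide; `a`/`b` mark anomers (each sugar has a default, so most are
dropped; GalNAc keeps its `b`), digits give linkage positions, and brackets
delimit branches. GM1a, IUPAC
`Galb1-3GalNAcb1-4[Neu5Aca2-3]Galb1-4GlcCer`, is `L3Vb4[S3]L4GT`.

Each enzyme is a donor plus one or more acceptor patterns with a rewrite,
in the transferase scheme Ax + B = A + xB (Ax the nucleotide sugar, B the
acceptor). For example the GM3 synthase ST3Gal-V is
`CMP-S + L4GT -> CMP + [S3]L4GT`. Patterns are anchored at the reducing-end
`T`; `*` is a wildcard for an unspecified stretch of the acceptor. The
simulator applies every active enzyme to every newly formed structure, one
synchronous generation per iteration, until no new product appears.
Starting from bare ceramide the default rule set converges after 11
productive iterations on **41 structures in 49 reactions**: the Gala arm
(GA4–GT4), the asialo precursors, and the 0-, a-, b- and c-series defined
by 0–3 Neu5Ac on the inner galactose (position II), each extendable by a
terminal sialyl chain on position IV and an α2,6 Neu5Ac on the core GalNAc
(the α-variants).

Every structure is named automatically: the systematic Svennerholm name is
`"G"` + total-sialic-acid letter (A, M, D, T, Q, P, H, S for 0–7) + core
number (4 − n + 1) + series letter (a/b/c) + optional `α`, and the IUPAC
ganglioside name lists the sialylated positions as Roman numerals over the
`Gg_n_Cer` core.

## Worked example

```r
library(gangliosim)

net <- expand_network()          # seed "T", default 10-enzyme rule set
glance(net)
#> # A tibble: 1 × 5
#>   n_structures n_reactions iterations_run truncated n_enzymes_used
#>          <int>       <int>          <int> <lgl>              <int>
#> 1           41          49             11 FALSE                 10

systematic_svennerholm("S3L3[S6]Vb4[S8S8S3]L4GT")
#> [1] "GP1cα"
iupac_ganglioside_name("S3L3[S6]Vb4[S8S8S3]L4GT", markup = TRUE)
#> [1] "IV^3^Neu5Ac,III^6^Neu5Ac,II^3^(Neu5Ac)_3_-Gg_4_Cer"

# A UGCG (glucosylceramide synthase) knockout leaves only the Gala arm:
glance(expand_network(knockouts = 1))
#> # A tibble: 1 × 5
#>   n_structures n_reactions iterations_run truncated n_enzymes_used
#>          <int>       <int>          <int> <lgl>              <int>
#> 1            4           4              4 FALSE                  4

# Which enzymes are needed to make GM1a?
infer_required_enzymes("L3Vb4[S3]L4GT")$enzymes
#> [1] 1 3 4 7 8
```

`glance()` reports the product count (seed excluded), reaction count and
the number of iterations that yielded novel structures; the five inferred
enzymes are the path GlcCer → LacCer → GM3 → GM2 → GM1a. Networks export
with `write_network_csv()`, `write_sbml()` (SBML Level 3 Version 1, ready
for Copasi and friends), `write_dot()` and `write_edgelist()`, plot with
`autoplot()`, and the same functionality is available from a shell via
`inst/cli/gangliosim` (subcommands `simulate`, `knockout`, `name`,
`convert`, `infer`).

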