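# unifynet

Rule-based unification of biological records and interaction-network
analysis.

Interaction and annotation data for the same molecule is spread across
repositories that disagree on identifiers: a yeast release factor is
`P12385` to a curated sequence database, `EBI-6533` to IntAct, `MINT-560710`
to MINT and `REACT_1034` to Reactome.  Pooling such sources without
deciding which records are the same molecule double-counts nodes and loses
edges.  unifynet is for bioinformaticians who need to integrate several
such sources on their own machine, keep full provenance, and analyze the
resulting networks.

## What it computes

**Unification.**  Records (`external entities`) from versioned sources are
partitioned into **user entities** by a *unification protocol*: a set of
rule atoms, each naming a pair of sources and a set of attributes.  Two
records are equivalent under an atom iff they share a value for **every**
attribute in it (AND within an atom); atoms are OR-ed and closed
transitively, so user entities are the connected components of the pair
graph.  Sources flagged **promiscuous** (domain/structure classifications)
may attach records to several classes but never merge classes or found one
alone.  Every class can be backtracked to its source rows and the exact
rule firings that fused them.

**Networks.**  User entities become nodes; relations (binary or n-ary,
lifted to cliques) become edges with provenance.  Networks grow
breadth-first from seed nodes — seeds at level 0, partners at level 1,
level *i+1* from level *i* — under optional relation-attribute
restrictions, and support tagging, linker degrees, degree-preserving
randomization and intersection/union.

**Edge prediction (generalized interologs).**  An edge x–y is predicted
when x–z is observed and y matches z by shared attributes (e.g. Pfam) or by
local sequence alignment passing similarity and coverage cutoffs
(conventionally 90%/90%; Smith–Waterman–Gotoh, BLOSUM62, affine gaps).
Predicted edges are flagged, carry evidence, and never overwrite observed
ones.

Readers are included for a generic tabular record format, PSI-MI TAB 2.5
and FASTA; networks export to SIF and a round-trippable provenance TSV.
A synthetic-data module generates every fixture deterministically, so the
whole package is testable offline.

## Worked example

Four sources each report the same protein under their own identifier; all
four records carry UniProt accession `P12385`.  Under the recommended rules
(accession OR sequence+taxon OR GeneID) they collapse into one node:

```r
library(unifynet)

fx <- make_worked_example_fixture()
ue <- unify(fx$registry, fx$protocol)
glance(ue)
#> # A tibble: 1 × 5
#>   n_user_entities n_records n_promiscuous_attachments n_singletons largest_class
#>             <int>     <int>                     <int>        <int>         <int>
#> 1               1         4                         0            0             4

backtrack(ue, 1)
#> <ue_report> user entity 1: 4 source record(s)
#>   #1 swisslike 1.0: name=P12385; UniprotAccession=P12385; UniprotEntry=ERF1_YEAST; ...
#>   #2 intactlike 1.0: name=EBI-6533; UniprotAccession=P12385
#>   #3 mintlike 1.0: name=MINT-560710; UniprotAccession=P12385
#>   #4 reactomelike 1.0: name=REACT_1034; UniprotAccession=P12385
#>   merge justifications:
#>     1 ~ 2 via atom 2 (UniprotAccession = p12385)
#>     ...
```

One user entity containing all four records: the accession rule fired for
every source pair, and the report shows each record's origin and the shared
value behind each merge.  Querying by any source's vocabulary
(`select_seeds(ue, list(UniprotEntry = "ERF1_YEAST"))`) finds the same
node, which can then seed `expand_network()`, `transfer_edges()` and the
rest of the session layer.

A shell pipeline covering the same ground:

```sh
Rscript inst/cli/unifynet.R fixtures --name worked_example --dir demo/
Rscript inst/cli/unifynet.R import --registry demo/reg.json --db swisslike \
    --db-version 1.0 --entities demo/swisslike.tsv
# ... import the remaining sources, then:
Rscript inst/cli/unifynet.R unify --registry demo/reg.json \
    --protocol demo/protocol_recommended.json --out demo/partition.tsv
```

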