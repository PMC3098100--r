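---
title: "Rule-based record unification and network inference with unifynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based record unification and network inference with unifynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unifynet)
```

## The problem

Molecular-interaction data is scattered across repositories that name the
same protein in incompatible ways: a UniProt accession here, an IntAct
internal id there, a Reactome identifier elsewhere.  Any network analysis
that pools such sources without first deciding which records are *the same
molecule* will double-count nodes and miss edges.  unifynet addresses this
with three layers:

1. a **registry** of raw records ("external entities") from versioned
   sources ("external databases"), each record carrying a multimap of
   attributes (accessions, sequences, taxon ids, gene ids, domain
   annotations, ...);
2. a **unification protocol** that partitions the records into **user
   entities** — the equivalence classes that become network nodes; and
3. a **session layer** that builds seed-anchored networks over user
   entities, annotates and randomizes them, and predicts new edges by
   transferring observed relations to entities with shared attributes or
   similar sequences (a generalization of interolog mapping).

Raw data is never rewritten: the registry stores records exactly as
imported, so any node or edge can be backtracked to the source rows and the
rule firings that fused them (`backtrack()`).

## The unification model

A protocol is a set of **atoms**.  One atom names an unordered pair of
databases and a set of attributes, and declares two records equivalent iff
they share at least one value for *every* attribute in the atom (AND within
an atom).  Atoms combine by union (OR across atoms), and equivalence is
closed transitively: the user entities are the connected components of the
pair graph.  A typical recommended rule set is "same UniProt accession, OR
same sequence AND taxon, OR same GeneID, over all source pairs":

```{r}
fx <- make_worked_example_fixture()
fx$protocol
ue <- unify(fx$registry, fx$protocol)
tidy(ue)
backtrack(ue, 1)
```

Which rules you pick matters.  The bundled demonstration fixture
(`make_figure_fixture()`) arranges four proteins from two sources so that
unifying by accession merges one pair, unifying by sequence-plus-taxon
merges nothing (the records carry different sequences), and unifying by
accession OR gene symbol chains all four into one node.

### Promiscuous sources

Domain and structure classifications (SCOP-like sources) annotate many
unrelated proteins with the same value.  Crossing them naively would fuse
every protein sharing a fold.  Sources can therefore be flagged
*promiscuous*: their records may be attached to several user entities but

- a pair with a promiscuous endpoint never merges two classes (components
  are computed over non-promiscuous pairs only),
- promiscuous-promiscuous pairs are ignored entirely, and
- a promiscuous record attached to no class appears in no user entity.

The first rule is a genuine design choice: membership multiplicity does not
by itself say whether promiscuous links may be transitive.  We chose
non-transitivity because the alternative lets one shared SCOP domain fuse
unrelated proteins, defeating the purpose of the flag — promiscuous sources
annotate, they do not unify.  The choice is enforced by construction
(classes are built before attachment) and checked by property tests.

### Normalization and determinism

Cross-database casing and whitespace are inconsistent, so values are
compared after normalization: identifiers case-insensitively, sequences
upper-cased with whitespace stripped, taxon and gene ids as integers
(records whose integer attributes do not parse are skipped at import, with
a log message).  Long sequences enter the inverted index as a 128-bit hash
plus length rather than as the literal string; at desk scale the collision
probability is negligible, and the full sequence is still stored on the
record.  All identifiers (`db_id`, `entity_id`, `ue_id`) are dense integers
assigned deterministically — `ue_id` by smallest member — so identical
inputs give byte-identical outputs, and the partition is invariant to atom
order and registration order (tested by permutation).

## Networks over user entities

`expand_network()` grows a network outward from seed user entities: seeds
are level 0, their relation partners level 1, and level *i+1* holds the
partners of level-*i* nodes, up to a chosen depth.  Relations can be
filtered by type and by attribute predicates (for example, detection
method) before they contribute edges; tightening a restriction can only
shrink the result.  Three choices here were genuinely open:

- **Edges at the boundary.**  Edges between two depth-level nodes are kept
  (both endpoints are already in the network; keeping the edge costs no
  extra node), while edges to deeper nodes are dropped.  This makes the
  depth-*d* network the full induced subgraph on nodes within distance
  *d*, and depth-*d* output is always a subgraph of depth-*d+1*.
- **n-ary relations** (complexes, pathways) lift to the clique over their
  participants' user entities, every resulting binary edge citing the same
  source relation as provenance.  Without bait/prey annotation this is the
  only lossless lift.
- **Promiscuous members** may carry relation participation (an edge can
  reach a class through a shared domain record) but never merge nodes.

Networks are undirected; each edge keeps its relation type, the source
relation ids (provenance), an `inferred` flag and free-text tags.  Analysis
helpers include tagging, `linker_degree()` (distinct neighbors carrying a
tag — the standard way to rank candidate linkers between two disease node
sets), degree-preserving randomization (double edge swaps via igraph,
reproducible under a seed, never introducing self-loops or multi-edges) and
set algebra over networks built on the same partition
(`combine_networks()`).  Anything beyond that — shortest paths,
centralities, components — is deliberately delegated: `as_igraph()` exports
the network to the ambient graph library instead of re-implementing it.

## Edge prediction by transfer

Let x, z, y be user entities.  If x–z is observed and y "matches" z under a
user-chosen criterion, x–y is predicted (both endpoints act as templates;
the rule is symmetric).  Matching is either

- **shared attributes**: y shares at least one value with z for every
  listed attribute (Pfam domains, say), or
- **sequence similarity**: some member sequence of y aligns to some member
  sequence of z at or above a similarity cutoff with at least a coverage
  cutoff of z's sequence aligned (90%/90% is the conventional operating
  point).

The built-in aligner is a Smith–Waterman–Gotoh local alignment with affine
gaps (default BLOSUM62, gap open 10, extend 1; total cost of a length-L gap
is open + extend·L).  Since "percent similarity" has no universal
definition, we define it as the percentage of alignment columns with a
positive substitution score (gap columns count in the denominator), with
percent identity available as an alternative measure; coverage of a
sequence is the percentage of its residues inside the aligned region.
Cutoffs are compared with ≥, traceback ties prefer the diagonal, and the
first best-scoring cell in row-major order anchors the traceback, so
results are deterministic.  E-value-based matching is out of scope for the
built-in aligner; precomputed external search results can be expressed as
shared attributes instead.

Predicted edges are flagged `inferred`, cite the template relation and the
evidence (shared values or alignment statistics), never overwrite an
observed edge, and are transferred from observed edges only — one round per
call, so iterating transfer is an explicit user decision rather than a
hidden fixpoint.

```{r}
hs <- random_homolog_set(n_proteins = 6, n_twin_pairs = 1, rng_seed = 3)
ue <- unify(hs$registry, hs$protocol)
ia <- random_interactome(ue, 0.4, rng_seed = 3)
net <- expand_network(ue, sort(unique(ue$membership$ue_id)), depth = 0)
crit <- transfer_criterion("sequence_similarity",
                           min_similarity = 90, min_coverage = 90)
glance(transfer_edges(net, ue, crit))
```

## What the synthetic data emulates — and what it does not

Every fixture is generated in code, deterministically under a seed:

- `make_worked_example_fixture()` — one protein reported by four
  repositories under four native identifiers, all carrying the same
  accession; the recommended rules must collapse them into one node.
- `make_figure_fixture()` — the protocol-sensitivity scenario above, plus a
  promiscuous domain source.
- `random_registry()` — multi-source registries with *planted* equivalence
  classes realized as chains of shared accession values (consecutive
  members share a fresh value), so the intended partition is exactly the
  transitive closure of the planted links and never leaks across classes.
  Optional promiscuous annotators attach to one or two classes through
  domain values crossed only against the annotator source.
- `random_interactome()` — relations sampled between classes with known
  ground-truth edges; `random_homolog_set()` — proteins with planted
  near-duplicate sequence pairs (one substitution on 40 residues, so twins
  clear 90/90 while unrelated random sequences do not).

These generators reproduce the *structural* difficulties of integration —
identifier overlap, chained equivalences, promiscuous annotation, n-ary
relations — at sizes of tens to a few hundred records per instance (the
property suites run 20–100 instances per law).  They do not emulate real
databases' record syntax, their error modes (stale cross-references,
merged/demerged accessions), paralog-rich sequence families, or
million-edge interactomes; passing tests therefore demonstrate correctness
of the algorithms under the stated model, not robustness to dirty
real-world dumps.  Sequences are short synthetic strings, which keeps the
alignment oracle exhaustive and fast but does not probe long-sequence
numerical behaviour (irrelevant here: the scoring is integer arithmetic).

## Numerical and degenerate-input choices

- Equality of DP scores is exact (integer substitution matrices and gap
  costs), so tie-breaking, not floating point, decides tracebacks.
- An alignment with no positive-scoring cell reports score 0 and empty
  alignment; empty sequences are an error.
- A relation needs ≥ 2 participants; self-relations (one id twice) are
  allowed and surface as self-loop edges, which level computation and
  randomization ignore.
- Depth-0 networks contain the seeds and any seed self-loops.
- `combine_networks()` refuses networks built over different partitions
  (checked via a partition fingerprint carried by every network file).
- Missing attributes never match anything (no wildcard semantics), and an
  atom whose attribute has no values anywhere simply fires nowhere.
- Unknown attribute names must be registered before use; importers register
  unknown MITAB namespaces on the fly instead, so no identifier is silently
  dropped before unification.

## Limitations

Re-unification after registry edits is a full recompute; merges carry no
confidence score; the MITAB reader targets the 15-column 2.5 core (extra
columns ignored, XML formats out of scope); and the CLI's `--seed` governs
only the package's own generators.  The registry is an in-memory store with
JSON persistence — appropriate for the desk-scale datasets the package
targets, not for warehouse-sized integration.
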