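---
title: "Join-aware source selection for federated RDF data cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Join-aware source selection for federated RDF data cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubefed)
```

## The problem

Clinical sites that cannot share patient-level records can still share
anonymised statistical summaries: multi-dimensional data cubes whose
observations count patients per combination of clinical conditions
(e.g. Diabetes = 1, Hypertension = 1, BMI_Abnormal = 0 → 26 cases).
Published in the W3C RDF Data Cube (QB) vocabulary, one cube per named
graph, one SPARQL endpoint per site, such data can be queried with
standard federation techniques — except that two requirements interact
badly with off-the-shelf engines:

* **Graph-level access control.** Read rights are granted per named
  graph (per cube), default deny. Source selection at the endpoint
  level is too coarse to enforce this before dispatch.
* **Efficiency.** Generic engines select sources per triple pattern,
  overestimating badly on cube data where most predicates (dimensions,
  `rdf:type`, `qb:dataSet`) occur in many cubes.

cubefed implements a federation engine specialised for this setting:
instance-free data summaries, two-level join-aware source selection at
the granularity of named graphs, policy filtering applied to the
selection before any sub-query is dispatched, and a graph-restricted
executor, together with a brute-force merged-dataset oracle used to
verify all of it.

## The model

A federation is a set of datasets $\mathcal D$; a dataset $D$ is a set
of named graphs $(u, G)$ published at endpoint $\mathrm{loc}(D)$, each
graph holding exactly one data cube. There is no default graph.
Two structural assumptions carry the whole design:

1. **No blank nodes.** Completeness of federated BGP evaluation is
   known to break in their presence; loaders reject them outright.
2. **Subject locality.** A subject IRI occurs in at most one named
   graph across the whole federation: cubes are self-contained, so a
   subject–subject (s–s) join can only be satisfied inside one graph.
   `validate_locality()` checks this on demand; the synthetic
   generators guarantee it structurally by prefixing observation IRIs
   with their graph IRI.

The *data summary* of $D$ stores $\mathrm{loc}(D)$, the graph names,
and the map from each predicate to the graphs containing it — no
instance data, so summary size is independent of observation counts and
a summary is cheap to recompute when a source changes (the package
deliberately recomputes from scratch rather than maintaining indexes
incrementally). From the summaries, `derive_indexes()` computes
$\mathrm{preds}(D)$, the per-graph unique predicates
$\mathrm{upreds}(u, D)$ (predicates occurring in $u$ and no other graph
of $D$) and $\mathrm{unames}(D)$, the graphs owning at least one unique
predicate. `rdf:type` and the QB structural predicates are indexed
exactly like domain predicates; the clinical worked example depends on
`rdf:type` matching all graphs.

## Source selection

Each BGP of the query is partitioned into *subject groups* (patterns
sharing one subject term, variable or constant; two distinct variables
never merge). For a group with bound predicate set $P_s$:

* a dataset $D$ is a candidate iff $P_s \subseteq \mathrm{preds}(D)$;
* within a candidate, if $P_s$ meets $\mathrm{upreds}(u, D)$ for
  exactly one graph $u$, the whole group is pinned to $u$; if it meets
  the unique predicates of two different graphs, no single graph can
  satisfy the s–s join and $D$ is discarded; otherwise all graphs of
  $D$ remain;
* each pattern is finally intersected with the graphs containing its
  predicate. This last step is a deliberate tightening beyond pure
  group-level selection: predicate presence is necessary for a pattern
  to match, so it can only remove graphs that cannot contribute, and
  the correctness property below is tested with it in place.

Variable-predicate patterns inherit their group's restriction when one
exists; otherwise, if subject or object is bound, one single-pattern
ASK probe per dataset decides whether all of that dataset's graphs are
added, and a fully unbound pattern matches every graph with no probe.
A group consisting only of variable-predicate patterns is resolved
pattern by pattern through that ASK branch (whether the original
formulation batches such probes is unspecified; per-pattern probing is
the conservative reading and the probe count is reported).

Selections are computed per BGP and kept separate, because the same
pattern may legitimately select different sources in different UNION
or OPTIONAL branches. Access control then removes every
(dataset, graph) pair whose graph the user cannot read — so an
unauthorised graph is never named in any later request, rather than
being refused by the remote endpoint at execution time. Only the
`read` right gates querying; `write` is carried in the policy model but
unused. Profile attributes (activity, location, organisation, position,
role) are parsed and preserved but not evaluated as conditions: in the
platform this models, attribute-based authentication happens in an
external PKI layer that the engine treats as a black box.

## Execution

Whole subject groups are pushed as one sub-query per dataset — a
`SELECT` over `GRAPH ?__g { ... }` with an inline `VALUES` clause
enumerating the permitted graphs (`rewrite_subquery()`). Locality makes
this *exclusive-group* pushdown safe: a subject group can never join
across graphs, so evaluating it per graph and unioning per-dataset
answers loses nothing, while sending far fewer requests than
per-pattern bind joins. Cross-group joins are local hash joins
(data.table), taken smallest-intermediate-first with
connected-before-cartesian ordering; ties keep query order.
Cardinalities are observed, not estimated — reasonable at the scale an
in-memory federation runs at. UNION branches are unioned, OPTIONAL
blocks left-joined, FILTERs evaluated on the joined bindings with
SPARQL error semantics collapsed to row removal, then DISTINCT /
ORDER BY / LIMIT. Bag semantics throughout.

The supported query fragment is SELECT with BGPs, FILTER
(comparisons, `&&`, `||`, `!`, `REGEX`, `BOUND`), UNION, OPTIONAL,
DISTINCT, ORDER BY and LIMIT. Aggregates, property paths, subqueries
and SERVICE are rejected with explicit errors. Filters are collected
globally and applied after the joins; for the fragment above this is
observationally equivalent for the tested query shapes, and queries
relying on filter scoping subtleties inside OPTIONAL are outside the
fragment. Subject groups are formed across the whole BGP regardless of
where FILTERs sit in the source text.

## The oracle and what the tests show

`evaluate_merged()` merges every named graph into one global dataset
and evaluates the query there with no selection, no summaries and no
clients — the definition of the correctness condition: for every
supported query over locality-respecting, blank-node-free data,

$$[\![\mathfrak D]\!]_{bgp} \;=\; [\![R(t_1)]\!]_{t_1} \bowtie \dots
\bowtie [\![R(t_n)]\!]_{t_n},$$

tested as multiset equality between `execute()` and
`evaluate_merged()`. The acceptance suite runs this on 100 seeded
random federations (2–5 datasets, 1–4 graphs each, a pool of 3–8
dimension predicates, 5–200 observations per graph) with 5 random
conjunctive queries each; policy-filtered execution is compared against
the oracle restricted to the user's readable graphs on two queries per
federation. Pruning soundness — forcing any single pruned
(dataset, graph) pair back into the selection never changes the result
— is checked exhaustively over all pruned pairs on the first query of
each federation and on one sampled pruned pair for the others; these
problem sizes keep the default suite comfortably inside a desk-scale
run while every branch of the selection algorithm (pinning, conflict
discard, all-graphs, ASK, inheritance) is exercised. One test
additionally cross-checks the clinical example against Python rdflib
as an independent SPARQL implementation.

What passing does *not* show: the generators emit regular, fully
populated binary cubes with uniformly drawn measures. Real cube
collections have skewed dimensions, missing combinations, SDMX
annotations, slices (`qb:Slice` is not generated — the selection
algorithm never inspects slices) and far larger observation counts, so
the suites validate algorithmic correctness, not performance or
robustness to messy vocabularies. Comparative benchmark figures from
the original evaluation setting (multi-machine Virtuoso deployments,
external LOD cube collections) are hardware- and data-dependent and are
not reproduced.

## Numerical and design choices

* **Terms** are stored in an N-Triples-like string encoding; numeric
  literals compare numerically in FILTERs and ORDER BY (non-numeric
  terms sort lexically by encoded form), everything else by exact term
  equality. Turtle shorthand integers parse to `xsd:integer` literals
  and serialise back to shorthand, making round trips exact.
* **Determinism**: all serialisers radix-sort their output, so equal
  inputs give byte-identical documents; generators take explicit seeds
  and restore the caller's RNG state.
* **Blank nodes / default-graph triples / duplicate graph names** are
  load-time errors, not warnings: silently dropping or skolemising
  would hide data from selection and void the correctness argument.
* **Degenerate inputs**: empty datasets yield valid empty summaries;
  a group whose predicates exist nowhere selects nothing and produces
  an empty result without dispatching requests; a user with no grants
  gets an empty result with zero data sub-queries.
* **Remote mode** builds the same rewritten sub-queries and speaks the
  SPARQL 1.1 protocol, trusting the endpoint to enforce the graph
  restriction in the query text; in-memory mode enforces it
  structurally. Endpoints that reject `VALUES` would need one request
  per graph; the in-memory client needs no such fallback.
* The **vocabulary namespaces** used for the clinical terms
  (`sehr:`), the policy/summary terms (`lmds:`) and the example graph
  names are illustrative constants; the summary RDF shape (one IRI
  cube node per graph carrying `lmds:graph` and repeated
  `lmds:cubeProperties`) is this package's concretisation, with JSON as
  the canonical interchange format. Cell values of the example cubes
  beyond the stated 26-cases row are fixed constructed fillers.

## A worked run

```{r example}
ex <- running_example()
index <- derive_indexes(build_summaries(ex$federation))
index$upreds$CHUV

sel <- select_sources(parse_query(ex$queries$subject_selection), index)
sel$per_bgp[[1]][[2]]   # sources for '?observation qb:dataSet ?dataset'

res <- execute(ex$queries$cases, ex$federation, index = index,
               policy = ex$policy, user = ex$user)
as.data.frame(res)
attr(res, "metrics")[c("subqueries", "asks")]
```

Restricted to Diabetes = 1, BMI_Abnormal = 0, Hypertension = 1, the
user James sees the 26-cases observation from `:CHUV-S1` and the
corresponding row from `:CING-S2`; `:ZEINCRO-S3` holds a matching row
but is removed from the selection by the policy before any request is
sent.

## Known limitations

* Joins other than s–s are never used for pruning (e.g. the s–o
  locality of `qb:dataSet` links could tighten selection further).
* No caching of ASK results across queries, no cardinality-based
  source ranking, no streaming joins: the executor is correct and
  simple rather than adaptive.
* Locality is assumed, optionally validated, never repaired; data that
  violates it silently under-reports joins in federated mode (the
  oracle will expose this, which is precisely its job).
* The SPARQL fragment excludes aggregates, so typical OLAP roll-ups
  must happen client-side on the returned bindings.
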