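# cubefed

Federated SPARQL querying of RDF Data Cube collections with graph-level
access control, in R.

## The problem

Clinical organisations that may not share patient-level records can
share anonymised statistical summaries: RDF data cubes (W3C QB
vocabulary) whose `qb:Observation`s count patients per combination of
clinical conditions. Each cube lives in its own named graph, each site
publishes its cubes at its own SPARQL endpoint, and read access is
granted per named graph with default deny. Answering a researcher's
query ("how many cases combine diabetes and hypertension without
abnormal BMI?") then requires a federation engine that selects sources
at the granularity of *graphs*, not endpoints — both to avoid asking
sources that cannot contribute and to never send a request that names a
graph the user may not read.

cubefed is that engine, for in-memory federations (TriG/N-Quads) and,
through the same interfaces, remote SPARQL 1.1 endpoints. It is aimed
at health-informatics and statistical-data practitioners who need
access-controlled integration of cube collections, and at anyone who
wants a compact, fully tested reference implementation of join-aware
graph-level source selection.

## The method

* **Data summaries.** Per dataset `D`: the endpoint URL, the graph
  names, and a predicate → graphs map. No instance data, so the summary
  size is independent of observation counts. Derived indexes:
  `preds(D)`; `upreds(u, D)`, the predicates unique to graph `u` within
  `D`; `unames(D)`, the graphs owning a unique predicate.
* **Two-level join-aware selection.** Triple patterns are grouped by
  subject. Under the *locality* assumption (a subject IRI occurs in at
  most one named graph federation-wide — cubes are self-contained), an
  s–s join is confined to one graph, so: a dataset is a candidate for a
  group only if it holds *all* the group's bound predicates; a
  predicate unique to graph `u` pins the whole group to `u`;
  predicates unique to two different graphs rule the dataset out
  entirely; per pattern, candidates are intersected with the graphs
  containing the pattern's predicate. Variable-predicate patterns
  inherit their group's restriction or trigger one single-pattern ASK
  probe per dataset.
* **Access control.** Policies grant `(user, graph, right)` with
  default deny; the selection is filtered *before* execution, so no
  sub-query ever names an unauthorised graph.
* **Execution.** Each subject group is pushed as one graph-restricted
  sub-query per selected dataset (`GRAPH ?__g` + `VALUES`), answers are
  unioned and hash-joined locally; UNION/OPTIONAL/FILTER/DISTINCT/
  ORDER BY/LIMIT are applied locally. `evaluate_merged()` — evaluation
  over the merge of all graphs into one dataset — serves as the
  brute-force correctness oracle: for blank-node-free,
  locality-respecting data, `execute()` must equal it as a multiset.

## Worked example

```r
library(cubefed)
ex <- running_example()        # three clinical sites, four cubes
index <- derive_indexes(build_summaries(ex$federation))
index$unames$CHUV
#> [1] "<http://example.org/l2s#CHUV-S1>" "<http://example.org/l2s#CHUV-S4>"

sel <- select_sources(parse_query(ex$queries$subject_selection), index)
sel$per_bgp[[1]][[2]]          # sources for the observation group
#>    dataset                               graph
#>     <char>                              <char>
#> 1:    CHUV    <http://example.org/l2s#CHUV-S1>
#> 2:    CING    <http://example.org/l2s#CING-S2>
#> 3: ZEINCRO <http://example.org/l2s#ZEINCRO-S3>
sel$ask_count
#> [1] 0

res <- execute(ex$queries$cases, ex$federation, index = index,
               policy = ex$policy, user = ex$user)
as.data.frame(res)[, "cases"]
#> [1] "\"26\"^^<http://www.w3.org/2001/XMLSchema#integer>"
#> [2] "\"33\"^^<http://www.w3.org/2001/XMLSchema#integer>"
```

The seven-pattern query decomposes into two subject groups; the
observation group selects exactly three cubes — `:CHUV-S4` also holds
diabetes counts but is pruned because the group's unique predicates pin
CHUV to `:CHUV-S1` — with zero ASK probes. With the policy, the user
James reads only `:CHUV-S1` (26 cases for Diabetes = 1,
BMI_Abnormal = 0, Hypertension = 1) and `:CING-S2` (33);
`:ZEINCRO-S3` is removed before any request is dispatched.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cubefed.R",package="cubefed"))')" \
  generate --example --out /tmp/fedex
Rscript .../cubefed.R index  --config /tmp/fedex/federation.yaml --out /tmp/fedex/summaries
Rscript .../cubefed.R select --config /tmp/fedex/federation.yaml --query /tmp/fedex/cases.rq
Rscript .../cubefed.R query  --config /tmp/fedex/federation.yaml --query /tmp/fedex/cases.rq \
  --policy /tmp/fedex/policy.ttl --user "<http://example.org/l2s#James>" --format tsv
```

## Package tour

| Area | Functions |
| --- | --- |
| Federation model | `load_federation`, `federation`, `dataset`, `validate_locality`, `write_federation` |
| Summaries | `build_summary`, `derive_indexes`, `serialize_summary`, `parse_summary` |
| Query model | `parse_query`, `group_by_subject` |
| Selection | `select_sources`, `select_for_group`, `resolve_unbound`, `tp_sources_selected` |
| Access control | `access_policy`, `authorised`, `filter_selection`, `read_policy` |
| Execution | `execute`, `evaluate_merged`, `rewrite_subquery`, `evaluate_group`, `join_groups`, `results_equal` |
| Fixtures | `running_example`, `generate_cube`, `generate_federation`, `random_federation_spec`, `random_conjunctive_query`, `random_policy` |
| CLI | `cmd_index`, `cmd_select`, `cmd_query`, `cmd_generate`, `cmd_validate` (+ `inst/cli/cubefed.R`) |

The methods vignette (`vignettes/cube-federation.Rmd`) documents the
model, its assumptions, the numerical choices and the limits of what
the synthetic suites demonstrate.
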