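Package: cubefed
Title: Federated SPARQL Querying of RDF Data Cubes with Graph-Level Access Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A federated query engine for collections of RDF Data Cubes
    (W3C QB vocabulary) partitioned into named graphs across multiple
    SPARQL sources. Builds lightweight, instance-free data summaries
    (endpoint URL, graph names, predicate-to-graph map), performs
    two-level join-aware source selection that exploits the subject
    locality of data cubes (subject-subject joins never span named
    graphs), enforces graph-level access-control policies with
    default-deny semantics before any sub-query is dispatched, and
    executes queries by pushing subject groups to the selected graphs
    and joining locally. Includes deterministic generators for synthetic
    cube federations and a brute-force merged-dataset oracle used to
    verify selection correctness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
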