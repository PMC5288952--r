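# tiny hand-built federation used by unit tests: two datasets, three
# graphs, predicates chosen so that every selection branch (pinning,
# conflict, all-graphs) is reachable by hand-written groups
ex_iri <- function(x) iri(paste0("http://example.org/t#", x))

tiny_quads <- function(graph, triples) {
  data.table::data.table(
    graph = graph,
    s = vapply(triples, `[[`, "", 1L),
    p = vapply(triples, `[[`, "", 2L),
    o = vapply(triples, `[[`, "", 3L)
  )
}

tiny_federation <- function() {
  gA1 <- ex_iri("A-g1")
  gA2 <- ex_iri("A-g2")
  gB1 <- ex_iri("B-g1")
  p1 <- ex_iri("p1"); p2 <- ex_iri("p2"); p3 <- ex_iri("p3")
  shared <- ex_iri("shared")
  qA1 <- tiny_quads(gA1, list(
    list(ex_iri("a1"), p1, lit("x")),
    list(ex_iri("a1"), shared, int_lit(1)),
    list(ex_iri("a2"), p1, lit("y"))
  ))
  qA2 <- tiny_quads(gA2, list(
    list(ex_iri("b1"), p2, int_lit(2)),
    list(ex_iri("b1"), shared, int_lit(1))
  ))
  qB1 <- tiny_quads(gB1, list(
    list(ex_iri("c1"), p3, int_lit(3)),
    list(ex_iri("c1"), shared, int_lit(1)),
    list(ex_iri("c2"), p1, lit("z"))
  ))
  federation(list(
    dataset("A", "http://a.example.org/sparql", rbind(qA1, qA2)),
    dataset("B", "http://b.example.org/sparql", qB1)
  ))
}

tiny_index <- function(fed = tiny_federation()) {
  derive_indexes(build_summaries(fed))
}

# a subject group built directly (bypassing the parser) for unit tests
make_group <- function(subject, pattern_list) {
  patterns <- lapply(seq_along(pattern_list), function(k) {
    tp <- pattern_list[[k]]
    list(s = subject, p = tp[[1]], o = tp[[2]], id = k)
  })
  preds <- vapply(patterns, function(tp) tp$p, "")
  list(subject = subject, patterns = patterns,
       bound_preds = unique(preds[!startsWith(preds, "?")]))
}
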