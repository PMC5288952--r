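ex <- running_example()

test_that("the subject-selection query parses to one BGP of seven patterns", {
  plan <- parse_query(ex$queries$subject_selection)
  expect_length(plan$bgps, 1L)
  expect_length(plan$bgps[[1]]$patterns, 7L)
  expect_equal(plan$vars,
               c("dataset", "observation", "diabetes", "bmi", "hypertension", "cases"))
})

test_that("subject grouping yields the two clinical sub-BGPs", {
  plan <- parse_query(ex$queries$subject_selection)
  groups <- group_by_subject(plan$bgps[[1]])
  expect_length(groups, 2L)
  expect_equal(groups[[1]]$subject, "?dataset")
  expect_length(groups[[1]]$patterns, 1L)
  expect_equal(groups[[2]]$subject, "?observation")
  expect_length(groups[[2]]$patterns, 6L)
  expect_setequal(groups[[2]]$bound_preds, c(
    RDF_TYPE, QB_DATASET_PRED,
    iri(paste0(SEHR_NS, c("Diabetes", "BMI_Abnormal", "Hypertension", "Cases")))
  ))
})

test_that("grouping partitions the BGP and distinct subjects never merge", {
  q <- "SELECT * WHERE { ?a <http://x/p> ?b . ?c <http://x/p> ?d . <http://x/s> <http://x/q> ?e . }"
  plan <- parse_query(q)
  groups <- group_by_subject(plan$bgps[[1]])
  expect_length(groups, 3L)
  expect_equal(sum(vapply(groups, function(g) length(g$patterns), 0L)), 3L)
  ids <- unlist(lapply(groups, function(g) vapply(g$patterns, function(tp) tp$id, 0L)))
  expect_setequal(ids, 1:3)

  # stability: reordering patterns changes internal order only
  q2 <- "SELECT * WHERE { ?x <http://x/p1> ?a . ?y <http://x/p2> ?b . ?x <http://x/p3> ?c . }"
  g2 <- group_by_subject(parse_query(q2)$bgps[[1]])
  expect_equal(vapply(g2, function(g) g$subject, ""), c("?x", "?y"))
  expect_length(g2[[1]]$patterns, 2L)
})

test_that("a fully unbound pattern parses with a variable predicate", {
  plan <- parse_query("SELECT * WHERE { ?s ?p ?o }")
  expect_length(plan$bgps, 1L)
  tp <- plan$bgps[[1]]$patterns[[1]]
  expect_true(is_variable(tp$p))
})

test_that("UNION branches become separate BGPs", {
  q <- "SELECT * WHERE { { ?s <http://x/p> ?o } UNION { ?s <http://x/q> ?o } }"
  plan <- parse_query(q)
  expect_length(plan$bgps, 2L)
  expect_equal(vapply(plan$bgps, function(b) b$role, ""), c("union", "union"))
  expect_equal(plan$bgps[[1]]$union_block, plan$bgps[[2]]$union_block)
})

test_that("OPTIONAL blocks become their own BGPs", {
  q <- "SELECT * WHERE { ?s <http://x/p> ?o . OPTIONAL { ?s <http://x/q> ?r } }"
  plan <- parse_query(q)
  expect_length(plan$bgps, 2L)
  expect_setequal(vapply(plan$bgps, function(b) b$role, ""), c("base", "optional"))
})

test_that("filters, modifiers and prefixes parse; unsupported features error", {
  q <- paste0(
    "PREFIX ex: <http://x/>\n",
    "SELECT DISTINCT ?s ?o WHERE { ?s ex:p ?o . FILTER (?o >= 2 && ?o != 5) }\n",
    "ORDER BY DESC(?o) LIMIT 3")
  plan <- parse_query(q)
  expect_true(plan$distinct)
  expect_length(plan$filters, 1L)
  expect_equal(plan$limit, 3L)
  expect_true(plan$order_by[[1]]$desc)

  expect_error(parse_query("SELECT ?s WHERE { ?s ?p ?o } GROUP BY ?s"),
               "unsupported")
  expect_error(parse_query("ASK { ?s ?p ?o }"), "unsupported")
  expect_error(parse_query("SELECT ?s WHERE { ?s <http://x/p> }"), "line")
})
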