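ex <- running_example()
summaries <- build_summaries(ex$federation)
index <- derive_indexes(summaries)
sehr <- function(x) iri(paste0(SEHR_NS, x))
exg <- function(x) iri(paste0(EX_NS, x))

test_that("CHUV summary lists the clinical predicates plus structural ones", {
  preds <- names(summaries$CHUV$pred_to_graphs)
  expect_true(all(sehr(c("Diabetes", "BMI_Abnormal", "Hypertension",
                         "Smoking", "Gender", "Cases")) %in% preds))
  expect_true(all(c(RDF_TYPE, QB_DATASET_PRED) %in% preds))
  expect_setequal(summaries$CHUV$graph_names, exg(c("CHUV-S1", "CHUV-S4")))
  # predicate -> graph map is exact
  expect_equal(summaries$CHUV$pred_to_graphs[[sehr("Hypertension")]],
               exg("CHUV-S1"))
  expect_setequal(summaries$CHUV$pred_to_graphs[[sehr("Diabetes")]],
                  exg(c("CHUV-S1", "CHUV-S4")))
})

test_that("unique-predicate indexes match the worked example", {
  expect_setequal(index$upreds$CHUV[[exg("CHUV-S1")]],
                  sehr(c("BMI_Abnormal", "Hypertension")))
  expect_setequal(index$upreds$CHUV[[exg("CHUV-S4")]],
                  sehr(c("Smoking", "Gender")))
  expect_setequal(index$unames$CHUV, exg(c("CHUV-S1", "CHUV-S4")))
  # single-graph dataset: every predicate is unique to its graph
  expect_setequal(index$upreds$CING[[exg("CING-S2")]],
                  names(summaries$CING$pred_to_graphs))
})

test_that("index invariants hold on random federations and match brute force", {
  for (seed in c(11L, 12L, 13L)) {
    fed <- generate_federation(random_federation_spec(seed, max_obs = 30L))
    sms <- build_summaries(fed)
    idx <- derive_indexes(sms)
    for (id in names(fed$datasets)) {
      ds <- fed$datasets[[id]]
      s <- sms[[id]]
      # oracle: direct scan over every quad
      scan <- unique(ds$quads[, c("p", "graph")])
      for (p in names(s$pred_to_graphs)) {
        expect_setequal(s$pred_to_graphs[[p]], scan$graph[scan$p == p])
      }
      # upreds: p unique to u iff pred_to_graphs[p] == {u}
      for (u in names(idx$upreds[[id]])) {
        for (p in idx$upreds[[id]][[u]]) {
          expect_identical(s$pred_to_graphs[[p]], u)
        }
      }
      # upreds sets of distinct graphs are pairwise disjoint
      all_up <- unlist(idx$upreds[[id]])
      expect_false(anyDuplicated(all_up) > 0L)
      # unames == graphs with nonempty upreds
      expect_setequal(idx$unames[[id]],
        names(idx$upreds[[id]])[lengths(idx$upreds[[id]]) > 0L])
    }
    # order independence
    idx_rev <- derive_indexes(rev(sms))
    expect_identical(idx_rev$preds, idx$preds)
    expect_identical(idx_rev$upreds, idx$upreds)
  }
})

test_that("summaries serialise and parse exactly in both formats", {
  for (fmt in c("json", "turtle")) {
    back <- parse_summary(serialize_summary(summaries, fmt), fmt)
    expect_identical(unname(lapply(back, unclass)),
                     unname(lapply(summaries[order(names(summaries))], unclass)))
  }
  # the RDF form describes 3 endpoints and 4 cubes with the lmds terms
  ttl <- serialize_summary(summaries, "turtle")
  expect_equal(length(gregexpr("lmds:endpointUrl", ttl)[[1]]), 3L)
  expect_equal(length(gregexpr("lmds:graph ", ttl)[[1]]), 4L)
  expect_match(ttl, "lmds:cubeProperties")
})

test_that("an empty dataset yields a valid empty summary document", {
  empty <- dataset("E", "http://e.example.org/sparql",
                   tiny_quads(character(0), list())[0, ])
  s <- build_summary(empty)
  expect_length(s$graph_names, 0L)
  expect_length(s$pred_to_graphs, 0L)
  ttl <- serialize_summary(s, "turtle")
  expect_match(ttl, "lmds:endpointUrl")
  expect_false(grepl("lmds:cube ", ttl))
  back <- parse_summary(ttl, "turtle")
  expect_identical(unclass(back[[1]]), unclass(s))
})

test_that("malformed summary documents name the offending node", {
  expect_error(parse_summary("<urn:x> <urn:y> <urn:z> .", "turtle"),
               "no lmds:endpointUrl")
  bad <- paste0("<urn:dataset:D> <", LMDS_NS, "endpointUrl> \"http://d\" .\n",
                "<urn:dataset:D> <", LMDS_NS, "cube> <urn:cube:D:1> .")
  expect_error(parse_summary(bad, "turtle"), "urn:cube:D:1")
})

test_that("summary size is independent of the number of observations", {
  spec10 <- cube_spec(ex_iri("g"), "D",
                      c(ex_iri("d1"), ex_iri("d2")), ex_iri("count"), 10L)
  spec100 <- cube_spec(ex_iri("g"), "D",
                       c(ex_iri("d1"), ex_iri("d2")), ex_iri("count"), 100L)
  d10 <- dataset("D", "http://d.example.org/sparql", generate_cube(spec10, seed = 5L))
  d100 <- dataset("D", "http://d.example.org/sparql", generate_cube(spec100, seed = 5L))
  s10 <- serialize_summary(build_summary(d10), "json")
  s100 <- serialize_summary(build_summary(d100), "json")
  expect_identical(s10, s100)
})
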