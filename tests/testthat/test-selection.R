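ex <- running_example()
index <- derive_indexes(build_summaries(ex$federation))
sehr <- function(x) iri(paste0(SEHR_NS, x))
exg <- function(x) iri(paste0(EX_NS, x))
pair_set <- function(p) paste(p$dataset, p$graph)

test_that("the observation group selects exactly the three relevant cubes", {
  plan <- parse_query(ex$queries$subject_selection)
  clients <- federation_clients(ex$federation)
  sel <- select_sources(plan, index, clients)
  expect_s3_class(sel, "cubefed_selection")
  expect_equal(sel$ask_count, 0L)
  # ?dataset a qb:DataSet matches all graphs of all datasets
  expect_setequal(pair_set(sel$per_bgp[[1]][[1]]), c(
    paste("CHUV", exg("CHUV-S1")), paste("CHUV", exg("CHUV-S4")),
    paste("CING", exg("CING-S2")), paste("ZEINCRO", exg("ZEINCRO-S3"))
  ))
  # every observation-group pattern maps to the same three pairs;
  # CHUV-S4 is excluded even for the sehr:Diabetes pattern it could match
  expected <- c(paste("CHUV", exg("CHUV-S1")), paste("CING", exg("CING-S2")),
                paste("ZEINCRO", exg("ZEINCRO-S3")))
  for (t in 2:7) expect_setequal(pair_set(sel$per_bgp[[1]][[t]]), expected)
  # the benchmark metric counts datasets per pattern: 3 + 6 patterns x 3
  expect_equal(tp_sources_selected(sel), 3L + 6L * 3L)
})

test_that("unique predicates from two graphs of one dataset discard it", {
  g <- make_group("?obs", list(
    list(sehr("Smoking"), "?a"),       # unique to CHUV-S4
    list(sehr("Hypertension"), "?b")   # unique to CHUV-S1
  ))
  sel <- select_for_group(g, index)
  expect_false("CHUV" %in% names(sel$restriction))
  expect_equal(sel$skipped$reason[sel$skipped$dataset == "CHUV"],
               "unique-predicate conflict")
  # CING/ZEINCRO lack sehr:Smoking entirely
  expect_length(sel$restriction, 0L)

  # brute-force confirmation: this s-s join is empty in every graph
  merged <- merged_quads(ex$federation)
  for (gname in unique(merged$graph)) {
    rows <- match_bgp(merged[merged$graph == gname, ], g$patterns)
    expect_equal(nrow(rows), 0L)
  }
})

test_that("a predicate absent from every dataset empties the selection", {
  plan <- parse_query(
    "SELECT * WHERE { ?s <http://example.org/sehr#Unknown> ?v . ?s <http://example.org/sehr#Cases> ?c . }")
  sel <- select_sources(plan, index)
  expect_equal(nrow(sel$per_bgp[[1]][[1]]), 0L)
  expect_equal(nrow(sel$per_bgp[[1]][[2]]), 0L)
  expect_setequal(sel$skipped$reason, "missing predicate")
})

test_that("variable-predicate patterns inherit their group's restriction", {
  plan <- parse_query(
    "SELECT * WHERE { ?obs <http://example.org/sehr#Hypertension> ?h . ?obs ?p ?o . }")
  clients <- federation_clients(ex$federation)
  sel <- select_sources(plan, index, clients)
  expect_equal(sel$ask_count, 0L)
  # Hypertension pins CHUV to S1; the unbound pattern inherits the
  # whole group restriction (CHUV-S1, CING-S2, ZEINCRO-S3)
  expect_setequal(pair_set(sel$per_bgp[[1]][[2]]), c(
    paste("CHUV", exg("CHUV-S1")), paste("CING", exg("CING-S2")),
    paste("ZEINCRO", exg("ZEINCRO-S3"))))
})

test_that("a bound-subject singleton probes each dataset once", {
  subj <- iri(paste0(EX_NS, "CHUV-S1/obs_1"))
  plan <- parse_query(sprintf("SELECT * WHERE { %s ?p ?o }", subj))
  clients <- federation_clients(ex$federation)
  sel <- select_sources(plan, index, clients)
  expect_equal(sel$ask_count, 3L)
  expect_equal(client_counters(clients)$asks, 3L)
  # only the owning dataset answers true; all its graphs are added
  expect_setequal(pair_set(sel$per_bgp[[1]][[1]]),
                  c(paste("CHUV", exg("CHUV-S1")), paste("CHUV", exg("CHUV-S4"))))
})

test_that("a fully unbound singleton matches all graphs with no probe", {
  plan <- parse_query("SELECT * WHERE { ?s ?p ?o }")
  clients <- federation_clients(ex$federation)
  sel <- select_sources(plan, index, clients)
  expect_equal(sel$ask_count, 0L)
  expect_equal(nrow(sel$per_bgp[[1]][[1]]), 4L)
})

test_that("per-BGP results are kept separate across union branches", {
  q <- paste0("SELECT * WHERE { { ?s <", SEHR_NS, "Smoking> ?v } UNION { ?s <",
              SEHR_NS, "Hypertension> ?v } }")
  sel <- select_sources(parse_query(q), index)
  expect_setequal(pair_set(sel$per_bgp[[1]][[1]]), paste("CHUV", exg("CHUV-S4")))
  expect_setequal(pair_set(sel$per_bgp[[2]][[1]]),
                  c(paste("CHUV", exg("CHUV-S1")), paste("CING", exg("CING-S2")),
                    paste("ZEINCRO", exg("ZEINCRO-S3"))))
})

test_that("selection granularity never exceeds naive per-pattern matching", {
  # datasets touched by group-aware selection are a subset of those
  # selected by predicate matching per individual triple pattern
  for (seed in c(21L, 22L, 23L)) {
    fed <- generate_federation(random_federation_spec(seed, max_obs = 30L))
    idx <- derive_indexes(build_summaries(fed))
    clients <- federation_clients(fed)
    for (qs in 1:3) {
      q <- random_conjunctive_query(fed, seed * 100L + qs)
      plan <- parse_query(q)
      sel <- select_sources(plan, idx, clients)
      for (b in seq_along(plan$bgps)) {
        for (t in seq_along(plan$bgps[[b]]$patterns)) {
          tp <- plan$bgps[[b]]$patterns[[t]]
          naive <- if (is_variable(tp$p)) {
            names(idx$summaries)
          } else {
            names(idx$summaries)[vapply(idx$summaries, function(s) {
              tp$p %in% names(s$pred_to_graphs)
            }, TRUE)]
          }
          expect_true(all(unique(sel$per_bgp[[b]][[t]]$dataset) %in% naive))
        }
      }
    }
  }
})
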