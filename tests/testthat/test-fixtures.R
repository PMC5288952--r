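test_that("generate_cube emits the QB structure with exact counts", {
  spec <- cube_spec(ex_iri("gq"), "D",
                    c(ex_iri("d1"), ex_iri("d2"), ex_iri("d3")),
                    ex_iri("count"), 8L)
  q <- generate_cube(spec, seed = 3L)
  # 1 dataset-node triple + 8 x (type, dataSet, 3 dims, measure)
  expect_equal(nrow(q), 1L + 8L * 6L)
  obs <- unique(q$s[q$p == QB_DATASET_PRED])
  expect_length(obs, 8L)
  expect_true(all(startsWith(obs, "<http://example.org/t#gq/obs_")))
  # every observation reaches the qb:DataSet node
  ds_node <- q$s[q$o == QB_DATASET_CLASS]
  expect_true(all(q$o[q$p == QB_DATASET_PRED] == ds_node))
  # dimension values stay in the binary domain
  dimvals <- q$o[q$p == ex_iri("d1")]
  expect_true(all(dimvals %in% int_lit(0:1)))

  # n = 0 leaves only the dataset node
  q0 <- generate_cube(cube_spec(ex_iri("g0"), "D", character(0),
                                ex_iri("count"), 0L), seed = 3L)
  expect_equal(nrow(q0), 1L)
})

test_that("cube generation is byte-identical for a fixed spec and seed", {
  spec <- cube_spec(ex_iri("gd"), "D", c(ex_iri("d1")), ex_iri("count"), 20L)
  doc_a <- write_trig(generate_cube(spec, seed = 9L))
  doc_b <- write_trig(generate_cube(spec, seed = 9L))
  expect_identical(doc_a, doc_b)
  doc_c <- write_trig(generate_cube(spec, seed = 10L))
  expect_false(identical(doc_a, doc_c))
})

test_that("random federations are deterministic and locality-clean", {
  for (seed in c(41L, 42L)) {
    fs <- random_federation_spec(seed, max_obs = 40L)
    fed1 <- generate_federation(fs)
    fed2 <- generate_federation(fs)
    expect_identical(
      lapply(fed1$datasets, function(d) write_trig(d$quads)),
      lapply(fed2$datasets, function(d) write_trig(d$quads))
    )
    expect_equal(nrow(validate_locality(fed1)), 0L)
    n_ds <- length(fed1$datasets)
    expect_true(n_ds >= 2L && n_ds <= 5L)
    expect_true(all(vapply(fed1$datasets, function(d) length(graph_names(d)), 0L) <= 4L))
  }
})

test_that("unique-predicate structure follows the spec configuration", {
  # disjoint dimension sets -> every graph has a unique predicate
  disjoint <- federation_spec(list(list(
    id = "D", location = "http://d/",
    cubes = list(
      cube_spec(ex_iri("u1"), "D", ex_iri("da"), ex_iri("count"), 3L),
      cube_spec(ex_iri("u2"), "D", ex_iri("db"), ex_iri("count"), 3L)
    ))), seed = 7L)
  idx <- derive_indexes(build_summaries(generate_federation(disjoint)))
  expect_setequal(idx$unames$D, ex_iri(c("u1", "u2")))

  # identical dimension sets -> no unique predicate anywhere
  shared <- federation_spec(list(list(
    id = "D", location = "http://d/",
    cubes = list(
      cube_spec(ex_iri("s1"), "D", ex_iri(c("da", "db")), ex_iri("count"), 3L),
      cube_spec(ex_iri("s2"), "D", ex_iri(c("da", "db")), ex_iri("count"), 3L)
    ))), seed = 7L)
  idx2 <- derive_indexes(build_summaries(generate_federation(shared)))
  expect_length(idx2$unames$D, 0L)
})

test_that("the running example matches its documented shape", {
  ex <- running_example()
  expect_length(ex$federation$datasets, 3L)
  expect_equal(nrow(validate_locality(ex$federation)), 0L)
  expect_false(authorised(ex$user, iri(paste0(EX_NS, "ZEINCRO-S3")), "read",
                          ex$policy))
  # the stated 26-cases cell is present in CHUV-S1
  chuv <- ex$federation$datasets$CHUV$quads
  s1 <- chuv[chuv$graph == iri(paste0(EX_NS, "CHUV-S1")), ]
  sehr <- function(x) iri(paste0(SEHR_NS, x))
  hit <- intersect(
    intersect(s1$s[s1$p == sehr("Diabetes") & s1$o == int_lit(1)],
              s1$s[s1$p == sehr("BMI_Abnormal") & s1$o == int_lit(0)]),
    s1$s[s1$p == sehr("Hypertension") & s1$o == int_lit(1)])
  expect_length(hit, 1L)
  expect_equal(s1$o[s1$s == hit & s1$p == sehr("Cases")], int_lit(26))
})

test_that("random policies stay within the federation's graphs", {
  fed <- generate_federation(random_federation_spec(55L, max_obs = 20L))
  all_graphs <- unlist(lapply(fed$datasets, graph_names))
  pol <- random_policy(fed, 56L)
  expect_true(all(pol$grants$graph %in% all_graphs))
  expect_true(all(pol$grants$right == "read"))
})
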