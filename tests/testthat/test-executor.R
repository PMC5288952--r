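ex <- running_example()
index <- derive_indexes(build_summaries(ex$federation))
exg <- function(x) iri(paste0(EX_NS, x))

test_that("rewrite_subquery emits a graph-restricted VALUES query, stably", {
  plan <- parse_query(ex$queries$subject_selection)
  groups <- group_by_subject(plan$bgps[[1]])
  q1 <- rewrite_subquery(groups[[2]], exg("CHUV-S1"))
  expect_match(q1, "VALUES \\?__g \\{ <http://example.org/l2s#CHUV-S1> \\}")
  expect_match(q1, "GRAPH \\?__g")
  expect_match(q1, "?observation", fixed = TRUE)
  # two graphs -> one query listing both, in sorted order regardless of input
  q2 <- rewrite_subquery(groups[[2]], exg(c("CING-S2", "CHUV-S1")))
  q2b <- rewrite_subquery(groups[[2]], exg(c("CHUV-S1", "CING-S2")))
  expect_identical(q2, q2b)
  expect_match(q2, "<http://example.org/l2s#CHUV-S1> <http://example.org/l2s#CING-S2>")
  expect_error(rewrite_subquery(groups[[2]], character(0)))
})

test_that("evaluate_group unions per-dataset answers and respects policy", {
  plan <- parse_query(ex$queries$subject_selection)
  clients <- federation_clients(ex$federation)
  sel <- select_sources(plan, index, clients)
  sel_j <- filter_selection(sel, ex$policy, ex$user)
  rows <- evaluate_group(sel_j$groups[[1]][[2]], sel_j, clients, bgp = 1L)
  expect_equal(nrow(rows), 16L)  # 8 observations each from CHUV-S1, CING-S2
  obs_graphs <- unique(sub("/obs_[0-9]+>$", ">", rows$observation))
  expect_setequal(obs_graphs, exg(c("CHUV-S1", "CING-S2")))
  # one sub-query per contributing dataset
  expect_equal(client_counters(clients)$selects, 2L)
})

test_that("join_groups implements natural-join semantics", {
  a <- data.table::data.table(.u = 1L, x = c("<u:1>", "<u:2>"), y = c("<v:1>", "<v:2>"))
  b <- data.table::data.table(.u = 1L, y = c("<v:1>", "<v:3>"), z = c("<w:1>", "<w:3>"))
  j <- join_groups(list(a, b))
  expect_equal(nrow(j), 1L)
  expect_equal(j$x, "<u:1>")
  expect_equal(j$z, "<w:1>")
  # disjoint variable sets degenerate to the cross product
  d <- data.table::data.table(.u = 1L, w = c("<q:1>", "<q:2>"))
  expect_equal(nrow(join_groups(list(a, d))), 4L)
})

test_that("the full clinical query returns the 26-cases row federatedly", {
  res <- execute(ex$queries$cases, ex$federation, index = index)
  df <- as.data.frame(res)
  expect_equal(nrow(df), 3L)  # one contributing row per relevant cube
  cases <- sort(vapply(df$cases, function(t) term_numeric(t), 0))
  expect_equal(cases, c(26, 33, 41), ignore_attr = TRUE)
  chuv_row <- df[grepl("CHUV-S1", df$observation), ]
  expect_equal(term_numeric(chuv_row$cases), 26)
  m <- attr(res, "metrics")
  expect_equal(m$asks, 0L)
})

test_that("execute equals the merged-dataset oracle on the running example", {
  for (q in ex$queries) {
    r1 <- execute(q, ex$federation, index = index)
    r2 <- evaluate_merged(q, ex$federation)
    expect_true(results_equal(r1, r2))
  }
})

test_that("policy-filtered execution equals the oracle over authorised graphs", {
  res <- execute(ex$queries$cases, ex$federation, index = index,
                 policy = ex$policy, user = ex$user)
  oracle <- evaluate_merged(ex$queries$cases, ex$federation,
                            graphs = readable_graphs(ex$user, ex$policy))
  expect_true(results_equal(res, oracle))
  expect_equal(nrow(res$rows), 2L)
})

test_that("a user with no grants gets an empty result and no data requests", {
  clients <- federation_clients(ex$federation)
  res <- execute(ex$queries$cases, ex$federation, index = index,
                 policy = access_policy(), user = ex$user, clients = clients)
  expect_equal(nrow(res$rows), 0L)
  expect_equal(client_counters(clients)$selects, 0L)
})

test_that("a policy without a user is refused", {
  expect_error(execute(ex$queries$cases, ex$federation, index = index,
                       policy = ex$policy), "user")
})

test_that("filters, DISTINCT, ORDER BY and LIMIT match the oracle", {
  q <- paste0(
    "PREFIX sehr: <", SEHR_NS, ">\n",
    "SELECT DISTINCT ?cases WHERE {\n",
    "  ?obs sehr:Diabetes ?d .\n  ?obs sehr:Hypertension ?h .\n",
    "  ?obs sehr:Cases ?cases .\n",
    "  FILTER (?d = 1 && ?h = 1)\n} ORDER BY DESC(?cases) LIMIT 4")
  r1 <- execute(q, ex$federation, index = index)
  r2 <- evaluate_merged(q, ex$federation)
  expect_true(results_equal(r1, r2))
  expect_equal(nrow(r1$rows), 4L)
  vals <- vapply(r1$rows$cases, term_numeric, 0)
  expect_equal(vals, sort(vals, decreasing = TRUE), ignore_attr = TRUE)
})

test_that("UNION and OPTIONAL combinations match the oracle", {
  q_union <- paste0(
    "PREFIX sehr: <", SEHR_NS, ">\n",
    "SELECT * WHERE { { ?s sehr:Smoking ?v } UNION { ?s sehr:BMI_Abnormal ?v } }")
  expect_true(results_equal(execute(q_union, ex$federation, index = index),
                            evaluate_merged(q_union, ex$federation)))
  q_opt <- paste0(
    "PREFIX sehr: <", SEHR_NS, ">\n",
    "SELECT * WHERE { ?s sehr:Diabetes ?d . OPTIONAL { ?s sehr:Smoking ?v } }")
  r1 <- execute(q_opt, ex$federation, index = index)
  r2 <- evaluate_merged(q_opt, ex$federation)
  expect_true(results_equal(r1, r2))
  expect_true(any(is.na(r1$rows$v)))  # left-join semantics visible
})

test_that("execution is deterministic and counters are exact", {
  clients <- federation_clients(ex$federation)
  r1 <- execute(ex$queries$subject_selection, ex$federation, index = index,
                clients = clients)
  c1 <- client_counters(clients)
  r2 <- execute(ex$queries$subject_selection, ex$federation, index = index)
  expect_true(results_equal(r1, r2))
  # 2 groups x 3 contributing datasets for observations + 3 for ?dataset
  expect_equal(c1$selects, attr(r1, "metrics")$subqueries)
  expect_equal(c1$asks, 0L)
})

test_that("the python rdflib engine agrees on the running example", {
  dir <- withr::local_tempdir()
  write_federation(ex$federation, dir)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import glob, sys, json",
    "from rdflib import Dataset",
    "ds = Dataset(default_union=True)",
    sprintf("for f in sorted(glob.glob('%s/*.trig')):", dir),
    "    ds.parse(f, format='trig')",
    "q = open(sys.argv[1]).read()",
    "rows = []",
    "for row in ds.query(q):",
    "    rows.append(sorted((str(k), str(v)) for k, v in row.asdict().items()))",
    "print(json.dumps(sorted(rows)))"
  ), script)
  qfile <- file.path(dir, "q.rq")
  writeLines(ex$queries$cases, qfile)
  out <- system2("python", c(script, qfile), stdout = TRUE)
  py <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  expect_length(py, 3L)
  py_cases <- sort(vapply(py, function(row) {
    as.numeric(Filter(function(cell) cell[[1]] == "cases", row)[[1]][[2]])
  }, 0))
  res <- execute(ex$queries$cases, ex$federation, index = index)
  r_cases <- sort(vapply(res$rows$cases, term_numeric, 0))
  expect_equal(py_cases, r_cases, ignore_attr = TRUE)
})
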