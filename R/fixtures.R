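## Deterministic generators for QB-vocabulary cube federations: the
## clinical running example (three sites, four cubes) and seeded random
## federations whose observation IRIs are graph-scoped, so the subject
## locality the selection algorithm relies on holds by construction.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic data cube
#'
#' @param graph_name Encoded graph IRI.
#' @param dataset_id Dataset label the cube belongs to.
#' @param dimension_preds Character vector of encoded dimension
#'   predicate IRIs.
#' @param measure_pred Encoded measure predicate IRI.
#' @param n_observations Number of observations (>= 0).
#' @param value_domain List (one entry per dimension) of allowed
#'   dimension values; defaults to binary 0/1, the encoding used for
#'   presence/absence of a clinical condition.
#' @param measure_range Integer interval the measure is drawn from.
#' @return A `cubefed_cube_spec`.
#' @export
cube_spec <- function(graph_name, dataset_id, dimension_preds, measure_pred,
                      n_observations,
                      value_domain = rep(list(0:1), length(dimension_preds)),
                      measure_range = c(0L, 500L)) {
  stopifnot(n_observations >= 0, length(value_domain) == length(dimension_preds),
            length(measure_range) == 2L)
  structure(
    list(graph_name = graph_name, dataset_id = dataset_id,
         dimension_preds = dimension_preds, measure_pred = measure_pred,
         n_observations = as.integer(n_observations),
         value_domain = value_domain,
         measure_range = as.integer(measure_range)),
    class = "cubefed_cube_spec"
  )
}

#' Generate one cube graph
#'
#' Emits one `qb:DataSet` node plus, per observation, an
#' `rdf:type qb:Observation` triple, a `qb:dataSet` link, one triple per
#' dimension and one measure triple. Observation IRIs are prefixed with
#' the graph IRI (`<graph>/obs_<k>`), making locality structural.
#' Deterministic for a fixed (spec, seed).
#'
#' @param spec A `cubefed_cube_spec`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param values Optional matrix/data.frame of fixed dimension values
#'   plus a `measure` column (overrides random drawing).
#' @return data.table of quads (columns `graph`, `s`, `p`, `o`).
#' @export
generate_cube <- function(spec, seed = NULL, values = NULL) {
  stopifnot(inherits(spec, "cubefed_cube_spec"))
  build <- function() {
    g <- spec$graph_name
    base <- substr(g, 2L, nchar(g) - 1L)
    ds_node <- iri(paste0(base, "/dataset"))
    n <- spec$n_observations
    nd <- length(spec$dimension_preds)
    if (is.null(values)) {
      dims <- lapply(seq_len(nd), function(d) {
        sample(spec$value_domain[[d]], n, replace = TRUE)
      })
      measure <- sample(seq(spec$measure_range[1], spec$measure_range[2]), n,
                        replace = TRUE)
    } else {
      stopifnot(nrow(values) == n, ncol(values) == nd + 1L)
      dims <- lapply(seq_len(nd), function(d) values[[d]])
      measure <- values[[nd + 1L]]
    }
    s <- c(ds_node)
    p <- c(RDF_TYPE)
    o <- c(QB_DATASET_CLASS)
    if (n > 0L) {
      obs <- iri(paste0(base, "/obs_", seq_len(n)))
      s <- c(s, obs, obs)
      p <- c(p, rep(RDF_TYPE, n), rep(QB_DATASET_PRED, n))
      o <- c(o, rep(QB_OBSERVATION_CLASS, n), rep(ds_node, n))
      for (d in seq_len(nd)) {
        s <- c(s, obs)
        p <- c(p, rep(spec$dimension_preds[d], n))
        o <- c(o, int_lit(dims[[d]]))
      }
      s <- c(s, obs)
      p <- c(p, rep(spec$measure_pred, n))
      o <- c(o, int_lit(measure))
    }
    data.table::data.table(graph = g, s = s, p = p, o = o)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Specify a synthetic federation
#'
#' @param datasets List of entries `list(id =, location =, cubes = list
#'   of cube_spec)`.
#' @param seed Integer seed driving all value drawing.
#' @return A `cubefed_federation_spec`.
#' @export
federation_spec <- function(datasets, seed) {
  structure(list(datasets = datasets, seed = as.integer(seed)),
            class = "cubefed_federation_spec")
}

#' Generate a federation from a spec
#'
#' Locality holds by construction (graph-scoped observation IRIs);
#' output is deterministic for a fixed spec.
#'
#' @param fspec A `cubefed_federation_spec`.
#' @return A `cubefed_federation`.
#' @export
generate_federation <- function(fspec) {
  stopifnot(inherits(fspec, "cubefed_federation_spec"))
  with_seed(fspec$seed, {
    federation(lapply(fspec$datasets, function(entry) {
      quads <- data.table::rbindlist(lapply(entry$cubes, generate_cube))
      dataset(entry$id, entry$location, quads)
    }))
  })
}

#' Draw a random federation spec
#'
#' Study conditions for the correctness suite: 2-5 datasets, 1-4 graphs
#' each, a global pool of 3-8 dimension predicates, up to `max_obs`
#' observations per graph. Per dataset, graphs either share dimension
#' pools (no unique predicate: group selection keeps all graphs) or get
#' disjoint extra dimensions (unique-predicate pinning and the
#' two-unique-predicates conflict both become reachable).
#'
#' @param seed Integer seed.
#' @param max_obs Upper bound on observations per graph.
#' @return A `cubefed_federation_spec`.
#' @export
random_federation_spec <- function(seed, max_obs = 200L) {
  with_seed(seed, {
    n_ds <- sample(2:5, 1)
    n_preds <- sample(3:8, 1)
    pool <- iri(paste0("http://example.org/vocab#d", seq_len(n_preds)))
    measure <- iri("http://example.org/vocab#count")
    datasets <- lapply(seq_len(n_ds), function(i) {
      id <- paste0("DS", i)
      n_g <- sample(1:4, 1)
      shared_mode <- runif(1) < 0.4
      cubes <- lapply(seq_len(n_g), function(j) {
        gname <- iri(sprintf("http://example.org/fed/%s/g%d", id, j))
        if (shared_mode) {
          # identical pool across the dataset's graphs: no unique predicate
          dims <- sort(pool[seq_len(min(3L, length(pool)))])
        } else {
          dims <- sample(pool, sample(1:min(4L, length(pool)), 1))
        }
        cube_spec(gname, id, dims, measure,
                  n_observations = sample(5:max_obs, 1))
      })
      list(id = id, location = sprintf("http://%s.example.org/sparql", tolower(id)),
           cubes = cubes)
    })
    federation_spec(datasets, seed = sample.int(2^30, 1))
  })
}

#' Draw a random conjunctive query against a federation
#'
#' Generates 1-3 subject groups whose predicates are drawn mostly from
#' one target graph (so answers can exist), sometimes from sibling
#' graphs of the same dataset (exercising unique-predicate pinning and
#' the conflict-discard branch), with occasional bound objects, an
#' occasional variable-predicate pattern (exercising restriction
#' inheritance and the ASK probe path), and an occasional
#' `qb:dataSet`/`qb:DataSet` link joining groups.
#'
#' @param fed An in-memory `cubefed_federation`.
#' @param seed Integer seed.
#' @return SPARQL SELECT text.
#' @export
random_conjunctive_query <- function(fed, seed) {
  with_seed(seed, {
    all_graphs <- unlist(lapply(fed$datasets, graph_names))
    n_groups <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
    measure <- iri("http://example.org/vocab#count")
    lines <- character(0)
    for (k in seq_len(n_groups)) {
      sv <- paste0("?s", k)
      g <- sample(all_graphs, 1)
      ds <- Filter(function(d) g %in% graph_names(d), fed$datasets)[[1]]
      gp <- unique(ds$quads$p[ds$quads$graph == g])
      gp <- setdiff(gp, RDF_TYPE)
      n_tp <- sample(1:3, 1)
      preds <- sample(gp, min(n_tp, length(gp)))
      if (runif(1) < 0.25 && length(graph_names(ds)) > 1L) {
        # predicate from a sibling graph: may pin elsewhere or conflict
        other_g <- sample(setdiff(graph_names(ds), g), 1)
        op <- setdiff(unique(ds$quads$p[ds$quads$graph == other_g]), RDF_TYPE)
        if (length(op)) preds <- unique(c(preds, sample(op, 1)))
      }
      for (j in seq_along(preds)) {
        obj <- if (runif(1) < 0.25) "1" else paste0("?v", k, "_", j)
        lines <- c(lines, sprintf("  %s %s %s .", sv, preds[j], obj))
      }
      if (runif(1) < 0.2) {
        lines <- c(lines, sprintf("  %s ?p%d ?w%d .", sv, k, k))
      }
      # keep multi-group queries connected (disjoint groups only yield
      # cross products): link each group to its predecessor through a
      # shared measure value, a selective o-o join across graphs
      if (k > 1L) {
        lk <- paste0("?m", k)
        lines <- c(lines,
                   sprintf("  ?s%d %s %s .", k - 1L, measure, lk),
                   sprintf("  %s %s %s .", sv, measure, lk))
      }
    }
    if (n_groups == 1L && runif(1) < 0.35) {
      lines <- c(lines,
                 sprintf("  ?s1 %s ?dataset .", QB_DATASET_PRED),
                 sprintf("  ?dataset %s %s .", RDF_TYPE, QB_DATASET_CLASS))
    }
    if (runif(1) < 0.15) {
      # bound-subject singleton with variable predicate: ASK probe path
      # (a handful of rows, so the cross product with the rest stays small)
      g <- sample(all_graphs, 1)
      subj <- iri(paste0(substr(g, 2L, nchar(g) - 1L), "/obs_1"))
      lines <- c(lines, sprintf("  %s ?pa ?oa .", subj))
    }
    distinct <- if (runif(1) < 0.3) "DISTINCT " else ""
    paste0("SELECT ", distinct, "* WHERE {\n", paste(lines, collapse = "\n"), "\n}")
  })
}

#' Draw a random graph-level read policy
#'
#' Grants the user read access to a random subset of the federation's
#' graphs (possibly none: default deny).
#'
#' @param fed An in-memory `cubefed_federation`.
#' @param seed Integer seed.
#' @param user Encoded user IRI.
#' @return A `cubefed_policy`.
#' @export
random_policy <- function(fed, seed, user = iri(paste0(EX_NS, "u1"))) {
  with_seed(seed, {
    graphs <- unlist(lapply(fed$datasets, graph_names))
    n <- sample(0:length(graphs), 1)
    granted <- if (n > 0L) sample(graphs, n) else character(0)
    grants <- if (length(granted)) {
      data.frame(user = user, graph = granted, right = "read",
                 stringsAsFactors = FALSE)
    } else NULL
    access_policy(grants)
  })
}

#' The clinical running example
#'
#' Three clinical sites publishing four data cubes: CHUV with
#' `:CHUV-S1` (dimensions Diabetes, BMI_Abnormal, Hypertension; measure
#' Cases) and `:CHUV-S4` (Smoking, Gender, Diabetes; Cases), CING with
#' `:CING-S2` and ZEINCRO with `:ZEINCRO-S3` (both with the S1
#' dimensions), so that within CHUV the predicates BMI_Abnormal and
#' Hypertension are unique to S1 and Smoking and Gender to S4.
#' `:CHUV-S1` holds the row Diabetes=1, BMI_Abnormal=0, Hypertension=1
#' with 26 cases; the remaining cell values are fixed constructed
#' fillers. The policy grants the user `:James` read access to
#' `:CHUV-S1` and `:CING-S2` only.
#'
#' @return List with `federation`, `policy`, `user` (encoded IRI of
#'   James), and `queries`: `subject_selection` (one BGP, seven triple
#'   patterns, two subject groups) and `cases` (the same shape with
#'   Diabetes=1, BMI_Abnormal=0, Hypertension=1 bound).
#' @export
running_example <- function() {
  sehr <- function(x) iri(paste0(SEHR_NS, x))
  exg <- function(x) iri(paste0(EX_NS, x))
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)[, c("a", "b", "c")]
  # (Diabetes, BMI_Abnormal, Hypertension) counts; row (1,0,1) -> 26
  s1_vals <- cbind(combos, measure = c(31L, 22L, 12L, 9L, 18L, 26L, 14L, 5L))
  s2_vals <- cbind(combos, measure = c(40L, 17L, 11L, 8L, 21L, 33L, 13L, 6L))
  s3_vals <- cbind(combos, measure = c(28L, 19L, 10L, 7L, 24L, 41L, 16L, 4L))
  # (Smoking, Gender, Diabetes) counts for CHUV-S4
  s4_vals <- cbind(combos, measure = c(35L, 23L, 15L, 11L, 20L, 27L, 13L, 8L))
  stopifnot(s1_vals$measure[s1_vals$a == 1 & s1_vals$b == 0 & s1_vals$c == 1] == 26L)

  dims_s1 <- c(sehr("Diabetes"), sehr("BMI_Abnormal"), sehr("Hypertension"))
  dims_s4 <- c(sehr("Smoking"), sehr("Gender"), sehr("Diabetes"))
  mk <- function(gname, id, dims, vals) {
    generate_cube(cube_spec(exg(gname), id, dims, sehr("Cases"), nrow(vals)),
                  values = vals)
  }
  chuv <- dataset("CHUV", "http://chuv.example.org/sparql",
    data.table::rbindlist(list(
      mk("CHUV-S1", "CHUV", dims_s1, s1_vals),
      mk("CHUV-S4", "CHUV", dims_s4, s4_vals)
    )))
  cing <- dataset("CING", "http://cing.example.org/sparql",
                  mk("CING-S2", "CING", dims_s1, s2_vals))
  zeincro <- dataset("ZEINCRO", "http://zeincro.example.org/sparql",
                     mk("ZEINCRO-S3", "ZEINCRO", dims_s1, s3_vals))
  fed <- federation(list(chuv, cing, zeincro))

  james <- exg("James")
  policy <- access_policy(
    grants = data.frame(
      user = james,
      graph = c(exg("CHUV-S1"), exg("CING-S2")),
      right = "read", stringsAsFactors = FALSE
    ),
    users = list(list(id = james, attributes = list(
      activity = "clinical research", location = "Lausanne",
      organisation = "CHUV", position = "researcher", role = "data analyst"
    )))
  )

  prologue <- paste0(
    "PREFIX rdf: <", RDF_NS, ">\n",
    "PREFIX qb: <", QB_NS, ">\n",
    "PREFIX sehr: <", SEHR_NS, ">\n"
  )
  subject_selection <- paste0(prologue,
    "SELECT ?dataset ?observation ?diabetes ?bmi ?hypertension ?cases WHERE {\n",
    "  ?dataset rdf:type qb:DataSet .\n",
    "  ?observation qb:dataSet ?dataset .\n",
    "  ?observation rdf:type qb:Observation .\n",
    "  ?observation sehr:Diabetes ?diabetes .\n",
    "  ?observation sehr:BMI_Abnormal ?bmi .\n",
    "  ?observation sehr:Hypertension ?hypertension .\n",
    "  ?observation sehr:Cases ?cases .\n",
    "}")
  cases <- paste0(prologue,
    "SELECT ?dataset ?observation ?cases WHERE {\n",
    "  ?dataset rdf:type qb:DataSet .\n",
    "  ?observation qb:dataSet ?dataset .\n",
    "  ?observation rdf:type qb:Observation .\n",
    "  ?observation sehr:Diabetes 1 .\n",
    "  ?observation sehr:BMI_Abnormal 0 .\n",
    "  ?observation sehr:Hypertension 1 .\n",
    "  ?observation sehr:Cases ?cases .\n",
    "}")

  list(federation = fed, policy = policy, user = james,
       queries = list(subject_selection = subject_selection, cases = cases))
}
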