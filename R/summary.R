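## Data summaries: the engine's only index. Per dataset it stores the
## endpoint URL, the graph names, and a predicate -> graphs map -- no
## instance data, so summary size is independent of observation counts
## and summaries are cheap to recompute when sources change. From the
## raw summaries three derived indexes feed source selection: preds(D),
## upreds(u, D) (predicates unique to graph u within D) and unames(D)
## (graphs owning at least one unique predicate).

LMDS_ENDPOINT <- paste0("<", LMDS_NS, "endpointUrl>")
LMDS_CUBE <- paste0("<", LMDS_NS, "cube>")
LMDS_GRAPH <- paste0("<", LMDS_NS, "graph>")
LMDS_CUBEPROPS <- paste0("<", LMDS_NS, "cubeProperties>")

new_summary <- function(dataset_id, endpoint_url, graph_names, pred_to_graphs) {
  graph_names <- sort(unique(graph_names), method = "radix")
  pred_to_graphs <- pred_to_graphs[order(names(pred_to_graphs), method = "radix")]
  pred_to_graphs <- lapply(pred_to_graphs, function(g) sort(unique(g), method = "radix"))
  stopifnot(all(unlist(pred_to_graphs) %in% graph_names))
  structure(
    list(dataset_id = dataset_id, endpoint_url = endpoint_url,
         graph_names = graph_names, pred_to_graphs = pred_to_graphs),
    class = "cubefed_summary"
  )
}

#' @export
print.cubefed_summary <- function(x, ...) {
  cat(sprintf("<cubefed summary> %s @ %s: %d graph(s), %d predicate(s)\n",
              x$dataset_id, x$endpoint_url, length(x$graph_names),
              length(x$pred_to_graphs)))
  invisible(x)
}

#' Build the data summary of a dataset
#'
#' In-memory datasets are scanned directly; remote datasets are
#' summarised with a single
#' `SELECT DISTINCT ?g ?p { GRAPH ?g { ?s ?p ?o } }` round trip (no
#' instance data is transferred).
#'
#' @param ds A `cubefed_dataset`.
#' @return A `cubefed_summary`.
#' @export
build_summary <- function(ds) {
  stopifnot(inherits(ds, "cubefed_dataset"))
  if (ds$remote) {
    res <- remote_select(ds$location,
      "SELECT DISTINCT ?g ?p WHERE { GRAPH ?g { ?s ?p ?o } }")
    pg <- data.table::data.table(p = res$p, graph = res$g)
  } else {
    pg <- unique(ds$quads[, c("p", "graph")])
  }
  preds <- sort(unique(pg$p), method = "radix")
  p2g <- lapply(stats::setNames(preds, preds), function(pp) unique(pg$graph[pg$p == pp]))
  gnames <- if (ds$remote) unique(pg$graph) else unique(ds$quads$graph)
  new_summary(ds$id, ds$location, gnames, p2g)
}

#' Build summaries for every dataset of a federation
#' @param fed A `cubefed_federation`.
#' @return Named list of `cubefed_summary`, keyed by dataset id.
#' @export
build_summaries <- function(fed) {
  stopifnot(inherits(fed, "cubefed_federation"))
  lapply(fed$datasets, build_summary)
}

#' Derive the selection indexes from data summaries
#'
#' Predicate uniqueness is judged within each dataset: `upreds[[D]][[u]]`
#' holds the predicates appearing in graph `u` and in no other graph of
#' `D`; `unames[[D]]` lists the graphs of `D` with at least one unique
#' predicate. The result is independent of the iteration order of the
#' input summaries.
#'
#' @param summaries List of `cubefed_summary`.
#' @return A `cubefed_index`: list with `preds`, `upreds`, `unames` and
#'   the input `summaries` (keyed by dataset id).
#' @export
derive_indexes <- function(summaries) {
  if (inherits(summaries, "cubefed_summary")) summaries <- list(summaries)
  ids <- vapply(summaries, function(s) s$dataset_id, "")
  names(summaries) <- ids
  summaries <- summaries[order(ids, method = "radix")]
  preds <- lapply(summaries, function(s) names(s$pred_to_graphs))
  upreds <- lapply(summaries, function(s) {
    per_graph <- lapply(stats::setNames(s$graph_names, s$graph_names), function(g) {
      mine <- names(s$pred_to_graphs)[vapply(s$pred_to_graphs,
        function(gs) identical(gs, g), TRUE)]
      sort(mine, method = "radix")
    })
    per_graph
  })
  unames <- lapply(upreds, function(per_graph) {
    sort(names(per_graph)[vapply(per_graph, length, 0L) > 0L], method = "radix")
  })
  structure(list(preds = preds, upreds = upreds, unames = unames,
                 summaries = summaries),
            class = "cubefed_index")
}

#' Serialise data summaries
#'
#' JSON is the canonical form; the RDF (Turtle) form uses the
#' access-policy-model terms `lmds:endpointUrl`, `lmds:cube`,
#' `lmds:graph` and `lmds:cubeProperties`, with one IRI-named cube node
#' per graph (blank nodes are excluded from the data model).
#'
#' @param summaries A `cubefed_summary` or list of them.
#' @param format `"json"` or `"turtle"`.
#' @return Character scalar with the document text.
#' @export
serialize_summary <- function(summaries, format = c("json", "turtle")) {
  format <- match.arg(format)
  if (inherits(summaries, "cubefed_summary")) summaries <- list(summaries)
  ids <- vapply(summaries, function(s) s$dataset_id, "")
  summaries <- summaries[order(ids, method = "radix")]
  if (format == "json") {
    payload <- lapply(summaries, function(s) {
      list(dataset_id = s$dataset_id, endpoint_url = s$endpoint_url,
           graph_names = s$graph_names, pred_to_graphs = s$pred_to_graphs)
    })
    return(as.character(jsonlite::toJSON(unname(payload), auto_unbox = TRUE,
                                         pretty = TRUE)))
  }
  s_col <- character(0); p_col <- character(0); o_col <- character(0)
  add <- function(s, p, o) {
    s_col <<- c(s_col, s); p_col <<- c(p_col, p); o_col <<- c(o_col, o)
  }
  for (s in summaries) {
    node <- iri(paste0("urn:dataset:", s$dataset_id))
    add(node, LMDS_ENDPOINT, lit(s$endpoint_url))
    for (k in seq_along(s$graph_names)) {
      g <- s$graph_names[k]
      cube <- iri(paste0("urn:cube:", s$dataset_id, ":", k))
      add(node, LMDS_CUBE, cube)
      add(cube, LMDS_GRAPH, g)
      for (p in names(s$pred_to_graphs)) {
        if (g %in% s$pred_to_graphs[[p]]) add(cube, LMDS_CUBEPROPS, p)
      }
    }
  }
  write_turtle(data.table::data.table(s = s_col, p = p_col, o = o_col))
}

#' Parse a serialised summary document
#'
#' @param text Document text (JSON or Turtle).
#' @param format `"json"` or `"turtle"`; guessed from the first
#'   character when missing.
#' @return A list of `cubefed_summary` (singletons are still returned as
#'   a length-one list), keyed and sorted by dataset id.
#' @export
parse_summary <- function(text, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("^\\s*\\[|^\\s*\\{", text)) "json" else "turtle"
  }
  if (format == "json") {
    payload <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    out <- lapply(payload, function(entry) {
      need <- c("dataset_id", "endpoint_url", "graph_names", "pred_to_graphs")
      miss <- setdiff(need, names(entry))
      if (length(miss)) {
        stop("malformed summary document: entry missing field(s) ",
             paste(miss, collapse = ", "))
      }
      new_summary(entry$dataset_id, entry$endpoint_url,
                  unlist(entry$graph_names) %||chr% character(0),
                  lapply(entry$pred_to_graphs, unlist))
    })
  } else {
    doc <- parse_trig(text, allow_default_graph = TRUE, what = "summary document")
    tr <- doc$quads
    ds_nodes <- sort(unique(tr$s[tr$p == LMDS_ENDPOINT]), method = "radix")
    if (!length(ds_nodes)) stop("malformed summary document: no lmds:endpointUrl node")
    out <- lapply(ds_nodes, function(node) {
      id <- sub("^<urn:dataset:(.*)>$", "\\1", node)
      if (id == node) stop("malformed summary document: dataset node ", node,
                           " is not an urn:dataset: IRI")
      url_term <- tr$o[tr$s == node & tr$p == LMDS_ENDPOINT][1]
      cubes <- tr$o[tr$s == node & tr$p == LMDS_CUBE]
      gnames <- character(0)
      pg_p <- character(0); pg_g <- character(0)
      for (cube in cubes) {
        g <- tr$o[tr$s == cube & tr$p == LMDS_GRAPH]
        if (length(g) != 1L) {
          stop("malformed summary document: cube node ", cube,
               " needs exactly one lmds:graph")
        }
        gnames <- c(gnames, g)
        props <- tr$o[tr$s == cube & tr$p == LMDS_CUBEPROPS]
        pg_p <- c(pg_p, props)
        pg_g <- c(pg_g, rep(g, length(props)))
      }
      preds <- sort(unique(pg_p), method = "radix")
      p2g <- lapply(stats::setNames(preds, preds), function(pp) pg_g[pg_p == pp])
      new_summary(id, term_fields(url_term)$value, gnames, p2g)
    })
  }
  ids <- vapply(out, function(s) s$dataset_id, "")
  names(out) <- ids
  out[order(ids, method = "radix")]
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

#' Write one summary file per dataset
#'
#' @param summaries List of `cubefed_summary`.
#' @param dir Output directory.
#' @param format `"json"` or `"turtle"`.
#' @return Invisibly, the written paths.
#' @export
write_summaries <- function(summaries, dir, format = c("json", "turtle")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "json") "json" else "ttl"
  paths <- vapply(summaries, function(s) {
    path <- file.path(dir, sprintf("summary-%s.%s", s$dataset_id, ext))
    writeLines(serialize_summary(s, format), path)
    path
  }, "")
  invisible(paths)
}

#' Read summaries from files
#' @param paths Summary file paths (JSON or Turtle, guessed per file).
#' @return Named list of `cubefed_summary`.
#' @export
read_summaries <- function(paths) {
  out <- list()
  for (p in paths) {
    text <- paste(readLines(p, warn = FALSE), collapse = "\n")
    out <- c(out, parse_summary(text))
  }
  ids <- vapply(out, function(s) s$dataset_id, "")
  names(out) <- ids
  out[order(ids, method = "radix")]
}
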