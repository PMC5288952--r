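## Endpoint clients. Every outgoing request is either a SELECT sub-query
## or an ASK probe and increments exactly one counter; the graphs named
## in each request are logged so tests can assert that no request ever
## touches an unauthorised graph. The in-memory client evaluates against
## the dataset's quad table with structural graph scoping; the remote
## client speaks the SPARQL 1.1 protocol and trusts the endpoint to
## honour the graph restriction written into the query.

#' Create an endpoint client for a dataset
#'
#' @param ds A `cubefed_dataset` (in-memory or remote).
#' @return A `cubefed_client` (environment with counters `selects`,
#'   `asks` and a log of graphs named per request).
#' @export
endpoint_client <- function(ds) {
  stopifnot(inherits(ds, "cubefed_dataset"))
  env <- new.env(parent = emptyenv())
  env$dataset <- ds
  env$selects <- 0L
  env$asks <- 0L
  env$graph_log <- character(0)
  class(env) <- "cubefed_client"
  env
}

#' Create one client per dataset of a federation
#' @param fed A `cubefed_federation`.
#' @return Named list of clients, keyed by dataset id.
#' @export
federation_clients <- function(fed) {
  lapply(fed$datasets, endpoint_client)
}

#' Request counters of a client (or list of clients)
#' @param client A `cubefed_client` or list of them.
#' @return List with `selects`, `asks` and `graphs_requested`.
#' @export
client_counters <- function(client) {
  if (inherits(client, "cubefed_client")) client <- list(client)
  list(
    selects = sum(vapply(client, function(c) c$selects, 0L)),
    asks = sum(vapply(client, function(c) c$asks, 0L)),
    graphs_requested = unique(unlist(lapply(client, function(c) c$graph_log)))
  )
}

## Dispatch a group sub-query: evaluate the subject group's patterns
## within each permitted graph and union the per-graph answers. Counts as
## one SELECT request (the rewritten query carries all graphs at once via
## VALUES). `query_text` is what a remote endpoint receives.
client_select_group <- function(client, group, graphs, query_text = NULL) {
  stopifnot(inherits(client, "cubefed_client"), length(graphs) > 0L)
  client$selects <- client$selects + 1L
  client$graph_log <- unique(c(client$graph_log, graphs))
  ds <- client$dataset
  if (ds$remote) {
    if (is.null(query_text)) query_text <- rewrite_subquery(group, graphs)
    return(remote_select(ds$location, query_text))
  }
  parts <- lapply(sort(graphs, method = "radix"), function(g) {
    match_bgp(ds$quads[ds$quads$graph == g, ], group$patterns)
  })
  rbind_bindings(parts)
}

## Dispatch a single-triple-pattern ASK probe, dataset-wide (no graph
## scope: the probe asks whether the dataset holds any matching triple).
client_ask <- function(client, pattern) {
  stopifnot(inherits(client, "cubefed_client"))
  client$asks <- client$asks + 1L
  ds <- client$dataset
  if (ds$remote) {
    return(remote_ask(ds$location, ask_query_text(pattern)))
  }
  nrow(match_pattern(ds$quads, pattern)) > 0L
}

ask_query_text <- function(pattern) {
  sprintf("ASK { GRAPH ?__g { %s %s %s } }", pattern$s, pattern$p, pattern$o)
}

## --- SPARQL 1.1 protocol (remote mode; not exercised offline) ---------

remote_http <- function(endpoint, query, accept) {
  url <- paste0(endpoint, if (grepl("\\?", endpoint)) "&" else "?",
                "query=", utils::URLencode(query, reserved = TRUE))
  con <- url(url, headers = c(Accept = accept))
  on.exit(close(con))
  tryCatch(paste(readLines(con, warn = FALSE), collapse = "\n"),
           error = function(e) {
             stop("endpoint unreachable: ", endpoint, " (", conditionMessage(e), ")",
                  call. = FALSE)
           })
}

remote_select <- function(endpoint, query) {
  txt <- remote_http(endpoint, query, "application/sparql-results+json")
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  vars <- unlist(res$head$vars)
  rows <- lapply(res$results$bindings, function(b) {
    vapply(vars, function(v) {
      cell <- b[[v]]
      if (is.null(cell)) return(NA_character_)
      switch(cell$type,
             uri = iri(cell$value),
             literal = lit(cell$value,
                           datatype = cell$datatype,
                           lang = cell[["xml:lang"]]),
             stop("unsupported term type in results: ", cell$type))
    }, "")
  })
  as_bindings(rows, vars)
}

remote_ask <- function(endpoint, query) {
  txt <- remote_http(endpoint, query, "application/sparql-results+json")
  isTRUE(jsonlite::fromJSON(txt)$boolean)
}
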