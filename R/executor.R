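## Graph-restricted federated execution. Whole subject groups are pushed
## as single sub-queries to each dataset holding selected graphs for the
## group (valid because subject locality confines s-s joins to one
## graph), per-dataset answers are unioned, groups are hash-joined
## locally in ascending order of observed cardinality, and cross-BGP
## combination (UNION, OPTIONAL as left join), FILTERs and solution
## modifiers are applied locally. evaluate_merged() is the brute-force
## oracle: the same query over the merge of every named graph into one
## global dataset, evaluated pattern by pattern with no selection at all.

#' Rewrite a subject group as a graph-restricted sub-query
#'
#' Emits the SPARQL text a remote endpoint receives: the group's
#' patterns wrapped in `GRAPH ?__g { ... }` with an inline `VALUES`
#' clause enumerating the permitted graphs. Output is bit-reproducible:
#' graphs are sorted and variables keep first-appearance order.
#'
#' @param group A subject group (from [group_by_subject()]).
#' @param graphs Non-empty character vector of encoded graph IRIs.
#' @return SPARQL query string.
#' @export
rewrite_subquery <- function(group, graphs) {
  stopifnot(length(graphs) > 0L)
  vars <- pattern_vars(group$patterns)
  triples <- vapply(group$patterns, function(tp) {
    sprintf("    %s %s %s .", tp$s, tp$p, tp$o)
  }, "")
  paste0(
    "SELECT ", paste0("?", vars, collapse = " "), " WHERE {\n",
    "  VALUES ?__g { ", paste(sort(graphs, method = "radix"), collapse = " "), " }\n",
    "  GRAPH ?__g {\n",
    paste(triples, collapse = "\n"), "\n",
    "  }\n}"
  )
}

## graphs selected per dataset for one group, unioned over its patterns
group_graphs_by_dataset <- function(group, bgp_pairs) {
  parts <- lapply(group$patterns, function(tp) bgp_pairs[[tp$id]])
  pairs <- unique(data.table::rbindlist(c(list(empty_pairs()), parts)))
  split(pairs$graph, pairs$dataset)
}

#' Evaluate one subject group over its selected sources
#'
#' Dispatches one sub-query per dataset holding selected graphs for the
#' group and unions the answers. If any predicate-bound pattern of the
#' group selected no source at all the group cannot produce rows and no
#' request is sent.
#'
#' @param group A subject group entry of `sel$groups[[bgp]]`.
#' @param sel A `cubefed_selection` (already policy-filtered if a policy
#'   applies).
#' @param clients Named list of `cubefed_client`.
#' @param bgp Index of the BGP the group belongs to.
#' @return Bindings table (multiset of solution mappings).
#' @export
evaluate_group <- function(group, sel, clients, bgp = 1L) {
  bgp_pairs <- sel$per_bgp[[bgp]]
  for (tp in group$patterns) {
    if (!is_variable(tp$p) && nrow(bgp_pairs[[tp$id]]) == 0L) {
      return(empty_bindings(pattern_vars(group$patterns)))
    }
  }
  by_ds <- group_graphs_by_dataset(group, bgp_pairs)
  parts <- lapply(sort(names(by_ds), method = "radix"), function(ds) {
    if (is.null(clients[[ds]])) stop("execution error: no client for dataset ", ds)
    client_select_group(clients[[ds]], group, unique(by_ds[[ds]]))
  })
  if (!length(parts)) return(empty_bindings(pattern_vars(group$patterns)))
  rbind_bindings(parts)
}

#' Join per-group results
#'
#' Hash join on shared variables, smallest observed intermediate first
#' (ties keep query order). Disjoint variable sets degenerate to the
#' cross product, per SPARQL join semantics.
#'
#' @param results List of bindings tables, in query order.
#' @return A single bindings table.
#' @export
join_groups <- function(results) {
  if (!length(results)) return(unit_bindings(1L))
  sizes <- vapply(results, nrow, 0L)
  remaining <- seq_along(results)
  first <- remaining[which.min(sizes)]
  out <- results[[first]]
  remaining <- setdiff(remaining, first)
  while (length(remaining)) {
    # among groups sharing a variable with the accumulated result, take
    # the smallest; fall back to the smallest overall (cross product)
    shares <- vapply(remaining, function(k) {
      length(setdiff(intersect(names(out), names(results[[k]])), ".u")) > 0L
    }, TRUE)
    cand <- if (any(shares)) remaining[shares] else remaining
    k <- cand[which.min(sizes[cand])]
    remaining <- setdiff(remaining, k)
    out <- if (nrow(out) == 0L) {
      # keep joining to accumulate the variable set of an empty result
      join_bindings(out, results[[k]][0L, ])
    } else {
      join_bindings(out, results[[k]])
    }
  }
  out
}

## evaluate one BGP through selection + clients
evaluate_bgp_federated <- function(bgp, sel, clients, b) {
  groups <- sel$groups[[b]]
  results <- lapply(groups, evaluate_group, sel = sel, clients = clients, bgp = b)
  join_groups(results)
}

## combine per-BGP results according to their roles
combine_bgps <- function(plan, bgp_results) {
  roles <- vapply(plan$bgps, function(b) b$role, "")
  out <- NULL
  base_idx <- which(roles == "base")
  if (length(base_idx)) out <- bgp_results[[base_idx[1]]]
  blocks <- unique(stats::na.omit(vapply(plan$bgps, function(b) {
    b$union_block %||% NA_integer_
  }, 0L)))
  for (blk in blocks) {
    members <- which(roles == "union" &
                       vapply(plan$bgps, function(b) identical(b$union_block, blk), TRUE))
    branch_union <- rbind_bindings(bgp_results[members])
    out <- if (is.null(out)) branch_union else join_bindings(out, branch_union)
  }
  for (k in which(roles == "optional")) {
    out <- if (is.null(out)) bgp_results[[k]] else
      leftjoin_bindings(out, bgp_results[[k]])
  }
  out %||list% unit_bindings(1L)
}

`%||list%` <- function(a, b) if (is.null(a)) b else a

## FILTERs, projection, DISTINCT, ORDER BY, LIMIT
finish_result <- function(plan, bindings) {
  for (f in plan$filters) {
    if (nrow(bindings) == 0L) break
    bindings <- bindings[eval_filter(f, bindings), ]
  }
  vars <- if (identical(plan$vars, "*")) {
    # all variables of the query's patterns, first-appearance order
    unique(unlist(lapply(plan$bgps, function(b) pattern_vars(b$patterns))))
  } else plan$vars
  for (v in vars) {
    if (!v %in% names(bindings)) bindings[, (v) := NA_character_]
  }
  rows <- bindings[, vars, with = FALSE, drop = FALSE]
  if (plan$distinct) rows <- unique(rows)
  if (length(plan$order_by)) {
    cols <- list()
    decr <- logical(0)
    for (ob in plan$order_by) {
      key <- term_sort_key(rows[[ob$var]])
      cols <- c(cols, list(key$num, key$lex))
      decr <- c(decr, ob$desc, ob$desc)
    }
    ord <- do.call(order, c(cols, list(method = "radix", decreasing = decr,
                                       na.last = TRUE)))
    rows <- rows[ord, , drop = FALSE]
  }
  if (!is.null(plan$limit)) rows <- utils::head(rows, plan$limit)
  structure(list(rows = rows, vars = vars, ordered = length(plan$order_by) > 0L),
            class = "cubefed_result")
}

#' @export
print.cubefed_result <- function(x, n = 10L, ...) {
  cat("<cubefed result>", nrow(x$rows), "row(s) over",
      paste0("?", x$vars, collapse = " "), "\n")
  if (nrow(x$rows)) print(utils::head(as.data.frame(x$rows), n))
  m <- attr(x, "metrics")
  if (!is.null(m)) {
    cat(sprintf("metrics: %d sub-queries, %d ASK probe(s), %d tp-wise sources\n",
                m$subqueries, m$asks, m$tp_sources))
  }
  invisible(x)
}

#' @export
as.data.frame.cubefed_result <- function(x, ...) {
  as.data.frame(x$rows, stringsAsFactors = FALSE)
}

#' Compare two result sets
#'
#' Multiset equality over the shared variable set; row order matters
#' only when both results are ordered (ORDER BY).
#'
#' @param a,b `cubefed_result` objects.
#' @return Logical scalar.
#' @export
results_equal <- function(a, b) {
  if (!setequal(a$vars, b$vars)) return(FALSE)
  ra <- as.data.frame(a$rows)[, sort(a$vars), drop = FALSE]
  rb <- as.data.frame(b$rows)[, sort(b$vars), drop = FALSE]
  if (nrow(ra) != nrow(rb)) return(FALSE)
  if (a$ordered && b$ordered) return(identical(unname(ra), unname(rb)))
  key <- function(df) {
    if (!nrow(df)) return(character(0))
    sort(do.call(paste, c(lapply(df, function(x) ifelse(is.na(x), "\x01NA", x)),
                          sep = "\x02")), method = "radix")
  }
  identical(key(ra), key(rb))
}

#' Execute a query over a federation
#'
#' End-to-end pipeline: parse, select sources from the data summaries,
#' filter the selection by the access policy (when given), push subject
#' groups to the selected graphs, join locally, and apply solution
#' modifiers. Metrics (sub-queries, ASK probes, triple-pattern-wise
#' sources, graphs requested) are attached as the `"metrics"` attribute.
#'
#' @param query SPARQL SELECT text or a `cubefed_plan`.
#' @param fed A `cubefed_federation`.
#' @param index Optional `cubefed_index`; built from `fed` when missing.
#' @param policy,user Optional access policy and encoded user IRI;
#'   supplying a policy without a user is an error.
#' @param clients Optional named list of `cubefed_client` (created from
#'   `fed` when missing).
#' @param sel_transform Optional function applied to the (possibly
#'   policy-filtered) selection before execution; used to study the
#'   effect of forcing pruned sources back in.
#' @return A `cubefed_result`.
#' @export
execute <- function(query, fed, index = NULL, policy = NULL, user = NULL,
                    clients = NULL, sel_transform = NULL) {
  plan <- if (inherits(query, "cubefed_plan")) query else parse_query(query)
  if (!is.null(policy) && is.null(user)) {
    stop("a user IRI is required when a policy is supplied")
  }
  if (is.null(index)) index <- derive_indexes(build_summaries(fed))
  if (is.null(clients)) clients <- federation_clients(fed)
  before <- client_counters(clients)
  sel <- select_sources(plan, index, clients)
  if (!is.null(policy)) sel <- filter_selection(sel, policy, user)
  if (!is.null(sel_transform)) sel <- sel_transform(sel)
  bgp_results <- lapply(seq_along(plan$bgps), function(b) {
    evaluate_bgp_federated(plan$bgps[[b]], sel, clients, b)
  })
  res <- finish_result(plan, combine_bgps(plan, bgp_results))
  after <- client_counters(clients)
  attr(res, "metrics") <- list(
    subqueries = after$selects - before$selects,
    asks = after$asks - before$asks,
    tp_sources = tp_sources_selected(sel),
    graphs_requested = setdiff(after$graphs_requested, before$graphs_requested)
  )
  attr(res, "selection") <- sel
  res
}

#' Evaluate a query over the merged federation (oracle)
#'
#' Merges every named graph of every dataset into one global dataset and
#' evaluates the query there, pattern by pattern, with no source
#' selection, no summaries and no clients. This is the correctness
#' reference: for locality-respecting, blank-node-free data,
#' [execute()] must return the same multiset. With `graphs` set to the
#' graphs a user may read, it is the reference for the policy-filtered
#' case.
#'
#' @param query SPARQL SELECT text or a `cubefed_plan`.
#' @param fed A `cubefed_federation` (in-memory).
#' @param graphs Optional restriction to a set of encoded graph IRIs.
#' @return A `cubefed_result`.
#' @export
evaluate_merged <- function(query, fed, graphs = NULL) {
  plan <- if (inherits(query, "cubefed_plan")) query else parse_query(query)
  quads <- merged_quads(fed, graphs)
  bgp_results <- lapply(plan$bgps, function(bgp) match_bgp(quads, bgp$patterns))
  finish_result(plan, combine_bgps(plan, bgp_results))
}
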