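## Two-level join-aware source selection. Level 1 picks candidate
## datasets per subject group (a dataset qualifies only if it holds every
## bound predicate of the group); level 2 picks graphs within each
## candidate using unique-predicate pinning: a predicate unique to one
## graph of a dataset pins the whole group to that graph, predicates
## unique to two different graphs of the same dataset rule the dataset
## out entirely (an s-s join can never span graphs under the locality
## assumption), and otherwise all graphs of the dataset stay in play.
## Within a candidate dataset each pattern is additionally intersected
## with the graphs that actually contain its predicate -- a tightening
## that can only drop graphs unable to match the pattern. Patterns with
## variable predicates inherit their subject group's restriction when one
## exists; otherwise a bound subject or object triggers one ASK probe per
## dataset, and a fully unbound pattern matches every graph with no probe.

empty_pairs <- function() {
  data.table::data.table(dataset = character(0), graph = character(0))
}

pairs_dt <- function(dataset, graphs) {
  if (!length(graphs)) return(empty_pairs())
  data.table::data.table(dataset = dataset, graph = sort(graphs, method = "radix"))
}

#' Graph restriction of one subject group, per dataset
#'
#' @param group A subject group from [group_by_subject()] with at least
#'   one bound predicate.
#' @param index A `cubefed_index` from [derive_indexes()].
#' @return List with `restriction` (named list dataset id -> character
#'   vector of graph IRIs the group may touch in that dataset) and
#'   `skipped` (data.frame of dataset/reason diagnostics).
#' @export
select_for_group <- function(group, index) {
  stopifnot(inherits(index, "cubefed_index"), length(group$bound_preds) > 0L)
  restriction <- list()
  skipped_ds <- character(0)
  skipped_why <- character(0)
  for (ds in names(index$summaries)) {
    if (!all(group$bound_preds %in% index$preds[[ds]])) {
      skipped_ds <- c(skipped_ds, ds)
      skipped_why <- c(skipped_why, "missing predicate")
      next
    }
    upg <- index$upreds[[ds]]
    hit <- names(upg)[vapply(upg, function(ps) any(group$bound_preds %in% ps), TRUE)]
    if (length(hit) >= 2L) {
      # predicates unique to different graphs: no graph can satisfy the join
      skipped_ds <- c(skipped_ds, ds)
      skipped_why <- c(skipped_why, "unique-predicate conflict")
      next
    }
    restriction[[ds]] <- if (length(hit) == 1L) hit else
      index$summaries[[ds]]$graph_names
  }
  list(restriction = restriction,
       skipped = data.frame(dataset = skipped_ds, reason = skipped_why,
                            stringsAsFactors = FALSE))
}

#' Resolve a variable-predicate pattern
#'
#' @param pattern Triple pattern whose predicate is a variable.
#' @param group_restriction Named list dataset -> graphs from
#'   [select_for_group()], or `NULL` when the pattern's subject group has
#'   no bound predicate.
#' @param index A `cubefed_index`.
#' @param clients Named list of `cubefed_client` (needed only when an
#'   ASK probe is required).
#' @return List with `pairs` (data.table dataset/graph) and `asks`
#'   (number of probes dispatched).
#' @export
resolve_unbound <- function(pattern, group_restriction, index, clients = NULL) {
  stopifnot(is_variable(pattern$p))
  if (!is.null(group_restriction)) {
    pairs <- data.table::rbindlist(c(list(empty_pairs()),
      lapply(names(group_restriction), function(ds) {
        pairs_dt(ds, group_restriction[[ds]])
      })))
    return(list(pairs = pairs, asks = 0L))
  }
  s_bound <- !is_variable(pattern$s)
  o_bound <- !is_variable(pattern$o)
  if (!s_bound && !o_bound) {
    pairs <- data.table::rbindlist(c(list(empty_pairs()),
      lapply(index$summaries, function(s) pairs_dt(s$dataset_id, s$graph_names))))
    return(list(pairs = pairs, asks = 0L))
  }
  if (is.null(clients)) {
    stop("resolve_unbound: ASK probes required but no clients supplied")
  }
  asks <- 0L
  parts <- list(empty_pairs())
  for (ds in names(index$summaries)) {
    if (is.null(clients[[ds]])) stop("no client for dataset ", ds)
    asks <- asks + 1L
    if (client_ask(clients[[ds]], pattern)) {
      parts[[length(parts) + 1L]] <-
        pairs_dt(ds, index$summaries[[ds]]$graph_names)
    }
  }
  list(pairs = data.table::rbindlist(parts), asks = asks)
}

#' Select sources for every triple pattern of a query plan
#'
#' Runs the group-level selection per BGP (BGPs are kept separate: the
#' same pattern may select different sources in different branches),
#' resolves variable-predicate patterns, and reports the number of ASK
#' probes dispatched.
#'
#' @param plan A `cubefed_plan` from [parse_query()].
#' @param index A `cubefed_index` from [derive_indexes()]; must cover
#'   every dataset the clients expose.
#' @param clients Optional named list of `cubefed_client` (required only
#'   if an ASK probe becomes necessary).
#' @return A `cubefed_selection`: list with `per_bgp` (per BGP, a list
#'   mapping pattern index -> data.table of dataset/graph pairs),
#'   `groups` (per BGP, the subject groups and their restrictions),
#'   `ask_count` and `skipped` diagnostics.
#' @export
select_sources <- function(plan, index, clients = NULL) {
  stopifnot(inherits(plan, "cubefed_plan"), inherits(index, "cubefed_index"))
  if (!is.null(clients)) {
    missing <- setdiff(names(clients), names(index$summaries))
    if (length(missing)) {
      stop("no data summary for dataset(s): ", paste(missing, collapse = ", "))
    }
  }
  ask_count <- 0L
  skipped <- list()
  per_bgp <- list()
  groups_out <- list()
  for (b in seq_along(plan$bgps)) {
    bgp <- plan$bgps[[b]]
    groups <- group_by_subject(bgp)
    pairs <- vector("list", length(bgp$patterns))
    ginfo <- list()
    for (g in groups) {
      restriction <- NULL
      if (length(g$bound_preds)) {
        sel <- select_for_group(g, index)
        restriction <- sel$restriction
        if (nrow(sel$skipped)) {
          sk <- sel$skipped
          sk$bgp <- b
          sk$subject <- g$subject
          skipped[[length(skipped) + 1L]] <- sk
        }
        for (tp in g$patterns) {
          if (is_variable(tp$p)) next
          parts <- list(empty_pairs())
          for (ds in names(restriction)) {
            keep <- intersect(restriction[[ds]],
                              index$summaries[[ds]]$pred_to_graphs[[tp$p]])
            parts[[length(parts) + 1L]] <- pairs_dt(ds, keep)
          }
          pairs[[tp$id]] <- data.table::rbindlist(parts)
        }
      }
      for (tp in g$patterns) {
        if (!is_variable(tp$p)) next
        res <- resolve_unbound(tp, restriction, index, clients)
        ask_count <- ask_count + res$asks
        pairs[[tp$id]] <- res$pairs
      }
      ginfo[[length(ginfo) + 1L]] <-
        list(subject = g$subject, patterns = g$patterns,
             bound_preds = g$bound_preds, restriction = restriction)
    }
    per_bgp[[b]] <- pairs
    groups_out[[b]] <- ginfo
  }
  skipped <- if (length(skipped)) {
    do.call(rbind, skipped)[, c("bgp", "subject", "dataset", "reason")]
  } else {
    data.frame(bgp = integer(0), subject = character(0),
               dataset = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(per_bgp = per_bgp, groups = groups_out,
                 ask_count = ask_count, skipped = skipped),
            class = "cubefed_selection")
}

#' Distinct dataset-graph pairs in a selection
#' @param sel A `cubefed_selection`.
#' @return data.table of distinct dataset/graph pairs across patterns.
#' @export
selected_pairs <- function(sel) {
  unique(data.table::rbindlist(c(list(empty_pairs()),
    lapply(sel$per_bgp, function(pairs) data.table::rbindlist(pairs)))))
}

#' Sum of triple-pattern-wise sources selected
#'
#' The evaluation metric used to compare selection granularity: the sum
#' over triple patterns of the number of distinct datasets selected for
#' that pattern.
#'
#' @param sel A `cubefed_selection`.
#' @return Integer.
#' @export
tp_sources_selected <- function(sel) {
  sum(vapply(sel$per_bgp, function(pairs) {
    sum(vapply(pairs, function(p) length(unique(p$dataset)), 0L))
  }, 0L))
}

#' @export
print.cubefed_selection <- function(x, ...) {
  cat("<cubefed selection>", length(x$per_bgp), "BGP(s),",
      x$ask_count, "ASK probe(s)\n")
  for (b in seq_along(x$per_bgp)) {
    for (t in seq_along(x$per_bgp[[b]])) {
      p <- x$per_bgp[[b]][[t]]
      cat(sprintf("  bgp %d pattern %d: %d pair(s)\n", b, t, nrow(p)))
    }
  }
  invisible(x)
}
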