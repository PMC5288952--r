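## Graph-level access control, default deny: a user may read a named
## graph iff the policy holds an explicit (user, graph, read) grant.
## Filtering happens after source selection and before any sub-query is
## dispatched, so an unauthorised graph is never named in a request
## (rather than being rejected at the remote endpoint).

#' Construct an access policy
#'
#' @param grants data.frame with columns `user`, `graph` (encoded IRIs)
#'   and `right` (`"read"` or `"write"`). Absence of a grant means
#'   denial.
#' @param users Optional list of user profiles: each a list with `id`
#'   (encoded IRI) and `attributes` (named list: activity, location,
#'   organisation, position, role). Attributes are carried for
#'   interchange; they are not evaluated as access conditions.
#' @return A `cubefed_policy`.
#' @export
access_policy <- function(grants = NULL, users = list()) {
  if (is.null(grants) || !nrow(grants)) {
    grants <- data.frame(user = character(0), graph = character(0),
                         right = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("user", "graph", "right") %in% names(grants)),
            all(grants$right %in% c("read", "write")))
  ids <- vapply(users, function(u) u$id, "")
  if (anyDuplicated(ids)) stop("duplicate user profile id: ", ids[duplicated(ids)][1])
  grants <- unique(grants[, c("user", "graph", "right")])
  grants <- grants[order(grants$user, grants$graph, grants$right, method = "radix"), ,
                   drop = FALSE]
  rownames(grants) <- NULL
  structure(list(grants = grants, users = users), class = "cubefed_policy")
}

#' Is a user granted a right on a graph?
#'
#' Pure lookup with default deny: unknown users and graphs simply yield
#' `FALSE`.
#'
#' @param user Encoded user IRI.
#' @param graph Encoded graph IRI.
#' @param right `"read"` or `"write"`.
#' @param policy A `cubefed_policy`.
#' @return Logical scalar.
#' @export
authorised <- function(user, graph, right, policy) {
  stopifnot(inherits(policy, "cubefed_policy"))
  g <- policy$grants
  any(g$user == user & g$graph == graph & g$right == right)
}

#' Graphs a user may read
#' @inheritParams authorised
#' @return Character vector of encoded graph IRIs.
#' @export
readable_graphs <- function(user, policy) {
  g <- policy$grants
  sort(unique(g$graph[g$user == user & g$right == "read"]), method = "radix")
}

#' Filter a selection by an access policy
#'
#' Removes every (dataset, graph) pair whose graph the user cannot read
#' from every pattern of every BGP (and from the recorded group
#' restrictions). Anti-monotone and idempotent.
#'
#' @param sel A `cubefed_selection`.
#' @param policy A `cubefed_policy`.
#' @param user Encoded user IRI.
#' @return The filtered `cubefed_selection`.
#' @export
filter_selection <- function(sel, policy, user) {
  stopifnot(inherits(sel, "cubefed_selection"))
  ok <- readable_graphs(user, policy)
  sel$per_bgp <- lapply(sel$per_bgp, function(pairs) {
    lapply(pairs, function(p) p[p$graph %in% ok, ])
  })
  sel$groups <- lapply(sel$groups, function(ginfo) {
    lapply(ginfo, function(g) {
      if (!is.null(g$restriction)) {
        g$restriction <- lapply(g$restriction, function(gr) intersect(gr, ok))
        g$restriction <- Filter(length, g$restriction)
      }
      g
    })
  })
  sel
}

LMDS_POLICY <- paste0("<", LMDS_NS, "hasAccessPolicy>")
LMDS_USER <- paste0("<", LMDS_NS, "user>")
LMDS_GRAPHP <- paste0("<", LMDS_NS, "graph>")
LMDS_RIGHT <- paste0("<", LMDS_NS, "right>")
PROFILE_ATTRS <- c("activity", "location", "organisation", "position", "role")

#' Serialise an access policy
#'
#' @param policy A `cubefed_policy`.
#' @param format `"json"` or `"turtle"`. The RDF form attaches each
#'   grant to its user via `lmds:hasAccessPolicy` pointing at an
#'   IRI-named policy node carrying `lmds:user`, `lmds:graph` and
#'   `lmds:right`; profile attributes use `lmds:<attribute>` predicates.
#' @return Character scalar with the document text.
#' @export
serialize_policy <- function(policy, format = c("json", "turtle")) {
  format <- match.arg(format)
  stopifnot(inherits(policy, "cubefed_policy"))
  if (format == "json") {
    payload <- list(
      users = lapply(policy$users, function(u) {
        list(id = u$id, attributes = u$attributes)
      }),
      grants = lapply(seq_len(nrow(policy$grants)), function(k) {
        as.list(policy$grants[k, ])
      })
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)))
  }
  s <- character(0); p <- character(0); o <- character(0)
  add <- function(ss, pp, oo) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
  }
  for (u in policy$users) {
    for (a in names(u$attributes)) {
      add(u$id, paste0("<", LMDS_NS, a, ">"), lit(u$attributes[[a]]))
    }
  }
  if (nrow(policy$grants)) {
    for (k in seq_len(nrow(policy$grants))) {
      gr <- policy$grants[k, ]
      node <- iri(paste0("urn:grant:", k))
      add(gr$user, LMDS_POLICY, node)
      add(node, LMDS_USER, gr$user)
      add(node, LMDS_GRAPHP, gr$graph)
      add(node, LMDS_RIGHT, lit(gr$right))
    }
  }
  write_turtle(data.table::data.table(s = s, p = p, o = o))
}

#' Parse an access policy document
#'
#' @param text Policy document text (JSON or Turtle; guessed).
#' @param format Optional `"json"` or `"turtle"`.
#' @return A `cubefed_policy`.
#' @export
parse_policy <- function(text, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("^\\s*\\{", text)) "json" else "turtle"
  }
  if (format == "json") {
    payload <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    grants <- if (length(payload$grants)) {
      do.call(rbind, lapply(payload$grants, function(g) {
        data.frame(user = g$user, graph = g$graph, right = g$right,
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    users <- lapply(payload$users, function(u) {
      list(id = u$id, attributes = lapply(u$attributes, as.character))
    })
    return(access_policy(grants, users))
  }
  doc <- parse_trig(text, allow_default_graph = TRUE, what = "policy document")
  tr <- doc$quads
  nodes <- unique(tr$o[tr$p == LMDS_POLICY])
  grants <- if (length(nodes)) {
    do.call(rbind, lapply(nodes, function(node) {
      u <- tr$o[tr$s == node & tr$p == LMDS_USER]
      g <- tr$o[tr$s == node & tr$p == LMDS_GRAPHP]
      r <- tr$o[tr$s == node & tr$p == LMDS_RIGHT]
      if (length(u) != 1L || length(g) != 1L || length(r) != 1L) {
        stop("malformed policy document: grant node ", node,
             " needs exactly one lmds:user, lmds:graph and lmds:right")
      }
      data.frame(user = u, graph = g, right = term_fields(r)$value,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  attr_preds <- paste0("<", LMDS_NS, PROFILE_ATTRS, ">")
  prof_subjects <- sort(unique(tr$s[tr$p %in% attr_preds]), method = "radix")
  users <- lapply(prof_subjects, function(su) {
    attrs <- list()
    for (a in PROFILE_ATTRS) {
      v <- tr$o[tr$s == su & tr$p == paste0("<", LMDS_NS, a, ">")]
      if (length(v)) attrs[[a]] <- term_fields(v[1])$value
    }
    list(id = su, attributes = attrs)
  })
  access_policy(grants, users)
}

#' Read a policy file (JSON or Turtle by extension)
#' @param path File path.
#' @return A `cubefed_policy`.
#' @export
read_policy <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  fmt <- if (tolower(tools::file_ext(path)) == "json") "json" else "turtle"
  parse_policy(text, fmt)
}
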