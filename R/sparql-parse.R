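## SPARQL 1.1 SELECT parser for the fragment the engine supports: basic
## graph patterns, FILTER (comparisons, &&/||/!, REGEX, BOUND), UNION,
## OPTIONAL, DISTINCT, ORDER BY, LIMIT. Property paths, aggregates,
## subqueries and SERVICE are rejected with an unsupported-feature error.
## The parse decomposes the query into one BGP per union/optional branch
## -- the unit the source selection algorithm operates on.

UNSUPPORTED_KEYWORDS <- c(
  "CONSTRUCT", "DESCRIBE", "ASK", "GROUP", "HAVING", "SERVICE", "MINUS",
  "EXISTS", "VALUES", "BIND", "COUNT", "SUM", "AVG", "MIN", "MAX", "OFFSET"
)

#' Parse a SPARQL SELECT query
#'
#' @param text SPARQL query text.
#' @return A `cubefed_plan`: list with `prefixes`, `vars` (projected
#'   variable names or `"*"`), `distinct`, `bgps` (each a list with
#'   `patterns`, `role` one of `"base"`/`"union"`/`"optional"`, and for
#'   union branches `union_block`), `filters` (expression ASTs),
#'   `order_by`, `limit` and the original `text`.
#' @export
parse_query <- function(text) {
  cur <- new_cursor(tokenize(text, "SPARQL query"), "SPARQL query")
  prefixes <- DEFAULT_PREFIXES[0]

  # prologue
  while (identical(toupper(cur_peek(cur) %||% ""), "PREFIX")) {
    cur_next(cur)
    ns_tok <- cur_next(cur)
    if (!is_pname_tok(ns_tok) || !endsWith(ns_tok, ":")) {
      cur$i <- cur$i - 1L
      cur_fail(cur, "expected 'prefix:' in PREFIX declaration")
    }
    iri_tok <- cur_next(cur)
    if (!is_iriref_tok(iri_tok)) cur_fail(cur, "expected IRI in PREFIX declaration")
    prefixes[substr(ns_tok, 1L, nchar(ns_tok) - 1L)] <-
      substr(iri_tok, 2L, nchar(iri_tok) - 1L)
  }

  head_tok <- toupper(cur_peek(cur) %||% "")
  if (head_tok %in% UNSUPPORTED_KEYWORDS) {
    cur_fail(cur, paste0("unsupported feature: ", head_tok))
  }
  if (!identical(head_tok, "SELECT")) cur_fail(cur, "expected SELECT")
  cur_next(cur)

  distinct <- FALSE
  if (identical(toupper(cur_peek(cur) %||% ""), "DISTINCT")) {
    distinct <- TRUE
    cur_next(cur)
  }
  vars <- character(0)
  if (identical(cur_peek(cur), "*")) {
    cur_next(cur)
    vars <- "*"
  } else {
    while (is_var_tok(cur_peek(cur) %||% "")) {
      vars <- c(vars, substring(cur_next(cur), 2L))
    }
    if (!length(vars)) cur_fail(cur, "SELECT needs projected variables or *")
  }

  if (identical(toupper(cur_peek(cur) %||% ""), "WHERE")) cur_next(cur)

  state <- new.env(parent = emptyenv())
  state$bgps <- list()
  state$filters <- list()
  state$union_blocks <- 0L
  parse_group(cur, prefixes, state, role = "base")

  order_by <- list()
  limit <- NULL
  while (!is.na(cur_peek(cur))) {
    kw <- toupper(cur_next(cur))
    if (kw == "ORDER") {
      if (!identical(toupper(cur_next(cur)), "BY")) cur_fail(cur, "expected BY after ORDER")
      repeat {
        t <- cur_peek(cur)
        if (is.na(t)) break
        if (is_var_tok(t)) {
          cur_next(cur)
          order_by[[length(order_by) + 1L]] <- list(var = substring(t, 2L), desc = FALSE)
        } else if (toupper(t) %in% c("ASC", "DESC")) {
          dirn <- toupper(cur_next(cur))
          cur_expect(cur, "(")
          v <- cur_next(cur)
          if (!is_var_tok(v)) cur_fail(cur, "expected variable in ORDER BY")
          cur_expect(cur, ")")
          order_by[[length(order_by) + 1L]] <-
            list(var = substring(v, 2L), desc = dirn == "DESC")
        } else break
      }
    } else if (kw == "LIMIT") {
      n_tok <- cur_next(cur)
      if (!grepl("^[0-9]+$", n_tok)) cur_fail(cur, "LIMIT expects an integer")
      limit <- as.integer(n_tok)
    } else if (kw %in% UNSUPPORTED_KEYWORDS) {
      cur$i <- cur$i - 1L
      cur_fail(cur, paste0("unsupported feature: ", kw))
    } else {
      cur$i <- cur$i - 1L
      cur_fail(cur, paste0("unexpected token '", cur_peek(cur), "'"))
    }
  }

  bgps <- state$bgps
  if (!length(bgps)) cur_fail(cur, "query has no triple patterns")
  structure(
    list(prefixes = prefixes, vars = vars, distinct = distinct,
         bgps = bgps, filters = state$filters, order_by = order_by,
         limit = limit, text = text),
    class = "cubefed_plan"
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

## parse '{ ... }' appending BGPs/filters to state
parse_group <- function(cur, prefixes, state, role, union_block = NA_integer_) {
  cur_expect(cur, "{")
  patterns <- list()
  flush_bgp <- function() {
    if (length(patterns)) {
      for (k in seq_along(patterns)) patterns[[k]]$id <- k
      state$bgps[[length(state$bgps) + 1L]] <<-
        list(patterns = patterns, role = role, union_block = union_block)
      patterns <<- list()
    }
  }
  repeat {
    t <- cur_peek(cur)
    if (is.na(t)) cur_fail(cur, "unterminated group pattern")
    if (identical(t, "}")) {
      cur_next(cur)
      break
    }
    up <- toupper(t)
    if (up %in% UNSUPPORTED_KEYWORDS) cur_fail(cur, paste0("unsupported feature: ", up))
    if (identical(up, "FILTER")) {
      cur_next(cur)
      state$filters[[length(state$filters) + 1L]] <- parse_filter(cur, prefixes)
      if (identical(cur_peek(cur), ".")) cur_next(cur)
      next
    }
    if (identical(up, "OPTIONAL")) {
      cur_next(cur)
      parse_group(cur, prefixes, state, role = "optional")
      if (identical(cur_peek(cur), ".")) cur_next(cur)
      next
    }
    if (identical(t, "{")) {
      # union block: { A } UNION { B } UNION ...
      state$union_blocks <- state$union_blocks + 1L
      blk <- state$union_blocks
      parse_group(cur, prefixes, state, role = "union", union_block = blk)
      while (identical(toupper(cur_peek(cur) %||% ""), "UNION")) {
        cur_next(cur)
        parse_group(cur, prefixes, state, role = "union", union_block = blk)
      }
      if (identical(cur_peek(cur), ".")) cur_next(cur)
      next
    }
    # triples statement
    stmt_patterns(cur, prefixes, function(s, p, o) {
      patterns[[length(patterns) + 1L]] <<- list(s = s, p = p, o = o, id = NA_integer_)
    })
    if (identical(cur_peek(cur), ".")) cur_next(cur)
  }
  flush_bgp()
  invisible(NULL)
}

## subject (predicate objectList (';' ...)*) with variables allowed
stmt_patterns <- function(cur, prefixes, emit) {
  s <- parse_term(cur, prefixes, allow_var = TRUE)
  if (is_literal(s)) cur_fail(cur, "subject cannot be a literal")
  repeat {
    p <- parse_term(cur, prefixes, allow_var = TRUE)
    if (is_literal(p)) cur_fail(cur, "predicate cannot be a literal")
    repeat {
      o <- parse_term(cur, prefixes, allow_var = TRUE)
      emit(s, p, o)
      if (identical(cur_peek(cur), ",")) cur_next(cur) else break
    }
    if (identical(cur_peek(cur), ";")) {
      cur_next(cur)
      nxt <- cur_peek(cur)
      if (is.na(nxt) || nxt %in% c(".", "}")) break
    } else break
  }
}

## --- FILTER expressions ----------------------------------------------

parse_filter <- function(cur, prefixes) {
  cur_expect(cur, "(")
  e <- parse_or(cur, prefixes)
  cur_expect(cur, ")")
  e
}

parse_or <- function(cur, prefixes) {
  e <- parse_and(cur, prefixes)
  while (identical(cur_peek(cur), "||")) {
    cur_next(cur)
    e <- list(type = "or", lhs = e, rhs = parse_and(cur, prefixes))
  }
  e
}

parse_and <- function(cur, prefixes) {
  e <- parse_unary(cur, prefixes)
  while (identical(cur_peek(cur), "&&")) {
    cur_next(cur)
    e <- list(type = "and", lhs = e, rhs = parse_unary(cur, prefixes))
  }
  e
}

parse_unary <- function(cur, prefixes) {
  t <- cur_peek(cur)
  if (identical(t, "!")) {
    cur_next(cur)
    return(list(type = "not", arg = parse_unary(cur, prefixes)))
  }
  if (identical(t, "(")) {
    cur_next(cur)
    e <- parse_or(cur, prefixes)
    cur_expect(cur, ")")
    return(maybe_cmp(cur, prefixes, e))
  }
  up <- toupper(t %||% "")
  if (up == "REGEX") {
    cur_next(cur)
    cur_expect(cur, "(")
    v <- parse_operand(cur, prefixes)
    cur_expect(cur, ",")
    pat <- parse_operand(cur, prefixes)
    flags <- NULL
    if (identical(cur_peek(cur), ",")) {
      cur_next(cur)
      flags <- parse_operand(cur, prefixes)
    }
    cur_expect(cur, ")")
    return(list(type = "regex", arg = v, pattern = pat, flags = flags))
  }
  if (up == "BOUND") {
    cur_next(cur)
    cur_expect(cur, "(")
    v <- parse_operand(cur, prefixes)
    cur_expect(cur, ")")
    return(list(type = "bound", arg = v))
  }
  maybe_cmp(cur, prefixes, NULL)
}

maybe_cmp <- function(cur, prefixes, lhs) {
  if (is.null(lhs)) lhs <- parse_operand(cur, prefixes)
  op <- cur_peek(cur)
  if (!is.na(op) && op %in% c("=", "!=", "<", "<=", ">", ">=")) {
    cur_next(cur)
    rhs <- parse_operand(cur, prefixes)
    return(list(type = "cmp", op = op, lhs = lhs, rhs = rhs))
  }
  lhs
}

parse_operand <- function(cur, prefixes) {
  t <- cur_peek(cur)
  if (is_var_tok(t %||% "")) {
    cur_next(cur)
    return(list(type = "var", name = substring(t, 2L)))
  }
  list(type = "const", term = parse_term(cur, prefixes))
}

## Evaluate a filter AST over a bindings table -> logical vector.
## SPARQL error semantics collapse to FALSE (rows with unbound or
## non-comparable operands are dropped).
eval_filter <- function(expr, dt) {
  n <- nrow(dt)
  operand_terms <- function(opnd) {
    if (opnd$type == "var") {
      if (opnd$name %in% names(dt)) dt[[opnd$name]] else rep(NA_character_, n)
    } else rep(opnd$term, n)
  }
  switch(expr$type,
    and = eval_filter(expr$lhs, dt) & eval_filter(expr$rhs, dt),
    or = eval_filter(expr$lhs, dt) | eval_filter(expr$rhs, dt),
    not = !eval_filter(expr$arg, dt),
    bound = !is.na(operand_terms(expr$arg)),
    regex = {
      x <- operand_terms(expr$arg)
      lex <- vapply(x, function(t) {
        if (is.na(t)) NA_character_ else term_fields(t)$value
      }, "")
      pat <- term_fields(expr$pattern$term)$value
      ic <- !is.null(expr$flags) && grepl("i", term_fields(expr$flags$term)$value)
      out <- grepl(pat, lex, ignore.case = ic, perl = TRUE)
      out & !is.na(lex)
    },
    cmp = {
      l <- operand_terms(expr$lhs)
      r <- operand_terms(expr$rhs)
      ln <- suppressWarnings(vapply(l, function(t) if (is.na(t)) NA_real_ else term_numeric(t), 0))
      rn <- suppressWarnings(vapply(r, function(t) if (is.na(t)) NA_real_ else term_numeric(t), 0))
      numeric_ok <- !is.na(ln) & !is.na(rn)
      res <- switch(expr$op,
        "=" = ifelse(numeric_ok, ln == rn, l == r),
        "!=" = ifelse(numeric_ok, ln != rn, l != r),
        "<" = ln < rn,
        "<=" = ln <= rn,
        ">" = ln > rn,
        ">=" = ln >= rn
      )
      res & !is.na(res)
    },
    stop("unknown filter expression type: ", expr$type)
  )
}
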