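## Hand-written TriG / Turtle / N-Quads reader and writer for the
## named-graph fragment the engine needs. Blank nodes and default-graph
## triples are rejected (see the data-model invariants): the source
## selection completeness argument assumes neither exists.

TOKEN_REGEX <- paste0(
  "#[^\n]*",                                            # comment
  "|@prefix",
  "|<[^<>\"{}|^`\\\\[:space:]]*>",                      # IRIREF
  "|\"(\\\\.|[^\"\\\\])*\"",                            # STRING
  "|@[A-Za-z]+(-[A-Za-z0-9]+)*",                        # LANGTAG
  "|\\^\\^",
  "|[+-]?([0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)([eE][+-]?[0-9]+)?", # NUMBER
  "|_:[A-Za-z0-9_.-]*",                                 # blank node label
  "|\\?[A-Za-z_][A-Za-z0-9_]*",                         # VAR (queries)
  "|([A-Za-z][A-Za-z0-9_.-]*)?:([A-Za-z0-9_]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?", # PNAME
  "|[A-Za-z][A-Za-z0-9_-]*",                            # bareword/keyword
  "|&&|\\|\\||!=|<=|>=|\\(|\\)|\\{|\\}|\\[|\\]|;|,|\\.|\\*|=|<|>|!"
)

## Tokenise a Turtle-family or SPARQL document. Returns a data.frame of
## token strings and 1-based line numbers; errors on any non-whitespace
## text no token matches.
tokenize <- function(text, what = "document") {
  m <- gregexpr(TOKEN_REGEX, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    toks <- character(0)
    starts <- integer(0)
    lens <- integer(0)
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    toks <- substring(text, starts, starts + lens - 1L)
  }
  # coverage check: the gaps between tokens must be pure whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) {
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(bad)) {
    line <- sum(chars[seq_len(bad[1])] == "\n") + 1L
    stop(sprintf("%s: unexpected character '%s' at line %d",
                 what, chars[bad[1]], line))
  }
  nl <- cumsum(chars == "\n")
  lines <- if (length(starts)) {
    # guard the 0 index (a token at position 1): R would drop it and
    # shift every later line number
    ifelse(starts == 1L, 1L, nl[pmax(starts - 1L, 1L)] + 1L)
  } else integer(0)
  keep <- !startsWith(toks, "#")
  data.frame(tok = toks[keep], line = lines[keep], stringsAsFactors = FALSE)
}

## cursor over a token table
new_cursor <- function(tokens, what) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens$tok
  env$lines <- tokens$line
  env$i <- 1L
  env$what <- what
  env
}
cur_peek <- function(cur) if (cur$i <= length(cur$toks)) cur$toks[cur$i] else NA_character_
cur_next <- function(cur) {
  t <- cur_peek(cur)
  if (is.na(t)) cur_fail(cur, "unexpected end of input")
  cur$i <- cur$i + 1L
  t
}
cur_line <- function(cur) {
  if (cur$i <= length(cur$lines)) cur$lines[cur$i] else
    if (length(cur$lines)) cur$lines[length(cur$lines)] else 1L
}
cur_fail <- function(cur, msg) {
  stop(sprintf("%s: %s at line %d", cur$what, msg, cur_line(cur)), call. = FALSE)
}
cur_expect <- function(cur, tok) {
  t <- cur_next(cur)
  if (!identical(t, tok)) {
    cur$i <- cur$i - 1L
    cur_fail(cur, sprintf("expected '%s', found '%s'", tok, t))
  }
  t
}

is_iriref_tok <- function(t) grepl("^<[^<>]*>$", t)
is_pname_tok <- function(t) {
  grepl("^([A-Za-z][A-Za-z0-9_.-]*)?:([A-Za-z0-9_]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?$", t)
}
is_string_tok <- function(t) startsWith(t, "\"")
is_number_tok <- function(t) grepl("^[+-]?([0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)([eE][+-]?[0-9]+)?$", t)
is_blank_tok <- function(t) startsWith(t, "_:") || t %in% c("[", "]")
is_var_tok <- function(t) grepl("^\\?[A-Za-z_][A-Za-z0-9_]*$", t)

## parse a term at the cursor (data positions: IRIs and literals only)
parse_term <- function(cur, prefixes, allow_var = FALSE) {
  t <- cur_next(cur)
  if (is_blank_tok(t)) {
    cur$i <- cur$i - 1L
    cur_fail(cur, sprintf("blank node '%s' not allowed (engine assumes blank-node-free data)", t))
  }
  if (is_iriref_tok(t)) return(t)
  if (identical(t, "a")) return(RDF_TYPE)
  if (allow_var && is_var_tok(t)) return(t)
  if (is_string_tok(t)) {
    nxt <- cur_peek(cur)
    if (!is.na(nxt) && identical(nxt, "^^")) {
      cur_next(cur)
      dt_tok <- cur_next(cur)
      dt <- if (is_iriref_tok(dt_tok)) dt_tok else if (is_pname_tok(dt_tok)) {
        expand_pname(dt_tok, prefixes)
      } else {
        cur$i <- cur$i - 1L
        cur_fail(cur, "expected datatype IRI after '^^'")
      }
      return(paste0(t, "^^", dt))
    }
    if (!is.na(nxt) && grepl("^@[A-Za-z]", nxt) && !identical(nxt, "@prefix")) {
      cur_next(cur)
      return(paste0(t, nxt))
    }
    return(t)
  }
  if (is_number_tok(t)) {
    dt <- if (grepl("[eE]", t)) XSD_DOUBLE else if (grepl("\\.", t)) XSD_DECIMAL else XSD_INTEGER
    return(paste0('"', t, '"^^<', dt, ">"))
  }
  if (t %in% c("true", "false")) {
    return(paste0('"', t, '"^^<', XSD_BOOLEAN, ">"))
  }
  if (is_pname_tok(t)) return(expand_pname(t, prefixes))
  cur$i <- cur$i - 1L
  cur_fail(cur, sprintf("expected an RDF term, found '%s'", t))
}

## triples block:  subject (pred objList (';' pred objList)*) '.'
## rows appended to acc (an environment holding s/p/o vectors)
parse_triples_stmt <- function(cur, prefixes, acc, terminator = ".") {
  s <- parse_term(cur, prefixes)
  if (!is_iri(s)) cur_fail(cur, "subject must be an IRI")
  repeat {
    p <- parse_term(cur, prefixes)
    if (!is_iri(p)) cur_fail(cur, "predicate must be an IRI")
    repeat {
      o <- parse_term(cur, prefixes)
      acc$s <- c(acc$s, s)
      acc$p <- c(acc$p, p)
      acc$o <- c(acc$o, o)
      if (identical(cur_peek(cur), ",")) cur_next(cur) else break
    }
    if (identical(cur_peek(cur), ";")) {
      cur_next(cur)
      # tolerate trailing ';' before terminator
      if (identical(cur_peek(cur), terminator) || identical(cur_peek(cur), "}")) break
    } else {
      break
    }
  }
}

#' Parse TriG or Turtle text
#'
#' Parses the Turtle-family fragment used for named-graph cube data and
#' for summary/policy documents: prefix declarations, graph blocks
#' (`<name> { ... }`, optionally introduced by `GRAPH`), predicate lists
#' (`;`), object lists (`,`), `a`, numeric/boolean shorthand literals,
#' language tags and datatypes. Blank nodes are rejected. Triples outside
#' a graph block are rejected unless `allow_default_graph = TRUE`
#' (Turtle mode, used for summary and policy documents).
#'
#' @param text Character scalar with the document text.
#' @param allow_default_graph Accept plain Turtle triples outside graph
#'   blocks (recorded with `graph = NA`).
#' @param what Label used in error messages (e.g. a file name).
#' @return A list with `quads` (a data.table with columns `graph`, `s`,
#'   `p`, `o`; encoded terms) and `prefixes` (named character vector).
#' @export
parse_trig <- function(text, allow_default_graph = FALSE, what = "TriG") {
  cur <- new_cursor(tokenize(text, what), what)
  prefixes <- DEFAULT_PREFIXES[0]
  graph <- character(0)
  s <- character(0); p <- character(0); o <- character(0)

  while (!is.na(cur_peek(cur))) {
    t <- cur_peek(cur)
    if (identical(t, "@prefix") || identical(toupper(t), "PREFIX")) {
      had_at <- identical(t, "@prefix")
      cur_next(cur)
      ns_tok <- cur_next(cur)
      if (!is_pname_tok(ns_tok) || !endsWith(ns_tok, ":")) {
        cur$i <- cur$i - 1L
        cur_fail(cur, "expected 'prefix:' in prefix declaration")
      }
      iri_tok <- cur_next(cur)
      if (!is_iriref_tok(iri_tok)) cur_fail(cur, "expected IRI in prefix declaration")
      pfx <- substr(ns_tok, 1L, nchar(ns_tok) - 1L)
      prefixes[pfx] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (had_at) cur_expect(cur, ".")
      next
    }
    if (identical(toupper(t), "GRAPH")) cur_next(cur)
    # graph block?  term '{' ... '}'
    save <- cur$i
    term1 <- tryCatch(parse_term(cur, prefixes), error = function(e) {
      stop(e)
    })
    if (identical(cur_peek(cur), "{")) {
      if (!is_iri(term1)) cur_fail(cur, "graph name must be an IRI")
      cur_next(cur)
      acc <- new.env(parent = emptyenv())
      acc$s <- character(0); acc$p <- character(0); acc$o <- character(0)
      while (!identical(cur_peek(cur), "}")) {
        if (is.na(cur_peek(cur))) cur_fail(cur, "unterminated graph block")
        parse_triples_stmt(cur, prefixes, acc)
        nxt <- cur_peek(cur)
        if (identical(nxt, ".")) cur_next(cur)
        else if (!identical(nxt, "}")) cur_fail(cur, "expected '.' or '}' in graph block")
      }
      cur_expect(cur, "}")
      if (identical(cur_peek(cur), ".")) cur_next(cur)
      n <- length(acc$s)
      graph <- c(graph, rep(term1, n))
      s <- c(s, acc$s); p <- c(p, acc$p); o <- c(o, acc$o)
    } else {
      # default-graph triples
      if (!allow_default_graph) {
        cur$i <- save
        cur_fail(cur, "triples outside a named graph block (no default graph is considered)")
      }
      cur$i <- save
      acc <- new.env(parent = emptyenv())
      acc$s <- character(0); acc$p <- character(0); acc$o <- character(0)
      parse_triples_stmt(cur, prefixes, acc)
      cur_expect(cur, ".")
      n <- length(acc$s)
      graph <- c(graph, rep(NA_character_, n))
      s <- c(s, acc$s); p <- c(p, acc$p); o <- c(o, acc$o)
    }
  }
  quads <- data.table::data.table(graph = graph, s = s, p = p, o = o)
  list(quads = unique(quads), prefixes = prefixes)
}

#' Parse N-Quads text
#'
#' Line-oriented parser; every statement must carry a graph label
#' (triples in the default graph are an error) and blank nodes are
#' rejected.
#'
#' @inheritParams parse_trig
#' @return Same shape as [parse_trig()].
#' @export
parse_nquads <- function(text, what = "N-Quads") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  graph <- character(0); s <- character(0); p <- character(0); o <- character(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line) || startsWith(line, "#")) next
    lab <- sprintf("%s line %d", what, k)
    cur <- new_cursor(tokenize(line, lab), lab)
    terms <- character(0)
    while (!is.na(cur_peek(cur)) && !identical(cur_peek(cur), ".")) {
      terms <- c(terms, parse_term(cur, DEFAULT_PREFIXES[0]))
    }
    cur_expect(cur, ".")
    if (!is.na(cur_peek(cur))) cur_fail(cur, "trailing tokens after '.'")
    if (length(terms) == 3L) {
      stop(lab, ": statement has no graph label (no default graph is considered)")
    }
    if (length(terms) != 4L) stop(lab, ": expected 4 terms, found ", length(terms))
    if (!is_iri(terms[4])) stop(lab, ": graph label must be an IRI")
    s <- c(s, terms[1]); p <- c(p, terms[2]); o <- c(o, terms[3])
    graph <- c(graph, terms[4])
  }
  quads <- data.table::data.table(graph = graph, s = s, p = p, o = o)
  list(quads = unique(quads), prefixes = character(0))
}

## serialise one encoded term to Turtle using a prefix map
format_term <- function(term, prefixes) {
  if (is_iri(term)) return(compact_iri(term, prefixes))
  if (is_literal(term)) {
    f <- term_fields(term)
    if (!is.null(f$datatype) && f$datatype == XSD_INTEGER &&
        grepl("^[+-]?[0-9]+$", f$value)) {
      return(f$value)
    }
    if (!is.null(f$datatype)) {
      return(paste0('"', escape_string(f$value), '"^^',
                    compact_iri(paste0("<", f$datatype, ">"), prefixes)))
    }
    if (!is.null(f$lang)) return(paste0('"', escape_string(f$value), '"@', f$lang))
    return(paste0('"', escape_string(f$value), '"'))
  }
  term  # variable
}

#' Serialise quads to TriG
#'
#' Deterministic output: graphs and triples are emitted in radix-sorted
#' order, so identical quad sets always yield byte-identical documents.
#'
#' @param quads data.table with columns `graph`, `s`, `p`, `o` (encoded
#'   terms); `graph` must be non-NA throughout.
#' @param prefixes Named character vector of prefix -> namespace.
#' @return Character scalar with the TriG document.
#' @export
write_trig <- function(quads, prefixes = DEFAULT_PREFIXES) {
  stopifnot(!anyNA(quads$graph))
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  ord <- order(quads$graph, quads$s, quads$p, quads$o, method = "radix")
  quads <- quads[ord, ]
  out <- header
  for (g in unique(quads$graph)) {
    gi <- quads[quads$graph == g, ]
    out <- c(out, "", paste0(format_term(g, prefixes), " {"))
    out <- c(out, sprintf("  %s %s %s .",
                          vapply(gi$s, format_term, "", prefixes = prefixes),
                          vapply(gi$p, format_term, "", prefixes = prefixes),
                          vapply(gi$o, format_term, "", prefixes = prefixes)))
    out <- c(out, "}")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

## Turtle (default graph) writer used for summaries and policies
write_turtle <- function(triples, prefixes = DEFAULT_PREFIXES) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  ord <- order(triples$s, triples$p, triples$o, method = "radix")
  triples <- triples[ord, ]
  body <- sprintf("%s %s %s .",
                  vapply(triples$s, format_term, "", prefixes = prefixes),
                  vapply(triples$p, format_term, "", prefixes = prefixes),
                  vapply(triples$o, format_term, "", prefixes = prefixes))
  paste0(paste(c(header, "", body), collapse = "\n"), "\n")
}
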