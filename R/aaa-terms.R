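## RDF terms are stored in an N-Triples-like lexical encoding:
##   IRI       "<http://...>"
##   literal   "\"lex\"", "\"lex\"@en", "\"lex\"^^<datatype>"
##   variable  "?name"          (query structures only, never stored data)
## Blank nodes are not representable: the engine's completeness argument
## assumes their absence, so loaders reject them outright.

.datatable.aware <- TRUE

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
QB_NS <- "http://purl.org/linked-data/cube#"

## Illustrative namespaces for the clinical running example (the Semantic
## EHR Model "sehr" terms and the access-policy "lmds" terms).
SEHR_NS <- "http://example.org/sehr#"
LMDS_NS <- "http://example.org/lmds#"
EX_NS <- "http://example.org/l2s#"

DEFAULT_PREFIXES <- stats::setNames(
  c(RDF_NS, XSD, QB_NS, SEHR_NS, LMDS_NS, EX_NS),
  c("rdf", "xsd", "qb", "sehr", "lmds", "")
)

RDF_TYPE <- paste0("<", RDF_NS, "type>")
QB_DATASET_CLASS <- paste0("<", QB_NS, "DataSet>")
QB_OBSERVATION_CLASS <- paste0("<", QB_NS, "Observation>")
QB_DATASET_PRED <- paste0("<", QB_NS, "dataSet>")
XSD_INTEGER <- paste0(XSD, "integer")
XSD_DECIMAL <- paste0(XSD, "decimal")
XSD_DOUBLE <- paste0(XSD, "double")
XSD_BOOLEAN <- paste0(XSD, "boolean")

#' Construct an IRI term
#'
#' Terms in cubefed are plain character strings in an N-Triples-like
#' encoding; `iri()`, `lit()` and `sparql_var()` build the three kinds.
#' Blank nodes are deliberately unrepresentable.
#'
#' @param x IRI string (without angle brackets).
#' @return Encoded term string.
#' @export
#' @examples
#' iri("http://example.org/g1")
iri <- function(x) {
  stopifnot(is.character(x))
  paste0("<", x, ">")
}

#' Construct a literal term
#'
#' @param value Lexical form (coerced to character).
#' @param datatype Optional datatype IRI (without brackets).
#' @param lang Optional language tag (mutually exclusive with `datatype`).
#' @return Encoded term string.
#' @export
lit <- function(value, datatype = NULL, lang = NULL) {
  if (!is.null(datatype) && !is.null(lang)) {
    stop("a literal cannot carry both a datatype and a language tag")
  }
  lex <- escape_string(as.character(value))
  out <- paste0('"', lex, '"')
  if (!is.null(lang)) out <- paste0(out, "@", lang)
  if (!is.null(datatype)) out <- paste0(out, "^^<", datatype, ">")
  out
}

#' Construct a typed integer literal
#' @param x Integer scalar or vector.
#' @return Encoded term string(s).
#' @export
int_lit <- function(x) lit_vec(as.character(as.integer(x)), XSD_INTEGER)

## vectorised typed-literal builder (no escaping; callers pass clean lexes)
lit_vec <- function(lex, datatype) paste0('"', lex, '"^^<', datatype, ">")

#' Construct a SPARQL variable term
#' @param name Variable name, without the leading `?`.
#' @return Encoded term string.
#' @export
sparql_var <- function(name) paste0("?", name)

#' @rdname iri
#' @param term Encoded term string.
#' @export
is_iri <- function(term) startsWith(term, "<")

#' @rdname iri
#' @export
is_literal <- function(term) startsWith(term, "\"")

#' @rdname iri
#' @export
is_variable <- function(term) startsWith(term, "?")

#' Decompose an encoded term
#'
#' @param term Encoded term string.
#' @return A list with `kind` (one of `"iri"`, `"literal"`, `"variable"`),
#'   `value` (IRI / lexical form / variable name), and for literals the
#'   optional `datatype` and `lang`.
#' @export
term_fields <- function(term) {
  if (is_iri(term)) {
    return(list(kind = "iri", value = substr(term, 2L, nchar(term) - 1L)))
  }
  if (is_variable(term)) {
    return(list(kind = "variable", value = substring(term, 2L)))
  }
  if (is_literal(term)) {
    # find closing quote of the lexical form (escapes handled)
    m <- regexpr('^"(\\\\.|[^"\\\\])*"', term)
    if (m == -1L) stop("malformed literal term: ", term)
    end <- attr(m, "match.length")
    lex <- unescape_string(substr(term, 2L, end - 1L))
    rest <- substring(term, end + 1L)
    dt <- NULL
    lang <- NULL
    if (startsWith(rest, "^^<")) {
      dt <- substr(rest, 4L, nchar(rest) - 1L)
    } else if (startsWith(rest, "@")) {
      lang <- substring(rest, 2L)
    } else if (nzchar(rest)) {
      stop("malformed literal term: ", term)
    }
    return(list(kind = "literal", value = lex, datatype = dt, lang = lang))
  }
  stop("unrecognised term encoding: ", term)
}

## numeric value of a literal term, NA if not numeric
term_numeric <- function(term) {
  if (!is_literal(term)) return(NA_real_)
  f <- term_fields(term)
  if (!is.null(f$datatype) &&
      f$datatype %in% c(XSD_INTEGER, XSD_DECIMAL, XSD_DOUBLE)) {
    return(suppressWarnings(as.numeric(f$value)))
  }
  suppressWarnings(as.numeric(f$value))
}

escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_string <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "\\" && i < n) {
      nxt <- chars[i + 1L]
      out <- c(out, switch(nxt,
        "n" = "\n", "r" = "\r", "t" = "\t",
        "\\" = "\\", '"' = '"', nxt
      ))
      i <- i + 2L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

## Expand a prefixed name given a prefix map (named character vector).
expand_pname <- function(pname, prefixes) {
  colon <- regexpr(":", pname, fixed = TRUE)
  pfx <- substr(pname, 1L, colon - 1L)
  local <- substring(pname, colon + 1L)
  hit <- match(pfx, names(prefixes))   # [[ cannot index the empty name
  if (is.na(hit)) {
    stop("undefined prefix '", pfx, ":' in ", pname)
  }
  paste0("<", unname(prefixes[hit]), local, ">")
}

## Compact an IRI term against a prefix map; fall back to full form.
compact_iri <- function(term, prefixes) {
  if (!is_iri(term)) return(term)
  value <- substr(term, 2L, nchar(term) - 1L)
  for (k in seq_along(prefixes)) {
    pfx <- names(prefixes)[k]
    ns <- unname(prefixes[k])
    if (startsWith(value, ns)) {
      local <- substring(value, nchar(ns) + 1L)
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, ".")) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  term
}

## Sort key for ORDER BY: numeric literals sort numerically, everything
## else lexically by encoded form.
term_sort_key <- function(terms) {
  num <- vapply(terms, function(t) {
    if (is.na(t) || !is_literal(t)) NA_real_ else term_numeric(t)
  }, numeric(1))
  list(num = num, lex = ifelse(is.na(terms), "", terms))
}
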