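## Solution mappings are data.tables with one character column per query
## variable plus a constant unit column `.u`. Joining two mapping tables
## on the intersection of their columns (which always contains `.u`)
## yields the SPARQL natural join: shared variables must agree, disjoint
## variable sets degenerate to the cross product. Bag (multiset)
## semantics throughout; DISTINCT collapses at projection time.

empty_bindings <- function(vars = character(0)) {
  cols <- c(list(.u = integer(0)),
            stats::setNames(rep(list(character(0)), length(vars)), vars))
  data.table::as.data.table(cols)
}

unit_bindings <- function(n = 1L) {
  data.table::data.table(.u = rep(1L, n))
}

as_bindings <- function(rows, vars) {
  if (!length(rows)) return(empty_bindings(vars))
  m <- do.call(rbind, rows)
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, vars)
  dt[, ".u" := 1L]
  dt
}

## Match one triple pattern against a quad (or triple) table.
## Returns a bindings table over the pattern's variables.
match_pattern <- function(quads, pattern) {
  keep <- rep(TRUE, nrow(quads))
  for (pos in c("s", "p", "o")) {
    t <- pattern[[pos]]
    if (!is_variable(t)) keep <- keep & quads[[pos]] == t
  }
  hit <- quads[keep, ]
  vars <- character(0)
  cols <- list()
  for (pos in c("s", "p", "o")) {
    t <- pattern[[pos]]
    if (is_variable(t)) {
      v <- substring(t, 2L)
      if (v %in% vars) {
        # repeated variable within one pattern: positions must agree
        prev_pos <- c("s", "p", "o")[match(paste0("?", v),
          c(pattern$s, pattern$p, pattern$o))]
        sel <- hit[[prev_pos]] == hit[[pos]]
        hit <- hit[sel, ]
        cols <- lapply(cols, function(x) x[sel])
      } else {
        vars <- c(vars, v)
        cols[[v]] <- hit[[pos]]
      }
    }
  }
  if (!length(vars)) return(unit_bindings(nrow(hit)))
  dt <- data.table::as.data.table(cols)
  dt[, ".u" := 1L]
  dt
}

## Natural join of two bindings tables (inner).
join_bindings <- function(a, b) {
  shared <- intersect(names(a), names(b))
  merge(a, b, by = shared, allow.cartesian = TRUE, sort = FALSE)
}

## Left (OPTIONAL) join: keep all rows of a, extend where b matches.
leftjoin_bindings <- function(a, b) {
  shared <- intersect(names(a), names(b))
  merge(a, b, by = shared, all.x = TRUE, allow.cartesian = TRUE, sort = FALSE)
}

## Union of bindings tables (bag union; missing variables stay NA).
rbind_bindings <- function(parts) {
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) return(unit_bindings(0L))
  data.table::rbindlist(parts, fill = TRUE)
}

## Join a list of triple patterns within one triple table. Patterns are
## taken in query order except that a pattern sharing a variable with
## the bindings accumulated so far is always preferred over one that
## does not (avoiding needless cross products; the result multiset is
## unaffected since joins commute).
match_bgp <- function(quads, patterns) {
  out <- unit_bindings(1L)
  remaining <- patterns
  bound <- character(0)
  while (length(remaining)) {
    pick <- 1L
    if (length(bound)) {
      for (k in seq_along(remaining)) {
        tp <- remaining[[k]]
        if (length(intersect(pattern_vars(list(tp)), bound))) {
          pick <- k
          break
        }
      }
    }
    tp <- remaining[[pick]]
    remaining <- remaining[-pick]
    bound <- union(bound, pattern_vars(list(tp)))
    out <- join_bindings(out, match_pattern(quads, tp))
    if (nrow(out) == 0L && !length(remaining)) break
  }
  out
}
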