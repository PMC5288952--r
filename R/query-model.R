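## Subject groups: the unit of join-aware selection. All triple patterns
## of a BGP sharing one subject term (exact term equality -- two distinct
## variables never merge) form a group; the group's bound predicates
## drive dataset candidacy and unique-predicate graph pinning.

#' Group a BGP's triple patterns by subject
#'
#' @param bgp A BGP from a [parse_query()] plan (list with `patterns`).
#' @return List of subject groups in order of first appearance, each a
#'   list with `subject` (encoded term), `patterns` (the group's triple
#'   patterns, query order) and `bound_preds` (predicate IRIs of the
#'   group's predicate-bound patterns).
#' @export
group_by_subject <- function(bgp) {
  patterns <- bgp$patterns
  stopifnot(length(patterns) > 0L)
  subjects <- vapply(patterns, function(tp) tp$s, "")
  keys <- unique(subjects)
  lapply(keys, function(k) {
    members <- patterns[subjects == k]
    preds <- vapply(members, function(tp) tp$p, "")
    list(
      subject = k,
      patterns = members,
      bound_preds = unique(preds[!startsWith(preds, "?")])
    )
  })
}

## variables mentioned by a list of patterns
pattern_vars <- function(patterns) {
  terms <- unlist(lapply(patterns, function(tp) c(tp$s, tp$p, tp$o)))
  unique(substring(terms[startsWith(terms, "?")], 2L))
}

## one-line rendering of a triple pattern (diagnostics, CLI tables)
format_pattern <- function(tp, prefixes = DEFAULT_PREFIXES) {
  paste(vapply(c(tp$s, tp$p, tp$o), function(t) {
    if (is_iri(t)) compact_iri(t, prefixes) else format_term(t, prefixes)
  }, ""), collapse = " ")
}

## dump a plan as a plain list (CLI --explain)
plan_to_list <- function(plan) {
  list(
    vars = plan$vars,
    distinct = plan$distinct,
    n_filters = length(plan$filters),
    order_by = lapply(plan$order_by, function(o) list(var = o$var, desc = o$desc)),
    limit = plan$limit,
    bgps = lapply(plan$bgps, function(bgp) {
      list(
        role = bgp$role,
        union_block = if (is.na(bgp$union_block %||% NA)) NULL else bgp$union_block,
        patterns = vapply(bgp$patterns, format_pattern, "")
      )
    })
  )
}
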