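## Federation data model: a federation is a set of datasets; each dataset
## is a set of named graphs (one RDF data cube per graph) published at an
## endpoint location. No default graph exists anywhere; graph names are
## globally unique; the engine's locality assumption (a subject IRI lives
## in at most one named graph federation-wide) is checkable on load.

#' Construct a dataset
#'
#' @param id Dataset label (e.g. `"CHUV"`).
#' @param location Endpoint URL of the dataset.
#' @param quads data.table of encoded terms with columns `graph`, `s`,
#'   `p`, `o` (in-memory mode) or `NULL` (remote mode).
#' @param remote `TRUE` for a dataset known only through its endpoint.
#' @return A `cubefed_dataset` object.
#' @export
dataset <- function(id, location, quads = NULL, remote = is.null(quads)) {
  if (!remote) {
    stopifnot(data.table::is.data.table(quads),
              all(c("graph", "s", "p", "o") %in% names(quads)))
    if (anyNA(quads$graph)) stop("dataset '", id, "': triples without a named graph")
  }
  structure(
    list(id = id, location = location, quads = quads, remote = remote),
    class = "cubefed_dataset"
  )
}

#' Graph names of a dataset
#' @param ds A `cubefed_dataset`.
#' @return Character vector of graph IRIs (encoded), sorted.
#' @export
graph_names <- function(ds) {
  stopifnot(inherits(ds, "cubefed_dataset"))
  if (ds$remote) stop("graph_names requires an in-memory dataset")
  sort(unique(ds$quads$graph), method = "radix")
}

#' Extract one named graph
#' @param ds A `cubefed_dataset`.
#' @param name Encoded graph IRI.
#' @return data.table with columns `s`, `p`, `o`.
#' @export
named_graph <- function(ds, name) {
  stopifnot(inherits(ds, "cubefed_dataset"))
  ds$quads[ds$quads$graph == name, c("s", "p", "o")]
}

#' Construct a federation
#'
#' Validates that graph names are pairwise distinct within each dataset's
#' quads (structural) and globally unique across datasets.
#'
#' @param datasets List of `cubefed_dataset` objects.
#' @return A `cubefed_federation` object.
#' @export
federation <- function(datasets) {
  ids <- vapply(datasets, function(d) d$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate dataset id: ", ids[duplicated(ids)][1])
  }
  names(datasets) <- ids
  all_graphs <- unlist(lapply(datasets, function(d) {
    if (d$remote) character(0) else unique(d$quads$graph)
  }))
  if (anyDuplicated(all_graphs)) {
    stop("graph name occurs in more than one dataset: ",
         all_graphs[duplicated(all_graphs)][1])
  }
  structure(list(datasets = datasets), class = "cubefed_federation")
}

#' @export
print.cubefed_federation <- function(x, ...) {
  cat("<cubefed federation>", length(x$datasets), "dataset(s)\n")
  for (d in x$datasets) {
    if (d$remote) {
      cat(sprintf("  %s @ %s (remote)\n", d$id, d$location))
    } else {
      cat(sprintf("  %s @ %s: %d graph(s), %d quad(s)\n", d$id, d$location,
                  length(unique(d$quads$graph)), nrow(d$quads)))
    }
  }
  invisible(x)
}

#' Load a federation from a config file or list
#'
#' The config (YAML or JSON file, or an equivalent list) holds a
#' `datasets` entry: a list of `{id, location, files}` for in-memory
#' datasets (TriG or N-Quads, chosen by file extension) or
#' `{id, endpoint}` for remote ones. File paths are resolved relative to
#' the config file's directory.
#'
#' @param config Path to a YAML/JSON config file, or a list already in
#'   config shape.
#' @return A `cubefed_federation`.
#' @export
load_federation <- function(config) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$datasets)) stop("federation config has no 'datasets' entry")
  datasets <- lapply(config$datasets, function(entry) {
    if (is.null(entry$id)) stop("federation config: dataset entry without an id")
    if (!is.null(entry$endpoint)) {
      return(dataset(entry$id, entry$endpoint, quads = NULL, remote = TRUE))
    }
    if (is.null(entry$location)) stop("dataset '", entry$id, "' has no location")
    files <- unlist(entry$files)
    quads <- data.table::rbindlist(lapply(files, function(f) {
      path <- if (file.exists(f)) f else file.path(base_dir, f)
      if (!file.exists(path)) stop("dataset '", entry$id, "': file not found: ", f)
      text <- paste(readLines(path, warn = FALSE), collapse = "\n")
      ext <- tolower(tools::file_ext(path))
      parsed <- if (ext %in% c("nq", "nquads")) {
        parse_nquads(text, what = f)
      } else {
        parse_trig(text, allow_default_graph = FALSE, what = f)
      }
      parsed$quads
    }))
    if (nrow(quads) == 0L) {
      quads <- data.table::data.table(graph = character(0), s = character(0),
                                      p = character(0), o = character(0))
    }
    dataset(entry$id, entry$location, unique(quads))
  })
  federation(datasets)
}

#' Check the subject-locality assumption
#'
#' The selection algorithm is correct only if every subject IRI occurs in
#' at most one named graph across the whole federation (data cubes are
#' self-contained). Returns one violation record per offending subject.
#'
#' @param fed A `cubefed_federation` (in-memory).
#' @return data.frame with columns `subject` and `graphs`
#'   (comma-separated encoded graph IRIs); zero rows iff locality holds.
#' @export
validate_locality <- function(fed) {
  stopifnot(inherits(fed, "cubefed_federation"))
  if (any(vapply(fed$datasets, function(d) d$remote, TRUE))) {
    stop("validate_locality requires an in-memory federation (full data access)")
  }
  sg <- data.table::rbindlist(lapply(fed$datasets, function(d) {
    unique(d$quads[, c("s", "graph")])
  }))
  if (nrow(sg) == 0L) {
    return(data.frame(subject = character(0), graphs = character(0),
                      stringsAsFactors = FALSE))
  }
  sg <- unique(sg)
  counts <- table(sg$s)
  bad <- names(counts)[counts > 1L]
  if (!length(bad)) {
    return(data.frame(subject = character(0), graphs = character(0),
                      stringsAsFactors = FALSE))
  }
  bad <- sort(bad, method = "radix")
  graphs <- vapply(bad, function(su) {
    paste(sort(sg$graph[sg$s == su], method = "radix"), collapse = ",")
  }, "")
  data.frame(subject = bad, graphs = unname(graphs), stringsAsFactors = FALSE)
}

#' Merge all datasets into one quad table
#'
#' Used by the brute-force oracle ([evaluate_merged()]): the global
#' dataset obtained by merging every named graph of every dataset.
#'
#' @param fed A `cubefed_federation` (in-memory).
#' @param graphs Optional character vector of encoded graph IRIs to
#'   restrict the merge to (e.g. the graphs a user may read).
#' @return data.table with columns `graph`, `s`, `p`, `o`.
#' @export
merged_quads <- function(fed, graphs = NULL) {
  stopifnot(inherits(fed, "cubefed_federation"))
  if (any(vapply(fed$datasets, function(d) d$remote, TRUE))) {
    stop("merged_quads requires an in-memory federation")
  }
  out <- data.table::rbindlist(lapply(fed$datasets, function(d) d$quads))
  if (nrow(out) == 0L) {
    out <- data.table::data.table(graph = character(0), s = character(0),
                                  p = character(0), o = character(0))
  }
  if (!is.null(graphs)) out <- out[out$graph %in% graphs, ]
  out
}

#' Serialise an in-memory federation to TriG
#'
#' One TriG document per dataset, written as `<id>.trig` in `dir`,
#' plus a `federation.yaml` config referencing them.
#'
#' @param fed A `cubefed_federation`.
#' @param dir Output directory (created if needed).
#' @param prefixes Prefix map for compaction.
#' @return Invisibly, the path of the written config file.
#' @export
write_federation <- function(fed, dir, prefixes = DEFAULT_PREFIXES) {
  stopifnot(inherits(fed, "cubefed_federation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(fed$datasets, function(d) {
    if (d$remote) return(list(id = d$id, endpoint = d$location))
    file <- paste0(d$id, ".trig")
    writeLines(write_trig(d$quads, prefixes), file.path(dir, file), sep = "")
    list(id = d$id, location = d$location, files = list(file))
  })
  cfg <- file.path(dir, "federation.yaml")
  yaml::write_yaml(list(datasets = unname(entries)), cfg)
  invisible(cfg)
}
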