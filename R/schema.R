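# Hierarchical vocabulary (schema) handling: loading, indexing, merging,
# short-form -> long-form resolution and is-a (descendant) tests.

# Structural tags open/close/subdivide event processes or introduce
# definitions; they never accept extension children (users must not invent
# specializations of the timeline machinery itself).
.structural_terms <- c("onset", "offset", "inset", "def", "definition",
                       "duration")

.valid_term <- function(term) {
  is.character(term) && length(term) == 1L && !is.na(term) &&
    nzchar(term) && !grepl("[/,()]", term)
}

#' Load a hierarchical tag vocabulary
#'
#' Reads a schema document describing a tree (forest) of annotation terms.
#' Each term is a single path component; a node's long form is its parent's
#' long form followed by `/` and its own term. Terms must be unique across
#' the whole vocabulary (case-insensitively), which is what makes short-form
#' annotation and is-a search unambiguous.
#'
#' The document is UTF-8 JSON of the form
#' `{"version": "...", "nodes": [{"term", "parent", "extension_allowed",
#' "takes_value", "unit_class"}, ...]}` where `parent` is a long-form path
#' or `null` for roots. `takes_value = true` marks a leaf that carries a
#' `/`-suffixed value (e.g. `Duration/0.5 s`, `Label/X`); `unit_class`
#' `"time"` makes that value a number with an optional time unit.
#' Structural terms (Onset, Offset, Inset, Def, Definition, Duration) never
#' allow extension regardless of the document.
#'
#' @param source path to a JSON schema document, a JSON string, or an
#'   already-parsed list with elements `version` and `nodes`.
#' @return an object of class `hed_schema` with the term index and node
#'   attribute table.
#' @examples
#' sch <- load_schema(generate_mini_schema())
#' long_form("Ingestible-object", sch)
#' @export
load_schema <- function(source) {
  doc <- if (is.list(source)) source else jsonlite::fromJSON(source,
                                                             simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$nodes) || length(doc$nodes) == 0L)
    stop("schema document is empty or has no 'nodes' entry")
  version <- if (is.null(doc$version)) "0.0.0" else as.character(doc$version)

  nodes <- list()   # keyed by tolower(long form)
  index <- character(0)  # tolower(term) -> canonical long form
  pending <- doc$nodes

  place <- function(nd, long, parent_long) {
    key <- tolower(long)
    tkey <- tolower(nd$term)
    if (tkey %in% names(index))
      stop(sprintf("duplicate schema term '%s' (already at '%s')",
                   nd$term, index[[tkey]]))
    ext <- if (is.null(nd$extension_allowed)) TRUE else isTRUE(nd$extension_allowed)
    if (tkey %in% .structural_terms) ext <- FALSE
    tv <- isTRUE(nd$takes_value)
    nodes[[key]] <<- list(
      term = nd$term, parent = parent_long, long = long,
      extension_allowed = ext, takes_value = tv,
      unit_class = if (is.null(nd$unit_class)) NA_character_ else nd$unit_class,
      children = character(0))
    index[[tkey]] <<- long
    if (!is.null(parent_long)) {
      pkey <- tolower(parent_long)
      nodes[[pkey]]$children <<- c(nodes[[pkey]]$children, long)
    }
  }

  repeat {
    progressed <- FALSE
    still <- list()
    for (nd in pending) {
      if (!.valid_term(nd$term %||% ""))
        stop("malformed schema node: missing or invalid 'term'")
      parent <- nd$parent
      if (is.null(parent) || (length(parent) == 1L && (is.na(parent) || !nzchar(parent)))) {
        place(nd, nd$term, NULL)
        progressed <- TRUE
      } else {
        pkey <- tolower(as.character(parent))
        if (pkey %in% names(nodes)) {
          pl <- nodes[[pkey]]$long
          if (nodes[[pkey]]$takes_value)
            stop(sprintf("value-taking node '%s' cannot have children", pl))
          place(nd, paste(pl, nd$term, sep = "/"), pl)
          progressed <- TRUE
        } else {
          still <- c(still, list(nd))
        }
      }
    }
    pending <- still
    if (length(pending) == 0L) break
    if (!progressed)
      stop(sprintf("schema has unknown parents or a cycle involving: %s",
                   paste(vapply(pending, function(n) n$term, ""), collapse = ", ")))
  }

  roots <- vapply(nodes[vapply(nodes, function(n) is.null(n$parent), TRUE)],
                  function(n) n$long, "")
  structure(list(version = version, nodes = nodes, index = index,
                 roots = unname(roots)),
            class = "hed_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hed_schema <- function(x, ...) {
  cat(sprintf("hed_schema version %s: %d terms, %d roots (%s)\n",
              x$version, length(x$index), length(x$roots),
              paste(utils::head(x$roots, 6), collapse = ", ")))
  invisible(x)
}

schema_node <- function(schema, long) schema$nodes[[tolower(long)]]

#' Merge a library vocabulary into a base schema
#'
#' Attaches every root of `lib` as a child of the node `attach_at` in
#' `base`, so that library terms participate in short-form resolution and
#' is-a search exactly like native terms. All library terms must be new
#' (term uniqueness holds across the merged vocabulary).
#'
#' @param base,lib `hed_schema` objects.
#' @param attach_at long-form path in `base` under which `lib`'s roots are
#'   placed.
#' @return the merged `hed_schema`.
#' @export
merge_library <- function(base, lib, attach_at) {
  stopifnot(inherits(base, "hed_schema"), inherits(lib, "hed_schema"))
  akey <- tolower(attach_at)
  if (!akey %in% names(base$nodes))
    stop(sprintf("attach point '%s' is not in the base schema", attach_at))
  at_long <- base$nodes[[akey]]$long
  if (base$nodes[[akey]]$takes_value)
    stop(sprintf("cannot attach a library under value-taking node '%s'", at_long))
  clash <- intersect(names(lib$index), names(base$index))
  if (length(clash))
    stop(sprintf("library terms already present in base schema: %s",
                 paste(clash, collapse = ", ")))
  merged <- base
  for (key in names(lib$nodes)) {
    nd <- lib$nodes[[key]]
    long <- paste(at_long, nd$long, sep = "/")
    parent <- if (is.null(nd$parent)) at_long else paste(at_long, nd$parent, sep = "/")
    nd$long <- long
    nd$parent <- parent
    nd$children <- if (length(nd$children))
      paste(at_long, nd$children, sep = "/") else character(0)
    merged$nodes[[tolower(long)]] <- nd
    merged$index[[tolower(nd$term)]] <- long
  }
  lib_roots <- paste(at_long, lib$roots, sep = "/")
  merged$nodes[[akey]]$children <- c(merged$nodes[[akey]]$children, lib_roots)
  merged
}

# Core resolver: walk a `/`-separated tag path into the schema.
# Returns list(node_long, node, value, extension, long) where `long` is the
# full long-form path including any extension components (but not the value).
resolve_path <- function(tag_path, schema) {
  stopifnot(inherits(schema, "hed_schema"))
  txt <- trimws(tag_path)
  if (!nzchar(txt)) stop("empty tag")
  comps <- strsplit(txt, "/", fixed = TRUE)[[1]]
  if (length(comps) == 0L || !nzchar(trimws(comps[1])))
    stop(sprintf("malformed tag '%s'", tag_path))
  comps <- trimws(comps)
  first <- tolower(comps[1])
  if (!first %in% names(schema$index))
    stop(sprintf("tag '%s': unknown term '%s'", tag_path, comps[1]))
  long <- schema$index[[first]]
  node <- schema_node(schema, long)
  i <- 2L
  while (i <= length(comps) && !node$takes_value) {
    kids <- node$children
    hit <- kids[tolower(basename_term(kids)) == tolower(comps[i])]
    if (length(hit) == 1L) {
      long <- hit
      node <- schema_node(schema, long)
      i <- i + 1L
    } else break
  }
  rest <- if (i <= length(comps)) comps[i:length(comps)] else character(0)
  value <- NULL
  extension <- NULL
  if (length(rest)) {
    if (node$takes_value) {
      value <- paste(rest, collapse = "/")
      if (!nzchar(value)) stop(sprintf("tag '%s': empty value", tag_path))
    } else if (node$extension_allowed) {
      if (any(!nzchar(rest)))
        stop(sprintf("tag '%s': empty extension component", tag_path))
      extension <- rest
      long <- paste(c(long, rest), collapse = "/")
    } else {
      stop(sprintf(
        "tag '%s': '%s' takes no value and does not allow extension",
        tag_path, node$term))
    }
  }
  list(node_long = node$long, node = node, value = value,
       extension = extension, long = long)
}

basename_term <- function(paths) {
  vapply(strsplit(paths, "/", fixed = TRUE),
         function(p) p[length(p)], "")
}

#' Resolve a tag path to its long form
#'
#' Expands a (possibly short-form) tag path to the full path from its root,
#' normalizing the case of schema components to their canonical spelling.
#' Trailing components not found in the schema are kept verbatim: as a value
#' when the deepest schema node takes a value, or as extension components
#' when it allows extension.
#'
#' @param tag_path tag text, e.g. `"Ingestible-object/Apple"`.
#' @param schema an `hed_schema`.
#' @return the long-form string, e.g. `"Item/Object/Ingestible-object/Apple"`.
#' @export
long_form <- function(tag_path, schema) {
  rp <- resolve_path(tag_path, schema)
  if (is.null(rp$value)) rp$long else paste(rp$long, rp$value, sep = "/")
}

#' Canonical short form of a tag path
#'
#' The short form is the deepest schema term on the path followed by any
#' extension components and value.
#'
#' @inheritParams long_form
#' @return the short-form string.
#' @export
short_form <- function(tag_path, schema) {
  rp <- resolve_path(tag_path, schema)
  out <- rp$node$term
  if (!is.null(rp$extension)) out <- paste(c(out, rp$extension), collapse = "/")
  if (!is.null(rp$value)) out <- paste(out, rp$value, sep = "/")
  out
}

#' Is-a (descendant) test between long-form paths
#'
#' `candidate` is a descendant of `ancestor` when `ancestor` equals
#' `candidate` or is a proper prefix of it at `/` component boundaries.
#' The test is reflexive and case-insensitive, and works for extension
#' components not present in any schema (an annotation `2D-shape/Star`
#' is still a `2D-shape`).
#'
#' @param candidate,ancestor long-form path strings.
#' @return logical.
#' @export
is_descendant <- function(candidate, ancestor) {
  a <- tolower(strsplit(trimws(ancestor), "/", fixed = TRUE)[[1]])
  c_ <- tolower(strsplit(trimws(candidate), "/", fixed = TRUE)[[1]])
  length(a) <= length(c_) && all(a == c_[seq_along(a)])
}
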