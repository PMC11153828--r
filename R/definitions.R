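# Named annotation templates: (Definition/Name, (content)) declares a
# reusable template; Def/Name references it. "Name/#" forms declare a
# single-placeholder family whose "#" is filled per reference (Def/Name/3).

# Split the value of a Def or Definition tag into name / value ("#" for a
# placeholder declaration).
def_parts <- function(tag) {
  v <- tag$value
  if (is.null(v) || !nzchar(v)) stop("Def/Definition tag without a name")
  comps <- strsplit(v, "/", fixed = TRUE)[[1]]
  name <- comps[1]
  rest <- if (length(comps) > 1L) paste(comps[-1], collapse = "/") else NULL
  list(name = name, value = rest)
}

new_definition <- function(name, takes_value, content) {
  structure(list(name = name, takes_value = takes_value, content = content),
            class = "hed_definition")
}

#' @export
print.hed_definition <- function(x, ...) {
  cat(sprintf("Definition/%s%s: %s\n", x$name,
              if (x$takes_value) "/#" else "", format(x$content)))
  invisible(x)
}

count_placeholders <- function(x) {
  sum(vapply(all_tags(x), function(t) {
    if (is.null(t$value)) 0L
    else lengths(regmatches(t$value, gregexpr("#", t$value, fixed = TRUE)))
  }, 0L))
}

forbidden_in_definition <- function(x) {
  bad <- c("def", "definition", "onset", "offset", "inset")
  for (t in all_tags(x)) {
    if (isTRUE(t$resolved) && tolower(basename_term(t$node_long)) %in% bad)
      return(t)
  }
  NULL
}

#' Collect Definition groups into a registry
#'
#' Scans resolved annotations for top-level groups whose first tag is
#' `Definition/...` and registers each as a named template. A name declared
#' as `Name/#` takes a value: its content must contain exactly one `#`
#' placeholder, substituted at each `Def/Name/<value>` reference. Names are
#' case-insensitive. Re-declaring a name with identical content is allowed;
#' conflicting content is an error. Definition content may not contain
#' Def, Definition, Onset, Offset, or Inset tags.
#'
#' @param strings list of resolved `hed_string` objects (a single string is
#'   accepted).
#' @param registry optionally, an existing registry to extend.
#' @return an object of class `hed_definitions` (a named registry).
#' @export
collect_definitions <- function(strings, registry = NULL) {
  if (inherits(strings, "hed_string")) strings <- list(strings)
  defs <- if (is.null(registry)) list() else registry$defs
  for (hs in strings) {
    for (it in hs$top) {
      if (!is_hed_group(it) || length(it$children) == 0L) next
      first <- it$children[[1]]
      if (!is_hed_tag(first) || !tag_is(first, "Definition")) next
      parts <- def_parts(first)
      takes_value <- identical(parts$value, "#")
      if (!is.null(parts$value) && !takes_value)
        stop(sprintf("Definition/%s: name may only be followed by '#'",
                     parts$name))
      rest <- it$children[-1]
      content <- if (length(rest) == 1L && is_hed_group(rest[[1]]))
        rest[[1]] else new_hed_group(rest)
      if (length(content$children) == 0L)
        stop(sprintf("Definition/%s has no content", parts$name))
      bad <- forbidden_in_definition(content)
      if (!is.null(bad))
        stop(sprintf("Definition/%s contains forbidden tag '%s'",
                     parts$name, format(bad)))
      nph <- count_placeholders(content)
      if (takes_value && nph != 1L)
        stop(sprintf("Definition/%s/# must contain exactly one '#' (found %d)",
                     parts$name, nph))
      if (!takes_value && nph != 0L)
        stop(sprintf("Definition/%s must not contain '#' placeholders",
                     parts$name))
      key <- tolower(parts$name)
      d <- new_definition(parts$name, takes_value, content)
      if (!is.null(defs[[key]])) {
        old <- defs[[key]]
        if (old$takes_value != takes_value ||
            !hed_equal(old$content, content))
          stop(sprintf("conflicting definitions for '%s'", parts$name))
      } else defs[[key]] <- d
    }
  }
  structure(list(defs = defs), class = "hed_definitions")
}

#' @export
print.hed_definitions <- function(x, ...) {
  cat(sprintf("hed_definitions: %d definitions (%s)\n", length(x$defs),
              paste(vapply(x$defs, function(d) d$name, ""), collapse = ", ")))
  invisible(x)
}

#' Remove Definition groups from an annotation
#'
#' Definition groups declare templates; they are not part of the event
#' content itself and are dropped once collected.
#'
#' @param hs a resolved `hed_string`.
#' @return `hs` without top-level Definition groups, or `NULL` if nothing
#'   remains.
#' @export
strip_definitions <- function(hs) {
  keep <- Filter(function(it) {
    !(is_hed_group(it) && length(it$children) > 0L &&
        is_hed_tag(it$children[[1]]) && tag_is(it$children[[1]], "Definition"))
  }, hs$top)
  if (length(keep) == 0L) return(NULL)
  new_hed_string(keep, hs$source_text)
}

substitute_placeholder <- function(content, value, schema = NULL) {
  fill <- function(t) {
    if (!is.null(t$value) && grepl("#", t$value, fixed = TRUE)) {
      t$value <- sub("#", value, t$value, fixed = TRUE)
      if (!is.null(schema)) {
        node <- schema_node(schema, t$node_long)
        pv <- parse_tag_value(node, t$value)
        t$numeric_value <- pv$numeric_value
        t$unit <- pv$unit
      }
    }
    t
  }
  new_hed_group(walk_items(list(content), fill)[[1]]$children)
}

#' Expand a Def reference
#'
#' Returns a copy of the referenced definition's content, with the
#' placeholder `#` replaced by the reference's value for placeholder
#' families. The Def tag itself is kept by callers as the anchor that ties
#' onset/offset/inset markers of one event process together.
#'
#' @param tag a resolved `hed_tag` whose path ends in `Def/<name>` or
#'   `Def/<name>/<value>`.
#' @param registry an `hed_definitions` registry.
#' @param schema optional schema used to re-parse substituted values of
#'   value-taking tags.
#' @return an `hed_group` with the expanded content.
#' @export
expand_def <- function(tag, registry, schema = NULL) {
  stopifnot(inherits(registry, "hed_definitions"))
  if (!tag_is(tag, "Def")) stop("not a Def tag")
  parts <- def_parts(tag)
  d <- registry$defs[[tolower(parts$name)]]
  if (is.null(d))
    stop(sprintf("Def/%s: no such definition", parts$name))
  if (d$takes_value && is.null(parts$value))
    stop(sprintf("Def/%s: definition takes a value but none was supplied",
                 parts$name))
  if (!d$takes_value && !is.null(parts$value))
    stop(sprintf("Def/%s/%s: definition does not take a value",
                 parts$name, parts$value))
  if (d$takes_value)
    substitute_placeholder(d$content, parts$value, schema)
  else d$content
}

#' Expand all Def references in an annotation
#'
#' Each Def tag keeps its place (as the process anchor) and the expanded
#' definition content is inserted beside it in the same group; a bare
#' top-level Def is wrapped into a group with its content. Definitions never
#' contain Def tags, so expansion is a fixpoint.
#'
#' @param hs a resolved `hed_string`.
#' @inheritParams expand_def
#' @param on_missing `"error"` for validation, or `"warn"` to keep an
#'   unknown Def opaque (so partially annotated data stay searchable).
#' @return the expanded `hed_string`.
#' @export
expand_defs <- function(hs, registry, schema = NULL,
                        on_missing = c("error", "warn")) {
  on_missing <- match.arg(on_missing)
  expand1 <- function(tag) {
    tryCatch(expand_def(tag, registry, schema),
             error = function(e) {
               if (on_missing == "warn") {
                 warning(conditionMessage(e), call. = FALSE)
                 NULL
               } else stop(e)
             })
  }
  already_there <- function(siblings, content) {
    any(vapply(siblings, function(s)
      is_hed_group(s) && hed_equal(s, content), TRUE))
  }
  rec <- function(items, wrap_bare) {
    out <- list()
    for (it in items) {
      if (is_hed_group(it)) {
        kids <- rec(it$children, wrap_bare = FALSE)
        out <- c(out, list(new_hed_group(kids)))
      } else if (tag_is(it, "Def")) {
        content <- expand1(it)
        if (is.null(content) || already_there(items, content))
          out <- c(out, list(it))  # idempotence: content already present
        else if (wrap_bare)
          out <- c(out, list(new_hed_group(list(it, content))))
        else out <- c(out, list(it), list(content))
      } else out <- c(out, list(it))
    }
    out
  }
  new_hed_string(rec(hs$top, wrap_bare = TRUE), hs$source_text)
}
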