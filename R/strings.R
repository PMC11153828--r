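# HED annotation string grammar: comma-separated tags with arbitrarily
# nested parenthesized groups, plus schema resolution of every tag.

new_hed_tag <- function(text) {
  structure(list(tag = text, path = NULL, node_long = NULL, value = NULL,
                 numeric_value = NULL, unit = NULL, resolved = FALSE),
            class = "hed_tag")
}

new_hed_group <- function(children) {
  structure(list(children = children), class = "hed_group")
}

new_hed_string <- function(top, source_text) {
  structure(list(top = top, source_text = source_text), class = "hed_string")
}

is_hed_tag <- function(x) inherits(x, "hed_tag")
is_hed_group <- function(x) inherits(x, "hed_group")

#' Parse a HED annotation string
#'
#' Commas separate sibling items; parentheses open groups, which may nest to
#' any depth; whitespace around separators is ignored. Tag paths are kept
#' verbatim (not yet schema-resolved). Note that commas inside Label or
#' Description values are not supported: a value runs to the next separator.
#'
#' @param text annotation string, e.g. `"(Red, Triangle)"`.
#' @return an object of class `hed_string`.
#' @examples
#' hs <- parse_hed("(Experiment-participant, (Move, (Left, Hand)))")
#' format(hs)
#' @export
parse_hed <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(trimws(text))) stop("empty annotation string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  # Each frame: children list and the child count at the last separator,
  # used to detect empty tags such as "a,,b" or "(a,)".
  frames <- list(list(children = list(), at_sep = 0L))
  buf <- character(0)

  flush_tag <- function() {
    t <- trimws(paste(buf, collapse = ""))
    buf <<- character(0)
    if (nzchar(t)) {
      d <- length(frames)
      frames[[d]]$children <<- c(frames[[d]]$children, list(new_hed_tag(t)))
    }
  }
  check_sep <- function(what) {
    d <- length(frames)
    if (length(frames[[d]]$children) == frames[[d]]$at_sep)
      stop(sprintf("empty tag before '%s' in: %s", what, text))
    frames[[d]]$at_sep <<- length(frames[[d]]$children)
  }

  for (ch in chars) {
    if (ch == "(") {
      if (nzchar(trimws(paste(buf, collapse = ""))))
        stop(sprintf("unexpected '(' after tag text in: %s", text))
      frames[[length(frames) + 1L]] <- list(children = list(), at_sep = 0L)
    } else if (ch == ")") {
      flush_tag()
      if (length(frames) == 1L)
        stop(sprintf("unbalanced ')' in: %s", text))
      d <- length(frames)
      if (length(frames[[d]]$children) == 0L)
        stop(sprintf("empty group '()' in: %s", text))
      if (length(frames[[d]]$children) == frames[[d]]$at_sep)
        stop(sprintf("empty tag before ')' in: %s", text))
      grp <- new_hed_group(frames[[d]]$children)
      frames[[d]] <- NULL
      d <- length(frames)
      frames[[d]]$children <- c(frames[[d]]$children, list(grp))
    } else if (ch == ",") {
      flush_tag()
      check_sep(",")
    } else {
      buf <- c(buf, ch)
    }
  }
  flush_tag()
  if (length(frames) > 1L)
    stop(sprintf("unbalanced '(' in: %s", text))
  top <- frames[[1]]
  if (length(top$children) == 0L)
    stop("empty annotation string")
  if (length(top$children) == top$at_sep && top$at_sep > 0L)
    stop(sprintf("empty tag at end of: %s", text))
  new_hed_string(top$children, text)
}

# Parse the value carried by a value-taking node. Returns list(value,
# numeric_value, unit). Time-class values are normalized to seconds.
parse_tag_value <- function(node, value, tag_text = value) {
  # placeholder values ("#", possibly with a unit as in "# s") are kept
  # verbatim until a Def reference substitutes them
  if (grepl("#", value, fixed = TRUE))
    return(list(value = value, numeric_value = NULL, unit = NULL))
  m <- regexec("^([+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?)(?:\\s+(\\S+))?$",
               value)
  g <- regmatches(value, m)[[1]]
  num <- NULL; unit <- NULL
  if (length(g)) {
    num <- as.numeric(g[2])
    unit <- if (nzchar(g[3])) g[3] else NA_character_
  }
  if (identical(node$unit_class, "time")) {
    if (is.null(num))
      stop(sprintf("tag '%s/%s': non-numeric value for a time-unit tag",
                   node$term, value))
    if (is.na(unit)) {
      warning(sprintf("tag '%s/%s': unit-less duration, assuming seconds",
                      node$term, value))
      unit <- "s"
    }
    fac <- switch(unit, s = 1, ms = 1e-3, min = 60,
                  stop(sprintf("tag '%s/%s': unrecognized time unit '%s'",
                               node$term, value, unit)))
    num <- num * fac
  }
  list(value = value, numeric_value = num,
       unit = if (is.null(num)) NULL else unit)
}

resolve_tag <- function(tag, schema) {
  src <- if (isTRUE(tag$resolved)) {
    if (is.null(tag$value)) tag$path else paste(tag$path, tag$value, sep = "/")
  } else tag$tag
  rp <- resolve_path(src, schema)
  tag$path <- rp$long
  tag$node_long <- rp$node_long
  if (!is.null(rp$value)) {
    pv <- parse_tag_value(rp$node, rp$value, src)
    tag$value <- pv$value
    tag$numeric_value <- pv$numeric_value
    tag$unit <- pv$unit
  } else {
    tag$value <- NULL; tag$numeric_value <- NULL; tag$unit <- NULL
  }
  tag$resolved <- TRUE
  tag
}

walk_items <- function(items, f) {
  lapply(items, function(it) {
    if (is_hed_group(it)) new_hed_group(walk_items(it$children, f)) else f(it)
  })
}

#' Resolve all tags of a parsed annotation against a schema
#'
#' Every tag path is expanded to long form; values of value-taking tags are
#' split off and, for time-class tags, parsed as `<number> [unit]` and
#' normalized to seconds. The input is not modified. Resolution is
#' idempotent.
#'
#' @param hs an `hed_string` from [parse_hed()].
#' @param schema an `hed_schema`.
#' @return a resolved `hed_string`.
#' @export
resolve_hed <- function(hs, schema) {
  stopifnot(inherits(hs, "hed_string"))
  new_hed_string(walk_items(hs$top, function(t) resolve_tag(t, schema)),
                 hs$source_text)
}

serialize_tag <- function(tag, form) {
  if (!isTRUE(tag$resolved)) return(tag$tag)
  base <- switch(form,
    long = tag$path,
    short = {
      short <- basename_term(tag$node_long)
      extra <- substring(tag$path, nchar(tag$node_long) + 2L)
      if (nzchar(extra)) paste(short, extra, sep = "/") else short
    })
  if (is.null(tag$value)) base else paste(base, tag$value, sep = "/")
}

serialize_items <- function(items, form) {
  paste(vapply(items, function(it) {
    if (is_hed_group(it))
      paste0("(", serialize_items(it$children, form), ")")
    else serialize_tag(it, form)
  }, ""), collapse = ", ")
}

#' Serialize an annotation back to text
#'
#' `parse_hed(format(hs))` is structurally equal to `hs`. For a resolved
#' string, `form = "short"` emits the deepest schema component plus any
#' extension/value suffix and `form = "long"` the full path; unresolved tags
#' are emitted verbatim.
#'
#' @param x an `hed_string` (or `hed_group`/`hed_tag`).
#' @param form `"short"` or `"long"`.
#' @param ... ignored.
#' @return a single string.
#' @export
format.hed_string <- function(x, form = c("short", "long"), ...) {
  serialize_items(x$top, match.arg(form))
}

#' @export
format.hed_group <- function(x, form = c("short", "long"), ...) {
  paste0("(", serialize_items(x$children, match.arg(form)), ")")
}

#' @export
format.hed_tag <- function(x, form = c("short", "long"), ...) {
  serialize_tag(x, match.arg(form))
}

#' @export
print.hed_string <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.hed_group <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.hed_tag <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

tag_key <- function(tag) {
  if (isTRUE(tag$resolved))
    paste0(tolower(tag$path), "\r", tolower(tag$value %||% ""))
  else tolower(gsub("\\s+", " ", tag$tag))
}

item_equal <- function(a, b, order_insensitive) {
  if (is_hed_tag(a) && is_hed_tag(b)) return(tag_key(a) == tag_key(b))
  if (is_hed_group(a) && is_hed_group(b))
    return(items_equal(a$children, b$children, order_insensitive))
  FALSE
}

items_equal <- function(xs, ys, order_insensitive) {
  if (length(xs) != length(ys)) return(FALSE)
  if (!order_insensitive)
    return(all(mapply(item_equal, xs, ys,
                      MoreArgs = list(order_insensitive = FALSE))))
  used <- rep(FALSE, length(ys))
  for (x in xs) {
    hit <- FALSE
    for (j in seq_along(ys)) {
      if (!used[j] && item_equal(x, ys[[j]], TRUE)) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Structural equality of annotations
#'
#' Tags compare by case-insensitive path and value; groups are compared as
#' multisets by default because grouping expresses association, not order.
#'
#' @param a,b `hed_string`, `hed_group`, or `hed_tag` objects.
#' @param order_insensitive compare group children as multisets.
#' @return logical.
#' @export
hed_equal <- function(a, b, order_insensitive = TRUE) {
  ia <- if (inherits(a, "hed_string")) a$top else list(a)
  ib <- if (inherits(b, "hed_string")) b$top else list(b)
  items_equal(ia, ib, order_insensitive)
}

#' Flatten an annotation
#'
#' `all_groups()` returns every group at any nesting depth; `all_tags()`
#' every tag. Useful for inspecting resolved annotations.
#'
#' @param x an `hed_string`, `hed_group`, or `hed_tag`.
#' @return a flat list of `hed_group` / `hed_tag` objects.
#' @export
all_groups <- function(x) {
  items <- if (inherits(x, "hed_string")) x$top
           else if (is_hed_group(x)) list(x)
           else list()
  out <- list()
  rec <- function(its) {
    for (it in its) {
      if (is_hed_group(it)) {
        out[[length(out) + 1L]] <<- it
        rec(it$children)
      }
    }
  }
  rec(items)
  out
}

#' @rdname all_groups
#' @export
all_tags <- function(x) {
  items <- if (inherits(x, "hed_string")) x$top
           else if (is_hed_group(x)) x$children
           else list(x)
  out <- list()
  rec <- function(its) {
    for (it in its) {
      if (is_hed_group(it)) rec(it$children)
      else out[[length(out) + 1L]] <<- it
    }
  }
  rec(items)
  out
}

# Does this resolved tag sit on/under the schema node whose term is `term`?
tag_is <- function(tag, term) {
  isTRUE(tag$resolved) &&
    tolower(basename_term(tag$node_long)) == tolower(term)
}
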