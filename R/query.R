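# Abstraction-aware search: a small query algebra over resolved
# annotations. A term query matches any tag that is the term or one of its
# is-a descendants (including user extensions); a group query requires its
# sub-queries to be satisfied directly among one group's children, mirroring
# grouping-as-association in the annotation grammar.

q_node <- function(kind, ...) structure(list(kind = kind, ...),
                                        class = "hed_query")

#' Query constructors
#'
#' `q_term(term)` matches annotations containing the term or any of its
#' descendants. `q_group(...)` matches when some single group (at any
#' nesting level) directly contains children satisfying every sub-query.
#' `q_and`, `q_or`, `q_not` are the boolean combinators; a `q_not` is only
#' legal inside a `q_and` (a bare negation would match almost everything).
#'
#' @param term tag path (short or long form).
#' @param ... sub-queries.
#' @param q a query to negate.
#' @return an object of class `hed_query`.
#' @name query
#' @export
q_term <- function(term) q_node("term", term = term)

#' @rdname query
#' @export
q_group <- function(...) q_node("group", sub = list(...))

#' @rdname query
#' @export
q_and <- function(...) q_node("and", sub = list(...))

#' @rdname query
#' @export
q_or <- function(...) q_node("or", sub = list(...))

#' @rdname query
#' @export
q_not <- function(q) q_node("not", sub = list(q))

#' @export
print.hed_query <- function(x, ...) {
  cat(deparse_query(x), "\n")
  invisible(x)
}

deparse_query <- function(q) {
  switch(q$kind,
    term = q$term,
    group = paste0("(", paste(vapply(q$sub, deparse_query, ""),
                              collapse = ", "), ")"),
    and = paste(vapply(q$sub, deparse_query, ""), collapse = " AND "),
    or = paste0("(", paste(vapply(q$sub, deparse_query, ""),
                           collapse = " OR "), ")"),
    not = paste0("NOT ", deparse_query(q$sub[[1]])))
}

# Surface syntax: terms, parentheses with commas for group queries,
# AND / OR / NOT keywords (case-insensitive); parentheses without a
# top-level comma group a boolean sub-expression.
tokenize_query <- function(text) {
  pat <- "\\(|\\)|,|\\b[Aa][Nn][Dd]\\b|\\b[Oo][Rr]\\b|\\b[Nn][Oo][Tt]\\b"
  toks <- character(0)
  rest <- text
  repeat {
    m <- regexpr(pat, rest)
    if (m == -1L) {
      if (nzchar(trimws(rest))) toks <- c(toks, trimws(rest))
      break
    }
    pre <- substr(rest, 1L, m - 1L)
    if (nzchar(trimws(pre))) toks <- c(toks, trimws(pre))
    toks <- c(toks, toupper(regmatches(rest, m)))
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  toks
}

#' Parse a query expression
#'
#' Grammar: terms; `A AND B`, `A OR B`, `A AND NOT B` (keywords
#' case-insensitive); `(q1, q2, ...)` is a group query whose sub-queries
#' must be satisfied within one annotation group; parentheses without a
#' top-level comma merely group boolean sub-expressions. `NOT` must appear
#' under an `AND`.
#'
#' @param text query string, e.g. `"Sensory-event AND NOT (Red, Triangle)"`.
#' @return an `hed_query`.
#' @export
parse_query <- function(text) {
  toks <- tokenize_query(text)
  if (length(toks) == 0L) stop("empty query")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(tok) {
    if (!identical(peek(), tok))
      stop(sprintf("query '%s': expected '%s' near position %d", text, tok, pos))
    take()
  }
  parse_or <- function() {
    x <- parse_and()
    subs <- list(x)
    while (identical(peek(), "OR")) { take(); subs <- c(subs, list(parse_and())) }
    if (length(subs) == 1L) x else q_node("or", sub = subs)
  }
  parse_and <- function() {
    subs <- list(parse_unary())
    while (identical(peek(), "AND")) { take(); subs <- c(subs, list(parse_unary())) }
    if (length(subs) == 1L) subs[[1]] else q_node("and", sub = subs)
  }
  parse_unary <- function() {
    if (identical(peek(), "NOT")) { take(); return(q_not(parse_unary())) }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) stop(sprintf("query '%s': unexpected end", text))
    if (t == "(") {
      take()
      subs <- list(parse_or())
      is_group <- FALSE
      while (identical(peek(), ",")) {
        take(); is_group <- TRUE
        subs <- c(subs, list(parse_or()))
      }
      expect(")")
      if (is_group) q_node("group", sub = subs) else subs[[1]]
    } else if (t %in% c(")", ",", "AND", "OR", "NOT")) {
      stop(sprintf("query '%s': unexpected '%s'", text, t))
    } else {
      take()
      q_term(t)
    }
  }
  q <- parse_or()
  if (pos <= length(toks))
    stop(sprintf("query '%s': trailing input '%s'", text, peek()))
  check_not_placement(q, under_and = FALSE)
  q
}

check_not_placement <- function(q, under_and) {
  if (q$kind == "not" && !under_and)
    stop("NOT is only allowed inside an AND (e.g. 'A AND NOT B')")
  if (!is.null(q$sub)) {
    ua <- q$kind == "and"
    for (s in q$sub) check_not_placement(s, under_and = ua)
  }
  invisible(TRUE)
}

as_query <- function(q) {
  if (inherits(q, "hed_query")) q else parse_query(as.character(q))
}

# Resolve a query term to a long form for descendant matching; unknown
# terms that extend a known prefix resolve through long_form's extension
# path, anything else is an error.
query_term_long <- function(term, schema) {
  long_form(term, schema)
}

tag_matches_term <- function(tag, term_long, include_description) {
  if (!isTRUE(tag$resolved)) return(FALSE)
  if (!include_description && tag_is(tag, "Description")) return(FALSE)
  full <- if (is.null(tag$value)) tag$path
          else paste(tag$path, tag$value, sep = "/")
  is_descendant(full, term_long)
}

#' Match a resolved annotation against a query
#'
#' A term query is satisfied by any tag anywhere in the annotation whose
#' long-form path has the term as an is-a prefix (so `2D-shape` matches
#' `Triangle` and the extension `2D-shape/Star` alike). A group query is
#' satisfied when some single group, at any nesting depth, directly
#' contains children satisfying all of its sub-queries. `Description` free
#' text never matches unless the query targets `Description` itself.
#'
#' @param annotation a resolved `hed_string` (or `hed_group`).
#' @param q an `hed_query` or query string.
#' @param schema an `hed_schema`.
#' @return logical.
#' @export
matches <- function(annotation, q, schema) {
  q <- as_query(q)
  if (is.null(annotation)) return(FALSE)
  eval_q <- function(q) {
    switch(q$kind,
      term = {
        tl <- query_term_long(q$term, schema)
        incl <- tolower(basename_term(tl)) == "description"
        any(vapply(all_tags(annotation), tag_matches_term, TRUE,
                   term_long = tl, include_description = incl))
      },
      group = any(vapply(all_groups(annotation), group_satisfies, TRUE,
                         sqs = q$sub, schema = schema)),
      and = all(vapply(q$sub, eval_q, TRUE)),
      or = any(vapply(q$sub, eval_q, TRUE)),
      not = !eval_q(q$sub[[1]]))
  }
  eval_q(q)
}

# Does group g directly contain, for every sub-query, a child satisfying it?
group_satisfies <- function(g, sqs, schema) {
  all(vapply(sqs, function(sq) {
    any(vapply(g$children, child_satisfies, TRUE, sq = sq, schema = schema))
  }, TRUE))
}

child_satisfies <- function(child, sq, schema) {
  switch(sq$kind,
    term = {
      tl <- query_term_long(sq$term, schema)
      incl <- tolower(basename_term(tl)) == "description"
      is_hed_tag(child) && tag_matches_term(child, tl, incl)
    },
    group = is_hed_group(child) && group_satisfies(child, sq$sub, schema),
    and = all(vapply(sq$sub, function(s) child_satisfies(child, s, schema), TRUE)),
    or = any(vapply(sq$sub, function(s) child_satisfies(child, s, schema), TRUE)),
    not = !child_satisfies(child, sq$sub[[1]], schema))
}

# Concatenate a marker annotation with the annotations of all processes
# active at its time (the ongoing + recording context).
enrich_annotation <- function(annotation, tl, t) {
  items <- if (is.null(annotation)) list() else annotation$top
  for (p in context_at(tl, t)) {
    if (is.null(p$annotation)) next
    extra <- if (inherits(p$annotation, "hed_string")) p$annotation$top
             else list(p$annotation)
    items <- c(items, extra)
  }
  if (length(items) == 0L) return(NULL)
  new_hed_string(items, "<enriched>")
}

#' Search a dataset for annotations matching a query
#'
#' With `enrich = TRUE` (marker scope) each marker's annotation is first
#' augmented with the annotations of every process active at its time —
#' the ongoing context plus the Recording process — so recording-level
#' facts such as `Left-handed` participate in per-event search.
#'
#' @param dataset an `hed_dataset` (see [hed_dataset()]).
#' @param q an `hed_query` or query string.
#' @param scope `"markers"` (one hit per matching event marker) or
#'   `"processes"` (one hit per matching event process).
#' @param enrich augment marker annotations with their ongoing context.
#' @return data frame of hits in (file, time) order: columns `file`, `row`,
#'   `onset` for markers; `file`, `anchor`, `onset`, `offset` for processes.
#' @export
hed_search <- function(dataset, q, scope = c("markers", "processes"),
                       enrich = FALSE) {
  scope <- match.arg(scope)
  q <- as_query(q)
  schema <- dataset$schema
  hits <- list()
  for (fname in names(dataset$files)) {
    fl <- dataset$files[[fname]]
    if (scope == "markers") {
      for (i in seq_along(fl$timeline$markers)) {
        m <- fl$timeline$markers[[i]]
        ann <- if (enrich) enrich_annotation(m$annotation, fl$timeline, m$time)
               else m$annotation
        if (!is.null(ann) && matches(ann, q, schema))
          hits[[length(hits) + 1L]] <- data.frame(
            file = fname, row = m$row, onset = m$time,
            stringsAsFactors = FALSE)
      }
    } else {
      for (p in c(list(fl$timeline$recording), fl$timeline$processes)) {
        if (!is.null(p$annotation) && matches(p$annotation, q, schema))
          hits[[length(hits) + 1L]] <- data.frame(
            file = fname, anchor = p$anchor, onset = p$onset_t,
            offset = p$offset_t, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    cols <- if (scope == "markers") c("file", "row", "onset")
            else c("file", "anchor", "onset", "offset")
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    out$onset <- numeric(0)
    if (scope == "markers") out$row <- integer(0) else out$offset <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, hits)
  out[order(out$file, out$onset), , drop = FALSE]
}

#' Extract a 0/1 factor matrix from named queries
#'
#' One row per event marker across the dataset, one column per named query;
#' a cell is 1 iff the (optionally context-enriched) marker annotation
#' matches the query. These indicator columns are design-matrix factors for
#' epoch selection.
#'
#' @param dataset an `hed_dataset`.
#' @param queries named list of `hed_query` objects or query strings.
#' @param enrich augment marker annotations with their ongoing context.
#' @return data frame with columns `file`, `row`, `onset`, then one 0/1
#'   column per query.
#' @export
factor_matrix <- function(dataset, queries, enrich = FALSE) {
  stopifnot(length(queries) >= 1L)
  nms <- names(queries)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("queries must be named")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate query names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  qs <- lapply(queries, as_query)
  schema <- dataset$schema
  rows <- list()
  for (fname in names(dataset$files)) {
    tl <- dataset$files[[fname]]$timeline
    for (m in tl$markers) {
      ann <- if (enrich) enrich_annotation(m$annotation, tl, m$time)
             else m$annotation
      vals <- vapply(qs, function(q) {
        as.integer(!is.null(ann) && matches(ann, q, schema))
      }, 0L)
      rec <- data.frame(file = fname, row = m$row, onset = m$time,
                        stringsAsFactors = FALSE)
      for (j in seq_along(nms)) rec[[nms[j]]] <- vals[[j]]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}
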