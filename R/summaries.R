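# Tag-frequency summaries and event transition graphs with task-compliance
# classification.

new_transition_graph <- function(nodes, edges, n_events, n_files) {
  structure(list(nodes = nodes, edges = edges, n_events = n_events,
                 n_files = n_files),
            class = "transition_graph")
}

#' Event transition graph of one events file
#'
#' Counts successions of event-marker labels: consecutive rows in time
#' order (same-time rows follow file row order) contribute one directed
#' edge each, so edge counts sum to `rows - 1`.
#'
#' @param table an `event_table` (or data frame with the label column and,
#'   optionally, `onset`).
#' @param label_column column holding the marker-type labels (default
#'   `"event_type"`).
#' @return an object of class `transition_graph`: `nodes`, `edges`
#'   (`data.frame(from, to, count)`), `n_events`, `n_files`.
#' @export
transition_graph <- function(table, label_column = "event_type") {
  if (!label_column %in% names(table))
    stop(sprintf("label column '%s' not found", label_column))
  labels <- as.character(table[[label_column]])
  if (length(labels) == 0L) stop("events table has no rows")
  nodes <- unique(labels)
  if (length(labels) >= 2L) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
    key <- paste(from, to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  new_transition_graph(nodes, edges, length(labels), 1L)
}

#' Consolidate transition graphs across files
#'
#' Edge counts are summed edge-wise; `n_events` and `n_files` accumulate,
#' preserving the conservation law `sum(counts) = n_events - n_files` (each
#' file contributes one fewer transition than it has markers).
#'
#' @param graphs list of `transition_graph` objects.
#' @return a consolidated `transition_graph`.
#' @export
consolidate <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  if (inherits(graphs, "transition_graph")) graphs <- list(graphs)
  edges <- do.call(rbind, lapply(graphs, function(g) g$edges))
  if (nrow(edges)) {
    agg <- stats::aggregate(count ~ from + to, data = edges, FUN = sum)
    agg <- agg[order(agg$from, agg$to), , drop = FALSE]
    rownames(agg) <- NULL
  } else agg <- edges
  new_transition_graph(
    nodes = unique(unlist(lapply(graphs, function(g) g$nodes))),
    edges = agg,
    n_events = sum(vapply(graphs, function(g) g$n_events, 0L)),
    n_files = sum(vapply(graphs, function(g) g$n_files, 0L)))
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("transition_graph: %d node(s), %d distinct edge(s), %d events in %d file(s)\n",
              length(x$nodes), nrow(x$edges), x$n_events, x$n_files))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Task rule set for transition compliance
#'
#' `allowed` maps a marker label to the set of successor labels consistent
#' with the task instructions; labels absent from the map permit any
#' successor.
#'
#' @param allowed named list of character vectors, or a path/JSON string of
#'   the form `{"allowed": {"node": ["succ", ...]}}`.
#' @return an object of class `task_rules`.
#' @export
task_rules <- function(allowed) {
  if (is.character(allowed)) {
    doc <- jsonlite::fromJSON(allowed, simplifyVector = TRUE)
    allowed <- as.list(doc$allowed)
  }
  stopifnot(is.list(allowed))
  allowed <- lapply(allowed, as.character)
  structure(list(allowed = allowed), class = "task_rules")
}

# round half away from zero, to `digits` decimals
round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Score a transition graph against task rules
#'
#' An edge `(a, b)` contravenes the task when `a` has an allowed-successor
#' set and `b` is not in it; counts are weighted by edge multiplicity. The
#' violation percentage is reported to one decimal (half away from zero).
#'
#' @param g a `transition_graph`.
#' @param rules a `task_rules` object (or value accepted by [task_rules()]).
#' @return an object of class `compliance_report`: the per-edge table with
#'   a `consistent` flag, `n_violations`, `n_transitions`, `pct_violations`.
#' @export
classify <- function(g, rules) {
  if (!inherits(rules, "task_rules")) rules <- task_rules(rules)
  edges <- g$edges
  cons <- rep(TRUE, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    allow <- rules$allowed[[edges$from[i]]]
    if (!is.null(allow) && !(edges$to[i] %in% allow)) cons[i] <- FALSE
  }
  edges$consistent <- cons
  n_tr <- sum(edges$count)
  n_v <- sum(edges$count[!cons])
  pct <- if (n_tr > 0L) round_half_away(100 * n_v / n_tr, 1L) else 0
  structure(list(edges = edges, n_violations = n_v, n_transitions = n_tr,
                 pct_violations = pct),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("compliance_report: %d of %d transitions (%.1f%%) contravene the task rules\n",
              x$n_violations, x$n_transitions, x$pct_violations))
  bad <- x$edges[!x$edges$consistent, , drop = FALSE]
  if (nrow(bad)) print(bad, row.names = FALSE)
  invisible(x)
}

#' Tag-frequency summary of a dataset
#'
#' Counts each long-form tag path over all marker annotations (optionally
#' context-enriched). A tag contributes to its own term only, not to its
#' ancestors — abstraction happens at query time, not in the counts.
#'
#' @param dataset an `hed_dataset`.
#' @param enrich include each marker's ongoing-context annotations.
#' @return named integer vector, term -> count, decreasing.
#' @export
tag_counts <- function(dataset, enrich = FALSE) {
  counts <- integer(0)
  for (fname in names(dataset$files)) {
    tl <- dataset$files[[fname]]$timeline
    for (m in tl$markers) {
      ann <- if (enrich) enrich_annotation(m$annotation, tl, m$time)
             else m$annotation
      if (is.null(ann)) next
      for (t in all_tags(ann)) {
        key <- if (isTRUE(t$resolved)) t$path else t$tag
        counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) + 1L
      }
    }
  }
  sort(counts, decreasing = TRUE)
}

#' Export a transition graph in DOT format
#'
#' Rule-contravening edges are colored red, mirroring the usual rendering
#' of task-inconsistent transitions.
#'
#' @param g a `transition_graph`.
#' @param path output file path, or `NULL` to return the DOT text.
#' @param rules optional `task_rules` used to color edges.
#' @return the DOT text, invisibly when written to a file.
#' @export
write_dot <- function(g, path = NULL, rules = NULL) {
  esc <- function(s) gsub('"', '\\"', s, fixed = TRUE)
  cons <- rep(TRUE, nrow(g$edges))
  if (!is.null(rules)) cons <- classify(g, rules)$edges$consistent
  lines <- c("digraph transitions {",
             sprintf('  "%s";', esc(g$nodes)),
             vapply(seq_len(nrow(g$edges)), function(i) {
               sprintf('  "%s" -> "%s" [label="%d"%s];',
                       esc(g$edges$from[i]), esc(g$edges$to[i]),
                       g$edges$count[i],
                       if (cons[i]) "" else ', color="red"')
             }, ""),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
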