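# Temporal assembly: turn per-row event markers into temporally extended
# event processes using Duration / Onset / Offset / Inset semantics, and
# derive the set of processes active (ongoing context) at any time point.

.time_tol <- 1e-9  # absolute tolerance for comparing marker times, seconds

# structured error with a machine-readable issue code (see hed_validate)
hed_stop <- function(code, msg) {
  stop(structure(class = c("hed_error", "error", "condition"),
                 list(message = msg, call = NULL, code = code)))
}

#' Build event markers from assembled row annotations
#'
#' @param annotations output of [assemble_annotations()].
#' @param file file label recorded in each marker's provenance.
#' @return list of `hed_marker` objects (time, annotation, file, row),
#'   in table order.
#' @export
event_markers <- function(annotations, file = "<memory>") {
  lapply(annotations, function(a) {
    structure(list(time = a$onset, annotation = a$annotation,
                   file = file, row = a$row),
              class = "hed_marker")
  })
}

# Classify the top-level items of a marker annotation into timeline actions.
# Returns a list of actions: list(kind, group, anchor, duration).
marker_actions <- function(marker) {
  ann <- marker$annotation
  if (is.null(ann)) return(list())
  acts <- list()
  for (it in ann$top) {
    if (!is_hed_group(it)) next
    tags <- Filter(is_hed_tag, it$children)
    has <- function(term) any(vapply(tags, tag_is, TRUE, term = term))
    def_tag <- NULL
    for (t in tags) if (tag_is(t, "Def")) { def_tag <- t; break }
    anchor <- NULL
    if (!is.null(def_tag)) {
      p <- def_parts(def_tag)
      anchor <- tolower(paste(c(p$name, p$value), collapse = "/"))
    }
    dur_tag <- NULL
    for (t in tags) if (tag_is(t, "Duration")) { dur_tag <- t; break }
    if (!is.null(dur_tag)) {
      acts <- c(acts, list(list(kind = "duration", group = it,
                                anchor = NULL,
                                duration = dur_tag$numeric_value)))
    } else if (has("Onset")) {
      if (is.null(def_tag))
        hed_stop("ONSET_NO_DEF",
                 sprintf("%s row %s @%g: Onset group lacks a Def anchor",
                         marker$file, marker$row, marker$time))
      acts <- c(acts, list(list(kind = "onset", group = it, anchor = anchor)))
    } else if (has("Offset")) {
      if (is.null(def_tag))
        hed_stop("OFFSET_NO_DEF",
                 sprintf("%s row %s @%g: Offset group lacks a Def anchor",
                         marker$file, marker$row, marker$time))
      acts <- c(acts, list(list(kind = "offset", group = it, anchor = anchor)))
    } else if (has("Inset")) {
      if (is.null(def_tag))
        hed_stop("INSET_NO_DEF",
                 sprintf("%s row %s @%g: Inset group lacks a Def anchor",
                         marker$file, marker$row, marker$time))
      acts <- c(acts, list(list(kind = "inset", group = it, anchor = anchor)))
    }
  }
  acts
}

new_process <- function(anchor, onset_t, offset_t, annotation,
                        insets = numeric(0), provenance = list()) {
  structure(list(anchor = anchor, onset_t = onset_t, offset_t = offset_t,
                 inset_ts = insets, annotation = annotation,
                 provenance = provenance),
            class = "hed_process")
}

#' @export
print.hed_process <- function(x, ...) {
  cat(sprintf("[%g, %g] %s%s: %s\n", x$onset_t, x$offset_t, x$anchor,
              if (length(x$inset_ts))
                sprintf(" (insets %s)", paste(x$inset_ts, collapse = ", "))
              else "",
              if (is.null(x$annotation)) "" else format(x$annotation)))
  invisible(x)
}

# Annotation attached to a process opened by an Onset group: the group
# itself minus the structural Onset tag (Def tag and its expanded content,
# plus any per-instance modifiers, persist for the process lifetime).
process_annotation <- function(group, drop = c("Onset", "Offset", "Inset",
                                               "Duration")) {
  keep <- Filter(function(it) {
    !(is_hed_tag(it) && any(vapply(drop, function(d) tag_is(it, d), TRUE)))
  }, group$children)
  if (length(keep) == 0L) NULL else new_hed_group(keep)
}

#' Assemble a timeline of event processes from markers
#'
#' Walks time-ordered markers and applies the phase-marker semantics:
#'
#' * a top-level group containing a `Duration` tag spawns an anonymous
#'   process covering `[t, t + duration]` whose annotation is the group's
#'   other tags; such processes may overlap freely;
#' * a group `(Def/X, ..., Onset)` opens a process anchored at `X` (the
#'   definition name plus any `/value`, so `Def/A/1` and `Def/A/2` run
#'   independently); an open `X` process is closed by `(Def/X, Offset)` or
#'   by the next `(Def/X, ..., Onset)`, which closes it and opens a new,
#'   temporally contiguous one;
#' * `(Def/X, Inset)` records an internal phase-transition time on the open
#'   `X` process;
#' * processes still open at the end of the recording are closed there with
#'   a warning.
#'
#' At equal marker times Offsets are applied before Onsets, so contiguous
#' chains touch without overlap; Insets are applied last. A conventional
#' Recording process spanning `[0, recording_end]` carries recording-level
#' context (participant traits, environment, acquisition parameters).
#'
#' @param markers list of `hed_marker` (see [event_markers()]), times
#'   non-decreasing.
#' @param registry an `hed_definitions` registry (used only for provenance;
#'   annotations are expected Def-expanded).
#' @param recording_end end of the recording in seconds; defaults to the
#'   largest marker or process end time.
#' @param recording_tags character vector of tag strings (or a single
#'   annotation string) attached to the Recording process.
#' @param schema optional schema used to resolve `recording_tags`.
#' @param on_error `"stop"` aborts on the first structural fault (unmatched
#'   Offset/Inset, Onset without a Def anchor); `"collect"` records each
#'   fault as an issue, skips the offending action, and attaches the issue
#'   table as attribute `"issues"` on the result (used by [hed_validate()]).
#' @return an object of class `hed_timeline` with elements `recording`,
#'   `processes`, `markers`, `recording_end`.
#' @export
assemble_timeline <- function(markers, registry = NULL, recording_end = NULL,
                              recording_tags = character(0), schema = NULL,
                              on_error = c("stop", "collect")) {
  on_error <- match.arg(on_error)
  times <- vapply(markers, function(m) m$time, 0)
  if (length(times) && any(diff(times) < -.time_tol))
    stop("markers are not time-sorted")
  issues <- list()
  note <- function(code, msg, mi) {
    m <- markers[[mi]]
    issues[[length(issues) + 1L]] <<- data.frame(
      file = m$file, row = m$row, code = code, message = msg,
      stringsAsFactors = FALSE)
  }
  fail <- function(code, msg, mi) {
    if (on_error == "stop") hed_stop(code, msg) else note(code, msg, mi)
  }
  acts <- list()
  for (mi in seq_along(markers)) {
    acts_i <- tryCatch(marker_actions(markers[[mi]]), hed_error = function(e) {
      if (on_error == "stop") stop(e)
      note(e$code, conditionMessage(e), mi)
      list()
    })
    for (a in acts_i) {
      a$time <- markers[[mi]]$time
      a$marker <- mi
      acts[[length(acts) + 1L]] <- a
    }
  }
  # tie rule at equal times: offsets first, then onsets/durations, insets last
  prio <- c(offset = 0L, onset = 1L, duration = 1L, inset = 2L)
  if (length(acts)) {
    ord <- order(vapply(acts, function(a) a$time, 0),
                 prio[vapply(acts, function(a) a$kind, "")],
                 vapply(acts, function(a) a$marker, 0L))
    acts <- acts[ord]
  }

  processes <- list()
  open <- list()   # anchor -> list(onset_t, annotation, insets, provenance)
  n_anon <- 0L
  close_open <- function(anchor, t) {
    p <- open[[anchor]]
    processes[[length(processes) + 1L]] <<-
      new_process(anchor, p$onset_t, t, p$annotation, p$insets, p$provenance)
    open[[anchor]] <<- NULL
  }
  max_end <- if (length(times)) max(times) else 0

  for (a in acts) {
    if (a$kind == "duration") {
      if (is.null(a$duration))
        stop(sprintf("@%g: Duration tag without a numeric value", a$time))
      n_anon <- n_anon + 1L
      processes[[length(processes) + 1L]] <- new_process(
        sprintf("duration-%d", n_anon), a$time, a$time + a$duration,
        process_annotation(a$group), provenance = list(a$marker))
      max_end <- max(max_end, a$time + a$duration)
    } else if (a$kind == "onset") {
      if (!is.null(open[[a$anchor]])) close_open(a$anchor, a$time)
      open[[a$anchor]] <- list(onset_t = a$time,
                               annotation = process_annotation(a$group),
                               insets = numeric(0),
                               provenance = list(a$marker))
    } else if (a$kind == "offset") {
      if (is.null(open[[a$anchor]])) {
        fail("UNMATCHED_OFFSET",
             sprintf("@%g: Offset for '%s' with no open process",
                     a$time, a$anchor), a$marker)
        next
      }
      close_open(a$anchor, a$time)
    } else if (a$kind == "inset") {
      if (is.null(open[[a$anchor]])) {
        fail("UNMATCHED_INSET",
             sprintf("@%g: Inset for '%s' with no open process",
                     a$time, a$anchor), a$marker)
        next
      }
      open[[a$anchor]]$insets <- c(open[[a$anchor]]$insets, a$time)
      open[[a$anchor]]$provenance <- c(open[[a$anchor]]$provenance,
                                       list(a$marker))
    }
  }

  if (is.null(recording_end)) recording_end <- max_end
  if (recording_end < max_end - .time_tol)
    stop(sprintf("recording_end (%g) precedes the last marker/process end (%g)",
                 recording_end, max_end))
  for (anchor in names(open)) {
    warning(sprintf("process '%s' still open at recording end (%g); closing",
                    anchor, recording_end), call. = FALSE)
    close_open(anchor, recording_end)
  }

  rec_ann <- NULL
  if (length(recording_tags)) {
    txt <- paste(recording_tags, collapse = ", ")
    rec_ann <- if (is.null(schema)) parse_hed(txt)
               else resolve_hed(parse_hed(txt), schema)
  }
  recording <- new_process("recording", 0, recording_end, rec_ann)
  tl <- structure(list(recording = recording, processes = processes,
                       markers = markers, recording_end = recording_end),
                  class = "hed_timeline")
  if (on_error == "collect")
    attr(tl, "issues") <- if (length(issues)) do.call(rbind, issues)
                          else data.frame(file = character(0), row = integer(0),
                                          code = character(0),
                                          message = character(0))
  tl
}

#' @export
print.hed_timeline <- function(x, ...) {
  cat(sprintf("hed_timeline: %d markers, %d processes on [0, %g]\n",
              length(x$markers), length(x$processes), x$recording_end))
  invisible(x)
}

#' Ongoing event context at a time point
#'
#' Returns every process whose half-open span `[onset_t, offset_t)` covers
#' `t`, always including the Recording process. At the shared boundary of a
#' contiguous Onset-chain only the newly opened process is active.
#'
#' @param tl an `hed_timeline`.
#' @param t time in seconds, within `[0, recording_end]`.
#' @return list of active `hed_process` objects (Recording first).
#' @export
context_at <- function(tl, t) {
  stopifnot(inherits(tl, "hed_timeline"))
  if (t < -.time_tol || t > tl$recording_end + .time_tol)
    stop(sprintf("time %g outside the recording [0, %g]", t, tl$recording_end))
  active <- Filter(function(p) p$onset_t <= t && t < p$offset_t, tl$processes)
  c(list(tl$recording), active)
}

#' Markers preceding a given marker
#'
#' Up to `k` markers strictly earlier in time than the reference marker,
#' most recent first (ties in time broken by row order), optionally
#' restricted to markers matching a query. This exposes preceding-event
#' context (e.g. how many rare targets immediately preceded this target)
#' explicitly rather than folding it into the ongoing context.
#'
#' @param tl an `hed_timeline`.
#' @param marker index of the reference marker in `tl$markers`, or the
#'   marker itself.
#' @param k maximum number of markers to return (`k >= 1`).
#' @param filter optional `hed_query`; only matching markers are returned.
#' @param schema schema for query evaluation (required with `filter`).
#' @return list of `hed_marker`, most recent first.
#' @export
preceding <- function(tl, marker, k, filter = NULL, schema = NULL) {
  stopifnot(inherits(tl, "hed_timeline"), k >= 1)
  idx <- if (is.numeric(marker)) as.integer(marker)
         else Position(function(m) identical(m, marker), tl$markers)
  if (is.null(idx) || is.na(idx) || idx < 1L || idx > length(tl$markers))
    stop("marker not found in timeline")
  t0 <- tl$markers[[idx]]$time
  earlier <- Filter(function(m) m$time < t0 - .time_tol,
                    tl$markers[seq_len(idx - 1L)])
  earlier <- rev(earlier)  # most recent first; row order breaks ties
  if (!is.null(filter))
    earlier <- Filter(function(m) {
      !is.null(m$annotation) && matches(m$annotation, filter, schema)
    }, earlier)
  utils::head(earlier, k)
}

#' Export a timeline's processes as a plain list
#'
#' Suitable for `jsonlite::toJSON`: one record per process with anchor,
#' onset, offset, inset times and the (short-form) annotation text.
#'
#' @param tl an `hed_timeline`.
#' @return unnamed list of process records.
#' @export
export_timeline <- function(tl) {
  lapply(c(list(tl$recording), tl$processes), function(p) {
    list(anchor = p$anchor, onset = p$onset_t, offset = p$offset_t,
         insets = as.numeric(p$inset_ts),
         tags = if (is.null(p$annotation)) "" else format(p$annotation))
  })
}
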