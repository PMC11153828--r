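# Dataset container: event tables + shared sidecar + schema, with per-file
# assembled annotations and timelines, ready for search and summaries.

#' Assemble an annotated dataset
#'
#' Reads (or accepts) one or more event tables and a shared sidecar,
#' resolves every row annotation, and builds a per-file timeline of event
#' processes. Recording-level context (e.g. participant handedness tags
#' derived from `participants.tsv`) is attached to each file's Recording
#' process so that context-enriched search sees it at every marker.
#'
#' @param events named list (or single value) of `*_events.tsv` paths or
#'   `event_table` objects; names label the files.
#' @param sidecar shared sidecar: path, JSON string, list, or
#'   `hed_sidecar`; may be `NULL` when tables carry a literal `HED` column.
#' @param schema an `hed_schema` or a schema document accepted by
#'   [load_schema()].
#' @param participants optional `participants.tsv` path or the data frame
#'   from [read_participants()].
#' @param file_participants optional named character vector mapping file
#'   labels to `participant_id` values, used to pick each file's
#'   recording-level tags.
#' @param recording_tags character vector of additional tag strings for
#'   every file's Recording process.
#' @param recording_end optional recording end time (seconds) applied to
#'   every file.
#' @return an object of class `hed_dataset`: per-file `table`,
#'   `annotations`, `timeline`, plus the shared `schema` and `registry`.
#' @export
hed_dataset <- function(events, sidecar = NULL, schema,
                        participants = NULL, file_participants = NULL,
                        recording_tags = character(0),
                        recording_end = NULL) {
  if (!inherits(schema, "hed_schema")) schema <- load_schema(schema)
  if (!is.null(sidecar) && !inherits(sidecar, "hed_sidecar"))
    sidecar <- read_sidecar(sidecar)
  if (inherits(events, "event_table") || (is.character(events) && length(events) == 1L))
    events <- list(events)
  if (is.null(names(events)) || any(!nzchar(names(events)))) {
    nm <- vapply(seq_along(events), function(i) {
      ev <- events[[i]]
      if (is.character(ev)) basename(ev) else sprintf("file%d", i)
    }, "")
    names(events) <- make.unique(nm)
  }
  if (!is.null(participants) && !is.data.frame(participants))
    participants <- read_participants(participants)
  registry <- if (is.null(sidecar)) collect_definitions(list())
              else sidecar_definitions(sidecar, schema)

  files <- list()
  for (fname in names(events)) {
    tab <- events[[fname]]
    if (!inherits(tab, "event_table")) tab <- read_events(tab)
    ann <- assemble_annotations(tab, sidecar, schema, registry)
    rtags <- recording_tags
    if (!is.null(participants) && !is.null(file_participants) &&
        fname %in% names(file_participants)) {
      pid <- file_participants[[fname]]
      hit <- which(participants$participant_id == pid)
      if (length(hit) == 1L)
        rtags <- c(rtags, participants$derived_tags[[hit]])
      else warning(sprintf("file '%s': participant '%s' not found", fname, pid),
                   call. = FALSE)
    }
    markers <- event_markers(ann, file = fname)
    tl <- assemble_timeline(markers, registry, recording_end = recording_end,
                            recording_tags = rtags, schema = schema)
    files[[fname]] <- list(table = tab, annotations = ann, timeline = tl)
  }
  structure(list(files = files, schema = schema, registry = registry,
                 sidecar = sidecar),
            class = "hed_dataset")
}

#' @export
print.hed_dataset <- function(x, ...) {
  nmk <- sum(vapply(x$files, function(f) length(f$timeline$markers), 0L))
  cat(sprintf("hed_dataset: %d file(s), %d markers, schema %s (%d terms)\n",
              length(x$files), nmk, x$schema$version, length(x$schema$index)))
  invisible(x)
}
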