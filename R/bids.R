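# BIDS-style tabular event I/O: *_events.tsv tables, *_events.json sidecars
# and participants.tsv metadata, plus per-row annotation assembly.

#' Read a BIDS-style events table
#'
#' Tab-separated UTF-8 with a header; an `onset` column (seconds from
#' recording start) is required and a `duration` column is conventional.
#' `"n/a"` cells are preserved as missing. Rows are stably sorted by onset,
#' so same-time rows keep file order; the original file row number of each
#' row is kept in the `.row` column.
#'
#' @param path path to a `*_events.tsv` file.
#' @return a `data.frame` of class `event_table` with numeric `onset` and
#'   `duration`, all other columns character, and attribute `source_path`.
#' @export
read_events <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  as_event_table(raw, source_path = path)
}

#' Construct an events table from a data frame
#'
#' @param df data frame with at least an `onset` column.
#' @param source_path label recorded as the table's provenance.
#' @return an `event_table` (see [read_events()]).
#' @export
as_event_table <- function(df, source_path = "<memory>") {
  if (!"onset" %in% names(df))
    stop(sprintf("%s: missing required 'onset' column", source_path))
  if (nrow(df) == 0L)
    stop(sprintf("%s: events table has no rows", source_path))
  df <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
  char_cols <- setdiff(names(df), c("onset", "duration"))
  for (cc in char_cols) df[[cc]] <- as.character(df[[cc]])
  onset <- suppressWarnings(as.numeric(df$onset))
  if (anyNA(onset) || any(!is.finite(onset)))
    stop(sprintf("%s: unparseable or non-finite onset value(s)", source_path))
  df$onset <- onset
  if ("duration" %in% names(df)) {
    dchr <- as.character(df$duration)
    dur <- suppressWarnings(as.numeric(ifelse(dchr == "n/a", NA, dchr)))
    if (any(!is.na(dur) & dur < 0))
      stop(sprintf("%s: negative duration", source_path))
    df$duration <- dur
  }
  df$.row <- seq_len(nrow(df))
  ord <- order(df$onset)  # stable
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source_path") <- source_path
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write an events table
#'
#' Inverse of [read_events()] for canonical fixtures: tab separators, no
#' quoting, missing cells written as `"n/a"`, numeric onsets/durations in
#' plain decimal notation.
#'
#' @param table an `event_table` or plain data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  df <- as.data.frame(table)
  df$.row <- NULL
  num_fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "n/a" else format(v, scientific = FALSE, trim = TRUE,
                                      drop0trailing = TRUE)
    }, "")
    out
  }
  for (nm in names(df)) {
    df[[nm]] <- if (is.numeric(df[[nm]])) num_fmt(df[[nm]])
                else ifelse(is.na(df[[nm]]), "n/a", as.character(df[[nm]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "n/a", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a JSON sidecar of column annotations
#'
#' Per-column entries carry either a categorical map (`{"HED": {"value":
#' "tag string", ...}}`) or a value template (`{"HED": "Duration/# s"}`)
#' whose single `#` is substituted with each row's cell value. A top-level
#' `"definitions"` entry (array of annotation strings) and Definition groups
#' inside any column string both contribute to the definition registry.
#'
#' @param source path to a `*_events.json` file, a JSON string, or a parsed
#'   list.
#' @return an object of class `hed_sidecar`.
#' @export
read_sidecar <- function(source) {
  doc <- if (is.list(source)) source else jsonlite::fromJSON(source,
                                                             simplifyVector = FALSE)
  columns <- list()
  definitions <- character(0)
  for (nm in names(doc)) {
    entry <- doc[[nm]]
    if (nm == "definitions") {
      definitions <- c(definitions, unlist(entry, use.names = FALSE))
      next
    }
    if (!is.list(entry) || is.null(entry$HED)) next
    hed <- entry$HED
    if (is.character(hed) && length(hed) == 1L) {
      nph <- lengths(regmatches(hed, gregexpr("#", hed, fixed = TRUE)))
      if (nph > 1L)
        stop(sprintf("sidecar column '%s': template has %d '#' placeholders",
                     nm, nph))
      parse_hed(hed)  # must at least parse
      columns[[nm]] <- list(type = "template", template = hed)
    } else if (is.list(hed)) {
      map <- vapply(hed, function(x) as.character(x)[1], "")
      for (s in map) parse_hed(s)
      columns[[nm]] <- list(type = "categorical", map = map)
    } else stop(sprintf("sidecar column '%s': malformed HED entry", nm))
  }
  structure(list(columns = columns, definitions = definitions),
            class = "hed_sidecar")
}

#' @export
print.hed_sidecar <- function(x, ...) {
  cat(sprintf("hed_sidecar: %d annotated columns (%s), %d definition string(s)\n",
              length(x$columns), paste(names(x$columns), collapse = ", "),
              length(x$definitions)))
  invisible(x)
}

#' Collect the definition registry declared by a sidecar
#'
#' @param sidecar an `hed_sidecar`.
#' @param schema an `hed_schema`.
#' @param registry optional registry to extend.
#' @return an `hed_definitions` registry.
#' @export
sidecar_definitions <- function(sidecar, schema, registry = NULL) {
  texts <- c(sidecar$definitions,
             unlist(lapply(sidecar$columns, function(col) {
               if (col$type == "categorical") unname(col$map) else character(0)
             }), use.names = FALSE))
  strings <- lapply(texts, function(s) resolve_hed(parse_hed(s), schema))
  collect_definitions(strings, registry = registry)
}

#' Assemble one resolved annotation per event-table row
#'
#' For each row, the HED strings contributed by all annotated columns are
#' concatenated in header order: categorical columns look the cell value up
#' in their map, template columns substitute the cell value for `#`, and a
#' literal `HED` column contributes its cell verbatim. The combined string
#' is parsed, resolved against the schema, Definition groups are stripped,
#' and Def references expanded. A cell value missing from a categorical map
#' produces a warning and contributes nothing; rows with no annotated
#' content yield `NULL` with a warning.
#'
#' @param table an `event_table`.
#' @param sidecar an `hed_sidecar` (or `NULL` for tables with only a
#'   literal `HED` column).
#' @param schema an `hed_schema`.
#' @param registry an `hed_definitions` registry; defaults to the one
#'   declared by the sidecar.
#' @return list with one element per row (in table order):
#'   `list(row, onset, annotation)` where `annotation` is a resolved,
#'   Def-expanded `hed_string` or `NULL`.
#' @export
assemble_annotations <- function(table, sidecar, schema, registry = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (is.null(registry)) {
    registry <- if (is.null(sidecar)) collect_definitions(list())
                else sidecar_definitions(sidecar, schema)
  }
  cols <- names(table)
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    pieces <- character(0)
    for (nm in cols) {
      cell <- table[[nm]][i]
      if (nm == "HED") {
        if (!is.na(cell) && nzchar(cell) && cell != "n/a")
          pieces <- c(pieces, cell)
        next
      }
      col <- sidecar$columns[[nm]]
      if (is.null(col)) next
      cellc <- as.character(cell)
      if (is.na(cellc) || cellc == "n/a" || !nzchar(cellc)) next
      if (col$type == "categorical") {
        if (!cellc %in% names(col$map)) {
          warning(sprintf("%s row %d: value '%s' of column '%s' not in sidecar map",
                          attr(table, "source_path"), table$.row[i], cellc, nm),
                  call. = FALSE)
          next
        }
        pieces <- c(pieces, col$map[[cellc]])
      } else {
        pieces <- c(pieces, gsub("#", cellc, col$template, fixed = TRUE))
      }
    }
    ann <- NULL
    if (length(pieces)) {
      hs <- resolve_hed(parse_hed(paste(pieces, collapse = ", ")), schema)
      hs <- strip_definitions(hs)
      if (!is.null(hs))
        ann <- expand_defs(hs, registry, schema, on_missing = "error")
    }
    if (is.null(ann))
      warning(sprintf("%s row %d: no annotated content",
                      attr(table, "source_path"), table$.row[i]),
              call. = FALSE)
    out[[i]] <- list(row = table$.row[i], onset = table$onset[i],
                     annotation = ann)
  }
  out
}

#' Normalize a participants.tsv handedness designation to a HED tag
#'
#' The designations `left, l, L, Left, LEFT` (any case of "left" or "l")
#' resolve to `Left-handed`; the right-hand family resolves analogously.
#' Unrecognized values yield `NA` with a warning.
#'
#' @param value handedness cell value.
#' @return `"Left-handed"`, `"Right-handed"`, or `NA_character_`.
#' @export
normalize_handedness <- function(value) {
  v <- tolower(trimws(as.character(value)))
  if (v %in% c("left", "l")) return("Left-handed")
  if (v %in% c("right", "r")) return("Right-handed")
  warning(sprintf("unrecognized handedness value '%s'", value), call. = FALSE)
  NA_character_
}

#' Read participants.tsv metadata
#'
#' @param path path to a tab-separated participants file with a
#'   `participant_id` column.
#' @return data frame with an additional `derived_tags` list-column holding
#'   the recording-level tags implied by recognized metadata (currently the
#'   handedness column).
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (!"participant_id" %in% names(df))
    stop(sprintf("%s: missing 'participant_id' column", path))
  tags <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ti <- character(0)
    if ("handedness" %in% names(df)) {
      h <- df$handedness[i]
      if (!is.na(h) && nzchar(h) && h != "n/a") {
        tag <- normalize_handedness(h)
        if (!is.na(tag)) ti <- c(ti, tag)
      }
    }
    tags[[i]] <- ti
  }
  df$derived_tags <- tags
  df
}
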