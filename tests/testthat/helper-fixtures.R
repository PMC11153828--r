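# Shared fixtures built in code: the 14-term mini schema, the SART task
# schema, and small builders used across test files.

mini_schema <- function() load_schema(generate_mini_schema())
task_schema <- function() load_schema(generate_task_schema())

# an event table with a literal HED column, from (onset, hed) pairs
hed_table <- function(onsets, heds, source = "fixture.tsv") {
  as_event_table(data.frame(onset = onsets, duration = "n/a", HED = heds,
                            stringsAsFactors = FALSE), source)
}

# resolve a single annotation string against a schema
rs <- function(text, schema) resolve_hed(parse_hed(text), schema)

# registry from plain definition strings
defs_registry <- function(texts, schema) {
  collect_definitions(lapply(texts, rs, schema = schema))
}

# anchors of the active processes at time t, sorted
active_anchors <- function(tl, t) {
  sort(vapply(context_at(tl, t), function(p) p$anchor, ""))
}

# build a timeline straight from (onset, hed) rows
timeline_from <- function(onsets, heds, schema, definitions = character(0),
                          recording_end = NULL, recording_tags = character(0)) {
  tab <- hed_table(onsets, heds)
  sc <- read_sidecar(list(definitions = as.list(definitions)))
  reg <- sidecar_definitions(sc, schema)
  ann <- assemble_annotations(tab, sc, schema, reg)
  assemble_timeline(event_markers(ann), reg, recording_end = recording_end,
                    recording_tags = recording_tags, schema = schema)
}
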