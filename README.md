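# hedline

Event annotation for time-series neuroimaging recordings (EEG, MEG, fMRI)
usually stops at a flat list of onset latencies and opaque type codes.
That representation cannot say what an event *was*, how long it lasted, or
what else was going on at the time — yet brain responses depend on exactly
that context. **hedline** is an R engine for annotating and analyzing
*events in context* with Hierarchical Event Descriptors (HED): it models
temporally extended **event processes** assembled from **event phase
markers** (onset, offset, intermediate insets) and makes both the events
and their ever-evolving context searchable.

It is aimed at researchers and data curators working with BIDS-style
datasets (`*_events.tsv` + JSON sidecars + `participants.tsv`) who want
machine-actionable event records: validation, context-aware search,
design-matrix extraction, and behavioral summaries.

## What it implements

* **Hierarchical vocabularies** — trees of unique terms where each child
  *is-a* specialization of its parent. Short forms resolve to long forms
  (`Ingestible-object` → `Item/Object/Ingestible-object`); library
  vocabularies merge under an attachment point; user extensions
  (`2D-shape/Star`) stay searchable through `is_descendant()`.
* **The annotation grammar** — comma-separated tags with arbitrarily
  nested parenthesized groups, value tags (`Duration/0.5 s`, `Label/X`),
  and named templates (`Definition`/`Def`, including `Name/#` placeholder
  families).
* **Temporal assembly** — `(Duration/0.5 s, (Label/X))` at time *t* yields
  a process on [*t*, *t* + 0.5]; `(Def/A, ..., Onset)` / `(Def/A, Offset)`
  chains contiguous processes anchored by a definition; `(Def/A, Inset)`
  records internal phase transitions; a Recording process spanning the
  whole file carries participant/environment context.
* **Search and factors** — abstraction-aware queries (a `2D-shape` query
  matches `Triangle`) with boolean and group combinators, optional
  context enrichment, and 0/1 factor matrices for epoching.
* **Transition graphs** — per-file and consolidated counts of marker
  successions, scored against a task rule set into a compliance report.
* **A SART simulator** — seeded, byte-reproducible go/no-go sessions
  (digits 0–9, respond to all but the target) with exact ground truth, so
  the whole pipeline is testable without any download.

## Worked example

Simulate a 2,000-trial SART session with a 10% false-alarm and 5% miss
rate, then ask how often the participant contravened the task
instructions:

```r
library(hedline)

sess   <- generate_sart(sart_config(n_trials = 2000,
                                    p_false_alarm = 0.10, p_miss = 0.05,
                                    seed = 7))
report <- classify(transition_graph(sess$table), sart_rules())
report
#> compliance_report: 109 of 3726 transitions (2.9%) contravene the task rules
#>        from         to count consistent
#>  non_target non_target    76      FALSE
#>  non_target     target    11      FALSE
#>      target   response    22      FALSE
```

The 22 `target → response` transitions are false alarms (responses to the
no-go digit); the 87 transitions leaving a `non_target` for the next
stimulus are misses. The generator's ground truth confirms the readout:
22 false alarms among 208 targets, 87 misses among 1,792 non-targets.

Assemble the annotated dataset and extract design factors:

```r
ds <- hed_dataset(list(run1 = sess$table), sess$sidecar, sess$schema)
fm <- factor_matrix(ds, list(stimulus = "Sensory-event",
                             action   = "Agent-action"))
colSums(fm[, c("stimulus", "action")])
#> stimulus   action
#>     2000     1727
```

Every one of the 2,000 stimulus markers matches the abstract
`Sensory-event` query through its definition content, and the 1,727
key-press markers match `Agent-action` — no per-dataset code needed.

Timeline semantics in one line: a marker at 0 annotated
`(Duration/0.5 s, (Label/X))` becomes a half-second process,

```r
tab <- as_event_table(data.frame(onset = 0, duration = "n/a",
                                 HED = "(Duration/0.5 s, (Label/X))"))
sch <- load_schema(generate_mini_schema())
tl  <- assemble_timeline(event_markers(assemble_annotations(tab, NULL, sch)))
tl$processes[[1]]
#> [0, 0.5] duration-1: ((Label/X))
```

See `vignettes/events-in-context.Rmd` for the full model, parameter
meanings, and design choices.

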