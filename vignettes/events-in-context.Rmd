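---
title: "Events in context: the hedline annotation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Events in context: the hedline annotation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedline)
```

## The event model

Time-series neuroimaging recordings (EEG, MEG, fMRI) are conventionally
annotated with a flat list of event *markers*: an onset latency and a type
code per row of a tab-separated events file. hedline implements a richer
model that distinguishes the **event process** — something that unfolds over
a period of the recording (a stimulus presentation, a movie scene, the
recording session itself) — from the **event phase markers** that locate its
phase transitions on the timeline: its *onset*, its *offset*, and any
intermediate *inset* transitions (say, camera-shot changes within a scene).

Annotations are strings over a hierarchical controlled vocabulary. A tag is
a path in a tree of terms (`Item/Object/Ingestible-object`), and a child
term is always a specialization (*is-a*) of its parent. Because every term
is unique across the vocabulary, annotators may write the short form
(`Ingestible-object`) and tools recover the long form unambiguously. Two
properties of the vocabulary do most of the analytic work:

* **Abstraction-aware search.** A query for `2D-shape` matches annotations
  containing `Triangle`, and also user *extensions* never formally added to
  the schema, such as `2D-shape/Star` — datasets annotated at different
  granularities stay jointly searchable.
* **Grouping as association.** Parentheses associate tags:
  `(Red, Triangle)` is a red triangle; sentence-like structure is
  `(subject, (predicate, direct object))`, e.g.
  `(Experiment-participant, (Move, (Left, Hand)))`.

## From markers to processes

Three mechanisms place processes on the timeline:

1. **Duration groups.** `(Duration/0.5 s, (Label/X))` at marker time $t$
   creates a process on $[t,\, t + 0.5]$. Duration-marked processes may
   overlap in any configuration; each group is its own process.
2. **Onset/Offset groups.** `(Def/A, (Label/X), Onset)` opens a process
   anchored by the named definition `A`; `(Def/A, Offset)` closes it. A
   repeated `(Def/A, ..., Onset)` closes the open process *and* opens a new
   one, so same-type processes chain contiguously. Anchor identity is the
   definition name plus any placeholder value, so `Def/A/1` and `Def/A/2`
   run concurrently and independently.
3. **Insets.** `(Def/A, Inset)` records an internal phase transition on the
   open `A` process. The same stretch of data can thus be represented
   either as three chained processes or as one process with two insets;
   both are supported and no automatic conversion between the two
   representations is attempted.

A conventional **Recording process** spans `[0, recording_end]` and carries
context that holds for the whole recording: participant traits (for
instance `Left-handed`, normalized from the `handedness` column of
`participants.tsv`, accepting `left`, `l`, `L`, `Left`, `LEFT` and the
right-hand analogues), environment and acquisition facts.

**Definitions.** `(Definition/A, (content))` in a JSON sidecar declares a
named template; `Def/A` references it. `Definition/A/#` declares a
single-placeholder family whose `#` is filled per reference (`Def/A/3`).
Definition content may not contain structural tags, so expansion is a
fixpoint. Modifier tags grouped with an Onset reference (`Label/X` beside
`Def/A`) are kept on that process for its whole lifetime — they describe the
process instance, not just its opening moment.

## Context

The *ongoing context* of a time point is the set of processes active there,
always including the Recording process. `context_at()` uses half-open
spans $[\text{onset}, \text{offset})$: at the shared boundary of a
contiguous chain exactly the newly opened process is active, so covered
time is partitioned with neither gap nor double-counting.

*Preceding context* (e.g. how many rare targets immediately preceded this
target) is deliberately **not** folded into the ongoing context:
`preceding()` exposes it explicitly, with a query filter and a history
bound `k`. Context-enriched search (`enrich = TRUE`) augments each
marker's annotation with the annotations of all processes active at its
time before matching, and therefore can only grow hit sets, never shrink
them.

## Queries and factors

The query surface supports terms, `AND`/`OR`/`NOT` (with `NOT` only inside
an `AND`, to keep queries from matching nearly everything), and
parenthesized comma lists as *group queries*. A group query is satisfied
when some single group, at any nesting depth, contains children satisfying
all sub-queries **directly among its children** — the stricter reading of
grouping-as-association, chosen because it is testable and keeps
`(Red, Triangle)` from matching `Red, (Blue, Triangle)`. `Description`
free text is excluded from matching unless the query targets `Description`
itself. `factor_matrix()` turns named queries into per-marker 0/1 design
factors for epoch selection.

## Transition graphs and task compliance

`transition_graph()` counts successions of marker labels (taken from a
designated column, default `event_type`, since type codes — not tags — are
what task designs prescribe); per-file graphs consolidate by edge-wise
summation, conserving `sum(counts) = n_events - n_files`. A task rule set
maps each label to its permitted successors; `classify()` flags
contravening edges and reports the violation percentage to one decimal,
rounding half away from zero. Labels without a rule entry permit any
successor, so an empty rule set never flags anything and adding an allowed
successor is monotone (violations can only decrease).

## The SART generator

The synthetic-data module emulates sessions of the sustained attention
response task (SART): digits 0–9 are presented in random order and the
participant presses a key after every digit except the target. Defaults
(all configurable through `sart_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_trials` | 200 | digit presentations per session |
| `target_digit` | 3 | the no-go digit |
| `p_false_alarm` | 0.10 | P(response after a target) |
| `p_miss` | 0.05 | P(no response after a non-target) |
| `stim_duration` | 0.25 s | digit presentation time |
| `isi` | 1.15 s | stimulus onset asynchrony |
| `rt_range` | (0.2, 1.0) s | uniform response-time range |

Digits are i.i.d. uniform (no sequence constraints), so targets occur on
about 10% of trials; response times are uniform with `rt_max < isi` so a
response always precedes the next stimulus. Stimulus rows are annotated
through a Def + Duration pattern, responses as an agent-action definition;
the generator returns the exact ground truth (per-trial digit,
responded, correct) along with the table and sidecar. The generator
emulates marker timing and error structure only — it makes no attempt at
realistic reaction-time distributions (uniform, not ex-Gaussian), digit
sequence constraints, or any neural signal, so passing tests demonstrate
correctness of the annotation/assembly machinery, not behavioral realism.

All randomness flows through a single seed; the caller's RNG state is
saved and restored, and identical seeds give byte-identical event files.

## Numerical and design choices

* Tag comparison is case-insensitive everywhere; canonical case is
  preserved for display.
* Marker times compare with absolute tolerance $10^{-9}$ s. At equal
  times, Offsets are applied before Onsets (so contiguous chains touch
  without overlap), and Insets after both.
* Durations: values match `<number> [unit]` with units `s`, `ms`, `min`,
  normalized to seconds; a unit-less duration is taken as seconds with a
  warning.
* Processes still open at the recording end are closed there with a
  warning rather than discarded. Insets on anonymous Duration processes
  are rejected (there is no anchor to attach them to).
* Extension components are unchecked free terms; they are not required to
  be unique across the schema (they are one-off descriptive detail, not
  vocabulary).
* Value-taking is an attribute of the named node itself (Duration, Label,
  Description, Def, Definition) rather than a separate placeholder child
  node, which keeps the term-uniqueness invariant unconditional.
* Group children compare as multisets (grouping expresses association, not
  order), but sibling order is preserved on output. Commas inside Label or
  Description values are not supported; a value runs to the next
  separator.
* Sidecar columns contribute in header order; a literal `HED` column
  contributes verbatim. When recording-level metadata could conflict
  across sources, later sources win with a warning.

## Scale of the shipped checks

The test suite runs entirely on generated fixtures: property tests use
~120 random annotations over the 14-term fixture schema, 20 random
timelines probed at 1,000 random time points each against a brute-force
interval oracle, and SART sessions of 2,000 trials for stochastic
error-rate recovery (within three binomial standard errors) plus 50 short
sessions for the consolidation conservation law. These sizes were chosen
to exercise every code path with comfortable statistical margins while
keeping the default check fast.

## Limitations

* One recording per file: processes cannot span files, and no clock
  alignment (`scans.tsv`) is performed.
* No curly-brace column references, no multi-schema tag prefixes, and no
  regular-expression matching in queries.
* Only first-order transition statistics; higher-order sequence structure
  needs different machinery.
* The shipped vocabularies are deliberately small fixtures; the engine is
  vocabulary-agnostic and loads any document in its JSON schema dialect,
  but no importer for external schema formats is included.
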