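test_that("a Duration group spawns a process of exactly that length", {
  sch <- mini_schema()
  tl <- timeline_from(2.0, "(Duration/0.5 s, (Label/X))", sch)
  expect_length(tl$processes, 1L)
  p <- tl$processes[[1]]
  expect_equal(p$onset_t, 2.0)
  expect_equal(p$offset_t, 2.5)
  expect_identical(format(p$annotation), "((Label/X))")
})

test_that("duration-marked processes may overlap freely", {
  sch <- mini_schema()
  tl <- timeline_from(c(1, 1.2), c("(Duration/2 s, (Label/A))",
                                   "(Duration/2 s, (Label/B))"), sch)
  expect_length(tl$processes, 2L)
  expect_setequal(active_anchors(tl, 1.5), c("duration-1", "duration-2",
                                             "recording"))
})

test_that("repeated Onsets of one anchor make contiguous processes", {
  sch <- mini_schema()
  tl <- timeline_from(
    c(1, 3, 5),
    c("(Def/A, (Label/X), Onset)", "(Def/A, (Label/Y), Onset)",
      "(Def/A, Offset)"),
    sch, definitions = "(Definition/A, (Label/Chain))")
  expect_length(tl$processes, 2L)
  spans <- t(vapply(tl$processes, function(p) c(p$onset_t, p$offset_t),
                    numeric(2)))
  expect_equal(spans, rbind(c(1, 3), c(3, 5)))
  # union covers [first onset, last offset] with no gap or overlap
  expect_equal(spans[1, 2], spans[2, 1])
  # per-instance modifiers persist on their own process
  expect_match(format(tl$processes[[1]]$annotation), "Label/X", fixed = TRUE)
  expect_match(format(tl$processes[[2]]$annotation), "Label/Y", fixed = TRUE)
})

test_that("placeholder anchors run concurrently and independently", {
  sch <- mini_schema()
  tl <- timeline_from(
    c(1, 2, 4, 6),
    c("(Def/A/1, Onset)", "(Def/A/2, Onset)", "(Def/A/1, Offset)",
      "(Def/A/2, Offset)"),
    sch, definitions = "(Definition/A/#, (Label/#))")
  expect_length(tl$processes, 2L)
  expect_setequal(active_anchors(tl, 3), c("a/1", "a/2", "recording"))
})

test_that("insets are recorded within their open process", {
  fx <- generate_overlap_fixture("inset_phases")
  ds <- hed_dataset(list(f = fx$table), fx$sidecar, fx$schema,
                    recording_end = fx$recording_end)
  tl <- ds$files$f$timeline
  expect_length(tl$processes, 1L)
  expect_equal(tl$processes[[1]]$inset_ts, c(3, 5))
  p <- tl$processes[[1]]
  expect_true(all(p$onset_t <= p$inset_ts & p$inset_ts < p$offset_t))
})

test_that("structural faults are errors with provenance", {
  sch <- mini_schema()
  defs <- "(Definition/A, (Label/Q))"
  expect_error(timeline_from(2, "(Def/A, Offset)", sch, defs),
               "Offset for 'a' with no open process")
  expect_error(timeline_from(2, "(Def/A, Inset)", sch, defs),
               "Inset for 'a' with no open process")
  expect_error(timeline_from(1, "(Label/X, Onset)", sch, defs),
               "Onset group lacks a Def anchor")
})

test_that("open processes are closed at recording end with a warning", {
  sch <- mini_schema()
  expect_warning(
    tl <- timeline_from(1, "(Def/A, Onset)", sch,
                        definitions = "(Definition/A, (Label/Q))",
                        recording_end = 9),
    "still open at recording end")
  expect_equal(tl$processes[[1]]$offset_t, 9)
})

test_that("context_at uses half-open spans and always includes Recording", {
  fx <- generate_overlap_fixture("nested_overlap")
  ds <- hed_dataset(list(f = fx$table), fx$sidecar, fx$schema,
                    recording_end = fx$recording_end)
  tl <- ds$files$f$timeline
  expect_setequal(active_anchors(tl, 5), c("a", "b", "c", "recording"))
  expect_setequal(active_anchors(tl, 9.5), "recording")
  expect_error(context_at(tl, 11), "outside the recording")

  # at a contiguity boundary only the newly opened process is active
  sch <- mini_schema()
  tl2 <- timeline_from(
    c(1, 3, 5), c("(Def/A, (Label/X), Onset)", "(Def/A, (Label/Y), Onset)",
                  "(Def/A, Offset)"),
    sch, definitions = "(Definition/A, (Label/C))")
  at3 <- Filter(function(p) p$anchor == "a", context_at(tl2, 3))
  expect_length(at3, 1L)
  expect_match(format(at3[[1]]$annotation), "Label/Y", fixed = TRUE)
})

test_that("preceding returns recent history, filtered and bounded", {
  s <- generate_sart(sart_config(n_trials = 30, p_false_alarm = 0,
                                 p_miss = 0, seed = 11))
  ds <- hed_dataset(list(f = s$table), s$sidecar, s$schema)
  tl <- ds$files$f$timeline
  expect_length(preceding(tl, 1, k = 5), 0L)
  pr <- preceding(tl, 10, k = 3)
  expect_length(pr, 3L)
  expect_true(all(diff(vapply(pr, function(m) m$time, 0)) < 0))
  expect_length(preceding(tl, 3, k = 100), 2L)
  # filtered: only stimulus markers
  prs <- preceding(tl, 10, k = 3, filter = "Sensory-event",
                   schema = ds$schema)
  expect_true(all(vapply(prs, function(m)
    matches(m$annotation, "Sensory-event", ds$schema), TRUE)))
  # brute-force count of targets among the 3 preceding a target
  ann <- ds$files$f$annotations
  types <- s$table$event_type
  ti <- which(types == "target")
  if (length(ti) >= 2) {
    i <- ti[length(ti)]
    want <- sum(types[max(1, i - 3):(i - 1)] == "target")
    got <- length(preceding(tl, i, k = 3, filter = "Def/Target-digit",
                            schema = ds$schema))
    expect_equal(got, want)
  }
})

test_that("assembly is invariant to stable reordering of same-time markers", {
  sch <- mini_schema()
  # offset of A and onset of B at t=3, in both row orders
  tl1 <- timeline_from(
    c(1, 3, 3, 6),
    c("(Def/A, Onset)", "(Def/A, Offset)", "(Def/B, Onset)", "(Def/B, Offset)"),
    sch, definitions = c("(Definition/A, (Label/Q))",
                         "(Definition/B, (Red))"))
  tl2 <- timeline_from(
    c(1, 3, 3, 6),
    c("(Def/A, Onset)", "(Def/B, Onset)", "(Def/A, Offset)", "(Def/B, Offset)"),
    sch, definitions = c("(Definition/A, (Label/Q))",
                         "(Definition/B, (Red))"))
  for (tl in list(tl1, tl2)) {
    spans <- lapply(tl$processes, function(p) c(p$onset_t, p$offset_t))
    expect_setequal(lapply(spans, paste, collapse = "-"), c("1-3", "3-6"))
  }
})

test_that("timeline export is JSON-ready", {
  sch <- mini_schema()
  tl <- timeline_from(1, "(Duration/1 s, (Label/X))", sch, recording_end = 5)
  ex <- export_timeline(tl)
  expect_length(ex, 2L)
  expect_identical(ex[[1]]$anchor, "recording")
  expect_equal(ex[[2]]$offset, 2)
  expect_silent(jsonlite::toJSON(ex, auto_unbox = TRUE))
})
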