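canonical_events <- c(
  "onset\tduration\tevent_type\tresponse_time",
  "0.5\t0.25\tshow_digit\tn/a",
  "1\tn/a\tpress\t0.42",
  "1.5\t0.25\tshow_digit\tn/a")

test_that("read_events parses, types and stably sorts rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(canonical_events, f)
  tab <- read_events(f)
  expect_s3_class(tab, "event_table")
  expect_equal(tab$onset, c(0.5, 1, 1.5))
  expect_equal(tab$duration, c(0.25, NA, 0.25))
  expect_identical(tab$.row, 1:3)

  # out-of-order onsets are sorted, original file row retained
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\tlab", "2\tn/a\tb", "1\tn/a\ta", "2\tn/a\tc"),
             f2)
  t2 <- read_events(f2)
  expect_equal(t2$lab, c("a", "b", "c"))  # stable: b before c at onset 2
  expect_equal(t2$.row, c(2L, 1L, 3L))
})

test_that("events without onset or with bad values are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("duration\tx", "1\ta"), f)
  expect_error(read_events(f), "missing required 'onset'")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tx", "abc\ta"), f2)
  expect_error(read_events(f2), "unparseable")
  expect_error(as_event_table(data.frame(onset = 1, duration = -2)),
               "negative duration")
})

test_that("write_events(read_events(f)) is byte-identical for canonical files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(canonical_events, f)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_events(read_events(f), out)
  expect_identical(readLines(out), canonical_events)
})

test_that("sidecar annotations assemble per row in header order", {
  sch <- task_schema()
  sc <- read_sidecar(list(
    event_type = list(HED = list(
      show_digit = "(Sensory-event, Visual-presentation)",
      press = "(Agent-action, (Experiment-participant, (Press, Keyboard-key)))")),
    response_time = list(HED = "Duration/# s")))
  tab <- as_event_table(data.frame(
    onset = c(0.5, 1), duration = "n/a",
    event_type = c("show_digit", "press"),
    response_time = c("n/a", "0.42"), stringsAsFactors = FALSE))
  ann <- assemble_annotations(tab, sc, sch)
  expect_identical(format(ann[[1]]$annotation),
                   "(Sensory-event, Visual-presentation)")
  # header order: event_type before response_time
  expect_identical(
    format(ann[[2]]$annotation),
    "(Agent-action, (Experiment-participant, (Press, Keyboard-key))), Duration/0.42 s")
  dur <- all_tags(ann[[2]]$annotation)
  dur <- dur[[length(dur)]]
  expect_equal(dur$numeric_value, 0.42)
})

test_that("unknown categorical values warn and contribute nothing", {
  sch <- task_schema()
  sc <- read_sidecar(list(event_type = list(HED = list(
    show_digit = "(Sensory-event, Visual-presentation)"))))
  tab <- as_event_table(data.frame(onset = c(0, 1), duration = "n/a",
                                   event_type = c("show_digit", "oops"),
                                   stringsAsFactors = FALSE))
  expect_warning(expect_warning(
    ann <- assemble_annotations(tab, sc, sch),
    "not in sidecar map"), "no annotated content")
  expect_null(ann[[2]]$annotation)
})

test_that("a literal HED column contributes verbatim", {
  sch <- mini_schema()
  tab <- hed_table(1, "(Red, Triangle)")
  ann <- assemble_annotations(tab, NULL, sch)
  expect_identical(format(ann[[1]]$annotation), "(Red, Triangle)")
})

test_that("non-numeric substitution into a Duration template is an error", {
  sch <- mini_schema()
  sc <- read_sidecar(list(rt = list(HED = "Duration/# s")))
  tab <- as_event_table(data.frame(onset = 0, duration = "n/a", rt = "soon",
                                   stringsAsFactors = FALSE))
  expect_error(assemble_annotations(tab, sc, sch), "non-numeric value")
})

test_that("sidecar templates allow at most one placeholder", {
  expect_error(read_sidecar(list(x = list(HED = "Label/#, Description/#"))),
               "2 '#' placeholders")
})

test_that("handedness designations normalize to participant trait tags", {
  for (v in c("left", "l", "L", "Left", "LEFT"))
    expect_identical(normalize_handedness(v), "Left-handed")
  for (v in c("right", "r", "R", "Right", "RIGHT"))
    expect_identical(normalize_handedness(v), "Right-handed")
  expect_warning(out <- normalize_handedness("ambi"), "unrecognized")
  expect_true(is.na(out))
})

test_that("participants.tsv yields derived recording tags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("participant_id\tage\thandedness",
               "sub-01\t31\tLEFT", "sub-02\t24\tn/a"), f)
  pp <- read_participants(f)
  expect_identical(pp$derived_tags[[1]], "Left-handed")
  expect_identical(pp$derived_tags[[2]], character(0))
})
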