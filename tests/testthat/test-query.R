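test_that("query surface syntax parses terms, groups and combinators", {
  q <- parse_query("Sensory-event AND NOT (Red, Triangle)")
  expect_identical(q$kind, "and")
  expect_identical(q$sub[[2]]$kind, "not")
  expect_identical(q$sub[[2]]$sub[[1]]$kind, "group")
  # parentheses without a comma are boolean grouping, not a group query
  q2 <- parse_query("(Red OR Triangle) AND Label/X")
  expect_identical(q2$sub[[1]]$kind, "or")
  expect_error(parse_query("NOT Red"), "only allowed inside an AND")
  expect_error(parse_query("Red OR NOT Triangle"), "only allowed inside an AND")
  expect_error(parse_query("Red AND"), "unexpected end")
  expect_error(parse_query(""), "empty query")
})

test_that("term queries match descendants and extensions", {
  sch <- mini_schema()
  expect_true(matches(rs("Red, Triangle", sch), "2D-shape", sch))
  expect_true(matches(rs("2D-shape/Star", sch), "2D-shape", sch))
  expect_true(matches(rs("Triangle", sch), "2D-shape", sch))
  expect_false(matches(rs("Red", sch), "2D-shape", sch))
  expect_false(matches(rs("Triangle", sch), "Red", sch))
  # unknown query terms are errors
  expect_error(matches(rs("Red", sch), "Banana", sch), "unknown term")
})

test_that("group queries require co-occurrence among direct children", {
  sch <- mini_schema()
  q <- parse_query("(Red, Triangle)")
  expect_true(matches(rs("(Red, Triangle)", sch), q, sch))
  expect_false(matches(rs("Red, (Label/B, Triangle)", sch), q, sch))
  # nested groups: the sub-query must hold in one group at some depth
  expect_true(matches(rs("(Label/X, (Red, Triangle))", sch), q, sch))
  # nested group sub-queries
  qn <- parse_query("(Label/X, (Red, Triangle))")
  expect_true(matches(rs("(Label/X, (Red, Triangle))", sch), qn, sch))
  expect_false(matches(rs("(Label/X, Red, Triangle)", sch), qn, sch))
})

test_that("Description free text is excluded unless targeted", {
  sch <- mini_schema()
  ann <- rs("Red, Description/a triangle to ignore", sch)
  expect_false(matches(ann, "Triangle", sch))
  expect_true(matches(ann, "Description", sch))
})

test_that("hit sets are monotone along every schema edge", {
  sch <- mini_schema()
  set.seed(505)
  anns <- lapply(1:120, function(i)
    rs(random_annotation_text(), sch))
  edges <- list()
  for (key in names(sch$nodes)) {
    nd <- sch$nodes[[key]]
    for (ch in nd$children) edges[[length(edges) + 1L]] <- c(nd$long, ch)
  }
  expect_gt(length(edges), 0L)
  for (e in edges) {
    hits_parent <- vapply(anns, matches, TRUE, q = q_term(e[1]), schema = sch)
    hits_child <- vapply(anns, matches, TRUE, q = q_term(e[2]), schema = sch)
    expect_true(all(hits_parent[hits_child]),
                label = sprintf("hits(%s) contains hits(%s)", e[1], e[2]))
  }
})

test_that("context enrichment adds recording-level tags to marker search", {
  s <- generate_sart(sart_config(n_trials = 15, p_false_alarm = 0,
                                 p_miss = 0, seed = 2))
  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("participant_id\thandedness", "sub-01\tl"), pf)
  ds <- hed_dataset(list(run = s$table), s$sidecar, s$schema,
                    participants = pf, file_participants = c(run = "sub-01"))
  n_markers <- length(ds$files$run$timeline$markers)
  expect_identical(nrow(hed_search(ds, "Left-handed", enrich = TRUE)),
                   n_markers)
  expect_identical(nrow(hed_search(ds, "Left-handed", enrich = FALSE)), 0L)
  expect_identical(nrow(hed_search(ds, "Ingestible-object")), 0L)
  # enrichment never shrinks any hit set
  for (q in c("Sensory-event", "Agent-action", "Label")) {
    h0 <- hed_search(ds, q, enrich = FALSE)
    h1 <- hed_search(ds, q, enrich = TRUE)
    k0 <- paste(h0$file, h0$row); k1 <- paste(h1$file, h1$row)
    expect_true(all(k0 %in% k1), label = q)
  }
})

test_that("process-scope search matches assembled process annotations", {
  fx <- generate_overlap_fixture("nested_overlap")
  ds <- hed_dataset(list(f = fx$table), fx$sidecar, fx$schema,
                    recording_end = fx$recording_end)
  hits <- hed_search(ds, "Label/InnerB", scope = "processes")
  expect_identical(hits$anchor, "b")
})

test_that("factor matrix columns agree with search counts and ground truth", {
  s <- generate_sart(sart_config(n_trials = 60, seed = 9))
  ds <- hed_dataset(list(run = s$table), s$sidecar, s$schema)
  qs <- list(target = "Def/Target-digit", non_target = "Def/Nontarget-digit",
             stimulus = "Sensory-event", absent = "Ingestible-object")
  fm <- factor_matrix(ds, qs)
  expect_identical(nrow(fm), length(ds$files$run$timeline$markers))
  for (nm in names(qs))
    expect_identical(sum(fm[[nm]]), nrow(hed_search(ds, qs[[nm]])),
                     label = nm)
  # mutually exclusive event types: row sums over those columns <= 1
  expect_true(all(fm$target + fm$non_target <= 1))
  expect_identical(sum(fm$stimulus), s$ground_truth$n_stimuli)
  expect_identical(sum(fm$absent), 0L)
  expect_error(factor_matrix(ds, stats::setNames(list("Red", "Red"),
                                                 c("a", "a"))),
               "duplicate query names")
})
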