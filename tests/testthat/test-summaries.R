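test_that("transition graphs count consecutive label pairs", {
  tab <- as_event_table(data.frame(onset = 1:3, duration = "n/a",
                                   event_type = c("a", "b", "a"),
                                   stringsAsFactors = FALSE))
  g <- transition_graph(tab)
  expect_identical(g$n_events, 3L)
  expect_identical(g$n_files, 1L)
  ed <- g$edges[order(g$edges$from), ]
  expect_equal(ed$count, c(1L, 1L))
  expect_equal(paste(ed$from, ed$to), c("a b", "b a"))

  single <- as_event_table(data.frame(onset = 1, duration = "n/a",
                                      event_type = "a"))
  expect_identical(nrow(transition_graph(single)$edges), 0L)
  expect_error(transition_graph(tab, "nope"), "not found")
})

test_that("edge counts match a brute-force pair scan", {
  set.seed(77)
  labs <- sample(letters[1:4], 300, replace = TRUE)
  tab <- as_event_table(data.frame(onset = seq_along(labs), duration = "n/a",
                                   event_type = labs, stringsAsFactors = FALSE))
  g <- transition_graph(tab)
  for (i in seq_len(nrow(g$edges))) {
    want <- sum(labs[-length(labs)] == g$edges$from[i] &
                  labs[-1] == g$edges$to[i])
    expect_identical(g$edges$count[i], want)
  }
  expect_identical(sum(g$edges$count), length(labs) - 1L)
})

test_that("consolidation sums edge-wise and preserves conservation", {
  tab <- as_event_table(data.frame(onset = 1:3, duration = "n/a",
                                   event_type = c("a", "b", "a"),
                                   stringsAsFactors = FALSE))
  g <- transition_graph(tab)
  gg <- consolidate(list(g, g))
  expect_equal(gg$edges$count, g$edges$count * 2L)
  expect_identical(gg$n_events, 6L)
  expect_identical(gg$n_files, 2L)
  expect_identical(sum(gg$edges$count), gg$n_events - gg$n_files)

  other <- transition_graph(as_event_table(
    data.frame(onset = 1:2, duration = "n/a", event_type = c("x", "y"))))
  un <- consolidate(list(g, other))
  expect_setequal(un$nodes, c("a", "b", "x", "y"))
})

test_that("classification counts rule contraventions with exact rounding", {
  # hand oracle: 400 transitions of which exactly 9 violate a -> {a}
  labs <- c(rep("a", 383), rep(c("b", "a"), 9))
  stopifnot(length(labs) == 401L)
  tab <- as_event_table(data.frame(onset = seq_along(labs), duration = "n/a",
                                   event_type = labs, stringsAsFactors = FALSE))
  rep_ <- classify(transition_graph(tab), task_rules(list(a = "a")))
  expect_identical(rep_$n_transitions, 400L)
  expect_identical(rep_$n_violations, 9L)  # 9/400 = 2.25% rounds half away
  expect_equal(rep_$pct_violations, 2.3)

  # empty rule set: nothing violates
  rep0 <- classify(transition_graph(tab), task_rules(list()))
  expect_identical(rep0$n_violations, 0L)
})

test_that("adding an allowed successor never increases violations", {
  s <- generate_sart(sart_config(n_trials = 300, seed = 21))
  g <- transition_graph(s$table)
  base <- list(target = c("target", "non_target"), non_target = "response")
  v0 <- classify(g, task_rules(base))$n_violations
  wider <- base
  wider$non_target <- c("response", "non_target")
  v1 <- classify(g, task_rules(wider))$n_violations
  expect_lte(v1, v0)
  wider$target <- c(base$target, "response")
  v2 <- classify(g, task_rules(wider))$n_violations
  expect_lte(v2, v1)
})

test_that("tag counts tally each term path, not its ancestors", {
  sch <- mini_schema()
  ds <- hed_dataset(list(f = hed_table(1, "(Red, Triangle)")),
                    sidecar = NULL, schema = sch)
  tc <- tag_counts(ds)
  expect_identical(tc[["Red"]], 1L)
  expect_identical(tc[["2D-shape/Triangle"]], 1L)
  expect_false("2D-shape" %in% names(tc))
  # generator dataset: stimulus definition content term count equals
  # the number of stimulus rows
  s <- generate_sart(sart_config(n_trials = 40, seed = 3))
  ds2 <- hed_dataset(list(run = s$table), s$sidecar, s$schema)
  tc2 <- tag_counts(ds2)
  expect_identical(unname(tc2["Visual-presentation"]),
                   s$ground_truth$n_stimuli)
})

test_that("DOT export lists nodes and colors contraventions red", {
  s <- generate_sart(sart_config(n_trials = 120, p_false_alarm = 1,
                                 p_miss = 0, seed = 5))
  g <- transition_graph(s$table)
  dot <- write_dot(g, rules = sart_rules())
  expect_match(dot, "digraph", fixed = TRUE)
  expect_match(dot, '"target" -> "response" \\[label="\\d+", color="red"\\]')
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, f)
  expect_true(file.exists(f))
})

test_that("rules round-trip through their JSON form", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(allowed = list(a = c("a", "b"), b = "a")), f)
  r <- task_rules(f)
  expect_identical(r$allowed$a, c("a", "b"))
  expect_identical(r$allowed$b, "a")
})
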