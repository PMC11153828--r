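# Random-case generators for property-style tests. All take explicit seeds
# so failures are reproducible.

# Random tree-shaped schema document: n terms T1..Tn with random parents.
random_schema <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  nodes <- list(list(term = "T1", parent = NULL,
                     extension_allowed = TRUE, takes_value = FALSE))
  longs <- "T1"
  for (i in 2:n) {
    parent <- if (stats::runif(1) < 0.3) NULL
              else sample(longs, 1)
    term <- sprintf("T%d", i)
    long <- if (is.null(parent)) term else paste(parent, term, sep = "/")
    nodes[[i]] <- list(term = term, parent = parent,
                       extension_allowed = TRUE, takes_value = FALSE)
    longs <- c(longs, long)
  }
  load_schema(list(version = "rand", nodes = nodes))
}

# Pool of non-structural tag texts for the mini schema, some with
# extensions and values.
mini_tag_pool <- function() {
  c("Item", "Object", "Ingestible-object", "Ingestible-object/Apple",
    "Ingestible-object/Fruit/Apple", "Red", "2D-shape", "Triangle",
    "2D-shape/Star", "Triangle/Isoceles", "Label/X", "Label/Y",
    "Description/free text here")
}

# Random well-formed annotation text over a tag pool.
random_annotation_text <- function(pool = mini_tag_pool(), max_items = 4L,
                                   depth = 0L) {
  n <- sample.int(max_items, 1)
  items <- vapply(seq_len(n), function(i) {
    if (depth < 2L && stats::runif(1) < 0.35)
      paste0("(", random_annotation_text(pool, max_items, depth + 1L), ")")
    else sample(pool, 1)
  }, "")
  paste(items, collapse = ", ")
}

# Random timeline fixture with exact ground-truth intervals.
# Emits Onset/Offset chains anchored by a placeholder Def family plus some
# anonymous Duration processes; returns the assembled timeline and the
# interval table the markers were generated from.
random_timeline <- function(n_proc = 8L, seed = 1L, schema = mini_schema()) {
  set.seed(seed)
  starts <- round(stats::runif(n_proc, 0, 20), 3)
  lens <- round(stats::runif(n_proc, 0.5, 8), 3)
  ends <- starts + lens
  use_duration <- stats::runif(n_proc) < 0.4
  onsets <- numeric(0)
  heds <- character(0)
  anchors <- character(0)
  k_dur <- 0L
  for (i in seq_len(n_proc)) {
    if (use_duration[i]) {
      k_dur <- k_dur + 1L
      onsets <- c(onsets, starts[i])
      heds <- c(heds, sprintf("(Duration/%s s, (Label/D%d))",
                              format(lens[i], scientific = FALSE), i))
      anchors <- c(anchors, sprintf("duration-%d", k_dur))
    } else {
      onsets <- c(onsets, starts[i], ends[i])
      heds <- c(heds, sprintf("(Def/P/%d, Onset)", i),
                sprintf("(Def/P/%d, Offset)", i))
      anchors <- c(anchors, sprintf("p/%d", i))
    }
  }
  ord <- order(onsets)
  recording_end <- max(ends) + 1
  tl <- timeline_from(onsets[ord], heds[ord], schema,
                      definitions = "(Definition/P/#, (Label/#))",
                      recording_end = recording_end)
  list(timeline = tl,
       truth = data.frame(anchor = anchors, start = starts, end = ends,
                          stringsAsFactors = FALSE),
       recording_end = recording_end)
}

# Brute-force oracle: the multiset of ground-truth intervals covering t
# (half-open), plus the recording span. Compared as sorted "start|end"
# strings so the check is independent of process naming.
oracle_active <- function(truth, t, recording_end) {
  hit <- truth$start <= t & t < truth$end
  sort(c(sprintf("0|%g", recording_end),
         sprintf("%g|%g", truth$start[hit], truth$end[hit])))
}

context_intervals <- function(tl, t) {
  sort(vapply(context_at(tl, t),
              function(p) sprintf("%g|%g", p$onset_t, p$offset_t), ""))
}
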