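# Synthetic fixtures with exact ground truth: SART go/no-go sessions,
# canonical overlap patterns for the timeline semantics, and the small
# vocabularies they annotate against. Everything is seeded and
# deterministic, so no external data are needed for testing.

# Run code under a given seed without leaking RNG state to the caller.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' The 14-term fixture vocabulary
#'
#' A deterministic miniature schema exercising every schema feature: the
#' `Item/Object/Ingestible-object` branch (extension playground), the
#' structural tags (Duration with time units, Onset, Offset, Inset, Def,
#' Definition), the free-text value tags Label and Description, and the
#' `2D-shape/Triangle` branch used for is-a search. Returned as JSON text;
#' regeneration is byte-identical.
#'
#' @return JSON schema document (single string), loadable by
#'   [load_schema()].
#' @export
generate_mini_schema <- function() {
  nd <- function(term, parent = NULL, extension_allowed = TRUE,
                 takes_value = FALSE, unit_class = NULL) {
    x <- list(term = term, parent = parent,
              extension_allowed = extension_allowed,
              takes_value = takes_value)
    if (!is.null(unit_class)) x$unit_class <- unit_class
    x
  }
  doc <- list(
    version = "fixture-1.0.0",
    nodes = list(
      nd("Item"),
      nd("Object", "Item"),
      nd("Ingestible-object", "Item/Object"),
      nd("Duration", extension_allowed = FALSE, takes_value = TRUE,
         unit_class = "time"),
      nd("Onset", extension_allowed = FALSE),
      nd("Offset", extension_allowed = FALSE),
      nd("Inset", extension_allowed = FALSE),
      nd("Def", extension_allowed = FALSE, takes_value = TRUE),
      nd("Definition", extension_allowed = FALSE, takes_value = TRUE),
      nd("Label", takes_value = TRUE),
      nd("Description", takes_value = TRUE),
      nd("Red"),
      nd("2D-shape"),
      nd("Triangle", "2D-shape")))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"))
}

#' The task vocabulary used by the SART generator
#'
#' The 14 fixture terms plus a small perception/action branch (Event >
#' Sensory-event / Agent-action, Visual-presentation, Experiment-participant,
#' Action > Press / Move, Keyboard-key and Hand under Item/Object) and the
#' participant-trait tags Left-handed / Right-handed. Deterministic JSON
#' text.
#'
#' @return JSON schema document (single string).
#' @export
generate_task_schema <- function() {
  doc <- jsonlite::fromJSON(generate_mini_schema(), simplifyVector = FALSE)
  nd <- function(term, parent = NULL) {
    list(term = term, parent = parent, extension_allowed = TRUE,
         takes_value = FALSE)
  }
  doc$version <- "fixture-task-1.0.0"
  doc$nodes <- c(doc$nodes, list(
    nd("Event"),
    nd("Sensory-event", "Event"),
    nd("Agent-action", "Event"),
    nd("Visual-presentation"),
    nd("Experiment-participant"),
    nd("Action"),
    nd("Press", "Action"),
    nd("Move", "Action"),
    nd("Keyboard-key", "Item/Object"),
    nd("Hand", "Item/Object"),
    nd("Left-handed"),
    nd("Right-handed")))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"))
}

#' SART session configuration
#'
#' In the sustained attention response task the participant sees a random
#' succession of digit images 0–9 and presses a key after every digit
#' except the target. A false alarm is a response to the target; a miss is
#' a withheld response to a non-target.
#'
#' @param n_trials number of digit presentations (>= 1).
#' @param target_digit the no-go digit, 0–9 (the task's canonical target
#'   is 3).
#' @param p_false_alarm probability of (incorrectly) responding after a
#'   target.
#' @param p_miss probability of (incorrectly) withholding the response
#'   after a non-target.
#' @param stim_duration digit presentation time, seconds.
#' @param isi stimulus-onset asynchrony, seconds.
#' @param rt_range response-time range `(min, max)` seconds, drawn
#'   uniformly; `max` must stay below `isi` so a response precedes the next
#'   stimulus.
#' @param seed RNG seed.
#' @return a validated `sart_config` list.
#' @export
sart_config <- function(n_trials = 200L, target_digit = 3L,
                        p_false_alarm = 0.10, p_miss = 0.05,
                        stim_duration = 0.25, isi = 1.15,
                        rt_range = c(0.2, 1.0), seed = 42L) {
  stopifnot(n_trials >= 1, target_digit %in% 0:9,
            p_false_alarm >= 0, p_false_alarm <= 1,
            p_miss >= 0, p_miss <= 1,
            stim_duration > 0, isi > 0,
            length(rt_range) == 2L, rt_range[1] > 0,
            rt_range[1] <= rt_range[2], rt_range[2] < isi)
  structure(list(n_trials = as.integer(n_trials),
                 target_digit = as.integer(target_digit),
                 p_false_alarm = p_false_alarm, p_miss = p_miss,
                 stim_duration = stim_duration, isi = isi,
                 rt_range = rt_range, seed = as.integer(seed)),
            class = "sart_config")
}

sart_sidecar_doc <- function(cfg) {
  dur <- format(cfg$stim_duration, scientific = FALSE, trim = TRUE,
                drop0trailing = TRUE)
  list(
    definitions = list(
      "(Definition/Target-digit, (Sensory-event, Visual-presentation, (Label/Target)))",
      "(Definition/Nontarget-digit, (Sensory-event, Visual-presentation, (Label/Nontarget)))",
      "(Definition/Key-press, (Agent-action, (Experiment-participant, (Press, Keyboard-key))))"),
    event_type = list(HED = list(
      target = sprintf("(Def/Target-digit, Duration/%s s)", dur),
      non_target = sprintf("(Def/Nontarget-digit, Duration/%s s)", dur),
      response = "Def/Key-press")),
    digit = list(HED = "Label/#"))
}

#' Generate a synthetic SART session
#'
#' Digits are drawn i.i.d. uniformly over 0–9; each stimulus row is labeled
#' `target` or `non_target`; response rows are inserted at stimulus onset
#' plus a uniform response time, with the configured false-alarm and miss
#' probabilities. The sidecar annotates stimuli with a Def + Duration
#' pattern and responses with an agent-action definition. Identical seeds
#' give byte-identical event tables.
#'
#' @param cfg a [sart_config()].
#' @return list with `table` (an `event_table` with columns onset,
#'   duration, event_type, digit, trial), `sidecar` (`hed_sidecar`),
#'   `sidecar_doc` (JSON-able list), `schema` (task schema JSON text), and
#'   `ground_truth` (counts and the per-trial record).
#' @export
generate_sart <- function(cfg = sart_config()) {
  stopifnot(inherits(cfg, "sart_config"))
  n <- cfg$n_trials
  res <- local_seed(cfg$seed, {
    digits <- sample(0:9, n, replace = TRUE)
    u <- stats::runif(n)
    rt <- stats::runif(n, cfg$rt_range[1], cfg$rt_range[2])
    list(digits = digits, u = u, rt = rt)
  })
  is_target <- res$digits == cfg$target_digit
  responded <- ifelse(is_target, res$u < cfg$p_false_alarm,
                      res$u >= cfg$p_miss)
  onsets <- (seq_len(n) - 1) * cfg$isi

  stim <- data.frame(
    onset = onsets,
    duration = cfg$stim_duration,
    event_type = ifelse(is_target, "target", "non_target"),
    digit = as.character(res$digits),
    trial = seq_len(n),
    stringsAsFactors = FALSE)
  resp <- data.frame(
    onset = onsets[responded] + res$rt[responded],
    duration = NA_real_,
    event_type = "response",
    digit = "n/a",
    trial = which(responded),
    stringsAsFactors = FALSE)
  tab <- rbind(stim, resp)
  tab$duration <- ifelse(is.na(tab$duration), "n/a",
                         format(tab$duration, scientific = FALSE,
                                trim = TRUE, drop0trailing = TRUE))
  tab$onset <- round(tab$onset, 6)
  table <- as_event_table(tab, source_path = sprintf("sart-seed%d", cfg$seed))

  trials <- data.frame(
    trial = seq_len(n), digit = res$digits, is_target = is_target,
    responded = responded,
    correct = (is_target & !responded) | (!is_target & responded))
  gt <- list(n_stimuli = n, n_responses = sum(responded),
             n_false_alarms = sum(is_target & responded),
             n_misses = sum(!is_target & !responded),
             n_targets = sum(is_target),
             n_non_targets = sum(!is_target),
             trials = trials)
  doc <- sart_sidecar_doc(cfg)
  list(table = table, sidecar = read_sidecar(doc), sidecar_doc = doc,
       schema = generate_task_schema(), ground_truth = gt)
}

#' The SART task instructions as a transition rule set
#'
#' A target must not be followed by a response (false alarm); a non-target
#' must be followed by a response before the next stimulus (anything else
#' is a miss); a response is followed by the next stimulus.
#'
#' @return a `task_rules` object.
#' @export
sart_rules <- function() {
  task_rules(list(target = c("target", "non_target"),
                  non_target = "response",
                  response = c("target", "non_target")))
}

#' Canonical overlap fixtures for timeline semantics
#'
#' Emits a small events table, its sidecar, and the exact expected process
#' list for one of the canonical patterns:
#'
#' * `duration_overlap` — three anonymous Duration processes, two overlapping;
#' * `onset_chain` — three temporally contiguous same-type processes
#'   opened by repeated `(Def/A, ..., Onset)` groups and closed by an
#'   Offset;
#' * `inset_phases` — the same span annotated as one process with two Inset
#'   phase transitions;
#' * `nested_overlap` — processes B and C overlapping inside process A (with
#'   the Recording process encompassing all).
#'
#' @param pattern one of the four pattern names.
#' @return list with `table` (`event_table` with a literal HED column),
#'   `sidecar` (`hed_sidecar` carrying the definitions), `schema` (the
#'   fixture schema JSON), `expected` (data frame anchor/onset/offset),
#'   `expected_insets` (numeric), and `recording_end`.
#' @export
generate_overlap_fixture <- function(pattern = c("duration_overlap",
                                                 "onset_chain",
                                                 "inset_phases",
                                                 "nested_overlap")) {
  pattern <- match.arg(pattern)
  defs <- list()
  if (pattern == "duration_overlap") {
    rows <- data.frame(
      onset = c(1, 4, 5), duration = "n/a",
      HED = c("(Duration/2 s, (Label/P1))",
              "(Duration/3 s, (Label/P2))",
              "(Duration/4 s, (Label/P3))"),
      stringsAsFactors = FALSE)
    expected <- data.frame(anchor = c("duration-1", "duration-2", "duration-3"),
                           onset = c(1, 4, 5), offset = c(3, 7, 9))
    insets <- numeric(0)
  } else if (pattern == "onset_chain") {
    defs <- list("(Definition/A, (Label/Chain))")
    rows <- data.frame(
      onset = c(1, 3, 5, 7), duration = "n/a",
      HED = c("(Def/A, (Label/X), Onset)",
              "(Def/A, (Label/Y), Onset)",
              "(Def/A, (Label/Z), Onset)",
              "(Def/A, Offset)"),
      stringsAsFactors = FALSE)
    expected <- data.frame(anchor = rep("a", 3),
                           onset = c(1, 3, 5), offset = c(3, 5, 7))
    insets <- numeric(0)
  } else if (pattern == "inset_phases") {
    defs <- list("(Definition/A, (Label/Scene))")
    rows <- data.frame(
      onset = c(1, 3, 5, 7), duration = "n/a",
      HED = c("(Def/A, (Label/X), Onset)",
              "(Def/A, Inset)",
              "(Def/A, Inset)",
              "(Def/A, Offset)"),
      stringsAsFactors = FALSE)
    expected <- data.frame(anchor = "a", onset = 1, offset = 7)
    insets <- c(3, 5)
  } else {
    defs <- list("(Definition/A, (Label/Outer))",
                 "(Definition/B, (Label/InnerB))",
                 "(Definition/C, (Label/InnerC))")
    rows <- data.frame(
      onset = c(1, 2, 4, 6, 8, 9), duration = "n/a",
      HED = c("(Def/A, Onset)", "(Def/B, Onset)", "(Def/C, Onset)",
              "(Def/B, Offset)", "(Def/C, Offset)", "(Def/A, Offset)"),
      stringsAsFactors = FALSE)
    expected <- data.frame(anchor = c("a", "b", "c"),
                           onset = c(1, 2, 4), offset = c(9, 6, 8))
    insets <- numeric(0)
  }
  table <- as_event_table(rows, source_path = pattern)
  list(table = table,
       sidecar = read_sidecar(list(definitions = defs)),
       schema = generate_mini_schema(),
       expected = expected, expected_insets = insets,
       recording_end = 10)
}
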