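Package: hedline
Title: Hierarchical Event Descriptors and Event-in-Context Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An engine for annotating and analyzing events in time-series
    neuroimaging recordings using hierarchical controlled vocabularies
    (Hierarchical Event Descriptors, HED). Loads and merges tree-structured
    tag vocabularies, parses comma/parenthesis tag strings, assembles
    temporally extended event processes from onset/offset/inset/duration
    phase markers in BIDS-style events.tsv files with JSON sidecars, derives
    the ongoing and recording context active at any time point, supports
    abstraction-aware (is-a) search and factor-vector extraction, and
    summarizes event-marker successions as transition graphs scored against
    task rules. Includes a synthetic SART (sustained attention response
    task) session generator with exact ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
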