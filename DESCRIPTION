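Package: taskherd
Title: Declarative Workflow Engine with Replicate Expansion and Recoverable Scheduling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow management engine for command-line analysis pipelines.
    Reusable task modules wrap one program each with typed parameter
    declarations; workflows are written in a small XML dialect with constants,
    executor declarations and process blocks that expand replicate data
    (numeric sequences, folder globs, sample-sheet tables, upstream return
    values) into subtasks. A dependency-aware scheduler enforces per-task and
    per-executor concurrency limits, checkpoints and scope filters, drives a
    recoverable task lifecycle state machine (restart, modify-and-restart,
    ignore, manual resolution), and supports resuming finished work from a
    journal. Executors are pluggable: a real local process-pool executor and a
    deterministic virtual-time executor for testing and dry runs are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    igraph,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    parallel,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
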