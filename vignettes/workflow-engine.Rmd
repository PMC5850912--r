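---
title: "Inside the taskherd workflow engine: model, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside the taskherd workflow engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskherd)
```

## The execution model

taskherd separates *what* a pipeline step does from *when and where* it
runs. A **module** is a typed wrapper around one command-line program; a
**workflow** is a DAG of tasks, each referencing a module and a parameter
assignment; the **scheduler** expands each task into subtasks (one per
process-block instance), resolves dependencies, and hands resolved command
invocations to an **executor**.

The core assumption is that every step is an ordinary child process judged
by its exit code and its file-system effects. The engine does not inspect a
tool's semantics; everything it knows about a step comes from the module
descriptor (parameter types, return parameters), the exit code, the
optional result checkers, and the `key<TAB>value` return file the process
may write to the path in `$TASKHERD_RETURN_FILE`.

### Subtask lifecycle

Every subtask is in exactly one state: `PENDING` → `READY` →
(`HELD_RESOURCE` | `HELD_CHECKPOINT`)\* → `RUNNING` → `SUCCEEDED` or
`FAILED_AWAITING_USER`, with the user actions *restart*,
*modify-and-restart* (attempt counter incremented, command re-rendered),
*ignore* (`IGNORED`) and *manual resolve* (`RESOLVED_MANUAL`). All other
transitions are rejected. Two invariants matter downstream: return values
exist only in terminal-successful states, and a subtask's resolved argv is
fixed at launch (so the resume journal can key on it).

A deliberate failure-policy choice: a failed subtask blocks **only its
forward dependency cone**. Independent tasks keep being scheduled, so one
corrupt sample does not stall a 100-sample run; the affected cone waits for
a user action.

### Dependencies and pipelining

Task-level dependencies are barriers: the dependent waits for *every*
subtask of the upstream task. Subtask-level (`separate="true"`)
dependencies match by subtask index: subtask *x* waits only for upstream
subtask *x*. Input process blocks are expanded *incrementally* when their
(single) dependency is subtask-level: as soon as upstream subtask *x*
succeeds and exposes return values, downstream subtask *x* is created and
may launch while upstream siblings still run. With `compareByIndex`, an
input block may join several subtask-level dependencies by equal index
(variable sets must not collide); otherwise exactly one input dependency is
required — how to join several without a key is ambiguous, so the parser
treats it as an error rather than guessing.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `maxRunning` | task | unlimited | concurrent subtasks of this task |
| `maxSlots` | executor | 1 | concurrent subtasks on this executor |
| `hosts`, `slotsPerHost` | virtual executor | 1, `maxSlots` | simulated topology |
| `slaveMode` | virtual executor | off | pin dependent subtasks to one host |
| `checkpoint` | task | off | hold dependents until released |
| `step` | sequence block | 1 | increment between instance values |
| `duration_of` | virtual config | 1.0 (virtual time units) | scripted runtime per subtask |

When no executor is declared, a single-slot local executor is assumed —
tasks then run one after another, which is the least surprising default for
a workflow that declares nothing about parallelism.

## Determinism

Execution order among simultaneously launchable subtasks is, semantically,
unspecified. The implementation nevertheless makes every run deterministic
— launch order is ascending (task id, subtask index), virtual hosts are
assigned lowest-free-index-first, simultaneous virtual completions are
processed in key order, and folder-block instances are sorted
lexicographically by path. This is an implementation policy, not an API
guarantee: it exists so that a trace can be compared byte-for-byte in
tests, and callers must not depend on it. The same reasoning fixed the
virtual executor's host choice (lowest free index) where a real distributed
back-end would distribute randomly.

Virtual time is event-driven: the clock jumps to the earliest pending
completion, so durations are exact rationals of the scripted values and
equality comparisons on trace times are safe up to a `1e-12` tie tolerance
used when several completions coincide.

## Numerical and degenerate-input choices

* Sequence blocks compute their length as `floor((end − start)/step) + 1`
  with a `1e-9` guard against floating-point undershoot; integral values
  are formatted without a decimal point so they are usable in file names.
  A zero step, or a step pointing away from `end`, is an error; `start ==
  end` yields a singleton.
* An empty folder match or a header-only table is a *warning plus an empty
  expansion*, not an error — a legitimate state for a workflow whose inputs
  appear later. A ragged table row or duplicate column is an error.
* Placeholder substitution never re-scans substituted text, so it is
  idempotent; `[k]` with fewer than `k` dot-suffixes is an error rather
  than a silent no-op.
* Constant references may chain (`${A}` → `${B}`) to depth 10; deeper
  chains are reported as self-referential.
* A run that can make no progress — nothing running, nothing launchable,
  and at least one non-terminal subtask *not* explained by a failure cone
  or a pending user action — is reported as a **deadlock with the blocked
  set**, instead of hanging. The common cause is an unreleased checkpoint
  in a headless run; attaching a handler (or `--disable-checkpoints` /
  `--auto-release-checkpoints` on the CLI) resolves it.

## Error judgment

The exit code gives the base verdict (only 0 is success). Checkers are then
evaluated in declaration order; each is a registered predicate constructed
from typed XML arguments and votes on the subtask's artifacts (stdout,
stderr, return file). One error vote — or a nonzero exit — makes the final
verdict a failure even when success was also detected; success checkers can
therefore never veto a failure, and only error-kind checkers can overturn
an exit-0 run. Checker order affects message order only. A checker that
cannot be instantiated counts as an error vote carrying the message, on the
grounds that an unverifiable result should not pass silently. Checkers are
looked up in a name→factory registry rather than loaded from compiled class
files; that keeps the mechanism portable and testable, at the cost of
requiring checkers to be registered before the run.

## The monitoring surface

The status/action interface is an in-process handle (`serve_status()`)
speaking JSON request/response: a snapshot endpoint (per-subtask rows plus
counters that always equal the row tallies) and an action endpoint
accepting the four recovery actions plus checkpoint and resource-hold
releases. Actions are idempotent under redelivery; unknown subtasks and
state-illegal actions return HTTP-style 404/409 error objects. Binding this
handle to an actual socket transport is deliberately left to the embedding
application — the engine's interaction contract is the handle, and every
recovery path is reachable headlessly through it (the test suite drives all
four actions this way).

## What the synthetic scenarios emulate — and what they do not

The bundled scenarios (`emit_scenario()`) are generated, self-contained
folders: workflow XML, module scripts using only `sh`, `awk`, `gzip`,
`cat`, and deterministic data (pseudo-random log files; gzipped FASTQ-like
files with exact record counts, random DNA and uniform qualities). They
emulate the *control-flow shapes* of real pipelines — replicate fan-out,
per-sample pipelining, barriers, concurrency caps (the extract/merge
example keeps sequence extraction serial and allows four concurrent header
extractions), failure and recovery. They do **not** emulate real data
properties: no read-quality model, no alignment, no tool-specific failure
modes, and runtimes in the seconds range. A passing suite therefore
demonstrates scheduling and recovery semantics, not the behaviour of any
particular bioinformatics tool stack. Test problem sizes were chosen small
(≤ 6 tasks, ≤ 5 instances per block, ≤ 50 reads per sample) because every
engine behaviour under test is size-invariant; the randomized property
suites cover the combinatorics.

## Other design decisions

* **Argv convention.** Modules receive parameters as GNU-style `--name
  value` pairs in descriptor declaration order (flags bare, multi-valued
  parameters repeated). Rendering order is independent of assignment-map
  order, so identical assignments always produce identical commands.
* **Return-value transport.** A per-subtask TSV file whose path is exported
  as `$TASKHERD_RETURN_FILE`. A file (rather than stdout parsing) keeps the
  channel available to programs whose stdout is meaningful output.
* **Journal matching.** Resume entries are keyed by (task, subtask, MD5 of
  the rendered argv). Matching on the command rather than on completion
  alone means an edited parameter invalidates exactly the affected
  subtasks.
* **Modify-and-restart re-renders from scratch** from the edited assignment
  map instead of patching the previous argv — simpler to reason about, and
  it guarantees the journal key changes iff the command changed.
* **Scope filters** (`--start`, `--stop`, `--include`, `--exclude`) select
  tasks by position in the dependency partial order; dependencies on
  inactive tasks count as satisfied, which is what makes "start in the
  middle" useful when upstream outputs already exist.
* **CLI exit statuses** are 0 (all successful), 1 (completed with failed or
  ignored subtasks, or deadlocked) and 2 (invalid input); the convention is
  this package's own.

## Known limitations

* SSH and DRMAA/Slurm executors are interface stubs: their declarations
  parse and dry-run, but launching on them raises "not configured".
* Task actions operate on the local file system only; remote file systems
  (HTTP/FTP/SFTP) are out of scope.
* Folder blocks do not recurse and patterns are globs, not regexes; tables
  must be TSV with a header row.
* No priorities, preemption, or wall-clock/memory quota enforcement; caps
  are slot counts only.
* The local executor relies on process forking (base R `parallel`), so
  true concurrency is available on Unix-alikes only.
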