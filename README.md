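# taskherd

A workflow management engine for command-line analysis pipelines, written in
R. It is aimed at bioinformaticians (and anyone else who chains shell tools
over replicated samples) who want three things a plain script does not give
them: declarative replicate handling, dependency-aware parallel scheduling
with resource limits, and recoverable error handling — restart a failed step
with edited parameters instead of re-running the whole analysis.

## The model

A pipeline is split into three layers:

* **Modules** wrap one command-line program each. A module descriptor
  declares the command and its typed parameters — name, type (string,
  integer, double, file, folder, flag, enum), requiredness, numeric ranges,
  occurrence bounds — plus optional *return parameters* the program can
  expose to downstream steps by writing a `key<TAB>value` file to
  `$TASKHERD_RETURN_FILE`. Parameter values are validated before anything
  runs; valid assignments render deterministically to GNU-style argv
  (`--name value`, bare `--name` for flags).

* **Workflows** are XML documents: a `settings` block (constants referenced
  as `${NAME}`, executor declarations, process blocks, extra module folders)
  and one element per task, named after its module. Tasks declare parameter
  templates, dependencies (by task id or name), per-task concurrency caps
  (`maxRunning`), checkpoints, stream redirects, environment variables,
  file-system task actions and custom result checkers.

* **Process blocks** turn replicate data into *instances* — one variable
  binding per replicate — and the engine spawns one *subtask* per instance.
  Four block types are built in: numeric sequences (a declarative for-loop),
  folder globs (one instance per matching file), tab-separated sample tables
  (one instance per row, variables named by the header) and *input blocks*
  fed by the return values of an upstream task's subtasks. Templates refer
  to instance variables with `{}` (the full value), `[k]` (the file name
  with the last `k` suffixes stripped) and `{$var}` (a named table/input
  variable).

The scheduler expands tasks, resolves dependencies — task-level (wait for
*all* upstream subtasks) or subtask-level (`separate="true"`: subtask *x*
waits only for upstream subtask *x*, enabling per-sample pipelining) —
enforces per-task and per-executor slot caps and checkpoint barriers, and
drives each subtask through a lifecycle state machine. A failed subtask
(nonzero exit, or a vote from an ordered list of success/error checkers;
mixed votes count as failure) waits for one of four user actions: restart,
modify parameters and restart, ignore (its dependents never run; everything
else continues), or resolve manually with user-supplied return values.
Executors are pluggable: a local process pool, a deterministic virtual-time
executor for dry runs and tests (with slave-mode host affinity for dependent
subtasks), and declared-but-stubbed SSH/DRMAA/Slurm types. A resume journal
lets a rerun replay finished subtasks — keyed by the rendered command, so
edited parameters force re-execution.

## A worked example

Compress every log file in a folder, at most two at a time:

```r
library(taskherd)

dir <- file.path(tempdir(), "demo")
emit_scenario("compress_logs", dir, n = 5)   # workflow + modules + 5 log files

reg  <- module_registry(file.path(dir, "modules"))
spec <- parse_workflow(file.path(dir, "workflow.xml"), reg)
spec
#> <workflow: 1 task(s), 0 constant(s), 1 block(s), 1 executor(s)>
#>   [1] compress (compressTask) block=logFiles

run <- run_workflow(spec, reg)
run
#> <workflow run: status 0; 5 subtask(s), 5 succeeded, 0 failed, 0 ignored>

tidy(run)
#> # A tibble: 5 × 7
#>   task_id subtask_index module       state     attempt host      exit_code
#>     <int>         <int> <chr>        <chr>       <int> <chr>         <int>
#> 1       1             1 compressTask SUCCEEDED       1 localhost         0
#> 2       1             2 compressTask SUCCEEDED       1 localhost         0
#> 3       1             3 compressTask SUCCEEDED       1 localhost         0
#> 4       1             4 compressTask SUCCEEDED       1 localhost         0
#> 5       1             5 compressTask SUCCEEDED       1 localhost         0
```

The folder block produced five instances, so the task ran as five subtasks;
`status 0` means every subtask finished successfully; each `.log` file now
has a `.gz` sibling under `out/`. `run$trace` holds the full event trace
(launches, holds, completions, per-event host) as a tibble, `glance(run)`
a one-row summary, and `autoplot(run)` a Gantt-style view of it. The same
workflow runs from a shell via the bundled CLI (`inst/cli/taskherd`):

```sh
taskherd run demo/workflow.xml        # exit 0 on success
taskherd check demo/workflow.xml      # static validation only
taskherd scaffold-module myTool --param input:file:required
```

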