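# Test helpers: build tiny module registries and workflow files in code.

# a module folder with an echo-style module taking one multi-valued string
# parameter; returns declared so it can feed input blocks
make_echo_registry <- function(dir = tempfile("mods_")) {
  dir.create(file.path(dir, "echoTask"), recursive = TRUE)
  writeLines(c(
    '<module name="echoTask" command="echoTask.sh">',
    '  <param name="text" type="string" required="true" maxOccurs="4"/>',
    '  <return name="out" type="string"/>',
    '</module>'
  ), file.path(dir, "echoTask", "echoTask.module.xml"))
  writeLines(c(
    "#!/bin/sh", "set -eu",
    "while [ $# -gt 0 ]; do case \"$1\" in",
    "  --text) printf '%s\\n' \"$2\"; shift 2 ;;",
    "  *) exit 64 ;;",
    "esac; done",
    "printf 'out\\tdone\\n' > \"$TASKHERD_RETURN_FILE\""
  ), file.path(dir, "echoTask", "echoTask.sh"))
  Sys.chmod(file.path(dir, "echoTask", "echoTask.sh"), "755")
  module_registry(dir, include_builtin = FALSE)
}

# write a workflow file from raw task XML snippets
write_workflow <- function(tasks_xml, settings_xml = "", path = tempfile(fileext = ".xml")) {
  writeLines(paste0(
    "<workflow><settings>",
    '<executors><executor name="v" type="virtual" maxSlots="8" default="true"/></executors>',
    settings_xml,
    "</settings><tasks>", tasks_xml, "</tasks></workflow>"
  ), path)
  path
}

echo_task_xml <- function(id, name = paste0("t", id), deps = integer(0),
                          separate = FALSE, block = NULL, text = "x",
                          extra_attrs = "", checkpoint = FALSE) {
  dep_xml <- if (length(deps)) {
    paste0("<dependencies>",
           paste(sprintf('<depends%s>%s</depends>',
                         if (separate) ' separate="true"' else "", deps),
                 collapse = ""),
           "</dependencies>")
  } else ""
  sprintf('<echoTask id="%d" name="%s"%s%s%s><parameter><text>%s</text></parameter>%s</echoTask>',
          id, name,
          if (!is.null(block)) sprintf(' processBlock="%s"', block) else "",
          if (checkpoint) ' checkpoint="true"' else "",
          extra_attrs, text, dep_xml)
}

# deterministic random DAG workflow over echoTask with sequence blocks;
# returns list(spec, registry, expected) where expected is the brute-force
# multiset of argv (computed independently of the engine: plain loops + gsub)
random_workflow <- function(n_tasks, seed) {
  set.seed(seed)
  reg <- make_echo_registry()
  blocks <- character(0)
  tasks <- character(0)
  expected <- character(0)
  block_values <- list()
  for (i in seq_len(n_tasks)) {
    n_inst <- sample(1:4, 1)
    use_block <- n_inst > 1 || stats::runif(1) < 0.5
    bname <- sprintf("b%d", i)
    if (use_block) {
      start <- sample(0:5, 1)
      step <- sample(1:3, 1)
      end <- start + step * (n_inst - 1)
      blocks <- c(blocks, sprintf(
        '<processSequence name="%s" start="%d" end="%d" step="%d"/>',
        bname, start, end, step))
      block_values[[bname]] <- as.character(seq(start, end, by = step))
    }
    deps <- if (i > 1) sample(seq_len(i - 1), sample(0:min(2, i - 1), 1)) else integer(0)
    tasks <- c(tasks, echo_task_xml(
      i, deps = deps, block = if (use_block) bname,
      text = if (use_block) "v{}" else paste0("c", i)))
    # independent expected argv: one per instance, '--text' rendering
    vals <- if (use_block) paste0("v", block_values[[bname]]) else paste0("c", i)
    mod_dir <- file.path(reg$folders[[1L]], "echoTask")
    exe <- file.path(normalizePath(mod_dir), "echoTask.sh")
    expected <- c(expected, unname(vapply(vals, function(v)
      paste(exe, "--text", v), character(1))))
  }
  path <- write_workflow(paste(tasks, collapse = ""),
                         paste0("<processBlock>", paste(blocks, collapse = ""),
                                "</processBlock>"))
  list(spec = parse_workflow(path, reg), registry = reg, expected = sort(expected))
}

run_argv_multiset <- function(run) {
  executed <- Filter(function(r) !is.null(r$resolved_argv) &&
                       r$state == "SUCCEEDED", run$records)
  sort(unname(vapply(executed, function(r)
    paste(r$resolved_argv, collapse = " "), character(1))))
}

# maximum number of simultaneously RUNNING subtasks in a trace, optionally
# restricted to one task
max_concurrency <- function(trace, task_id = NULL) {
  tr <- trace[trace$transition %in% c("RUNNING", "SUCCEEDED",
                                      "FAILED_AWAITING_USER"), ]
  if (!is.null(task_id)) tr <- tr[tr$task_id == task_id, ]
  if (nrow(tr) == 0L) return(0L)
  delta <- ifelse(tr$transition == "RUNNING", 1L, -1L)
  # at equal times, completions are processed before launches in the engine
  ord <- order(tr$time, delta)
  max(cummax(cumsum(delta[ord])))
}
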