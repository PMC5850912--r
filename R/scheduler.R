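#' Task lifecycle state machine
#'
#' Every subtask moves through a fixed set of states:
#' `PENDING` (dependencies unresolved) -> `READY` -> `RUNNING` ->
#' `SUCCEEDED` or `FAILED_AWAITING_USER`. A ready subtask can instead be
#' parked in `HELD_RESOURCE` (concurrency cap reached) or `HELD_CHECKPOINT`
#' (upstream checkpoint not yet released). A failed subtask waits for one of
#' four user actions: restart, modify parameters and restart (attempt count
#' incremented, command re-rendered), ignore (`IGNORED`: dependents never
#' run, everything else continues), or manual resolution
#' (`RESOLVED_MANUAL`: user-supplied return values feed downstream input
#' blocks). `SUCCEEDED`, `IGNORED`, `RESOLVED_MANUAL` and `EXCLUDED` are
#' terminal.
#'
#' @name task_lifecycle
NULL

TERMINAL_STATES <- c("SUCCEEDED", "IGNORED", "RESOLVED_MANUAL", "EXCLUDED")
SUCCESS_STATES <- c("SUCCEEDED", "RESOLVED_MANUAL")

.transition_table <- list(
  PENDING = c(ready = "READY", exclude = "EXCLUDED",
              replay = "SUCCEEDED", replay_manual = "RESOLVED_MANUAL"),
  READY = c(launch = "RUNNING", hold = "HELD_RESOURCE",
            hold_checkpoint = "HELD_CHECKPOINT"),
  HELD_RESOURCE = c(release = "READY", launch = "RUNNING"),
  HELD_CHECKPOINT = c(release = "READY", launch = "RUNNING"),
  RUNNING = c(succeed = "SUCCEEDED", fail = "FAILED_AWAITING_USER"),
  FAILED_AWAITING_USER = c(user_restart = "READY",
                           user_modify_restart = "READY",
                           user_ignore = "IGNORED",
                           user_resolve = "RESOLVED_MANUAL")
)

new_subtask_record <- function(task_id, subtask_index, instance = NULL,
                               state = "PENDING") {
  structure(list(
    task_id = as.integer(task_id), subtask_index = as.integer(subtask_index),
    instance = instance, state = state, resolved_argv = NULL,
    exit_code = NULL, return_values = character(0), attempt = 1L,
    host = NULL, messages = character(0), resource_hold_released = FALSE
  ), class = "subtask_record")
}

#' Apply a lifecycle event to a subtask record
#'
#' The only way a record changes state; illegal events for the current state
#' raise an error.
#'
#' @param record A subtask record.
#' @param event One of `ready`, `launch`, `hold`, `hold_checkpoint`,
#'   `release`, `succeed`, `fail`, `user_restart`, `user_modify_restart`,
#'   `user_ignore`, `user_resolve`, `exclude`, `replay`, `replay_manual`.
#' @param ... Event payload: `argv`/`host` for launch, `exit_code` and
#'   `return_values` for succeed, `exit_code`/`messages` for fail,
#'   `assignments` for modify-restart, `return_values` for resolve/replay.
#' @return The updated record.
#' @export
apply_transition <- function(record, event, ...) {
  payload <- list(...)
  allowed <- .transition_table[[record$state]]
  if (is.null(allowed) || !event %in% names(allowed)) {
    th_abort(sprintf("illegal transition: subtask %s in state %s cannot take event '%s'",
                     subtask_key(record$task_id, record$subtask_index),
                     record$state, event),
             "taskherd_state_error")
  }
  record$state <- allowed[[event]]
  switch(event,
    launch = {
      if (!is.null(payload$argv)) record$resolved_argv <- payload$argv
      record$host <- payload$host %||% record$host
    },
    succeed = {
      record$exit_code <- as.integer(payload$exit_code %||% 0L)
      record$return_values <- payload$return_values %||% character(0)
    },
    fail = {
      record$exit_code <- as.integer(payload$exit_code %||% -1L)
      record$messages <- c(record$messages, payload$messages %||% character(0))
      record$return_values <- character(0)
    },
    user_restart = {
      record$attempt <- record$attempt + 1L
      record$exit_code <- NULL
      record$messages <- character(0)
    },
    user_modify_restart = {
      record$attempt <- record$attempt + 1L
      record$exit_code <- NULL
      record$messages <- character(0)
      record$modified_assignments <- payload$assignments
    },
    user_resolve = ,
    replay_manual = {
      record$return_values <- unlist(payload$return_values %||% character(0))
    },
    replay = {
      record$return_values <- unlist(payload$return_values %||% character(0))
      record$exit_code <- 0L
    },
    NULL
  )
  record
}

#' Scope filter for partial workflow execution
#'
#' Restricts a run to part of the workflow: start execution at a task (it
#' and everything downstream), stop after a task (it and everything
#' upstream), and explicitly include or exclude individual tasks.
#' Dependencies of active tasks on inactive tasks count as satisfied.
#'
#' @param start,stop Optional task references (id or name).
#' @param include,exclude Character vectors of task references (disjoint).
#' @param disable_checkpoints When TRUE, checkpoints never hold anything.
#' @return A `scope_filter` object.
#' @export
scope_filter <- function(start = NULL, stop = NULL, include = character(0),
                         exclude = character(0), disable_checkpoints = FALSE) {
  if (length(intersect(include, exclude)) > 0L) {
    th_abort("include and exclude lists must be disjoint", "taskherd_scope_error")
  }
  structure(list(start = start, stop = stop, include = include,
                 exclude = exclude,
                 disable_checkpoints = isTRUE(disable_checkpoints)),
            class = "scope_filter")
}

#' Build the task dependency graph
#'
#' Nodes are task ids, edges the declared dependencies (upstream ->
#' downstream). The initial frontier is the set of tasks with no incoming
#' edges.
#'
#' @param spec A `workflow_spec`.
#' @return An igraph object with a `frontier` attribute (integer task ids).
#' @export
build_graph <- function(spec) {
  g <- task_graph(spec)
  if (!igraph::is_dag(g)) {
    th_abort("dependency cycle among tasks", "taskherd_parse_error")
  }
  frontier <- as.integer(igraph::V(g)$name[igraph::degree(g, mode = "in") == 0])
  attr(g, "frontier") <- sort(frontier)
  g
}

#' Compute the active task set under a scope filter
#'
#' @param spec A `workflow_spec`.
#' @param filter A [scope_filter()].
#' @return Sorted integer vector of active task ids.
#' @export
apply_scope <- function(spec, filter = scope_filter()) {
  g <- build_graph(spec)
  ids <- as.integer(igraph::V(g)$name)
  active <- ids
  ref_id <- function(ref) resolve_task_ref(spec, ref)$id
  if (!is.null(filter$start)) {
    s <- ref_id(filter$start)
    down <- igraph::subcomponent(g, as.character(s), mode = "out")
    active <- intersect(active, as.integer(names(down)))
  }
  if (!is.null(filter$stop)) {
    s <- ref_id(filter$stop)
    up <- igraph::subcomponent(g, as.character(s), mode = "in")
    active <- intersect(active, as.integer(names(up)))
  }
  if (length(filter$exclude)) {
    active <- setdiff(active, vapply(filter$exclude, ref_id, integer(1)))
  }
  if (length(filter$include)) {
    active <- union(active, vapply(filter$include, ref_id, integer(1)))
  }
  sort(active)
}

# ---- engine ----------------------------------------------------------------

task_assignments <- function(task, instance = NULL) {
  asn <- list()
  for (p in task$parameters) {
    v <- p$value
    if (!is.null(instance)) v <- substitute_placeholders(v, instance)
    asn[[p$name]] <- c(asn[[p$name]], v)
  }
  asn
}

engine_new <- function(spec, registry, filter, virtual_config, dry_run,
                       resume_journal, scratch_dir, handler) {
  eng <- new.env(parent = emptyenv())
  eng$spec <- resolve_constants(spec)
  eng$registry <- registry
  eng$filter <- filter
  eng$dry_run <- isTRUE(dry_run)
  eng$scratch <- scratch_dir
  dir.create(file.path(scratch_dir, "streams"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(scratch_dir, "returns"), recursive = TRUE, showWarnings = FALSE)
  eng$handler <- handler
  eng$journal_path <- resume_journal
  eng$journal <- load_journal(resume_journal)
  eng$records <- list()
  eng$trace <- list()
  eng$log <- character(0)
  eng$released_checkpoints <- integer(0)
  eng$launch_count <- 0L
  eng$spawned <- 0L

  eng$wf_dir <- if (!is.null(spec$source_path)) {
    dirname(normalizePath(spec$source_path, mustWork = FALSE))
  } else getwd()

  eng$active <- apply_scope(spec, filter)
  eng$graph <- build_graph(spec)

  eng$executors <- list()
  for (decl in eng$spec$executors) {
    eng$executors[[decl$name]] <- make_executor(decl, virtual_config, dry_run)
  }
  default_name <- names(eng$spec$executors)[vapply(eng$spec$executors, `[[`,
                                                   logical(1), "default")][1]
  eng$default_executor <- default_name

  eng$tasks <- list()
  for (t in eng$spec$tasks) {
    mod <- if (!is.null(registry)) registry_lookup(registry, t$module_ref)
    eng$tasks[[as.character(t$id)]] <- list(
      spec = t, module = mod, expanded = FALSE,
      active = t$id %in% eng$active,
      executor = t$executor_ref %||% default_name,
      input_indices_done = integer(0)
    )
    if (!t$id %in% eng$active) {
      key <- subtask_key(t$id, 0L)
      rec <- new_subtask_record(t$id, 0L)
      eng$records[[key]] <- apply_transition(rec, "exclude")
      trace_event(eng, 0, t$id, 0L, "EXCLUDED", NULL)
    }
  }
  eng
}

trace_event <- function(eng, time, task_id, subtask_index, transition, host) {
  last <- if (length(eng$trace)) eng$trace[[length(eng$trace)]]$time else 0
  eng$trace[[length(eng$trace) + 1L]] <- list(
    time = max(time, last), task_id = as.integer(task_id),
    subtask_index = as.integer(subtask_index), transition = transition,
    host = host %||% NA_character_
  )
  invisible(NULL)
}

eng_log <- function(eng, msg) {
  eng$log <- c(eng$log, msg)
  invisible(NULL)
}

task_entry <- function(eng, id) eng$tasks[[as.character(id)]]

task_records <- function(eng, id) {
  ks <- names(eng$records)
  sel <- vapply(eng$records, function(r) r$task_id == id, logical(1))
  eng$records[ks[sel]]
}

dep_targets <- function(eng, task) {
  lapply(task$dependencies, function(d) {
    list(task = resolve_task_ref(eng$spec, d$target), separate = d$separate)
  })
}

task_finished_successfully <- function(eng, id) {
  te <- task_entry(eng, id)
  if (!te$active) return(TRUE)  # inactive dependency counts as satisfied
  if (!te$expanded) return(FALSE)
  recs <- task_records(eng, id)
  length(recs) > 0L && all(vapply(recs, function(r) r$state %in% SUCCESS_STATES,
                                  logical(1)))
}

checkpoint_open <- function(eng, dep_task) {
  # is the upstream checkpoint (if any) passable?
  if (!dep_task$checkpoint || eng$filter$disable_checkpoints) return(TRUE)
  if (!task_entry(eng, dep_task$id)$active) return(TRUE)
  dep_task$id %in% eng$released_checkpoints
}

subtask_dep_ok <- function(eng, dep_task, index) {
  te <- task_entry(eng, dep_task$id)
  if (!te$active) return(TRUE)
  recs <- task_records(eng, dep_task$id)
  idxs <- vapply(recs, `[[`, integer(1), "subtask_index")
  if (length(recs) == 1L && idxs[[1L]] == 0L) {
    # upstream has no process block: fall back to task level
    return(task_finished_successfully(eng, dep_task$id))
  }
  hit <- which(idxs == index)
  length(hit) == 1L && recs[[hit]]$state %in% SUCCESS_STATES
}

deps_satisfied <- function(eng, task, index) {
  for (d in dep_targets(eng, task)) {
    ok <- if (d$separate) subtask_dep_ok(eng, d$task, index)
          else task_finished_successfully(eng, d$task$id)
    if (!ok) return(FALSE)
  }
  TRUE
}

deps_checkpoints_open <- function(eng, task) {
  for (d in dep_targets(eng, task)) {
    if (!checkpoint_open(eng, d$task)) return(FALSE)
  }
  TRUE
}

# upstream host of a separate dependency (for slave-mode affinity)
pinned_host_for <- function(eng, task, index, executor) {
  if (!isTRUE(executor$slave_mode)) return(NULL)
  for (d in dep_targets(eng, task)) {
    if (!d$separate) next
    recs <- task_records(eng, d$task$id)
    idxs <- vapply(recs, `[[`, integer(1), "subtask_index")
    hit <- which(idxs == index)
    if (length(hit) == 1L && !is.null(recs[[hit]]$host_index)) {
      return(recs[[hit]]$host_index)
    }
  }
  NULL
}

# ---- expansion -------------------------------------------------------------

# relative folder/table paths are taken relative to the workflow file
localize_block <- function(blk, wf_dir) {
  if (!is.null(blk$folder) && nzchar(blk$folder) && !grepl("^/", blk$folder)) {
    blk$folder <- file.path(wf_dir, blk$folder)
  }
  if (!is.null(blk$table) && nzchar(blk$table) && !grepl("^/", blk$table)) {
    blk$table <- file.path(wf_dir, blk$table)
  }
  blk
}

input_dep_info <- function(eng, task) {
  deps <- dep_targets(eng, task)
  blk <- eng$spec$blocks[[task$process_block_ref]]
  list(deps = deps, block = blk,
       incremental = length(deps) >= 1L &&
         (isTRUE(blk$compare_by_index) ||
            (length(deps) == 1L && deps[[1L]]$separate)))
}

expand_ready_tasks <- function(eng) {
  progress <- FALSE
  for (id in eng$active) {
    te <- task_entry(eng, id)
    if (te$expanded) next
    task <- te$spec
    blk <- if (!is.null(task$process_block_ref))
      eng$spec$blocks[[task$process_block_ref]]

    if (is.null(blk)) {
      # block-less task: single subtask with index 0
      add_record(eng, task, 0L, NULL)
      te$expanded <- TRUE
      eng$tasks[[as.character(id)]] <- te
      progress <- TRUE
      next
    }

    if (blk$kind == "input") {
      info <- input_dep_info(eng, task)
      if (!info$incremental && length(info$deps) != 1L) {
        th_abort(sprintf("task %d: a process input block needs exactly one dependency (or compareByIndex over separate dependencies)", id),
                 "taskherd_block_error")
      }
      if (info$incremental) {
        progress <- expand_input_incremental(eng, task, info) || progress
      } else {
        dep <- info$deps[[1L]]
        if (task_finished_successfully(eng, dep$task$id) &&
            task_entry(eng, dep$task$id)$active) {
          recs <- task_records(eng, dep$task$id)
          insts <- expand_input(unname(recs), name = blk$name)
          for (i in seq_along(insts)) add_record(eng, task, i, insts[[i]])
          te$expanded <- TRUE
          eng$tasks[[as.character(id)]] <- te
          progress <- TRUE
        } else if (!task_entry(eng, dep$task$id)$active) {
          # upstream excluded: nothing to derive instances from
          add_record(eng, task, 0L, NULL)
          te$expanded <- TRUE
          eng$tasks[[as.character(id)]] <- te
          progress <- TRUE
        }
      }
      next
    }

    # sequence/folder/table/plugin blocks: expand once task-level deps are
    # finished and separate-dep targets are themselves expanded
    ok <- TRUE
    for (d in dep_targets(eng, task)) {
      ok <- if (d$separate) {
        !task_entry(eng, d$task$id)$active || task_entry(eng, d$task$id)$expanded
      } else {
        task_finished_successfully(eng, d$task$id)
      }
      if (!ok) break
    }
    if (!ok) next
    insts <- expand_block(localize_block(blk, eng$wf_dir))
    for (i in seq_along(insts)) add_record(eng, task, i, insts[[i]])
    if (length(insts) == 0L) {
      eng_log(eng, sprintf("task %d: process block '%s' produced no instances", id, blk$name))
    }
    te$expanded <- TRUE
    eng$tasks[[as.character(id)]] <- te
    progress <- TRUE
  }
  progress
}

# per-index expansion for pipelined input blocks
expand_input_incremental <- function(eng, task, info) {
  progress <- FALSE
  te <- task_entry(eng, task$id)
  dep_tasks <- lapply(info$deps, `[[`, "task")
  dep_recs <- lapply(dep_tasks, function(dt) task_records(eng, dt$id))
  if (any(!vapply(dep_tasks, function(dt) task_entry(eng, dt$id)$expanded ||
                    !task_entry(eng, dt$id)$active, logical(1)))) {
    return(FALSE)
  }
  idx_sets <- lapply(dep_recs, function(recs)
    vapply(recs, `[[`, integer(1), "subtask_index"))
  candidate <- sort(Reduce(intersect, idx_sets))
  for (i in setdiff(candidate, te$input_indices_done)) {
    ready <- all(vapply(seq_along(dep_recs), function(k) {
      recs <- dep_recs[[k]]
      r <- recs[[which(idx_sets[[k]] == i)]]
      r$state %in% SUCCESS_STATES && length(r$return_values) > 0L
    }, logical(1)))
    if (!ready) next
    vars <- character(0)
    src <- NULL
    for (k in seq_along(dep_recs)) {
      r <- dep_recs[[k]][[which(idx_sets[[k]] == i)]]
      clash <- intersect(names(vars), names(r$return_values))
      if (length(clash)) {
        th_abort(sprintf("task %d: input variable collision on '%s'",
                         task$id, clash[[1L]]), "taskherd_block_error")
      }
      vars <- c(vars, r$return_values)
      src <- subtask_key(r$task_id, r$subtask_index)
    }
    inst <- new_instance(vars, info$block$name, i, source_key = src)
    add_record(eng, task, i, inst)
    te$input_indices_done <- c(te$input_indices_done, i)
    progress <- TRUE
  }
  # fully expanded once every upstream subtask is terminal
  all_term <- all(vapply(unlist(dep_recs, recursive = FALSE), function(r)
    r$state %in% TERMINAL_STATES || r$state == "FAILED_AWAITING_USER", logical(1)))
  if (all_term && length(unlist(dep_recs, recursive = FALSE)) > 0L) {
    done_all <- all(vapply(dep_tasks, function(dt)
      task_finished_successfully(eng, dt$id), logical(1)))
    if (done_all) {
      te$expanded <- TRUE
    }
  }
  eng$tasks[[as.character(task$id)]] <- te
  progress
}

add_record <- function(eng, task, index, instance) {
  key <- subtask_key(task$id, index)
  if (!is.null(eng$records[[key]])) return(invisible(NULL))
  rec <- new_subtask_record(task$id, index, instance)
  # resume journal replay: match on argv hash so parameter edits re-execute
  if (length(eng$journal) > 0L) {
    argv <- tryCatch(render_record_argv(eng, task, rec), error = function(e) NULL)
    if (!is.null(argv)) {
      h <- argv_hash(argv)
      entry <- eng$journal[[paste(key, h, sep = "@")]]
      if (!is.null(entry) && entry$state %in% c("SUCCEEDED", "RESOLVED_MANUAL")) {
        ev <- if (entry$state == "SUCCEEDED") "replay" else "replay_manual"
        rec <- apply_transition(rec, ev, return_values = entry$return_values)
        rec$resolved_argv <- argv
        eng$records[[key]] <- rec
        trace_event(eng, eng_now(eng, task), task$id, index, "REPLAYED", NULL)
        return(invisible(NULL))
      }
    }
  }
  eng$records[[key]] <- rec
  invisible(NULL)
}

eng_now <- function(eng, task = NULL) {
  exn <- if (!is.null(task)) task_entry(eng, task$id)$executor else eng$default_executor
  eng$executors[[exn]]$now()
}

render_record_argv <- function(eng, task, rec) {
  te <- task_entry(eng, task$id)
  if (is.null(te$module)) {
    th_abort(sprintf("task %d: no module registry attached", task$id),
             "taskherd_module_error")
  }
  asn <- rec$modified_assignments %||% task_assignments(task, rec$instance)
  render_command(te$module, asn)
}

# ---- readiness -------------------------------------------------------------

numeric_record_order <- function(recs) {
  order(vapply(recs, `[[`, integer(1), "task_id"),
        vapply(recs, `[[`, integer(1), "subtask_index"))
}

#' Identify the subtasks that can be launched now
#'
#' A subtask is launchable iff (a) every task-level dependency has all of
#' its subtasks finished successfully, (b) every subtask-level dependency
#' has the index-matched upstream subtask finished successfully, (c) no
#' upstream checkpoint is unreleased, and (d) the task's `maxRunning` cap
#' and its executor's slot capacity are not exhausted. Launch order among
#' eligible subtasks is ascending (task id, subtask index).
#'
#' @param eng An engine handle (as passed to run/monitor callbacks).
#' @return Character vector of subtask keys to launch, in launch order.
#' @export
resolve_ready <- function(eng) {
  promote_pending(eng)
  launchable <- character(0)
  # per-wave bookkeeping so caps hold within the wave as well
  run_by_task <- integer(0)
  free_by_exec <- integer(0)
  for (te in eng$tasks) {
    if (!te$active) next
    n <- sum(vapply(eng$records, function(r)
      r$task_id == te$spec$id && r$state == "RUNNING", logical(1)))
    run_by_task[[as.character(te$spec$id)]] <- n
  }
  for (exn in names(eng$executors)) {
    free_by_exec[[exn]] <- eng$executors[[exn]]$free_slots()
  }

  ord <- numeric_record_order(eng$records)
  for (rec in eng$records[ord]) {
    if (!rec$state %in% c("READY", "HELD_RESOURCE", "HELD_CHECKPOINT")) next
    task <- task_entry(eng, rec$task_id)$spec
    if (!deps_satisfied(eng, task, rec$subtask_index)) next
    if (!deps_checkpoints_open(eng, task)) next
    exn <- task_entry(eng, rec$task_id)$executor
    cap <- task$max_running %||% Inf
    tid <- as.character(rec$task_id)
    if (!rec$resource_hold_released && run_by_task[[tid]] >= cap) next
    if (free_by_exec[[exn]] <= 0L) next
    launchable <- c(launchable, subtask_key(rec$task_id, rec$subtask_index))
    run_by_task[[tid]] <- run_by_task[[tid]] + 1L
    free_by_exec[[exn]] <- free_by_exec[[exn]] - 1L
  }
  launchable
}

promote_pending <- function(eng) {
  ord <- numeric_record_order(eng$records)
  for (rec in eng$records[ord]) {
    key <- subtask_key(rec$task_id, rec$subtask_index)
    task <- task_entry(eng, rec$task_id)$spec
    if (rec$state == "PENDING" && deps_satisfied(eng, task, rec$subtask_index)) {
      rec <- apply_transition(rec, "ready")
      eng$records[[key]] <- rec
    }
    # record checkpoint holds for observability
    if (rec$state == "READY" && deps_satisfied(eng, task, rec$subtask_index) &&
        !deps_checkpoints_open(eng, task)) {
      rec <- apply_transition(rec, "hold_checkpoint")
      eng$records[[key]] <- rec
      trace_event(eng, eng_now(eng, task), rec$task_id, rec$subtask_index,
                  "HELD_CHECKPOINT", NULL)
    }
    if (rec$state == "HELD_CHECKPOINT" && deps_checkpoints_open(eng, task)) {
      rec <- apply_transition(rec, "release")
      eng$records[[key]] <- rec
    }
  }
  invisible(NULL)
}

# mark ready-but-capped subtasks as held (observability; they return to
# READY automatically when a slot frees)
mark_resource_holds <- function(eng, launched_keys) {
  ord <- numeric_record_order(eng$records)
  for (rec in eng$records[ord]) {
    if (rec$state != "READY") next
    key <- subtask_key(rec$task_id, rec$subtask_index)
    if (key %in% launched_keys) next
    task <- task_entry(eng, rec$task_id)$spec
    if (!deps_satisfied(eng, task, rec$subtask_index)) next
    if (!deps_checkpoints_open(eng, task)) next
    # deps fine but no capacity: a resource hold
    rec <- apply_transition(rec, "hold")
    eng$records[[key]] <- rec
    trace_event(eng, eng_now(eng, task), rec$task_id, rec$subtask_index,
                "HELD_RESOURCE", NULL)
  }
  invisible(NULL)
}

# ---- launch & completion ---------------------------------------------------

launch_one <- function(eng, key) {
  rec <- eng$records[[key]]
  te <- task_entry(eng, rec$task_id)
  task <- te$spec
  ex <- eng$executors[[te$executor]]

  argv <- rec$resolved_argv
  if (is.null(argv) || rec$attempt > 1L) {
    argv <- render_record_argv(eng, task, rec)
  }

  pinned <- pinned_host_for(eng, task, rec$subtask_index, ex)
  if (!is.null(pinned)) {
    h <- ex$host_for(key, pinned)
    if (is.na(h)) return(FALSE)  # pinned host busy; retry next wave
  }

  subst <- function(p) {
    if (is.null(p)) return(NULL)
    if (!is.null(rec$instance)) substitute_placeholders(p, rec$instance) else p
  }

  if (!eng$dry_run) {
    bf <- tryCatch({
      run_task_actions(task$task_actions, "before", rec$instance,
                       on_log = function(m) eng_log(eng, sprintf("[%s] %s", key, m)))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(bf)) {
      rec <- apply_transition(rec, "launch", argv = argv, host = NULL)
      rec <- apply_transition(rec, "fail", exit_code = -1L, messages = bf)
      eng$records[[key]] <- rec
      trace_event(eng, ex$now(), rec$task_id, rec$subtask_index, "RUNNING", NULL)
      trace_event(eng, ex$now(), rec$task_id, rec$subtask_index,
                  "FAILED_AWAITING_USER", NULL)
      return(TRUE)
    }
  }

  is_virtual <- inherits(ex, "virtual_executor")
  inv <- command_invocation(
    argv = argv,
    env = te$spec$env,
    workdir = dirname(normalizePath(eng$spec$source_path %||% ".",
                                    mustWork = FALSE)),
    stdout_path = subst(task$stdout_path) %||%
      if (!is_virtual) file.path(eng$scratch, "streams", paste0(key, ".out")),
    stderr_path = subst(task$stderr_path) %||%
      if (!is_virtual) file.path(eng$scratch, "streams", paste0(key, ".err")),
    return_file = file.path(eng$scratch, "returns", paste0(key, ".tsv"))
  )

  host <- ex$launch(key, inv, pinned_host = pinned)
  if (!eng$dry_run && !is_virtual) eng$spawned <- eng$spawned + 1L
  rec <- apply_transition(rec, "launch", argv = argv, host = as.character(host))
  if (is.numeric(host)) rec$host_index <- host
  if (is_virtual && !is.null(host)) {
    rec$host_index <- if (is.numeric(host)) host else
      as.integer(sub("^vhost", "", as.character(host)))
    rec$host <- if (is.numeric(host)) sprintf("vhost%d", host) else as.character(host)
  }
  rec$inv <- inv
  eng$records[[key]] <- rec
  eng$launch_count <- eng$launch_count + 1L
  trace_event(eng, ex$now(), rec$task_id, rec$subtask_index, "RUNNING", rec$host)
  TRUE
}

process_completions <- function(eng) {
  # poll the executor with the earliest pending completion
  with_running <- Filter(function(exn) length(eng$executors[[exn]]$running_keys()) > 0L,
                         names(eng$executors))
  if (length(with_running) == 0L) return(FALSE)
  exn <- with_running[[1L]]
  if (length(with_running) > 1L) {
    nows <- vapply(with_running, function(e) eng$executors[[e]]$now(), numeric(1))
    exn <- with_running[[which.min(nows)]]
  }
  ex <- eng$executors[[exn]]
  comps <- ex$poll()
  if (length(comps) == 0L) return(FALSE)
  ordc <- order(vapply(comps, function(c) {
    p <- strsplit(c$key, "-", fixed = TRUE)[[1L]]
    as.numeric(p[[1L]]) * 1e6 + as.numeric(p[[2L]])
  }, numeric(1)))
  for (comp in comps[ordc]) {
    key <- comp$key
    rec <- eng$records[[key]]
    te <- task_entry(eng, rec$task_id)
    task <- te$spec
    rec$exit_code <- comp$exit_code
    rv <- comp$return_values
    artifacts <- list(
      stdout_path = rec$inv$stdout_path, stderr_path = rec$inv$stderr_path,
      return_file = rec$inv$return_file
    )
    verdict <- judge_result(rec, task$checkers, artifacts)
    if (verdict$final == "SUCCESS") {
      rec <- apply_transition(rec, "succeed", exit_code = comp$exit_code,
                              return_values = rv)
      rec$host_index <- comp$host_index %||% rec$host_index
      eng$records[[key]] <- rec
      if (!eng$dry_run) {
        run_task_actions(task$task_actions, "after_success", rec$instance,
                         on_log = function(m) eng_log(eng, sprintf("[%s] %s", key, m)))
      }
      journal_write(eng, rec)
      trace_event(eng, comp$time, rec$task_id, rec$subtask_index, "SUCCEEDED",
                  rec$host)
    } else {
      rec <- apply_transition(rec, "fail", exit_code = comp$exit_code,
                              messages = verdict$messages)
      eng$records[[key]] <- rec
      if (!eng$dry_run) {
        run_task_actions(task$task_actions, "after_failure", rec$instance,
                         on_log = function(m) eng_log(eng, sprintf("[%s] %s", key, m)))
      }
      eng_log(eng, sprintf(
        "FAILURE %s host=%s cmd=%s exit=%d: %s", key, rec$host %||% "?",
        paste(rec$resolved_argv, collapse = " "), comp$exit_code,
        paste(verdict$messages, collapse = "; ")))
      trace_event(eng, comp$time, rec$task_id, rec$subtask_index,
                  "FAILED_AWAITING_USER", rec$host)
    }
  }
  TRUE
}

# ---- journal ---------------------------------------------------------------

load_journal <- function(path) {
  if (is.null(path) || !file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) next
    rv <- if (length(f) >= 5L && nzchar(f[[5L]])) {
      unlist(jsonlite::fromJSON(f[[5L]]))
    } else character(0)
    key <- paste(subtask_key(f[[1L]], f[[2L]]), f[[3L]], sep = "@")
    out[[key]] <- list(state = f[[4L]], return_values = rv)
  }
  out
}

journal_write <- function(eng, rec) {
  if (is.null(eng$journal_path)) return(invisible(NULL))
  h <- argv_hash(rec$resolved_argv %||% character(0))
  rv <- if (length(rec$return_values)) {
    jsonlite::toJSON(as.list(rec$return_values), auto_unbox = TRUE)
  } else ""
  cat(sprintf("%d\t%d\t%s\t%s\t%s\n", rec$task_id, rec$subtask_index, h,
              rec$state, rv),
      file = eng$journal_path, append = TRUE)
  invisible(NULL)
}

# ---- blocked-state classification ------------------------------------------

# task ids whose forward cone is cut by a failed/ignored upstream
blocked_by_failure <- function(eng) {
  bad_tasks <- integer(0)
  for (rec in eng$records) {
    if (rec$state %in% c("FAILED_AWAITING_USER", "IGNORED")) {
      bad_tasks <- c(bad_tasks, rec$task_id)
    }
  }
  if (length(bad_tasks) == 0L) return(integer(0))
  down <- integer(0)
  for (b in unique(bad_tasks)) {
    sub <- igraph::subcomponent(eng$graph, as.character(b), mode = "out")
    down <- union(down, as.integer(names(sub)))
  }
  down
}

nonterminal_state <- function(eng) {
  vapply(eng$records, function(r)
    !(r$state %in% TERMINAL_STATES), logical(1))
}

# ---- the run loop ----------------------------------------------------------

#' Execute a workflow
#'
#' Drives the engine loop — expand process blocks, resolve dependencies,
#' launch on executors, judge completions, transition states — until every
#' subtask is terminal or waiting for user action. A handler callback can be
#' attached to act on failures and checkpoints headlessly (it receives the
#' engine handle; see [serve_status()] for the action interface).
#'
#' @param spec A `workflow_spec` from [parse_workflow()].
#' @param registry A [module_registry()] resolving the workflow's modules.
#' @param filter A [scope_filter()].
#' @param resume_journal Optional journal path; subtasks whose rendered argv
#'   matches a SUCCEEDED entry are replayed without execution, and new
#'   successes are appended.
#' @param virtual_config Optional list configuring virtual executors
#'   (`hosts`, `slots_per_host`, `duration_of`, `exit_code_of`,
#'   `returns_of`, `slave_mode`).
#' @param dry_run Run every executor as a virtual executor; no child process
#'   is spawned and no task action touches the file system.
#' @param handler Optional `function(eng)` called whenever the run is
#'   blocked (failures awaiting user, unreleased checkpoints); return TRUE
#'   after performing an action to continue, FALSE to stop.
#' @param scratch_dir Directory for stream redirects and return files.
#' @return A `workflow_run` object: final records, the execution trace
#'   (tibble), the run log, and an exit status (0 all successful, 1
#'   otherwise, with `deadlock` diagnostics when the engine stalled).
#' @export
run_workflow <- function(spec, registry = NULL, filter = scope_filter(),
                         resume_journal = NULL, virtual_config = NULL,
                         dry_run = FALSE, handler = NULL,
                         scratch_dir = tempfile("taskherd_run_")) {
  eng <- engine_new(spec, registry, filter, virtual_config, dry_run,
                    resume_journal, scratch_dir, handler)
  deadlock <- NULL
  repeat {
    progress <- expand_ready_tasks(eng)
    keys <- resolve_ready(eng)
    launched <- character(0)
    for (key in keys) {
      if (launch_one(eng, key)) launched <- c(launched, key)
    }
    if (length(launched)) progress <- TRUE
    mark_resource_holds(eng, launched)
    if (process_completions(eng)) progress <- TRUE
    if (progress) next

    nonterm <- eng$records[nonterminal_state(eng)]
    unexp <- Filter(function(te) te$active && !te$expanded, eng$tasks)
    if (length(nonterm) == 0L && length(unexp) == 0L) break

    awaiting <- vapply(nonterm, function(r)
      r$state == "FAILED_AWAITING_USER", logical(1))
    cut <- blocked_by_failure(eng)
    explained <- vapply(nonterm, function(r)
      r$state == "FAILED_AWAITING_USER" || r$task_id %in% cut, logical(1))
    unexp_explained <- vapply(unexp, function(te) te$spec$id %in% cut, logical(1))

    if (!is.null(eng$handler)) {
      acted <- isTRUE(eng$handler(eng))
      if (acted) next
    }
    if (all(explained) && (length(unexp) == 0L || all(unexp_explained))) {
      break  # blocked on user action / failure cones only
    }
    blocked_keys <- names(nonterm)[!explained]
    blocked_tasks <- vapply(unexp[!unexp_explained], function(te) te$spec$id, integer(1))
    deadlock <- list(
      blocked_subtasks = blocked_keys,
      blocked_tasks = as.integer(blocked_tasks),
      message = sprintf(
        "deadlock: nothing running, nothing launchable; blocked: %s",
        paste(c(blocked_keys, if (length(blocked_tasks))
          paste0("task ", blocked_tasks)), collapse = ", "))
    )
    eng_log(eng, deadlock$message)
    break
  }
  finalize_run(eng, deadlock)
}

finalize_run <- function(eng, deadlock = NULL) {
  recs <- eng$records[numeric_record_order(eng$records)]
  active_recs <- Filter(function(r) r$state != "EXCLUDED", recs)
  all_ok <- length(active_recs) == 0L ||
    all(vapply(active_recs, function(r) r$state %in% SUCCESS_STATES, logical(1)))
  unexp <- Filter(function(te) te$active && !te$expanded, eng$tasks)
  if (length(unexp) > 0L) all_ok <- FALSE
  status <- if (!is.null(deadlock)) 1L else if (all_ok) 0L else 1L
  structure(list(
    records = recs,
    spec = eng$spec,
    trace = trace_tibble(eng$trace),
    log = eng$log,
    status = status,
    deadlock = deadlock,
    launch_count = eng$launch_count,
    spawned = eng$spawned,
    scratch = eng$scratch
  ), class = "workflow_run")
}

trace_tibble <- function(events) {
  tibble::tibble(
    time = vapply(events, function(e) as.numeric(e$time), numeric(1)),
    task_id = vapply(events, `[[`, integer(1), "task_id"),
    subtask_index = vapply(events, `[[`, integer(1), "subtask_index"),
    transition = vapply(events, `[[`, character(1), "transition"),
    host = vapply(events, function(e) as.character(e$host %||% NA), character(1))
  )
}

#' Release a checkpoint on the running engine
#'
#' After a checkpointed task finishes, its dependents are held until this is
#' called (or checkpoints are disabled via the scope filter).
#'
#' @param eng Engine handle.
#' @param task_ref Task id or name of the checkpointed task.
#' @export
release_checkpoint <- function(eng, task_ref) {
  task <- resolve_task_ref(eng$spec, task_ref)
  if (!task$checkpoint) {
    th_abort(sprintf("task %d has no checkpoint", task$id), "taskherd_state_error")
  }
  eng$released_checkpoints <- union(eng$released_checkpoints, task$id)
  invisible(TRUE)
}

# engine-level user action entry point (shared by monitor and handlers)
engine_action <- function(eng, task_id, subtask_index, action,
                          params = NULL, returns = NULL) {
  key <- subtask_key(task_id, subtask_index)
  rec <- eng$records[[key]]
  if (is.null(rec)) {
    th_abort(sprintf("unknown subtask %s", key), "taskherd_action_unknown")
  }
  te <- task_entry(eng, rec$task_id)
  idempotent_done <- switch(action,
    ignore = rec$state == "IGNORED",
    resolve = rec$state == "RESOLVED_MANUAL",
    release_resource_hold = isTRUE(rec$resource_hold_released),
    FALSE
  )
  if (idempotent_done) return(invisible(rec))
  rec <- switch(action,
    restart = apply_transition(rec, "user_restart"),
    modify_restart = {
      r <- apply_transition(rec, "user_modify_restart", assignments = params)
      r$resolved_argv <- NULL
      r
    },
    ignore = apply_transition(rec, "user_ignore"),
    resolve = resolve_manually(rec, returns, te$module),
    release_resource_hold = { rec$resource_hold_released <- TRUE; rec },
    th_abort(sprintf("unknown action '%s'", action), "taskherd_action_unknown")
  )
  eng$records[[key]] <- rec
  if (action %in% c("ignore", "resolve")) {
    trace_event(eng, eng_now(eng, te$spec), rec$task_id, rec$subtask_index,
                rec$state, rec$host)
  }
  invisible(rec)
}
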