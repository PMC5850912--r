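#' Executors: where resolved commands actually run
#'
#' The scheduler hands fully resolved command invocations to an *executor*.
#' Two concrete executors ship with the package: a local process-pool
#' executor that forks real child processes under a slot cap, and a
#' deterministic virtual-time executor that simulates execution on a
#' configurable set of hosts — the back-end for dry runs and for every
#' timing-sensitive test. Remote (SSH) and cluster (DRMAA/Slurm) executor
#' types are declared in the dialect and registered as interface stubs;
#' launching on them raises "not configured". New executor types register
#' with [register_executor_type()].
#'
#' @name executors
NULL

#' Register a new executor type
#'
#' `factory(decl, context)` receives the workflow's executor declaration and
#' must return an executor object implementing the internal launch/poll
#' contract (see [virtual_executor()] for the reference implementation).
#'
#' @param type_name The `type` attribute value in executor declarations.
#' @param factory Constructor function.
#' @export
register_executor_type <- function(type_name, factory) {
  .taskherd_env$executor_types[[type_name]] <- factory
  invisible(type_name)
}

executor_type_factory <- function(type_name) .taskherd_env$executor_types[[type_name]]

#' Build a command invocation
#'
#' @param argv Non-empty character vector of command tokens.
#' @param env Named character vector merged over the parent environment
#'   (task entries win on collision).
#' @param workdir Working directory for the child.
#' @param stdout_path,stderr_path Optional redirect targets.
#' @param return_file Path the child may write `key<TAB>value` return
#'   parameters to; exported to the child as `TASKHERD_RETURN_FILE`.
#' @return A `command_invocation` object.
#' @export
command_invocation <- function(argv, env = character(0), workdir = ".",
                               stdout_path = NULL, stderr_path = NULL,
                               return_file = tempfile("returns_")) {
  if (length(argv) == 0L || !nzchar(argv[[1L]])) {
    th_abort("invocation argv must be non-empty", "taskherd_exec_error")
  }
  structure(list(argv = as.character(argv), env = env, workdir = workdir,
                 stdout_path = stdout_path, stderr_path = stderr_path,
                 return_file = return_file),
            class = "command_invocation")
}

run_child <- function(inv) {
  env <- c(inv$env, TASKHERD_RETURN_FILE = inv$return_file)
  owd <- getwd()
  on.exit(setwd(owd), add = TRUE)
  code <- tryCatch({
    setwd(inv$workdir)
    if (length(env)) do.call(Sys.setenv, as.list(env))
    status <- suppressWarnings(system2(
      inv$argv[[1L]], shQuote(inv$argv[-1L]),
      stdout = inv$stdout_path %||% FALSE,
      stderr = inv$stderr_path %||% FALSE
    ))
    as.integer(status)
  }, error = function(e) -1L)
  if (is.na(code)) code <- -1L
  code
}

#' Execute one invocation on the local host
#'
#' Runs the child synchronously with environment and working directory set,
#' stdout/stderr redirected when paths are given, and parses the return file
#' (if written) into a named vector. Concurrency with a slot cap is handled
#' by [local_executor()]; this is the single-invocation primitive.
#'
#' @param inv A [command_invocation()].
#' @return List with `exit_code` (integer; `-1` on spawn failure) and
#'   `return_values` (named character).
#' @export
execute_local <- function(inv) {
  code <- run_child(inv)
  rv <- if (file.exists(inv$return_file)) read_kv_tsv(inv$return_file) else character(0)
  list(exit_code = code, return_values = rv)
}

# ---- local process-pool executor -------------------------------------------

#' Local process-pool executor
#'
#' Forks one child process per launched subtask (base R `parallel`), never
#' keeping more than `slots` children alive at once (the scheduler enforces
#' the cap through `free_slots()`).
#'
#' @param slots Maximum concurrent child processes.
#' @param name Executor name (for traces).
#' @return An executor object.
#' @export
local_executor <- function(slots = 1L, name = "local") {
  ex <- new.env(parent = emptyenv())
  ex$name <- name
  ex$max_slots <- as.integer(slots)
  ex$jobs <- list()      # key -> mcparallel job
  ex$invs <- list()      # key -> invocation
  ex$t0 <- as.numeric(Sys.time())

  ex$free_slots <- function() ex$max_slots - length(ex$jobs)
  ex$running_keys <- function() names(ex$jobs)
  ex$now <- function() as.numeric(Sys.time()) - ex$t0
  ex$host_for <- function(key, pinned = NULL) "localhost"

  ex$launch <- function(key, inv, pinned_host = NULL) {
    if (ex$free_slots() <= 0L) {
      th_abort(sprintf("executor '%s': no free slot", name), "taskherd_exec_error")
    }
    ex$jobs[[key]] <- parallel::mcparallel(run_child(inv))
    ex$invs[[key]] <- inv
    "localhost"
  }

  ex$poll <- function() {
    if (length(ex$jobs) == 0L) return(list())
    repeat {
      res <- parallel::mccollect(ex$jobs, wait = FALSE, timeout = 0.05)
      done <- names(res)[!vapply(res, is.null, logical(1))]
      ready <- names(ex$jobs)[vapply(ex$jobs, function(j)
        as.character(j$pid) %in% done, logical(1))]
      if (length(ready) > 0L) {
        out <- list()
        for (key in sort(ready)) {
          job <- ex$jobs[[key]]
          code <- res[[as.character(job$pid)]]
          if (!is.numeric(code) || length(code) != 1L || is.na(code)) code <- -1L
          inv <- ex$invs[[key]]
          rv <- if (file.exists(inv$return_file)) read_kv_tsv(inv$return_file)
                else character(0)
          out[[length(out) + 1L]] <- list(
            key = key, exit_code = as.integer(code), return_values = rv,
            host = "localhost", time = ex$now()
          )
          ex$jobs[[key]] <- NULL
          ex$invs[[key]] <- NULL
        }
        return(out)
      }
    }
  }
  class(ex) <- c("local_executor", "taskherd_executor")
  ex
}

# ---- virtual (simulated-time) executor -------------------------------------

#' Virtual-time executor
#'
#' A deterministic discrete-event simulation of task execution: each
#' launched subtask occupies one slot on its assigned host for a scripted
#' duration, then completes with a scripted exit code and scripted return
#' values. Host assignment is the lowest-index host with a free slot unless
#' the subtask is pinned (slave-mode affinity). Identical configuration and
#' launch sequence give an identical event sequence.
#'
#' @param hosts Number of simulated hosts.
#' @param slots_per_host Concurrent slots per host.
#' @param duration_of Named list/vector mapping subtask key
#'   (`"taskId-index"`) to duration; default 1.0.
#' @param exit_code_of Same-keyed map of exit codes; default 0.
#' @param returns_of Same-keyed map of named character return values.
#' @param slave_mode Pin dependent subtasks to the host of their upstream
#'   subtask?
#' @param name Executor name.
#' @return An executor object.
#' @export
virtual_executor <- function(hosts = 1L, slots_per_host = 1L,
                             duration_of = list(), exit_code_of = list(),
                             returns_of = list(), slave_mode = FALSE,
                             name = "virtual") {
  stopifnot(hosts >= 1L, slots_per_host >= 1L)
  if (length(duration_of) && any(unlist(duration_of) <= 0)) {
    th_abort("virtual executor durations must be > 0", "taskherd_exec_error")
  }
  ex <- new.env(parent = emptyenv())
  ex$name <- name
  ex$hosts <- as.integer(hosts)
  ex$slots_per_host <- as.integer(slots_per_host)
  ex$max_slots <- ex$hosts * ex$slots_per_host
  ex$slave_mode <- isTRUE(slave_mode)
  ex$clock <- 0
  ex$running <- list()  # key -> list(host, end, exit_code)
  ex$config <- list(duration_of = duration_of, exit_code_of = exit_code_of,
                    returns_of = returns_of)

  host_load <- function() {
    load <- integer(ex$hosts)
    for (r in ex$running) load[[r$host]] <- load[[r$host]] + 1L
    load
  }
  ex$free_slots <- function() ex$max_slots - length(ex$running)
  ex$running_keys <- function() names(ex$running)
  ex$now <- function() ex$clock

  ex$host_for <- function(key, pinned = NULL) {
    load <- host_load()
    if (!is.null(pinned)) {
      if (load[[pinned]] < ex$slots_per_host) return(pinned)
      return(NA_integer_)
    }
    free <- which(load < ex$slots_per_host)
    if (length(free) == 0L) NA_integer_ else free[[1L]]
  }

  ex$launch <- function(key, inv, pinned_host = NULL) {
    host <- ex$host_for(key, pinned_host)
    if (is.na(host)) {
      th_abort(sprintf("virtual executor '%s': no free slot%s", name,
                       if (!is.null(pinned_host))
                         sprintf(" on pinned host %d", pinned_host) else ""),
               "taskherd_exec_error")
    }
    dur <- as.numeric(ex$config$duration_of[[key]] %||% 1.0)
    ex$running[[key]] <- list(host = host, end = ex$clock + dur)
    host
  }

  ex$poll <- function() {
    if (length(ex$running) == 0L) return(list())
    ends <- vapply(ex$running, `[[`, numeric(1), "end")
    t_next <- min(ends)
    ex$clock <- t_next
    done <- sort(names(ends)[abs(ends - t_next) < 1e-12])
    out <- list()
    for (key in done) {
      r <- ex$running[[key]]
      ex$running[[key]] <- NULL
      out[[length(out) + 1L]] <- list(
        key = key,
        exit_code = as.integer(ex$config$exit_code_of[[key]] %||% 0L),
        return_values = {
          rv <- ex$config$returns_of[[key]]
          if (is.null(rv)) character(0) else unlist(rv)
        },
        host = sprintf("vhost%d", r$host), host_index = r$host,
        time = t_next
      )
    }
    out
  }
  class(ex) <- c("virtual_executor", "taskherd_executor")
  ex
}

#' Compute slave-mode host assignments
#'
#' In slave mode, subtasks connected by (subtask-level) dependency edges
#' must run on the same execution host so they can share temporary files on
#' its local disk. Connected components of the dependency-edge graph are
#' each pinned to one host (components assigned round-robin).
#'
#' @param edges Two-column matrix or data frame of subtask keys
#'   (`"taskId-index"`): each row one dependency edge upstream -> downstream.
#' @param n_hosts Number of hosts available.
#' @param slots_per_host Slot capacity per host; a component whose largest
#'   same-task width exceeds it is reported infeasible.
#' @return Named integer vector: subtask key -> host index.
#' @export
apply_affinity <- function(edges, n_hosts, slots_per_host = 1L) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) return(stats::setNames(integer(0), character(0)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  if (slots_per_host < 1L) {
    th_abort("affinity infeasible: hosts have no slots", "taskherd_exec_error")
  }
  hosts <- ((comp - 1L) %% n_hosts) + 1L
  stats::setNames(as.integer(hosts), names(comp))
}

# ---- task actions ----------------------------------------------------------

#' Run a task's file-system actions for one phase
#'
#' Actions let a task prepare or clean up its surroundings on the local file
#' system: `create` (a directory, parents included), `delete`, and `copy`
#' (src to dst). `before`
#' actions run prior to launch and their failure fails the subtask;
#' `after_success` / `after_failure` actions run post-judgment and failures
#' are logged only.
#'
#' @param actions List of action declarations (`phase`, `action`, `src`,
#'   `dst`).
#' @param phase Which phase to run.
#' @param instance Optional instance for placeholder substitution in paths.
#' @param on_log Callback for log lines.
#' @return Invisibly TRUE; `before`-phase failures raise an error.
#' @export
run_task_actions <- function(actions, phase, instance = NULL,
                             on_log = function(msg) {}) {
  subst <- function(p) {
    if (is.null(p)) return(NULL)
    if (!is.null(instance)) substitute_placeholders(p, instance) else p
  }
  for (a in actions) {
    if (!identical(a$phase, phase)) next
    src <- subst(a$src); dst <- subst(a$dst)
    res <- tryCatch({
      switch(a$action,
        create = {
          if (is.null(src)) stop("create action needs src")
          dir.create(src, recursive = TRUE, showWarnings = FALSE)
          if (!dir.exists(src)) stop("could not create ", src)
        },
        delete = {
          if (is.null(src) || !file.exists(src)) stop("delete: no such path: ", src)
          unlink(src, recursive = TRUE)
        },
        copy = {
          if (is.null(src) || is.null(dst)) stop("copy action needs src and dst")
          if (!file.exists(src)) stop("copy: no such path: ", src)
          dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
          ok <- if (dir.exists(src)) {
            file.copy(src, dst, recursive = TRUE, overwrite = TRUE)
          } else {
            file.copy(src, dst, overwrite = TRUE)
          }
          if (!ok) stop("copy failed: ", src, " -> ", dst)
        },
        stop("unknown action type: ", a$action)
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      if (phase == "before") {
        th_abort(sprintf("task action (%s/%s) failed: %s", phase, a$action, res),
                 "taskherd_action_error")
      } else {
        on_log(sprintf("action (%s/%s) failed: %s", phase, a$action, res))
      }
    } else {
      on_log(sprintf("action (%s/%s) ok: %s", phase, a$action, src %||% ""))
    }
  }
  invisible(TRUE)
}

register_builtin_executors <- function() {
  stub <- function(kind) {
    function(decl, context = list()) {
      ex <- new.env(parent = emptyenv())
      ex$name <- decl$name
      ex$max_slots <- decl$max_slots
      ex$free_slots <- function() ex$max_slots
      ex$running_keys <- function() character(0)
      ex$now <- function() 0
      ex$host_for <- function(key, pinned = NULL) NA_integer_
      ex$launch <- function(key, inv, pinned_host = NULL) {
        th_abort(sprintf("%s executor '%s' is declared but not configured in this build",
                         kind, decl$name), "taskherd_exec_error")
      }
      ex$poll <- function() list()
      class(ex) <- c(paste0(kind, "_executor_stub"), "taskherd_executor")
      ex
    }
  }
  register_executor_type("ssh", stub("ssh"))
  register_executor_type("drmaa", stub("drmaa"))
  register_executor_type("slurm", stub("slurm"))
}

# create the executor instance for a declaration
make_executor <- function(decl, virtual_config = NULL, dry_run = FALSE) {
  if (dry_run || identical(decl$exec_type, "virtual")) {
    cfg <- virtual_config %||% list()
    hosts <- as.integer(decl$attributes$hosts %||% cfg$hosts %||% 1L)
    sph <- as.integer(decl$attributes$slotsPerHost %||% cfg$slots_per_host %||%
                        decl$max_slots)
    virtual_executor(
      hosts = hosts, slots_per_host = sph,
      duration_of = cfg$duration_of %||% list(),
      exit_code_of = cfg$exit_code_of %||% list(),
      returns_of = cfg$returns_of %||% list(),
      slave_mode = identical(decl$attributes$slaveMode, "true") ||
        isTRUE(cfg$slave_mode),
      name = decl$name
    )
  } else if (identical(decl$exec_type, "local")) {
    local_executor(slots = decl$max_slots, name = decl$name)
  } else {
    fac <- executor_type_factory(decl$exec_type)
    if (is.null(fac)) {
      th_abort(sprintf("unknown executor type '%s'", decl$exec_type),
               "taskherd_exec_error")
    }
    fac(decl)
  }
}
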