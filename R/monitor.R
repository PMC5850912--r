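#' Status snapshot of an engine or finished run
#'
#' One row per subtask (task id, subtask index, module, state, attempt,
#' host, exit code) plus workflow counters; the counters always equal the
#' row tallies.
#'
#' @param x An engine handle (inside a handler callback) or a
#'   `workflow_run`.
#' @return A `status_snapshot` list with `rows` (tibble), `counters` and
#'   `timestamp`.
#' @export
status_snapshot <- function(x) {
  records <- x$records
  modules <- function(task_id) {
    if (is.null(x$spec)) return(NA_character_)
    resolve_task_ref(x$spec, task_id, quiet = TRUE)$module_ref %||% NA_character_
  }
  recs <- records[order(vapply(records, `[[`, integer(1), "task_id"),
                        vapply(records, `[[`, integer(1), "subtask_index"))]
  rows <- tibble::tibble(
    task_id = vapply(recs, `[[`, integer(1), "task_id"),
    subtask_index = vapply(recs, `[[`, integer(1), "subtask_index"),
    module = vapply(recs, function(r) modules(r$task_id), character(1)),
    state = vapply(recs, `[[`, character(1), "state"),
    attempt = vapply(recs, `[[`, integer(1), "attempt"),
    host = vapply(recs, function(r) r$host %||% NA_character_, character(1)),
    exit_code = vapply(recs, function(r) as.integer(r$exit_code %||% NA),
                       integer(1))
  )
  counters <- list(
    running = sum(rows$state == "RUNNING"),
    pending = sum(rows$state %in% c("PENDING", "READY", "HELD_RESOURCE",
                                    "HELD_CHECKPOINT")),
    failed_awaiting_user = sum(rows$state == "FAILED_AWAITING_USER"),
    succeeded = sum(rows$state %in% c("SUCCEEDED", "RESOLVED_MANUAL"))
  )
  structure(list(rows = rows, counters = counters, timestamp = Sys.time()),
            class = "status_snapshot")
}

#' @export
print.status_snapshot <- function(x, ...) {
  cat(sprintf("status at %s: %d running, %d pending, %d failed-awaiting-user, %d succeeded\n",
              format(x$timestamp), x$counters$running, x$counters$pending,
              x$counters$failed_awaiting_user, x$counters$succeeded))
  print(x$rows)
  invisible(x)
}

#' Attach a status/action interface to a running engine
#'
#' The headless counterpart of a monitoring web interface: a handle whose
#' `status_json()` returns the current snapshot as JSON and whose
#' `post_action(request)` applies a user action to one subtask. Requests are
#' JSON strings (or equivalent lists) of the form
#' `{"task_id":1, "subtask_index":2, "action":"ignore"}`; `modify_restart`
#' takes a `params` object, `resolve` a `returns` object, and
#' `release_checkpoint` only a `task_id`. Every action is idempotent on
#' repeat delivery; unknown subtasks or actions illegal for the current
#' state yield an error response (`ok = FALSE`, HTTP-style `code` 404/409).
#'
#' @param eng Engine handle (as passed to a `run_workflow()` handler).
#' @return A `status_server` handle.
#' @export
serve_status <- function(eng) {
  handle <- list(
    status_json = function() {
      snap <- status_snapshot(eng)
      jsonlite::toJSON(list(
        timestamp = as.numeric(snap$timestamp),
        counters = snap$counters,
        subtasks = snap$rows
      ), dataframe = "rows", auto_unbox = TRUE, na = "null")
    },
    post_action = function(request) {
      req <- if (is.character(request)) jsonlite::fromJSON(request) else request
      out <- tryCatch({
        if (identical(req$action, "release_checkpoint")) {
          release_checkpoint(eng, req$task_id)
          list(ok = TRUE, code = 200L, state = "released")
        } else {
          rec <- engine_action(eng, req$task_id, req$subtask_index %||% 0L,
                               req$action,
                               params = req$params, returns = req$returns)
          list(ok = TRUE, code = 200L, state = rec$state)
        }
      },
      taskherd_action_unknown = function(e)
        list(ok = FALSE, code = 404L, error = conditionMessage(e)),
      taskherd_error = function(e)
        list(ok = FALSE, code = 409L, error = conditionMessage(e)))
      jsonlite::toJSON(out, auto_unbox = TRUE)
    }
  )
  class(handle) <- "status_server"
  handle
}

# ---- tidy surface ----------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a finished workflow run
#'
#' One row per subtask with its terminal state, attempt count, exit code and
#' host.
#'
#' @param x A `workflow_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.workflow_run <- function(x, ...) {
  status_snapshot(x)$rows
}

#' One-row summary of a workflow run
#'
#' @param x A `workflow_run`.
#' @param ... Unused.
#' @return A one-row tibble: subtask totals, launches, status.
#' @export
glance.workflow_run <- function(x, ...) {
  st <- vapply(x$records, `[[`, character(1), "state")
  tibble::tibble(
    n_subtasks = length(st),
    n_succeeded = sum(st %in% c("SUCCEEDED", "RESOLVED_MANUAL")),
    n_failed = sum(st == "FAILED_AWAITING_USER"),
    n_ignored = sum(st == "IGNORED"),
    n_excluded = sum(st == "EXCLUDED"),
    launches = x$launch_count,
    deadlocked = !is.null(x$deadlock),
    status = x$status
  )
}

#' @export
print.workflow_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<workflow run: status %d; %d subtask(s), %d succeeded, %d failed, %d ignored>\n",
              g$status, g$n_subtasks, g$n_succeeded, g$n_failed, g$n_ignored))
  if (!is.null(x$deadlock)) cat(" ", x$deadlock$message, "\n")
  invisible(x)
}

#' Gantt-style plot of an execution trace
#'
#' Draws one horizontal segment per executed subtask from its launch to its
#' terminal event, coloured by host — useful for eyeballing concurrency caps
#' and pipelining on the virtual executor.
#'
#' @param object A `workflow_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.workflow_run <- function(object, ...) {
  tr <- object$trace
  runs <- tr[tr$transition == "RUNNING", ]
  ends <- tr[tr$transition %in% c("SUCCEEDED", "FAILED_AWAITING_USER"), ]
  if (nrow(runs) == 0L) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "empty trace"))
  }
  seg <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    later <- ends[ends$task_id == r$task_id &
                    ends$subtask_index == r$subtask_index &
                    ends$time >= r$time, ]
    data.frame(
      subtask = subtask_key(r$task_id, r$subtask_index),
      start = r$time,
      end = if (nrow(later)) later$time[[1L]] else r$time,
      host = r$host
    )
  }))
  ggplot2::ggplot(seg, ggplot2::aes(y = .data$subtask)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$subtask,
                                       colour = .data$host),
                          linewidth = 3) +
    ggplot2::labs(x = "time", y = "subtask", colour = "host") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
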