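#' Error detection: exit codes plus ordered custom checkers
#'
#' A finished subtask is judged in two stages. First the exit code: zero
#' means the command technically succeeded, anything else is a failure.
#' Because many tools exit 0 even when their output is useless (and a run
#' can "succeed" with, say, a suspiciously low mapping rate), tasks may
#' additionally declare *checkers* — named success/error predicates applied
#' in declaration order to the subtask's artifacts (stdout, stderr, return
#' file). A single error vote, or a nonzero exit, makes the final verdict a
#' failure even if success was also detected.
#'
#' @name error_handling
NULL

#' Judge an exit code
#' @param exit_code Integer exit code (`-1` is the spawn-failure sentinel).
#' @return List with `success` (logical) and `message`.
#' @export
judge_exit <- function(exit_code) {
  if (identical(as.integer(exit_code), 0L)) {
    list(success = TRUE, message = "exit code 0")
  } else {
    list(success = FALSE, message = sprintf("nonzero exit code %d", as.integer(exit_code)))
  }
}

#' Register a checker factory
#'
#' Checkers live in a name -> factory registry; the workflow XML refers to
#' them by name. `factory(...)` receives the declared constructor arguments
#' (already converted to their declared types) and must return a predicate
#' `function(record, artifacts)` yielding a list with `ok` (logical: does
#' the checked condition hold?) and optional `message`. A checker declared
#' with `kind = "success"` votes success when the condition holds; declared
#' with `kind = "error"` it votes error when the condition does *not* hold.
#' A plugin may instead return an explicit `vote` of `"success"`, `"error"`
#' or `"none"` to bypass that mapping.
#'
#' @param name Registry key used in `checker name=` declarations.
#' @param factory Constructor function.
#' @export
register_checker <- function(name, factory) {
  .taskherd_env$checkers[[name]] <- factory
  invisible(name)
}

checker_factory <- function(name) .taskherd_env$checkers[[name]]

parse_checker_decl <- function(nd, path, task_id) {
  nm <- xml_attr_or(nd, "name")
  kind <- xml_attr_or(nd, "kind", "error")
  if (is.null(nm)) {
    th_abort(sprintf("%s: task %d: <checker> without name", path, task_id),
             "taskherd_parse_error")
  }
  if (!kind %in% c("success", "error")) {
    th_abort(sprintf("%s: task %d: checker kind must be success|error", path, task_id),
             "taskherd_parse_error")
  }
  args <- list()
  spec <- xml_attr_or(nd, "args", "")
  if (nzchar(spec)) {
    for (tok in strsplit(spec, ",", fixed = TRUE)[[1L]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      if (length(kv) < 2L || !kv[[1L]] %in% c("string", "integer", "double", "boolean")) {
        th_abort(sprintf("%s: task %d: bad checker arg '%s' (want type:value)",
                         path, task_id, tok), "taskherd_parse_error")
      }
      value <- paste(kv[-1L], collapse = ":")
      if (is.null(parse_typed(value, kv[[1L]]))) {
        th_abort(sprintf("%s: task %d: checker arg '%s' does not parse as %s",
                         path, task_id, value, kv[[1L]]), "taskherd_parse_error")
      }
      args[[length(args) + 1L]] <- list(type = kv[[1L]], value = value)
    }
  }
  checker_decl(nm, kind, args)
}

#' Declare a checker invocation
#' @param checker_name Registered checker name.
#' @param kind `"success"` or `"error"` — what a positive hit votes for.
#' @param ctor_args List of `list(type=, value=)` constructor arguments.
#' @return A `checker_decl` object.
#' @export
checker_decl <- function(checker_name, kind = "error", ctor_args = list()) {
  stopifnot(kind %in% c("success", "error"))
  structure(list(checker_name = checker_name, kind = kind, ctor_args = ctor_args),
            class = "checker_decl")
}

convert_ctor_arg <- function(a) {
  switch(a$type,
    integer = as.integer(a$value),
    double = as.numeric(a$value),
    boolean = tolower(a$value) %in% c("true", "1"),
    a$value
  )
}

#' Judge a finished subtask
#'
#' Computes the base exit judgment, then applies each declared checker in
#' order. The verdict is `FAILURE` iff the exit judgment failed or at least
#' one error vote was cast — success votes can never override an error
#' (mixed detections are treated as failure). A checker that cannot be
#' instantiated counts as an error vote carrying the instantiation message.
#'
#' @param record Subtask record with `exit_code` set.
#' @param checkers List of [checker_decl()] objects (declaration order).
#' @param artifacts List with optional `stdout_path`, `stderr_path`,
#'   `return_file` entries.
#' @return A `verdict` list: `success_votes`, `error_votes`, `messages`,
#'   `final` (`"SUCCESS"` or `"FAILURE"`).
#' @export
judge_result <- function(record, checkers = list(), artifacts = list()) {
  base <- judge_exit(record$exit_code %||% -1L)
  success_votes <- 0L
  error_votes <- 0L
  messages <- character(0)
  if (!base$success) messages <- base$message

  for (decl in checkers) {
    fac <- checker_factory(decl$checker_name)
    res <- if (is.null(fac)) {
      list(vote = "error",
           message = sprintf("checker '%s' is not registered", decl$checker_name))
    } else {
      args <- lapply(decl$ctor_args, convert_ctor_arg)
      tryCatch({
        fn <- do.call(fac, args)
        out <- fn(record, artifacts)
        if (is.null(out$vote)) {
          out$vote <- if (decl$kind == "success") {
            if (isTRUE(out$ok)) "success" else "none"
          } else {
            if (isTRUE(out$ok)) "none" else "error"
          }
        }
        out
      }, error = function(e) {
        list(vote = "error",
             message = sprintf("checker '%s' failed: %s", decl$checker_name,
                               conditionMessage(e)))
      })
    }
    if (identical(res$vote, "success")) success_votes <- success_votes + 1L
    if (identical(res$vote, "error")) error_votes <- error_votes + 1L
    if (!is.null(res$message)) messages <- c(messages, res$message)
  }

  final <- if (!base$success || error_votes > 0L) "FAILURE" else "SUCCESS"
  if (final == "FAILURE" && length(messages) == 0L) {
    messages <- "failure detected by checker vote"
  }
  structure(list(success_votes = success_votes, error_votes = error_votes,
                 messages = messages, final = final),
            class = "verdict")
}

#' Manually resolve a failed subtask
#'
#' Marks a subtask awaiting user action as successfully resolved, with
#' user-supplied return values standing in for the output the failed run
#' should have produced. The values must cover exactly the module's declared
#' return parameters and parse as their types, so downstream input blocks
#' can consume them like real ones.
#'
#' @param record Subtask record in state `FAILED_AWAITING_USER`.
#' @param user_returns Named character vector/list of return values.
#' @param module The task's [module_descriptor()].
#' @return The updated record in state `RESOLVED_MANUAL`.
#' @export
resolve_manually <- function(record, user_returns, module) {
  if (!identical(record$state, "FAILED_AWAITING_USER")) {
    th_abort(sprintf("subtask %s is %s; only failed subtasks can be resolved manually",
                     subtask_key(record$task_id, record$subtask_index), record$state),
             "taskherd_state_error")
  }
  declared <- vapply(module$returns, `[[`, character(1), "name")
  user_returns <- unlist(user_returns)
  missing <- setdiff(declared, names(user_returns))
  extra <- setdiff(names(user_returns), declared)
  if (length(missing)) {
    th_abort(sprintf("manual resolution is missing return value(s): %s",
                     paste(missing, collapse = ", ")), "taskherd_state_error")
  }
  if (length(extra)) {
    th_abort(sprintf("manual resolution has undeclared return value(s): %s",
                     paste(extra, collapse = ", ")), "taskherd_state_error")
  }
  for (r in module$returns) {
    if (is.null(parse_typed(user_returns[[r$name]], r$type))) {
      th_abort(sprintf("return value '%s' = '%s' does not parse as %s",
                       r$name, user_returns[[r$name]], r$type),
               "taskherd_state_error")
    }
  }
  apply_transition(record, "user_resolve", return_values = user_returns)
}

# ---- built-in checkers -----------------------------------------------------

register_builtin_checkers <- function() {
  # condition: stderr matches the pattern at most max_hits times
  register_checker("stderr_pattern", function(pattern, max_hits = 0L) {
    force(pattern); force(max_hits)
    function(record, artifacts) {
      p <- artifacts$stderr_path
      hits <- if (!is.null(p) && file.exists(p)) {
        sum(grepl(pattern, readLines(p, warn = FALSE)))
      } else 0L
      if (hits > max_hits) {
        list(ok = FALSE,
             message = sprintf("stderr matches '%s' %d time(s) (max %d)",
                               pattern, hits, max_hits))
      } else list(ok = TRUE)
    }
  })
  # condition: the path exists after the run
  register_checker("file_exists", function(path) {
    force(path)
    function(record, artifacts) {
      if (file.exists(path)) list(ok = TRUE) else
        list(ok = FALSE, message = sprintf("expected file missing: %s", path))
    }
  })
  # condition: the file exists and is at least `bytes` long
  register_checker("min_file_size", function(path, bytes) {
    force(path); force(bytes)
    function(record, artifacts) {
      ok <- file.exists(path) && file.size(path) >= bytes
      if (ok) list(ok = TRUE) else
        list(ok = FALSE,
             message = sprintf("file %s smaller than %d byte(s)", path, bytes))
    }
  })
}
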