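#' Process blocks: declarative generators of subtask instances
#'
#' A process block turns replicate data into a list of instances, each a
#' named set of variables; the scheduler spawns one subtask per instance.
#' Four block types are built in: numeric sequences, folder globs,
#' tab-separated sample tables, and input blocks fed by upstream return
#' values. New block types can be registered with
#' [register_block_type()].
#'
#' @name process_blocks
NULL

new_instance <- function(variables, block, ordinal, source_key = NULL) {
  if (length(variables) == 0L) {
    th_abort("an instance must carry at least one variable", "taskherd_block_error")
  }
  structure(list(variables = variables, block = block,
                 ordinal = as.integer(ordinal), source_key = source_key),
            class = "block_instance")
}

#' Expand a numeric sequence block
#'
#' Comparable to a for-loop: instances hold the values `start`, `start+step`,
#' ... up to (and including, when hit exactly) `end`. Integral sequences are
#' formatted without a decimal point so the values are safe in file names.
#'
#' @param start,end,step Sequence bounds and increment (`step` defaults to 1,
#'   must be non-zero and point from start towards end).
#' @param name Block name used in instance provenance.
#' @return List of instances, each with the single variable `value`.
#' @export
expand_sequence <- function(start, end, step = 1, name = "sequence") {
  if (!is.finite(start) || !is.finite(end) || !is.finite(step)) {
    th_abort("sequence bounds and step must be finite", "taskherd_block_error")
  }
  if (step == 0) th_abort("sequence step must be non-zero", "taskherd_block_error")
  if (start != end && sign(step) != sign(end - start)) {
    th_abort("sequence step points away from end", "taskherd_block_error")
  }
  n <- floor((end - start) / step + 1e-9) + 1
  vals <- start + step * (seq_len(n) - 1)
  lapply(seq_along(vals), function(i) {
    new_instance(c(value = format_block_number(vals[[i]])), name, i)
  })
}

#' Expand a folder block
#'
#' One instance per regular file in `folder` matching the glob `pattern`
#' (no recursion); the instance value is the absolute path. Output is sorted
#' lexicographically by path so repeated expansion is identical.
#'
#' @param folder Parent folder to scan.
#' @param pattern Filename glob, e.g. `"*.log"`.
#' @param name Block name.
#' @return List of instances (empty, with a warning, when nothing matches).
#' @export
expand_folder <- function(folder, pattern = "*", name = "folder") {
  if (!nzchar(pattern)) th_abort("folder pattern must be non-empty", "taskherd_block_error")
  if (!dir.exists(folder)) {
    th_abort(sprintf("process folder does not exist: %s", folder), "taskherd_block_error")
  }
  hits <- list.files(folder, pattern = utils::glob2rx(pattern), full.names = TRUE)
  hits <- hits[file.exists(hits) & !dir.exists(hits)]
  hits <- sort(vapply(hits, normalizePath, character(1), USE.NAMES = FALSE))
  if (length(hits) == 0L) {
    warning(sprintf("folder block '%s': no file matches '%s' in %s",
                    name, pattern, folder), call. = FALSE)
    return(list())
  }
  lapply(seq_along(hits), function(i) {
    new_instance(c(value = hits[[i]]), name, i)
  })
}

#' Expand a table block
#'
#' Reads a UTF-8 tab-separated file whose first row is a header of unique
#' column names; every following row becomes one instance whose variables are
#' named by the header.
#'
#' @param table_path Path to the TSV file.
#' @param name Block name.
#' @return List of instances in row order.
#' @export
expand_table <- function(table_path, name = "table") {
  if (!file.exists(table_path)) {
    th_abort(sprintf("process table does not exist: %s", table_path),
             "taskherd_block_error")
  }
  lines <- readLines(table_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    th_abort(sprintf("process table is empty: %s", table_path), "taskherd_block_error")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header)) {
    th_abort(sprintf("duplicate column name '%s' in %s",
                     header[duplicated(header)][1L], table_path),
             "taskherd_block_error")
  }
  rows <- lines[-1L]
  if (length(rows) == 0L) {
    warning(sprintf("table block '%s': header-only file %s", name, table_path),
            call. = FALSE)
    return(list())
  }
  lapply(seq_along(rows), function(i) {
    cells <- strsplit(rows[[i]], "\t", fixed = TRUE)[[1L]]
    # a trailing empty cell is dropped by strsplit; pad one back
    if (length(cells) == length(header) - 1L && grepl("\t$", rows[[i]])) {
      cells <- c(cells, "")
    }
    if (length(cells) != length(header)) {
      th_abort(sprintf("ragged row %d in %s: %d cell(s) under %d-column header",
                       i, table_path, length(cells), length(header)),
               "taskherd_block_error")
    }
    vars <- stats::setNames(cells, header)
    new_instance(vars, name, i)
  })
}

#' Expand an input block from finished upstream subtasks
#'
#' Instances are derived from the return values of the subtasks of the task
#' this task depends on: one instance per finished subtask, variables equal
#' to that subtask's return-value map. All records must expose the same
#' variable names.
#'
#' @param dep_records List of subtask records in state `SUCCEEDED` or
#'   `RESOLVED_MANUAL` with non-empty return values.
#' @param name Block name.
#' @return List of instances ordered by source subtask index.
#' @export
expand_input <- function(dep_records, name = "input") {
  if (length(dep_records) == 0L) return(list())
  for (r in dep_records) {
    if (!r$state %in% c("SUCCEEDED", "RESOLVED_MANUAL")) {
      th_abort(sprintf("input block: subtask %s is %s, not finished-successful",
                       subtask_key(r$task_id, r$subtask_index), r$state),
               "taskherd_block_error")
    }
    if (length(r$return_values) == 0L) {
      th_abort(sprintf("input block: subtask %s exposes no return values",
                       subtask_key(r$task_id, r$subtask_index)),
               "taskherd_block_error")
    }
  }
  keys <- lapply(dep_records, function(r) sort(names(r$return_values)))
  if (length(unique(vapply(keys, paste, character(1), collapse = "\x1f"))) > 1L) {
    th_abort("input block: conflicting variable sets across upstream subtasks",
             "taskherd_block_error")
  }
  ord <- order(vapply(dep_records, function(r) r$subtask_index, numeric(1)))
  dep_records <- dep_records[ord]
  lapply(seq_along(dep_records), function(i) {
    r <- dep_records[[i]]
    new_instance(r$return_values, name, i,
                 source_key = subtask_key(r$task_id, r$subtask_index))
  })
}

#' Substitute instance placeholders into a template
#'
#' Three placeholder forms are replaced:
#' \describe{
#'   \item{`{}`}{the full value of a single-variable instance (e.g. the
#'     complete file path from a folder block);}
#'   \item{`[k]`}{the base file name of that value with the last `k`
#'     dot-suffixes removed (`[1]` on `/tmp/a.log` gives `a`);}
#'   \item{`{$var}`}{the named variable of a multi-variable instance.}
#' }
#' Text without placeholders is returned unchanged; substituted values are
#' never re-scanned, so the operation is idempotent on its own output.
#'
#' @param template Template text.
#' @param instance An instance from one of the `expand_*` functions.
#' @return The substituted text.
#' @export
substitute_placeholders <- function(template, instance) {
  stopifnot(inherits(instance, "block_instance"))
  vars <- instance$variables
  single <- length(vars) == 1L
  out <- ""
  rest <- template
  repeat {
    m <- regexpr("\\{\\$[A-Za-z_][A-Za-z0-9_]*\\}|\\{\\}|\\[[0-9]+\\]", rest)
    if (m == -1L) { out <- paste0(out, rest); break }
    out <- paste0(out, substr(rest, 1L, m - 1L))
    tok <- substr(rest, m, m + attr(m, "match.length") - 1L)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
    if (tok == "{}") {
      if (!single) {
        th_abort("placeholder {} requires a single-variable instance",
                 "taskherd_placeholder_error")
      }
      out <- paste0(out, vars[[1L]])
    } else if (startsWith(tok, "{$")) {
      var <- substr(tok, 3L, nchar(tok) - 1L)
      if (!var %in% names(vars)) {
        th_abort(sprintf("unknown instance variable '%s'", var),
                 "taskherd_placeholder_error")
      }
      out <- paste0(out, vars[[var]])
    } else {  # [k]
      if (!single) {
        th_abort("placeholder [k] requires a single-variable instance",
                 "taskherd_placeholder_error")
      }
      k <- as.integer(substr(tok, 2L, nchar(tok) - 1L))
      if (k < 1L) {
        th_abort("placeholder [k] requires k >= 1", "taskherd_placeholder_error")
      }
      base <- basename(vars[[1L]])
      parts <- strsplit(base, ".", fixed = TRUE)[[1L]]
      if (length(parts) - 1L < k) {
        th_abort(sprintf("[%d]: '%s' has only %d dot-suffix(es)", k, base,
                         length(parts) - 1L), "taskherd_placeholder_error")
      }
      out <- paste0(out, paste(parts[seq_len(length(parts) - k)], collapse = "."))
    }
  }
  out
}

# ---- block declarations & plugin registry ----------------------------------

.taskherd_env <- new.env(parent = emptyenv())
.taskherd_env$block_types <- list()
.taskherd_env$executor_types <- list()
.taskherd_env$checkers <- list()

#' Register a new process-block type
#'
#' Extends the workflow dialect: a settings child element `element_name` is
#' parsed by `parse_fn(xml_node) -> block declaration` and expanded by
#' `expand_fn(block, context) -> list of instances` (stable 1-based
#' ordinals). Built-in types cannot be overridden.
#'
#' @param element_name XML element name under the `processBlock` settings
#'   group.
#' @param parse_fn Function turning the XML node into a block declaration
#'   list; must keep the `name` attribute.
#' @param expand_fn Function producing the instances.
#' @export
register_block_type <- function(element_name, parse_fn, expand_fn) {
  builtin <- c("processSequence", "processFolder", "processTable", "processInput")
  if (element_name %in% builtin) {
    th_abort(sprintf("cannot override built-in block type '%s'", element_name),
             "taskherd_block_error")
  }
  .taskherd_env$block_types[[element_name]] <-
    list(parse = parse_fn, expand = expand_fn)
  invisible(element_name)
}

block_plugin <- function(element_name) .taskherd_env$block_types[[element_name]]

#' Expand a parsed block declaration into instances
#'
#' Dispatches on the declaration's `kind` (sequence, folder, table, input or
#' a registered plugin type).
#'
#' @param block A block declaration from [parse_workflow()].
#' @param dep_records For input blocks: the finished upstream subtask
#'   records.
#' @return List of instances.
#' @export
expand_block <- function(block, dep_records = NULL) {
  switch(block$kind,
    sequence = expand_sequence(block$start, block$end, block$step, name = block$name),
    folder = expand_folder(block$folder, block$pattern, name = block$name),
    table = expand_table(block$table, name = block$name),
    input = expand_input(dep_records %||% list(), name = block$name),
    {
      plug <- block_plugin(block$kind)
      if (is.null(plug)) {
        th_abort(sprintf("unknown block kind '%s'", block$kind), "taskherd_block_error")
      }
      plug$expand(block, dep_records)
    }
  )
}
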