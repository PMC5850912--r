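#' The workflow XML dialect
#'
#' Workflows are XML documents with root `<workflow>`. A `<settings>` element
#' declares constants, executors, process blocks and extra module folders; a
#' `<tasks>` element holds one element per task, *named after its module*
#' (e.g. `<sleepTask id="1" name="sleep">`). Task attributes: `id`, `name`,
#' `processBlock`, `executor`, `maxRunning`, `checkpoint`. Task children:
#' `parameter` (one child element per parameter, text content is the value
#' template), `dependencies/depends` (text = target id or name, attribute
#' `separate="true"` for subtask-level dependencies), `streams/stdout|stderr
#' path=`, `environment/var name= value=`, `actions/action phase= type= src=
#' dst=`, and `checkers/checker name= kind= args=`.
#'
#' Parameter templates may reference constants as `${NAME}` and, when the
#' task has a process block, instance placeholders `{}`, `[k]` and `{$var}`
#' (see [substitute_placeholders()]).
#'
#' @name workflow_dialect
NULL

CONST_RE <- "\\$\\{[A-Za-z_][A-Za-z0-9_]*\\}"
PLACEHOLDER_RE <- "\\{\\$[A-Za-z_][A-Za-z0-9_]*\\}|\\{\\}|\\[[0-9]+\\]"

new_executor_decl <- function(name, exec_type, max_slots = 1L, default = FALSE,
                              attributes = list()) {
  structure(list(name = name, exec_type = exec_type,
                 max_slots = as.integer(max_slots), default = isTRUE(default),
                 attributes = attributes),
            class = "executor_decl")
}

parse_error <- function(path, msg) {
  th_abort(sprintf("%s: %s", path, msg), "taskherd_parse_error")
}

parse_settings <- function(settings, path) {
  constants <- character(0)
  for (nd in xml2::xml_find_all(settings, "./constants/const")) {
    nm <- xml_attr_or(nd, "name")
    if (is.null(nm)) parse_error(path, "<const> without name attribute")
    if (nm %in% names(constants)) parse_error(path, sprintf("duplicate constant '%s'", nm))
    constants[[nm]] <- xml_attr_or(nd, "value", "")
  }

  executors <- list()
  for (nd in xml2::xml_find_all(settings, "./executors/executor")) {
    nm <- xml_attr_or(nd, "name")
    if (is.null(nm)) parse_error(path, "<executor> without name")
    if (nm %in% names(executors)) parse_error(path, sprintf("duplicate executor '%s'", nm))
    known <- c("name", "type", "maxSlots", "default")
    all_attrs <- xml2::xml_attrs(nd)
    executors[[nm]] <- new_executor_decl(
      name = nm,
      exec_type = xml_attr_or(nd, "type", "local"),
      max_slots = as.integer(xml_attr_or(nd, "maxSlots", "1")),
      default = identical(xml_attr_or(nd, "default", "false"), "true"),
      attributes = as.list(all_attrs[setdiff(names(all_attrs), known)])
    )
  }
  if (sum(vapply(executors, `[[`, logical(1), "default")) > 1L) {
    parse_error(path, "more than one executor marked default")
  }
  if (length(executors) == 0L) {
    # sequential local execution is the default when nothing is declared
    executors <- list(local = new_executor_decl("local", "local", 1L, default = TRUE))
  } else if (!any(vapply(executors, `[[`, logical(1), "default"))) {
    executors[[1L]]$default <- TRUE
  }

  blocks <- list()
  for (nd in xml2::xml_find_all(settings, "./processBlock/*")) {
    kind_el <- xml2::xml_name(nd)
    nm <- xml_attr_or(nd, "name")
    if (is.null(nm)) parse_error(path, sprintf("<%s> without name", kind_el))
    if (nm %in% names(blocks)) parse_error(path, sprintf("duplicate process block '%s'", nm))
    blk <- switch(kind_el,
      processSequence = list(kind = "sequence", name = nm,
        start = as.numeric(xml_attr_or(nd, "start")),
        end = as.numeric(xml_attr_or(nd, "end")),
        step = as.numeric(xml_attr_or(nd, "step", "1"))),
      processFolder = list(kind = "folder", name = nm,
        folder = xml_attr_or(nd, "folder", ""),
        pattern = xml_attr_or(nd, "pattern", "*")),
      processTable = list(kind = "table", name = nm,
        table = xml_attr_or(nd, "table", "")),
      processInput = list(kind = "input", name = nm,
        compare_by_index = identical(xml_attr_or(nd, "compareByIndex", "false"), "true")),
      {
        plug <- block_plugin(kind_el)
        if (is.null(plug)) parse_error(path, sprintf("unknown process block type <%s>", kind_el))
        b <- plug$parse(nd)
        b$kind <- kind_el
        b$name <- nm
        b
      }
    )
    if (blk$kind == "sequence") {
      if (anyNA(c(blk$start, blk$end, blk$step))) {
        parse_error(path, sprintf("sequence block '%s': start/end/step must be numeric", nm))
      }
      if (blk$step == 0 ||
          (blk$start != blk$end && sign(blk$step) != sign(blk$end - blk$start))) {
        parse_error(path, sprintf("sequence block '%s': invalid step", nm))
      }
    }
    if (blk$kind == "folder" && !nzchar(blk$pattern)) {
      parse_error(path, sprintf("folder block '%s': empty pattern", nm))
    }
    blocks[[nm]] <- blk
  }

  module_folders <- character(0)
  for (nd in xml2::xml_find_all(settings, "./moduleFolders/folder")) {
    p <- xml_attr_or(nd, "path")
    if (is.null(p)) parse_error(path, "<folder> without path")
    module_folders <- c(module_folders, p)
  }

  list(constants = constants, executors = executors, blocks = blocks,
       module_folders = module_folders)
}

parse_task <- function(nd, path) {
  module_ref <- xml2::xml_name(nd)
  id <- xml_attr_or(nd, "id")
  if (is.null(id) || !grepl("^[0-9]+$", id) || as.integer(id) < 1L) {
    parse_error(path, sprintf("task <%s> needs a positive integer id", module_ref))
  }
  id <- as.integer(id)
  name <- xml_attr_or(nd, "name", as.character(id))

  parameters <- list()
  for (p in xml2::xml_find_all(nd, "./parameter/*")) {
    pn <- xml2::xml_name(p)
    parameters[[length(parameters) + 1L]] <-
      list(name = pn, value = xml2::xml_text(p))
  }

  dependencies <- list()
  for (d in xml2::xml_find_all(nd, "./dependencies/depends")) {
    dependencies[[length(dependencies) + 1L]] <- list(
      target = trimws(xml2::xml_text(d)),
      separate = identical(xml_attr_or(d, "separate", "false"), "true")
    )
  }

  actions <- list()
  for (a in xml2::xml_find_all(nd, "./actions/action")) {
    phase <- xml_attr_or(a, "phase", "before")
    type <- xml_attr_or(a, "type")
    if (!phase %in% c("before", "after_success", "after_failure")) {
      parse_error(path, sprintf("task %d: unknown action phase '%s'", id, phase))
    }
    if (is.null(type) || !type %in% c("create", "delete", "copy")) {
      parse_error(path, sprintf("task %d: unknown action type '%s'", id, type %||% ""))
    }
    actions[[length(actions) + 1L]] <- list(
      phase = phase, action = type,
      src = xml_attr_or(a, "src"), dst = xml_attr_or(a, "dst")
    )
  }

  checkers <- list()
  for (ck in xml2::xml_find_all(nd, "./checkers/checker")) {
    checkers[[length(checkers) + 1L]] <- parse_checker_decl(ck, path, id)
  }

  env <- character(0)
  for (v in xml2::xml_find_all(nd, "./environment/var")) {
    env[[xml_attr_or(v, "name", "")]] <- xml_attr_or(v, "value", "")
  }

  mr <- xml_attr_or(nd, "maxRunning")
  structure(list(
    id = id, name = name, module_ref = module_ref,
    parameters = parameters, dependencies = dependencies,
    process_block_ref = xml_attr_or(nd, "processBlock"),
    executor_ref = xml_attr_or(nd, "executor"),
    max_running = if (!is.null(mr)) as.integer(mr),
    checkpoint = identical(xml_attr_or(nd, "checkpoint", "false"), "true"),
    stdout_path = xml_attr_or(xml2::xml_find_first(nd, "./streams/stdout"), "path"),
    stderr_path = xml_attr_or(xml2::xml_find_first(nd, "./streams/stderr"), "path"),
    env = env, task_actions = actions, checkers = checkers
  ), class = "task_spec")
}

has_placeholder <- function(x) grepl(PLACEHOLDER_RE, x)

task_templates <- function(task) {
  c(vapply(task$parameters, `[[`, character(1), "value"),
    task$stdout_path %||% character(0), task$stderr_path %||% character(0),
    unlist(lapply(task$task_actions, function(a) c(a$src, a$dst))),
    unname(task$env))
}

check_spec_invariants <- function(spec, path) {
  tasks <- spec$tasks
  ids <- vapply(tasks, `[[`, integer(1), "id")
  nms <- vapply(tasks, `[[`, character(1), "name")
  if (anyDuplicated(ids)) parse_error(path, sprintf("duplicate task id %d", ids[duplicated(ids)][1L]))
  if (anyDuplicated(nms)) parse_error(path, sprintf("duplicate task name '%s'", nms[duplicated(nms)][1L]))

  for (t in tasks) {
    for (d in t$dependencies) {
      if (is.null(resolve_task_ref(spec, d$target, quiet = TRUE))) {
        parse_error(path, sprintf("task %d: unresolved dependency target '%s'", t$id, d$target))
      }
    }
    if (!is.null(t$process_block_ref) && !t$process_block_ref %in% names(spec$blocks)) {
      parse_error(path, sprintf("task %d: unresolved process block '%s'",
                                t$id, t$process_block_ref))
    }
    if (!is.null(t$executor_ref) && !t$executor_ref %in% names(spec$executors)) {
      parse_error(path, sprintf("task %d: unresolved executor '%s'", t$id, t$executor_ref))
    }
    if (is.null(t$process_block_ref) && any(has_placeholder(task_templates(t)))) {
      parse_error(path, sprintf("task %d: instance placeholder used without a process block", t$id))
    }
  }

  g <- task_graph(spec)
  if (!igraph::is_dag(g)) parse_error(path, "dependency cycle among tasks")
  invisible(spec)
}

task_graph <- function(spec) {
  ids <- as.character(vapply(spec$tasks, `[[`, integer(1), "id"))
  edges <- character(0)
  for (t in spec$tasks) {
    for (d in t$dependencies) {
      up <- resolve_task_ref(spec, d$target)
      edges <- c(edges, as.character(up$id), as.character(t$id))
    }
  }
  igraph::graph_from_data_frame(
    d = if (length(edges)) as.data.frame(matrix(edges, ncol = 2, byrow = TRUE)) else
      data.frame(from = character(0), to = character(0)),
    vertices = data.frame(name = ids), directed = TRUE
  )
}

#' Resolve a task reference (id or name) to its task spec
#' @param spec A workflow spec.
#' @param ref Task id (as integer or digit string) or task name.
#' @param quiet Return `NULL` instead of erroring when unresolved.
#' @return The matching `task_spec`, or `NULL` with `quiet = TRUE`.
#' @export
resolve_task_ref <- function(spec, ref, quiet = FALSE) {
  ref <- as.character(ref)
  for (t in spec$tasks) {
    if (identical(as.character(t$id), ref) || identical(t$name, ref)) return(t)
  }
  if (quiet) return(NULL)
  th_abort(sprintf("unresolvable task reference '%s'", ref), "taskherd_parse_error")
}

#' Parse a workflow file
#'
#' Reads and statically validates a workflow document (see
#' [workflow_dialect]): settings are collected, each task element is matched
#' to its module name, references (dependencies, executors, process blocks)
#' are resolved and the task dependency graph is checked to be acyclic.
#' Constants are *not* yet substituted — see [resolve_constants()].
#'
#' @param xml_path Path to the workflow XML file.
#' @param registry Optional [module_registry()]; when given, unknown module
#'   element names are rejected at parse time.
#' @return A `workflow_spec` object.
#' @export
parse_workflow <- function(xml_path, registry = NULL) {
  if (!file.exists(xml_path)) {
    th_abort(sprintf("workflow file not found: %s", xml_path), "taskherd_parse_error")
  }
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    parse_error(xml_path, paste("XML syntax error:", conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "workflow") {
    parse_error(xml_path, "root element must be <workflow>")
  }

  settings_nd <- xml2::xml_find_first(root, "./settings")
  settings <- if (inherits(settings_nd, "xml_missing")) {
    list(constants = character(0),
         executors = list(local = new_executor_decl("local", "local", 1L, default = TRUE)),
         blocks = list(), module_folders = character(0))
  } else {
    parse_settings(settings_nd, xml_path)
  }

  tasks_nd <- xml2::xml_find_first(root, "./tasks")
  mail <- if (!inherits(tasks_nd, "xml_missing")) xml_attr_or(tasks_nd, "mail")
  if (!is.null(mail)) {
    # parsed for dialect compatibility; notification goes to the log instead
    message(sprintf("note: 'mail' attribute ('%s') is parsed and ignored; see run log", mail))
  }
  tasks <- list()
  if (!inherits(tasks_nd, "xml_missing")) {
    for (nd in xml2::xml_children(tasks_nd)) {
      t <- parse_task(nd, xml_path)
      if (!is.null(registry)) registry_lookup(registry, t$module_ref)
      tasks[[length(tasks) + 1L]] <- t
    }
  }

  spec <- structure(
    list(constants = settings$constants, executors = settings$executors,
         blocks = settings$blocks,
         module_folders = settings$module_folders,
         tasks = tasks, mail = mail, source_path = xml_path),
    class = "workflow_spec"
  )
  check_spec_invariants(spec, xml_path)
  spec
}

#' @export
print.workflow_spec <- function(x, ...) {
  cat(sprintf("<workflow: %d task(s), %d constant(s), %d block(s), %d executor(s)>\n",
              length(x$tasks), length(x$constants), length(x$blocks),
              length(x$executors)))
  for (t in x$tasks) {
    cat(sprintf("  [%d] %s (%s)%s%s\n", t$id, t$name, t$module_ref,
                if (!is.null(t$process_block_ref))
                  paste0(" block=", t$process_block_ref) else "",
                if (length(t$dependencies))
                  paste0(" deps=", paste(vapply(t$dependencies, `[[`, character(1),
                                               "target"), collapse = ",")) else ""))
  }
  invisible(x)
}

expand_constants_in <- function(text, constants, depth = 0L) {
  if (depth > 10L) {
    th_abort("constant expansion exceeds depth 10 (self-referential chain?)",
             "taskherd_parse_error")
  }
  m <- gregexpr(CONST_RE, text)[[1L]]
  if (m[1L] == -1L) return(text)
  toks <- regmatches(text, gregexpr(CONST_RE, text))[[1L]]
  for (tok in unique(toks)) {
    nm <- substr(tok, 3L, nchar(tok) - 1L)
    if (!nm %in% names(constants)) {
      th_abort(sprintf("undefined constant '%s'", nm), "taskherd_parse_error")
    }
    text <- gsub(tok, constants[[nm]], text, fixed = TRUE)
  }
  expand_constants_in(text, constants, depth + 1L)
}

#' Substitute `${NAME}` constants throughout a workflow spec
#'
#' Every constant reference in parameter values, stream paths, environment
#' values and task-action paths is replaced by the constant's value
#' (constants may reference other constants up to depth 10). Instance
#' placeholders are left untouched. Idempotent.
#'
#' @param spec A `workflow_spec`.
#' @return The spec with constants substituted.
#' @export
resolve_constants <- function(spec) {
  stopifnot(inherits(spec, "workflow_spec"))
  cst <- spec$constants
  sub1 <- function(x) if (is.null(x)) NULL else expand_constants_in(x, cst)
  spec$tasks <- lapply(spec$tasks, function(t) {
    t$parameters <- lapply(t$parameters, function(p) {
      p$value <- sub1(p$value); p
    })
    t$stdout_path <- sub1(t$stdout_path)
    t$stderr_path <- sub1(t$stderr_path)
    if (length(t$env)) t$env[] <- vapply(t$env, sub1, character(1))
    t$task_actions <- lapply(t$task_actions, function(a) {
      a$src <- sub1(a$src); a$dst <- sub1(a$dst); a
    })
    t
  })
  spec
}

#' Statically validate a workflow against its modules
#'
#' A lint pass: re-checks parse-time invariants and type-checks every task's
#' parameters against its module descriptor (after constant resolution;
#' values still containing instance placeholders are checked for placeholder
#' legality only). Returns diagnostics instead of throwing.
#'
#' @param spec A `workflow_spec`.
#' @param registry A [module_registry()].
#' @return A tibble with columns `task_id` and `message`; empty when the
#'   workflow is clean.
#' @export
validate_workflow <- function(spec, registry) {
  diags <- list()
  note <- function(task_id, msg) {
    diags[[length(diags) + 1L]] <<- list(task_id = task_id, message = msg)
  }
  rspec <- tryCatch(resolve_constants(spec), error = function(e) {
    note(NA_integer_, conditionMessage(e)); NULL
  })
  if (!is.null(rspec)) {
    for (t in rspec$tasks) {
      mod <- tryCatch(registry_lookup(registry, t$module_ref), error = function(e) {
        note(t$id, conditionMessage(e)); NULL
      })
      if (is.null(t$process_block_ref) && any(has_placeholder(task_templates(t)))) {
        note(t$id, "instance placeholder used without a process block")
      }
      if (is.null(mod)) next
      # collect per-name values; skip type checks for placeholder templates
      asn <- split(
        vapply(t$parameters, `[[`, character(1), "value"),
        vapply(t$parameters, `[[`, character(1), "name")
      )
      concrete <- lapply(asn, function(v) v[!has_placeholder(v)])
      holders <- names(asn)[vapply(asn, function(v) any(has_placeholder(v)), logical(1))]
      pn <- vapply(mod$params, `[[`, character(1), "name")
      for (h in holders) {
        if (!h %in% pn) note(t$id, sprintf("unknown parameter '%s'", h))
      }
      # treat placeholder-valued params as assigned strings for requiredness
      probe <- concrete
      for (h in intersect(holders, pn)) {
        p <- mod$params[[match(h, pn)]]
        if (p$type %in% c("string", "file", "folder")) {
          probe[[h]] <- c(probe[[h]], "placeholder")
        } else {
          probe[[h]] <- NULL  # cannot type-check until instantiation
          pidx <- match(h, pn)
          if (mod$params[[pidx]]$required && length(concrete[[h]]) == 0L) {
            probe[[h]] <- "0"  # placeholder satisfies requiredness
          }
        }
      }
      probe <- probe[lengths(probe) > 0L]
      tryCatch(render_command(mod, probe), error = function(e) {
        note(t$id, conditionMessage(e))
      })
    }
  }
  tibble::tibble(
    task_id = vapply(diags, function(d) as.integer(d$task_id), integer(1)),
    message = vapply(diags, `[[`, character(1), "message")
  )
}

# ---- serialization (round-trip surface) ------------------------------------

#' Serialize a workflow spec back to XML text
#'
#' Produces a document in the workflow dialect that parses back to an equal
#' spec (`parse -> serialize -> parse` is a fixed point).
#'
#' @param spec A `workflow_spec`.
#' @return A single XML string.
#' @export
workflow_to_xml <- function(spec) {
  root <- xml2::xml_new_root("workflow")
  st <- xml2::xml_add_child(root, "settings")
  if (length(spec$constants)) {
    cs <- xml2::xml_add_child(st, "constants")
    for (nm in names(spec$constants)) {
      xml2::xml_add_child(cs, "const", name = nm, value = spec$constants[[nm]])
    }
  }
  ex <- xml2::xml_add_child(st, "executors")
  for (e in spec$executors) {
    nd <- xml2::xml_add_child(ex, "executor", name = e$name, type = e$exec_type,
                              maxSlots = as.character(e$max_slots))
    if (e$default) xml2::xml_set_attr(nd, "default", "true")
    for (a in names(e$attributes)) xml2::xml_set_attr(nd, a, e$attributes[[a]])
  }
  if (length(spec$blocks)) {
    pb <- xml2::xml_add_child(st, "processBlock")
    for (b in spec$blocks) {
      switch(b$kind,
        sequence = xml2::xml_add_child(pb, "processSequence", name = b$name,
          start = format_block_number(b$start), end = format_block_number(b$end),
          step = format_block_number(b$step)),
        folder = xml2::xml_add_child(pb, "processFolder", name = b$name,
          folder = b$folder, pattern = b$pattern),
        table = xml2::xml_add_child(pb, "processTable", name = b$name, table = b$table),
        input = {
          nd <- xml2::xml_add_child(pb, "processInput", name = b$name)
          if (isTRUE(b$compare_by_index)) xml2::xml_set_attr(nd, "compareByIndex", "true")
        },
        {
          nd <- xml2::xml_add_child(pb, b$kind, name = b$name)
          for (f in setdiff(names(b), c("kind", "name"))) {
            xml2::xml_set_attr(nd, f, as.character(b[[f]]))
          }
        }
      )
    }
  }
  if (length(spec$module_folders)) {
    mf <- xml2::xml_add_child(st, "moduleFolders")
    for (p in spec$module_folders) xml2::xml_add_child(mf, "folder", path = p)
  }

  ts <- xml2::xml_add_child(root, "tasks")
  if (!is.null(spec$mail)) xml2::xml_set_attr(ts, "mail", spec$mail)
  for (t in spec$tasks) {
    nd <- xml2::xml_add_child(ts, t$module_ref, id = as.character(t$id), name = t$name)
    if (!is.null(t$process_block_ref)) xml2::xml_set_attr(nd, "processBlock", t$process_block_ref)
    if (!is.null(t$executor_ref)) xml2::xml_set_attr(nd, "executor", t$executor_ref)
    if (!is.null(t$max_running)) xml2::xml_set_attr(nd, "maxRunning", as.character(t$max_running))
    if (t$checkpoint) xml2::xml_set_attr(nd, "checkpoint", "true")
    if (length(t$parameters)) {
      pnd <- xml2::xml_add_child(nd, "parameter")
      for (p in t$parameters) {
        ch <- xml2::xml_add_child(pnd, p$name)
        xml2::xml_set_text(ch, p$value)
      }
    }
    if (length(t$dependencies)) {
      dnd <- xml2::xml_add_child(nd, "dependencies")
      for (d in t$dependencies) {
        ch <- xml2::xml_add_child(dnd, "depends")
        xml2::xml_set_text(ch, d$target)
        if (d$separate) xml2::xml_set_attr(ch, "separate", "true")
      }
    }
    if (!is.null(t$stdout_path) || !is.null(t$stderr_path)) {
      snd <- xml2::xml_add_child(nd, "streams")
      if (!is.null(t$stdout_path)) xml2::xml_add_child(snd, "stdout", path = t$stdout_path)
      if (!is.null(t$stderr_path)) xml2::xml_add_child(snd, "stderr", path = t$stderr_path)
    }
    if (length(t$env)) {
      end_ <- xml2::xml_add_child(nd, "environment")
      for (nm in names(t$env)) {
        xml2::xml_add_child(end_, "var", name = nm, value = t$env[[nm]])
      }
    }
    if (length(t$task_actions)) {
      and <- xml2::xml_add_child(nd, "actions")
      for (a in t$task_actions) {
        ch <- xml2::xml_add_child(and, "action", phase = a$phase, type = a$action)
        if (!is.null(a$src)) xml2::xml_set_attr(ch, "src", a$src)
        if (!is.null(a$dst)) xml2::xml_set_attr(ch, "dst", a$dst)
      }
    }
    if (length(t$checkers)) {
      cnd <- xml2::xml_add_child(nd, "checkers")
      for (ck in t$checkers) {
        args <- paste(vapply(ck$ctor_args, function(a) paste0(a$type, ":", a$value),
                             character(1)), collapse = ",")
        ch <- xml2::xml_add_child(cnd, "checker", name = ck$checker_name, kind = ck$kind)
        if (nzchar(args)) xml2::xml_set_attr(ch, "args", args)
      }
    }
  }
  as.character(root)
}
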