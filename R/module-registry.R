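#' Declare a module parameter
#'
#' A module wraps one command-line program; its parameters are declared with a
#' name, a value type and optional constraints so that workflow-supplied
#' values can be validated before any command is launched.
#'
#' @param name Parameter name (non-empty, unique within a module).
#' @param type One of `"string"`, `"integer"`, `"double"`, `"file"`,
#'   `"folder"`, `"flag"`, `"enum"`.
#' @param required Is the parameter mandatory? Required parameters have
#'   `min_occurs >= 1`.
#' @param default Optional default value rendered when the parameter is not
#'   assigned in the workflow.
#' @param min,max Optional numeric range, only legal for integer/double.
#' @param min_occurs,max_occurs Occurrence bounds; a multi-valued parameter is
#'   rendered once per value.
#' @param enum_values Allowed values for `type = "enum"`.
#' @return A `param_def` object.
#' @export
param_def <- function(name, type = "string", required = FALSE, default = NULL,
                      min = NULL, max = NULL,
                      min_occurs = if (required) 1L else 0L, max_occurs = 1L,
                      enum_values = NULL) {
  if (!is_string(name) || !nzchar(name)) {
    th_abort("parameter name must be a non-empty string", "taskherd_module_error")
  }
  types <- c("string", "integer", "double", "file", "folder", "flag", "enum")
  if (!is_string(type) || !type %in% types) {
    th_abort(sprintf("unknown value type '%s' for parameter '%s'", type, name),
             "taskherd_module_error")
  }
  if ((!is.null(min) || !is.null(max)) && !type %in% c("integer", "double")) {
    th_abort(sprintf("numeric range not permitted on %s parameter '%s'", type, name),
             "taskherd_module_error")
  }
  if (!is.null(min) && !is.null(max) && as.numeric(min) > as.numeric(max)) {
    th_abort(sprintf("range min > max for parameter '%s'", name), "taskherd_module_error")
  }
  if (type == "flag" && (!is.null(default) || !is.null(min) || !is.null(max))) {
    th_abort(sprintf("flag parameter '%s' takes no value, default or range", name),
             "taskherd_module_error")
  }
  if (type == "enum" && (is.null(enum_values) || length(enum_values) == 0L)) {
    th_abort(sprintf("enum parameter '%s' needs enum_values", name), "taskherd_module_error")
  }
  min_occurs <- as.integer(min_occurs)
  max_occurs <- as.integer(max_occurs)
  if (min_occurs < 0L || max_occurs < 0L || min_occurs > max_occurs) {
    th_abort(sprintf("invalid occurrence bounds for parameter '%s'", name),
             "taskherd_module_error")
  }
  required <- isTRUE(required) || min_occurs >= 1L
  if (required && min_occurs < 1L) min_occurs <- 1L
  structure(
    list(name = name, type = type, required = required,
         default = default, min = min, max = max,
         min_occurs = min_occurs, max_occurs = max_occurs,
         enum_values = enum_values),
    class = "param_def"
  )
}

#' Declare a module return parameter
#'
#' Return parameters are key-value outputs a finished subtask exposes (via its
#' return file) so downstream tasks can consume them through an input process
#' block.
#'
#' @param name Return parameter name.
#' @param type One of `"string"`, `"integer"`, `"double"`, `"boolean"`.
#' @return A `return_def` object.
#' @export
return_def <- function(name, type = "string") {
  if (!is_string(name) || !nzchar(name)) {
    th_abort("return parameter name must be non-empty", "taskherd_module_error")
  }
  if (!type %in% c("string", "integer", "double", "boolean")) {
    th_abort(sprintf("unknown return type '%s'", type), "taskherd_module_error")
  }
  structure(list(name = name, type = type), class = "return_def")
}

#' Construct a module descriptor
#'
#' @param module_name Name the workflow uses as the task element name.
#' @param command Character vector of argv tokens (executable + fixed args).
#' @param params List of [param_def()] objects.
#' @param returns List of [return_def()] objects.
#' @param module_dir Folder the descriptor lives in (scripts are resolved
#'   relative to it).
#' @return A `module_descriptor` object.
#' @export
module_descriptor <- function(module_name, command, params = list(),
                              returns = list(), module_dir = NULL) {
  if (!is_string(module_name) || !nzchar(module_name)) {
    th_abort("module name must be non-empty", "taskherd_module_error")
  }
  if (length(command) == 0L || !nzchar(command[[1L]])) {
    th_abort(sprintf("module '%s': command must be non-empty", module_name),
             "taskherd_module_error")
  }
  pnames <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(pnames)) {
    th_abort(sprintf("module '%s': duplicate parameter '%s'",
                     module_name, pnames[duplicated(pnames)][1L]),
             "taskherd_module_error")
  }
  rnames <- vapply(returns, `[[`, character(1), "name")
  if (anyDuplicated(rnames)) {
    th_abort(sprintf("module '%s': duplicate return parameter '%s'",
                     module_name, rnames[duplicated(rnames)][1L]),
             "taskherd_module_error")
  }
  structure(
    list(module_name = module_name, command = as.character(command),
         params = params, returns = returns, module_dir = module_dir),
    class = "module_descriptor"
  )
}

#' @export
print.module_descriptor <- function(x, ...) {
  cat(sprintf("<module '%s'> command: %s\n", x$module_name,
              paste(x$command, collapse = " ")))
  for (p in x$params) {
    cat(sprintf("  param %s (%s%s)\n", p$name, p$type,
                if (p$required) ", required" else ""))
  }
  for (r in x$returns) cat(sprintf("  return %s (%s)\n", r$name, r$type))
  invisible(x)
}

#' Load a module descriptor from disk
#'
#' Reads a `<name>.module.xml` descriptor: root `module` element with `name`
#' and `command` attributes (command whitespace-split into argv) and `param` /
#' `return` children. A relative executable token is resolved against the
#' module folder at render time.
#'
#' @param descriptor_path Path to the descriptor XML file.
#' @return A validated [module_descriptor()].
#' @export
load_module <- function(descriptor_path) {
  if (!file.exists(descriptor_path)) {
    th_abort(sprintf("module descriptor not found: %s", descriptor_path),
             "taskherd_module_error")
  }
  doc <- tryCatch(xml2::read_xml(descriptor_path), error = function(e) {
    th_abort(sprintf("malformed module XML '%s': %s", descriptor_path,
                     conditionMessage(e)), "taskherd_module_error")
  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "module") {
    th_abort(sprintf("'%s': root element must be <module>", descriptor_path),
             "taskherd_module_error")
  }
  name <- xml_attr_or(root, "name")
  cmd <- xml_attr_or(root, "command")
  if (is.null(name) || is.null(cmd)) {
    th_abort(sprintf("'%s': <module> needs name and command attributes",
                     descriptor_path), "taskherd_module_error")
  }
  argv <- strsplit(trimws(cmd), "[[:space:]]+")[[1L]]

  params <- lapply(xml2::xml_find_all(root, "./param"), function(nd) {
    mn <- xml_attr_or(nd, "min"); mx <- xml_attr_or(nd, "max")
    enum <- xml_attr_or(nd, "enum")
    param_def(
      name = xml_attr_or(nd, "name", ""),
      type = xml_attr_or(nd, "type", "string"),
      required = identical(xml_attr_or(nd, "required", "false"), "true"),
      default = xml_attr_or(nd, "default"),
      min = if (!is.null(mn)) as.numeric(mn),
      max = if (!is.null(mx)) as.numeric(mx),
      min_occurs = as.integer(xml_attr_or(nd, "minOccurs",
        if (identical(xml_attr_or(nd, "required", "false"), "true")) "1" else "0")),
      max_occurs = as.integer(xml_attr_or(nd, "maxOccurs", "1")),
      enum_values = if (!is.null(enum)) strsplit(enum, ",", fixed = TRUE)[[1L]]
    )
  })
  returns <- lapply(xml2::xml_find_all(root, "./return"), function(nd) {
    return_def(xml_attr_or(nd, "name", ""), xml_attr_or(nd, "type", "string"))
  })
  module_descriptor(name, argv, params, returns,
                    module_dir = normalizePath(dirname(descriptor_path)))
}

truthy_flag <- function(v) tolower(v) %in% c("true", "1", "yes")

#' Render a command invocation from validated parameter assignments
#'
#' Produces the argv for one subtask: the module's fixed command followed by
#' one `--name value` pair per non-flag assignment (repeated per occurrence,
#' in descriptor declaration order) and a bare `--name` for set flags.
#' Unassigned optional parameters with a default are rendered with the
#' default. Output is deterministic: permuting the assignment map never
#' changes the argv.
#'
#' @param descriptor A [module_descriptor()].
#' @param assignments Named list mapping parameter name to a character vector
#'   of values (flags: `"true"`/`"false"`).
#' @return Character vector of argv tokens.
#' @export
render_command <- function(descriptor, assignments = list()) {
  stopifnot(inherits(descriptor, "module_descriptor"))
  pnames <- vapply(descriptor$params, `[[`, character(1), "name")
  unknown <- setdiff(names(assignments), pnames)
  if (length(unknown) > 0L) {
    th_abort(sprintf("module '%s': unknown parameter '%s'",
                     descriptor$module_name, unknown[[1L]]),
             "taskherd_render_error")
  }
  argv <- descriptor$command
  # resolve a relative executable against the module folder
  if (!is.null(descriptor$module_dir) && !grepl("^/", argv[[1L]]) &&
      file.exists(file.path(descriptor$module_dir, argv[[1L]]))) {
    argv[[1L]] <- file.path(descriptor$module_dir, argv[[1L]])
  }
  for (p in descriptor$params) {
    vals <- assignments[[p$name]]
    if (is.null(vals) && !is.null(p$default) && p$type != "flag") vals <- p$default
    if (is.null(vals) || length(vals) == 0L) {
      if (p$required) {
        th_abort(sprintf("module '%s': missing required parameter '%s'",
                         descriptor$module_name, p$name), "taskherd_render_error")
      }
      next
    }
    vals <- as.character(vals)
    if (p$type == "flag") {
      if (length(vals) > 1L || is.null(parse_typed(vals, "boolean"))) {
        th_abort(sprintf("flag '%s' must be a single true/false value", p$name),
                 "taskherd_render_error")
      }
      if (truthy_flag(vals)) argv <- c(argv, paste0("--", p$name))
      next
    }
    n_eff <- length(vals)
    if (n_eff < p$min_occurs || n_eff > p$max_occurs) {
      th_abort(sprintf("parameter '%s': %d value(s) given, %d..%d allowed",
                       p$name, n_eff, p$min_occurs, p$max_occurs),
               "taskherd_render_error")
    }
    for (v in vals) {
      if (is.null(parse_typed(v, p$type))) {
        th_abort(sprintf("parameter '%s': value '%s' is not a valid %s",
                         p$name, v, p$type), "taskherd_render_error")
      }
      if (p$type %in% c("integer", "double")) {
        x <- as.numeric(v)
        if ((!is.null(p$min) && x < p$min) || (!is.null(p$max) && x > p$max)) {
          th_abort(sprintf("parameter '%s': value %s outside range [%s, %s]",
                           p$name, v, p$min %||% "-Inf", p$max %||% "Inf"),
                   "taskherd_render_error")
        }
      }
      if (p$type == "enum" && !v %in% p$enum_values) {
        th_abort(sprintf("parameter '%s': '%s' not in {%s}", p$name, v,
                         paste(p$enum_values, collapse = ", ")),
                 "taskherd_render_error")
      }
      argv <- c(argv, paste0("--", p$name), v)
    }
  }
  argv
}

param_to_xml_attrs <- function(p) {
  attrs <- c(name = p$name, type = p$type)
  if (p$required) attrs <- c(attrs, required = "true")
  if (!is.null(p$default)) attrs <- c(attrs, default = as.character(p$default))
  if (!is.null(p$min)) attrs <- c(attrs, min = format_block_number(p$min))
  if (!is.null(p$max)) attrs <- c(attrs, max = format_block_number(p$max))
  if (p$min_occurs != (if (p$required) 1L else 0L)) {
    attrs <- c(attrs, minOccurs = as.character(p$min_occurs))
  }
  if (p$max_occurs != 1L) attrs <- c(attrs, maxOccurs = as.character(p$max_occurs))
  if (!is.null(p$enum_values)) attrs <- c(attrs, enum = paste(p$enum_values, collapse = ","))
  attrs
}

#' Scaffold a new module folder
#'
#' Writes a module folder containing a descriptor file that round-trips
#' through [load_module()], and optionally an executable POSIX shell skeleton
#' that parses the declared `--name value` arguments and exits 0 — a starting
#' point the developer edits to call the real program.
#'
#' @param name Module name; also the folder and script name.
#' @param param_specs List of [param_def()] objects.
#' @param with_skeleton Also write the skeleton script and point the module
#'   command at it?
#' @param parent_dir Directory in which the module folder is created.
#' @param returns Optional list of [return_def()] objects.
#' @param command Fixed argv for descriptor-only scaffolds (ignored when
#'   `with_skeleton` is TRUE). Defaults to `"true"`.
#' @return Invisibly, the created module folder path.
#' @export
scaffold_module <- function(name, param_specs = list(), with_skeleton = TRUE,
                            parent_dir = ".", returns = list(),
                            command = "true") {
  target <- file.path(parent_dir, name)
  if (file.exists(target)) {
    th_abort(sprintf("module folder already exists: %s", target),
             "taskherd_module_error")
  }
  desc <- module_descriptor(
    name, if (with_skeleton) paste0(name, ".sh") else command,
    param_specs, returns
  )  # validates param specs before anything is written
  dir.create(target, recursive = TRUE)

  root <- xml2::xml_new_root("module", name = name,
                             command = paste(desc$command, collapse = " "))
  for (p in param_specs) {
    nd <- xml2::xml_add_child(root, "param")
    attrs <- param_to_xml_attrs(p)
    for (a in names(attrs)) xml2::xml_set_attr(nd, a, attrs[[a]])
  }
  for (r in returns) {
    xml2::xml_add_child(root, "return", name = r$name, type = r$type)
  }
  xml2::write_xml(root, file.path(target, paste0(name, ".module.xml")))

  if (with_skeleton) {
    script <- file.path(target, paste0(name, ".sh"))
    lines <- c(
      "#!/bin/sh",
      sprintf("# %s: generated skeleton; add the real program call below.", name),
      "set -eu"
    )
    for (p in param_specs) {
      lines <- c(lines, sprintf("%s=''", toupper(p$name)))
    }
    lines <- c(lines,
      "while [ $# -gt 0 ]; do",
      "  case \"$1\" in")
    for (p in param_specs) {
      if (p$type == "flag") {
        lines <- c(lines, sprintf("    --%s) %s=true; shift ;;", p$name, toupper(p$name)))
      } else {
        lines <- c(lines, sprintf("    --%s) %s=\"$2\"; shift 2 ;;", p$name, toupper(p$name)))
      }
    }
    lines <- c(lines,
      "    *) echo \"unknown argument: $1\" >&2; exit 64 ;;",
      "  esac",
      "done",
      "exit 0")
    writeLines(lines, script)
    Sys.chmod(script, "755")
  }
  invisible(target)
}

#' Build a module registry from a search path
#'
#' Scans each folder for module sub-folders containing `*.module.xml`
#' descriptors. Lookup resolves a workflow task element name to the first
#' descriptor with that module name along the search path; the package's
#' built-in `modules/` folder is always appended last.
#'
#' @param module_folders Character vector of folders to search, in priority
#'   order.
#' @param include_builtin Append the built-in module folder shipped with the
#'   package?
#' @return A `module_registry` object.
#' @export
module_registry <- function(module_folders = character(0), include_builtin = TRUE) {
  folders <- as.character(module_folders)
  if (include_builtin) {
    builtin <- system.file("modules", package = "taskherd")
    if (nzchar(builtin)) folders <- c(folders, builtin)
  }
  modules <- list()
  for (folder in folders) {
    if (!dir.exists(folder)) next
    descs <- list.files(folder, pattern = "\\.module\\.xml$",
                        recursive = TRUE, full.names = TRUE)
    for (d in sort(descs)) {
      m <- load_module(d)
      if (is.null(modules[[m$module_name]])) modules[[m$module_name]] <- m
    }
  }
  structure(list(modules = modules, folders = folders), class = "module_registry")
}

#' Look up a module by name
#' @param registry A [module_registry()].
#' @param name Module name (the workflow's task element name).
#' @return The [module_descriptor()], or an error if unknown.
#' @export
registry_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "module_registry"))
  m <- registry$modules[[name]]
  if (is.null(m)) {
    th_abort(sprintf("unknown module '%s' (searched: %s)", name,
                     paste(registry$folders, collapse = ", ")),
             "taskherd_module_error")
  }
  m
}

#' @export
print.module_registry <- function(x, ...) {
  cat(sprintf("<module registry: %d module(s)>\n", length(x$modules)))
  for (nm in names(x$modules)) cat(" -", nm, "\n")
  invisible(x)
}
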