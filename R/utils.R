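# Internal helpers shared across the engine.

th_abort <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "taskherd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# subtask key "taskId-index" (index 0 for block-less tasks)
subtask_key <- function(task_id, subtask_index) {
  paste0(task_id, "-", subtask_index)
}

# Stable content hash for journal matching; argv tokens joined with an
# unprintable separator so no legal argv collides.
argv_hash <- function(argv) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(charToRaw(paste(argv, collapse = "\x1f")), tmp)
  unname(tools::md5sum(tmp))
}

# TSV key<TAB>value reader used for return-value files and journals.
read_kv_tsv <- function(path) {
  if (!file.exists(path)) return(character(0))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  if (any(bad)) {
    th_abort(sprintf("unparsable return file '%s': line without key<TAB>value", path),
             "taskherd_return_file_error")
  }
  vals <- vapply(parts, function(p) paste(p[-1L], collapse = "\t"), character(1))
  names(vals) <- vapply(parts, `[[`, character(1), 1L)
  vals
}

# parse a value against a declared scalar type; returns normalized text or NULL
parse_typed <- function(value, type) {
  switch(type,
    string = value,
    file = value,
    folder = value,
    integer = {
      if (grepl("^[+-]?[0-9]+$", value)) value else NULL
    },
    double = {
      x <- suppressWarnings(as.numeric(value))
      if (is.na(x)) NULL else value
    },
    boolean = {
      if (tolower(value) %in% c("true", "false", "0", "1")) value else NULL
    },
    flag = value,
    enum = value,
    NULL
  )
}

xml_attr_or <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

# format numbers for instance values: integral values without decimal point
format_block_number <- function(x) {
  if (isTRUE(all.equal(x, round(x))) && abs(x) < 1e15) {
    sprintf("%.0f", round(x))
  } else {
    format(x, trim = TRUE, scientific = FALSE)
  }
}
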