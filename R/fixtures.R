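#' Synthetic inputs and bundled demonstration scenarios
#'
#' Everything a test or demo run needs is generated in code: folders of toy
#' log files, gzipped FASTQ-like read files, and self-contained scenario
#' folders (workflow XML + modules + data) each demonstrating one engine
#' feature. Generation is a pure function of its parameters and seed.
#'
#' @name fixtures
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a folder of toy log files
#'
#' Writes `n` plain-text files `sample_001.log` ... with deterministic
#' pseudo-random content; the same seed gives byte-identical files.
#'
#' @param dir Target folder (created if needed).
#' @param n Number of files.
#' @param seed RNG seed.
#' @return Invisibly, the file paths.
#' @export
make_log_folder <- function(dir, n, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    th_abort(sprintf("cannot create log folder %s", dir), "taskherd_fixture_error")
  }
  paths <- character(0)
  with_seed(seed, {
    for (i in seq_len(n)) {
      p <- file.path(dir, sprintf("sample_%03d.log", i))
      lines <- sprintf("%s event=%s value=%.4f",
                       format(as.POSIXct("2024-01-01", tz = "UTC") + i * 60,
                              "%Y-%m-%dT%H:%M:%S"),
                       sample(c("start", "stop", "warn", "info"), 20, replace = TRUE),
                       stats::runif(20))
      writeLines(lines, p)
      paths <- c(paths, p)
    }
  })
  invisible(paths)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate gzipped toy FASTQ files
#'
#' One gzip-compressed FASTQ file per sample with exactly
#' `reads_per_sample` four-line records. A small stand-in for a real
#' sequencing dataset; read content is random DNA with uniform qualities
#' and makes no biological claim.
#'
#' @param dir Target folder.
#' @param samples Number of sample files.
#' @param reads_per_sample Records per file.
#' @param seed RNG seed.
#' @return Invisibly, the file paths.
#' @export
make_toy_fastq <- function(dir, samples = 2L, reads_per_sample = 100L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  with_seed(seed, {
    for (s in seq_len(samples)) {
      p <- file.path(dir, sprintf("sample%d.fastq.gz", s))
      con <- gzfile(p, "wb")
      lines <- character(0)
      for (r in seq_len(reads_per_sample)) {
        seqline <- random_dna(50L)
        lines <- c(lines,
                   sprintf("@sample%d.read%d", s, r),
                   seqline,
                   "+",
                   paste(rep("I", nchar(seqline)), collapse = ""))
      }
      writeLines(lines, con)
      close(con)
      paths <- c(paths, p)
    }
  })
  invisible(paths)
}

write_scenario_module <- function(modules_dir, name, script_lines,
                                  params = list(), returns = list()) {
  dir.create(file.path(modules_dir, name), recursive = TRUE, showWarnings = FALSE)
  root <- xml2::xml_new_root("module", name = name, command = paste0(name, ".sh"))
  for (p in params) {
    nd <- xml2::xml_add_child(root, "param")
    attrs <- param_to_xml_attrs(p)
    for (a in names(attrs)) xml2::xml_set_attr(nd, a, attrs[[a]])
  }
  for (r in returns) xml2::xml_add_child(root, "return", name = r$name, type = r$type)
  xml2::write_xml(root, file.path(modules_dir, name, paste0(name, ".module.xml")))
  script <- file.path(modules_dir, name, paste0(name, ".sh"))
  writeLines(c("#!/bin/sh", "set -eu", script_lines), script)
  Sys.chmod(script, "755")
  invisible(name)
}

# the standard --name value parser prologue for scenario module scripts
sh_argparse <- function(...) {
  names <- c(...)
  c(vapply(names, function(n) sprintf("%s=''", toupper(n)), character(1)),
    "while [ $# -gt 0 ]; do case \"$1\" in",
    vapply(names, function(n)
      sprintf("  --%s) %s=\"$2\"; shift 2 ;;", n, toupper(n)), character(1)),
    "  *) echo \"unknown arg $1\" >&2; exit 64 ;;",
    "esac; done")
}

SCENARIOS <- c("sleep_constant", "block_demo", "compress_logs", "task_barrier",
               "subtask_pipeline", "parallel_hosts", "extract_merge")

#' Emit a self-contained demonstration scenario
#'
#' Writes a folder holding `workflow.xml`, a `modules/` library and any data
#' the workflow needs, ready for [cli_run()] or [run_workflow()]. Available
#' scenarios:
#' \describe{
#'   \item{sleep_constant}{one sleep task whose `wait` parameter comes from
#'     the constant `WAIT_TIME` (default 30).}
#'   \item{block_demo}{a 3-instance numeric sequence (1, 5, 9) and a folder
#'     block over generated log files, each feeding an echo task.}
#'   \item{compress_logs}{compress every log file in a folder; at most two
#'     subtasks run simultaneously (`maxRunning=2`).}
#'   \item{task_barrier}{task B task-level-depends on A1, A2 (3-instance
#'     sequence block) and A3 — five completions before B starts.}
#'   \item{subtask_pipeline}{stage A emits per-file return values consumed
#'     by stage B through an input block with a subtask-level dependency —
#'     B_x starts as soon as A_x is done.}
#'   \item{parallel_hosts}{two pipelined 2-instance tasks on a declared
#'     virtual executor with two hosts and slave-mode affinity.}
#'   \item{extract_merge}{the full portable example: decompress gzipped
#'     FASTQ, extract headers (at most 4 in parallel) and sequences (serial)
#'     per sample, recompress, and merge — only gzip/awk/cat needed.}
#' }
#'
#' @param scenario One of the scenario names above.
#' @param outdir Folder to create (must not already contain a workflow).
#' @param n Number of log files / instances for folder-based scenarios.
#' @param samples,reads_per_sample FASTQ scenario size.
#' @param seed RNG seed for data generation.
#' @param wait_time Constant value for `sleep_constant` (seconds).
#' @return Invisibly, the path to the emitted `workflow.xml`.
#' @export
emit_scenario <- function(scenario, outdir, n = 5L, samples = 2L,
                          reads_per_sample = 50L, seed = 1L, wait_time = 30L) {
  scenario <- match.arg(scenario, SCENARIOS)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  modules_dir <- file.path(outdir, "modules")
  wf_path <- file.path(outdir, "workflow.xml")

  echo_module <- function() {
    write_scenario_module(modules_dir, "echoTask",
      c(sh_argparse("text"), "printf '%s\\n' \"$TEXT\""),
      params = list(param_def("text", "string", required = TRUE)))
  }

  xml <- switch(scenario,
    sleep_constant = {
      write_scenario_module(modules_dir, "sleepTask",
        c(sh_argparse("wait"), "sleep \"$WAIT\""),
        params = list(param_def("wait", "integer", required = TRUE, min = 0)))
      sprintf(
'<workflow>
  <settings>
    <constants>
      <const name="WAIT_TIME" value="%d"/>
    </constants>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <sleepTask id="1" name="sleep">
      <parameter><wait>${WAIT_TIME}</wait></parameter>
    </sleepTask>
  </tasks>
</workflow>', wait_time)
    },

    block_demo = {
      echo_module()
      make_log_folder(file.path(outdir, "logs"), n, seed)
      sprintf(
'<workflow>
  <settings>
    <executors><executor name="local" type="local" maxSlots="4" default="true"/></executors>
    <processBlock>
      <processSequence name="num" start="1" end="9" step="4"/>
      <processFolder name="logFiles" folder="%s" pattern="*.log"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <echoTask id="1" name="echoNum" processBlock="num">
      <parameter><text>{}</text></parameter>
    </echoTask>
    <echoTask id="2" name="echoLog" processBlock="logFiles">
      <parameter><text>[1]</text></parameter>
    </echoTask>
  </tasks>
</workflow>', file.path(outdir, "logs"))
    },

    compress_logs = {
      write_scenario_module(modules_dir, "compressTask",
        c(sh_argparse("input", "output"),
          "mkdir -p \"$(dirname \"$OUTPUT\")\"",
          "gzip -c \"$INPUT\" > \"$OUTPUT\""),
        params = list(param_def("input", "file", required = TRUE),
                      param_def("output", "file", required = TRUE)),
        returns = list(return_def("file", "string")))
      make_log_folder(file.path(outdir, "logs"), n, seed)
      sprintf(
'<workflow>
  <settings>
    <executors><executor name="local" type="local" maxSlots="8" default="true"/></executors>
    <processBlock>
      <processFolder name="logFiles" folder="%s" pattern="*.log"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <compressTask id="1" name="compress" processBlock="logFiles" maxRunning="2">
      <parameter><input>{}</input><output>%s/[1].gz</output></parameter>
    </compressTask>
  </tasks>
</workflow>', file.path(outdir, "logs"), file.path(outdir, "out"))
    },

    task_barrier = {
      echo_module()
      paste0(
'<workflow>
  <settings>
    <executors><executor name="sim" type="virtual" maxSlots="8" default="true"/></executors>
    <processBlock>
      <processSequence name="three" start="1" end="3" step="1"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <echoTask id="1" name="A1"><parameter><text>a1</text></parameter></echoTask>
    <echoTask id="2" name="A2" processBlock="three">
      <parameter><text>{}</text></parameter>
    </echoTask>
    <echoTask id="3" name="A3"><parameter><text>a3</text></parameter></echoTask>
    <echoTask id="4" name="B">
      <parameter><text>b</text></parameter>
      <dependencies>
        <depends>A1</depends>
        <depends>A2</depends>
        <depends>A3</depends>
      </dependencies>
    </echoTask>
  </tasks>
</workflow>')
    },

    subtask_pipeline = {
      make_log_folder(file.path(outdir, "logs"), n, seed)
      write_scenario_module(modules_dir, "countTask",
        c(sh_argparse("input"),
          "N=$(wc -l < \"$INPUT\")",
          "printf 'file\\t%s\\nfCount\\t%s\\n' \"$INPUT\" \"$N\" > \"$TASKHERD_RETURN_FILE\""),
        params = list(param_def("input", "file", required = TRUE)),
        returns = list(return_def("file", "string"), return_def("fCount", "integer")))
      echo_module()
      sprintf(
'<workflow>
  <settings>
    <executors><executor name="local" type="local" maxSlots="4" default="true"/></executors>
    <processBlock>
      <processFolder name="logFiles" folder="%s" pattern="*.log"/>
      <processInput name="fromCount"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <countTask id="1" name="count" processBlock="logFiles">
      <parameter><input>{}</input></parameter>
    </countTask>
    <echoTask id="2" name="report" processBlock="fromCount">
      <parameter><text>{$file}:{$fCount}</text></parameter>
      <dependencies><depends separate="true">count</depends></dependencies>
    </echoTask>
  </tasks>
</workflow>', file.path(outdir, "logs"))
    },

    parallel_hosts = {
      echo_module()
      paste0(
'<workflow>
  <settings>
    <executors>
      <executor name="sim" type="virtual" maxSlots="2" hosts="2" slotsPerHost="1" slaveMode="true" default="true"/>
    </executors>
    <processBlock>
      <processSequence name="two" start="1" end="2" step="1"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <echoTask id="1" name="stage1" processBlock="two">
      <parameter><text>{}</text></parameter>
    </echoTask>
    <echoTask id="2" name="stage2" processBlock="two">
      <parameter><text>{}</text></parameter>
      <dependencies><depends separate="true">stage1</depends></dependencies>
    </echoTask>
  </tasks>
</workflow>')
    },

    extract_merge = {
      make_toy_fastq(file.path(outdir, "data"), samples, reads_per_sample, seed)
      work <- file.path(outdir, "work")
      out <- file.path(outdir, "out")
      write_scenario_module(modules_dir, "gunzipTask",
        c(sh_argparse("input", "output"),
          "mkdir -p \"$(dirname \"$OUTPUT\")\"",
          "gzip -dc \"$INPUT\" > \"$OUTPUT\"",
          "printf 'file\\t%s\\n' \"$OUTPUT\" > \"$TASKHERD_RETURN_FILE\""),
        params = list(param_def("input", "file", required = TRUE),
                      param_def("output", "file", required = TRUE)),
        returns = list(return_def("file", "string")))
      write_scenario_module(modules_dir, "extractTask",
        c(sh_argparse("input", "output", "line"),
          "mkdir -p \"$(dirname \"$OUTPUT\")\"",
          "awk -v k=\"$LINE\" 'NR % 4 == k % 4' \"$INPUT\" > \"$OUTPUT\"",
          "printf 'file\\t%s\\n' \"$OUTPUT\" > \"$TASKHERD_RETURN_FILE\""),
        params = list(param_def("input", "file", required = TRUE),
                      param_def("output", "file", required = TRUE),
                      param_def("line", "integer", required = TRUE, min = 1, max = 4)),
        returns = list(return_def("file", "string")))
      write_scenario_module(modules_dir, "compressTask",
        c(sh_argparse("input", "output"),
          "mkdir -p \"$(dirname \"$OUTPUT\")\"",
          "gzip -c \"$INPUT\" > \"$OUTPUT\"",
          "printf 'file\\t%s\\n' \"$OUTPUT\" > \"$TASKHERD_RETURN_FILE\""),
        params = list(param_def("input", "file", required = TRUE),
                      param_def("output", "file", required = TRUE)),
        returns = list(return_def("file", "string")))
      write_scenario_module(modules_dir, "mergeTask",
        c(sh_argparse("indir", "pattern", "output"),
          "mkdir -p \"$(dirname \"$OUTPUT\")\"",
          "cat \"$INDIR\"/$PATTERN > \"$OUTPUT\""),
        params = list(param_def("indir", "folder", required = TRUE),
                      param_def("pattern", "string", required = TRUE),
                      param_def("output", "file", required = TRUE)))
      sprintf(
'<workflow>
  <settings>
    <constants>
      <const name="WORK" value="%s"/>
      <const name="OUT" value="%s"/>
    </constants>
    <executors><executor name="local" type="local" maxSlots="4" default="true"/></executors>
    <processBlock>
      <processFolder name="fastqGz" folder="%s" pattern="*.fastq.gz"/>
      <processInput name="decompressed"/>
      <processInput name="headerFiles"/>
      <processInput name="seqFiles"/>
    </processBlock>
    <moduleFolders><folder path="modules"/></moduleFolders>
  </settings>
  <tasks>
    <gunzipTask id="1" name="decompress" processBlock="fastqGz">
      <parameter><input>{}</input><output>${WORK}/[2].fastq</output></parameter>
    </gunzipTask>
    <extractTask id="2" name="extractHeaders" processBlock="decompressed" maxRunning="4">
      <parameter><input>{$file}</input><output>{$file}.headers</output><line>1</line></parameter>
      <dependencies><depends separate="true">decompress</depends></dependencies>
    </extractTask>
    <extractTask id="3" name="extractSeqs" processBlock="decompressed" maxRunning="1">
      <parameter><input>{$file}</input><output>{$file}.seqs</output><line>2</line></parameter>
      <dependencies><depends separate="true">decompress</depends></dependencies>
    </extractTask>
    <compressTask id="4" name="compressHeaders" processBlock="headerFiles">
      <parameter><input>{$file}</input><output>{$file}.gz</output></parameter>
      <dependencies><depends separate="true">extractHeaders</depends></dependencies>
    </compressTask>
    <compressTask id="5" name="compressSeqs" processBlock="seqFiles">
      <parameter><input>{$file}</input><output>{$file}.gz</output></parameter>
      <dependencies><depends separate="true">extractSeqs</depends></dependencies>
    </compressTask>
    <mergeTask id="6" name="mergeHeaders">
      <parameter><indir>${WORK}</indir><pattern>*.headers.gz</pattern><output>${OUT}/merged_headers.gz</output></parameter>
      <dependencies><depends>compressHeaders</depends></dependencies>
    </mergeTask>
    <mergeTask id="7" name="mergeSeqs">
      <parameter><indir>${WORK}</indir><pattern>*.seqs.gz</pattern><output>${OUT}/merged_seqs.gz</output></parameter>
      <dependencies><depends>compressSeqs</depends></dependencies>
    </mergeTask>
  </tasks>
</workflow>', work, out, file.path(outdir, "data"))
    }
  )
  writeLines(xml, wf_path)
  invisible(wf_path)
}

#' List available demonstration scenarios
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() SCENARIOS
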