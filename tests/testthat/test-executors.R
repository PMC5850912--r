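test_that("execute_local runs children with env, redirects and return files", {
  inv0 <- command_invocation(c("sh", "-c", "exit 0"))
  expect_equal(execute_local(inv0)$exit_code, 0L)

  rf <- tempfile()
  inv <- command_invocation(
    c("sh", "-c", "printf 'n\t5\n' > \"$TASKHERD_RETURN_FILE\""),
    return_file = rf)
  res <- execute_local(inv)
  expect_equal(res$exit_code, 0L)
  expect_equal(res$return_values, c(n = "5"))

  expect_equal(execute_local(command_invocation(c("sh", "-c", "exit 3")))$exit_code, 3L)

  # stdout redirection and working directory
  out <- tempfile()
  wd <- tempfile(); dir.create(wd)
  inv2 <- command_invocation(c("sh", "-c", "pwd; printf '%s\n' \"$MYVAR\""),
                             env = c(MYVAR = "hello"), workdir = wd,
                             stdout_path = out)
  expect_equal(execute_local(inv2)$exit_code, 0L)
  lines <- readLines(out)
  expect_equal(normalizePath(lines[[1]]), normalizePath(wd))
  expect_equal(lines[[2]], "hello")
})

test_that("the local executor never exceeds its slot cap (marker probe)", {
  d <- tempfile(); dir.create(d)
  # each child writes a start marker, sleeps, then writes an end marker
  sreg_dir <- tempfile(); dir.create(file.path(sreg_dir, "probeTask"), recursive = TRUE)
  writeLines(c('<module name="probeTask" command="probeTask.sh">',
               '  <param name="tag" type="string" required="true"/>',
               "</module>"),
             file.path(sreg_dir, "probeTask", "probeTask.module.xml"))
  writeLines(c("#!/bin/sh", "set -eu",
               sprintf("D=%s", d),
               'TAG=""',
               'while [ $# -gt 0 ]; do case "$1" in --tag) TAG="$2"; shift 2;; *) exit 64;; esac; done',
               'date +%s.%N > "$D/start_$TAG"',
               "sleep 0.4",
               'date +%s.%N > "$D/end_$TAG"'),
             file.path(sreg_dir, "probeTask", "probeTask.sh"))
  Sys.chmod(file.path(sreg_dir, "probeTask", "probeTask.sh"), "755")
  reg <- module_registry(sreg_dir, include_builtin = FALSE)
  p <- tempfile(fileext = ".xml")
  writeLines(
'<workflow>
  <settings>
    <executors><executor name="pool" type="local" maxSlots="2" default="true"/></executors>
    <processBlock><processSequence name="four" start="1" end="4" step="1"/></processBlock>
  </settings>
  <tasks>
    <probeTask id="1" name="probe" processBlock="four">
      <parameter><tag>{}</tag></parameter>
    </probeTask>
  </tasks>
</workflow>', p)
  run <- run_workflow(parse_workflow(p, reg), reg)
  expect_equal(run$status, 0L)
  starts <- sort(vapply(list.files(d, "^start_", full.names = TRUE),
                        function(f) as.numeric(readLines(f)), numeric(1)))
  ends <- sort(vapply(list.files(d, "^end_", full.names = TRUE),
                      function(f) as.numeric(readLines(f)), numeric(1)))
  expect_length(starts, 4L)
  # concurrency from the interval overlap of the children's own timestamps
  times <- c(starts, ends)
  delta <- c(rep(1L, 4L), rep(-1L, 4L))
  ord <- order(times, delta)
  expect_lte(max(cumsum(delta[ord])), 2L)
})

test_that("the virtual executor is a deterministic discrete-event simulation", {
  mk <- function() virtual_executor(hosts = 1L, slots_per_host = 2L)
  ex <- mk()
  inv <- command_invocation("true")
  for (k in paste0("1-", 1:2)) ex$launch(k, inv)
  expect_equal(ex$free_slots(), 0L)
  done1 <- ex$poll()
  expect_equal(vapply(done1, `[[`, numeric(1), "time"), c(1, 1))
  for (k in paste0("1-", 3:4)) ex$launch(k, inv)
  done2 <- ex$poll()
  expect_equal(vapply(done2, `[[`, numeric(1), "time"), c(2, 2))
  expect_equal(vapply(done2, `[[`, character(1), "key"), c("1-3", "1-4"))

  # single subtask runs at t=0 on host 1
  ex2 <- virtual_executor()
  h <- ex2$launch("2-1", inv)
  expect_equal(h, 1L)
  expect_equal(ex2$now(), 0)
  expect_equal(ex2$poll()[[1]]$host, "vhost1")

  # scripted exit codes surface on exactly the scripted subtask
  ex3 <- virtual_executor(slots_per_host = 2L, exit_code_of = list("2-1" = 1L))
  ex3$launch("2-1", inv); ex3$launch("2-2", inv)
  codes <- vapply(ex3$poll(), function(c) c$exit_code, integer(1))
  expect_equal(codes, c(1L, 0L))

  expect_error(virtual_executor(duration_of = list("1-1" = 0)), "> 0")

  # same config + launches => identical event sequence
  run_once <- function() {
    ex <- virtual_executor(hosts = 2L, slots_per_host = 1L,
                           duration_of = list("1-1" = 2, "1-2" = 1))
    ex$launch("1-1", inv); ex$launch("1-2", inv)
    out <- list()
    while (length(ex$running_keys())) out <- c(out, ex$poll())
    out
  }
  expect_identical(run_once(), run_once())
})

test_that("slave-mode affinity pins dependency chains to a single host", {
  edges <- rbind(c("1-1", "2-1"), c("2-1", "3-1"),
                 c("1-2", "2-2"), c("2-2", "3-2"))
  hosts <- apply_affinity(edges, n_hosts = 2L, slots_per_host = 1L)
  expect_equal(hosts[["1-1"]], hosts[["2-1"]])
  expect_equal(hosts[["2-1"]], hosts[["3-1"]])
  expect_equal(hosts[["1-2"]], hosts[["3-2"]])
  # two chains spread over the two hosts
  expect_equal(sort(unique(unname(hosts))), c(1L, 2L))
  # no dependencies: nothing constrained
  expect_length(apply_affinity(matrix(character(0), ncol = 2), 2L), 0L)
  # single host: trivially satisfiable
  expect_true(all(apply_affinity(edges, 1L) == 1L))

  # end to end: in a two-stage pipeline each chain stays on its host
  d <- tempfile()
  emit_scenario("parallel_hosts", d)
  reg <- module_registry(file.path(d, "modules"), include_builtin = FALSE)
  run <- run_workflow(parse_workflow(file.path(d, "workflow.xml"), reg), reg,
                      dry_run = TRUE)
  tr <- run$trace[run$trace$transition == "RUNNING", ]
  for (i in 1:2) {
    expect_equal(tr$host[tr$task_id == 1 & tr$subtask_index == i],
                 tr$host[tr$task_id == 2 & tr$subtask_index == i])
  }
})

test_that("task actions run per phase on the local file system", {
  base <- tempfile(); dir.create(base)
  inst <- structure(list(variables = c(value = "/tmp/s1.log"), block = "b",
                         ordinal = 1L), class = "block_instance")
  acts <- list(
    list(phase = "before", action = "create",
         src = file.path(base, "out_[1]"), dst = NULL),
    list(phase = "after_success", action = "delete",
         src = file.path(base, "scratch.txt"), dst = NULL))
  run_task_actions(acts, "before", inst)
  expect_true(dir.exists(file.path(base, "out_s1")))

  file.create(file.path(base, "scratch.txt"))
  run_task_actions(acts, "after_success", inst)
  expect_false(file.exists(file.path(base, "scratch.txt")))

  # before-phase failure throws; after-phase failure only logs
  bad <- list(list(phase = "before", action = "delete",
                   src = file.path(base, "missing"), dst = NULL))
  expect_error(run_task_actions(bad, "before"), "no such path")
  bad_after <- list(list(phase = "after_failure", action = "delete",
                         src = file.path(base, "missing"), dst = NULL))
  logged <- character(0)
  run_task_actions(bad_after, "after_failure",
                   on_log = function(m) logged <<- c(logged, m))
  expect_match(logged, "failed")

  # copy
  src <- file.path(base, "a.txt"); writeLines("x", src)
  cp <- list(list(phase = "before", action = "copy", src = src,
                  dst = file.path(base, "sub", "b.txt")))
  run_task_actions(cp, "before")
  expect_equal(readLines(file.path(base, "sub", "b.txt")), "x")
})

test_that("declared remote executor types parse but refuse to launch", {
  reg <- make_echo_registry()
  p <- tempfile(fileext = ".xml")
  writeLines(sprintf(
'<workflow>
  <settings>
    <executors>
      <executor name="local" type="local" maxSlots="2" default="true"/>
      <executor name="goliath" type="ssh" maxSlots="4" host="goliath" key="~/.ssh/id"/>
      <executor name="cluster" type="drmaa" maxSlots="16" queue="short"/>
    </executors>
    <moduleFolders><folder path="%s"/></moduleFolders>
  </settings>
  <tasks>
    <echoTask id="1" name="onCluster" executor="cluster">
      <parameter><text>x</text></parameter>
    </echoTask>
  </tasks>
</workflow>', make_echo_registry()$folders[[1]]), p)
  spec <- parse_workflow(p, reg)
  expect_length(spec$executors, 3L)
  expect_equal(spec$executors[["cluster"]]$attributes$queue, "short")
  expect_equal(spec$executors[["goliath"]]$exec_type, "ssh")
  # running on the stub raises "not configured"
  expect_error(run_workflow(spec, reg), "not configured")
  # but a dry run simulates it fine
  expect_equal(run_workflow(spec, reg, dry_run = TRUE)$status, 0L)
})
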