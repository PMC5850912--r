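reg <- make_echo_registry()

barrier_spec <- function() {
  # B depends task-level on A1, A2 (3-instance block) and A3
  p <- write_workflow(
    paste0(echo_task_xml(1, name = "A1"),
           echo_task_xml(2, name = "A2", block = "three", text = "v{}"),
           echo_task_xml(3, name = "A3"),
           echo_task_xml(4, name = "B", deps = c(1, 2, 3))),
    settings_xml = '<processBlock><processSequence name="three" start="1" end="3" step="1"/></processBlock>')
  parse_workflow(p, reg)
}

test_that("the dependency graph exposes edges and the dependency-free frontier", {
  spec <- barrier_spec()
  g <- build_graph(spec)
  expect_equal(sort(attr(g, "frontier")), c(1L, 2L, 3L))
  expect_equal(igraph::degree(g, "4", mode = "in"), c("4" = 3))

  p <- write_workflow(paste0(echo_task_xml(1), echo_task_xml(2, deps = 1),
                             echo_task_xml(3, deps = 2)))
  g2 <- build_graph(parse_workflow(p, reg))
  expect_equal(attr(g2, "frontier"), 1L)
  g3 <- build_graph(parse_workflow(write_workflow(echo_task_xml(1)), reg))
  expect_equal(attr(g3, "frontier"), 1L)
})

test_that("scope filters select contiguous regions of the partial order", {
  p <- write_workflow(paste0(echo_task_xml(1), echo_task_xml(2, deps = 1),
                             echo_task_xml(3, deps = 2)))
  spec <- parse_workflow(p, reg)
  expect_equal(apply_scope(spec), c(1L, 2L, 3L))
  expect_equal(apply_scope(spec, scope_filter(start = "2")), c(2L, 3L))
  expect_equal(apply_scope(spec, scope_filter(stop = "2")), c(1L, 2L))
  expect_equal(apply_scope(spec, scope_filter(start = "2", exclude = "3")), 2L)
  expect_error(apply_scope(spec, scope_filter(start = "99")), "unresolvable")
  expect_error(scope_filter(include = "1", exclude = "1"), "disjoint")

  # start mid-chain: the upstream task is never launched, downstream runs
  run <- run_workflow(spec, reg, dry_run = TRUE, filter = scope_filter(start = "2"))
  expect_equal(run$status, 0L)
  expect_false(any(run$trace$task_id == 1 & run$trace$transition == "RUNNING"))
  expect_true(any(run$trace$task_id == 2 & run$trace$transition == "RUNNING"))
})

test_that("lifecycle transitions follow the state machine and reject illegal events", {
  r <- taskherd:::new_subtask_record(1L, 1L)
  expect_equal(r$state, "PENDING")
  r <- apply_transition(r, "ready")
  r <- apply_transition(r, "launch", argv = c("prog", "--x", "1"), host = "h")
  expect_equal(r$state, "RUNNING")
  expect_equal(r$resolved_argv, c("prog", "--x", "1"))
  r_ok <- apply_transition(r, "succeed", exit_code = 0L,
                           return_values = c(n = "5"))
  expect_equal(r_ok$state, "SUCCEEDED")
  expect_equal(r_ok$return_values, c(n = "5"))
  expect_error(apply_transition(r_ok, "launch"), "illegal transition")

  r_fail <- apply_transition(r, "fail", exit_code = 3L, messages = "boom")
  expect_equal(r_fail$state, "FAILED_AWAITING_USER")
  expect_length(r_fail$return_values, 0L)
  # the four user actions
  expect_equal(apply_transition(r_fail, "user_ignore")$state, "IGNORED")
  rr <- apply_transition(r_fail, "user_restart")
  expect_equal(rr$state, "READY")
  expect_equal(rr$attempt, 2L)
  rm_ <- apply_transition(r_fail, "user_modify_restart",
                          assignments = list(x = "2"))
  expect_equal(rm_$attempt, 2L)
  rv <- apply_transition(r_fail, "user_resolve",
                         return_values = c(file = "/x", fCount = "7"))
  expect_equal(rv$state, "RESOLVED_MANUAL")
  expect_equal(rv$return_values, c(file = "/x", fCount = "7"))
  expect_error(apply_transition(rv, "user_ignore"), "illegal transition")
  # holds release back to READY
  h <- apply_transition(apply_transition(taskherd:::new_subtask_record(1L, 2L),
                                         "ready"), "hold")
  expect_equal(h$state, "HELD_RESOURCE")
  expect_equal(apply_transition(h, "release")$state, "READY")
})

test_that("task-level dependencies form a barrier over all upstream subtasks", {
  spec <- barrier_spec()
  run <- run_workflow(spec, reg, dry_run = TRUE)
  expect_equal(run$status, 0L)
  tr <- run$trace
  b_start <- tr$time[tr$task_id == 4 & tr$transition == "RUNNING"]
  a_ends <- tr$time[tr$task_id %in% 1:3 & tr$transition == "SUCCEEDED"]
  expect_length(a_ends, 5L)  # A1, A2-1..A2-3, A3 all complete first
  expect_gte(b_start, max(a_ends))
})

test_that("subtask-level dependencies pipeline index-matched subtasks", {
  p <- write_workflow(
    paste0(echo_task_xml(1, name = "A", block = "two", text = "a{}"),
           echo_task_xml(2, name = "B", block = "two", text = "b{}",
                         deps = 1, separate = TRUE)),
    settings_xml = '<processBlock><processSequence name="two" start="1" end="2" step="1"/></processBlock>')
  spec <- parse_workflow(p, reg)
  run <- run_workflow(spec, reg, dry_run = TRUE,
                      virtual_config = list(hosts = 1, slots_per_host = 8,
                                            duration_of = list("1-1" = 5, "1-2" = 1)))
  tr <- run$trace
  b2_start <- tr$time[tr$task_id == 2 & tr$subtask_index == 2 &
                        tr$transition == "RUNNING"]
  a1_end <- tr$time[tr$task_id == 1 & tr$subtask_index == 1 &
                      tr$transition == "SUCCEEDED"]
  a2_end <- tr$time[tr$task_id == 1 & tr$subtask_index == 2 &
                      tr$transition == "SUCCEEDED"]
  expect_gte(b2_start, a2_end)   # waits for its own upstream index
  expect_lt(b2_start, a1_end)    # but not for the sibling
})

test_that("per-task concurrency caps hold and the overflow subtask is held", {
  p <- write_workflow(
    echo_task_xml(1, block = "five", text = "v{}",
                  extra_attrs = ' maxRunning="2"'),
    settings_xml = '<processBlock><processSequence name="five" start="1" end="5" step="1"/></processBlock>')
  spec <- parse_workflow(p, reg)
  run <- run_workflow(spec, reg, dry_run = TRUE)
  expect_equal(run$status, 0L)
  expect_equal(max_concurrency(run$trace, task_id = 1L), 2L)
  expect_gte(sum(run$trace$transition == "HELD_RESOURCE"), 1L)
  # all five eventually succeed
  expect_equal(sum(run$trace$transition == "SUCCEEDED"), 5L)
})

test_that("executed argv match an independent brute-force expansion", {
  for (seed in 1:6) {
    w <- random_workflow(n_tasks = sample(2:6, 1), seed = seed)
    run <- run_workflow(w$spec, w$registry, dry_run = TRUE)
    expect_equal(run$status, 0L)
    expect_equal(run_argv_multiset(run), w$expected)
  }
})

test_that("no subtask runs before its dependencies' terminal events (safety)", {
  for (seed in 7:10) {
    w <- random_workflow(n_tasks = 5, seed = seed)
    run <- run_workflow(w$spec, w$registry, dry_run = TRUE)
    tr <- run$trace
    for (t in w$spec$tasks) {
      for (d in t$dependencies) {
        up <- resolve_task_ref(w$spec, d$target)
        starts <- tr[tr$task_id == t$id & tr$transition == "RUNNING", ]
        up_ends <- tr[tr$task_id == up$id & tr$transition == "SUCCEEDED", ]
        expect_true(all(vapply(starts$time, function(s)
          all(up_ends$time <= s), logical(1))))
      }
    }
  }
})

test_that("identical spec and virtual configuration give identical traces", {
  w <- random_workflow(n_tasks = 5, seed = 99)
  r1 <- run_workflow(w$spec, w$registry, dry_run = TRUE)
  r2 <- run_workflow(w$spec, w$registry, dry_run = TRUE)
  expect_identical(r1$trace, r2$trace)
})

test_that("a journal replays finished work and parameter edits force re-execution", {
  d <- tempfile()
  emit_scenario("subtask_pipeline", d, n = 3)
  sreg <- module_registry(file.path(d, "modules"), include_builtin = FALSE)
  spec <- parse_workflow(file.path(d, "workflow.xml"), sreg)
  j <- tempfile()
  r1 <- run_workflow(spec, sreg, resume_journal = j)
  expect_equal(r1$status, 0L)
  expect_equal(r1$launch_count, 6L)
  # rerun: everything replayed, zero launches
  r2 <- run_workflow(spec, sreg, resume_journal = j)
  expect_equal(r2$status, 0L)
  expect_equal(r2$launch_count, 0L)
  expect_equal(sum(r2$trace$transition == "REPLAYED"), 6L)
  # edit a parameter: the edited task re-executes, argv hash no longer matches
  spec2 <- spec
  spec2$tasks[[2]]$parameters[[1]]$value <- "CHANGED:{$file}"
  r3 <- run_workflow(spec2, sreg, resume_journal = j)
  expect_equal(r3$status, 0L)
  expect_equal(r3$launch_count, 3L)  # only the downstream task's subtasks
})

test_that("ignoring a failure blocks only its forward cone", {
  # diamond: 1 -> {2,3} -> 4 plus independent 5; subtask of 2 fails
  p <- write_workflow(paste0(
    echo_task_xml(1), echo_task_xml(2, deps = 1), echo_task_xml(3, deps = 1),
    echo_task_xml(4, deps = c(2, 3)), echo_task_xml(5)))
  spec <- parse_workflow(p, reg)
  handler <- function(eng) {
    snap <- status_snapshot(eng)
    failed <- snap$rows[snap$rows$state == "FAILED_AWAITING_USER", ]
    if (nrow(failed) == 0L) return(FALSE)
    taskherd:::engine_action(eng, failed$task_id[1], failed$subtask_index[1],
                             "ignore")
    TRUE
  }
  run <- run_workflow(spec, reg, dry_run = TRUE,
                      virtual_config = list(exit_code_of = list("2-0" = 1L)),
                      handler = handler)
  st <- vapply(run$records, `[[`, character(1), "state")
  expect_equal(unname(st[c("1-0", "3-0", "5-0")]),
               rep("SUCCEEDED", 3))          # outside the cone: unaffected
  expect_equal(unname(st[["2-0"]]), "IGNORED")
  expect_equal(unname(st[["4-0"]]), "PENDING")  # inside the cone: never launched
  expect_equal(run$status, 1L)
  expect_null(run$deadlock)
})

test_that("manual resolution feeds scripted return values to downstream input blocks", {
  d <- tempfile()
  emit_scenario("subtask_pipeline", d, n = 2)
  sreg <- module_registry(file.path(d, "modules"), include_builtin = FALSE)
  spec <- parse_workflow(file.path(d, "workflow.xml"), sreg)
  handler <- function(eng) {
    snap <- status_snapshot(eng)
    failed <- snap$rows[snap$rows$state == "FAILED_AWAITING_USER", ]
    if (nrow(failed) == 0L) return(FALSE)
    taskherd:::engine_action(eng, failed$task_id[1], failed$subtask_index[1],
                             "resolve",
                             returns = c(file = "/manual.log", fCount = "42"))
    TRUE
  }
  run <- run_workflow(spec, sreg, dry_run = TRUE,
                      virtual_config = list(
                        exit_code_of = list("1-1" = 1L),
                        returns_of = list("1-2" = list(file = "/b.log",
                                                       fCount = "7"))),
                      handler = handler)
  expect_equal(run$status, 0L)
  expect_equal(run$records[["1-1"]]$state, "RESOLVED_MANUAL")
  # downstream instance built from the manually entered values
  argv2 <- run$records[["2-1"]]$resolved_argv
  expect_true(any(grepl("/manual.log:42", argv2, fixed = TRUE)))
})

test_that("checkpoints hold dependents until released, or are disabled wholesale", {
  p <- write_workflow(paste0(echo_task_xml(1, checkpoint = TRUE),
                             echo_task_xml(2, deps = 1)))
  spec <- parse_workflow(p, reg)
  # headless, no interaction channel: reported as a deadlock, not a hang
  r_stuck <- run_workflow(spec, reg, dry_run = TRUE)
  expect_false(is.null(r_stuck$deadlock))
  expect_true("2-0" %in% r_stuck$deadlock$blocked_subtasks)
  expect_true(any(r_stuck$trace$transition == "HELD_CHECKPOINT"))

  # releasing through a handler lets the dependent run; releasing a task
  # without a checkpoint is rejected
  r_rel <- run_workflow(spec, reg, dry_run = TRUE, handler = function(eng) {
    if (!1L %in% eng$released_checkpoints) {
      expect_error(release_checkpoint(eng, "2"), "no checkpoint")
      release_checkpoint(eng, "1"); TRUE
    } else FALSE
  })
  expect_equal(r_rel$status, 0L)
  expect_null(r_rel$deadlock)

  # disabling checkpoints reproduces the checkpoint-free trace
  p_free <- write_workflow(paste0(echo_task_xml(1), echo_task_xml(2, deps = 1)))
  r_free <- run_workflow(parse_workflow(p_free, reg), reg, dry_run = TRUE)
  r_dis <- run_workflow(spec, reg, dry_run = TRUE,
                        filter = scope_filter(disable_checkpoints = TRUE))
  expect_identical(r_dis$trace, r_free$trace)
})

test_that("an empty workflow runs to success with an empty trace", {
  p <- write_workflow("")
  run <- run_workflow(parse_workflow(p, reg), reg, dry_run = TRUE)
  expect_equal(run$status, 0L)
  expect_equal(nrow(run$trace), 0L)
})
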