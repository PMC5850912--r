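inst_values <- function(insts) {
  vapply(insts, function(i) i$variables[["value"]], character(1))
}

test_that("sequence blocks enumerate like a for-loop, end included when hit", {
  expect_equal(inst_values(expand_sequence(1, 9, 4)), c("1", "5", "9"))
  expect_equal(inst_values(expand_sequence(5, 7, 1)), c("5", "6", "7"))
  expect_equal(inst_values(expand_sequence(3, 3, 1)), "3")
  # end not hit exactly: last value does not pass end
  expect_equal(inst_values(expand_sequence(1, 8, 4)), c("1", "5"))
  # descending and fractional steps
  expect_equal(inst_values(expand_sequence(3, 1, -1)), c("3", "2", "1"))
  expect_equal(inst_values(expand_sequence(0, 1, 0.5)), c("0", "0.5", "1"))

  expect_error(expand_sequence(1, 9, 0), "non-zero")
  expect_error(expand_sequence(1, 9, -1), "away")
  expect_error(expand_sequence(1, Inf, 1), "finite")
})

test_that("sequence cardinality matches brute-force enumeration", {
  set.seed(7)
  for (i in 1:30) {
    start <- sample(-10:10, 1)
    step <- sample(c(1:4, -(1:4)), 1)
    n <- sample(1:12, 1)
    end <- start + step * (n - 1) + sample(0:(abs(step) - 1), 1) * sign(step)
    insts <- expand_sequence(start, end, step)
    # independent count: walk the loop by hand
    cnt <- 0L; v <- start
    while ((step > 0 && v <= end) || (step < 0 && v >= end)) {
      cnt <- cnt + 1L; v <- v + step
    }
    expect_length(insts, cnt)
    expect_length(insts, floor((end - start) / step) + 1)
    expect_equal(vapply(insts, `[[`, integer(1), "ordinal"), seq_len(cnt))
  }
})

test_that("folder blocks match globs, sort, and skip directories", {
  d <- tempfile()
  dir.create(file.path(d, "sub.log"), recursive = TRUE)  # a directory, not a file
  for (f in c("b.log", "a.log", "c.txt")) file.create(file.path(d, f))
  insts <- expand_folder(d, "*.log")
  expect_length(insts, 2L)
  vals <- inst_values(insts)
  expect_equal(basename(vals), c("a.log", "b.log"))
  expect_true(all(startsWith(vals, "/")))
  # repeated expansion identical
  expect_identical(insts, expand_folder(d, "*.log"))

  expect_warning(empty <- expand_folder(d, "*.nomatch"), "no file matches")
  expect_length(empty, 0L)
  d2 <- tempfile(); dir.create(d2); file.create(file.path(d2, "only"))
  one <- expand_folder(d2, "*")
  expect_equal(basename(inst_values(one)), "only")
  expect_error(expand_folder(tempfile(), "*"), "does not exist")
})

test_that("table blocks yield one instance per row, variables from the header", {
  p <- tempfile()
  writeLines(c("name\ttype", "s1\twt", "s2\tko"), p)
  insts <- expand_table(p)
  expect_length(insts, 2L)
  expect_equal(insts[[1]]$variables, c(name = "s1", type = "wt"))
  expect_equal(insts[[2]]$variables, c(name = "s2", type = "ko"))
  expect_equal(vapply(insts, `[[`, integer(1), "ordinal"), 1:2)

  writeLines("name\ttype", p)
  expect_warning(expect_length(expand_table(p), 0L), "header-only")

  writeLines(c("name\ttype", "a\tb\tc"), p)
  expect_error(expand_table(p), "ragged")
  writeLines(c("name\tname", "a\tb"), p)
  expect_error(expand_table(p), "duplicate column")
  writeLines(character(0), p)
  expect_error(expand_table(p), "empty")
})

test_that("input blocks derive instances from upstream return values", {
  rec <- function(task, idx, state = "SUCCEEDED", rv) {
    list(task_id = task, subtask_index = idx, state = state, return_values = rv)
  }
  recs <- list(rec(1, 2, rv = c(file = "/b.sam", fCount = "20")),
               rec(1, 1, rv = c(file = "/a.sam", fCount = "10")))
  insts <- expand_input(recs)
  expect_length(insts, 2L)
  # ordered by source subtask index regardless of list order
  expect_equal(insts[[1]]$variables[["file"]], "/a.sam")
  expect_equal(insts[[2]]$variables[["fCount"]], "20")
  expect_equal(insts[[1]]$source_key, "1-1")

  single <- expand_input(list(rec(3, 1, rv = c(x = "1"))))
  expect_length(single, 1L)
  # manually resolved upstream subtasks are acceptable sources
  ok <- expand_input(list(rec(1, 1, state = "RESOLVED_MANUAL", rv = c(x = "9"))))
  expect_equal(ok[[1]]$variables[["x"]], "9")

  expect_error(expand_input(list(rec(1, 1, rv = c(a = "1")),
                                 rec(1, 2, rv = c(b = "2")))),
               "conflicting variable")
  expect_error(expand_input(list(rec(1, 1, state = "RUNNING", rv = c(a = "1")))),
               "not finished")
  expect_error(expand_input(list(rec(1, 1, rv = character(0)))), "no return values")
})

test_that("placeholders substitute the full value, stripped names and named vars", {
  single <- function(v) structure(list(variables = c(value = v), block = "b",
                                       ordinal = 1L), class = "block_instance")
  multi <- structure(list(variables = c(name = "s1", type = "wt"), block = "b",
                          ordinal = 1L), class = "block_instance")
  expect_equal(substitute_placeholders("{}", single("/tmp/a.log")), "/tmp/a.log")
  expect_equal(substitute_placeholders("[1].gz", single("/tmp/a.log")), "a.gz")
  expect_equal(substitute_placeholders("[2]", single("/d/x.tar.gz")), "x")
  expect_equal(substitute_placeholders("{$name}-{$type}", multi), "s1-wt")
  expect_equal(substitute_placeholders("gzip {} > out/[1].gz", single("/t/b.log")),
               "gzip /t/b.log > out/b.gz")
  expect_equal(substitute_placeholders("no placeholders", single("/x")),
               "no placeholders")

  expect_error(substitute_placeholders("[2]", single("/tmp/a.log")), "suffix")
  expect_error(substitute_placeholders("{$missing}", multi), "unknown instance variable")
  expect_error(substitute_placeholders("{}", multi), "single-variable")
})

test_that("substitution is idempotent on its own output", {
  set.seed(11)
  singles <- replicate(10, paste0("/data/", paste(sample(letters, 6), collapse = ""),
                                  ".log"))
  for (v in singles) {
    inst <- structure(list(variables = c(value = v), block = "b", ordinal = 1L),
                      class = "block_instance")
    for (tpl in c("{}", "[1].gz", "cp {} out/[1].txt")) {
      once <- substitute_placeholders(tpl, inst)
      expect_identical(substitute_placeholders(once, inst), once)
    }
  }
})

test_that("new block types can be registered and used in workflows", {
  register_block_type("processLetters",
    parse_fn = function(nd) list(n = as.integer(xml2::xml_attr(nd, "n"))),
    expand_fn = function(block, deps) {
      lapply(seq_len(block$n), function(i)
        taskherd:::new_instance(c(value = letters[[i]]), block$name, i))
    })
  reg <- make_echo_registry()
  p <- write_workflow(
    echo_task_xml(1, block = "abc", text = "{}"),
    settings_xml = '<processBlock><processLetters name="abc" n="3"/></processBlock>')
  spec <- parse_workflow(p, reg)
  run <- run_workflow(spec, reg, dry_run = TRUE)
  expect_equal(run$status, 0L)
  texts <- vapply(Filter(function(r) r$task_id == 1L, run$records),
                  function(r) r$resolved_argv[[3]], character(1))
  expect_equal(sort(unname(texts)), c("a", "b", "c"))
  expect_error(register_block_type("processSequence", identity, identity),
               "built-in")
})
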