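test_that("a well-formed design validates cleanly", {
  d <- build_paradigm("renewal_aba")$design
  expect_identical(validate_design(d), character(0))
})

test_that("violations are reported, not thrown", {
  cat_ <- stimulus_catalog("CS", "A")
  tr <- list(trial_spec("CS+", "CS", 1))
  d_badctx <- design(cat_, tr,
                     groups = list(g = list(stage("s", "Z", "CS+"))),
                     validate = FALSE)
  v <- validate_design(d_badctx)
  expect_length(v, 1L)
  expect_match(v, "Z")

  d_both <- design(cat_, tr,
                   groups = list(g = list(
                     stage("s", "A", "CS+", delay_steps = 100))),
                   validate = FALSE)
  expect_length(validate_design(d_both), 1L)

  d_neither <- design(cat_, tr,
                      groups = list(g = list(stage("s", "A"))),
                      validate = FALSE)
  expect_match(validate_design(d_neither), "neither")

  expect_error(design(cat_, tr, groups = list(g = list(stage("s", "Z", "CS+")))),
               "invalid design")
})

test_that("expansion places each trial after its ITI run", {
  d <- design(stimulus_catalog("CS", "A"), list(trial_spec("CS+", "CS", 1)),
              groups = list(g = list(stage("cond", "A", rep("CS+", 2), 5))))
  ts <- expand_design(d, "g")
  expect_equal(nrow(ts$x), 12L)
  expect_equal(which(ts$info$type == "trial"), c(6L, 12L))
  # ITI steps: context only, no US
  iti <- ts$info$type == "iti"
  expect_true(all(ts$x[iti, "A"] == 1))
  expect_true(all(ts$x[iti, "CS"] == 0))
  expect_true(all(ts$y[iti] == 0))
  # trial steps carry context + cues and the US
  expect_true(all(ts$x[!iti, c("CS", "A")] == 1))
  expect_equal(sum(ts$y), 2)
})

test_that("delay stages emit featureless steps", {
  ts <- expand_design(fix_delay_only(1000), "main")
  expect_equal(nrow(ts$x), 1000L)
  expect_true(all(ts$x == 0))
  expect_true(all(ts$y == 0))
  expect_true(all(ts$info$type == "delay"))
})

test_that("unknown group is rejected by name", {
  expect_error(expand_design(fix_cond_ext(), "nope"), "nope")
})

test_that("expansion is deterministic and conserves US count", {
  for (nm in c("renewal_aba", "inhibitor_nonextinction", "gradual_extinction")) {
    d <- build_paradigm(nm)$design
    for (g in names(d$groups)) {
      a <- expand_design(d, g)
      b <- expand_design(d, g)
      expect_identical(a, b)
      n_us <- sum(vapply(d$groups[[g]], function(st)
        sum(vapply(st$trials, function(tn) d$trials[[tn]]$us, 0)), 0))
      expect_equal(sum(a$y), n_us)
    }
  }
})

test_that("exactly one context is present on every non-delay step", {
  for (nm in c("renewal_abc", "multi_context_extinction", "reinstatement_context")) {
    d <- build_paradigm(nm)$design
    for (g in names(d$groups)) {
      ts <- expand_design(d, g)
      ctx_count <- rowSums(ts$x[, d$catalog$contexts, drop = FALSE])
      expect_true(all(ctx_count[ts$info$type != "delay"] == 1))
      expect_true(all(ctx_count[ts$info$type == "delay"] == 0))
    }
  }
})

test_that("designs round-trip through JSON and YAML files", {
  d <- build_paradigm("forgetting_of_inhibition")$design
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_design(d, path)
    d2 <- read_design(path)
    for (g in names(d$groups))
      expect_identical(expand_design(d2, g), expand_design(d, g))
    unlink(path)
  }
})

test_that("interleave cycles its blocks round-robin", {
  expect_identical(interleave(rep("A+", 2), rep("AX-", 2)),
                   c("A+", "AX-", "A+", "AX-"))
  expect_identical(interleave(c("a", "b"), c("x", "y"), c("u", "v")),
                   c("a", "x", "u", "b", "y", "v"))
})

test_that("time-step export has one 0/1 column per stimulus", {
  ts <- expand_design(fix_cond_ext(2, 2), "main")
  df <- as.data.frame(ts)
  expect_true(all(c("step", "stage", "is_trial", "trial_name", "CS", "A", "y")
                  %in% names(df)))
  expect_equal(sum(df$is_trial), 4L)
})
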