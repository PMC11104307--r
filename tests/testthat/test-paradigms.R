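test_that("every packaged paradigm has a valid design and resolvable contrasts", {
  for (nm in list_paradigms()) {
    p <- build_paradigm(nm)
    expect_identical(validate_design(p$design), character(0))
    groups_of <- function(x) {
      if (inherits(x, "rw_cell_diff")) c(groups_of(x$a), groups_of(x$b))
      else x$group
    }
    for (cs in p$contrasts) {
      expect_true(all(c(groups_of(cs$left), groups_of(cs$right))
                      %in% names(p$design$groups)))
    }
  }
})

test_that("unknown paradigm names list the available ones", {
  expect_error(build_paradigm("renewal_xyz"), "renewal_aba")
})

test_that("running a paradigm yields one result row per contrast", {
  p <- build_paradigm("renewal_aba")
  run <- run_paradigm(p)
  expect_equal(nrow(run$results), length(p$contrasts))
  expect_named(run$trajectories, c("Same", "Different"))
})

test_that("paradigm defaults carry the hand-tuned figure parameters", {
  expect_equal(build_paradigm("spontaneous_recovery")$params$rho, 0.002)
  expect_equal(build_paradigm("renewal_aba")$params$lambda, 0.3)
  expect_equal(build_paradigm("occasion_setting_renewal")$params$lambda, 0.2)
  expect_equal(build_paradigm("preexposure")$params$lambda_min, 0.1)
  gp <- build_paradigm("gradual_extinction")$params
  expect_equal(gp[c("rho", "mu", "lambda_min", "m", "p")],
               list(rho = 0.01, mu = 1.5, lambda_min = 0.15, m = 8, p = 0.5))
})

test_that("contrast directions survive doubling the extinction trial count", {
  for (nm in c("renewal_aba", "spontaneous_recovery", "multi_context_extinction")) {
    run <- run_paradigm(build_paradigm(nm, n_extinction = 60))
    expect_true(all(run$results$passed), label = paste(nm, "doubled extinction"))
  }
})

test_that("paradigm runs are pure functions of their configuration", {
  a <- run_paradigm(build_paradigm("reinstatement"))
  b <- run_paradigm(build_paradigm("reinstatement"))
  expect_identical(a$results, b$results)
  expect_identical(a$trajectories$ExtraShock$W, b$trajectories$ExtraShock$W)
})

test_that("trajectory CSV export round-trips key columns", {
  run <- run_paradigm(build_paradigm("renewal_aba", n_extinction = 5))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(run$trajectories$Same, path)
  df <- utils::read.csv(path)
  expect_true(all(c("step", "stage", "is_trial", "y", "y_hat", "feature", "w")
                  %in% names(df)))
  expect_equal(length(unique(df$feature)), nrow(run$trajectories$Same$basis))
  unlink(path)
})

test_that("the command-line interface lists paradigms with their defaults", {
  cli <- system.file("cli", "fearsim.R", package = "fearsim")
  expect_true(nzchar(cli))
  out <- system2("Rscript", c(cli, "list", "--json"), stdout = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_true(all(c("renewal_aba", "gradual_extinction") %in% parsed$paradigm))
  expect_equal(parsed$params$rho[parsed$paradigm == "spontaneous_recovery"],
               0.002)
})
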