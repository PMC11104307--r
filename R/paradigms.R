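make_paradigm <- function(name, design, params, contrasts) {
  structure(list(name = name, design = design, params = params,
                 contrasts = contrasts), class = "rw_paradigm")
}

#' @export
print.rw_paradigm <- function(x, ...) {
  cat("<rw_paradigm> ", x$name, " (", x$params$variant, " model)\n", sep = "")
  print(x$design)
  for (cs in x$contrasts) cat("  contrast: ", cs$label, "\n", sep = "")
  invisible(x)
}

# -- shared building blocks ---------------------------------------------------

cs_trials <- function(cs = "CS") list(trial_spec(paste0(cs, "+"), cs, 1),
                                      trial_spec(paste0(cs, "-"), cs, 0))

cond_ext_test <- function(ctx_cond, ctx_ext, ctx_test, n_cond, n_ext, n_test,
                          iti, delay = 0) {
  st <- list(stage("conditioning", ctx_cond, rep("CS+", n_cond), iti),
             stage("extinction", ctx_ext, rep("CS-", n_ext), iti))
  if (delay > 0) st <- c(st, list(stage("delay", NA, delay_steps = delay)))
  c(st, list(stage("test", ctx_test, rep("CS-", n_test), iti)))
}

# -- builders -----------------------------------------------------------------

build_renewal <- function(kind, n_cond, n_ext, n_test, iti) {
  ctxs <- switch(kind, aba = c("A", "B"), abc = c("A", "B", "C"), aab = c("A", "B"))
  test_ctx <- switch(kind, aba = "A", abc = "C", aab = "B")
  ext_ctx <- switch(kind, aba = "B", abc = "B", aab = "A")
  d <- design(
    stimulus_catalog("CS", ctxs), cs_trials(),
    groups = list(
      Same = cond_ext_test("A", "A", "A", n_cond, n_ext, n_test, iti),
      Different = cond_ext_test("A", ext_ctx, test_ctx, n_cond, n_ext, n_test, iti)))
  contrasts <- list(
    contrast_spec("renewal: Different tested outside the extinction context > Same",
                  cell("Different", "test"), cell("Same", "test"), "greater"),
    contrast_spec("return of fear: test exceeds end-of-extinction responding",
                  cell("Different", "test"),
                  cell("Different", "extinction", select = "last"), "greater"))
  make_paradigm(paste0("renewal_", kind), d, model_params("basic", lambda = 0.3),
                contrasts)
}

build_occasion_setting <- function(n_cond, n_ext, n_test, iti) {
  tests <- function(first, second)
    list(stage("test_B", "B", rep(paste0(first, "-"), n_test), iti),
         stage("test_C", "C", rep(paste0(second, "-"), n_test), iti))
  common <- list(
    stage("conditioning", "A",
          interleave(rep("CS1+", n_cond), rep("CS2+", n_cond)), iti),
    stage("extinction_B", "B", rep("CS1-", n_ext), iti),
    stage("extinction_C", "C", rep("CS2-", n_ext), iti))
  d <- design(
    stimulus_catalog(c("CS1", "CS2"), c("A", "B", "C")),
    c(cs_trials("CS1"), cs_trials("CS2")),
    groups = list(Matched = c(common, tests("CS1", "CS2")),
                  Mismatched = c(common, tests("CS2", "CS1"))))
  contrasts <- list(
    contrast_spec("occasion setting: CS tested in the other CS's extinction context > matched",
                  cell("Mismatched", c("test_B", "test_C")),
                  cell("Matched", c("test_B", "test_C")), "greater"))
  make_paradigm("occasion_setting_renewal", d,
                model_params("configural", lambda = 0.2), contrasts)
}

build_spontaneous_recovery <- function(n_cond, n_ext, n_test, iti,
                                       delays = c(Immediate = 0, Delay = 1000)) {
  groups <- lapply(delays, function(k)
    cond_ext_test("A", "A", "A", n_cond, n_ext, n_test, iti, delay = k))
  d <- design(stimulus_catalog("CS", "A"), cs_trials(), groups = groups)
  gl <- names(delays)
  contrasts <- list(
    contrast_spec("spontaneous recovery: responding grows with the extinction-test delay",
                  cell(gl[length(gl)], "test"), cell(gl[1L], "test"), "greater"))
  make_paradigm("spontaneous_recovery", d,
                model_params("decay", lambda = 0.3, rho = 0.002), contrasts)
}

build_sr_context_dependence <- function(n_cond, n_ext, n_test, iti,
                                        delay = 1000) {
  grp <- function(test_ctx, k)
    cond_ext_test("A", "B", test_ctx, n_cond, n_ext, n_test, iti, delay = k)
  d <- design(
    stimulus_catalog("CS", c("A", "B", "C")), cs_trials(),
    groups = list(Same_Immediate = grp("B", 0), Same_Delay = grp("B", delay),
                  Different_Immediate = grp("C", 0), Different_Delay = grp("C", delay)))
  contrasts <- list(
    contrast_spec("recovery in the extinction context",
                  cell("Same_Delay", "test"), cell("Same_Immediate", "test"),
                  "greater"),
    contrast_spec("spontaneous recovery is context dependent: delay gain larger in the extinction context",
                  cell_diff(cell("Same_Delay", "test"), cell("Same_Immediate", "test")),
                  cell_diff(cell("Different_Delay", "test"), cell("Different_Immediate", "test")),
                  "greater"))
  make_paradigm("sr_context_dependence", d,
                model_params("decay", lambda = 0.3, rho = 0.002), contrasts)
}

build_reinstatement <- function(n_cond, n_ext, n_test, iti, n_shock = 4) {
  trials <- c(cs_trials(), list(trial_spec("shock", character(), 1),
                                trial_spec("ctx_only", character(), 0)))
  grp <- function(shock_trial)
    list(stage("conditioning", "A", rep("CS+", n_cond), iti),
         stage("extinction", "A", rep("CS-", n_ext), iti),
         stage("shocks", "A", rep(shock_trial, n_shock), iti),
         stage("test", "A", rep("CS-", n_test), iti))
  d <- design(stimulus_catalog("CS", "A"), trials,
              groups = list(ExtraShock = grp("shock"),
                            NoExtraShock = grp("ctx_only")))
  contrasts <- list(
    contrast_spec("reinstatement: unsignaled post-extinction shocks raise test responding",
                  cell("ExtraShock", "test"), cell("NoExtraShock", "test"),
                  "greater"))
  make_paradigm("reinstatement", d, model_params("basic", lambda = 0.3), contrasts)
}

build_reinstatement_context <- function(n_cond, n_ext, n_test, iti, n_shock = 4) {
  trials <- c(cs_trials(), list(trial_spec("shock", character(), 1)))
  grp <- function(shock_ctx)
    list(stage("conditioning", "A", rep("CS+", n_cond), iti),
         stage("extinction", "A", rep("CS-", n_ext), iti),
         stage("shocks", shock_ctx, rep("shock", n_shock), iti),
         stage("test", "A", rep("CS-", n_test), iti))
  d <- design(stimulus_catalog("CS", c("A", "B")), trials,
              groups = list(ShockSame = grp("A"), ShockDifferent = grp("B")))
  contrasts <- list(
    contrast_spec("reinstatement is context dependent: shocks in the test context do more",
                  cell("ShockSame", "test"), cell("ShockDifferent", "test"),
                  "greater"))
  make_paradigm("reinstatement_context", d, model_params("basic", lambda = 0.3),
                contrasts)
}

build_inhibitor_nonextinction <- function(n_train = 15, n_expo = 30, n_test = 4,
                                          iti = 5) {
  trials <- list(trial_spec("A+", "A", 1), trial_spec("AX-", c("A", "X"), 0),
                 trial_spec("AY-", c("A", "Y"), 0), trial_spec("X-", "X", 0))
  d <- design(
    stimulus_catalog(c("A", "X", "Y"), "CTX"), trials,
    groups = list(Main = list(
      stage("training", "CTX",
            interleave(rep("A+", n_train), rep("AX-", n_train), rep("AY-", n_train)),
            iti),
      stage("exposure", "CTX", rep("X-", n_expo), iti),
      stage("test", "CTX", interleave(rep("AX-", n_test), rep("AY-", n_test)),
            iti))))
  contrasts <- list(
    contrast_spec("non-extinction of an inhibitor: exposed (X) and unexposed (Y) inhibitors work equally",
                  cell("Main", "test", trial = "AX-"),
                  cell("Main", "test", trial = "AY-"), "approx_equal"))
  make_paradigm("inhibitor_nonextinction", d, model_params("basic", lambda = 0.3),
                contrasts)
}

build_forgetting_of_inhibition <- function(n_train = 15, n_test = 4, iti = 5,
                                           delay = 1000) {
  trials <- list(trial_spec("A+", "A", 1), trial_spec("B+", "B", 1),
                 trial_spec("BX-", c("B", "X"), 0), trial_spec("A-", "A", 0),
                 trial_spec("AX-", c("A", "X"), 0))
  grp <- function(k) {
    st <- list(stage("training", "CTX",
                     interleave(rep("A+", n_train), rep("B+", n_train),
                                rep("BX-", n_train)), iti))
    if (k > 0) st <- c(st, list(stage("delay", NA, delay_steps = k)))
    c(st, list(stage("test", "CTX",
                     interleave(rep("A-", n_test), rep("AX-", n_test)), iti)))
  }
  d <- design(stimulus_catalog(c("A", "B", "X"), "CTX"), trials,
              groups = list(NoDelay = grp(0), Delay = grp(delay)))
  contrasts <- list(
    contrast_spec("excitation survives the delay: responding to A alone unchanged",
                  cell("Delay", "test", trial = "A-", select = "first"),
                  cell("NoDelay", "test", trial = "A-", select = "first"),
                  "approx_equal"),
    contrast_spec("forgetting of inhibition: A.X responding larger after the delay",
                  cell("Delay", "test", trial = "AX-", select = "first"),
                  cell("NoDelay", "test", trial = "AX-", select = "first"),
                  "greater"),
    contrast_spec("dissociation: delay affects the inhibited compound far more than A alone",
                  cell_diff(cell("Delay", "test", trial = "AX-", select = "first"),
                            cell("NoDelay", "test", trial = "AX-", select = "first")),
                  cell_diff(cell("Delay", "test", trial = "A-", select = "first"),
                            cell("NoDelay", "test", trial = "A-", select = "first")),
                  "greater"))
  make_paradigm("forgetting_of_inhibition", d,
                model_params("decay", lambda = 0.3, rho = 0.002), contrasts)
}

build_preexposure <- function(n_pre = 30, n_acq = 10, iti = 5) {
  d <- design(
    stimulus_catalog("CS", "A"), cs_trials(),
    groups = list(
      PreExposed = list(stage("preexposure", "A", rep("CS-", n_pre), iti),
                        stage("acquisition", "A", rep("CS+", n_acq), iti)),
      Control = list(stage("acquisition", "A", rep("CS+", n_acq), iti))))
  contrasts <- list(
    contrast_spec("pre-exposure effect: acquisition is slower after CS pre-exposure",
                  cell("Control", "acquisition"), cell("PreExposed", "acquisition"),
                  "greater"))
  make_paradigm("preexposure", d,
                model_params("familiarity", lambda_min = 0.1, p = 1.5), contrasts)
}

build_compound_extinction <- function(n_cond = 10, n_ext = 15, n_compound = 10,
                                      n_test = 4, iti = 5, delay = 1000) {
  trials <- list(trial_spec("A+", "A", 1), trial_spec("X+", "X", 1),
                 trial_spec("A-", "A", 0), trial_spec("X-", "X", 0),
                 trial_spec("AX-", c("A", "X"), 0))
  grp <- function(extra_trial)
    list(stage("conditioning", "CTX",
               interleave(rep("A+", n_cond), rep("X+", n_cond)), iti),
         stage("extinction", "CTX",
               interleave(rep("A-", n_ext), rep("X-", n_ext)), iti),
         stage("further_extinction", "CTX", rep(extra_trial, n_compound), iti),
         stage("delay", NA, delay_steps = delay),
         stage("test", "CTX", rep("X-", n_test), iti))
  d <- design(stimulus_catalog(c("A", "X"), "CTX"), trials,
              groups = list(Compound = grp("AX-"), Element = grp("X-")))
  contrasts <- list(
    contrast_spec("deepened extinction: compound trials reduce later recovery of X",
                  cell("Compound", "test"), cell("Element", "test"), "less"))
  make_paradigm("compound_extinction", d,
                model_params("decay", lambda = 0.3, rho = 0.002), contrasts)
}

build_unpaired_shocks <- function(n_cond = 10, n_ext = 30, n_test = 4, iti = 5,
                                  shock_every = 3) {
  trials <- c(cs_trials(), list(trial_spec("shock", character(), 1)))
  ext_seq <- function(with_shocks) {
    if (!with_shocks) return(rep("CS-", n_ext))
    out <- character()
    for (i in seq_len(n_ext)) {
      out <- c(out, "CS-")
      if (i %% shock_every == 0) out <- c(out, "shock")
    }
    out
  }
  grp <- function(with_shocks)
    list(stage("conditioning", "A", rep("CS+", n_cond), iti),
         stage("extinction", "B", ext_seq(with_shocks), iti),
         stage("test", "A", rep("CS-", n_test), iti))
  d <- design(stimulus_catalog("CS", c("A", "B")), trials,
              groups = list(Unpaired = grp(TRUE), Control = grp(FALSE)))
  contrasts <- list(
    contrast_spec("unpaired shocks during extinction reduce ABA renewal",
                  cell("Unpaired", "test"), cell("Control", "test"), "less"))
  make_paradigm("unpaired_shocks_extinction", d,
                model_params("basic", lambda = 0.3), contrasts)
}

build_multi_context <- function(n_cond = 10, n_ext = 30, n_test = 4, iti = 5) {
  per_ctx <- n_ext %/% 3L
  d <- design(
    stimulus_catalog("CS", c("A", "B", "C", "D", "E")), cs_trials(),
    groups = list(
      Multi = list(stage("conditioning", "A", rep("CS+", n_cond), iti),
                   stage("extinction_B", "B", rep("CS-", per_ctx), iti),
                   stage("extinction_C", "C", rep("CS-", per_ctx), iti),
                   stage("extinction_D", "D", rep("CS-", per_ctx), iti),
                   stage("test", "E", rep("CS-", n_test), iti)),
      Single = list(stage("conditioning", "A", rep("CS+", n_cond), iti),
                    stage("extinction_B", "B", rep("CS-", 3L * per_ctx), iti),
                    stage("test", "E", rep("CS-", n_test), iti))))
  contrasts <- list(
    contrast_spec("extinction in multiple contexts reduces renewal in a novel context",
                  cell("Multi", "test"), cell("Single", "test"), "less"))
  make_paradigm("multi_context_extinction", d, model_params("basic", lambda = 0.3),
                contrasts)
}

build_gradual_extinction <- function(n_cond = 10, n_ext = 24, n_test = 4, iti = 5,
                                     delay = 1000,
                                     gradual_positions = c(1, 4, 9, 16),
                                     reverse_positions = c(9, 16, 21, 24)) {
  ext_seq <- function(reinforced) {
    out <- rep("CS-", n_ext)
    out[reinforced] <- "CS+"
    out
  }
  grp <- function(reinforced)
    list(stage("conditioning", "A", rep("CS+", n_cond), iti),
         stage("extinction", "A", ext_seq(reinforced), iti),
         stage("delay", NA, delay_steps = delay),
         stage("test", "A", rep("CS-", n_test), iti))
  d <- design(stimulus_catalog("CS", "A"), cs_trials(),
              groups = list(Gradual = grp(gradual_positions),
                            GradualReverse = grp(reverse_positions),
                            Standard = grp(integer())))
  contrasts <- list(
    contrast_spec("gradual extinction reduces spontaneous recovery vs standard extinction",
                  cell("Gradual", "test"), cell("Standard", "test"), "less"),
    contrast_spec("timing matters: late reinforcement (gradual reverse) does not help",
                  cell("Gradual", "test"), cell("GradualReverse", "test"), "less"))
  make_paradigm("gradual_extinction", d,
                model_params("compact", rho = 0.01, mu = 1.5, lambda_min = 0.15,
                             m = 8, p = 0.5), contrasts)
}

PARADIGM_BUILDERS <- list(
  renewal_aba = function(n_conditioning = 10, n_extinction = 30, n_test = 4,
                         iti_steps = 5)
    build_renewal("aba", n_conditioning, n_extinction, n_test, iti_steps),
  renewal_abc = function(n_conditioning = 10, n_extinction = 30, n_test = 4,
                         iti_steps = 5)
    build_renewal("abc", n_conditioning, n_extinction, n_test, iti_steps),
  renewal_aab = function(n_conditioning = 10, n_extinction = 30, n_test = 4,
                         iti_steps = 5)
    build_renewal("aab", n_conditioning, n_extinction, n_test, iti_steps),
  occasion_setting_renewal = function(n_conditioning = 10, n_extinction = 30,
                                      n_test = 4, iti_steps = 5)
    build_occasion_setting(n_conditioning, n_extinction, n_test, iti_steps),
  spontaneous_recovery = function(n_conditioning = 10, n_extinction = 30,
                                  n_test = 4, iti_steps = 5,
                                  delays = c(Immediate = 0, Delay = 1000))
    build_spontaneous_recovery(n_conditioning, n_extinction, n_test, iti_steps,
                               delays),
  sr_context_dependence = function(n_conditioning = 10, n_extinction = 30,
                                   n_test = 4, iti_steps = 5, delay = 1000)
    build_sr_context_dependence(n_conditioning, n_extinction, n_test, iti_steps,
                                delay),
  reinstatement = function(n_conditioning = 10, n_extinction = 30, n_test = 4,
                           iti_steps = 5, n_shock = 4)
    build_reinstatement(n_conditioning, n_extinction, n_test, iti_steps, n_shock),
  reinstatement_context = function(n_conditioning = 10, n_extinction = 30,
                                   n_test = 4, iti_steps = 5, n_shock = 4)
    build_reinstatement_context(n_conditioning, n_extinction, n_test, iti_steps,
                                n_shock),
  inhibitor_nonextinction = build_inhibitor_nonextinction,
  forgetting_of_inhibition = build_forgetting_of_inhibition,
  preexposure = build_preexposure,
  compound_extinction = function(n_conditioning = 10, n_extinction = 15,
                                 n_compound = 10, n_test = 4, iti_steps = 5,
                                 delay = 1000)
    build_compound_extinction(n_conditioning, n_extinction, n_compound, n_test,
                              iti_steps, delay),
  unpaired_shocks_extinction = function(n_conditioning = 10, n_extinction = 30,
                                        n_test = 4, iti_steps = 5,
                                        shock_every = 3)
    build_unpaired_shocks(n_conditioning, n_extinction, n_test, iti_steps,
                          shock_every),
  multi_context_extinction = function(n_conditioning = 10, n_extinction = 30,
                                      n_test = 4, iti_steps = 5)
    build_multi_context(n_conditioning, n_extinction, n_test, iti_steps),
  gradual_extinction = function(n_conditioning = 10, n_extinction = 24,
                                n_test = 4, iti_steps = 5, delay = 1000,
                                gradual_positions = c(1, 4, 9, 16),
                                reverse_positions = c(9, 16, 21, 24))
    build_gradual_extinction(n_conditioning, n_extinction, n_test, iti_steps,
                             delay, gradual_positions, reverse_positions))

#' Available paradigm names
#' @return Character vector of names accepted by [build_paradigm()].
#' @export
list_paradigms <- function() names(PARADIGM_BUILDERS)

#' Build one of the packaged conditioning paradigms
#'
#' Returns the multi-group design, the model variant and hand-tuned
#' parameters it is simulated with, and the ordinal contrasts that define
#' the phenomenon. Trial counts, ITIs, and delays are configurable through
#' `...` (see the individual builders' arguments).
#'
#' @param name A name from [list_paradigms()].
#' @param ... Builder-specific overrides, e.g. `n_extinction = 60`.
#' @return An object of class `rw_paradigm` with elements `name`, `design`,
#'   `params`, `contrasts`.
#' @examples
#' p <- build_paradigm("renewal_aba")
#' vapply(p$contrasts, `[[`, "", "label")
#' @export
build_paradigm <- function(name, ...) {
  if (!name %in% names(PARADIGM_BUILDERS))
    stop("unknown paradigm '", name, "'; available: ",
         paste(list_paradigms(), collapse = ", "))
  PARADIGM_BUILDERS[[name]](...)
}

#' Run a paradigm: simulate every group and evaluate its contrasts
#'
#' @param paradigm An `rw_paradigm`.
#' @param params Optional `rw_params` overriding the paradigm default (e.g.
#'   to rerun an occasion-setting design under the basic model).
#' @return List of class `rw_paradigm_run` with `paradigm`, `params`,
#'   `trajectories` (named by group), and `results` (see
#'   [evaluate_contrasts()]).
#' @export
run_paradigm <- function(paradigm, params = NULL) {
  if (is.null(params)) params <- paradigm$params
  basis <- build_basis(paradigm$design$catalog,
                       include_configural = uses_configural(params))
  trajectories <- lapply(names(paradigm$design$groups), function(g)
    run_learner(paradigm$design, g, basis, params))
  names(trajectories) <- names(paradigm$design$groups)
  structure(list(paradigm = paradigm, params = params,
                 trajectories = trajectories,
                 results = evaluate_contrasts(paradigm$contrasts, trajectories)),
            class = "rw_paradigm_run")
}

#' @export
print.rw_paradigm_run <- function(x, ...) {
  cat("<rw_paradigm_run> ", x$paradigm$name, " (", x$params$variant, ")\n",
      sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Within-design renewal magnitude
#'
#' The degree of renewal is scored as test responding minus responding on
#' the final extinction trial of the same group, so designs with different
#' test contexts can be compared on a common footing.
#'
#' @param run An `rw_paradigm_run` of a renewal paradigm.
#' @param group Group to score (default `"Different"`).
#' @return Scalar renewal magnitude.
#' @export
renewal_magnitude <- function(run, group = "Different") {
  tr <- run$trajectories[[group]]
  test_response(tr, "test") - test_response(tr, "extinction", select = "last")
}

#' Run the full paradigm battery
#'
#' Simulates every packaged paradigm with its default model and parameters
#' and aggregates the contrast results.
#'
#' @param names Paradigms to run (default: all).
#' @return Object of class `rw_battery`: list with `runs` (named list of
#'   `rw_paradigm_run`) and `results` (data frame with a `paradigm` column
#'   prepended to the per-contrast results).
#' @export
run_battery <- function(names = list_paradigms()) {
  runs <- lapply(names, function(nm) run_paradigm(build_paradigm(nm)))
  names(runs) <- names
  results <- do.call(rbind, lapply(names, function(nm)
    cbind(paradigm = nm, runs[[nm]]$results, stringsAsFactors = FALSE)))
  rownames(results) <- NULL
  structure(list(runs = runs, results = results), class = "rw_battery")
}

#' @export
print.rw_battery <- function(x, ...) {
  df <- x$results
  df$left_value <- round(df$left_value, 4)
  df$right_value <- round(df$right_value, 4)
  print(df, row.names = FALSE)
  cat(sum(df$passed), "/", nrow(df), " contrasts passed\n", sep = "")
  invisible(x)
}
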