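#' Stimulus catalog
#'
#' Declares the discrete cues (CSs) and contexts available to an experiment.
#' Contexts are background stimuli that stay constant within a session
#' (chamber, odor, lighting); each is modeled as a single stimulus that is
#' present on every non-delay time step of a stage run in that context.
#'
#' @param cs Character vector of discrete-cue labels (may be empty).
#' @param contexts Character vector of context labels (at least one).
#' @return An object of class `rw_catalog` with elements `cs` and `contexts`.
#' @examples
#' stimulus_catalog(cs = "CS", contexts = c("A", "B"))
#' @export
stimulus_catalog <- function(cs = character(), contexts) {
  cs <- as.character(cs)
  contexts <- as.character(contexts)
  stopifnot(length(contexts) >= 1L)
  labels <- c(cs, contexts)
  if (anyDuplicated(labels))
    stop("stimulus labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(cs = cs, contexts = contexts), class = "rw_catalog")
}

#' All stimulus labels of a catalog, CSs first then contexts
#' @param catalog An `rw_catalog`.
#' @return Character vector of stimulus labels.
#' @export
stimuli <- function(catalog) c(catalog$cs, catalog$contexts)

#' Trial specification
#'
#' A trial is a single time step on which discrete cues may be present and
#' the US may occur. The stage context is always added at expansion time, so
#' `cues` lists only discrete cues; an empty `cues` with `us = 1` is an
#' unsignaled US presentation.
#'
#' @param name Trial-type identifier, referenced by stages.
#' @param cues Character vector of CS labels present on the trial.
#' @param us 0 or 1; whether the US occurs.
#' @return An object of class `rw_trial`.
#' @examples
#' trial_spec("CS+", cues = "CS", us = 1)
#' trial_spec("shock", cues = character(), us = 1)
#' @export
trial_spec <- function(name, cues = character(), us = 0) {
  stopifnot(is.character(name), length(name) == 1L, us %in% c(0, 1))
  structure(list(name = name, cues = as.character(cues), us = as.numeric(us)),
            class = "rw_trial")
}

#' Stage of an experiment
#'
#' A stage is either a block of trials run in one context (each trial
#' preceded by `iti_steps` context-only steps), or a pure delay: a run of
#' featureless steps standing for time spent away from all experimental
#' stimuli (e.g. the home cage between extinction and test).
#'
#' @param label Stage identifier, unique within a group.
#' @param context Context label for trial stages; `NA` for delay stages.
#' @param trials Character vector of trial-type names in the literal order
#'   they are presented (use [interleave()] to round-robin trial types).
#' @param iti_steps Number of context-only steps preceding every trial.
#' @param delay_steps Number of featureless steps (delay stages only).
#' @return An object of class `rw_stage`.
#' @examples
#' stage("conditioning", "A", rep("CS+", 10))
#' stage("delay", NA, delay_steps = 1000)
#' @export
stage <- function(label, context = NA, trials = character(),
                  iti_steps = 5L, delay_steps = 0L) {
  stopifnot(is.character(label), length(label) == 1L,
            iti_steps >= 0L, delay_steps >= 0L)
  structure(list(label = label,
                 context = if (is.na(context[1L])) NA_character_ else as.character(context),
                 trials = as.character(trials),
                 iti_steps = as.integer(iti_steps),
                 delay_steps = as.integer(delay_steps)),
            class = "rw_stage")
}

#' Round-robin interleaving of trial-type blocks
#'
#' Cycles through its arguments, taking the next element of each in turn, the
#' standard way reinforced and nonreinforced trial types are intermixed in
#' conditioned-inhibition and discrimination training.
#'
#' @param ... Character vectors of trial names (recycled to the longest).
#' @return A single character vector in round-robin order.
#' @examples
#' interleave(rep("A+", 2), rep("AX-", 2))  # A+, AX-, A+, AX-
#' @export
interleave <- function(...) {
  blocks <- list(...)
  len <- max(lengths(blocks))
  blocks <- lapply(blocks, function(b) rep_len(b, len))
  as.character(do.call(rbind, blocks))
}

#' Experiment design
#'
#' The declarative description of a (possibly multi-group) conditioning
#' experiment: a stimulus catalog, a dictionary of trial types, and per
#' group an ordered list of stages.
#'
#' @param catalog An [stimulus_catalog()].
#' @param trials List of [trial_spec()] objects.
#' @param groups Named list; each element an ordered list of [stage()]s.
#' @param validate Check invariants and stop on violation (default `TRUE`).
#' @return An object of class `rw_design`.
#' @seealso [validate_design()], [expand_design()]
#' @export
design <- function(catalog, trials, groups, validate = TRUE) {
  if (inherits(trials, "rw_trial")) trials <- list(trials)
  names(trials) <- vapply(trials, `[[`, "", "name")
  d <- structure(list(catalog = catalog, trials = trials, groups = groups),
                 class = "rw_design")
  if (validate) {
    v <- validate_design(d)
    if (length(v)) stop("invalid design:\n  ", paste(v, collapse = "\n  "))
  }
  d
}

#' Validate a design
#'
#' Checks every structural invariant of a design and reports violations as
#' human-readable strings. Validation never throws; an empty return value
#' means the design is well formed.
#'
#' @param design An `rw_design`.
#' @return Character vector of violations (empty if valid).
#' @export
validate_design <- function(design) {
  v <- character()
  cat_ <- design$catalog
  all_stim <- stimuli(cat_)
  if (anyDuplicated(all_stim))
    v <- c(v, "duplicate stimulus labels in catalog")
  if (length(cat_$contexts) < 1L)
    v <- c(v, "catalog must declare at least one context")
  for (tr in design$trials) {
    bad <- setdiff(tr$cues, cat_$cs)
    if (length(bad))
      v <- c(v, sprintf("trial '%s' references undefined cue(s): %s",
                        tr$name, paste(bad, collapse = ", ")))
    if (!tr$us %in% c(0, 1))
      v <- c(v, sprintf("trial '%s' has non-binary us", tr$name))
  }
  if (!length(design$groups) || is.null(names(design$groups)))
    v <- c(v, "design must have at least one named group")
  for (g in names(design$groups)) {
    stages <- design$groups[[g]]
    if (!length(stages)) {
      v <- c(v, sprintf("group '%s' has no stages", g))
      next
    }
    labs <- vapply(stages, `[[`, "", "label")
    if (anyDuplicated(labs))
      v <- c(v, sprintf("group '%s' has duplicate stage labels", g))
    for (st in stages) {
      has_trials <- length(st$trials) > 0L
      has_delay <- st$delay_steps > 0L
      if (has_trials && has_delay)
        v <- c(v, sprintf("stage '%s' (group '%s') has both trials and delay_steps",
                          st$label, g))
      if (!has_trials && !has_delay)
        v <- c(v, sprintf("stage '%s' (group '%s') has neither trials nor delay_steps",
                          st$label, g))
      if (has_trials) {
        if (is.na(st$context))
          v <- c(v, sprintf("trial stage '%s' (group '%s') has no context",
                            st$label, g))
        else if (!st$context %in% cat_$contexts)
          v <- c(v, sprintf("stage '%s' (group '%s') references undefined context '%s'",
                            st$label, g, st$context))
        missing <- setdiff(unique(st$trials), names(design$trials))
        if (length(missing))
          v <- c(v, sprintf("stage '%s' (group '%s') references undefined trial(s): %s",
                            st$label, g, paste(missing, collapse = ", ")))
      }
      if (has_delay && !has_trials && !is.na(st$context))
        v <- c(v, sprintf("delay stage '%s' (group '%s') must not have a context",
                          st$label, g))
    }
  }
  v
}

#' Expand a design into a time-step sequence
#'
#' Deterministically unrolls one group's stages into the per-step cue and US
#' observations the learner sees. Every trial is preceded by exactly
#' `iti_steps` context-only steps; delay stages emit featureless steps; no
#' steps follow the final trial of a stage.
#'
#' @param design A valid `rw_design`.
#' @param group Group label.
#' @return An object of class `rw_timesteps`: a list with `info` (data frame
#'   with columns `step`, `stage`, `type` in trial/iti/delay, `trial`), `x`
#'   (steps-by-stimuli 0/1 matrix), and `y` (US vector).
#' @examples
#' d <- design(stimulus_catalog("CS", "A"),
#'             trial_spec("CS+", "CS", 1),
#'             groups = list(g = list(stage("cond", "A", rep("CS+", 2)))))
#' ts <- expand_design(d, "g")
#' nrow(ts$x)  # 12 steps: (5 ITI + 1 trial) x 2
#' @export
expand_design <- function(design, group) {
  if (!group %in% names(design$groups))
    stop("unknown group '", group, "'; available: ",
         paste(names(design$groups), collapse = ", "))
  stim <- stimuli(design$catalog)
  stage_v <- character(); type_v <- character(); trial_v <- character()
  x_rows <- list(); y_v <- numeric()
  zero <- stats::setNames(numeric(length(stim)), stim)
  for (st in design$groups[[group]]) {
    if (st$delay_steps > 0L) {
      k <- st$delay_steps
      stage_v <- c(stage_v, rep(st$label, k))
      type_v <- c(type_v, rep("delay", k))
      trial_v <- c(trial_v, rep(NA_character_, k))
      x_rows <- c(x_rows, rep(list(zero), k))
      y_v <- c(y_v, numeric(k))
      next
    }
    ctx_row <- zero
    ctx_row[st$context] <- 1
    for (tn in st$trials) {
      tr <- design$trials[[tn]]
      k <- st$iti_steps
      if (k > 0L) {
        stage_v <- c(stage_v, rep(st$label, k))
        type_v <- c(type_v, rep("iti", k))
        trial_v <- c(trial_v, rep(NA_character_, k))
        x_rows <- c(x_rows, rep(list(ctx_row), k))
        y_v <- c(y_v, numeric(k))
      }
      row <- ctx_row
      row[tr$cues] <- 1
      stage_v <- c(stage_v, st$label)
      type_v <- c(type_v, "trial")
      trial_v <- c(trial_v, tn)
      x_rows <- c(x_rows, list(row))
      y_v <- c(y_v, tr$us)
    }
  }
  x <- do.call(rbind, c(x_rows, list(deparse.level = 0)))
  if (is.null(x)) x <- matrix(0, 0, length(stim))
  colnames(x) <- stim
  structure(list(
    info = data.frame(step = seq_along(y_v), stage = stage_v, type = type_v,
                      trial = trial_v, stringsAsFactors = FALSE),
    x = x, y = y_v), class = "rw_timesteps")
}

#' @export
print.rw_timesteps <- function(x, ...) {
  cat("<rw_timesteps> ", nrow(x$x), " steps (",
      sum(x$info$type == "trial"), " trials), stimuli: ",
      paste(colnames(x$x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.rw_design <- function(x, ...) {
  cat("<rw_design> stimuli: ", paste(stimuli(x$catalog), collapse = ", "),
      "\n  trial types: ", paste(names(x$trials), collapse = ", "), "\n", sep = "")
  for (g in names(x$groups)) {
    labs <- vapply(x$groups[[g]], `[[`, "", "label")
    cat("  group ", g, ": ", paste(labs, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a time-step sequence as a long-format data frame
#'
#' @param x An `rw_timesteps`.
#' @param ... Unused.
#' @return Data frame with columns `step`, `stage`, `is_trial`, `trial_name`,
#'   one 0/1 column per stimulus, and `y`.
#' @export
as.data.frame.rw_timesteps <- function(x, ...) {
  cbind(data.frame(step = x$info$step, stage = x$info$stage,
                   is_trial = as.integer(x$info$type == "trial"),
                   trial_name = x$info$trial, stringsAsFactors = FALSE),
        as.data.frame(x$x), y = x$y)
}
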