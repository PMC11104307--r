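#' Mean test-stage response
#'
#' The conditioned fear response is read out as the predicted US value on
#' trial steps; ITI and delay steps are excluded, matching how conditioning
#' data are scored (responding during the CS, not the intervals).
#'
#' @param traj An `rw_trajectory`.
#' @param stage Stage label(s) to score.
#' @param trial Optional trial-name filter.
#' @param select `"all"` (mean over matching trials), `"last"` (final
#'   matching trial only, e.g. end-of-extinction responding), or `"first"`
#'   (first matching trial — the uncontaminated probe, before learning
#'   within the test stage itself alters responding).
#' @return Mean predicted US value over the selected trial steps.
#' @export
test_response <- function(traj, stage, trial = NULL,
                          select = c("all", "last", "first")) {
  select <- match.arg(select)
  keep <- traj$info$type == "trial" & traj$info$stage %in% stage
  if (!is.null(trial)) keep <- keep & traj$info$trial %in% trial
  idx <- which(keep)
  if (!length(idx))
    stop("no trial steps match stage '", paste(stage, collapse = "/"),
         "'", if (!is.null(trial)) paste0(" trial '", paste(trial, collapse = "/"), "'"))
  if (select == "last") idx <- max(idx)
  if (select == "first") idx <- min(idx)
  mean(traj$yhat[idx])
}

#' Measurement cell of a contrast
#'
#' Identifies one quantity: the mean trial response of one group in one (or
#' several) stage(s), optionally filtered by trial type.
#'
#' @param group Group label.
#' @param stage Stage label(s).
#' @param trial Optional trial-name filter.
#' @param select `"all"` or `"last"` (see [test_response()]).
#' @return An object of class `rw_cell`.
#' @export
cell <- function(group, stage, trial = NULL, select = "all") {
  structure(list(group = group, stage = stage, trial = trial, select = select),
            class = "rw_cell")
}

#' Difference of two measurement cells
#'
#' Evaluates to `a - b`; used for within-design magnitudes (test minus
#' end-of-extinction responding) and for difference-of-difference
#' (interaction) contrasts.
#'
#' @param a,b [cell()]s.
#' @return An object of class `rw_cell_diff`.
#' @export
cell_diff <- function(a, b) structure(list(a = a, b = b), class = "rw_cell_diff")

cell_value <- function(x, trajectories) {
  if (inherits(x, "rw_cell_diff"))
    return(cell_value(x$a, trajectories) - cell_value(x$b, trajectories))
  if (!x$group %in% names(trajectories))
    stop("no trajectory for group '", x$group, "'")
  test_response(trajectories[[x$group]], x$stage, x$trial, x$select)
}

#' Ordinal contrast specification
#'
#' An ordinal claim about two quantities: `left` greater/less than `right`
#' by at least `margin`, or equal to within `tolerance`. Margins are small
#' guards against float noise, far below the effect sizes the simulations
#' produce; the claims themselves are directional.
#'
#' @param label Human-readable description of the claim.
#' @param left,right [cell()] or [cell_diff()] objects.
#' @param relation `"greater"`, `"less"`, or `"approx_equal"`.
#' @param margin Minimum absolute difference for greater/less.
#' @param tolerance Maximum absolute difference for approx_equal.
#' @return An object of class `rw_contrast`.
#' @export
contrast_spec <- function(label, left, right,
                          relation = c("greater", "less", "approx_equal"),
                          margin = 0.01, tolerance = 0.02) {
  relation <- match.arg(relation)
  structure(list(label = label, left = left, right = right,
                 relation = relation, margin = margin, tolerance = tolerance),
            class = "rw_contrast")
}

#' Evaluate contrasts against group trajectories
#'
#' @param contrasts List of [contrast_spec()]s.
#' @param trajectories Named list of `rw_trajectory`, one per group.
#' @return Data frame with one row per contrast: `label`, `left_value`,
#'   `right_value`, `relation`, `margin`, `passed`.
#' @export
evaluate_contrasts <- function(contrasts, trajectories) {
  rows <- lapply(contrasts, function(cs) {
    lv <- cell_value(cs$left, trajectories)
    rv <- cell_value(cs$right, trajectories)
    passed <- switch(cs$relation,
      greater = lv - rv > cs$margin,
      less = rv - lv > cs$margin,
      approx_equal = abs(lv - rv) <= cs$tolerance)
    data.frame(label = cs$label, left_value = lv, right_value = rv,
               relation = cs$relation,
               margin = if (cs$relation == "approx_equal") cs$tolerance else cs$margin,
               passed = passed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
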