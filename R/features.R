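#' Build a feature basis from a stimulus catalog
#'
#' Maps stimuli to the features the learner associates with the US. Every
#' stimulus gets one elemental feature, active whenever the stimulus is
#' present. With `include_configural`, one configural feature is added per
#' unordered pair of stimuli that can co-occur — every CS-by-CS and
#' CS-by-context pair; context-by-context pairs are omitted because exactly
#' one context is present at a time. Configural features act like interaction
#' terms in a regression: active only when both constituents are present.
#'
#' `include_contexts = FALSE` drops context features entirely, giving the
#' impoverished representation of a learner that ignores the background —
#' useful for showing that extinction then reduces to pure unlearning.
#'
#' @param catalog An [stimulus_catalog()].
#' @param include_configural Add pairwise configural features?
#' @param include_contexts Represent contexts at all? (default `TRUE`)
#' @return An object of class `rw_basis`: a data frame with columns `id`,
#'   `kind` (elemental/configural), `s1`, `s2` (`NA` for elemental).
#' @examples
#' b <- build_basis(stimulus_catalog("CS", "A"), include_configural = TRUE)
#' b$id  # "CS" "A" "CS:A"
#' @export
build_basis <- function(catalog, include_configural = FALSE,
                        include_contexts = TRUE) {
  stim <- if (include_contexts) stimuli(catalog) else catalog$cs
  if (!length(stim)) stop("catalog yields no stimuli to featurize")
  df <- data.frame(id = stim, kind = "elemental", s1 = stim,
                   s2 = NA_character_, stringsAsFactors = FALSE)
  if (include_configural && length(stim) > 1L) {
    pairs <- utils::combn(stim, 2L)
    keep <- !(pairs[1L, ] %in% catalog$contexts & pairs[2L, ] %in% catalog$contexts)
    pairs <- pairs[, keep, drop = FALSE]
    if (ncol(pairs)) {
      df <- rbind(df, data.frame(
        id = paste0(pairs[1L, ], ":", pairs[2L, ]), kind = "configural",
        s1 = pairs[1L, ], s2 = pairs[2L, ], stringsAsFactors = FALSE))
    }
  }
  class(df) <- c("rw_basis", "data.frame")
  df
}

#' Feature activations for cue-presence vectors
#'
#' Elemental features copy the presence of their stimulus; configural
#' features are 1 exactly when both constituents are present. Activations
#' are binary.
#'
#' @param x Named 0/1 vector over catalog stimuli, or a steps-by-stimuli
#'   matrix with stimulus column names.
#' @param basis An [build_basis()] result.
#' @return Activation vector (or matrix) with one entry per feature, named
#'   by feature id.
#' @export
featurize <- function(x, basis) {
  if (is.matrix(x)) {
    need <- unique(c(basis$s1, stats::na.omit(basis$s2)))
    if (!all(need %in% colnames(x)))
      stop("cue matrix lacks stimuli: ",
           paste(setdiff(need, colnames(x)), collapse = ", "))
    f <- x[, basis$s1, drop = FALSE]
    cfg <- which(basis$kind == "configural")
    if (length(cfg))
      f[, cfg] <- f[, cfg, drop = FALSE] * x[, basis$s2[cfg], drop = FALSE]
    colnames(f) <- basis$id
    return(f)
  }
  if (is.null(names(x))) stop("cue vector must be named by stimulus")
  drop(featurize(matrix(x, 1L, dimnames = list(NULL, names(x))), basis))
}

#' Export a feature basis as JSON
#'
#' @param basis An `rw_basis`.
#' @param path File path; if `NULL`, returns the JSON string.
#' @return The path (invisibly) or a JSON string.
#' @export
write_basis_json <- function(basis, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(unclass(basis), stringsAsFactors = FALSE),
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
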