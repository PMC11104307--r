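design_to_list <- function(design) {
  list(
    catalog = list(cs = design$catalog$cs, contexts = design$catalog$contexts),
    trials = lapply(unname(design$trials), function(tr)
      list(name = tr$name, cues = tr$cues, us = tr$us)),
    groups = lapply(design$groups, function(stages)
      lapply(stages, function(st)
        list(label = st$label,
             context = if (is.na(st$context)) NULL else st$context,
             trials = st$trials, iti_steps = st$iti_steps,
             delay_steps = st$delay_steps))))
}

design_from_list <- function(x, validate = TRUE) {
  catalog <- stimulus_catalog(unlist(x$catalog$cs), unlist(x$catalog$contexts))
  trials <- lapply(x$trials, function(tr)
    trial_spec(tr$name, unlist(tr$cues), tr$us))
  groups <- lapply(x$groups, function(stages)
    lapply(stages, function(st)
      stage(st$label,
            context = if (is.null(st$context)) NA else st$context,
            trials = unlist(st$trials),
            iti_steps = if (is.null(st$iti_steps)) 5L else st$iti_steps,
            delay_steps = if (is.null(st$delay_steps)) 0L else st$delay_steps)))
  design(catalog, trials, groups, validate = validate)
}

#' Write a design to a JSON (or YAML) file
#'
#' The file mirrors the design structure — catalog, trial dictionary, and
#' per-group stage lists — so exported paradigms can be edited by hand and
#' re-run.
#'
#' @param design An `rw_design`.
#' @param path Output path; `.yaml`/`.yml` extensions select YAML.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  x <- design_to_list(design)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, null = "null"),
               path)
  }
  invisible(path)
}

#' Read a design from a JSON or YAML file
#'
#' @param path File path (format chosen by extension; YAML is an equivalent
#'   dialect of the JSON schema).
#' @param validate Stop on invariant violations (default `TRUE`).
#' @return An `rw_design`.
#' @export
read_design <- function(path, validate = TRUE) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  design_from_list(x, validate = validate)
}
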