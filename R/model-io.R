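#' Read a metabolic model from its native JSON format
#'
#' The schema holds `format_version`, `metabolites` (list of `{id}`),
#' `reactions` (list of `{id, stoichiometry, lower_bound, upper_bound,
#' reversible, gpr, subsystem}`) and `objective`. GPR strings are parsed
#' eagerly so malformed rules fail at load time with the offending
#' reaction named.
#'
#' @param path path to the JSON file.
#' @return A [metabolic_model].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions", "objective")) {
    if (is.null(doc[[field]])) {
      stopf("model schema violation at /%s: field missing", field)
    }
  }
  mets <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stopf("model schema violation at /metabolites: missing id")
    as.character(m$id)
  }, character(1L))
  rxns <- list()
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    if (is.null(r$id)) {
      stopf("model schema violation at /reactions/%d: missing id", k - 1L)
    }
    st <- unlist(r$stoichiometry %||% list())
    rxns[[as.character(r$id)]] <- list(
      stoichiometry = st,
      lower_bound = r$lower_bound %||% 0,
      upper_bound = r$upper_bound %||% 1000,
      reversible = r$reversible %||% ((r$lower_bound %||% 0) < 0),
      gpr = r$gpr %||% "",
      subsystem = r$subsystem %||% "Unassigned")
  }
  metabolic_model(mets, rxns, as.character(doc$objective))
}

#' Write a metabolic model to the native JSON format
#'
#' @param model a [metabolic_model].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- lapply(seq_along(model$rxns), function(j) {
    st <- model$S[, j]
    st <- st[st != 0]
    list(id = model$rxns[j],
         stoichiometry = as.list(st),
         lower_bound = model$lb[j],
         upper_bound = model$ub[j],
         reversible = model$reversible[j],
         gpr = model$gpr[j],
         subsystem = model$subsystem[j])
  })
  doc <- list(format_version = "1.0",
              metabolites = lapply(model$mets, function(m) list(id = m)),
              reactions = rxns,
              objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
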