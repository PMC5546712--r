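# Declarative model-file format (YAML, schema "dendsig-model-v1"):
#   name: <string>
#   schema: dendsig-model-v1
#   species:   [{name, loc, D, init}, ...]
#   reactions: [{eq, kf, kr, units, tag}, ...]
#   moieties:  {<name>: {<species>: <weight>, ...}, ...}

MODEL_SCHEMA <- "dendsig-model-v1"

#' Load a model definition from a YAML config file
#'
#' @param config_path path to a model file in the package's declarative
#'   format (see [write_model()] for the schema).
#' @return a `sig_model`.
#' @export
load_model <- function(config_path) {
  if (!file.exists(config_path)) stop("no such model file: ", config_path)
  doc <- tryCatch(yaml::read_yaml(config_path), error = function(e)
    stop("model file parse failure in '", config_path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!identical(doc$schema, MODEL_SCHEMA))
    stop("unsupported or missing schema (expected '", MODEL_SCHEMA, "')")
  sp <- do.call(rbind, lapply(seq_along(doc$species), function(i) {
    s <- doc$species[[i]]
    tryCatch(
      sig_species(s$name, loc = s$loc %||% "cyt", D = s$D %||% 0,
                  init = s$init %||% 0),
      error = function(e) stop("species entry ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }))
  rx <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    out <- tryCatch(
      sig_reaction(r$eq, kf = r$kf, kr = r$kr %||% 0, tag = r$tag %||% ""),
      error = function(e) stop("reaction entry ", i, " ('", r$eq, "'): ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(r$units)) out$units <- r$units
    out
  })
  moieties <- lapply(doc$moieties %||% list(), function(w)
    structure(as.numeric(unlist(w)), names = names(w)))
  m <- tryCatch(
    sig_model(sp, rx, name = doc$name %||% "model", moieties = moieties),
    error = function(e) stop("model validation error: ", conditionMessage(e),
                             call. = FALSE))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model definition to a YAML config file
#'
#' @param m a `sig_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  doc <- list(
    name = m$name,
    schema = MODEL_SCHEMA,
    species = lapply(seq_len(nrow(m$species)), function(i)
      list(name = m$species$name[i], loc = m$species$loc[i],
           D = m$species$D[i], init = m$species$init[i])),
    reactions = lapply(m$reactions, function(r)
      list(eq = r$eq, kf = r$kf, kr = r$kr,
           units = r$units %||% order_units(sum(r$reactants)), tag = r$tag)),
    moieties = lapply(m$moieties, as.list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Flat reaction table for audit
#'
#' @param m a `sig_model`.
#' @return data.frame with one row per reaction (equation, rates, units,
#'   order, pathway tag); write with [utils::write.csv()] for export.
#' @export
reaction_table <- function(m) {
  data.frame(
    eq = vapply(m$reactions, `[[`, "", "eq"),
    kf = vapply(m$reactions, `[[`, 0, "kf"),
    kr = vapply(m$reactions, `[[`, 0, "kr"),
    order = vapply(m$reactions, function(r) sum(r$reactants), 0L),
    units = vapply(m$reactions, function(r)
      r$units %||% order_units(sum(r$reactants)), ""),
    reversible = vapply(m$reactions, `[[`, TRUE, "reversible"),
    tag = vapply(m$reactions, `[[`, "", "tag"),
    stringsAsFactors = FALSE)
}
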