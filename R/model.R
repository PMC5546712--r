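#' @keywords internal
"_PACKAGE"

# Localization codes:
#   cyt  -- cytosolic, diffusible (present in every region)
#   sub  -- anchored in dendrite submembrane + spine head
#   psd  -- anchored in the PSD
#   head -- anchored in the spine head only
LOCALIZATIONS <- c("cyt", "sub", "psd", "head")

#' Define a molecular species
#'
#' @param name species identifier.
#' @param loc localization: `"cyt"` (cytosolic, diffusible), `"sub"`
#'   (anchored in dendrite submembrane and spine head), `"psd"` (anchored in
#'   the postsynaptic density) or `"head"` (spine head only).
#' @param D diffusion constant in um^2/s; must be 0 for anchored species.
#' @param init initial concentration (nM) within the species' region(s).
#' @return a one-row data.frame usable with [sig_model()].
#' @export
sig_species <- function(name, loc = "cyt", D = 0, init = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  loc <- match.arg(loc, LOCALIZATIONS)
  if (D < 0) stop("diffusion constant must be >= 0: ", name)
  if (loc != "cyt" && D != 0)
    stop("anchored species must have zero diffusion constant: ", name)
  data.frame(name = name, loc = loc, D = D, init = init,
             stringsAsFactors = FALSE)
}

#' Define a reaction from a chemical-equation string
#'
#' Reactions are at most bimolecular in each direction. The equation syntax is
#' `"A + B <-> C"` (reversible) or `"A + B -> C"` (irreversible); repeated
#' reactants are written explicitly (`"X + X -> D"`) or with an integer
#' stoichiometry prefix (`"2 X -> D"`). Zeroth-order production is written
#' with an empty left-hand side (`" -> Ca"`), and pure removal with an empty
#' right-hand side.
#'
#' @param eq equation string.
#' @param kf forward rate constant (units: /s for first order, /nM/s for
#'   second order, nM/s for zeroth order).
#' @param kr reverse rate constant (0 for irreversible reactions).
#' @param tag pathway-block tag (free-form label, e.g. `"CaMKII"`).
#' @return a `sig_reaction` list.
#' @export
sig_reaction <- function(eq, kf, kr = 0, tag = "") {
  sides <- strsplit(eq, "<->|->", perl = TRUE)[[1]]
  reversible <- grepl("<->", eq, fixed = TRUE)
  if (length(sides) > 2L) stop("malformed equation: ", eq)
  lhs <- parse_side(if (length(sides) >= 1L) sides[1] else "")
  rhs <- parse_side(if (length(sides) == 2L) sides[2] else "")
  if (!reversible && kr != 0) stop("kr given for irreversible reaction: ", eq)
  r <- list(reactants = lhs, products = rhs, kf = kf, kr = kr,
            reversible = reversible, tag = tag, eq = eq)
  class(r) <- "sig_reaction"
  validate_reaction(r)
  r
}

parse_side <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  out <- integer(0)
  for (t in terms) {
    m <- regmatches(t, regexec("^([0-9]+)\\s+(.*)$", t))[[1]]
    if (length(m) == 3L) {
      n <- as.integer(m[2]); sp <- m[3]
    } else {
      n <- 1L; sp <- t
    }
    if (!nzchar(sp)) stop("malformed species term: '", t, "'")
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + n
  }
  out
}

validate_reaction <- function(r) {
  if (any(r$reactants <= 0) || any(r$products <= 0))
    stop("stoichiometries must be positive integers: ", r$eq)
  if (sum(r$reactants) > 2L)
    stop("reaction order exceeds 2 (bimolecular at most): ", r$eq)
  if (r$reversible && sum(r$products) > 2L)
    stop("reverse reaction order exceeds 2: ", r$eq)
  if (r$kf < 0 || r$kr < 0) stop("negative rate constant: ", r$eq)
  invisible(r)
}

#' Assemble a reaction-network model
#'
#' @param species data.frame from rbinding [sig_species()] rows.
#' @param reactions list of [sig_reaction()] objects.
#' @param name model name.
#' @param moieties optional named list; each element is a named numeric vector
#'   giving, per species, how many copies of the conserved moiety that species
#'   carries. Used by [validate_model()].
#' @param volume_factor volume scaling applied when converting concentrations
#'   to molecule counts (see [scale_model()]).
#' @return an object of class `sig_model`.
#' @export
sig_model <- function(species, reactions, name = "model",
                      moieties = list(), volume_factor = 1) {
  stopifnot(is.data.frame(species), is.list(reactions))
  if (anyDuplicated(species$name))
    stop("duplicated species: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  m <- structure(list(name = name, species = species, reactions = reactions,
                      moieties = moieties, volume_factor = volume_factor),
                 class = "sig_model")
  unknown <- setdiff(referenced_species(m), species$name)
  if (length(unknown))
    stop("reactions reference unknown species: ",
         paste(unknown, collapse = ", "))
  m
}

referenced_species <- function(m) {
  unique(unlist(lapply(m$reactions, function(r)
    c(names(r$reactants), names(r$products)))))
}

#' @export
print.sig_model <- function(x, ...) {
  cat("<sig_model> ", x$name, "\n", sep = "")
  cat("  species:   ", nrow(x$species), "\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      " (", sum(vapply(x$reactions, `[[`, TRUE, "reversible")),
      " reversible)\n", sep = "")
  if (length(x$moieties))
    cat("  declared conserved moieties: ",
        paste(names(x$moieties), collapse = ", "), "\n", sep = "")
  if (x$volume_factor != 1)
    cat("  volume factor: ", x$volume_factor, "\n", sep = "")
  invisible(x)
}

#' @export
summary.sig_model <- function(object, ...) {
  tags <- vapply(object$reactions, `[[`, "", "tag")
  out <- list(name = object$name,
              n_species = nrow(object$species),
              n_reactions = length(object$reactions),
              by_tag = table(tags),
              by_loc = table(object$species$loc),
              validation = validate_model(object))
  class(out) <- "summary.sig_model"
  out
}

#' @export
print.summary.sig_model <- function(x, ...) {
  cat("Model:", x$name, "-", x$n_species, "species,",
      x$n_reactions, "reactions\n")
  cat("Localization:\n"); print(x$by_loc)
  cat("Pathway blocks:\n"); print(x$by_tag)
  print(x$validation)
  invisible(x)
}

#' Stoichiometry matrix
#'
#' @param m a `sig_model`.
#' @param elementary if `TRUE`, reversible reactions are expanded into
#'   separate forward and backward columns (the engine's reaction channels);
#'   otherwise each reaction is a single signed column.
#' @return integer matrix, species x reactions.
#' @export
stoich_matrix <- function(m, elementary = FALSE) {
  sp <- m$species$name
  cols <- list()
  for (r in m$reactions) {
    v <- numeric(length(sp)); names(v) <- sp
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    v[names(r$products)] <- v[names(r$products)] + r$products
    cols[[length(cols) + 1L]] <- v
    if (elementary && r$reversible) cols[[length(cols) + 1L]] <- -v
  }
  S <- if (length(cols)) do.call(cbind, cols)
       else matrix(0, length(sp), 0)
  rownames(S) <- sp
  S
}

# Elementary channels: one row per direction of each reaction.
# Returns list with reactant index/stoich matrices used by both engines.
reaction_channels <- function(m) {
  sp <- m$species$name
  idx <- function(x) match(x, sp)
  chan <- list()
  for (ri in seq_along(m$reactions)) {
    r <- m$reactions[[ri]]
    chan[[length(chan) + 1L]] <-
      list(re = idx(names(r$reactants)), rs = unname(r$reactants),
           pr = idx(names(r$products)), ps = unname(r$products),
           k = r$kf, reaction = ri, dir = 1L)
    if (r$reversible)
      chan[[length(chan) + 1L]] <-
        list(re = idx(names(r$products)), rs = unname(r$products),
             pr = idx(names(r$reactants)), ps = unname(r$reactants),
             k = r$kr, reaction = ri, dir = -1L)
  }
  chan
}

#' Validate a model
#'
#' Checks (i) declared moiety conservation against the stoichiometry matrix,
#' (ii) rate-unit consistency with reaction order (when unit declarations are
#' present, as in loaded config files), (iii) dangling species (never
#' referenced by any reaction), and (iv) localization consistency (anchored
#' species must have zero diffusion constant, diffusible species must be
#' cytosolic).
#'
#' @param m a `sig_model`.
#' @return a `sig_validation` report; `pass` is `TRUE` iff all failure lists
#'   are empty.
#' @export
validate_model <- function(m) {
  S <- stoich_matrix(m)
  moiety_failures <- character(0)
  for (nm in names(m$moieties)) {
    y <- numeric(nrow(m$species)); names(y) <- m$species$name
    w <- m$moieties[[nm]]
    bad <- setdiff(names(w), m$species$name)
    if (length(bad)) {
      moiety_failures <- c(moiety_failures,
        paste0(nm, ": unknown species ", paste(bad, collapse = ",")))
      next
    }
    y[names(w)] <- w
    resid <- drop(y %*% S)
    viol <- which(abs(resid) > 1e-9)
    if (length(viol))
      moiety_failures <- c(moiety_failures, paste0(
        nm, ": not conserved by reaction(s) ",
        paste(vapply(viol, function(j) m$reactions[[attr_col_rxn(m, j)]]$eq, ""),
              collapse = "; ")))
  }
  unit_errors <- character(0)
  for (r in m$reactions) {
    if (!is.null(r$units)) {
      expected <- order_units(sum(r$reactants))
      if (!identical(r$units, expected))
        unit_errors <- c(unit_errors, paste0(
          r$eq, ": declared '", r$units, "', order implies '", expected, "'"))
    }
  }
  dangling <- setdiff(m$species$name, referenced_species(m))
  if (length(m$reactions) == 0L) dangling <- m$species$name
  loc_errors <- character(0)
  bad <- m$species$loc != "cyt" & m$species$D > 0
  if (any(bad))
    loc_errors <- c(loc_errors,
      paste0("anchored species with nonzero D: ",
             paste(m$species$name[bad], collapse = ", ")))
  rep <- list(moiety_failures = moiety_failures, unit_errors = unit_errors,
              dangling_species = dangling, localization_errors = loc_errors)
  rep$pass <- all(lengths(rep[1:4]) == 0L)
  class(rep) <- "sig_validation"
  rep
}

# map a (non-elementary) stoichiometry column index to its reaction index
attr_col_rxn <- function(m, j) j

#' @export
print.sig_validation <- function(x, ...) {
  cat("Model validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (f in c("moiety_failures", "unit_errors", "dangling_species",
              "localization_errors"))
    if (length(x[[f]]))
      cat("  ", f, ": ", paste(x[[f]], collapse = "; "), "\n", sep = "")
  invisible(x)
}

order_units <- function(order) {
  switch(as.character(order), "0" = "nM/s", "1" = "/s", "2" = "/nM/s",
         stop("unsupported order ", order))
}

#' Conserved moieties derived from the stoichiometry matrix
#'
#' Left null space of the stoichiometry matrix: every returned vector `y`
#' satisfies `y %*% S == 0`, i.e. the weighted species total is invariant
#' under every reaction.
#'
#' @param m a `sig_model`.
#' @return matrix with one column per independent conserved combination.
#' @export
conserved_moieties <- function(m) {
  S <- stoich_matrix(m)
  ns <- null_space(t(S))
  rownames(ns) <- m$species$name
  ns
}

null_space <- function(A, tol = 1e-10) {
  s <- svd(A, nu = 0, nv = ncol(A))
  keep <- s$d < tol * max(s$d, 1)
  r <- sum(s$d >= tol * max(s$d, 1))
  if (r == ncol(A)) return(matrix(numeric(0), nrow = ncol(A), ncol = 0))
  s$v[, (r + 1):ncol(A), drop = FALSE]
}

#' Rescale model volume at fixed concentrations
#'
#' Molecule counts used by the stochastic engine scale with the volume factor
#' while concentrations -- and hence all deterministic dynamics -- are
#' unchanged. Used to build reduced-scale stochastic models.
#'
#' @param m a `sig_model`.
#' @param volume_factor positive scaling of all compartment volumes.
#' @return rescaled `sig_model`.
#' @export
scale_model <- function(m, volume_factor) {
  if (!is.numeric(volume_factor) || length(volume_factor) != 1 ||
      volume_factor <= 0)
    stop("volume_factor must be a positive number")
  m$volume_factor <- m$volume_factor * volume_factor
  m
}

#' Scale initial amounts of selected species
#'
#' @param m a `sig_model`.
#' @param factors named numeric vector, species name -> multiplier applied to
#'   the initial concentration.
#' @return modified model.
#' @export
scale_initials <- function(m, factors) {
  bad <- setdiff(names(factors), m$species$name)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  i <- match(names(factors), m$species$name)
  m$species$init[i] <- m$species$init[i] * unname(factors)
  m
}

#' Modify rate constants of tagged reactions
#'
#' @param m a `sig_model`.
#' @param tag pathway tag to match.
#' @param kf_factor,kr_factor multipliers applied to matching reactions.
#' @return modified model.
#' @export
scale_rates <- function(m, tag, kf_factor = 1, kr_factor = 1) {
  hit <- FALSE
  for (i in seq_along(m$reactions)) {
    if (m$reactions[[i]]$tag == tag) {
      m$reactions[[i]]$kf <- m$reactions[[i]]$kf * kf_factor
      m$reactions[[i]]$kr <- m$reactions[[i]]$kr * kr_factor
      hit <- TRUE
    }
  }
  if (!hit) stop("no reactions with tag: ", tag)
  m
}
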