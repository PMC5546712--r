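#' Simulation trajectory container
#'
#' Holds per-compartment concentration time series (nM) with complete
#' metadata (engine mode, seed, timestep, protocol).
#'
#' @param times sample times (s).
#' @param conc array `[species, compartment, time]` of concentrations (nM).
#' @param species species names.
#' @param comp list with `names`, `volume` (um^3) and `spine` index per
#'   compartment.
#' @param meta metadata list.
#' @return object of class `sig_trajectory`.
#' @keywords internal
new_trajectory <- function(times, conc, species, comp, meta) {
  stopifnot(!is.unsorted(times))
  structure(list(times = times, conc = conc, species = species,
                 comp = comp, meta = meta),
            class = "sig_trajectory")
}

#' @export
print.sig_trajectory <- function(x, ...) {
  cat("<sig_trajectory> ", length(x$species), " species x ",
      length(x$comp$names), " compartments x ", length(x$times),
      " samples [", min(x$times), ", ", max(x$times), "] s\n", sep = "")
  cat("  mode: ", x$meta$mode,
      if (!is.null(x$meta$seed)) paste0(", seed ", x$meta$seed),
      if (!is.null(x$meta$protocol)) paste0(", protocol ", x$meta$protocol),
      "\n", sep = "")
  invisible(x)
}

comp_ids <- function(traj, where = c("spine", "dendrite", "all"),
                     spine = NULL) {
  where <- match.arg(where)
  nm <- traj$comp$names
  if (where == "all") return(seq_along(nm))
  if (where == "dendrite") return(which(nm %in% c("dend_sub", "dend_cyt")))
  i <- grep("^head", nm)
  if (!is.null(spine)) i <- i[traj$comp$spine[i] %in% spine]
  if (!length(i)) stop("no spine-head compartment matches")
  i
}

#' Extract an aggregated concentration trace
#'
#' Sums molecule numbers of the requested species over the requested
#' compartments and divides by their total volume, giving a concentration
#' (nM) time series.
#'
#' @param traj a `sig_trajectory`.
#' @param species character vector of species names (summed).
#' @param where `"spine"` (spine head incl. PSD), `"dendrite"` (submembrane +
#'   cytosol) or `"all"`.
#' @param spine optional spine index (for multi-spine meshes).
#' @return numeric vector along `traj$times`.
#' @export
species_trace <- function(traj, species, where = "all", spine = NULL) {
  si <- match(species, traj$species)
  if (anyNA(si))
    stop("species not in trajectory: ",
         paste(species[is.na(si)], collapse = ", "))
  ci <- comp_ids(traj, where, spine)
  v <- traj$comp$volume[ci]
  sub <- traj$conc[si, ci, , drop = FALSE]
  mol <- apply(sweep(sub, 2, v, `*`), 3, sum)
  mol / sum(v)
}

#' @export
plot.sig_trajectory <- function(x, species, where = "all", spine = NULL,
                                ...) {
  y <- species_trace(x, species, where, spine)
  plot(x$times, y, type = "l", xlab = "time (s)",
       ylab = paste0("[", paste(species, collapse = "+"), "] (nM)"), ...)
  invisible(x)
}

#' Convert a trajectory to a long data.frame
#' @param x a `sig_trajectory`.
#' @param species subset of species (default all).
#' @param ... unused.
#' @return data.frame (time, species, compartment, conc).
#' @export
as.data.frame.sig_trajectory <- function(x, species = x$species, ...) {
  si <- match(species, x$species)
  nt <- length(x$times); nc <- length(x$comp$names)
  data.frame(
    time = rep(x$times, each = length(si) * nc),
    species = rep(species, times = nt * nc)[seq_len(length(si) * nc * nt)],
    compartment = rep(rep(x$comp$names, each = length(si)), times = nt),
    conc = as.vector(x$conc[si, , , drop = FALSE]))
}
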