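#' Single well-mixed subvolume
#'
#' Minimal `sig_compartments` object for toy models: one cytosolic
#' subvolume of the given volume.
#'
#' @param volume um^3; the default makes 1 nM correspond to exactly one
#'   molecule, so counts and concentrations coincide numerically.
#' @return a `sig_compartments`.
#' @export
single_volume <- function(volume = 1 / COUNT_PER_NM_UM3) {
  regvol <- matrix(0, 1, length(REGIONS), dimnames = list(NULL, REGIONS))
  regvol[1, "dend_cyt"] <- volume
  structure(list(names = "dend_cyt", volume = volume,
                 region_volume = regvol,
                 exchange = data.frame(i = integer(0), j = integer(0),
                                       Ad = numeric(0)),
                 spine = NA_integer_),
            class = "sig_compartments")
}

#' Synthetic test fixtures with analytic oracles
#'
#' Builds small models whose exact behavior is known in closed form (or by
#' direct linear algebra), for validating the simulation engines:
#'
#' * `"birth-death"`: zeroth-order production at `k1` (molecules/s) and
#'   first-order decay at `k2` (/s). Oracle: stationary count is Poisson
#'   with mean and variance `k1/k2`; the deterministic relaxation is
#'   `x(t) = m + (x0 - m) exp(-k2 t)` with `m = k1/k2`.
#' * `"reversible-binding"`: `A + B <-> C`. Oracle: equilibrium from the
#'   quadratic mass-action formula.
#' * `"enzyme-cycle"`: `E + S <-> ES -> E + P`, `P -> S`. Oracle: steady
#'   state by direct solve.
#' * `"distributive-4site"`: substrate with four sequential
#'   phosphorylation sites, a clamped kinase pool and first-order
#'   dephosphorylation. Oracle: 5-state ladder occupancy by linear solve.
#' * `"reduced-ca1"`: the full CA1 model volume-scaled by
#'   `pars$volume_factor` (deterministic dynamics invariant).
#'
#' @param kind fixture kind.
#' @param pars named list of parameters (see defaults in the code).
#' @return list with `model`, `mesh` (a `sig_compartments`), and `oracle`
#'   (a function returning the exact expected statistics).
#' @export
make_fixture <- function(kind = c("birth-death", "reversible-binding",
                                  "enzyme-cycle", "distributive-4site",
                                  "reduced-ca1"),
                         pars = list()) {
  kind <- match.arg(kind)
  sv <- single_volume()
  if (kind == "birth-death") {
    p <- utils::modifyList(list(k1 = 10, k2 = 1, x0 = 0), pars)
    m <- sig_model(
      sig_species("X", "cyt", 0, p$x0),
      list(sig_reaction(" -> X", p$k1, tag = "birth"),
           sig_reaction("X -> ", p$k2, tag = "death")),
      name = "birth-death")
    oracle <- function() {
      mean <- p$k1 / p$k2
      list(mean = mean, var = mean,
           traj = function(t) mean + (p$x0 - mean) * exp(-p$k2 * t))
    }
    return(list(model = m, mesh = sv, oracle = oracle))
  }
  if (kind == "reversible-binding") {
    p <- utils::modifyList(list(a0 = 100, b0 = 60, kf = 0.01, kr = 1), pars)
    m <- sig_model(
      rbind(sig_species("A", "cyt", 0, p$a0),
            sig_species("B", "cyt", 0, p$b0),
            sig_species("C", "cyt", 0, 0)),
      list(sig_reaction("A + B <-> C", p$kf, p$kr, tag = "binding")),
      name = "reversible-binding",
      moieties = list(A = c(A = 1, C = 1), B = c(B = 1, C = 1)))
    oracle <- function() {
      Kd <- p$kr / p$kf
      s <- p$a0 + p$b0 + Kd
      c_eq <- (s - sqrt(s^2 - 4 * p$a0 * p$b0)) / 2
      list(A = p$a0 - c_eq, B = p$b0 - c_eq, C = c_eq)
    }
    return(list(model = m, mesh = sv, oracle = oracle))
  }
  if (kind == "enzyme-cycle") {
    p <- utils::modifyList(list(e0 = 10, s0 = 100, k1 = 0.01, km1 = 1,
                                kcat = 2, krec = 0.5), pars)
    m <- sig_model(
      rbind(sig_species("E", "cyt", 0, p$e0),
            sig_species("S", "cyt", 0, p$s0),
            sig_species("ES", "cyt", 0, 0),
            sig_species("P", "cyt", 0, 0)),
      list(sig_reaction("E + S <-> ES", p$k1, p$km1, tag = "enzyme"),
           sig_reaction("ES -> E + P", p$kcat, tag = "enzyme"),
           sig_reaction("P -> S", p$krec, tag = "recycle")),
      name = "enzyme-cycle",
      moieties = list(E = c(E = 1, ES = 1), S = c(S = 1, ES = 1, P = 1)))
    oracle <- function() {
      # steady state: solve for ES from the quadratic conservation system
      f <- function(es) {
        e <- p$e0 - es
        pp <- p$kcat * es / p$krec
        s <- p$s0 - es - pp
        p$k1 * e * s - (p$km1 + p$kcat) * es
      }
      es <- stats::uniroot(f, c(0, min(p$e0, p$s0) - 1e-9))$root
      pp <- p$kcat * es / p$krec
      list(E = p$e0 - es, ES = es, P = pp, S = p$s0 - es - pp)
    }
    return(list(model = m, mesh = sv, oracle = oracle))
  }
  if (kind == "distributive-4site") {
    p <- utils::modifyList(list(x0 = 100, kin = 5, kf = c(1, 2, 4, 8) * 1e-3,
                                kdeph = 0.05), pars)
    species <- do.call(rbind, c(
      list(sig_species("K", "cyt", 0, p$kin)),
      lapply(0:4, function(i) sig_species(paste0("X", i), "cyt", 0,
                                          if (i == 0) p$x0 else 0))))
    rxns <- list(sig_reaction("K -> K", 0, tag = "clamp"))
    for (i in 0:3) {
      rxns[[length(rxns) + 1L]] <-
        sig_reaction(sprintf("X%d + K -> X%d + K", i, i + 1), p$kf[i + 1],
                     tag = "kinase")
      rxns[[length(rxns) + 1L]] <-
        sig_reaction(sprintf("X%d -> X%d", i + 1, i), p$kdeph,
                     tag = "phosphatase")
    }
    m <- sig_model(species, rxns, name = "distributive-4site",
                   moieties = list(X = structure(rep(1, 5),
                                                 names = paste0("X", 0:4))))
    oracle <- function(kin = p$kin) {
      # stationary ladder occupancy: detailed-balance chain
      r <- p$kf * kin / p$kdeph
      w <- cumprod(c(1, r))
      w * p$x0 / sum(w)
    }
    return(list(model = m, mesh = sv, oracle = oracle))
  }
  # reduced-ca1
  p <- utils::modifyList(list(volume_factor = 0.05), pars)
  m <- scale_model(ca1_model(), p$volume_factor)
  mesh <- compartments(build_mesh(geometry_spec(), resolution = 0.25))
  list(model = m, mesh = mesh,
       oracle = function() list(volume_factor = p$volume_factor))
}

#' AC/PDE4 robustness perturbation variants
#'
#' The base model plus the two joint perturbations of adenylyl-cyclase and
#' PDE4 abundance used for robustness analysis: 70% of both, and 130% AC
#' with 120% PDE4 (varied together to preserve the ~30 nM basal cAMP
#' balance).
#'
#' @param m base model (default [ca1_model()]).
#' @return named list of three `sig_model`s: `base`, `low` (70%/70%),
#'   `high` (130%/120%).
#' @export
make_perturbations <- function(m = ca1_model()) {
  list(base = m,
       low = scale_initials(m, c(AC1 = 0.7, AC8 = 0.7, PDE4 = 0.7)),
       high = scale_initials(m, c(AC1 = 1.3, AC8 = 1.3, PDE4 = 1.2)))
}

#' Multi-spine stimulation setup
#'
#' Eight spines on a 20 um dendrite; spines 6 and 7 are adjacent (1.5 um
#' apart) and spines 3 and 7 are separated (8 um apart). Builds the
#' geometry, reduces AC and PDE4 to 70% of baseline, and constructs a
#' 4xHFS-80s program delivered to the named spines only (dendritic pulses
#' are delivered regardless, plus NE co-release).
#'
#' @param stim_spines indices (1..8) of stimulated spines; may be empty for
#'   a dendrite-only program.
#' @param calib a [calibration_set()].
#' @return list with `geometry`, `model`, and `program`.
#' @export
multispine_setup <- function(stim_spines = c(6L, 7L),
                             calib = calibration_set()) {
  positions <- c(1.5, 4.0, 7.5, 9.5, 11.5, 14.0, 15.5, 18.0)
  if (length(stim_spines) && (any(stim_spines < 1) || any(stim_spines > 8)))
    stop("invalid spine index (expected 1..8)")
  g <- geometry_spec(dendrite_length = 20, dendrite_diameter = 0.6,
                     spine_positions = positions)
  m <- scale_initials(ca1_model(), c(AC1 = 0.7, AC8 = 0.7, PDE4 = 0.7))
  prog <- build_protocol("4xHFS-80s", calib,
                         spines = if (length(stim_spines)) stim_spines
                                  else integer(0))
  if (!length(stim_spines)) {
    keep <- prog$injections$target != "psd"
    prog$injections <- prog$injections[keep, , drop = FALSE]
  }
  list(geometry = g, model = m, program = prog)
}

#' Ultrasensitivity of the receptor phosphorylation ladder
#'
#' Clamps the PKA catalytic subunit at a range of activities, drives a
#' stand-alone copy of the four-site distributive beta2AR phosphorylation
#' ladder to steady state, and fits an effective Hill coefficient to the
#' fraction of fully phosphorylated receptor (slope of the logit-log
#' dose-response around the midpoint). Cooperative, distributive multisite
#' phosphorylation yields a coefficient above 1.
#'
#' @param pkac_levels clamped PKAc concentrations (nM).
#' @param params CA1 parameter list (ladder rates are taken from it).
#' @param t_end equilibration horizon per level (s).
#' @return effective Hill coefficient; attribute `scan` holds the
#'   dose-response table.
#' @export
ladder_hill_coefficient <- function(pkac_levels = c(1, 2, 5, 10, 20, 50,
                                                    100, 200),
                                    params = ca1_params(), t_end = 5000) {
  p <- params
  pre <- c("", "p", "pp", "ppp", "pppp")
  SP <- list(); RX <- list()
  SP[["PKAc"]] <- sig_species("PKAc", "cyt", 0, 0)
  for (i in 0:4)
    SP[[paste0(pre[i + 1], "R")]] <-
      sig_species(paste0(pre[i + 1], "R"), "cyt", 0, if (i == 0) 100 else 0)
  for (i in 0:3) {
    x <- paste0(pre[i + 1], "R"); xp <- paste0(pre[i + 2], "R")
    cplx <- paste0("PKAc", x)
    SP[[cplx]] <- sig_species(cplx, "cyt", 0, 0)
    kf_i <- p$pka_r_kf0 * p$pka_r_coop^i
    RX[[length(RX) + 1L]] <- sig_reaction(
      paste0(x, " + PKAc <-> ", cplx), kf_i, p$pka_r_kr, "PKAc")
    RX[[length(RX) + 1L]] <- sig_reaction(
      paste0(cplx, " -> ", xp, " + PKAc"), p$pka_r_kcat, tag = "PKAc")
    RX[[length(RX) + 1L]] <- sig_reaction(
      paste0(xp, " -> ", x), p$r_dephos, tag = "dephos")
  }
  m <- sig_model(do.call(rbind, SP), RX, name = "ladder-scan")
  sv <- single_volume()
  frac <- vapply(pkac_levels, function(lvl) {
    stim <- stim_program("clamp", baths = data.frame(
      species = "PKAc", on = 0, off = Inf, conc = lvl))
    cfg <- engine_config("deterministic", t_end = t_end,
                         sample_interval = t_end / 10)
    tr <- run_sim(m, sv, stim, cfg)
    nt <- length(tr$times)
    tot <- sum(tr$conc[grep("R$", m$species$name), 1, nt])
    tr$conc["ppppR", 1, nt] / tot
  }, 0)
  scan <- data.frame(pkac = pkac_levels, frac = frac)
  mid <- frac > 0.05 & frac < 0.95
  if (sum(mid) < 2) {
    # fall back to the two points bracketing the midpoint
    o <- order(abs(frac - 0.5))[1:2]
    mid <- seq_along(frac) %in% o
  }
  fit <- stats::lm(stats::qlogis(pmin(pmax(frac[mid], 1e-6), 1 - 1e-6)) ~
                     log(pkac_levels[mid]))
  hill <- unname(stats::coef(fit)[2])
  attr(hill, "scan") <- scan
  hill
}
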