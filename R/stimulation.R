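#' Parameters of the neurotransmitter (norepinephrine) release model
#'
#' Three-state synaptic resource model (recovered R, effective E, inactive
#' I, with R + E + I = 1) and a facilitating release probability u. The
#' default parameters are this package's fit-free defaults for
#' electrically evoked norepinephrine release (facilitation at short
#' inter-pulse intervals, depression under sustained drive).
#'
#' @param tau_r recovery time constant (s), I -> R.
#' @param tau_i inactivation time constant (s), E -> I.
#' @param tau_f facilitation decay time constant of u (s).
#' @param U_SE utilization increment per action potential (0, 1].
#' @param A_SE absolute synaptic efficacy (amplitude units).
#' @return a `release_params` list.
#' @export
release_params <- function(tau_r = 5, tau_i = 2, tau_f = 1,
                           U_SE = 0.25, A_SE = 1) {
  if (any(c(tau_r, tau_i, tau_f) <= 0)) stop("time constants must be > 0")
  if (U_SE <= 0 || U_SE > 1) stop("U_SE must be in (0, 1]")
  structure(list(tau_r = tau_r, tau_i = tau_i, tau_f = tau_f,
                 U_SE = U_SE, A_SE = A_SE), class = "release_params")
}

#' Norepinephrine release amplitudes for a spike train
#'
#' Integrates the three-state release model analytically between action
#' potentials (all relaxations are exponentials) and applies the jump
#' updates at each AP: first `u <- u + U_SE * (1 - u)`, then a fraction
#' `u * R` of recovered resources is released (transferred R -> E). The
#' per-AP release amplitude is `A_SE * E` immediately after the jump.
#'
#' @param params a [release_params()] object.
#' @param ap_times sorted action-potential times (s).
#' @return data.frame with one row per AP: `time`, `amplitude`, and the
#'   post-jump state variables `R`, `E`, `I`, `u`.
#' @export
ne_release <- function(params, ap_times) {
  stopifnot(inherits(params, "release_params"))
  if (is.unsorted(ap_times)) stop("ap_times must be sorted")
  n <- length(ap_times)
  out <- data.frame(time = ap_times, amplitude = numeric(n),
                    released = numeric(n), R = numeric(n),
                    E = numeric(n), I = numeric(n), u = numeric(n))
  if (n == 0L) return(out)
  R <- 1; E <- 0; u <- 0; t_prev <- ap_times[1]
  ti <- params$tau_i; tr <- params$tau_r
  if (abs(ti - tr) < 1e-12) ti <- ti * (1 + 1e-9)
  for (k in seq_len(n)) {
    dt <- ap_times[k] - t_prev
    if (dt > 0) {
      u <- u * exp(-dt / params$tau_f)
      E0 <- E; R0 <- R
      E <- E0 * exp(-dt / ti)
      a <- -E0 * ti / (ti - tr)
      cc <- R0 - 1 - a
      R <- 1 + a * exp(-dt / ti) + cc * exp(-dt / tr)
    }
    u <- u + params$U_SE * (1 - u)
    rel <- u * R
    R <- R - rel
    E <- E + rel
    out$amplitude[k] <- params$A_SE * E
    out$released[k] <- rel
    out$R[k] <- R; out$E[k] <- E; out$I[k] <- 1 - R - E; out$u[k] <- u
    t_prev <- ap_times[k]
  }
  out
}

#' Construct a stimulus program
#'
#' @param name protocol name.
#' @param injections data.frame with columns `time` (s), `species`, `target`
#'   (`"psd"`, `"spine_head"`, `"dend_focal"`, `"dend"`, `"all"`), `amount`
#'   (molecules at full scale) and `spine` (index or `NA`).
#' @param baths data.frame with columns `species`, `on`, `off` (s) and
#'   `conc` (nM); bath species are clamped at `conc` while active.
#' @param modifiers character vector of model modifiers (`"noPKA"`,
#'   `"epac8x"`).
#' @return a `stim_program`.
#' @export
stim_program <- function(name = "custom",
                         injections = empty_injections(),
                         baths = empty_baths(),
                         modifiers = character(0)) {
  stopifnot(all(c("time", "species", "target", "amount", "spine") %in%
                  names(injections)),
            all(c("species", "on", "off", "conc") %in% names(baths)))
  if (nrow(injections) && any(injections$amount < 0))
    stop("injection amounts must be >= 0")
  injections <- injections[order(injections$time), , drop = FALSE]
  structure(list(name = name, injections = injections, baths = baths,
                 modifiers = modifiers),
            class = "stim_program")
}

empty_injections <- function()
  data.frame(time = numeric(0), species = character(0), target = character(0),
             amount = numeric(0), spine = integer(0))

empty_baths <- function()
  data.frame(species = character(0), on = numeric(0), off = numeric(0),
             conc = numeric(0))

#' @export
print.stim_program <- function(x, ...) {
  cat("<stim_program> ", x$name, ": ", nrow(x$injections),
      " injection events, ", nrow(x$baths), " bath(s)", sep = "")
  if (length(x$modifiers)) cat(" [", paste(x$modifiers, collapse = ", "), "]",
                               sep = "")
  cat("\n")
  invisible(x)
}

# model-level protocol modifiers
apply_modifiers <- function(m, stim) {
  for (mod in stim$modifiers) {
    if (mod == "noPKA") {
      m <- scale_rates(m, "PKAc", kf_factor = 0)
    } else if (mod == "epac8x") {
      m <- scale_initials(m, c(Epac = 8))
    } else stop("unknown modifier: ", mod)
  }
  m
}

#' Calibration set for protocol construction
#'
#' @param ca_spine_amount molecules of calcium injected into the PSD for the
#'   first pulse of an HFS train (calibrated so peak free spine Ca is 10 uM).
#' @param ca_dend_amount molecules per dendritic pulse (peak free 2 uM).
#' @param spine_profile relative amplitudes of consecutive spine pulses
#'   within a 100 Hz train (first element 1).
#' @param ne_scale molecules of NE injected at the spine release site per
#'   unit release amplitude.
#' @param release release-model parameters.
#' @return a `calibration_set`.
#' @export
calibration_set <- function(ca_spine_amount = 730, ca_dend_amount = 800,
                            spine_profile = NULL, ne_scale = 300,
                            release = release_params()) {
  if (is.null(spine_profile)) {
    # per-pulse released fraction u*R at 100 Hz, normalized to the first pulse
    rel <- ne_release(release, seq(0, by = 0.01, length.out = 100))
    spine_profile <- rel$released / rel$released[1]
  }
  structure(list(ca_spine_amount = ca_spine_amount,
                 ca_dend_amount = ca_dend_amount,
                 spine_profile = spine_profile, ne_scale = ne_scale,
                 release = release),
            class = "calibration_set")
}

PROTOCOLS <- c("LFS", "ISO", "HFS", "4xHFS-3s", "ISO+HFS", "4xHFS-80s",
               "ISO+LFS")

#' Experimentally characterized protocol outcomes
#'
#' The outcome column used to calibrate signature thresholds: which of the
#' seven control protocols experimentally produce a long-lasting form of LTP
#' and which produce E-LTP.
#' @return data.frame (protocol, lltp, eltp).
#' @export
protocol_outcomes <- function() {
  data.frame(
    protocol = PROTOCOLS,
    lltp = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    eltp = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
}

#' Build the stimulus program for a named protocol
#'
#' Timing conventions: electrical stimulation starts at `onset` (default
#' 300 s, after equilibration). ISO protocols clamp 1 uM bath ISO starting
#' at 300 s with electrical stimulation 10 min later (900 s). Antagonist
#' variants apply the drug bath at 300 s with stimulation 200-250 s later.
#' HFS trains are 100 pulses at 100 Hz; spine pulse amplitudes within a
#' train follow the calibration profile, dendritic pulses are uniform; every
#' electrical pulse is accompanied by norepinephrine release at the spine
#' site. ISO+LFS increases calcium influx by 50% (PKA-enhanced NMDAR
#' conductance).
#'
#' @param name protocol name: one of `r paste(PROTOCOLS, collapse=", ")`,
#'   optionally with modifiers, e.g. `"4xHFS-80s+noPKA"`,
#'   `"Propranolol+4xHFS"`, `"ICI+4xHFS"`, `"Carvedilol+HFS"`,
#'   `"Carvedilol+2xHFS"`, `"Carvedilol+3xHFS"`, `"Carvedilol+LFS"`.
#' @param calib a [calibration_set()].
#' @param spines spine index/indices receiving the spine-targeted pulses.
#' @return a `stim_program`; attribute `t_end` gives the recommended
#'   simulation end time, attribute `stim_onset` the electrical onset.
#' @export
build_protocol <- function(name, calib = calibration_set(), spines = 1L) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  nopka <- "noPKA" %in% parts
  parts <- setdiff(parts, "noPKA")
  drug <- intersect(c("Propranolol", "ICI", "Carvedilol"), parts)
  parts <- setdiff(parts, drug)
  iso <- "ISO" %in% parts
  parts <- setdiff(parts, "ISO")
  elec <- if (length(parts)) parts else if (iso) "none" else
    stop("unknown protocol name: ", name)
  if (length(elec) != 1L ||
      !elec %in% c("none", "LFS", "HFS", "2xHFS", "3xHFS", "4xHFS-3s",
                   "4xHFS-80s", "4xHFS"))
    stop("unknown protocol name: ", name)

  onset <- 300
  baths <- empty_baths()
  if (iso) {
    baths <- rbind(baths, data.frame(species = "ISO", on = 300, off = Inf,
                                     conc = 1000))
    onset <- 900
  }
  if (length(drug)) {
    dsp <- c(Propranolol = "Prop", ICI = "ICI", Carvedilol = "Carv")[drug]
    dconc <- c(Propranolol = 1000, ICI = 100, Carvedilol = 10000)[drug]
    baths <- rbind(baths, data.frame(species = dsp, on = 300, off = Inf,
                                     conc = dconc))
    onset <- if (drug == "Carvedilol") 550 else 500
  }
  # the 50% calcium-influx increase with ISO reflects PKA phosphorylation
  # of NMDARs, so it is absent when PKA is blocked
  ca_scale <- if (iso && elec == "LFS" && !nopka) 1.5 else 1.0

  train_starts <- switch(elec,
                         none = numeric(0),
                         LFS = 0,
                         HFS = 0,
                         `2xHFS` = c(0, 80),
                         `3xHFS` = c(0, 80, 160),
                         `4xHFS` = ,
                         `4xHFS-80s` = c(0, 80, 160, 240),
                         `4xHFS-3s` = c(0, 4, 8, 12)) + onset
  inj <- empty_injections()
  rel_state_times <- numeric(0)
  for (ts in train_starts) {
    if (elec == "LFS") {
      pt <- ts + seq(0, by = 0.2, length.out = 900)
      amp <- rep(1, length(pt))     # all pulses equal the first HFS pulse
    } else {
      pt <- ts + seq(0, by = 0.01, length.out = 100)
      amp <- calib$spine_profile
    }
    rel_state_times <- c(rel_state_times, pt)
    for (s in spines)
      inj <- rbind(inj,
                   data.frame(time = pt, species = "Ca", target = "psd",
                              amount = calib$ca_spine_amount * amp * ca_scale,
                              spine = s, row.names = NULL))
    inj <- rbind(inj,
                 data.frame(time = pt, species = "Ca", target = "dend_focal",
                            amount = calib$ca_dend_amount * ca_scale,
                            spine = NA_integer_, row.names = NULL))
  }
  # NE co-release accompanies all electrical pulses (blocked only if the
  # release site itself were absent; antagonists act at the receptor)
  if (length(rel_state_times)) {
    rel <- ne_release(calib$release, sort(rel_state_times))
    ne_amt <- calib$ne_scale * rel$amplitude
    inj <- rbind(inj, data.frame(time = rel$time, species = "NE",
                                 target = "spine_head", amount = ne_amt,
                                 spine = spines[1], row.names = NULL))
  }
  modifiers <- if (nopka) "noPKA" else character(0)
  prog <- stim_program(name, inj, baths, modifiers)
  attr(prog, "stim_onset") <- onset
  # baseline window ends when the first stimulus (bath or electrical) starts
  attr(prog, "t_base") <- min(onset, if (nrow(baths)) min(baths$on) else Inf)
  attr(prog, "t_end") <- onset + 900
  prog
}

#' Calibrate calcium injection amounts
#'
#' Searches injection amounts such that the first HFS pulse produces a peak
#' free calcium concentration of `target_spine` in the spine head and
#' `target_dend` in the dendrite (deterministic mode, fine sampling around
#' the pulse).
#'
#' @param m a `sig_model`.
#' @param mesh mesh or compartments.
#' @param cfg engine configuration.
#' @param target_spine,target_dend peak free Ca targets (nM).
#' @param state optional pre-equilibrated state.
#' @param iterations secant iterations.
#' @return a [calibration_set()] with calibrated amounts; attributes
#'   `achieved_spine` and `achieved_dend` give the attained peaks (nM).
#' @export
calibrate_calcium <- function(m, mesh, cfg = engine_config(),
                              target_spine = 10000, target_dend = 2000,
                              state = NULL, iterations = 8) {
  sv <- as_subvolumes(mesh)
  if (is.null(state)) state <- equilibrate(m, mesh, cfg)$state
  peak <- function(a_sp, a_de) {
    stim <- stim_program("ca-cal", data.frame(
      time = c(0.02, 0.02), species = "Ca", target = c("psd", "dend_focal"),
      amount = c(a_sp, a_de), spine = c(1L, NA_integer_)))
    cfg2 <- cfg; cfg2$t_end <- 0.1; cfg2$sample_interval <- 5e-4
    tr <- run_sim(m, mesh, stim, cfg2, init = state)
    c(spine = max(species_trace(tr, "Ca", "spine")),
      dend = max(species_trace(tr, "Ca", "dendrite")))
  }
  a_sp <- target_spine * COUNT_PER_NM_UM3 *
    sum(sv$volume[grep("^head", sv$names)])
  a_de <- target_dend * COUNT_PER_NM_UM3 *
    sum(sv$volume[sv$names %in% c("dend_cyt", "dend_sub")])
  for (it in seq_len(iterations)) {
    pk <- peak(a_sp, a_de)
    if (pk["spine"] <= 0 || pk["dend"] <= 0)
      stop("calcium calibration failed to bracket targets (amounts ",
           a_sp, ", ", a_de, ")")
    a_sp <- a_sp * target_spine / pk["spine"]
    a_de <- a_de * target_dend / pk["dend"]
    if (abs(pk["spine"] / target_spine - 1) < 0.02 &&
        abs(pk["dend"] / target_dend - 1) < 0.02) break
  }
  pk <- peak(a_sp, a_de)
  out <- calibration_set(ca_spine_amount = unname(a_sp),
                         ca_dend_amount = unname(a_de))
  attr(out, "achieved_spine") <- unname(pk["spine"])
  attr(out, "achieved_dend") <- unname(pk["dend"])
  out
}

#' Calibrate antagonist Gi-coupling against isoproterenol
#'
#' Adjusts the Gi-binding rate of the carvedilol- and propranolol-bound
#' receptor so that, at steady state under the standard bath
#' concentrations, (i) Gi-bound receptor under 10 uM carvedilol is 1/3 of
#' that under 1 uM ISO and (ii) the ERK proxy (released Gi beta-gamma)
#' reaches 10% (propranolol) and ~30% (carvedilol) of the ISO level.
#'
#' @param m a `sig_model` built by [ca1_model()].
#' @param mesh mesh or compartments.
#' @param cfg engine configuration.
#' @param t_measure bath duration before measurement (s).
#' @return list with the retuned `model`, the achieved ratios, and the ISO
#'   reference levels.
#' @export
calibrate_antagonists <- function(m, mesh, cfg = engine_config(),
                                  t_measure = 900) {
  eq <- equilibrate(m, mesh, cfg)
  measure <- function(model, species, conc) {
    stim <- stim_program(paste0("bath-", species),
                         baths = data.frame(species = species, on = 0,
                                            off = Inf, conc = conc))
    cfg2 <- cfg; cfg2$t_end <- t_measure; cfg2$sample_interval <- 2
    tr <- run_sim(model, mesh, stim, cfg2, init = eq$state)
    nt <- length(tr$times)
    win <- tr$times > 0.8 * t_measure
    gib <- species_trace(tr, model$signatures$gi_bound_receptor)
    erk <- species_trace(tr, model$signatures$erk_proxy)
    c(gi_bound = mean(gib[win]), erk = mean(erk[win]))
  }
  iso <- measure(m, "ISO", 1000)
  if (iso["gi_bound"] <= 0) stop("no Gi recruitment under ISO; cannot calibrate")
  tune <- function(model, drug_tag, species, conc, target_ratio, field) {
    for (it in 1:3) {
      cur <- measure(model, species, conc)
      ratio <- cur[[field]] / iso[[field]]
      if (ratio <= 0) stop("antagonist calibration target unreachable: ",
                           species)
      if (abs(ratio / target_ratio - 1) < 0.05) break
      adj <- target_ratio / ratio
      model <- scale_rate_match(model, drug_tag, adj)
    }
    model
  }
  m <- tune(m, "CarvR + Gi", "Carv", 10000, 1 / 3, "gi_bound")
  m <- tune(m, "PropR + Gi", "Prop", 1000, 0.10, "erk")
  carv <- measure(m, "Carv", 10000)
  prop <- measure(m, "Prop", 1000)
  list(model = m,
       achieved = c(carv_gi_ratio = unname(carv["gi_bound"] / iso["gi_bound"]),
                    carv_erk_ratio = unname(carv["erk"] / iso["erk"]),
                    prop_erk_ratio = unname(prop["erk"] / iso["erk"])),
       iso = iso)
}

# multiply kf of the reaction whose equation starts with `prefix`
scale_rate_match <- function(m, prefix, factor) {
  hit <- FALSE
  for (i in seq_along(m$reactions)) {
    if (startsWith(m$reactions[[i]]$eq, prefix)) {
      m$reactions[[i]]$kf <- m$reactions[[i]]$kf * factor
      hit <- TRUE
    }
  }
  if (!hit) stop("no reaction matching: ", prefix)
  m
}
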