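#' Engine configuration
#'
#' @param mode `"deterministic"` (compartmental ODE), `"stochastic"`
#'   (fixed-timestep tau-leaping with binomially partitioned diffusion jumps)
#'   or `"ssa"` (exact Gillespie, intended for small oracle models).
#' @param timestep stochastic leap timestep (s). The full-scale default is
#'   2.9e-6 s; reduced-scale test models use coarser steps.
#' @param seed RNG seed for the stochastic modes.
#' @param sample_interval trajectory sampling interval (s).
#' @param equilibration equilibration time (s) used by [equilibrate()].
#' @param t_end simulation end time (s).
#' @param rtol,atol deterministic integrator tolerances.
#' @return an `engine_config` list.
#' @export
engine_config <- function(mode = c("deterministic", "stochastic", "ssa"),
                          timestep = 2.9e-6, seed = 1L,
                          sample_interval = 0.5, equilibration = 300,
                          t_end = 900, rtol = 1e-6, atol = 1e-4) {
  mode <- match.arg(mode)
  if (timestep <= 0) stop("timestep must be > 0")
  if (equilibration < 0) stop("equilibration must be >= 0")
  structure(list(mode = mode, timestep = timestep, seed = as.integer(seed),
                 sample_interval = sample_interval,
                 equilibration = equilibration, t_end = t_end,
                 rtol = rtol, atol = atol),
            class = "engine_config")
}

# Normalize a voxel_mesh or sig_compartments into the engine's subvolume form
as_subvolumes <- function(x) {
  if (inherits(x, "sig_compartments")) return(x)
  if (inherits(x, "voxel_mesh")) {
    v <- x$voxels
    regvol <- matrix(0, nrow(v), length(REGIONS),
                     dimnames = list(NULL, REGIONS))
    for (k in seq_len(nrow(v))) regvol[k, v$region[k]] <- v$volume[k]
    ex <- data.frame(i = x$couplings$i, j = x$couplings$j,
                     Ad = x$couplings$A / x$couplings$d)
    return(structure(list(names = paste0(v$region, v$id),
                          volume = v$volume, region_volume = regvol,
                          exchange = ex, spine = v$spine),
                     class = "sig_compartments"))
  }
  stop("expected a voxel_mesh or sig_compartments")
}

# initial concentration matrix [species x subvolume] (nM)
initial_conc <- function(m, sv) {
  nsp <- nrow(m$species); nc <- length(sv$names)
  C <- matrix(0, nsp, nc, dimnames = list(m$species$name, sv$names))
  for (i in seq_len(nsp)) {
    regs <- loc_regions(m$species$loc[i])
    frac <- rowSums(sv$region_volume[, regs, drop = FALSE]) / sv$volume
    C[i, ] <- m$species$init[i] * frac
  }
  C
}

# compiled channel structure shared by both engines
compile_channels <- function(m) {
  chan <- reaction_channels(m)
  i1 <- vapply(chan, function(ch) if (length(ch$re) >= 1L) ch$re[1] else 0L, 0L)
  i2 <- vapply(chan, function(ch) {
    if (length(ch$re) == 2L) ch$re[2]
    else if (length(ch$re) == 1L && ch$rs[1] == 2L) ch$re[1] else 0L
  }, 0L)
  k <- vapply(chan, `[[`, 0, "k")
  nsp <- nrow(m$species)
  Sel <- matrix(0, nsp, length(chan))
  for (j in seq_along(chan)) {
    ch <- chan[[j]]
    Sel[ch$re, j] <- Sel[ch$re, j] - ch$rs
    Sel[ch$pr, j] <- Sel[ch$pr, j] + ch$ps
  }
  ord <- (i1 > 0) + (i2 > 0)
  list(i1 = i1, i2 = i2, k = k, ord = ord, Sel = Sel, n = length(chan))
}

# resolve an injection target to subvolume indices
target_subvols <- function(sv, target, spine) {
  nm <- sv$names
  pick_spine <- function(idx) {
    if (!is.na(spine)) idx <- idx[sv$spine[idx] %in% spine]
    idx
  }
  idx <- switch(target,
    psd = {
      i <- which(sv$region_volume[, "psd"] > 0); pick_spine(i)
    },
    spine_head = pick_spine(which(sv$region_volume[, "spine_head"] > 0)),
    dend_focal = {
      i <- which(sv$region_volume[, "dend_cyt"] > 0)
      if (length(i) > 1L) i[ceiling(length(i) / 2)] else i
    },
    dend = which(rowSums(sv$region_volume[, c("dend_cyt", "dend_sub"),
                                          drop = FALSE]) > 0),
    all = seq_along(nm),
    stop("unknown injection target: ", target))
  if (!length(idx)) stop("injection target '", target, "' has no subvolumes")
  idx
}

#' Run a simulation
#'
#' Dispatches on `cfg$mode`: the deterministic compartmental mode integrates
#' mass-action ODEs with inter-compartment exchange (stiff LSODA); the
#' stochastic mode uses fixed-timestep tau-leaping with per-subvolume
#' reaction firing and binomially partitioned diffusion jumps (negative-count
#' excursions are handled by rejecting and subdividing the step); `"ssa"`
#' runs an exact Gillespie simulation for small oracle models.
#'
#' @param m a validated `sig_model`.
#' @param mesh a `voxel_mesh` or [compartments()] reduction.
#' @param stim a [stim_program()] or `NULL`.
#' @param cfg an [engine_config()].
#' @param init optional initial concentration matrix (species x subvolume),
#'   e.g. from [equilibrate()].
#' @return a `sig_trajectory`.
#' @export
run_sim <- function(m, mesh, stim = NULL, cfg = engine_config(),
                    init = NULL) {
  sv <- as_subvolumes(mesh)
  if (!is.null(stim)) {
    m <- apply_modifiers(m, stim)
    bad <- stim$injections$time > cfg$t_end
    if (any(bad)) stop(sum(bad), " stimulus events fall after t_end")
  }
  C0 <- if (is.null(init)) initial_conc(m, sv) else init
  switch(cfg$mode,
         deterministic = run_det(m, sv, stim, cfg, C0),
         stochastic = run_stoch(m, sv, stim, cfg, C0, exact = FALSE),
         ssa = run_stoch(m, sv, stim, cfg, C0, exact = TRUE))
}

#' @rdname run_sim
#' @param object,nsim,... [stats::simulate()] interface: runs `nsim`
#'   stochastic replicates with seeds `seed + 0:(nsim-1)`.
#' @param seed base seed.
#' @export
simulate.sig_model <- function(object, nsim = 1, seed = 1L, mesh,
                               stim = NULL, cfg = engine_config("stochastic"),
                               ...) {
  lapply(seq_len(nsim) - 1L, function(k) {
    cfg$seed <- as.integer(seed + k)
    run_sim(object, mesh, stim, cfg)
  })
}

# ---- deterministic engine ------------------------------------------------

run_det <- function(m, sv, stim, cfg, C0) {
  nsp <- nrow(m$species); nc <- length(sv$names)
  ch <- compile_channels(m)
  Dvec <- m$species$D
  diff_idx <- which(Dvec > 0)
  ex <- sv$exchange
  baths <- if (!is.null(stim)) stim$baths else NULL
  has_baths <- !is.null(baths) && nrow(baths) > 0
  bsp <- if (has_baths) match(baths$species, m$species$name) else integer(0)
  if (has_baths && anyNA(bsp)) stop("bath species not in model")
  i1 <- pmax(ch$i1, 1L); z1 <- ch$i1 == 0L
  i2 <- pmax(ch$i2, 1L); z2 <- ch$i2 == 0L
  kvec <- ch$k; Sel <- ch$Sel
  Vc <- sv$volume

  rhs <- function(t, y, p) {
    C <- matrix(pmax(y, 0), nsp, nc)
    F1 <- C[i1, , drop = FALSE]; F1[z1, ] <- 1
    F2 <- C[i2, , drop = FALSE]; F2[z2, ] <- 1
    rate <- kvec * F1 * F2
    dC <- Sel %*% rate
    if (length(diff_idx) && nrow(ex)) {
      Cd <- C[diff_idx, , drop = FALSE]
      for (e in seq_len(nrow(ex))) {
        i <- ex$i[e]; j <- ex$j[e]
        f <- Dvec[diff_idx] * ex$Ad[e] * (Cd[, i] - Cd[, j])
        dC[diff_idx, i] <- dC[diff_idx, i] - f / Vc[i]
        dC[diff_idx, j] <- dC[diff_idx, j] + f / Vc[j]
      }
    }
    if (has_baths) {
      act <- bsp[baths$on <= t & t < baths$off]
      if (length(act)) dC[act, ] <- 0
    }
    list(as.vector(dC))
  }

  times <- unique(sort(c(seq(0, cfg$t_end, by = cfg$sample_interval),
                         cfg$t_end)))
  ev <- build_events(m, sv, stim, nsp)
  y0 <- as.vector(C0)
  names(y0) <- paste0(rep(m$species$name, nc), ".",
                      rep(seq_len(nc), each = nsp))
  out <- deSolve::lsodes(y0, times, rhs, parms = NULL,
                         rtol = cfg$rtol, atol = cfg$atol, maxsteps = 50000,
                         events = if (!is.null(ev)) list(data = ev) else NULL)
  # deSolve merges event times into the output grid (duplicating rows at
  # coincident times); keep the post-event state at the requested samples
  out <- out[!duplicated(round(out[, 1], 9), fromLast = TRUE), , drop = FALSE]
  out <- out[round(out[, 1], 9) %in% round(times, 9), , drop = FALSE]
  tt <- out[, 1]
  conc <- array(t(out[, -1, drop = FALSE]), dim = c(nsp, nc, length(tt)),
                dimnames = list(m$species$name, sv$names, NULL))
  new_trajectory(tt, conc, m$species$name,
                 list(names = sv$names, volume = sv$volume,
                      spine = sv$spine),
                 meta = list(mode = "deterministic",
                             protocol = if (!is.null(stim)) stim$name,
                             timestep = NA_real_, seed = NA_integer_))
}

# deSolve events table: injections add concentration; bath on/off replace
build_events <- function(m, sv, stim, nsp) {
  if (is.null(stim)) return(NULL)
  rows <- list()
  state_index <- function(s, c) (c - 1L) * nsp + s
  inj <- stim$injections
  if (!is.null(inj) && nrow(inj)) {
    for (r in seq_len(nrow(inj))) {
      s <- match(inj$species[r], m$species$name)
      if (is.na(s)) stop("injection species not in model: ", inj$species[r])
      tg <- target_subvols(sv, inj$target[r], inj$spine[r])
      for (c in tg)
        rows[[length(rows) + 1L]] <- data.frame(
          var = state_index(s, c), time = inj$time[r],
          value = inj$amount[r] / length(tg) /
            (COUNT_PER_NM_UM3 * sv$volume[c]),
          method = "add")
    }
  }
  baths <- stim$baths
  if (!is.null(baths) && nrow(baths)) {
    for (r in seq_len(nrow(baths))) {
      s <- match(baths$species[r], m$species$name)
      for (c in seq_along(sv$names)) {
        rows[[length(rows) + 1L]] <- data.frame(
          var = state_index(s, c), time = baths$on[r],
          value = baths$conc[r], method = "replace")
      }
    }
  }
  if (!length(rows)) return(NULL)
  ev <- do.call(rbind, rows)
  ev[order(ev$time), ]
}

#' Equilibrate a model
#'
#' Runs the deterministic (or stochastic) engine with no stimulus for
#' `cfg$equilibration` seconds, checks for residual drift by comparing
#' windowed means over the last two 10% windows, and returns the final
#' state together with basal readouts.
#'
#' @param m a `sig_model`.
#' @param mesh a `voxel_mesh` or [compartments()] object.
#' @param cfg an [engine_config()].
#' @param drift_tol relative windowed-mean drift tolerance.
#' @return list with `state` (species x subvolume concentrations), `traj`,
#'   and `basal` (named basal concentrations incl. total cAMP).
#' @export
equilibrate <- function(m, mesh, cfg = engine_config(), drift_tol = 0.05) {
  cfg$t_end <- cfg$equilibration
  if (cfg$equilibration <= 0) {
    sv <- as_subvolumes(mesh)
    C0 <- initial_conc(m, sv)
    return(list(state = C0, traj = NULL, basal = rowMeans(C0)))
  }
  traj <- run_sim(m, mesh, stim = NULL, cfg = cfg)
  nt <- length(traj$times)
  w <- max(2L, floor(nt / 10))
  i1 <- (nt - 2L * w + 1L):(nt - w); i2 <- (nt - w + 1L):nt
  m1 <- apply(traj$conc[, , i1, drop = FALSE], 1, mean)
  m2 <- apply(traj$conc[, , i2, drop = FALSE], 1, mean)
  scale <- pmax(m1, 1e-3)
  drift <- abs(m2 - m1) / scale
  bad <- which(drift > drift_tol & pmax(m1, m2) > 0.1)
  if (length(bad))
    warning("drift detected during equilibration: ",
            paste(traj$species[bad], collapse = ", "))
  state <- traj$conc[, , nt]
  if (is.null(dim(state))) state <- matrix(state, ncol = 1)
  dimnames(state) <- dimnames(traj$conc)[1:2]
  basal <- c(cAMP = tail_trace(traj, "cAMP"),
             Ca = tail_trace(traj, "Ca"))
  list(state = state, traj = traj, basal = basal)
}

tail_trace <- function(traj, sp) {
  if (!sp %in% traj$species) return(NA_real_)
  y <- species_trace(traj, sp)
  mean(y[max(1, length(y) - 5):length(y)])
}

# ---- stochastic engine ---------------------------------------------------

run_stoch <- function(m, sv, stim, cfg, C0, exact = FALSE) {
  set.seed(cfg$seed)
  nsp <- nrow(m$species); nc <- length(sv$names)
  ch <- compile_channels(m)
  vf <- m$volume_factor
  Om <- COUNT_PER_NM_UM3 * sv$volume * vf
  N <- matrix(round(C0 * rep(Om, each = nsp)), nsp, nc)
  Dvec <- m$species$D
  diff_idx <- which(Dvec > 0)
  ex <- sv$exchange
  n_ex <- nrow(ex)
  # per-channel, per-subvolume rate prefactor
  kmat <- matrix(0, ch$n, nc)
  for (j in seq_len(ch$n)) {
    kmat[j, ] <- switch(ch$ord[j] + 1L,
                        ch$k[j] * Om,         # zeroth order
                        rep(ch$k[j], nc),     # first order
                        ch$k[j] / Om)         # second order
  }
  i1 <- pmax(ch$i1, 1L); z1 <- ch$i1 == 0L
  i2 <- pmax(ch$i2, 1L); z2 <- ch$i2 == 0L
  same <- ch$i1 == ch$i2 & ch$i1 > 0L
  Sel <- ch$Sel
  # diffusion jump rate per molecule, i->j and j->i
  if (n_ex) {
    rate_ij <- outer(Dvec[diff_idx], ex$Ad / (sv$volume[ex$i] * vf))
    rate_ji <- outer(Dvec[diff_idx], ex$Ad / (sv$volume[ex$j] * vf))
  }
  baths <- if (!is.null(stim)) stim$baths else NULL
  has_baths <- !is.null(baths) && nrow(baths) > 0
  bsp <- if (has_baths) match(baths$species, m$species$name) else integer(0)
  inj <- if (!is.null(stim)) stim$injections else NULL

  clamp <- function(N, t) {
    if (has_baths) {
      act <- which(baths$on <= t & t < baths$off)
      for (r in act) N[bsp[r], ] <- round(baths$conc[r] * Om)
    }
    N
  }
  propensity <- function(N) {
    F1 <- N[i1, , drop = FALSE]; F1[z1, ] <- 1
    F2 <- N[i2, , drop = FALSE]; F2[z2, ] <- 1
    F2[same, ] <- pmax(F2[same, , drop = FALSE] - 1, 0)
    kmat * F1 * F2
  }
  n_subdiv <- 0L

  leap <- function(N, dt, depth = 0L) {
    a <- propensity(N)
    fire <- matrix(rpois(length(a), a * dt), nrow(a), ncol(a))
    dN <- Sel %*% fire
    if (n_ex && length(diff_idx)) {
      Nd <- N[diff_idx, , drop = FALSE]
      for (e in seq_len(n_ex)) {
        p1 <- pmin(rate_ij[, e] * dt, 1)
        p2 <- pmin(rate_ji[, e] * dt, 1)
        m12 <- rbinom(length(diff_idx), Nd[, ex$i[e]], p1)
        m21 <- rbinom(length(diff_idx), Nd[, ex$j[e]], p2)
        dN[diff_idx, ex$i[e]] <- dN[diff_idx, ex$i[e]] - m12 + m21
        dN[diff_idx, ex$j[e]] <- dN[diff_idx, ex$j[e]] + m12 - m21
      }
    }
    Nn <- N + dN
    if (any(Nn < 0)) {
      if (depth >= 25L) stop("tau-leap step subdivision limit reached")
      n_subdiv <<- n_subdiv + 1L
      Nh <- leap(N, dt / 2, depth + 1L)
      return(leap(Nh, dt / 2, depth + 1L))
    }
    Nn
  }
  ssa_step_to <- function(N, t0, t1) {
    # exact simulation between t0 and t1 (reactions + diffusion jumps)
    t <- t0
    repeat {
      a <- propensity(N)
      arate <- as.vector(a)
      drate <- numeric(0)
      if (n_ex && length(diff_idx)) {
        Nd <- N[diff_idx, , drop = FALSE]
        drate <- c(as.vector(rate_ij * Nd[, ex$i, drop = FALSE]),
                   as.vector(rate_ji * Nd[, ex$j, drop = FALSE]))
      }
      tot <- sum(arate) + sum(drate)
      if (tot <= 0) return(list(N = N, t = t1))
      t <- t + rexp(1, tot)
      if (t >= t1) return(list(N = N, t = t1))
      pick <- sample.int(length(arate) + length(drate), 1,
                         prob = c(arate, drate))
      if (pick <= length(arate)) {
        jj <- (pick - 1L) %% ch$n + 1L
        cc <- (pick - 1L) %/% ch$n + 1L
        N[, cc] <- N[, cc] + Sel[, jj]
      } else {
        pick <- pick - length(arate)
        half <- length(diff_idx) * n_ex
        fwd <- pick <= half
        if (!fwd) pick <- pick - half
        srow <- (pick - 1L) %% length(diff_idx) + 1L
        e <- (pick - 1L) %/% length(diff_idx) + 1L
        s <- diff_idx[srow]
        from <- if (fwd) ex$i[e] else ex$j[e]
        to <- if (fwd) ex$j[e] else ex$i[e]
        N[s, from] <- N[s, from] - 1L; N[s, to] <- N[s, to] + 1L
      }
    }
  }

  sample_times <- unique(sort(c(seq(0, cfg$t_end, by = cfg$sample_interval),
                                cfg$t_end)))
  bounds <- sample_times
  if (!is.null(inj) && nrow(inj)) bounds <- c(bounds, inj$time)
  if (has_baths) bounds <- c(bounds, baths$on, baths$off)
  bounds <- unique(sort(bounds[bounds <= cfg$t_end]))
  conc <- array(NA_real_, c(nsp, nc, length(sample_times)))
  rec <- function(k, N) conc[, , k] <<- N / rep(Om, each = nsp)
  N <- clamp(N, 0)
  si <- 1L
  if (sample_times[1] == 0) { rec(1L, N); si <- 2L }
  t <- 0
  for (b in bounds[bounds > 0]) {
    while (t < b - 1e-12) {
      dt <- min(cfg$timestep, b - t)
      if (exact) {
        N <- ssa_step_to(N, t, t + dt)$N
      } else {
        N <- leap(N, dt)
      }
      t <- t + dt
      N <- clamp(N, t)
    }
    if (!is.null(inj) && nrow(inj)) {
      hit <- which(abs(inj$time - b) < 1e-12)
      for (r in hit) {
        s <- match(inj$species[r], m$species$name)
        tg <- target_subvols(sv, inj$target[r], inj$spine[r])
        for (c in tg)
          N[s, c] <- N[s, c] + rpois(1, inj$amount[r] * vf / length(tg))
      }
    }
    while (si <= length(sample_times) && sample_times[si] <= b + 1e-12) {
      rec(si, N); si <- si + 1L
    }
  }
  dimnames(conc) <- list(m$species$name, sv$names, NULL)
  new_trajectory(sample_times, conc, m$species$name,
                 list(names = sv$names, volume = sv$volume * vf,
                      spine = sv$spine),
                 meta = list(mode = if (exact) "ssa" else "stochastic",
                             protocol = if (!is.null(stim)) stim$name,
                             timestep = cfg$timestep, seed = cfg$seed,
                             volume_factor = vf, n_subdivisions = n_subdiv))
}
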