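#' Run a named stimulation protocol
#'
#' Convenience wrapper: builds the protocol program, extends the simulation
#' window to onset + 900 s, and runs the engine from a pre-equilibrated
#' state.
#'
#' @param m a `sig_model`.
#' @param mesh mesh or compartments.
#' @param name protocol name (see [build_protocol()]).
#' @param calib a [calibration_set()].
#' @param cfg an [engine_config()].
#' @param state optional equilibrated state matrix.
#' @param spines stimulated spine indices.
#' @return a `sig_trajectory` with attribute `t_on` (electrical onset, or
#'   bath onset for pure-bath protocols).
#' @export
run_protocol <- function(m, mesh, name, calib = calibration_set(),
                         cfg = engine_config(), state = NULL, spines = 1L) {
  prog <- build_protocol(name, calib, spines)
  cfg$t_end <- attr(prog, "t_end")
  if (is.null(state)) state <- equilibrate(m, mesh, cfg)$state
  if (length(prog$modifiers)) {
    # modifiers emulate pre-applied pharmacology: re-equilibrate the
    # modified model so baselines reflect the blocked steady state
    m_mod <- apply_modifiers(m, prog)
    cfg_pre <- cfg; cfg_pre$t_end <- 900; cfg_pre$sample_interval <- 50
    pre <- run_sim(m_mod, mesh, NULL, cfg_pre, init = state)
    state <- pre$conc[, , dim(pre$conc)[3]]
    if (is.null(dim(state))) state <- matrix(state, ncol = 1)
  }
  traj <- run_sim(m, mesh, prog, cfg, init = state)
  attr(traj, "t_on") <- attr(prog, "stim_onset")
  attr(traj, "t_base") <- attr(prog, "t_base")
  traj
}

#' Run the seven control protocols and calibrate norms and thresholds
#'
#' Deterministic (or reduced-scale stochastic) implementation of the
#' signature calibration: run all control protocols, compute component fold
#' traces per region, derive the normalization set (max over protocols of
#' trial-mean peak folds), and grid-search amplitude thresholds such that
#' exactly the protocols that experimentally produce long-lasting LTP
#' exceed the threshold for more than the duration threshold in both
#' regions (the spine threshold additionally keeps HFS above it).
#'
#' @param m a `sig_model`.
#' @param mesh mesh or compartments.
#' @param calib a [calibration_set()].
#' @param cfg an [engine_config()].
#' @param state equilibrated state (computed if missing).
#' @param n_trials trials per protocol (use >1 with stochastic engines;
#'   seeds increment from `cfg$seed`).
#' @param duration duration threshold (s).
#' @param mode duration mode for threshold calibration.
#' @return list with `norms`, `thresholds` (a [threshold_set()]), `sigs`
#'   (per protocol mean signature traces per region), `folds` (per protocol
#'   per trial component folds), `trajs` (trial 1 trajectories), `t_on` per
#'   protocol.
#' @export
control_suite <- function(m, mesh, calib = calibration_set(),
                          cfg = engine_config(), state = NULL,
                          n_trials = 1L, duration = 10, mode = "cumulative") {
  if (is.null(state)) state <- equilibrate(m, mesh, cfg)$state
  protocols <- PROTOCOLS
  folds_sp <- list(); folds_de <- list(); trajs <- list(); t_ons <- c()
  for (pr in protocols) {
    fs <- list(); fd <- list()
    for (tr in seq_len(n_trials)) {
      cfg_i <- cfg; cfg_i$seed <- cfg$seed + tr - 1L
      traj <- run_protocol(m, mesh, pr, calib, cfg_i, state = state)
      t_on <- attr(traj, "t_base")
      fs[[tr]] <- component_folds(traj, m, "spine", t_on)
      fd[[tr]] <- component_folds(traj, m, "dendrite", t_on)
      if (tr == 1L) { trajs[[pr]] <- traj; t_ons[pr] <- t_on }
    }
    folds_sp[[pr]] <- fs; folds_de[[pr]] <- fd
  }
  norms <- list(spine = compute_norms(folds_sp),
                dendrite = compute_norms(folds_de))
  mean_sig <- function(fl, nm) {
    traces <- lapply(fl, function(f) signature_trace(f, nm)$S)
    list(times = fl[[1]]$times, S = Reduce(`+`, traces) / length(traces))
  }
  sigs <- list(
    spine = lapply(folds_sp, mean_sig, nm = norms$spine),
    dendrite = lapply(folds_de, mean_sig, nm = norms$dendrite))
  out <- protocol_outcomes()
  lltp <- out$protocol[out$lltp]
  pampar <- vapply(protocols, function(pr)
    pampar_fold(trajs[[pr]], t_ons[[pr]]), 0)
  eltp_pos <- out$protocol[out$eltp]; eltp_neg <- setdiff(protocols, eltp_pos)
  lo_e <- max(pampar[eltp_neg]); hi_e <- min(pampar[eltp_pos])
  if (lo_e >= hi_e)
    warning("no feasible E-LTP pAMPAR threshold; using the boundary")
  eltp_th <- (lo_e + hi_e) / 2
  th_sp <- calibrate_threshold(sigs$spine,
                               positives = c(lltp, "HFS"),
                               negatives = c("LFS", "ISO"),
                               duration = duration, mode = mode)
  th_de <- calibrate_threshold(sigs$dendrite,
                               positives = lltp,
                               negatives = c("LFS", "ISO", "HFS"),
                               duration = duration, mode = mode)
  list(norms = norms,
       thresholds = threshold_set(th_sp, th_de, duration = duration,
                                  eltp = eltp_th),
       pampar = pampar,
       sigs = sigs, folds = list(spine = folds_sp, dendrite = folds_de),
       trajs = trajs, t_on = t_ons)
}
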