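#' Component fold-increase traces for the molecular signatures
#'
#' Extracts, for each signature component, the region-aggregated
#' concentration trace and converts it to a fold increase over the
#' pre-stimulus baseline, `fold(t) = (X(t) + eps) / (X(baseline) + eps)`.
#' The regularization keeps folds finite for components with near-zero
#' resting levels while preserving the identity that an unchanged
#' component has fold 1.
#'
#' @param traj a `sig_trajectory` from a protocol run.
#' @param m the `sig_model` (supplies `m$signatures` component sets).
#' @param region `"spine"` or `"dendrite"`.
#' @param t_on stimulus onset time (s); the baseline window is
#'   `[0, min(t_on, 30)]` -- the initial samples at the pre-stimulus
#'   equilibrium (model modifiers such as PKA block act from t = 0, so
#'   later pre-stimulus samples can already drift).
#' @param spine spine index for multi-spine meshes.
#' @param eps baseline floor (nM).
#' @return list with `times` and a named list `fold` of component series.
#' @export
component_folds <- function(traj, m, region = c("spine", "dendrite"),
                            t_on = 300, spine = NULL, eps = 1e-3) {
  region <- match.arg(region)
  comp_sets <- m$signatures[[if (region == "spine") "spine" else "dendrite"]]
  where <- if (region == "spine") "spine" else "dendrite"
  base_idx <- traj$times <= min(t_on, 30)
  if (!any(base_idx)) stop("no pre-stimulus samples before t_on")
  folds <- lapply(comp_sets, function(spp) {
    y <- species_trace(traj, spp, where, spine)
    b <- mean(y[base_idx])
    (y + eps) / (b + eps)
  })
  list(times = traj$times, fold = folds)
}

#' Normalization set from the control protocols
#'
#' For every component: per protocol, the mean over trials of the per-trial
#' peak fold; the normalization value is the maximum of these protocol means
#' over the seven control protocols.
#'
#' @param trial_folds nested list: `trial_folds[[protocol]][[trial]]` is a
#'   [component_folds()] result.
#' @return named numeric vector of `maxDelta` values per component, with
#'   attribute `per_protocol` (matrix protocol x component of trial-mean
#'   peaks).
#' @export
compute_norms <- function(trial_folds) {
  if (!length(trial_folds)) stop("empty trial set")
  comps <- names(trial_folds[[1]][[1]]$fold)
  res <- vapply(trial_folds, function(trials) {
    if (!length(trials)) stop("protocol with empty trial set")
    peaks <- vapply(trials, function(tr)
      vapply(tr$fold, max, 0)[comps], numeric(length(comps)))
    if (is.null(dim(peaks))) peaks <- matrix(peaks, nrow = length(comps))
    rowMeans(peaks)
  }, numeric(length(comps)))
  per_prot <- if (is.null(dim(res))) matrix(res, ncol = 1,
                                            dimnames = list(names(trial_folds)))
              else t(res)
  colnames(per_prot) <- comps
  norms <- apply(per_prot, 2, max)
  if (any(norms <= 0)) stop("non-positive normalization value")
  attr(norms, "per_protocol") <- per_prot
  norms
}

#' Combined molecular signature trace
#'
#' Sum of baseline-normalized component folds divided by their
#' normalization values: each term contributes 1 when the component reaches
#' the maximum (across control protocols) of its trial-mean peak fold.
#'
#' @param folds a [component_folds()] result.
#' @param norms normalization vector from [compute_norms()] for the same
#'   region.
#' @return list with `times` and `S` (signature trace).
#' @export
signature_trace <- function(folds, norms) {
  comps <- names(folds$fold)
  if (!length(comps)) stop("no signature components in folds")
  missing <- setdiff(comps, names(norms))
  if (length(missing)) stop("norms missing components: ",
                            paste(missing, collapse = ", "))
  S <- Reduce(`+`, lapply(comps, function(cc) folds$fold[[cc]] / norms[[cc]]))
  list(times = folds$times, S = S)
}

#' Spine molecular signature
#'
#' Three-term signature: normalized fold increases of phosphorylated
#' CaMKII, cAMP-bound Epac, and phosphorylated PKA targets in the spine.
#' @inheritParams component_folds
#' @param norms spine normalization vector.
#' @return list with `times` and `S`.
#' @export
spine_signature <- function(traj, m, norms, t_on = 300, spine = NULL)
  signature_trace(component_folds(traj, m, "spine", t_on, spine), norms)

#' Dendritic molecular signature
#'
#' Four-term signature: normalized fold increases of cAMP-bound Epac,
#' phosphorylated CaMKII, phosphorylated Inhibitor-1 + PDE4, and released
#' Gi beta-gamma (reporting beta2AR phosphorylation) in the dendrite.
#' @inheritParams component_folds
#' @param norms dendrite normalization vector.
#' @return list with `times` and `S`.
#' @export
dendrite_signature <- function(traj, m, norms, t_on = 300, spine = NULL)
  signature_trace(component_folds(traj, m, "dendrite", t_on, spine), norms)

#' Time spent above an amplitude threshold
#'
#' @param x signature values (uniformly sampled).
#' @param times sample times (s).
#' @param threshold amplitude threshold.
#' @param mode `"cumulative"` sums all supra-threshold time; `"uninterrupted"`
#'   returns the longest contiguous supra-threshold run.
#' @return duration in seconds.
#' @export
duration_above <- function(x, times, threshold,
                           mode = c("cumulative", "uninterrupted")) {
  mode <- match.arg(mode)
  if (!length(x)) stop("empty series")
  if (length(x) < 2L) return(0)
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop("duration_above requires uniform sampling")
  above <- x > threshold
  if (mode == "cumulative") return(sum(dt[above[-length(above)]]))
  r <- rle(above)
  runs <- r$lengths[r$values]
  if (!length(runs)) return(0)
  max(runs) * dt[1]
}

#' Calibrate signature amplitude thresholds
#'
#' Grid search over amplitude thresholds: a threshold is feasible when
#' every protocol that experimentally produces the outcome spends more than
#' the duration threshold above it, and every other protocol does not.
#' Returns the extremes of the feasible set.
#'
#' @param sigs named list protocol -> signature (list with `times`, `S`);
#'   for stochastic trial sets pass the per-trial mean trace or calibrate
#'   per trial.
#' @param positives,negatives protocol names required above / below.
#' @param duration duration threshold (s), default 10.
#' @param mode duration mode.
#' @param n_grid grid points between baseline and the global maximum.
#' @return numeric `c(lower, upper)` with attribute `feasible` (grid values)
#'   and `margins` per protocol; error if the feasible set is empty.
#' @export
calibrate_threshold <- function(sigs, positives, negatives, duration = 10,
                                mode = "cumulative", n_grid = 200) {
  stopifnot(all(positives %in% names(sigs)), all(negatives %in% names(sigs)))
  lo <- min(vapply(sigs, function(s) min(s$S), 0))
  hi <- max(vapply(sigs, function(s) max(s$S), 0))
  grid <- seq(lo, hi, length.out = n_grid)
  dur <- function(nm, th) duration_above(sigs[[nm]]$S, sigs[[nm]]$times,
                                         th, mode)
  ok <- vapply(grid, function(th) {
    all(vapply(positives, dur, 0, th = th) > duration) &&
      all(vapply(negatives, dur, 0, th = th) <= duration)
  }, TRUE)
  if (!any(ok)) {
    margins <- vapply(names(sigs), function(nm)
      max(vapply(grid, dur, 0, nm = nm)), 0)
    stop("empty feasible threshold interval; max durations: ",
         paste(names(sigs), round(margins, 1), sep = "=", collapse = ", "))
  }
  out <- c(lower = min(grid[ok]), upper = max(grid[ok]))
  attr(out, "feasible") <- grid[ok]
  out
}

#' Threshold set for classification
#'
#' @param spine,dendrite `c(lower, upper)` amplitude thresholds.
#' @param duration duration threshold (s).
#' @param eltp pAMPAR fold threshold for E-LTP.
#' @return a `threshold_set`.
#' @export
threshold_set <- function(spine, dendrite, duration = 10, eltp = 2) {
  stopifnot(spine[1] <= spine[2], dendrite[1] <= dendrite[2], duration > 0)
  structure(list(spine = unname(spine), dendrite = unname(dendrite),
                 duration = duration, eltp = eltp),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> spine [", signif(x$spine[1], 3), ",",
      signif(x$spine[2], 3), "], dendrite [", signif(x$dendrite[1], 3), ",",
      signif(x$dendrite[2], 3), "], duration >", x$duration,
      "s, E-LTP pAMPAR fold >", x$eltp, "\n")
  invisible(x)
}

#' Fold change of phosphorylated GluA1
#'
#' Peak of total phosphorylated GluA1 (S845, S831 and doubly phosphorylated
#' forms, including phosphatase-bound complexes) in the PSD relative to the
#' pre-stimulus steady state.
#'
#' @inheritParams component_folds
#' @return scalar fold change.
#' @export
pampar_fold <- function(traj, t_on = 300, spine = NULL) {
  forms <- c("pS845", "pS831", "pS845pS831",
             "pS845_PP1", "pS845_PP2BCaM", "pS831_PP1",
             "pS845pS831_PP1", "pS845pS831_PP2BCaM")
  forms <- intersect(forms, traj$species)
  if (!length(forms)) stop("no phosphorylated GluA1 traces in trajectory")
  y <- species_trace(traj, forms, "spine", spine)
  b <- mean(y[traj$times <= min(t_on, 30)])
  if (b <= 0) stop("zero baseline GluA1 phosphorylation")
  max(y) / b
}

#' Classify a protocol outcome
#'
#' L-LTP requires both the spine and the dendritic signature to stay above
#' their amplitude thresholds for longer than the duration threshold; E-LTP
#' requires the pAMPAR fold change to exceed its single threshold.
#'
#' @param spine_dur,dendrite_dur durations above threshold (s).
#' @param pampar pAMPAR fold change.
#' @param th a [threshold_set()].
#' @return one of `"no-change"`, `"E-LTP-only"`, `"L-LTP"`.
#' @export
classify_outcome <- function(spine_dur, dendrite_dur, pampar, th) {
  lltp <- spine_dur > th$duration && dendrite_dur > th$duration
  eltp <- pampar > th$eltp
  if (lltp) "L-LTP" else if (eltp) "E-LTP-only" else "no-change"
}

#' Full signature analysis of one protocol trajectory
#'
#' @param traj protocol trajectory (with `stim_onset` attribute or explicit
#'   `t_on`).
#' @param m model.
#' @param norms list with `spine` and `dendrite` normalization vectors.
#' @param th a [threshold_set()].
#' @param t_on stimulus onset (s).
#' @param spine spine index.
#' @param mode duration mode.
#' @return a `signature_result` with traces, durations (lower threshold),
#'   pAMPAR fold and classification.
#' @export
signature_result <- function(traj, m, norms, th, t_on = 300, spine = NULL,
                             mode = "cumulative") {
  ss <- spine_signature(traj, m, norms$spine, t_on, spine)
  ds <- dendrite_signature(traj, m, norms$dendrite, t_on, spine)
  sd <- duration_above(ss$S, ss$times, th$spine[1], mode)
  dd <- duration_above(ds$S, ds$times, th$dendrite[1], mode)
  sdu <- duration_above(ss$S, ss$times, th$spine[2], mode)
  ddu <- duration_above(ds$S, ds$times, th$dendrite[2], mode)
  pf <- pampar_fold(traj, t_on, spine)
  structure(list(spine = ss, dendrite = ds,
                 spine_dur = sd, dendrite_dur = dd,
                 spine_dur_upper = sdu, dendrite_dur_upper = ddu,
                 pampar_fold = pf,
                 outcome = classify_outcome(sd, dd, pf, th),
                 protocol = traj$meta$protocol),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result> ", x$protocol %||% "?", ": ", x$outcome, "\n",
      "  spine duration >lower/upper: ", round(x$spine_dur, 1), "/",
      round(x$spine_dur_upper, 1), " s; dendrite: ",
      round(x$dendrite_dur, 1), "/", round(x$dendrite_dur_upper, 1),
      " s; pAMPAR fold ", round(x$pampar_fold, 2), "\n", sep = "")
  invisible(x)
}

#' Trial statistics for duration-above-threshold tables
#'
#' Success counts (duration exceeding the duration threshold), mean and
#' standard error over trials, and a one-sided t-test of the durations
#' against the duration threshold.
#'
#' @param durations per-trial durations (s).
#' @param duration_threshold the threshold (s), default 10.
#' @return data.frame row: success, total, mean, sem, p.
#' @export
trial_stats <- function(durations, duration_threshold = 10) {
  n <- length(durations)
  mu <- mean(durations)
  se <- if (n > 1) stats::sd(durations) / sqrt(n) else NA_real_
  p <- if (n > 1 && stats::sd(durations) > 0)
    stats::t.test(durations, mu = duration_threshold,
                  alternative = "greater")$p.value
  else NA_real_
  data.frame(success = sum(durations > duration_threshold), total = n,
             mean = mu, sem = se, p = p)
}
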