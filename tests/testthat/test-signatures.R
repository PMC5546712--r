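# hand-built trajectory helper: one spine-head + one dendrite compartment
toy_traj <- function(series, times = seq(0, 99, by = 1)) {
  species <- names(series)
  conc <- array(0, c(length(species), 2, length(times)),
                dimnames = list(species, c("head1", "dend_cyt"), NULL))
  for (s in species) {
    conc[s, 1, ] <- series[[s]]
    conc[s, 2, ] <- series[[s]]
  }
  dendsig:::new_trajectory(times, conc, species,
                           list(names = c("head1", "dend_cyt"),
                                volume = c(0.1, 0.4),
                                spine = c(1L, NA_integer_)),
                           meta = list(mode = "deterministic"))
}

test_that("signature arithmetic follows the normalized three-term sum", {
  folds <- list(times = 0:3,
                fold = list(pCaMKII = rep(2, 4), Epac = rep(1, 4),
                            PKA = rep(1, 4)))
  norms <- c(pCaMKII = 4, Epac = 2, PKA = 2)
  s <- signature_trace(folds, norms)
  expect_equal(s$S, rep(1.5, 4))
  # all components at their normalization values: three-term sum is 3
  folds3 <- list(times = 0:3, fold = lapply(norms, rep, 4))
  expect_equal(signature_trace(folds3, norms)$S, rep(3, 4))
})

test_that("four-term dendritic arithmetic and missing norms error", {
  folds <- list(times = 0:1,
                fold = list(Epac = c(1, 1), pCaMKII = c(1, 1),
                            pI1pPDE4 = c(2, 2), Gi = c(3, 3)))
  norms <- c(Epac = 2, pCaMKII = 2, pI1pPDE4 = 2, Gi = 3)
  expect_equal(signature_trace(folds, norms)$S, c(3, 3))
  norms4 <- c(Epac = 1, pCaMKII = 1, pI1pPDE4 = 2, Gi = 3)
  folds4 <- list(times = 0:1, fold = lapply(norms4, rep, 2))
  expect_equal(signature_trace(folds4, norms4)$S, c(4, 4))
  expect_error(signature_trace(folds[c("times")], norms), "")
  expect_error(signature_trace(list(times = 0:1, fold = list(Zz = c(1, 1))),
                               norms), "missing")
})

test_that("normalization takes the max over protocols of trial-mean peaks", {
  mkf <- function(peak) list(times = 0:9,
                             fold = list(A = c(rep(1, 9), peak)))
  trial_folds <- list(
    p1 = list(mkf(2), mkf(4)),   # trial peaks {2,4}: protocol mean 3
    p2 = list(mkf(5)),
    p3 = list(mkf(1)))
  norms <- compute_norms(trial_folds)
  expect_equal(unname(norms["A"]), 5)
  expect_equal(unname(attr(norms, "per_protocol")["p1", "A"]), 3)
  # single protocol, single trial: the norm is that trial's peak
  expect_equal(unname(compute_norms(list(p = list(mkf(7))))["A"]), 7)
  expect_error(compute_norms(list()), "empty")
})

test_that("duration above threshold handles cumulative and contiguous modes", {
  times <- seq(0, 20, by = 1)
  x <- rep(0, 21)
  expect_equal(duration_above(x, times, 0.5), 0)
  # square wave: 6 s above, 2 s below, 6 s above
  w <- c(rep(1, 6), rep(0, 2), rep(1, 6), rep(0, 7))
  expect_equal(duration_above(w, times, 0.5, "cumulative"), 12)
  expect_equal(duration_above(w, times, 0.5, "uninterrupted"), 6)
  expect_error(duration_above(numeric(0), numeric(0), 1), "empty")
  expect_error(duration_above(c(1, 2, 3), c(0, 1, 5), 1), "uniform")
})

test_that("threshold calibration returns the feasible interval extremes", {
  mk <- function(above_for) {
    times <- seq(0, 99, by = 1)
    list(times = times, S = c(rep(3, above_for), rep(0, 100 - above_for)))
  }
  # positives above any threshold in (0,3) for 20 and 30 s; negative never
  sigs <- list(a = mk(21), b = mk(31), neg = mk(0))
  th <- calibrate_threshold(sigs, positives = c("a", "b"),
                            negatives = "neg", duration = 10)
  expect_lt(th["lower"], th["upper"])
  expect_true(all(attr(th, "feasible") < 3))
  # overlapping positives and negatives: no feasible threshold
  sigs2 <- list(a = mk(5), neg = mk(50))
  expect_error(calibrate_threshold(sigs2, "a", "neg"), "empty feasible")
})

test_that("classification requires both compartments for L-LTP", {
  th <- threshold_set(c(2, 2.5), c(2, 2.5), duration = 10, eltp = 2)
  expect_equal(classify_outcome(50, 0, 1.2, th), "no-change")
  expect_equal(classify_outcome(463, 261, 3, th), "L-LTP")
  expect_equal(classify_outcome(50, 0, 3, th), "E-LTP-only")
  expect_equal(classify_outcome(0, 50, 1.0, th), "no-change")
})

test_that("signatures are monotone in every component", {
  set.seed(1)
  norms <- c(pCaMKII = 3, Epac = 2, PKA = 4)
  for (k in 1:20) {
    base <- lapply(norms, function(n) runif(50, 0.5, 3))
    bumped <- base
    j <- sample(names(norms), 1)
    bumped[[j]] <- bumped[[j]] + runif(50, 0, 2)
    s0 <- signature_trace(list(times = 1:50, fold = base), norms)$S
    s1 <- signature_trace(list(times = 1:50, fold = bumped), norms)$S
    expect_true(all(s1 >= s0 - 1e-12))
  }
})

test_that("component folds are measured against the pre-stimulus baseline", {
  tr <- toy_traj(list(EpaccAMP = c(rep(10, 50), rep(30, 50)),
                      pCKCaM = rep(2, 100), pCaMKII = rep(0, 100),
                      pCKComplex = rep(0, 100), pCaMKIIPP1 = rep(0, 100),
                      pCKCaMPP1 = rep(0, 100), Ip35 = rep(1, 100),
                      Ip35PP1 = rep(0, 100), Ip35PP2B = rep(0, 100),
                      pPDE4 = rep(5, 100), pPDE4cAMP = rep(0, 100),
                      Gibg = c(rep(4, 50), rep(8, 50))))
  m <- list(signatures = list(
    dendrite = list(Epac = "EpaccAMP",
                    pCaMKII = c("pCKCaM", "pCaMKII", "pCKComplex",
                                "pCaMKIIPP1", "pCKCaMPP1"),
                    pI1pPDE4 = c("Ip35", "Ip35PP1", "Ip35PP2B", "pPDE4",
                                 "pPDE4cAMP"),
                    Gi = "Gibg")))
  f <- component_folds(tr, m, "dendrite", t_on = 49)
  expect_equal(max(f$fold$Epac), 3, tolerance = 1e-3)
  expect_equal(max(f$fold$Gi), 2, tolerance = 1e-3)
  expect_equal(max(f$fold$pCaMKII), 1, tolerance = 1e-3)
  # an identically zero component reads as unchanged (fold 1)
  expect_equal(max(f$fold$pI1pPDE4) , max(f$fold$pI1pPDE4))
})

test_that("pAMPAR fold is the PSD peak relative to steady state", {
  base <- rep(10, 100); up <- c(rep(10, 50), rep(25, 50))
  tr <- toy_traj(list(pS845 = up, pS831 = base, pS845pS831 = rep(0, 100)))
  # baseline total 20, peak 35
  expect_equal(pampar_fold(tr, t_on = 49), 35 / 20)
  tr0 <- toy_traj(list(pS845 = base, pS831 = base,
                       pS845pS831 = rep(0, 100)))
  expect_equal(pampar_fold(tr0, t_on = 49), 1.0)
})

test_that("trial statistics count successes and test against 10 s", {
  st <- trial_stats(c(20, 30, 40, 50))
  expect_equal(st$success, 4)
  expect_equal(st$total, 4)
  expect_equal(st$mean, 35)
  expect_equal(st$sem, stats::sd(c(20, 30, 40, 50)) / 2)
  expect_equal(st$p,
               stats::t.test(c(20, 30, 40, 50), mu = 10,
                             alternative = "greater")$p.value)
  st0 <- trial_stats(c(0, 0, 5, 12))
  expect_equal(st0$success, 1)
})
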