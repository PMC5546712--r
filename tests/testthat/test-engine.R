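test_that("deterministic birth-death relaxes along the closed form", {
  fx <- make_fixture("birth-death", list(k1 = 10, k2 = 0.5, x0 = 2))
  tr <- run_fixture_det(fx, t_end = 20, sample = 0.25)
  o <- fx$oracle()
  expect_equal(as.vector(tr$conc["X", 1, ]), o$traj(tr$times),
               tolerance = 1e-4)
})

test_that("stochastic birth-death reproduces the Poisson stationary law", {
  fx <- make_fixture("birth-death", list(k1 = 10, k2 = 1, x0 = 10))
  cfg <- engine_config("stochastic", timestep = 0.02, seed = 7,
                       sample_interval = 0.5, t_end = 2000)
  tr <- run_sim(fx$model, fx$mesh, cfg = cfg)
  x <- as.vector(tr$conc["X", 1, tr$times > 100])
  o <- fx$oracle()
  n <- length(x)
  neff <- n / 10  # autocorrelation-adjusted effective sample size
  expect_lt(abs(mean(x) - o$mean), 3 * sqrt(o$var / neff))
  expect_lt(abs(var(x) - o$var), 3 * o$var * sqrt(2 / neff))
})

test_that("the exact SSA agrees with the analytic stationary distribution", {
  fx <- make_fixture("birth-death", list(k1 = 5, k2 = 1, x0 = 5))
  cfg <- engine_config("ssa", timestep = 1, seed = 11,
                       sample_interval = 0.5, t_end = 800)
  tr <- run_sim(fx$model, fx$mesh, cfg = cfg)
  x <- as.vector(tr$conc["X", 1, tr$times > 50])
  neff <- length(x) / 10
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / neff))
})

test_that("a model with no reactions and no stimulus stays constant", {
  m <- sig_model(sig_species("X", "cyt", D = 2, init = 50),
                 list(sig_reaction("X -> X", 0)))
  comp <- compartments(build_mesh(geometry_spec(), 0.25))
  trd <- run_sim(m, comp, cfg = engine_config("deterministic", t_end = 10,
                                              sample_interval = 1))
  expect_lt(max(abs(trd$conc["X", , ] - 50)), 1e-8)
  trs <- run_sim(m, comp, cfg = engine_config("stochastic", timestep = 0.01,
                                              t_end = 5, seed = 3,
                                              sample_interval = 1))
  mol <- apply(trs$conc["X", , ], 2, function(cc)
    sum(cc * trs$comp$volume))
  expect_equal(max(mol), min(mol), tolerance = 1e-9)  # reflective boundary
})

test_that("seed determinism gives bit-identical stochastic trajectories", {
  fx <- make_fixture("reversible-binding")
  cfg <- engine_config("stochastic", timestep = 0.005, seed = 99,
                       sample_interval = 0.5, t_end = 20)
  t1 <- run_sim(fx$model, fx$mesh, cfg = cfg)
  t2 <- run_sim(fx$model, fx$mesh, cfg = cfg)
  expect_identical(t1$conc, t2$conc)
  cfg$seed <- 100L
  t3 <- run_sim(fx$model, fx$mesh, cfg = cfg)
  expect_false(identical(t1$conc, t3$conc))
})

test_that("stochastic runs conserve moieties exactly", {
  fx <- make_fixture("reversible-binding", list(a0 = 50, b0 = 30))
  cfg <- engine_config("stochastic", timestep = 0.005, seed = 5,
                       sample_interval = 0.2, t_end = 30)
  tr <- run_sim(fx$model, fx$mesh, cfg = cfg)
  a_tot <- tr$conc["A", 1, ] + tr$conc["C", 1, ]
  b_tot <- tr$conc["B", 1, ] + tr$conc["C", 1, ]
  expect_equal(max(a_tot), min(a_tot), tolerance = 1e-12)
  expect_equal(max(b_tot), min(b_tot), tolerance = 1e-12)
})

test_that("reversible binding equilibrates at the quadratic closed form", {
  fx <- make_fixture("reversible-binding", list(a0 = 120, b0 = 80,
                                                kf = 0.02, kr = 0.8))
  o <- fx$oracle()
  tr <- run_fixture_det(fx, t_end = 50)
  nt <- dim(tr$conc)[3]
  expect_equal(tr$conc["C", 1, nt], o$C, tolerance = 1e-5)
  expect_equal(tr$conc["A", 1, nt], o$A, tolerance = 1e-5)
  # equilibrate() reports the same state
  eq <- equilibrate(fx$model, fx$mesh,
                    engine_config("deterministic", equilibration = 50,
                                  sample_interval = 1))
  expect_equal(unname(eq$state["C", 1]), o$C, tolerance = 1e-4)
})

test_that("enzyme cycle reaches its steady state", {
  fx <- make_fixture("enzyme-cycle")
  o <- fx$oracle()
  tr <- run_fixture_det(fx, t_end = 200)
  nt <- dim(tr$conc)[3]
  for (s in c("E", "ES", "S", "P"))
    expect_equal(unname(tr$conc[s, 1, nt]), o[[s]], tolerance = 1e-4)
})

test_that("stochastic mean matches deterministic mode on a reduced model", {
  # reversible binding at reduced scale: mean over seeds vs ODE
  fx <- make_fixture("reversible-binding", list(a0 = 200, b0 = 150,
                                                kf = 0.005, kr = 0.5))
  o <- fx$oracle()
  n_seeds <- 32
  finals <- vapply(seq_len(n_seeds), function(s) {
    cfg <- engine_config("stochastic", timestep = 0.01, seed = s,
                         sample_interval = 5, t_end = 40)
    tr <- run_sim(fx$model, fx$mesh, cfg = cfg)
    mean(tr$conc["C", 1, tr$times >= 20])
  }, 0)
  se <- stats::sd(finals) / sqrt(n_seeds)
  expect_lt(abs(mean(finals) - o$C), 3 * se + 1e-9)
})

test_that("volume scaling shrinks counts but not concentration dynamics", {
  fx <- make_fixture("birth-death", list(k1 = 20, k2 = 1, x0 = 20))
  # deterministic trace invariant under volume_factor
  tr1 <- run_fixture_det(fx, t_end = 10)
  fx$model <- scale_model(fx$model, 0.1)
  tr2 <- run_fixture_det(fx, t_end = 10)
  expect_equal(tr1$conc, tr2$conc, tolerance = 1e-10)
  # stochastic: stationary mean count scales, CV grows as 1/sqrt(count)
  run_cv <- function(vf, seed) {
    m <- scale_model(make_fixture("birth-death",
                                  list(k1 = 20, k2 = 1, x0 = 20))$model, vf)
    cfg <- engine_config("stochastic", timestep = 0.02, seed = seed,
                         sample_interval = 0.5, t_end = 1500)
    tr <- run_sim(m, single_volume(), cfg = cfg)
    x <- tr$conc["X", 1, tr$times > 100] * 0.602214076 *
      tr$comp$volume  # counts
    c(mean = mean(x), cv = stats::sd(x) / mean(x))
  }
  full <- run_cv(1, 21); tenth <- run_cv(0.1, 22)
  expect_equal(unname(tenth["mean"] / full["mean"]), 0.1, tolerance = 0.15)
  expect_equal(unname(tenth["cv"] / full["cv"]), sqrt(10), tolerance = 0.35)
})

test_that("tau-leap rejects and subdivides negative-count excursions", {
  # aggressive timestep forces candidate negatives; counts must stay >= 0
  fx <- make_fixture("reversible-binding", list(a0 = 5, b0 = 5,
                                                kf = 0.5, kr = 10))
  cfg <- engine_config("stochastic", timestep = 0.5, seed = 1,
                       sample_interval = 1, t_end = 50)
  tr <- run_sim(fx$model, fx$mesh, cfg = cfg)
  expect_true(all(tr$conc >= 0))
  expect_gt(tr$meta$n_subdivisions, 0)
})

test_that("the distributive four-site ladder matches its linear-solve oracle", {
  fx <- make_fixture("distributive-4site",
                     list(x0 = 200, kin = 10, kdeph = 0.02))
  tr <- run_fixture_det(fx, t_end = 2000, sample = 20)
  nt <- dim(tr$conc)[3]
  got <- tr$conc[paste0("X", 0:4), 1, nt]
  expect_equal(unname(got), unname(fx$oracle(10)), tolerance = 1e-3)
})
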