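test_that("release model conserves R+E+I and handles trivial trains", {
  p <- release_params()
  expect_equal(nrow(ne_release(p, numeric(0))), 0)

  # single AP from rest: released fraction U_SE, amplitude A_SE * U_SE
  one <- ne_release(p, 0)
  expect_equal(one$amplitude, p$A_SE * p$U_SE, tolerance = 1e-12)
  expect_equal(one$E, p$U_SE, tolerance = 1e-12)

  # R + E + I = 1 to machine precision along random trains
  set.seed(42)
  for (rep in 1:5) {
    ap <- cumsum(rexp(50, rate = 5))
    out <- ne_release(p, ap)
    expect_lt(max(abs(out$R + out$E + out$I - 1)), 1e-12)
    expect_true(all(out$u >= 0 & out$u <= 1))
  }
  expect_error(ne_release(p, c(2, 1)), "sorted")
  expect_error(release_params(U_SE = 1.5), "U_SE")
})

test_that("analytic inter-AP integration matches a brute-force integrator", {
  p <- release_params(tau_r = 3, tau_i = 1.5, tau_f = 0.8, U_SE = 0.3)
  ap <- c(0, 0.25, 0.6, 1.4, 1.45, 3.0)
  exact <- ne_release(p, ap)
  brute <- brute_release(p, ap, dt = 2e-6)
  expect_lt(max(abs(exact$amplitude - brute$amplitude) /
                  pmax(brute$amplitude, 1e-12)), 1e-3)
})

test_that("facilitation and depression emerge from the release model", {
  # long facilitation, slow utilization: successive u non-decreasing
  p <- release_params(tau_f = 10, U_SE = 0.1)
  out <- ne_release(p, seq(0, 0.9, by = 0.1))
  expect_true(all(diff(out$u) >= -1e-12))
  # strong utilization depletes R: amplitudes eventually decrease
  p2 <- release_params(tau_r = 20, tau_f = 5, U_SE = 0.8)
  out2 <- ne_release(p2, seq(0, 0.9, by = 0.1))
  expect_lt(out2$amplitude[10], max(out2$amplitude))
  expect_true(all(diff(out2$R) <= 1e-12) || out2$R[10] < out2$R[1])
})

test_that("protocol programs implement the standard train structures", {
  calib <- calibration_set()
  # 4xHFS-80s: 400 spine calcium events in 4 blocks with 80 s between starts
  p80 <- build_protocol("4xHFS-80s", calib)
  ca_sp <- subset(p80$injections, species == "Ca" & target == "psd")
  expect_equal(nrow(ca_sp), 400)
  starts <- sort(unique(round(ca_sp$time - (ca_sp$time - 300) %% 100)))
  expect_equal(sort(unique(floor((ca_sp$time - 300) / 80))), 0:3)
  expect_equal(min(ca_sp$time), 300)

  # ISO: a single bath producing 1 uM, no calcium events
  piso <- build_protocol("ISO", calib)
  expect_equal(nrow(subset(piso$injections, species == "Ca")), 0)
  expect_equal(piso$baths$species, "ISO")
  expect_equal(piso$baths$conc, 1000)
  expect_equal(piso$baths$on, 300)

  # LFS: 900 spine pulses over 180 s, all of equal amplitude (first HFS pulse)
  plfs <- build_protocol("LFS", calib)
  lfs_sp <- subset(plfs$injections, species == "Ca" & target == "psd")
  expect_equal(nrow(lfs_sp), 900)
  expect_equal(max(lfs_sp$time) - min(lfs_sp$time), 179.8)
  expect_equal(unique(lfs_sp$amount), calib$ca_spine_amount)

  # dendritic pulses are uniform within a train; spine pulses follow the
  # release-probability profile
  hfs <- build_protocol("HFS", calib)
  de <- subset(hfs$injections, species == "Ca" & target == "dend_focal")
  expect_equal(length(unique(de$amount)), 1)
  sp <- subset(hfs$injections, species == "Ca" & target == "psd")
  expect_equal(sp$amount / calib$ca_spine_amount, calib$spine_profile,
               tolerance = 1e-9)

  # ISO+HFS: bath 10 minutes before the electrical onset
  pih <- build_protocol("ISO+HFS", calib)
  expect_equal(attr(pih, "stim_onset") - pih$baths$on, 600)

  # ISO+LFS increases calcium influx by 50%, but not under PKA block
  pil <- build_protocol("ISO+LFS", calib)
  expect_equal(unique(subset(pil$injections, target == "psd")$amount),
               1.5 * calib$ca_spine_amount)
  piln <- build_protocol("ISO+LFS+noPKA", calib)
  expect_equal(unique(subset(piln$injections, target == "psd")$amount),
               calib$ca_spine_amount)

  # NE co-release accompanies every electrical pulse
  ne <- subset(hfs$injections, species == "NE")
  expect_equal(nrow(ne), 100)

  expect_error(build_protocol("8xHFS", calib), "unknown protocol")
})

test_that("drug baths use the standard concentrations", {
  calib <- calibration_set()
  for (cs in list(c("Propranolol+4xHFS", "Prop", 1000),
                  c("ICI+4xHFS", "ICI", 100),
                  c("Carvedilol+2xHFS", "Carv", 10000))) {
    p <- build_protocol(cs[1], calib)
    expect_equal(p$baths$species, cs[2])
    expect_equal(p$baths$conc, as.numeric(cs[3]))
  }
  p2 <- build_protocol("Carvedilol+2xHFS", calib)
  ca2 <- subset(p2$injections, species == "Ca" & target == "psd")
  expect_equal(nrow(ca2), 200)
})

test_that("PKA-block modifier zeroes catalytic-subunit rates only", {
  m <- ca1_model()
  prog <- build_protocol("HFS+noPKA", calibration_set())
  expect_equal(prog$modifiers, "noPKA")
  m2 <- dendsig:::apply_modifiers(m, prog)
  tags <- vapply(m2$reactions, `[[`, "", "tag")
  kfs <- vapply(m2$reactions, `[[`, 0, "kf")
  expect_true(all(kfs[tags == "PKAc"] == 0))
  expect_true(all(kfs[tags == "PKA"] > 0))  # holoenzyme cycle preserved
})

test_that("Epac over-expression modifier multiplies initial Epac by 8", {
  m <- ca1_model()
  stim <- stim_program("epac", modifiers = "epac8x")
  m2 <- dendsig:::apply_modifiers(m, stim)
  i <- match("Epac", m2$species$name)
  expect_equal(m2$species$init[i], 8 * m$species$init[i])
})
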