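test_that("reaction equations parse with stoichiometry and direction", {
  r <- sig_reaction("A + B <-> C", kf = 2, kr = 1)
  expect_equal(r$reactants, c(A = 1L, B = 1L))
  expect_equal(r$products, c(C = 1L))
  expect_true(r$reversible)

  r2 <- sig_reaction("2 X -> D", kf = 0.1)
  expect_equal(r2$reactants, c(X = 2L))
  expect_false(r2$reversible)

  r3 <- sig_reaction(" -> Ca", kf = 5)
  expect_length(r3$reactants, 0)

  expect_error(sig_reaction("A + B + C -> D", kf = 1), "order")
  expect_error(sig_reaction("A -> B", kf = 1, kr = 2), "kr")
  expect_error(sig_reaction("A -> B", kf = -1), "negative")
})

test_that("models reject unknown species and duplicated names", {
  sp <- rbind(sig_species("A"), sig_species("B"))
  expect_error(sig_model(sp, list(sig_reaction("A -> C", 1))), "unknown")
  expect_error(sig_model(rbind(sig_species("A"), sig_species("A")),
                         list()), "duplicated")
  expect_error(sig_species("X", loc = "psd", D = 5), "zero diffusion")
})

test_that("declared moieties are checked against the stoichiometry", {
  sp <- rbind(sig_species("A", init = 10), sig_species("B", init = 5),
              sig_species("C"))
  ok <- sig_model(sp, list(sig_reaction("A + B <-> C", 1, 1)),
                  moieties = list(A = c(A = 1, C = 1), B = c(B = 1, C = 1)))
  rep <- validate_model(ok)
  expect_true(rep$pass)

  # a reaction creating B from nothing breaks the B moiety
  bad <- sig_model(sp, list(sig_reaction("A + B <-> C", 1, 1),
                            sig_reaction(" -> B", 1)),
                   moieties = list(B = c(B = 1, C = 1)))
  repb <- validate_model(bad)
  expect_false(repb$pass)
  expect_match(repb$moiety_failures, "B")
})

test_that("validation reports dangling species and unit mismatches", {
  m <- sig_model(rbind(sig_species("A"), sig_species("Z")),
                 list(sig_reaction("A -> ", 1)))
  rep <- validate_model(m)
  expect_equal(rep$dangling_species, "Z")
  expect_false(rep$pass)

  # zero reactions: everything dangles
  m0 <- sig_model(sig_species("A"), list())
  expect_equal(validate_model(m0)$dangling_species, "A")

  r <- sig_reaction("A + A -> ", 1); r$units <- "/s"
  m2 <- sig_model(sig_species("A"), list(r))
  expect_match(validate_model(m2)$unit_errors, "order implies")
})

test_that("conserved moieties match the left null space of the stoichiometry", {
  fx <- make_fixture("reversible-binding")
  ns <- conserved_moieties(fx$model)
  expect_equal(ncol(ns), 2)  # two independent conserved totals
  S <- stoich_matrix(fx$model)
  expect_lt(max(abs(t(ns) %*% S)), 1e-10)
})

test_that("the CA1 model builds, validates, and declares conserved moieties", {
  m <- ca1_model()
  expect_gt(nrow(m$species), 100)
  rep <- validate_model(m)
  expect_true(rep$pass)
  expect_true(all(c("CaM", "B2AR", "GluR1", "PKAC", "Gia", "Ade") %in%
                    names(m$moieties)))
  # beta2AR ladder: exactly four phosphorylation levels above unphosphorylated
  expect_true(all(c("R", "pR", "ppR", "pppR", "ppppR") %in% m$species$name))
  expect_false("pppppR" %in% m$species$name)
  # only the fully phosphorylated receptor binds Gi
  eqs <- vapply(m$reactions, `[[`, "", "eq")
  expect_true(any(grepl("^ppppR \\+ Gi ", eqs)))
  expect_false(any(grepl("^pppR \\+ Gi ", eqs)))
  # a single phosphorylation decouples from Gs: no Gs reactions for pX forms
  expect_false(any(grepl("^p+R \\+ Gs", eqs)))
  expect_false(any(grepl("^p+NER \\+ Gs", eqs)))
})

test_that("volume scaling leaves concentrations untouched and scales counts", {
  fx <- make_fixture("reversible-binding")
  m1 <- fx$model
  m2 <- scale_model(m1, 1)
  expect_identical(m1, m2)
  m3 <- scale_model(m1, 0.1)
  expect_equal(m3$volume_factor, 0.1)
  expect_identical(m3$species$init, m1$species$init)
  expect_error(scale_model(m1, 0), "positive")
  g <- geometry_spec()
  mesh <- build_mesh(g, 0.25)
  rt1 <- region_totals(mesh, ca1_model())
  rt3 <- region_totals(mesh, scale_model(ca1_model(), 0.1))
  i <- which(rownames(rt1) == "CaMKII")
  expect_equal(sum(rt3[i, ]) / sum(rt1[i, ]), 0.1, tolerance = 0.01)
})

test_that("model files round-trip through the YAML format", {
  fx <- make_fixture("enzyme-cycle")
  path <- tempfile(fileext = ".yaml")
  write_model(fx$model, path)
  m2 <- load_model(path)
  expect_equal(m2$species$name, fx$model$species$name)
  expect_equal(m2$species$init, fx$model$species$init)
  expect_equal(length(m2$reactions), length(fx$model$reactions))
  expect_equal(vapply(m2$reactions, `[[`, 0, "kf"),
               vapply(fx$model$reactions, `[[`, 0, "kf"))
  expect_equal(m2$moieties, fx$model$moieties, tolerance = 1e-12)
  expect_true(validate_model(m2)$pass)
  expect_error(load_model(tempfile()), "no such model file")
})

test_that("the shipped model config reproduces the built-in network", {
  path <- system.file("extdata", "ca1-model.yaml", package = "dendsig")
  m2 <- load_model(path)
  m1 <- ca1_model()
  expect_equal(m2$species$name, m1$species$name)
  expect_equal(m2$species$init, m1$species$init, tolerance = 1e-12)
  expect_equal(vapply(m2$reactions, `[[`, 0, "kf"),
               vapply(m1$reactions, `[[`, 0, "kf"), tolerance = 1e-12)
  expect_true(validate_model(m2)$pass)
})

test_that("the reaction table exposes rates, units and tags for audit", {
  tab <- reaction_table(ca1_model())
  expect_true(all(c("eq", "kf", "kr", "order", "units", "tag") %in%
                    names(tab)))
  expect_true(all(tab$order <= 2))
  expect_true(all(tab$units[tab$order == 2] == "/nM/s"))
  expect_gt(sum(tab$tag == "PKAc"), 5)
})
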