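test_that("topology covers backbone, restrained side chains and chemistry rules", {
  topo <- build_topology("APC", c("3:SG"))
  a1 <- topo$atoms[topo$atoms$res == 1, "atom"]
  expect_true(all(c("N", "HN", "CA", "HA", "CB", "HB", "C", "O") %in% a1))
  # proline has no amide proton
  expect_false("HN" %in% topo$atoms[topo$atoms$res == 2, "atom"])
  expect_true("SG" %in% topo$atoms[topo$atoms$res == 3, "atom"])
  # methionine sulfur chain is pulled in as a unit
  topo2 <- build_topology("AM", c("2:SD"))
  expect_true(all(c("CB", "CG", "SD") %in%
                    topo2$atoms[topo2$atoms$res == 2, "atom"]))
  expect_error(build_topology("AM", c("2:SG")), "not available")
  expect_error(build_topology("AG", c("2:CB")), "not available")
  # deterministic ordering
  topo3 <- build_topology("APC", c("3:SG"))
  expect_identical(topo$atoms, topo3$atoms)
})

test_that("annealing with no restraints yields clean geometry and zero restraint energies", {
  topo <- build_topology("GAVG")
  cf <- anneal(topo, restraint_set(), seed = 3,
               schedule = anneal_schedule(n_stages = 4, maxit = 80,
                                          final_maxit = 200))
  expect_equal(unname(cf$energy["noe"]), 0)
  expect_equal(unname(cf$energy["hbond"]), 0)
  expect_equal(unname(cf$energy["dihedral"]), 0)
  expect_equal(unname(cf$energy["metal"]), 0)
  expect_lt(unname(cf$energy["geometry"]), 5)
  # decomposition sums to total
  expect_equal(sum(cf$energy), cf$total_energy)
})

test_that("annealing is deterministic for a fixed seed", {
  topo <- build_topology("GAVG")
  sch <- anneal_schedule(n_stages = 3, maxit = 50, final_maxit = 100)
  c1 <- anneal(topo, restraint_set(), seed = 11, schedule = sch)
  c2 <- anneal(topo, restraint_set(), seed = 11, schedule = sch)
  expect_identical(c1$xyz, c2$xyz)
  c3 <- anneal(topo, restraint_set(), seed = 12, schedule = sch)
  expect_false(identical(c1$xyz, c3$xyz))
})

test_that("trigonal metal restraints refine to the published coordination geometry", {
  # three cysteines on a short scaffold, explicit-mode site
  topo <- build_topology("GCGGCGGCG", paste0(c(2, 5, 8), ":SG"), metal = TRUE)
  site <- data.frame(res = c(2, 5, 8), atom = "SG", attached = "CB")
  rs <- make_metal_restraints(site, "explicit")
  cf <- anneal(topo, rs, seed = 2,
               schedule = anneal_schedule(n_stages = 5, maxit = 100,
                                          final_maxit = 300))
  ag <- irafold:::atom_index(topo, 0, "AG")
  sg <- vapply(c(2, 5, 8), function(r) irafold:::atom_index(topo, r, "SG"),
               numeric(1))
  bond <- sqrt(rowSums((cf$xyz[sg, ] - matrix(cf$xyz[ag, ], 3, 3,
                                              byrow = TRUE))^2))
  expect_equal(bond, rep(2.3, 3), tolerance = 0.05)
  ss <- as.numeric(dist(cf$xyz[sg, ]))
  expect_equal(ss, rep(2 * 2.3 * sin(pi / 3), 3), tolerance = 0.1 / 3.98)
})

test_that("ensemble selection ranks by combined energy and pseudo-energy", {
  topo <- build_topology("GAV")
  mk <- function(e) {
    structure(list(xyz = matrix(rnorm(nrow(topo$atoms) * 3), ncol = 3),
                   topology = topo,
                   energy = c(geometry = e, noe = 0, hbond = 0, dihedral = 0,
                              metal = 0, ncs = 0, shift_pseudo = 0)),
              class = "conformer")
  }
  pool <- lapply(c(5, 1, 3), mk)
  ens <- select_ensemble(pool, n_select = 2)
  expect_equal(ens$selected, c(2, 3))
  expect_warning(all3 <- select_ensemble(pool, n_select = 10), "pool")
  expect_length(all3$models, 3)
  # ties broken by conformer index
  tied <- lapply(c(2, 2, 2), mk)
  expect_equal(select_ensemble(tied, n_select = 1)$selected, 1)
})

test_that("shift predictor discriminates via the pseudo-energy term", {
  truth <- test_truth()
  obs <- test_shifts(quiet_zero_noise())
  good <- structure(list(xyz = truth$xyz_apo, topology = truth$topology,
                         energy = c(geometry = 0, noe = 0, hbond = 0,
                                    dihedral = 0, metal = 0, ncs = 0,
                                    shift_pseudo = 0)), class = "conformer")
  # scrambled conformer: same topology, coordinates from an extended chain
  bad <- good
  bad$xyz <- irafold:::init_extended(truth$topology)
  ens <- select_ensemble(list(bad, good), obs, default_shift_predictor(),
                         n_select = 1)
  expect_equal(ens$selected, 2)
  ps <- ens$scores$pseudo
  expect_lt(ps[1], ps[2])  # scores are ordered best-first
})
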