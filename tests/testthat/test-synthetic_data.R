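test_that("toy fold construction is seeded-deterministic with a valid site", {
  truth <- test_truth()
  expect_equal(truth$n_residues, 30L)
  expect_equal(truth$site_residues, c(12L, 18L, 21L))
  s_idx <- vapply(1:3, function(i)
    irafold:::atom_index(truth$topology, truth$site_atoms$res[i],
                         truth$site_atoms$atom[i]), numeric(1))
  ss <- as.numeric(dist(truth$xyz_apo[s_idx, ]))
  expect_true(all(ss >= 3.8 & ss <= 4.2))
  # bound form sits at ideal trigonal geometry around the metal
  sb <- vapply(1:3, function(i)
    irafold:::atom_index(truth$topology_bound, truth$site_atoms$res[i],
                         truth$site_atoms$atom[i]), numeric(1))
  ssb <- as.numeric(dist(truth$xyz_bound[sb, ]))
  expect_equal(ssb, rep(2 * 2.3 * sin(pi / 3), 3), tolerance = 0.02)

  truth2 <- make_toy_fold(6, seed = 1)
  expect_identical(truth$xyz_apo, truth2$xyz_apo)
  expect_error(make_toy_fold(20, seed = 1), "outside supported range")
})

test_that("toy sheet carries an antiparallel hydrogen-bond registry", {
  truth <- test_truth()
  topo <- truth$topology
  # paired strand residues: at least some HN..O contacts under 2.5 A
  hn <- vapply(truth$regions$s1, function(r)
    irafold:::atom_index(topo, r, "HN"), numeric(1))
  o3 <- vapply(rev(truth$regions$s3), function(r)
    irafold:::atom_index(topo, r, "O"), numeric(1))
  d <- sqrt(rowSums((truth$xyz_apo[hn, ] - truth$xyz_apo[o3, ])^2))
  expect_true(sum(d < 2.6) >= 2)
})

test_that("zero-noise shifts separate forms as designed", {
  truth <- test_truth()
  sh <- simulate_shifts(truth, noise = quiet_zero_noise())
  # U-form against itself is exactly flat
  u <- sh[sh$form == "U", ]
  expect_equal(max(compute_delta_rms(u, u)$value), 0)
  # S-form minus U-form reproduces the injected strand + dispersion offsets
  s <- sh[sh$form == "S", ]
  m <- merge(as.data.frame(s), as.data.frame(u),
             by = c("residue_index", "atom"))
  hn <- m[m$atom == "HN" & m$residue_index %in% truth$regions$s1, ]
  inj <- irafold:::STRAND_OFFSETS["HN"] +
    truth$disp[hn$residue_index, "HN"] - truth$u_disp[hn$residue_index, "HN"]
  expect_equal(hn$shift.x - hn$shift.y, unname(inj), tolerance = 1e-10)
})

test_that("binding-site ranking closes the loop on bound-state perturbations", {
  truth <- test_truth()
  apo <- simulate_shifts(truth, forms = "S", state = "apo",
                         noise = quiet_zero_noise())
  bound <- simulate_shifts(truth, forms = "S", state = "bound",
                           noise = quiet_zero_noise())
  prof <- compute_delta_rms(apo, bound)
  top <- rank_binding_site(prof, 3)
  expect_setequal(top$residue_index, truth$site_residues)
})

test_that("NOESY intensities recover the -6 distance exponent", {
  truth <- test_truth()
  sim <- test_noesy()
  tm <- sim$truth_map[!sim$truth_map$is_decoy, ]
  inten <- c(stats::setNames(sim$peaks$n15$intensity, sim$peaks$n15$peak_id),
             stats::setNames(sim$peaks$c13$intensity, sim$peaks$c13$peak_id))
  fit <- stats::lm(log(inten[tm$peak_id]) ~ log(tm$r))
  expect_equal(unname(coef(fit)[2]), -6, tolerance = 0.3 / 6)
})

test_that("every peak carries provenance and decoys live on the U form", {
  sim <- test_noesy()
  all_ids <- c(sim$peaks$n15$peak_id, sim$peaks$c13$peak_id)
  expect_setequal(sim$truth_map$peak_id, all_ids)
  expect_true(all(sim$truth_map$form[sim$truth_map$is_decoy] == "U"))
  expect_true(all(abs(sim$truth_map$res_a[sim$truth_map$is_decoy] -
                        sim$truth_map$res_b[sim$truth_map$is_decoy]) <= 1))
})

test_that("r^-6 law: halving the distance scales intensity 64-fold", {
  truth <- test_truth()
  sim <- simulate_noesy(truth, noise = quiet_zero_noise())
  tm <- sim$truth_map
  inten <- c(stats::setNames(sim$peaks$n15$intensity, sim$peaks$n15$peak_id),
             stats::setNames(sim$peaks$c13$intensity, sim$peaks$c13$peak_id))
  near <- tm[which.min(abs(tm$r - 2.4)), ]
  far <- tm[which.min(abs(tm$r - 4.8)), ]
  expect_equal(inten[near$peak_id] / inten[far$peak_id],
               (near$r / far$r)^-6, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("titration series follows binding, dropout and U-form conversion", {
  truth <- test_truth()
  ser <- simulate_titration(truth)
  gt <- attr(ser, "ground_truth")
  expect_equal(ser$points[[1]]$ratio, 0)
  # apo point contains S and U peaks for every amide residue
  expect_equal(nrow(ser$points[[1]]$peaks),
               2 * sum(strsplit(truth$sequence, "")[[1]] != "P"))
  # site-residue S-form peaks are absent at intermediate bound fractions
  mid <- which(gt$bound_fraction > 0.2 & gt$bound_fraction < 0.8)[1]
  expect_false(any(gt$residue_maps[[mid]]$res %in% truth$site_residues &
                     gt$residue_maps[[mid]]$form == "S"))
  # and present again near saturation
  last <- length(ser$points)
  expect_true(all(truth$site_residues %in%
                    gt$residue_maps[[last]]$res[gt$residue_maps[[last]]$form == "S"]))
  # U-form population is (almost) gone at the endpoint: any remaining U
  # peak has a few percent of its apo intensity
  u_first <- ser$points[[1]]$peaks$intensity[gt$residue_maps[[1]]$form == "U"]
  u_last <- ser$points[[last]]$peaks$intensity[gt$residue_maps[[last]]$form == "U"]
  if (length(u_last)) {
    expect_lt(max(u_last) / mean(u_first), 0.05)
  }
  expect_error(simulate_titration(truth, ratios = c(0.5, 1)), "include 0")
})

test_that("dihedral predictions reflect the true backbone with Strong core tags", {
  truth <- test_truth()
  dp <- simulate_dihedral_predictions(truth)
  expect_true(all(dp$class[dp$residue_index %in% c(2, truth$n_residues - 1)] == "Dyn"))
  strand_phi <- dp[dp$angle == "phi" &
                     dp$residue_index %in% truth$regions$s1[2:5], ]
  expect_true(all(strand_phi$class == "Strong"))
  expect_true(all(dp$spread[dp$class == "Strong" &
                              dp$residue_index %in% truth$regions$s1] == 10))
  # predicted values scatter around the angles measured in the truth
  topo <- truth$topology
  gx <- function(r, a) truth$xyz_apo[irafold:::atom_index(topo, r, a), ]
  for (i in seq_len(nrow(strand_phi))) {
    r <- strand_phi$residue_index[i]
    true_phi <- irafold:::dihedral_angle(gx(r - 1, "C"), gx(r, "N"),
                                         gx(r, "CA"), gx(r, "C")) * 180 / pi
    expect_lt(abs(irafold:::wrap_deg(strand_phi$value[i] - true_phi)),
              strand_phi$spread[i])
  }
})
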