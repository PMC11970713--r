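test_that("NOE calibration follows the inverse-sixth-power law", {
  cal <- calibrate_noe_distance(1, 1, 4.25)
  expect_equal(cal$target, 4.25)
  expect_equal(cal$lower, 4.25 * 0.67)
  expect_equal(cal$upper, 4.25 * 1.33)
  # 64-fold stronger peak -> half the distance (64^(-1/6) = 1/2)
  expect_equal(calibrate_noe_distance(64, 1, 4.25)$target, 2.125)
  expect_equal(calibrate_noe_distance(1, 1, 5.0)$target, 5.0)
  expect_warning(clamped <- calibrate_noe_distance(0.5, 1, 4.25), "clamped")
  expect_equal(clamped$target, 4.25)
})

test_that("calibration is monotone nonincreasing and bounded by d_max", {
  set.seed(1)
  ii <- sort(exp(rnorm(200, sd = 2)))
  d <- calibrate_noe_distance(ii, min(ii), 4.25)$target
  expect_true(all(diff(d) <= 1e-12))
  expect_true(all(d <= 4.25 + 1e-12))
})

test_that("effective distance of ambiguous sets never exceeds the minimum member", {
  expect_equal(effective_distance(3), 3)
  expect_equal(effective_distance(c(3, 3)), 3 * 2^(-1 / 6), tolerance = 1e-12)
  expect_equal(effective_distance(c(3, 3)), 2.673, tolerance = 1e-3)
  set.seed(2)
  for (i in 1:50) {
    d <- runif(sample(1:6, 1), 2, 8)
    expect_lte(effective_distance(d), min(d) + 1e-12)
  }
})

test_that("square-well energy is zero inside the inclusive well, harmonic outside", {
  r <- distance_restraint(data.frame(res_a = 1, atom_a = "HA", res_b = 5,
                                     atom_b = "HA"), 4, 3, 5)
  expect_equal(square_well_energy(4, r), 0)
  expect_equal(square_well_energy(5, r), 0)   # boundary inclusive
  expect_equal(square_well_energy(3, r), 0)
  expect_equal(square_well_energy(5.5, r), 0.25)
  expect_equal(square_well_energy(2.5, r), 0.25)
  expect_equal(square_well_energy(5.5, r, k_force = 2), 0.5)
  # continuity at the boundary
  eps <- 1e-8
  expect_lt(square_well_energy(5 + eps, r), 1e-12)
})

test_that("hydrogen-bond restraints implement the two-alternative edge rule", {
  seqv <- "AVTIRG"
  bp <- c("3" = 0.8)
  rs <- make_hbond_restraints(bp, seqv, c(1, 6))
  expect_length(rs, 2)
  for (r in rs) {
    expect_equal(r$target, 1.7)
    expect_equal(r$lower, 1.4)
    expect_equal(r$upper, 2.0)
    expect_equal(r$kind, "hbond")
    # both alternatives present: fixed HN and fixed C-prime groups
    expect_true(any(r$pairs$atom_a == "HN" & r$pairs$atom_b == "C"))
  }
  # restraint 1 couples HN(i)/C'(x) with HN(x)/C'(i-1)
  expect_true(any(rs[[1]]$pairs$res_a == 3 & rs[[1]]$pairs$atom_a == "HN"))
  expect_true(any(rs[[1]]$pairs$res_b == 2 & rs[[1]]$pairs$atom_b == "C"))

  # below-threshold probability yields nothing (threshold is exclusive)
  expect_length(make_hbond_restraints(c("3" = 0.70), seqv, c(1, 6)), 0)
  expect_length(make_hbond_restraints(c("3" = 0.75), seqv, c(1, 6)), 0)

  # two adjacent qualifying residues -> four restraints
  expect_length(make_hbond_restraints(c("3" = 0.8, "4" = 0.8), seqv, c(1, 6)), 4)
})

test_that("sequence-separation floor and prolines restrict hbond partners", {
  rs <- make_hbond_restraints(c("3" = 0.9), "AVPIRG", c(1, 6))
  for (r in rs) {
    # no HN on the proline at position 3... and x respects the separation floor
    expect_false(any(r$pairs$res_a == 3 & r$pairs$atom_a == "HN"))
    hn_fixed <- r$pairs$res_a[r$pairs$atom_b == "C" &
                                r$pairs$res_b %in% c(2, 3)]
    expect_true(all(abs(hn_fixed - r$pairs$res_b[r$pairs$atom_b == "C" &
                                                   r$pairs$res_b %in% c(2, 3)]) >= 2))
  }
})

test_that("dihedral restraints keep only Strong predictions at twice the spread", {
  preds <- data.frame(residue_index = c(5, 6, 7), residue_type = "V",
                      angle = c("phi", "psi", "phi"),
                      value = c(-120, 130, -60), spread = c(10, 12, 0),
                      class = c("Strong", "Dyn", "Strong"))
  expect_warning(rs <- make_dihedral_restraints(preds), "spread")
  expect_length(rs, 2)
  expect_equal(rs[[1]]$target, -120)
  expect_equal(rs[[1]]$halfwidth, 20)
  expect_equal(rs[[2]]$halfwidth, 5)  # minimum substituted for zero spread
})

test_that("metal restraints: explicit trigonal geometry and implicit S-S mode", {
  site <- data.frame(res = c(12, 18, 21), atom = c("SD", "SG", "SD"),
                     attached = c("CE", "CB", "CE"))
  ex <- make_metal_restraints(site, "explicit")
  expect_length(ex$distance, 3)
  expect_length(ex$angle, 6)
  expect_true(all(vapply(ex$distance, `[[`, numeric(1), "target") == 2.3))
  angs <- vapply(ex$angle, `[[`, numeric(1), "target")
  expect_equal(sort(unique(angs)), c(109.5, 120))
  expect_equal(sum(angs == 120), 3)
  expect_equal(sum(angs == 109.5), 3)
  expect_s3_class(attr(ex, "metal"), "data.frame")

  im <- make_metal_restraints(site, "implicit")
  expect_length(im$distance, 3)
  expect_true(all(vapply(im$distance, `[[`, numeric(1), "target") == 4.0))
  expect_length(im$angle, 0)

  # the implicit target is consistent with ideal trigonal geometry
  expect_equal(2 * 2.3 * sin(pi / 3), 3.983, tolerance = 1e-3)
  expect_lt(abs(4.0 - 2 * 2.3 * sin(pi / 3)), 0.1)

  expect_error(make_metal_restraints(site[1:2, ], "explicit"), "three")
})

test_that("NCS coupling validates segments and counts backbone residues", {
  ncs <- make_ncs_coupling(list(c(37, 41), c(49, 55), c(63, 68)),
                           list(c(42, 48), c(56, 62)))
  expect_length(ncs$residues, 5 + 7 + 6)
  expect_length(ncs$free_residues, 14)
  expect_error(make_ncs_coupling(list(c(37, 45)), list(c(42, 48))), "overlap")
  expect_error(make_ncs_coupling(list()), "empty")
})

test_that("restraint tables round-trip exactly through TSV", {
  rs <- restraint_set(
    distance = list(
      distance_restraint(data.frame(res_a = c(1, 1), atom_a = c("HN", "HN"),
                                    res_b = c(5, 6), atom_b = c("HA", "HA")),
                         3.2, 2.5, 3.9, kind = "noe"),
      distance_restraint(data.frame(res_a = 2, atom_a = "HN", res_b = 7,
                                    atom_b = "C"), 1.7, 1.4, 2.0,
                         kind = "hbond")),
    angle = list(angle_restraint(data.frame(res = c(12, 0, 18),
                                            atom = c("SD", "AG", "SG")),
                                 120, 5)),
    dihedral = list(dihedral_restraint(5, "phi", -120, 20)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rs, f)
  rs2 <- read_restraints(f)
  expect_length(rs2$distance, 2)
  expect_equal(rs2$distance[[1]]$target, 3.2)
  expect_equal(rs2$distance[[1]]$pairs$res_b, c(5, 6))
  expect_equal(rs2$angle[[1]]$target, 120)
  expect_equal(rs2$dihedral[[1]]$halfwidth, 20)
})
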