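# Shared fixtures. The toy ground truth is expensive to construct, so it
# is built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

test_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$truth <- make_toy_fold(6, seed = 1)
  }
  .fixture_env$truth
}

test_shifts <- function(noise = noise_model()) {
  key <- paste0("shifts_", noise$position_jitter[["HN"]])
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_shifts(test_truth(), noise = noise)
  }
  .fixture_env[[key]]
}

test_noesy <- function(noise = noise_model()) {
  key <- paste0("noesy_", noise$position_jitter[["HN"]], "_", noise$decoy_rate)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_noesy(test_truth(), noise = noise)
  }
  .fixture_env[[key]]
}

quiet_zero_noise <- function() {
  noise_model(position_jitter = c(HN = 0, H = 0, N = 0, C = 0),
              intensity_sdlog = 0, miss_prob = 0, decoy_rate = 0)
}

# exact-distance ground-truth restraints (narrow wells) from the truth map
truth_restraints <- function(truth, truth_map, tol = 0.1) {
  tm <- truth_map[!truth_map$is_decoy, ]
  restraint_set(distance = lapply(seq_len(nrow(tm)), function(i) {
    distance_restraint(
      data.frame(res_a = tm$res_a[i], atom_a = tm$atom_a[i],
                 res_b = tm$res_b[i], atom_b = tm$atom_b[i]),
      target = tm$r[i], lower = tm$r[i] - tol, upper = tm$r[i] + tol)
  }))
}

# true backbone dihedral restraints measured in the ground-truth structure
truth_dihedrals <- function(truth, halfwidth = 20) {
  topo <- truth$topology
  gx <- function(r, a) truth$xyz_apo[irafold:::atom_index(topo, r, a), ]
  out <- list()
  for (r in 2:(truth$n_residues - 1L)) {
    phi <- irafold:::dihedral_angle(gx(r - 1, "C"), gx(r, "N"), gx(r, "CA"),
                                    gx(r, "C")) * 180 / pi
    psi <- irafold:::dihedral_angle(gx(r, "N"), gx(r, "CA"), gx(r, "C"),
                                    gx(r + 1, "N")) * 180 / pi
    out[[length(out) + 1]] <- dihedral_restraint(r, "phi", phi, halfwidth)
    out[[length(out) + 1]] <- dihedral_restraint(r, "psi", psi, halfwidth)
  }
  out
}

backbone_selection <- function(topology, residues = NULL) {
  at <- topology$atoms
  keep <- at$atom %in% c("N", "CA", "C")
  if (!is.null(residues)) keep <- keep & at$res %in% residues
  which(keep)
}
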