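test_that("superposition recovers rigid transformations exactly", {
  set.seed(4)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(P, P)$rmsd, 0, tolerance = 1e-10)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q <- P %*% t(R) + matrix(rep(c(3, -2, 5), each = 10), 10, 3)
  sup <- superpose_rmsd(P, Q)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(sup$rotation, R, tolerance = 1e-6)

  expect_error(superpose_rmsd(P[1:2, ], Q[1:2, ]), "at least 3")
  col <- cbind(1:5, 0, 0)
  expect_error(superpose_rmsd(col, col + 1), "collinear")
})

test_that("superposition RMSD agrees with an independent quaternion solver", {
  # Horn's quaternion method as the oracle
  quat_rmsd <- function(P, Q) {
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    M <- crossprod(Pc, Qc)
    S <- matrix(0, 4, 4)
    S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
    S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
    S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
    S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
    S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
    S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
    S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
    S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
    S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
    S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
    lam <- max(eigen(S, symmetric = TRUE)$values)
    msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
    sqrt(max(msd, 0))
  }
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    expect_equal(superpose_rmsd(P, Q)$rmsd, quat_rmsd(P, Q), tolerance = 1e-8)
  }
})

test_that("analytic gradients of the full energy match finite differences", {
  topo <- build_topology("ACMG", c("2:SG", "3:SD"))
  rs <- restraint_set(
    distance = list(
      distance_restraint(data.frame(res_a = 1, atom_a = "HA", res_b = 4,
                                    atom_b = "HA"), 4, 3, 5),
      distance_restraint(data.frame(res_a = c(1, 1), atom_a = c("HA", "HN"),
                                    res_b = c(4, 4), atom_b = c("HA", "HA")),
                         6, 5, 7)),
    angle = list(angle_restraint(data.frame(res = c(2, 2, 2),
                                            atom = c("CA", "CB", "SG")),
                                 109.5, 2)),
    dihedral = list(dihedral_restraint(2, "phi", -120, 10),
                    dihedral_restraint(3, "psi", 130, 10)))
  ce <- irafold:::compile_energy(topo, rs)
  set.seed(42)
  x <- irafold:::init_extended(topo) +
    matrix(rnorm(3 * nrow(topo$atoms), sd = 0.4), ncol = 3)
  ev <- irafold:::energy_eval(ce, x, w_rep = 1)
  h <- 1e-6
  idx <- sample(seq_len(nrow(x)), 12)
  for (i in idx) for (j in 1:3) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    gn <- (irafold:::energy_eval(ce, xp, 1)$total -
             irafold:::energy_eval(ce, xm, 1)$total) / (2 * h)
    expect_equal(ev$grad[i, j], gn, tolerance = 1e-4)
  }
})
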