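# Low-level geometry: superposition, dihedrals and their gradients.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
mcross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Least-squares superposition of P onto Q (n x 3 each): returns rotation R
# and translation t with fit = P %*% t(R) + t, plus the residual rmsd.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-8) stop("degenerate (collinear) atom selection for superposition")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  fit <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Qc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Optimal superposition and RMSD between two models
#'
#' Least-squares (Kabsch) superposition of `model_a` onto `model_b` over an
#' atom selection.
#'
#' @param model_a,model_b conformers (with `$xyz`) or plain n x 3 matrices.
#' @param atom_selection integer atom indices into the shared atom ordering
#'   (default: all rows).
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
superpose_rmsd <- function(model_a, model_b, atom_selection = NULL) {
  A <- if (is.list(model_a)) model_a$xyz else model_a
  B <- if (is.list(model_b)) model_b$xyz else model_b
  if (is.null(atom_selection)) atom_selection <- seq_len(nrow(A))
  if (length(atom_selection) < 3) stop("need at least 3 atoms to superpose")
  kabsch(A[atom_selection, , drop = FALSE], B[atom_selection, , drop = FALSE])
}

# Dihedral angle (radians, in (-pi, pi]) over rows p1..p4 of x.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Dihedral plus analytic gradient: returns list(phi, g) with g a 4 x 3
# matrix of d(phi)/d(p_i).
dihedral_angle_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  m1 <- vcross(n1, b2 / nb2)
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  if (n1sq < 1e-12 || n2sq < 1e-12) {
    return(list(phi = phi, g = matrix(0, 4, 3)))
  }
  F <- nb2 / n1sq * n1
  H <- -nb2 / n2sq * n2
  a <- sum(b1 * b2) / nb2^2
  b <- sum(b3 * b2) / nb2^2
  g <- rbind(F,
             -(1 + a) * F + b * H,
             a * F - (1 + b) * H,
             H)
  list(phi = phi, g = g)
}

# Bond angle (radians) at vertex p2, with analytic gradient (3 x 3).
bond_angle_grad <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  ct <- sum(u * v) / (nu * nv)
  ct <- max(-1 + 1e-10, min(1 - 1e-10, ct))
  th <- acos(ct)
  st <- sqrt(1 - ct^2)
  dth_du <- -(v / (nu * nv) - ct * u / nu^2) / st
  dth_dv <- -(u / (nu * nv) - ct * v / nv^2) / st
  g <- rbind(dth_du, -(dth_du + dth_dv), dth_dv)
  list(theta = th, g = g)
}

# wrap an angle difference (degrees) into (-180, 180]
wrap_deg <- function(d) {
  w <- (d + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
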