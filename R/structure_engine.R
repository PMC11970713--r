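# Desk-scale restrained conformer generation.
#
# Reduced all-atom representation: backbone N, HN, CA, HA, C, O per residue
# plus CB and any side-chain atoms referenced by a restraint (e.g. SG for
# Cys, CG/SD/CE for Met), plus an optional metal atom (residue 0, AG).
# Covalent geometry is modeled as harmonic distance terms (bonds, 1-3
# distances derived from ideal angles, a trans-peptide CA-CA term), CA
# chirality as a signed-volume term, sterics as a soft-sphere repulsion.
# Restraints add square-well distance terms (with r^-6 ambiguous
# averaging), flat-bottom bond-angle terms and square-well backbone
# torsion terms. Conformers are generated by a simulated-annealing-style
# schedule of seeded coordinate perturbations with L-BFGS quenches.

BOND_LENGTHS <- c("N-CA" = 1.458, "CA-C" = 1.525, "C-N" = 1.329,
                  "C-O" = 1.231, "N-HN" = 0.980, "CA-HA" = 1.090,
                  "CA-CB" = 1.530, "CB-HB" = 1.050, "CB-SG" = 1.810,
                  "CB-CG" = 1.520, "CG-SD" = 1.800, "SD-CE" = 1.790)

# 1-3 distances implied by ideal bond angles (law of cosines).
PAIR13 <- list(
  c("N", "C", 2.459), c("CA", "+N", 2.425), c("C", "+CA", 2.435),
  c("CA", "O", 2.401), c("O", "+N", 2.250), c("HN", "CA", 2.113),
  c("-C", "HN", 2.002), c("HA", "N", 2.073), c("HA", "C", 2.144),
  c("HA", "CB", 2.153), c("CB", "N", 2.455), c("CB", "C", 2.504),
  c("CA", "SG", 2.805), c("CA", "CG", 2.558), c("CB", "SD", 2.770),
  c("CG", "CE", 2.754), c("CA", "HB", 2.140))

# Signed-volume targets for CA chirality: (N - CA) . ((C - CA) x (X - CA)),
# X = CB (or HA for glycine). L-configuration.
CHIR_TARGET_CB <- 2.510
CHIR_TARGET_HA <- -1.874

SIDECHAIN_ATOMS <- list(
  C = c("CB", "SG"), M = c("CB", "CG", "SD", "CE"), G = character(0))

sidechain_for <- function(res_type, wanted) {
  allowed <- SIDECHAIN_ATOMS[[res_type]] %||% "CB"
  bad <- setdiff(wanted, allowed)
  if (length(bad)) {
    stop("atom ", paste(bad, collapse = ","), " not available in residue type ",
         res_type)
  }
  # atoms are chained: include everything up to the deepest requested atom
  if (!length(wanted)) return(character(0))
  allowed[seq_len(max(match(wanted, allowed)))]
}

#' Build a reduced topology for a sequence
#'
#' @param sequence one-letter amino-acid string.
#' @param restraint_atoms character vector of `"res:ATOM"` references that
#'   must be resolvable (side-chain atoms are added as needed); an atom a
#'   residue type cannot carry is an error.
#' @param first_residue construct index of the first sequence position.
#' @param metal if `TRUE`, append a metal ion atom (residue 0, `AG`).
#' @return a `topology`: atom table, bond/angle term tables, lookup index.
#' @export
build_topology <- function(sequence, restraint_atoms = character(0),
                           first_residue = 1L, metal = FALSE) {
  seqv <- strsplit(sequence, "")[[1]]
  n_res <- length(seqv)
  res_ids <- first_residue + seq_len(n_res) - 1L
  ra <- if (length(restraint_atoms)) split_atom_ref(restraint_atoms) else
    data.frame(res = integer(0), atom = character(0))
  ra <- ra[ra$res != 0L, , drop = FALSE]

  rows <- list()
  for (k in seq_len(n_res)) {
    rt <- seqv[k]; ri <- res_ids[k]
    wanted_all <- unique(toupper(ra$atom[ra$res == ri]))
    if (rt == "G" && any(wanted_all %in% c("CB", "HB"))) {
      stop("atom ", paste(intersect(wanted_all, c("CB", "HB")), collapse = ","),
           " not available in residue type G")
    }
    wanted <- setdiff(wanted_all,
                      c("N", "HN", "CA", "HA", "C", "O", "CB", "HB"))
    side <- sidechain_for(rt, wanted)
    if (rt != "G" && !"CB" %in% side) side <- c("CB", side)
    # pseudo-proton representing the beta protons, one per CB
    if ("CB" %in% side) side <- append(side, "HB", after = match("CB", side))
    names <- c("N", if (rt != "P") "HN", "CA", "HA", side, "C", "O")
    rows[[k]] <- data.frame(res = ri, res_type = rt, atom = names,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (metal) atoms <- rbind(atoms, data.frame(res = 0L, res_type = "X", atom = "AG"))
  atoms$element <- element_of(atoms$atom)
  idx <- stats::setNames(seq_len(nrow(atoms)), paste0(atoms$res, ":", atoms$atom))

  find <- function(res, atom) unname(idx[paste0(res, ":", atom)])
  bonds <- list(); p13 <- list()
  add_bond <- function(r1, a1, r2, a2, d) {
    i <- find(r1, a1); j <- find(r2, a2)
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <<- c(i, j, d)
  }
  add_13 <- function(r1, a1, r2, a2, d) {
    i <- find(r1, a1); j <- find(r2, a2)
    if (!is.na(i) && !is.na(j)) p13[[length(p13) + 1]] <<- c(i, j, d)
  }
  for (k in seq_len(n_res)) {
    ri <- res_ids[k]
    add_bond(ri, "N", ri, "CA", BOND_LENGTHS["N-CA"])
    add_bond(ri, "CA", ri, "C", BOND_LENGTHS["CA-C"])
    add_bond(ri, "C", ri, "O", BOND_LENGTHS["C-O"])
    add_bond(ri, "N", ri, "HN", BOND_LENGTHS["N-HN"])
    add_bond(ri, "CA", ri, "HA", BOND_LENGTHS["CA-HA"])
    add_bond(ri, "CA", ri, "CB", BOND_LENGTHS["CA-CB"])
    add_bond(ri, "CB", ri, "HB", BOND_LENGTHS["CB-HB"])
    add_bond(ri, "CB", ri, "SG", BOND_LENGTHS["CB-SG"])
    add_bond(ri, "CB", ri, "CG", BOND_LENGTHS["CB-CG"])
    add_bond(ri, "CG", ri, "SD", BOND_LENGTHS["CG-SD"])
    add_bond(ri, "SD", ri, "CE", BOND_LENGTHS["SD-CE"])
    for (p in PAIR13) {
      a1 <- p[1]; a2 <- p[2]; d <- as.numeric(p[3])
      r1 <- ri; r2 <- ri
      if (startsWith(a1, "-")) { r1 <- ri - 1L; a1 <- substring(a1, 2) }
      if (startsWith(a2, "+")) { r2 <- ri + 1L; a2 <- substring(a2, 2) }
      add_13(r1, a1, r2, a2, d)
    }
    if (k < n_res) {
      add_bond(ri, "C", ri + 1L, "N", BOND_LENGTHS["C-N"])
      # trans peptide: CA(i)-CA(i+1) ~ 3.80 A
      add_13(ri, "CA", ri + 1L, "CA", 3.80)
    }
  }
  bonds <- do.call(rbind, bonds)
  p13 <- do.call(rbind, p13)

  chir <- list()
  for (k in seq_len(n_res)) {
    ri <- res_ids[k]
    x_atom <- if (seqv[k] == "G") "HA" else "CB"
    tgt <- if (seqv[k] == "G") CHIR_TARGET_HA else CHIR_TARGET_CB
    ids <- c(find(ri, "CA"), find(ri, "N"), find(ri, "C"), find(ri, x_atom))
    if (!anyNA(ids)) chir[[length(chir) + 1]] <- c(ids, tgt)
  }
  chir <- do.call(rbind, chir)

  # bond-graph distances for repulsion exclusion (<= 3 bonds apart)
  n_atoms <- nrow(atoms)
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env(hash = TRUE)
  for (i in seq_len(n_atoms)) {
    lvl1 <- adj[[i]]
    lvl2 <- unique(unlist(adj[lvl1]))
    lvl3 <- unique(unlist(adj[lvl2]))
    near <- unique(c(i, lvl1, lvl2, lvl3))
    for (j in near[near > i]) assign(paste(i, j), TRUE, envir = excl)
  }
  excl_keys <- ls(excl)

  structure(list(sequence = sequence, first_residue = first_residue,
                 residues = res_ids, res_types = seqv, atoms = atoms,
                 index = idx, bonds = bonds, p13 = p13, chir = chir,
                 excluded_pairs = excl_keys, metal = metal),
            class = "topology")
}

atom_index <- function(topology, res, atom) {
  i <- unname(topology$index[paste0(res, ":", toupper(atom))])
  if (anyNA(i)) {
    stop("atom(s) not in topology: ",
         paste(paste0(res, ":", atom)[is.na(i)], collapse = ", "))
  }
  i
}

# Assemble precomputed energy-term tables for fast evaluation.
compile_energy <- function(topology, restraints,
                           k = list(bond = 100, p13 = 30, chir = 10,
                                    rep = 20, noe = 5, hbond = 5,
                                    metal = 20, angle = 30, dihedral = 30,
                                    ncs = 0)) {
  at <- topology$atoms
  n <- nrow(at)
  # repulsion pair list (precomputed once; all pairs beyond 3 bonds)
  radius <- ifelse(at$element %in% c("H"), 1.0,
                   ifelse(at$element == "S", 1.55,
                          ifelse(at$element == "AG", 1.2, 1.45)))
  cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keys <- paste(cmb[, 1], cmb[, 2])
  keep <- !(keys %in% topology$excluded_pairs)
  rep_ia <- cmb[keep, 1]; rep_ib <- cmb[keep, 2]
  rep_r0 <- 0.9 * (radius[rep_ia] + radius[rep_ib])

  # distance restraints -> grouped member-pair table
  mem <- list(); gmeta <- list()
  for (gi in seq_along(restraints$distance)) {
    r <- restraints$distance[[gi]]
    ia <- atom_index(topology, r$pairs$res_a, r$pairs$atom_a)
    ib <- atom_index(topology, r$pairs$res_b, r$pairs$atom_b)
    kk <- switch(r$kind, noe = k$noe, hbond = k$hbond, ncs = k$ncs, k$metal)
    comp <- switch(r$kind, noe = "noe", hbond = "hbond", "metal")
    mem[[gi]] <- cbind(gi, ia, ib)
    gmeta[[gi]] <- data.frame(lower = r$lower, upper = r$upper,
                              k = kk * r$weight, comp = comp,
                              stringsAsFactors = FALSE)
  }
  mem <- if (length(mem)) do.call(rbind, mem) else matrix(0, 0, 3)
  gmeta <- if (length(gmeta)) do.call(rbind, gmeta) else
    data.frame(lower = numeric(0), upper = numeric(0), k = numeric(0),
               comp = character(0))

  ang <- lapply(restraints$angle, function(r) {
    list(ids = atom_index(topology, r$atoms$res, r$atoms$atom),
         target = r$target * pi / 180, halfwidth = r$halfwidth * pi / 180,
         k = k$angle * r$weight)
  })

  dih <- list()
  for (r in restraints$dihedral) {
    ri <- r$residue_index
    ids <- if (r$angle_name == "phi") {
      tryCatch(c(atom_index(topology, ri - 1L, "C"), atom_index(topology, ri, "N"),
                 atom_index(topology, ri, "CA"), atom_index(topology, ri, "C")),
               error = function(e) NULL)
    } else {
      tryCatch(c(atom_index(topology, ri, "N"), atom_index(topology, ri, "CA"),
                 atom_index(topology, ri, "C"), atom_index(topology, ri + 1L, "N")),
               error = function(e) NULL)
    }
    if (is.null(ids)) next  # chain-terminal angle: silently skipped
    dih[[length(dih) + 1]] <- c(ids, r$target, r$halfwidth,
                                k$dihedral * r$weight)
  }
  dih <- if (length(dih)) do.call(rbind, dih) else matrix(0, 0, 7)

  list(topology = topology, k = k,
       bonds = topology$bonds, p13 = topology$p13, chir = topology$chir,
       rep_ia = rep_ia, rep_ib = rep_ib, rep_r0 = rep_r0,
       mem = mem, gmeta = gmeta, ang = ang,
       dih_ids = dih[, 1:4, drop = FALSE], dih_target = dih[, 5],
       dih_halfwidth = dih[, 6], dih_k = dih[, 7])
}

# cache so that optim's separate fn/gr calls at the same point cost one
# energy evaluation
make_objective <- function(eval_fn) {
  last_v <- NULL
  last <- NULL
  refresh <- function(v) {
    if (!identical(v, last_v)) {
      last <<- eval_fn(v)
      last_v <<- v
    }
  }
  list(fn = function(v) { refresh(v); last$total },
       gr = function(v) { refresh(v); last$grad })
}

# harmonic pair energy + gradient accumulation helper
pair_grad_accum <- function(g, ia, ib, coef, dvec) {
  # coef = dE/dd / d per pair; dvec = x[ia,] - x[ib,]
  gc <- dvec * coef
  for (col in 1:3) {
    s <- rowsum(gc[, col], ia)
    g[as.integer(rownames(s)), col] <- g[as.integer(rownames(s)), col] + s
    s <- rowsum(gc[, col], ib)
    g[as.integer(rownames(s)), col] <- g[as.integer(rownames(s)), col] - s
  }
  g
}

# Total energy and gradient; with decompose=TRUE returns component vector.
# w_geom scales the covalent terms (bonds, 1-3, chirality) -- the
# embedding stage fits restraints with soft geometry first.
energy_eval <- function(ce, x, w_rep = 1, decompose = FALSE, w_geom = 1) {
  n <- nrow(x)
  g <- matrix(0, n, 3)
  comp <- c(geometry = 0, noe = 0, hbond = 0, dihedral = 0, metal = 0,
            ncs = 0, shift_pseudo = 0)
  kp <- ce$k

  hterm <- function(tab, kk) {
    ia <- tab[, 1]; ib <- tab[, 2]; d0 <- tab[, 3]
    dv <- x[ia, , drop = FALSE] - x[ib, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    e <- sum(kk * (d - d0)^2)
    coef <- 2 * kk * (d - d0) / pmax(d, 1e-8)
    g <<- pair_grad_accum(g, ia, ib, coef, dv)
    e
  }
  if (nrow(ce$bonds)) comp["geometry"] <- comp["geometry"] + hterm(ce$bonds, w_geom * kp$bond)
  if (nrow(ce$p13)) comp["geometry"] <- comp["geometry"] + hterm(ce$p13, w_geom * kp$p13)

  # chirality: signed volume terms (vectorized over residues)
  if (!is.null(ce$chir) && nrow(ce$chir)) {
    k_chir <- w_geom * kp$chir
    ch <- ce$chir
    ca <- x[ch[, 1], , drop = FALSE]
    a <- x[ch[, 2], , drop = FALSE] - ca
    b <- x[ch[, 3], , drop = FALSE] - ca
    cc <- x[ch[, 4], , drop = FALSE] - ca
    bxc <- mcross(b, cc)
    V <- rowSums(a * bxc)
    comp["geometry"] <- comp["geometry"] + sum(k_chir * (V - ch[, 5])^2)
    dV <- 2 * k_chir * (V - ch[, 5])
    ga <- bxc * dV
    gb <- mcross(cc, a) * dV
    gc <- mcross(a, b) * dV
    acc <- function(idx, gm) {
      for (col in 1:3) {
        s <- rowsum(gm[, col], idx)
        g[as.integer(rownames(s)), col] <<- g[as.integer(rownames(s)), col] + s
      }
    }
    acc(ch[, 2], ga); acc(ch[, 3], gb); acc(ch[, 4], gc)
    acc(ch[, 1], -(ga + gb + gc))
  }

  # soft-sphere repulsion
  if (w_rep > 0 && length(ce$rep_ia)) {
    dv <- x[ce$rep_ia, , drop = FALSE] - x[ce$rep_ib, , drop = FALSE]
    d2 <- rowSums(dv^2)
    hit <- which(d2 < ce$rep_r0^2)
    if (length(hit)) {
      d <- sqrt(d2[hit])
      over <- ce$rep_r0[hit] - d
      kk <- w_rep * kp$rep
      comp["geometry"] <- comp["geometry"] + sum(kk * over^2)
      coef <- -2 * kk * over / pmax(d, 1e-8)
      g <- pair_grad_accum(g, ce$rep_ia[hit], ce$rep_ib[hit], coef,
                           dv[hit, , drop = FALSE])
    }
  }

  # square-well distance restraints with r^-6 ambiguous averaging
  if (nrow(ce$mem)) {
    gi <- ce$mem[, 1]; ia <- ce$mem[, 2]; ib <- ce$mem[, 3]
    dv <- x[ia, , drop = FALSE] - x[ib, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dv^2)), 1e-6)
    s <- as.numeric(rowsum(d^-6, gi))  # gi runs 1..G in order
    reff <- s^(-1 / 6)
    lo <- ce$gmeta$lower; up <- ce$gmeta$upper; kk <- ce$gmeta$k
    excess <- ifelse(reff < lo, reff - lo, ifelse(reff > up, reff - up, 0))
    e_g <- kk * excess^2
    for (cn in unique(ce$gmeta$comp)) {
      comp[cn] <- comp[cn] + sum(e_g[ce$gmeta$comp == cn])
    }
    dE_dreff <- 2 * kk * excess
    # dr_eff/dr_k = (r_eff / r_k)^7
    fac <- dE_dreff[gi] * (reff[gi] / d)^7
    coef <- fac / d
    live <- which(fac != 0)
    if (length(live)) {
      g <- pair_grad_accum(g, ia[live], ib[live], coef[live],
                           dv[live, , drop = FALSE])
    }
  }

  # flat-bottom angle restraints
  for (a in ce$ang) {
    ids <- a$ids
    bg <- bond_angle_grad(x[ids[1], ], x[ids[2], ], x[ids[3], ])
    dlt <- bg$theta - a$target
    exc <- sign(dlt) * max(0, abs(dlt) - a$halfwidth)
    if (exc != 0) {
      a_k <- w_geom * a$k
      comp["metal"] <- comp["metal"] + a_k * exc^2
      dE <- 2 * a_k * exc
      g[ids[1], ] <- g[ids[1], ] + dE * bg$g[1, ]
      g[ids[2], ] <- g[ids[2], ] + dE * bg$g[2, ]
      g[ids[3], ] <- g[ids[3], ] + dE * bg$g[3, ]
    }
  }

  # square-well backbone torsions (degrees wrapped, evaluated in radians;
  # vectorized over all torsion restraints)
  if (!is.null(ce$dih_ids) && nrow(ce$dih_ids)) {
    di <- ce$dih_ids
    p1 <- x[di[, 1], , drop = FALSE]; p2 <- x[di[, 2], , drop = FALSE]
    p3 <- x[di[, 3], , drop = FALSE]; p4 <- x[di[, 4], , drop = FALSE]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- mcross(b1, b2); n2 <- mcross(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    m1 <- mcross(n1, b2 / nb2)
    phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
    dlt <- wrap_deg(phi * 180 / pi - ce$dih_target)
    exc <- sign(dlt) * pmax(0, abs(dlt) - ce$dih_halfwidth)
    live <- which(exc != 0)
    if (length(live)) {
      exc_r <- exc[live] * pi / 180
      d_k <- w_geom * ce$dih_k[live]
      comp["dihedral"] <- comp["dihedral"] + sum(d_k * exc_r^2)
      dE <- 2 * d_k * exc_r
      n1sq <- rowSums(n1^2)[live]; n2sq <- rowSums(n2^2)[live]
      Fv <- n1[live, , drop = FALSE] * (nb2[live] / n1sq)
      Hv <- n2[live, , drop = FALSE] * (-nb2[live] / n2sq)
      av <- rowSums(b1 * b2)[live] / nb2[live]^2
      bv <- rowSums(b3 * b2)[live] / nb2[live]^2
      g1 <- Fv * dE
      g2 <- (-(1 + av) * Fv + bv * Hv) * dE
      g3 <- (av * Fv - (1 + bv) * Hv) * dE
      g4 <- Hv * dE
      acc2 <- function(idx, gm) {
        for (col in 1:3) {
          s <- rowsum(gm[, col], idx)
          g[as.integer(rownames(s)), col] <<- g[as.integer(rownames(s)), col] + s
        }
      }
      acc2(di[live, 1], g1); acc2(di[live, 2], g2)
      acc2(di[live, 3], g3); acc2(di[live, 4], g4)
    }
  }

  if (decompose) list(total = sum(comp), comp = comp, grad = g)
  else list(total = sum(comp), grad = g)
}

# Metric-matrix distance-geometry embedding: exact bounds from covalent
# geometry, square-well uppers from unambiguous distance restraints,
# triangle-inequality smoothing, then a random distance matrix within
# bounds projected to 3D (classical MDS). The returned hand is the one
# that better satisfies the chirality targets.
embed_coords <- function(ce, topology) {
  n <- nrow(topology$atoms)
  U <- matrix(50, n, n)
  L <- matrix(1.8, n, n)
  diag(U) <- diag(L) <- 0
  fix <- function(i, j, d, tol = 0.05) {
    U[cbind(i, j)] <<- U[cbind(j, i)] <<- d + tol
    L[cbind(i, j)] <<- L[cbind(j, i)] <<- pmax(d - tol, 0)
  }
  fix(ce$bonds[, 1], ce$bonds[, 2], ce$bonds[, 3])
  fix(ce$p13[, 1], ce$p13[, 2], ce$p13[, 3], tol = 0.2)
  if (nrow(ce$mem)) {
    sizes <- table(ce$mem[, 1])
    unamb <- ce$mem[ce$mem[, 1] %in% as.integer(names(sizes)[sizes == 1]), ,
                    drop = FALSE]
    if (nrow(unamb)) {
      up <- ce$gmeta$upper[unamb[, 1]]
      ia <- unamb[, 2]; ib <- unamb[, 3]
      cur <- U[cbind(ia, ib)]
      U[cbind(ia, ib)] <- U[cbind(ib, ia)] <- pmin(cur, up)
    }
  }
  # triangle smoothing of upper bounds
  for (k in seq_len(n)) U <- pmin(U, outer(U[, k], U[k, ], "+"))
  L <- pmin(L, U)
  # sample distances biased toward the mid-range of the bounds (smoothed
  # uppers overestimate sparse long-range distances)
  D <- matrix(stats::runif(n * n, 0.55, 0.95), n, n)
  D <- L + D * (U - L)
  D <- pmax((D + t(D)) / 2, L)
  x <- stats::cmdscale(D, k = 3)
  # choose the hand that agrees with the chirality targets
  chir_e <- function(x) {
    sum(apply(ce$chir, 1, function(row) {
      ids <- row[1:4]
      ca <- x[ids[1], ]
      V <- sum((x[ids[2], ] - ca) * vcross(x[ids[3], ] - ca, x[ids[4], ] - ca))
      (V - row[5])^2
    }))
  }
  xm <- x; xm[, 3] <- -xm[, 3]
  if (chir_e(xm) < chir_e(x)) x <- xm
  x
}

# extended-chain starting coordinates with ideal-ish local placement
init_extended <- function(topology) {
  at <- topology$atoms
  x <- matrix(0, nrow(at), 3)
  for (k in seq_along(topology$residues)) {
    ri <- topology$residues[k]
    ox <- (k - 1) * 3.6
    flip <- if (k %% 2 == 0) 1 else -1
    base <- c(ox, 0, 0)
    offs <- list(N = c(-1.2, 0.3 * flip, 0), HN = c(-1.4, 1.25 * flip, 0),
                 CA = c(0, 0, 0), HA = c(0.1, -0.4 * flip, 1.0),
                 CB = c(0.15, -1.0 * flip, -1.05),
                 HB = c(0.2, -1.7 * flip, -1.6),
                 SG = c(0.2, -2.2 * flip, -2.1),
                 CG = c(0.2, -2.1 * flip, -1.6), SD = c(0.3, -2.6 * flip, -3.1),
                 CE = c(0.4, -4.0 * flip, -3.6), C = c(1.3, 0.75 * flip, 0),
                 O = c(1.3, 1.95 * flip, 0.2))
    rows <- which(at$res == ri)
    for (i in rows) x[i, ] <- base + offs[[at$atom[i]]]
  }
  if (topology$metal) {
    # seed the metal at the sulfur centroid (or chain midpoint fallback)
    s_rows <- which(at$element == "S")
    m_row <- which(at$atom == "AG")
    x[m_row, ] <- if (length(s_rows)) colMeans(x[s_rows, , drop = FALSE]) + c(0, 0, 2)
                  else colMeans(x) + c(0, 0, 5)
  }
  x
}

#' Annealing schedule
#' @param n_stages number of perturb-and-quench stages after embedding.
#' @param perturb0 initial random displacement amplitude (Angstrom),
#'   decaying over the stages.
#' @param maxit L-BFGS iterations per stage.
#' @param final_maxit iterations of the final quenches.
#' @export
anneal_schedule <- function(n_stages = 8, perturb0 = 1.2, maxit = 150,
                            final_maxit = 400) {
  list(n_stages = n_stages, perturb0 = perturb0, maxit = maxit,
       final_maxit = final_maxit)
}

#' Restrained annealing of one conformer
#'
#' Seeded coordinate perturbations of decaying amplitude, each followed by
#' an L-BFGS quench of the combined geometry + restraint energy; sterics
#' are switched on after the first third of the schedule, and the run ends
#' with full-weight quenches (so the energy tail is monotone
#' nonincreasing). Identical inputs and seed give identical output.
#'
#' @param topology from [build_topology()].
#' @param restraints a [restraint_set()].
#' @param seed integer seed.
#' @param schedule an [anneal_schedule()].
#' @param x0 optional starting coordinates (defaults to an extended chain).
#' @param k_overrides optional named list overriding force constants.
#' @return a `conformer`: `xyz`, `topology`, `energy` decomposition
#'   (named vector summing to `total`).
#' @export
anneal <- function(topology, restraints, seed = 1,
                   schedule = anneal_schedule(), x0 = NULL,
                   k_overrides = list()) {
  k <- utils::modifyList(
    list(bond = 100, p13 = 30, chir = 10, rep = 20, noe = 5, hbond = 5,
         metal = 20, angle = 30, dihedral = 30, ncs = 0), k_overrides)
  ce <- compile_energy(topology, restraints, k)
  with_seed(seed, {
    n <- nrow(topology$atoms)
    if (is.null(x0)) {
      x <- embed_coords(ce, topology)
      # settle the embedded coordinates under soft geometry, sterics off
      for (wg in c(0.1, 0.3)) {
        obj <- make_objective(function(v) {
          e <- energy_eval(ce, matrix(v, n, 3), w_rep = 0, w_geom = wg)
          list(total = e$total, grad = as.numeric(e$grad))
        })
        opt <- stats::optim(as.numeric(x), obj$fn, obj$gr, method = "L-BFGS-B",
                            control = list(maxit = 2 * schedule$maxit))
        x <- matrix(opt$par, n, 3)
      }
    } else {
      x <- x0
    }
    if (topology$metal) {
      s_rows <- which(topology$atoms$element == "S")
      if (length(s_rows) >= 3) {
        x[which(topology$atoms$atom == "AG"), ] <- colMeans(x[s_rows, , drop = FALSE])
      }
    }
    S <- schedule$n_stages
    for (s in seq_len(S)) {
      frac <- s / S
      amp <- schedule$perturb0 * (1 - (s - 1) / S)^1.5
      x <- x + matrix(stats::rnorm(3 * n, sd = amp), n, 3)
      # geometry hardens and sterics switch on as the fold settles
      w_geom <- min(1, 0.3 + 0.7 * frac * 1.5)
      w_rep <- max(0, min(1, (frac - 0.3) / 0.4))
      obj <- make_objective(function(v) {
        e <- energy_eval(ce, matrix(v, n, 3), w_rep, w_geom = w_geom)
        list(total = e$total, grad = as.numeric(e$grad))
      })
      opt <- stats::optim(as.numeric(x), obj$fn, obj$gr, method = "L-BFGS-B",
                          control = list(maxit = schedule$maxit))
      x <- matrix(opt$par, n, 3)
    }
    for (q in 1:2) {
      obj <- make_objective(function(v) {
        e <- energy_eval(ce, matrix(v, n, 3), 1)
        list(total = e$total, grad = as.numeric(e$grad))
      })
      opt <- stats::optim(as.numeric(x), obj$fn, obj$gr, method = "L-BFGS-B",
                          control = list(maxit = schedule$final_maxit))
      x <- matrix(opt$par, n, 3)
    }
    ed <- energy_eval(ce, x, 1, decompose = TRUE)
    if (!is.finite(ed$total)) stop("non-finite energy after annealing")
    structure(list(xyz = x, topology = topology, energy = ed$comp,
                   total_energy = ed$total, seed = seed),
              class = "conformer")
  })
}

#' Anneal a pool of conformers with derived seeds
#' @param topology,restraints,schedule,k_overrides as [anneal()].
#' @param n_pool pool size.
#' @param seed base seed; conformer i uses `(seed + 7919 * i) mod 2^31-1`.
#' @export
anneal_pool <- function(topology, restraints, n_pool = 20, seed = 1,
                        schedule = anneal_schedule(), k_overrides = list()) {
  lapply(seq_len(n_pool), function(i) {
    si <- (as.integer(seed) + 7919L * i) %% 2147483647L
    anneal(topology, restraints, seed = si, schedule = schedule,
           k_overrides = k_overrides)
  })
}

#' Coupled two-form annealing under an NCS penalty
#'
#' The apo and metal-bound forms are refined simultaneously; every
#' superposition-update round, the bound form's coupled-segment backbone is
#' optimally superposed onto the apo form's and a harmonic inter-form
#' penalty (in the superposed frame) is added for those atoms. Free
#' segments feel no coupling.
#'
#' @param topology shared topology (built with `metal = TRUE` if the bound
#'   restraints reference the metal ion).
#' @param restraints_apo,restraints_bound restraint sets for the two forms.
#' @param ncs an [make_ncs_coupling()] (or `NULL` for independent control
#'   runs).
#' @param seed integer seed.
#' @param schedule an [anneal_schedule()].
#' @param n_superpose_rounds superposition updates per stage.
#' @return list of two conformers `apo`, `bound`, each with an `ncs`
#'   energy component (half the joint penalty).
#' @export
anneal_coupled <- function(topology, restraints_apo, restraints_bound,
                           ncs = NULL, seed = 1,
                           schedule = anneal_schedule(),
                           n_superpose_rounds = 3) {
  ceA <- compile_energy(topology, restraints_apo)
  ceB <- compile_energy(topology, restraints_bound)
  n <- nrow(topology$atoms)
  sel <- if (!is.null(ncs)) {
    unlist(lapply(ncs$residues, function(r)
      vapply(ncs$atoms, function(a) atom_index(topology, r, a), numeric(1))))
  } else integer(0)
  w_ncs <- if (!is.null(ncs)) ncs$weight else 0

  with_seed(seed, {
    xA <- init_extended(topology)
    xB <- xA + matrix(stats::rnorm(3 * n, sd = 0.1), n, 3)
    S <- schedule$n_stages
    joint_min <- function(xA, xB, w_rep, maxit) {
      for (rd in seq_len(n_superpose_rounds)) {
        if (length(sel) >= 3) {
          sup <- kabsch(xB[sel, , drop = FALSE], xA[sel, , drop = FALSE])
          R <- sup$rotation; tv <- sup$translation
        } else { R <- diag(3); tv <- c(0, 0, 0) }
        obj <- make_objective(function(v) {
          xa <- matrix(v[1:(3 * n)], n, 3); xb <- matrix(v[-(1:(3 * n))], n, 3)
          ea <- energy_eval(ceA, xa, w_rep)
          eb <- energy_eval(ceB, xb, w_rep)
          e <- ea$total + eb$total
          ga <- ea$grad; gb <- eb$grad
          if (length(sel)) {
            fitB <- sweep(xb[sel, , drop = FALSE] %*% t(R), 2, tv, "+")
            diff <- xa[sel, , drop = FALSE] - fitB
            e <- e + w_ncs * sum(diff^2)
            ga[sel, ] <- ga[sel, ] + 2 * w_ncs * diff
            gb[sel, ] <- gb[sel, ] - 2 * w_ncs * (diff %*% R)
          }
          list(total = e, grad = c(as.numeric(ga), as.numeric(gb)))
        })
        opt <- stats::optim(c(as.numeric(xA), as.numeric(xB)), obj$fn, obj$gr,
                            method = "L-BFGS-B",
                            control = list(maxit = ceiling(maxit / n_superpose_rounds)))
        xA <- matrix(opt$par[1:(3 * n)], n, 3)
        xB <- matrix(opt$par[-(1:(3 * n))], n, 3)
      }
      list(xA = xA, xB = xB)
    }
    for (s in seq_len(S)) {
      amp <- schedule$perturb0 * (1 - (s - 1) / S)^1.5
      xA <- xA + matrix(stats::rnorm(3 * n, sd = amp), n, 3)
      xB <- xB + matrix(stats::rnorm(3 * n, sd = amp), n, 3)
      w_rep <- if (s <= ceiling(S / 3)) 0 else min(1, (s - ceiling(S / 3)) / (S / 3))
      res <- joint_min(xA, xB, w_rep, schedule$maxit)
      xA <- res$xA; xB <- res$xB
    }
    res <- joint_min(xA, xB, 1, schedule$final_maxit)
    xA <- res$xA; xB <- res$xB

    ncs_e <- 0
    if (length(sel) >= 3) {
      sup <- kabsch(xB[sel, , drop = FALSE], xA[sel, , drop = FALSE])
      fitB <- sweep(xB[sel, , drop = FALSE] %*% t(sup$rotation), 2,
                    sup$translation, "+")
      ncs_e <- w_ncs * sum((xA[sel, , drop = FALSE] - fitB)^2)
    }
    mk <- function(x, ce) {
      ed <- energy_eval(ce, x, 1, decompose = TRUE)
      comp <- ed$comp
      comp["ncs"] <- ncs_e / 2
      structure(list(xyz = x, topology = topology, energy = comp,
                     total_energy = sum(comp), seed = seed),
                class = "conformer")
    }
    list(apo = mk(xA, ceA), bound = mk(xB, ceB))
  })
}

#' Average structure of an ensemble
#'
#' Superposes every model onto the first over `atom_selection` (default:
#' all atoms) and averages the coordinates — the usual single-structure
#' summary when an NMR ensemble is compared against one reference model.
#'
#' @param models list of conformers, or an `ensemble`.
#' @param atom_selection atom indices used for the superposition.
#' @return n x 3 coordinate matrix.
#' @export
average_structure <- function(models, atom_selection = NULL) {
  if (inherits(models, "ensemble")) models <- models$models
  stopifnot(length(models) >= 1)
  ref <- models[[1]]$xyz
  if (is.null(atom_selection)) atom_selection <- seq_len(nrow(ref))
  acc <- ref
  for (m in models[-1]) {
    sup <- kabsch(m$xyz[atom_selection, , drop = FALSE],
                  ref[atom_selection, , drop = FALSE])
    acc <- acc + sweep(m$xyz %*% t(sup$rotation), 2, sup$translation, "+")
  }
  acc / length(models)
}

#' Select the best conformers by combined energy and shift pseudo-energy
#'
#' Ranks a conformer pool by the sum of its energy decomposition plus a
#' chemical-shift pseudo-energy: the sum of squared (sigma-scaled)
#' differences between observed shifts and shifts back-calculated from the
#' conformer by `predictor`. With `predictor = NULL` the pseudo term is 0
#' and ranking is by energy alone. Ties break by conformer index.
#'
#' @param conformers list of conformers (e.g. from [anneal_pool()]).
#' @param observed_shifts a [shift_table] (S-form entries are used).
#' @param predictor `function(conformer) -> shift_table`, e.g.
#'   [default_shift_predictor()]; or `NULL`.
#' @param n_select ensemble size, default 10.
#' @param pseudo_weight multiplier on the pseudo-energy term.
#' @return an `ensemble`: `models` (selected conformers, pseudo energy
#'   filled into their decomposition), `scores` (full pool ranking).
#' @export
select_ensemble <- function(conformers, observed_shifts = NULL,
                            predictor = NULL, n_select = 10,
                            pseudo_weight = 1) {
  stopifnot(length(conformers) >= 1)
  if (n_select > length(conformers)) {
    warning("n_select exceeds pool size; returning all ", length(conformers))
    n_select <- length(conformers)
  }
  pseudo <- vapply(seq_along(conformers), function(i) {
    if (is.null(predictor) || is.null(observed_shifts)) return(0)
    pred <- predictor(conformers[[i]])
    obs <- as.data.frame(observed_shifts)
    obs <- obs[obs$form == "S", ]
    m <- merge(obs, as.data.frame(pred), by = c("residue_index", "atom"),
               suffixes = c("_obs", "_calc"))
    if (!nrow(m)) return(0)
    sig <- sigma_for_nucleus(m$nucleus_obs, c(H = 1, N = 10, C = 4))
    pseudo_weight * sum(((m$shift_obs - m$shift_calc) / sig)^2)
  }, numeric(1))
  etot <- vapply(conformers, function(cf) sum(cf$energy), numeric(1))
  score <- etot + pseudo
  ord <- order(score, seq_along(score))
  sel_idx <- ord[seq_len(n_select)]
  models <- lapply(sel_idx, function(i) {
    cf <- conformers[[i]]
    cf$energy["shift_pseudo"] <- pseudo[i]
    cf$total_energy <- sum(cf$energy)
    cf
  })
  structure(list(models = models,
                 scores = data.frame(conformer = seq_along(score),
                                     energy = etot, pseudo = pseudo,
                                     total = score)[ord, ],
                 selected = sel_idx),
            class = "ensemble")
}
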