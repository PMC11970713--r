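# Ground-truth generator: a miniature three-strand antiparallel beta-sheet
# with two loops whose tips meet at a trigonal tri-sulfur metal site
# (one methionine on the first loop, a Cys-Pro-X-Met knuckle on the
# second), mimicking the fold class of heavy-metal-binding domains.
# Every simulated observable carries its true origin in a side channel so
# the pipeline can be scored against ground truth.

#' Noise model for simulated NMR observables
#'
#' @param position_jitter per-nucleus peak-position jitter sd (ppm).
#' @param intensity_sdlog lognormal sd of simulated NOE intensities.
#' @param miss_prob probability that a real cross peak is absent.
#' @param decoy_rate inclusion probability for U-form decoy peaks.
#' @export
noise_model <- function(position_jitter = c(HN = 0.004, H = 0.004,
                                            N = 0.04, C = 0.05),
                        intensity_sdlog = 0.3, miss_prob = 0.05,
                        decoy_rate = 0.5) {
  stopifnot(all(position_jitter >= 0), intensity_sdlog >= 0,
            miss_prob >= 0, miss_prob <= 1, decoy_rate >= 0, decoy_rate <= 1)
  structure(list(position_jitter = position_jitter,
                 intensity_sdlog = intensity_sdlog,
                 miss_prob = miss_prob, decoy_rate = decoy_rate),
            class = "noise_model")
}

zero_noise <- function() noise_model(position_jitter = c(HN = 0, H = 0, N = 0, C = 0),
                                     intensity_sdlog = 0, miss_prob = 0,
                                     decoy_rate = 0)

# interior points of an arc from p0 to p1 bulging toward `dir`, spaced so
# consecutive points sit ~`spacing` apart (quadratic bezier, apex height
# solved to give the required path length)
arc_points <- function(p0, p1, n_mid, dir, spacing = 3.8) {
  need <- (n_mid + 1) * spacing
  dir <- dir / sqrt(sum(dir^2))
  mid <- (p0 + p1) / 2
  bez_len <- function(h) {
    cp <- mid + h * dir
    tt <- seq(0, 1, length.out = 200)
    pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), cp) + outer(tt^2, p1)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  h <- stats::uniroot(function(h) bez_len(h) - need, c(0.01, 60))$root
  cp <- mid + h * dir
  tt <- seq(0, 1, length.out = 400)
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), cp) + outer(tt^2, p1)
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  want <- cum[length(cum)] * seq_len(n_mid) / (n_mid + 1)
  t(vapply(want, function(w) pts[which.min(abs(cum - w)), ], numeric(3)))
}

# relax full-atom coordinates against ideal covalent geometry plus point
# pins (CA trace, site sulfurs, sheet hydrogen bonds)
relax_to_pins <- function(topology, x0, pins, hbond_pairs, seed,
                          maxit = 400) {
  ce <- compile_energy(topology, restraint_set())
  n <- nrow(x0)
  pin_idx <- pins$idx; pin_xyz <- as.matrix(pins[, c("x", "y", "z")])
  pin_k <- pins$k
  hb <- hbond_pairs
  eval_fn <- function(w_rep, pin_scale = 1) {
    function(v) {
      x <- matrix(v, n, 3)
      e <- energy_eval(ce, x, w_rep)
      tot <- e$total; g <- e$grad
      kk <- ifelse(pins$soften, pin_scale, 1) * pin_k
      dv <- x[pin_idx, , drop = FALSE] - pin_xyz
      tot <- tot + sum(kk * rowSums(dv^2))
      g[pin_idx, ] <- g[pin_idx, ] + 2 * kk * dv
      if (nrow(hb)) {
        dvh <- x[hb$ia, , drop = FALSE] - x[hb$ib, , drop = FALSE]
        d <- sqrt(rowSums(dvh^2))
        tot <- tot + sum(hb$k * (d - hb$target)^2)
        coef <- 2 * hb$k * (d - hb$target) / pmax(d, 1e-8)
        g <- pair_grad_accum(g, hb$ia, hb$ib, coef, dvh)
      }
      list(total = tot, grad = as.numeric(g))
    }
  }
  with_seed(seed, {
    x <- x0 + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
    # design pins shape the fold, then soften so covalent geometry
    # settles near-ideal (pair terms keep the site and sheet in place)
    stages <- list(c(0, 1), c(0.5, 1), c(1, 1), c(1, 0.1), c(1, 0.02))
    for (st in stages) {
      obj <- make_objective(eval_fn(st[1], st[2]))
      opt <- stats::optim(as.numeric(x), obj$fn, obj$gr, method = "L-BFGS-B",
                          control = list(maxit = maxit))
      x <- matrix(opt$par, n, 3)
    }
    x
  })
}

#' Generate the toy ground-truth fold
#'
#' Builds a miniature domain: two-residue N-tail, strand beta1 (middle of
#' the sheet), a six-residue loop carrying a methionine, a two-residue
#' strand beta2, a seven-residue loop with a Cys-Pro-X-Met knuckle, strand
#' beta3 paired antiparallel with beta1, and a one-residue C-tail. The
#' three site sulfurs (loop-1 Met SD, knuckle Cys SG and Met SD) are placed
#' as a near-trigonal cluster at the tip where the two loops meet: pairwise
#' S-S distances fall in [3.8, 4.2] Angstrom in the apo form and relax to
#' ideal trigonal geometry around the silver ion in the bound form, whose
#' loops are displaced by ~1.5 Angstrom.
#'
#' @param n_strand_residues residues per long strand (total size
#'   `18 + 2n` must lie in [15, 40]).
#' @param seed integer seed (fixes the fold and all derived offsets).
#' @return a `toy_truth` object: sequence, topologies (apo and bound),
#'   ground-truth coordinates `xyz_apo`/`xyz_bound`, site residue/atom
#'   table, secondary-structure labels, sheet pairing, metal position.
#' @export
make_toy_fold <- function(n_strand_residues = 6, seed = 1) {
  n <- n_strand_residues
  total <- 18L + 2L * n
  if (total < 15 || total > 40) stop("total residue count ", total,
                                     " outside supported range [15, 40]")
  s1_pat <- c("K", "T", "V", "T", "I", "R", "E", "L", "F", "T", "V")
  s3_pat <- c("E", "T", "V", "I", "V", "K", "T", "L", "Y", "T", "I")
  seqv <- c("G", "S", s1_pat[1:n], c("G", "D", "A", "M", "G", "S"),
            c("R", "Q"), c("G", "C", "P", "A", "M", "G", "L"),
            s3_pat[1:n], "K")
  sequence <- paste(seqv, collapse = "")
  regions <- list(tail1 = 1:2, s1 = 2L + 1:n, l1 = 2L + n + 1:6,
                  s2 = 8L + n + 1:2, l2 = 10L + n + 1:7,
                  s3 = 17L + n + 1:n, tail2 = total)
  site <- c(regions$l1[4], regions$l2[2], regions$l2[5])  # M, C, M
  site_atoms <- data.frame(res = site, atom = c("SD", "SG", "SD"),
                           attached = c("CE", "CB", "CE"),
                           stringsAsFactors = FALSE)
  ss <- rep("loop", total)
  ss[c(regions$s1, regions$s2, regions$s3)] <- "strand"

  top_y <- (n - 1) * 3.4
  ca <- matrix(NA_real_, total, 3)
  ca[regions$s1, ] <- cbind(0, (seq_len(n) - 1) * 3.4, 0)
  ca[regions$s2, ] <- cbind(-4.8, top_y - (0:1) * 3.4, 0)
  ca[regions$s3, ] <- cbind(4.8, top_y - (seq_len(n) - 1) * 3.4, 0)
  ca[regions$tail1, ] <- rbind(c(1.2, -6.6, 1.2), c(0.4, -3.4, 0.7))
  ca[regions$tail2, ] <- c(5.6, top_y - (n - 1) * 3.4 - 3.6, 0.6)
  ca[regions$l1, ] <- arc_points(c(0, top_y, 0), c(-4.8, top_y, 0), 6,
                                 c(0.15, 0.72, 0.60))
  ca[regions$l2, ] <- arc_points(c(-4.8, top_y - 3.4, 0), c(4.8, top_y, 0), 7,
                                 c(-0.05, 0.62, 0.72))

  site_center <- c(-0.4, top_y + 7.0, 4.4)
  tri <- function(center, side) {
    r <- side / sqrt(3)
    e1 <- c(1, 0, 0); e2 <- c(0, 0.45, 0.89); e2 <- e2 / sqrt(sum(e2^2))
    t(vapply(c(90, 210, 330), function(a) {
      center + r * (cos(a * pi / 180) * e1 + sin(a * pi / 180) * e2)
    }, numeric(3)))
  }

  restraint_refs <- c(atom_ref(site_atoms$res, site_atoms$atom),
                      atom_ref(site_atoms$res, site_atoms$attached))
  topo <- build_topology(sequence, restraint_refs)
  topo_bound <- build_topology(sequence, restraint_refs, metal = TRUE)

  # initial full-atom placement around the CA trace
  place_atoms <- function(topology, ca) {
    at <- topology$atoms
    x <- matrix(0, nrow(at), 3)
    for (k in seq_len(total)) {
      prev <- ca[max(1, k - 1), ]; nxt <- ca[min(total, k + 1), ]
      e <- nxt - prev; e <- e / max(sqrt(sum(e^2)), 1e-6)
      up <- c(0, 0, 1)
      perp <- vcross(e, up); perp <- perp / max(sqrt(sum(perp^2)), 1e-6)
      flip <- if (k %% 2 == 0) 1 else -1
      offs <- list(N = -1.2 * e + 0.45 * perp * flip,
                   HN = -1.6 * e + 1.3 * perp * flip,
                   CA = c(0, 0, 0), HA = 0.4 * perp * -flip + c(0, 0, 0.9),
                   CB = 1.0 * perp * -flip + c(0, 0, -1.0),
                   HB = 1.7 * perp * -flip + c(0, 0, -1.4),
                   SG = 2.2 * perp * -flip + c(0, 0, -1.6),
                   CG = 2.0 * perp * -flip + c(0, 0, -1.5),
                   SD = 2.8 * perp * -flip + c(0, 0, -2.3),
                   CE = 4.0 * perp * -flip + c(0, 0, -2.6),
                   C = 1.25 * e + 0.45 * perp * flip,
                   O = 1.3 * e + 1.6 * perp * flip)
      for (i in which(at$res == k)) x[i, ] <- ca[k, ] + offs[[at$atom[i]]]
    }
    x
  }

  pins_for <- function(topology, ca, s_targets, metal_target = NULL) {
    idx <- vapply(seq_len(total), function(r) atom_index(topology, r, "CA"),
                  numeric(1))
    # loops stay soft so they can flex to carry the sulfurs to the site;
    # CA trace pins soften in the final idealization stages, the site
    # pins do not
    ca_k <- ifelse(seq_len(total) %in% c(regions$l1, regions$l2), 0.3, 2)
    pins <- data.frame(idx = idx, x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       k = ca_k, soften = TRUE)
    s_idx <- vapply(seq_len(3), function(i)
      atom_index(topology, site_atoms$res[i], site_atoms$atom[i]), numeric(1))
    pins <- rbind(pins, data.frame(idx = s_idx, x = s_targets[, 1],
                                   y = s_targets[, 2], z = s_targets[, 3],
                                   k = 60, soften = FALSE))
    if (!is.null(metal_target)) {
      m_idx <- atom_index(topology, 0, "AG")
      pins <- rbind(pins, data.frame(idx = m_idx, x = metal_target[1],
                                     y = metal_target[2], z = metal_target[3],
                                     k = 25, soften = FALSE))
    }
    pins
  }

  hb_pairs_for <- function(topology) {
    # antiparallel registry: beta1 with beta3 over the full strand length,
    # beta1's top two residues with beta2; alternate pairs hydrogen bonded
    pairs <- list()
    s1 <- regions$s1; s3 <- rev(regions$s3); s2 <- rev(regions$s2)
    reg <- rbind(data.frame(i = s1, j = s3),
                 data.frame(i = s1[(n - 1):n], j = s2))
    hb <- list()
    for (r in seq_len(nrow(reg))) {
      if (r %% 2 == 1) next  # alternating registry
      i <- reg$i[r]; j <- reg$j[r]
      for (pr in list(c(i, j), c(j, i))) {
        hn <- tryCatch(atom_index(topology, pr[1], "HN"), error = function(e) NA)
        o <- tryCatch(atom_index(topology, pr[2], "O"), error = function(e) NA)
        if (!is.na(hn) && !is.na(o)) {
          hb[[length(hb) + 1]] <- data.frame(ia = hn, ib = o, target = 1.95,
                                             k = 10)
        }
      }
    }
    if (length(hb)) do.call(rbind, hb) else
      data.frame(ia = integer(0), ib = integer(0), target = numeric(0),
                 k = numeric(0))
  }

  # direct S-S pair terms keep the triangle side lengths exact even where
  # the absolute-position pins fight the covalent attachment
  ss_pairs_for <- function(topology, side) {
    s_idx <- vapply(seq_len(3), function(i)
      atom_index(topology, site_atoms$res[i], site_atoms$atom[i]), numeric(1))
    cmb <- utils::combn(3, 2)
    data.frame(ia = s_idx[cmb[1, ]], ib = s_idx[cmb[2, ]], target = side,
               k = 150)
  }

  s_tri_apo <- tri(site_center, 4.05)
  xyz_apo <- relax_to_pins(topo, place_atoms(topo, ca),
                           pins_for(topo, ca, s_tri_apo),
                           rbind(hb_pairs_for(topo), ss_pairs_for(topo, 4.05)),
                           seed = seed)

  # bound form: loops carry the sulfurs to an ideal trigonal site around
  # the metal, displacing the site center
  bound_center <- site_center + c(0.4, 1.0, 1.0)
  s_tri_bound <- tri(bound_center, 2 * 2.3 * sin(pi / 3))
  x0_bound <- place_atoms(topo_bound, ca)
  x0_bound[atom_index(topo_bound, 0, "AG"), ] <- bound_center
  xyz_bound <- relax_to_pins(topo_bound, x0_bound,
                             pins_for(topo_bound, ca, s_tri_bound, bound_center),
                             rbind(hb_pairs_for(topo_bound),
                                   ss_pairs_for(topo_bound, 2 * 2.3 * sin(pi / 3))),
                             seed = seed + 1L)

  s_idx <- vapply(seq_len(3), function(i)
    atom_index(topo, site_atoms$res[i], site_atoms$atom[i]), numeric(1))
  ss_d <- as.numeric(stats::dist(xyz_apo[s_idx, ]))
  if (any(ss_d < 3.8 | ss_d > 4.2)) {
    stop("toy site construction failed: S-S distances ",
         paste(sprintf("%.2f", ss_d), collapse = ", "))
  }

  # deterministic per-(residue, atom) tertiary-dispersion offsets for the
  # structured form, and small offsets for the unstructured form
  disp_sd <- c(HN = 0.35, N = 2.5, HA = 0.30, CA = 0.8, C = 0.8, HB = 0.25,
               CB = 0.8)
  u_sd <- c(HN = 0.03, N = 0.25, HA = 0.02, CA = 0.10, C = 0.10, HB = 0.02,
            CB = 0.10)
  na <- length(SHIFT_ATOMS)
  disp <- with_seed(seed + 101L, {
    m <- matrix(stats::rnorm(total * na), total, na,
                dimnames = list(NULL, SHIFT_ATOMS))
    sweep(m, 2, disp_sd[SHIFT_ATOMS], "*")
  })
  u_disp <- with_seed(seed + 102L, {
    m <- matrix(stats::rnorm(total * na), total, na,
                dimnames = list(NULL, SHIFT_ATOMS))
    sweep(m, 2, u_sd[SHIFT_ATOMS], "*")
  })
  csp_sign <- with_seed(seed + 103L, sample(c(-1, 1), total, replace = TRUE))

  structure(list(sequence = sequence, n_residues = total, regions = regions,
                 site_residues = site, site_atoms = site_atoms, ss = ss,
                 topology = topo, topology_bound = topo_bound,
                 xyz_apo = xyz_apo, xyz_bound = xyz_bound,
                 metal_position = xyz_bound[atom_index(topo_bound, 0, "AG"), ],
                 disp = disp, u_disp = u_disp, csp_sign = csp_sign,
                 seed = seed, n_strand_residues = n),
            class = "toy_truth")
}

# true (noise-free) shift value for one residue/atom
true_shift <- function(truth, res, atom, form = "S", state = "apo") {
  rt <- strsplit(truth$sequence, "")[[1]][res]
  v <- coil_shift(rt, atom)
  if (is.na(v)) return(NA_real_)
  if (form == "U") return(v + truth$u_disp[res, atom])
  v <- v + truth$disp[res, atom]
  if (truth$ss[res] == "strand") v <- v + STRAND_OFFSETS[atom]
  if (state == "bound") {
    csp <- c(HN = 0.30, N = 1.8, HA = 0.20, CA = 1.0, C = 0.8, HB = 0.25,
             CB = 1.2)
    drift <- c(HN = 0.015, N = 0.10, HA = 0.010, CA = 0.05, C = 0.05,
               HB = 0.010, CB = 0.05)
    if (res %in% truth$site_residues) {
      v <- v + truth$csp_sign[res] * csp[atom]
    } else if (any(abs(res - truth$site_residues) == 1)) {
      v <- v + truth$csp_sign[res] * 0.3 * csp[atom]
    } else {
      v <- v + truth$csp_sign[res] * drift[atom]
    }
  }
  unname(v)
}

#' Simulate assigned chemical shifts for the toy system
#'
#' U-form entries are random-coil values plus a small fixed per-residue
#' offset (low dispersion, as for an unstructured chain); S-form entries
#' add beta-strand offsets and a deterministic tertiary-dispersion term.
#' In the bound state, site residues receive large shift perturbations,
#' their sequence neighbours moderate ones, everything else a small drift.
#'
#' @param truth a [make_toy_fold()] object.
#' @param forms which forms to emit (`"S"`, `"U"` or both).
#' @param state `"apo"` or `"bound"`.
#' @param noise a [noise_model()]; the per-nucleus position jitter (halved,
#'   as assigned shifts average several observations) perturbs each entry.
#' @param seed seed for the measurement jitter.
#' @return a [shift_table].
#' @export
simulate_shifts <- function(truth, forms = c("S", "U"), state = "apo",
                            noise = noise_model(), seed = truth$seed + 7L) {
  rows <- list()
  seqv <- strsplit(truth$sequence, "")[[1]]
  for (form in forms) {
    for (res in seq_len(truth$n_residues)) {
      for (a in SHIFT_ATOMS) {
        v <- true_shift(truth, res, a, form, state)
        if (is.na(v)) next
        rows[[length(rows) + 1]] <- data.frame(
          residue_index = res, residue_type = seqv[res], atom = a,
          shift = v, form = form, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  jit_sd <- vapply(df$atom, function(a) {
    nuc <- nucleus_of(a)
    key <- if (nuc %in% names(noise$position_jitter)) nuc else
      if (nuc %in% c("H", "HN")) "H" else if (nuc == "Cprime") "C" else nuc
    unname(noise$position_jitter[key])
  }, numeric(1))
  df$shift <- df$shift + with_seed(seed, stats::rnorm(nrow(df), sd = jit_sd / 2))
  shift_table(df)
}

# protons available for NOESY simulation (HN, HA and the beta
# pseudo-proton of every residue)
noesy_protons <- function(truth) {
  at <- truth$topology$atoms
  at[at$atom %in% c("HN", "HA", "HB"), c("res", "atom")]
}

#' Simulate NOESY peak lists from the toy structure
#'
#' Emits a 3D 15N-edited list (dims HN, N, H: every directed pair whose
#' origin proton is an amide) and a 3D 13C-edited list (dims H, C, H:
#' directed pairs whose origin proton is carbon-attached, HA or HB, with
#' the attached-carbon shift in the second dimension), for all proton
#' pairs closer than `cutoff` in the S-form structure. Intensities follow
#' k * r^-6 with lognormal noise; positions are true shifts plus
#' per-nucleus jitter; real peaks drop out with the miss probability; decoy
#' peaks from the unstructured form (intra-residue and sequential pairs at
#' U-form positions) are added at the decoy rate.
#'
#' @param truth a [make_toy_fold()] result.
#' @param cutoff distance cutoff (Angstrom), default 5.0.
#' @param noise a [noise_model()].
#' @param seed seed for all stochastic parts.
#' @param state structure used for distances (`"apo"` or `"bound"`).
#' @return list with `peaks` (named list of [peak_list]s: `n15`, `c13`) and
#'   `truth_map` (per peak: true atoms, form, decoy flag) -- the side
#'   channel, never consumed by the pipeline under test.
#' @export
simulate_noesy <- function(truth, cutoff = 5.0, noise = noise_model(),
                           seed = truth$seed + 11L, state = "apo") {
  xyz <- if (state == "bound") truth$xyz_bound else truth$xyz_apo
  topo <- if (state == "bound") truth$topology_bound else truth$topology
  pr <- noesy_protons(truth)
  idx <- vapply(seq_len(nrow(pr)), function(i)
    atom_index(topo, pr$res[i], pr$atom[i]), numeric(1))
  np <- nrow(pr)
  with_seed(seed, {
    jit <- function(nuc, n) stats::rnorm(n, sd = {
      key <- if (nuc %in% names(noise$position_jitter)) nuc else
        if (nuc == "Cprime") "C" else "H"
      noise$position_jitter[key]
    })
    rows_n15 <- list(); rows_c13 <- list(); tmap <- list()
    for (i in seq_len(np)) {
      heavy <- ATTACHED_HEAVY[pr$atom[i]]
      for (j in seq_len(np)) {
        if (i == j) next
        r <- sqrt(sum((xyz[idx[i], ] - xyz[idx[j], ])^2))
        if (r >= cutoff) next
        if (stats::runif(1) < noise$miss_prob) next
        inten <- r^-6 * exp(stats::rnorm(1, sd = noise$intensity_sdlog))
        h_orig <- true_shift(truth, pr$res[i], pr$atom[i], "S", state)
        hv_orig <- true_shift(truth, pr$res[i], heavy, "S", state)
        h_dest <- true_shift(truth, pr$res[j], pr$atom[j], "S", state)
        if (anyNA(c(h_orig, hv_orig, h_dest))) next
        if (pr$atom[i] == "HN") {
          w <- c(h_orig + jit("HN", 1), hv_orig + jit("N", 1),
                 h_dest + jit("H", 1))
          rows_n15[[length(rows_n15) + 1]] <- c(w, inten)
          ln <- "n15"
        } else {
          w <- c(h_orig + jit("H", 1), hv_orig + jit("C", 1),
                 h_dest + jit("H", 1))
          rows_c13[[length(rows_c13) + 1]] <- c(w, inten)
          ln <- "c13"
        }
        tmap[[length(tmap) + 1]] <- data.frame(
          list_name = ln, res_a = pr$res[i], atom_a = pr$atom[i],
          res_b = pr$res[j], atom_b = pr$atom[j], form = "S",
          is_decoy = FALSE, r = r, stringsAsFactors = FALSE)
      }
    }
    # U-form decoys: intra-residue and sequential contacts of a random coil
    decoy_defs <- list()
    for (res in seq_len(truth$n_residues)) {
      decoy_defs[[length(decoy_defs) + 1]] <- c(res, "HN", res, "HA", 2.6)
      if (res > 1) {
        decoy_defs[[length(decoy_defs) + 1]] <- c(res, "HN", res - 1, "HA", 2.4)
        decoy_defs[[length(decoy_defs) + 1]] <- c(res, "HN", res - 1, "HN", 3.3)
      }
    }
    for (dd in decoy_defs) {
      if (stats::runif(1) >= noise$decoy_rate) next
      ra <- as.integer(dd[1]); rb <- as.integer(dd[3]); rr <- as.numeric(dd[5])
      wa <- true_shift(truth, ra, "HN", "U", "apo")
      wn <- true_shift(truth, ra, "N", "U", "apo")
      wb <- true_shift(truth, rb, dd[4], "U", "apo")
      if (anyNA(c(wa, wn, wb))) next
      inten <- rr^-6 * exp(stats::rnorm(1, sd = noise$intensity_sdlog)) * 2
      rows_n15[[length(rows_n15) + 1]] <-
        c(wa + jit("HN", 1), wn + jit("N", 1), wb + jit("H", 1), inten)
      tmap[[length(tmap) + 1]] <- data.frame(
        list_name = "n15", res_a = ra, atom_a = "HN", res_b = rb,
        atom_b = dd[4], form = "U", is_decoy = TRUE, r = rr,
        stringsAsFactors = FALSE)
    }
    m_n15 <- do.call(rbind, rows_n15)
    m_c13 <- if (length(rows_c13)) do.call(rbind, rows_c13) else NULL
    tm <- do.call(rbind, tmap)
    tm$peak_id <- NA_character_
    pk_n15 <- peak_list(m_n15[, 1:3, drop = FALSE], c("HN", "N", "H"),
                        m_n15[, 4], sprintf("n15_%04d", seq_len(nrow(m_n15))))
    tm$peak_id[tm$list_name == "n15"] <- pk_n15$peak_id
    peaks <- list(n15 = pk_n15)
    if (!is.null(m_c13)) {
      pk_c13 <- peak_list(m_c13[, 1:3, drop = FALSE], c("H", "C", "H"),
                          m_c13[, 4], sprintf("c13_%04d", seq_len(nrow(m_c13))))
      tm$peak_id[tm$list_name == "c13"] <- pk_c13$peak_id
      peaks$c13 <- pk_c13
    }
    list(peaks = peaks, truth_map = tm)
  })
}

#' Simulate TALOS-style backbone dihedral predictions from the toy truth
#'
#' Phi/psi angles measured in the ground-truth structure plus prediction
#' noise; core residues are classified `Strong` (spread 10 deg for
#' strands, 15 deg for loops), chain termini `Dyn` (and therefore ignored
#' by restraint generation).
#'
#' @param truth a [make_toy_fold()] result.
#' @param seed seed for prediction noise.
#' @param state `"apo"` or `"bound"`.
#' @return data.frame in the layout of [parse_dihedral_predictions()].
#' @export
simulate_dihedral_predictions <- function(truth, seed = truth$seed + 31L,
                                          state = "apo") {
  topo <- if (state == "bound") truth$topology_bound else truth$topology
  xyz <- if (state == "bound") truth$xyz_bound else truth$xyz_apo
  seqv <- strsplit(truth$sequence, "")[[1]]
  core <- 3:(truth$n_residues - 2L)
  gx <- function(r, a) xyz[atom_index(topo, r, a), ]
  with_seed(seed, {
    rows <- list()
    for (r in 2:(truth$n_residues - 1L)) {
      spread <- if (truth$ss[r] == "strand") 10 else 15
      cls <- if (r %in% core) "Strong" else "Dyn"
      phi <- dihedral_angle(gx(r - 1, "C"), gx(r, "N"), gx(r, "CA"),
                            gx(r, "C")) * 180 / pi
      psi <- dihedral_angle(gx(r, "N"), gx(r, "CA"), gx(r, "C"),
                            gx(r + 1, "N")) * 180 / pi
      for (ang in c("phi", "psi")) {
        v <- wrap_deg((if (ang == "phi") phi else psi) +
                        stats::rnorm(1, sd = spread / 4))
        rows[[length(rows) + 1]] <- data.frame(
          residue_index = r, residue_type = seqv[r], angle = ang,
          value = v, spread = spread, class = cls, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate per-residue beta-strand probabilities
#'
#' Mimics the output of shift-based secondary-structure prediction:
#' strand residues of the toy fold get high probabilities, everything
#' else low, with seeded jitter.
#'
#' @param truth a [make_toy_fold()] result.
#' @param seed seed for the jitter.
#' @return named numeric vector (names = residue indices), values in [0, 1].
#' @export
simulate_beta_probabilities <- function(truth, seed = truth$seed + 41L) {
  with_seed(seed, {
    p <- ifelse(truth$ss == "strand",
                stats::runif(truth$n_residues, 0.82, 0.97),
                stats::runif(truth$n_residues, 0.02, 0.30))
    stats::setNames(p, seq_len(truth$n_residues))
  })
}

#' Simulate a metal-titration HSQC series
#'
#' Single-site stoichiometric binding at dissociation constant `kd` sets
#' the bound fraction at each molar ratio. Non-site S-form peaks drift
#' linearly with bound fraction (fast exchange); site-residue peaks are
#' absent while the bound fraction is inside the intermediate-exchange
#' dropout window and reappear at perturbed positions near saturation;
#' U-form peak intensities scale with the unbound fraction (the
#' unstructured form converts to the structured form upon binding).
#'
#' @param truth a [make_toy_fold()] result.
#' @param ratios molar ratios, ordered, starting at 0.
#' @param kd dissociation constant in protein-concentration units
#'   (protein total = 1), default 0.005 (tight binding).
#' @param noise a [noise_model()].
#' @param seed seed.
#' @param dropout bound-fraction window of intermediate-exchange dropout.
#' @return a [titration_series] with attribute `ground_truth` (site
#'   residues, bound fractions, per-point residue maps).
#' @export
simulate_titration <- function(truth, ratios = c(0, 0.125, 0.25, 0.5, 0.75, 1, 1.2),
                               kd = 0.005, noise = noise_model(),
                               seed = truth$seed + 23L,
                               dropout = c(0.2, 0.8)) {
  if (!0 %in% ratios) stop("titration ratios must include 0 (apo reference)")
  if (is.unsorted(ratios)) stop("ratios must be ordered")
  seqv <- strsplit(truth$sequence, "")[[1]]
  amide <- which(seqv != "P")
  fb_of <- function(ratio) {
    P <- 1; L <- ratio * P
    ((P + L + kd) - sqrt((P + L + kd)^2 - 4 * P * L)) / (2 * P)
  }
  with_seed(seed, {
    points <- list()
    maps <- list()
    for (pi in seq_along(ratios)) {
      fb <- fb_of(ratios[pi])
      rows <- list(); map <- list()
      for (res in amide) {
        a_hn <- true_shift(truth, res, "HN", "S", "apo")
        a_n <- true_shift(truth, res, "N", "S", "apo")
        b_hn <- true_shift(truth, res, "HN", "S", "bound")
        b_n <- true_shift(truth, res, "N", "S", "bound")
        is_site <- res %in% truth$site_residues
        if (is_site && fb > dropout[1] && fb < dropout[2]) next
        w <- c(a_hn + fb * (b_hn - a_hn), a_n + fb * (b_n - a_n)) +
          stats::rnorm(2, sd = noise$position_jitter[c("HN", "N")])
        rows[[length(rows) + 1]] <- c(w, 1 + fb)
        map[[length(map) + 1]] <- data.frame(res = res, form = "S")
      }
      u_scale <- 1 - fb
      if (u_scale > 0.02) {
        for (res in amide) {
          w <- c(true_shift(truth, res, "HN", "U", "apo"),
                 true_shift(truth, res, "N", "U", "apo")) +
            stats::rnorm(2, sd = noise$position_jitter[c("HN", "N")])
          rows[[length(rows) + 1]] <- c(w, 2 * u_scale)
          map[[length(map) + 1]] <- data.frame(res = res, form = "U")
        }
      }
      m <- do.call(rbind, rows)
      points[[pi]] <- list(
        ratio = ratios[pi],
        peaks = peak_list(m[, 1:2, drop = FALSE], c("HN", "N"), m[, 3],
                          sprintf("t%02d_%04d", pi, seq_len(nrow(m)))))
      maps[[pi]] <- do.call(rbind, map)
    }
    ser <- titration_series(points)
    attr(ser, "ground_truth") <- list(site_residues = truth$site_residues,
                                      bound_fraction = vapply(ratios, fb_of, numeric(1)),
                                      residue_maps = maps)
    ser
  })
}
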