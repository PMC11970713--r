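# Typed restraints and their potentials.
#
# Distance restraints carry absolute lower/upper bounds (a square well) and
# an ambiguous member-pair set evaluated through the r^-6 effective
# distance. Atom references are "residue:atom" with construct numbering;
# the metal ion is residue 0, atom AG.

#' Build "residue:atom" references
#' @param res residue index (0 = metal ion).
#' @param atom atom name.
#' @export
atom_ref <- function(res, atom) paste0(res, ":", toupper(atom))

split_atom_ref <- function(ref) {
  parts <- strsplit(ref, ":", fixed = TRUE)
  data.frame(res = as.integer(vapply(parts, `[`, "", 1)),
             atom = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Create a distance restraint
#'
#' @param pairs data.frame with columns `res_a`, `atom_a`, `res_b`,
#'   `atom_b`; more than one row makes the restraint ambiguous (satisfied
#'   through the r^-6-summed effective distance).
#' @param target,lower,upper target distance and well bounds (Angstrom).
#' @param kind one of `noe`, `hbond`, `metal_bond`, `metal_implicit`.
#' @param weight force-constant multiplier.
#' @param peak_id optional provenance tag.
#' @export
distance_restraint <- function(pairs, target, lower, upper,
                               kind = "noe", weight = 1, peak_id = NA_character_) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("res_a", "atom_a", "res_b", "atom_b") %in% names(pairs)))
  if (!(lower <= target && target <= upper)) stop("need lower <= target <= upper")
  pairs$atom_a <- toupper(pairs$atom_a)
  pairs$atom_b <- toupper(pairs$atom_b)
  structure(list(pairs = pairs, target = target, lower = lower, upper = upper,
                 kind = kind, weight = weight, peak_id = peak_id),
            class = "distance_restraint")
}

#' Create an angle restraint (three atoms, degrees)
#' @param atoms data.frame with one row per atom (columns `res`, `atom`),
#'   vertex atom second.
#' @param target,halfwidth target angle and flat halfwidth (degrees).
#' @param kind `metal_bond_angle` or `metal_ligand_angle`.
#' @param weight force-constant multiplier.
#' @export
angle_restraint <- function(atoms, target, halfwidth = 5, kind = "metal_bond_angle",
                            weight = 1) {
  stopifnot(nrow(atoms) == 3)
  if (!(target > 0 && target <= 180)) stop("angle target must be in (0, 180]")
  atoms$atom <- toupper(atoms$atom)
  structure(list(atoms = atoms, target = target, halfwidth = halfwidth,
                 kind = kind, weight = weight),
            class = "angle_restraint")
}

#' Create a backbone dihedral restraint
#' @param residue_index residue carrying the angle.
#' @param angle_name `"phi"` or `"psi"`.
#' @param target target angle (degrees).
#' @param halfwidth flat square-well halfwidth (degrees), > 0.
#' @param weight force-constant multiplier.
#' @export
dihedral_restraint <- function(residue_index, angle_name, target, halfwidth,
                               weight = 1) {
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  stopifnot(angle_name %in% c("phi", "psi"))
  structure(list(residue_index = as.integer(residue_index),
                 angle_name = angle_name, target = target,
                 halfwidth = halfwidth, weight = weight),
            class = "dihedral_restraint")
}

#' Bundle restraints into a set
#' @param distance,angle,dihedral lists of the respective restraint objects.
#' @param ncs optional [make_ncs_coupling()] object.
#' @export
restraint_set <- function(distance = list(), angle = list(), dihedral = list(),
                          ncs = NULL) {
  structure(list(distance = distance, angle = angle, dihedral = dihedral,
                 ncs = ncs),
            class = "restraint_set")
}

#' Merge restraint sets
#' @param ... restraint sets.
#' @export
merge_restraints <- function(...) {
  sets <- list(...)
  restraint_set(
    distance = do.call(c, lapply(sets, `[[`, "distance")),
    angle = do.call(c, lapply(sets, `[[`, "angle")),
    dihedral = do.call(c, lapply(sets, `[[`, "dihedral")),
    ncs = Reduce(function(a, b) a %||% b, lapply(sets, `[[`, "ncs")))
}

#' Calibrate a NOE intensity into a target distance
#'
#' d = d_max * (I / I_min)^(-1/6), so the weakest peak in the set maps to
#' the maximum target distance and stronger peaks to shorter distances.
#' The square well spans target +/- 0.33 * target.
#'
#' @param intensity peak intensity (same arbitrary units as `i_min`).
#' @param i_min smallest intensity observed in the peak set.
#' @param d_max maximum target distance (Angstrom), default 4.25.
#' @param flat_frac relative flat width of the well, default 0.33.
#' @return list `target`, `lower`, `upper` (vectorized over `intensity`).
#' @export
calibrate_noe_distance <- function(intensity, i_min, d_max = 4.25,
                                   flat_frac = 0.33) {
  stopifnot(i_min > 0, d_max > 0)
  if (any(intensity < i_min)) {
    warning("intensity below i_min clamped to i_min (weakest-peak convention)")
    intensity <- pmax(intensity, i_min)
  }
  d <- d_max * (intensity / i_min)^(-1 / 6)
  list(target = d, lower = d * (1 - flat_frac), upper = d * (1 + flat_frac))
}

#' Effective distance of an ambiguous restraint
#'
#' r_eff = (sum_i r_i^-6)^(-1/6); never larger than the smallest member
#' distance, and equal to it for a single pair.
#'
#' @param distances numeric vector of member distances (Angstrom).
#' @export
effective_distance <- function(distances) {
  stopifnot(length(distances) >= 1, all(distances > 0))
  sum(distances^-6)^(-1 / 6)
}

#' Square-well restraint energy
#'
#' Zero inside the inclusive [lower, upper] well, harmonic in the excess
#' outside. For ambiguous restraints `distance` may be a vector of member
#' distances, combined by [effective_distance()].
#'
#' @param distance member distance(s) (Angstrom).
#' @param restraint a [distance_restraint].
#' @param k_force force constant (energy / Angstrom^2).
#' @export
square_well_energy <- function(distance, restraint, k_force = 1) {
  r <- effective_distance(distance)
  excess <- if (r < restraint$lower) restraint$lower - r
            else if (r > restraint$upper) r - restraint$upper
            else 0
  k_force * restraint$weight * excess^2
}

#' Beta-sheet hydrogen-bond restraints from strand probabilities
#'
#' For every residue i with beta probability above `threshold`, two
#' ambiguous HN/C' restraints are emitted, encoding that at least one edge
#' of the strand must be hydrogen bonded:
#' (1) HN(i)/C'(x) or HN(x)/C'(i-1) and (2) HN(i+1)/C'(x) or HN(x)/C'(i),
#' with x ranging over the modeled range at sequence separation >=
#' `min_separation` from the fixed residue. Target 1.7 A, bounds 1.4-2.0 A.
#' Alternatives that fall off the chain terminus, or whose HN sits on a
#' proline, are omitted (logged via message).
#'
#' @param beta_probabilities named numeric vector (names = residue indices),
#'   values in [0, 1].
#' @param sequence one-letter sequence of the modeled range (used to skip
#'   proline HN); names or position give residue indices.
#' @param residue_range integer range c(first, last) that x runs over.
#' @param threshold inclusion threshold, default 0.75 (exclusive).
#' @param min_separation sequence-separation floor for x, default 2.
#' @return list of [distance_restraint]s of kind `hbond`.
#' @export
make_hbond_restraints <- function(beta_probabilities, sequence, residue_range,
                                  threshold = 0.75, min_separation = 2) {
  stopifnot(all(beta_probabilities >= 0 & beta_probabilities <= 1))
  first <- residue_range[1]; last <- residue_range[2]
  res_ids <- first:last
  seqv <- strsplit(sequence, "")[[1]]
  stopifnot(length(seqv) == length(res_ids))
  is_pro <- stats::setNames(seqv == "P", res_ids)
  qualifying <- as.integer(names(beta_probabilities))[beta_probabilities > threshold]
  out <- list()
  add_restraint <- function(hn_fixed, cp_fixed) {
    # alternative A: HN(hn_fixed)/C'(x); alternative B: HN(x)/C'(cp_fixed)
    pairs <- list()
    if (!is.na(hn_fixed) && hn_fixed >= first && hn_fixed <= last &&
        !is_pro[as.character(hn_fixed)]) {
      x <- res_ids[abs(res_ids - hn_fixed) >= min_separation]
      if (length(x)) pairs[[length(pairs) + 1]] <-
        data.frame(res_a = hn_fixed, atom_a = "HN", res_b = x, atom_b = "C")
    } else {
      message("hbond alternative with HN(", hn_fixed, ") omitted (terminus or proline)")
    }
    if (!is.na(cp_fixed) && cp_fixed >= first && cp_fixed <= last) {
      x <- res_ids[abs(res_ids - cp_fixed) >= min_separation &
                     !is_pro[as.character(res_ids)]]
      if (length(x)) pairs[[length(pairs) + 1]] <-
        data.frame(res_a = x, atom_a = "HN", res_b = cp_fixed, atom_b = "C")
    } else {
      message("hbond alternative with C'(", cp_fixed, ") omitted (terminus)")
    }
    if (!length(pairs)) return(NULL)
    distance_restraint(do.call(rbind, pairs), target = 1.7, lower = 1.4,
                       upper = 2.0, kind = "hbond")
  }
  for (i in qualifying) {
    r1 <- add_restraint(i, i - 1L)
    r2 <- add_restraint(i + 1L, i)
    if (!is.null(r1)) out[[length(out) + 1]] <- r1
    if (!is.null(r2)) out[[length(out) + 1]] <- r2
  }
  out
}

#' Dihedral restraints from TALOS-style predictions
#'
#' Only predictions classified `Strong` are used; the square-well halfwidth
#' is twice the prediction spread.
#'
#' @param predictions data.frame from [parse_dihedral_predictions()].
#' @param min_halfwidth substituted (with a warning) when a spread of 0
#'   would give a degenerate well. Degrees, default 5.
#' @return list of [dihedral_restraint]s.
#' @export
make_dihedral_restraints <- function(predictions, min_halfwidth = 5) {
  keep <- predictions$class == "Strong"
  out <- list()
  for (i in which(keep)) {
    hw <- 2 * predictions$spread[i]
    if (hw <= 0) {
      warning("zero prediction spread at residue ", predictions$residue_index[i],
              "; substituting minimum halfwidth ", min_halfwidth)
      hw <- min_halfwidth
    }
    out[[length(out) + 1]] <- dihedral_restraint(
      predictions$residue_index[i], predictions$angle[i],
      predictions$value[i], hw)
  }
  out
}

#' Trigonal metal-site coordination restraints
#'
#' Explicit mode models the metal ion: three metal-sulfur bond restraints
#' (2.3 A), three S-metal-S angle restraints (120 deg) and three
#' metal-S-C angle restraints (109.5 deg), with the metal initialized at
#' the geometric center of the three sulfurs. Implicit mode carries no
#' metal atom: three pairwise S-S distance restraints at 4.0 A (the
#' distance implied by ideal trigonal geometry, 2 * 2.3 * sin 60 deg ~
#' 3.98 A).
#'
#' @param coordinating_atoms data.frame with exactly three rows, columns
#'   `res`, `atom` (the sulfur, e.g. `SG`/`SD`) and `attached` (the carbon
#'   bonded to it, e.g. `CB`/`CG`/`CE`), caller-specified.
#' @param mode `"explicit"` or `"implicit"`.
#' @param bond_length metal-S bond target (A), default 2.3.
#' @param s_metal_s_angle S-metal-S target (deg), default 120.
#' @param metal_s_c_angle metal-S-C target (deg), default 109.5.
#' @param implicit_target S-S target in implicit mode (A), default 4.0.
#' @return a [restraint_set]; in explicit mode its `metal` attribute names
#'   the sulfur atoms whose centroid seeds the metal position.
#' @export
make_metal_restraints <- function(coordinating_atoms,
                                  mode = c("explicit", "implicit"),
                                  bond_length = 2.3, s_metal_s_angle = 120,
                                  metal_s_c_angle = 109.5,
                                  implicit_target = 4.0) {
  mode <- match.arg(mode)
  ca <- coordinating_atoms
  if (nrow(ca) != 3) stop("exactly three coordinating sulfur atoms required (trigonal site)")
  ca$atom <- toupper(ca$atom)
  dist_list <- list()
  ang_list <- list()
  if (mode == "implicit") {
    combs <- utils::combn(3, 2)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      dist_list[[k]] <- distance_restraint(
        data.frame(res_a = ca$res[i], atom_a = ca$atom[i],
                   res_b = ca$res[j], atom_b = ca$atom[j]),
        target = implicit_target, lower = implicit_target - 0.2,
        upper = implicit_target + 0.2, kind = "metal_implicit", weight = 5)
    }
    rs <- restraint_set(distance = dist_list)
    attr(rs, "metal") <- NULL
    return(rs)
  }
  # coordination terms are covalent-strength: much stiffer than the NOE
  # wells they compete with
  for (i in 1:3) {
    dist_list[[i]] <- distance_restraint(
      data.frame(res_a = 0L, atom_a = "AG", res_b = ca$res[i], atom_b = ca$atom[i]),
      target = bond_length, lower = bond_length - 0.02,
      upper = bond_length + 0.02, kind = "metal_bond", weight = 80)
  }
  combs <- utils::combn(3, 2)
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    ang_list[[length(ang_list) + 1]] <- angle_restraint(
      data.frame(res = c(ca$res[i], 0L, ca$res[j]),
                 atom = c(ca$atom[i], "AG", ca$atom[j])),
      target = s_metal_s_angle, halfwidth = 0, kind = "metal_bond_angle",
      weight = 50)
  }
  for (i in 1:3) {
    ang_list[[length(ang_list) + 1]] <- angle_restraint(
      data.frame(res = c(0L, ca$res[i], ca$res[i]),
                 atom = c("AG", ca$atom[i], ca$attached[i])),
      target = metal_s_c_angle, halfwidth = 0, kind = "metal_ligand_angle",
      weight = 10)
  }
  rs <- restraint_set(distance = dist_list, angle = ang_list)
  attr(rs, "metal") <- data.frame(res = ca$res, atom = ca$atom,
                                  stringsAsFactors = FALSE)
  rs
}

#' NCS coupling between the two simultaneously refined forms
#'
#' Names the residue segments whose backbone atoms are kept superimposable
#' between the apo and metal-bound structures; the free segments (the
#' metal-hosting loops) are recorded for audit and move independently.
#'
#' @param superimpose_segments list of `c(first, last)` residue ranges.
#' @param free_segments list of `c(first, last)` ranges allowed to differ.
#' @param atoms backbone atom names entering the penalty.
#' @param weight harmonic coupling weight.
#' @export
make_ncs_coupling <- function(superimpose_segments, free_segments = list(),
                              atoms = c("N", "CA", "C"), weight = 10) {
  if (!length(superimpose_segments)) stop("empty superimpose segment list")
  sup <- unlist(lapply(superimpose_segments, function(s) s[1]:s[2]))
  fre <- unlist(lapply(free_segments, function(s) s[1]:s[2]))
  if (length(intersect(sup, fre))) {
    stop("superimposed and free segments overlap at residues ",
         paste(intersect(sup, fre), collapse = ", "))
  }
  structure(list(residues = sort(unique(sup)), free_residues = sort(unique(fre)),
                 atoms = atoms, weight = weight),
            class = "ncs_coupling")
}

# ---- restraint table export/import -------------------------------------

#' Export a restraint set as a TSV table
#'
#' One row per member pair (distance), per atom (angle) or per restraint
#' (dihedral), tied together by `group_id`. Round-trips exactly through
#' [read_restraints()].
#'
#' @param rs a [restraint_set].
#' @param path output path.
#' @export
write_restraints <- function(rs, path) {
  rows <- list()
  gid <- 0L
  for (r in rs$distance) {
    gid <- gid + 1L
    for (i in seq_len(nrow(r$pairs))) {
      rows[[length(rows) + 1]] <- data.frame(
        record = "distance", group_id = gid, kind = r$kind,
        res_a = r$pairs$res_a[i], atom_a = r$pairs$atom_a[i],
        res_b = r$pairs$res_b[i], atom_b = r$pairs$atom_b[i], res_c = NA,
        atom_c = NA, angle = NA, target = r$target, lower = r$lower,
        upper = r$upper, halfwidth = NA, weight = r$weight,
        stringsAsFactors = FALSE)
    }
  }
  for (r in rs$angle) {
    gid <- gid + 1L
    rows[[length(rows) + 1]] <- data.frame(
      record = "angle", group_id = gid, kind = r$kind,
      res_a = r$atoms$res[1], atom_a = r$atoms$atom[1],
      res_b = r$atoms$res[2], atom_b = r$atoms$atom[2],
      res_c = r$atoms$res[3], atom_c = r$atoms$atom[3], angle = NA,
      target = r$target, lower = NA, upper = NA, halfwidth = r$halfwidth,
      weight = r$weight, stringsAsFactors = FALSE)
  }
  for (r in rs$dihedral) {
    gid <- gid + 1L
    rows[[length(rows) + 1]] <- data.frame(
      record = "dihedral", group_id = gid, kind = "dihedral",
      res_a = r$residue_index, atom_a = NA, res_b = NA, atom_b = NA,
      res_c = NA, atom_c = NA, angle = r$angle_name, target = r$target,
      lower = NA, upper = NA, halfwidth = r$halfwidth, weight = r$weight,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a restraint table written by [write_restraints()]
#' @param path file path.
#' @return a [restraint_set].
#' @export
read_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  dist_list <- list(); ang_list <- list(); dih_list <- list()
  for (g in unique(df$group_id)) {
    sub <- df[df$group_id == g, , drop = FALSE]
    rec <- sub$record[1]
    if (rec == "distance") {
      dist_list[[length(dist_list) + 1]] <- distance_restraint(
        data.frame(res_a = sub$res_a, atom_a = sub$atom_a,
                   res_b = sub$res_b, atom_b = sub$atom_b,
                   stringsAsFactors = FALSE),
        target = sub$target[1], lower = sub$lower[1], upper = sub$upper[1],
        kind = sub$kind[1], weight = sub$weight[1])
    } else if (rec == "angle") {
      ang_list[[length(ang_list) + 1]] <- angle_restraint(
        data.frame(res = c(sub$res_a, sub$res_b, sub$res_c),
                   atom = c(sub$atom_a, sub$atom_b, sub$atom_c),
                   stringsAsFactors = FALSE),
        target = sub$target, halfwidth = sub$halfwidth, kind = sub$kind,
        weight = sub$weight)
    } else {
      dih_list[[length(dih_list) + 1]] <- dihedral_restraint(
        sub$res_a, sub$angle, sub$target, sub$halfwidth, sub$weight)
    }
  }
  restraint_set(distance = dist_list, angle = ang_list, dihedral = dih_list)
}
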