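# Chemical-shift comparison between two states or forms, and titration
# analysis. The central statistic is the weighted, truncated rms shift
# difference: per residue,
#
#   ddrms = (1/n) * sum_i chi(|d_a_i - d_b_i| / sigma_i, tau_i)
#   chi(x, tau) = x^2 if x >= 2*tau, else 0
#
# where sigma_i scales shifts of different nuclei onto a common axis
# (1.0 / 10.0 / 4.0 ppm for H / N / C) and tau_i truncates differences that
# are within measurement precision. Note the statistic, despite its "rms"
# name, is the mean of truncated squares; `apply_sqrt` takes the root.

# tau class of an atom: amide proton, amide nitrogen and carbonyl each get
# their own precision; all other protons and carbons share one per nucleus.
tau_class_of <- function(atom) {
  nuc <- nucleus_of(atom)
  ifelse(nuc == "HN", "HN",
    ifelse(nuc == "N", "N",
      ifelse(nuc == "Cprime", "Cprime",
        ifelse(nuc == "H", "H", ifelse(nuc == "C", "C", NA_character_)))))
}

sigma_for_nucleus <- function(nucleus, sigma_by_nucleus) {
  key <- ifelse(nucleus %in% c("H", "HN"), "H",
                ifelse(nucleus %in% c("C", "Cprime"), "C", "N"))
  unname(sigma_by_nucleus[key])
}

#' Configuration for chemical-shift-perturbation analysis
#'
#' @param sigma_by_nucleus scale weights (ppm) dividing shift differences,
#'   named `H`, `N`, `C`. Defaults 1.0, 10.0, 4.0.
#' @param tau_by_atomclass truncation thresholds (on the sigma-scaled axis)
#'   per atom class `HN`, `N`, `Cprime`, `H` (other protons), `C` (other
#'   carbons). Overridable by [estimate_tau()].
#' @param apply_sqrt if `TRUE`, report the square root of the mean truncated
#'   square. Default `FALSE` (mean of truncated squares, as-defined).
#' @export
csp_config <- function(sigma_by_nucleus = c(H = 1.0, N = 10.0, C = 4.0),
                       tau_by_atomclass = c(HN = 0.01977, N = 0.01761,
                                            Cprime = 0.01780, H = 0.02620,
                                            C = 0.042974),
                       apply_sqrt = FALSE) {
  stopifnot(all(sigma_by_nucleus > 0), all(tau_by_atomclass >= 0))
  structure(list(sigma_by_nucleus = sigma_by_nucleus,
                 tau_by_atomclass = tau_by_atomclass,
                 apply_sqrt = isTRUE(apply_sqrt)),
            class = "csp_config")
}

#' Per-residue weighted truncated rms shift difference between two states
#'
#' Only atoms present in both tables contribute; a residue with no shared
#' atoms is absent from the profile (not reported as zero).
#'
#' @param shifts_a,shifts_b [shift_table]s sharing residue indexing
#'   (e.g. apo vs metal-bound, or S-form vs U-form). If a table contains
#'   both forms, filter before calling.
#' @param config a [csp_config].
#' @return a `csp_profile` data.frame: `residue_index`, `value`, `n_atoms`,
#'   `atoms` (comma-joined contributing atom names).
#' @export
compute_delta_rms <- function(shifts_a, shifts_b, config = csp_config()) {
  a <- as.data.frame(shifts_a)
  b <- as.data.frame(shifts_b)
  m <- merge(a, b, by = c("residue_index", "atom"), suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    out <- data.frame(residue_index = integer(0), value = numeric(0),
                      n_atoms = integer(0), atoms = character(0))
    class(out) <- c("csp_profile", "data.frame")
    return(out)
  }
  sig <- sigma_for_nucleus(m$nucleus_a, config$sigma_by_nucleus)
  tau <- unname(config$tau_by_atomclass[tau_class_of(m$atom)])
  x <- abs(m$shift_a - m$shift_b) / sig
  contrib <- ifelse(x >= 2 * tau, x^2, 0)
  sp <- split(seq_len(nrow(m)), m$residue_index)
  out <- data.frame(
    residue_index = as.integer(names(sp)),
    value = vapply(sp, function(i) mean(contrib[i]), numeric(1)),
    n_atoms = vapply(sp, length, integer(1)),
    atoms = vapply(sp, function(i) paste(m$atom[i], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (config$apply_sqrt) out$value <- sqrt(out$value)
  out <- out[order(out$residue_index), ]
  rownames(out) <- NULL
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Estimate truncation thresholds from reference residues
#'
#' The thresholds represent measurement precision: per atom class, the
#' sample standard deviation of the sigma-scaled shift difference over
#' residues known to be unaffected (e.g. the unstructured tails, whose
#' shifts barely move between states).
#'
#' @param shifts_a,shifts_b [shift_table]s.
#' @param reference_residues integer vector of unaffected residue indices.
#' @param config a [csp_config]; supplies fallback defaults for classes with
#'   fewer than 2 reference observations (with a warning).
#' @return named numeric vector of tau per atom class.
#' @export
estimate_tau <- function(shifts_a, shifts_b, reference_residues,
                         config = csp_config()) {
  if (!length(reference_residues)) stop("empty reference residue set")
  a <- as.data.frame(shifts_a)
  b <- as.data.frame(shifts_b)
  m <- merge(a, b, by = c("residue_index", "atom"), suffixes = c("_a", "_b"))
  m <- m[m$residue_index %in% reference_residues, , drop = FALSE]
  cls <- tau_class_of(m$atom)
  sig <- sigma_for_nucleus(m$nucleus_a, config$sigma_by_nucleus)
  d <- (m$shift_a - m$shift_b) / sig
  out <- config$tau_by_atomclass
  for (cl in names(out)) {
    v <- d[cls == cl]
    if (length(v) >= 2) {
      out[cl] <- stats::sd(v)
    } else {
      warning("tau class ", cl, " has <2 reference observations; using configured default")
    }
  }
  out
}

#' Track peaks through a titration series
#'
#' Greedy nearest-neighbour matching from each titration point to the next:
#' a trajectory's last matched position is matched against the unclaimed
#' peaks of the next point within per-dimension radii. Competing candidate
#' matches are resolved by smallest cost — radius-scaled displacement plus
#' an intensity-consistency penalty (`intensity_weight * |log I ratio|`),
#' so a fading peak of the other conformational form does not capture a
#' trajectory whose own peak is nearby; exact ties keep stable input
#' order. A trajectory unmatched at a point is `broadened_out` there; lost
#' trajectories search with radii widened by `reappear_factor` (peaks of
#' binding-site residues reappear at substantially perturbed positions
#' near saturation) and are `reappeared` once matched again.
#'
#' @param series a [titration_series].
#' @param matching_radius_by_nucleus named radii (ppm), e.g.
#'   `c(HN = 0.06, N = 0.6)`.
#' @param intensity_weight weight of the intensity-consistency term in the
#'   matching cost (0 disables it).
#' @param reappear_factor radius multiplier for trajectories currently
#'   broadened out.
#' @return list of trajectories: `peak_id`, `status` (per point),
#'   `drift` (final minus apo position per dimension, NA if lost at the
#'   final point).
#' @export
track_titration <- function(series, matching_radius_by_nucleus = c(HN = 0.06, N = 0.6, H = 0.06),
                            intensity_weight = 1, reappear_factor = 5) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  if (length(pts) < 2) stop("titration series needs at least two points")
  if (any(matching_radius_by_nucleus <= 0)) stop("matching radii must be > 0")
  dims <- peak_dims(pts[[1]]$peaks)
  rad <- vapply(dims, function(d) {
    key <- if (d %in% names(matching_radius_by_nucleus)) d
           else if (d %in% c("H", "HN")) intersect(c("H", "HN"), names(matching_radius_by_nucleus))[1]
           else d
    r <- matching_radius_by_nucleus[key]
    if (is.na(r)) stop("no matching radius for dimension ", d)
    unname(r)
  }, numeric(1))

  apo <- pts[[1]]$peaks
  n_traj <- nrow(apo)
  pos_last <- peak_positions(apo)
  int_last <- apo$intensity
  status <- matrix("matched", n_traj, length(pts),
                   dimnames = list(apo$peak_id, NULL))
  pos_final <- pos_last
  lost_now <- rep(FALSE, n_traj)
  ever_lost <- rep(FALSE, n_traj)

  for (tp in seq_along(pts)[-1]) {
    pk <- pts[[tp]]$peaks
    cand_pos <- peak_positions(pk)
    claimed <- rep(FALSE, nrow(pk))
    # candidate (trajectory, peak) pairs within the per-dimension radii
    # (widened for lost trajectories searching for a reappearance)
    pairs <- list()
    for (i in seq_len(n_traj)) {
      if (!nrow(pk)) break
      rad_i <- rad * if (lost_now[i]) reappear_factor else 1
      d <- sweep(cand_pos, 2, pos_last[i, ], "-")
      ok <- which(apply(abs(d), 1, function(r) all(r <= rad_i)))
      for (j in ok) {
        cost <- sqrt(sum((d[j, ] / rad)^2)) +
          intensity_weight * abs(log(pk$intensity[j] / int_last[i]))
        pairs[[length(pairs) + 1L]] <- c(i, j, cost)
      }
    }
    matched_now <- rep(FALSE, n_traj)
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(pm[, 3]), , drop = FALSE]  # stable for ties
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; j <- pm[r, 2]
        if (!matched_now[i] && !claimed[j]) {
          matched_now[i] <- TRUE
          claimed[j] <- TRUE
          pos_last[i, ] <- cand_pos[j, ]
          pos_final[i, ] <- cand_pos[j, ]
          int_last[i] <- pk$intensity[j]
          status[i, tp] <- if (ever_lost[i]) "reappeared" else "matched"
        }
      }
    }
    status[!matched_now, tp] <- "broadened_out"
    lost_now <- !matched_now
    ever_lost <- ever_lost | lost_now
  }

  apo_pos <- peak_positions(apo)
  lapply(seq_len(n_traj), function(i) {
    drift <- pos_final[i, ] - apo_pos[i, ]
    if (status[i, length(pts)] == "broadened_out") drift <- rep(NA_real_, length(dims))
    list(peak_id = apo$peak_id[i],
         status = unname(status[i, ]),
         drift = stats::setNames(drift, dims))
  })
}

#' Rank residues by shift perturbation
#'
#' Residues sorted by profile value, descending; zero-valued residues never
#' make the list (a flat zero profile yields an empty ranking).
#'
#' @param profile a `csp_profile` from [compute_delta_rms()].
#' @param k number of residues to return.
#' @return data.frame `residue_index`, `value`, ordered by decreasing value.
#' @export
rank_binding_site <- function(profile, k = 3) {
  if (!nrow(profile)) stop("empty profile")
  hits <- profile[profile$value > 0, , drop = FALSE]
  if (!nrow(hits)) {
    message("flat zero profile: no residues above threshold")
    return(data.frame(residue_index = integer(0), value = numeric(0)))
  }
  hits <- hits[order(-hits$value, hits$residue_index), ]
  if (k > nrow(hits)) {
    warning("k exceeds number of perturbed residues; returning all ", nrow(hits))
    k <- nrow(hits)
  }
  out <- hits[seq_len(k), c("residue_index", "value")]
  rownames(out) <- NULL
  out
}
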