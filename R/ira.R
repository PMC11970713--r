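# Inferential Restraint Assignment (IRA).
#
# Each NOESY cross peak is given a set of assignment candidates (atom
# tuples consistent with the assigned chemical shifts). A candidate's
# probability is the product P = P_F * P_D of a frequency-agreement factor
# and a distance-plausibility factor:
#
#   P_F = prod_dims exp(-Delta_d^2 / 2),  Delta_d = (mu_d - a_d) /
#                                         sqrt(sigma_F_d^2 + gamma_F_d^2)
#   P_D = k_D * Phi( n (r_min - r_0) / sqrt(n^2 sigma_D^2 + gamma_D^2) )
#
# with mu the assigned shift, a the peak position, r_0 the proton-proton
# distance in a template structure (class priors when none exists yet),
# n = 6 the NOE distance exponent, and Phi the standard normal CDF. Over
# iterative cycles of assignment and structure calculation, candidates
# with P below P_max/f (per peak) are stripped, with f tightening and
# sigma_D shrinking on a fixed schedule.

#' IRA configuration
#'
#' Defaults follow the published protocol: gamma_F = 0.2 / 0.02 / 0.3 /
#' 0.05 ppm for N / HN / C / H; P_F retention gate 0.07 (about 2.3 combined
#' standardized deviations under the unit-max kernel); gamma_D = 1.0;
#' stripping factors f = 50, 50, 20, 10, 5 and sigma_D = 0.15, 0.15, 0.15,
#' 0.1, 0.05 over five consecutive cycles; template-free distance priors
#' 1.0 / 0.5 / 0.3 / 0.2 / 0.15 / 0.1 for intra-residue, sequential,
#' residue difference 2, 3, 4 and long-range candidates.
#'
#' @param gamma_F_by_nucleus frequency-uncertainty floor per nucleus (ppm).
#' @param pf_threshold minimum P_F for a candidate to be considered.
#' @param n_exponent NOE distance exponent (6).
#' @param gamma_D intensity (log-normal) uncertainty scale.
#' @param k_D overall P_D scale (only ratios matter for ranking).
#' @param r_min distance below which half of peaks are observable
#'   (Angstrom); defaults to the maximum calibration distance 4.25.
#' @param sigma_D_schedule per-cycle distance uncertainty.
#' @param f_schedule per-cycle stripping factors (> 1), same length.
#' @param no_template_pd class priors used before a template exists.
#' @param sigma_f optional named per-resonance frequency sd (ppm), names
#'   `"form:res:atom"`, e.g. from [estimate_sigma_f()]; anything absent
#'   falls back to the floor gamma_F / 2.
#' @param normalized_pf if `TRUE`, use the density-normalized Gaussian
#'   rather than the unit-max kernel (changes the meaning of the 0.07 gate).
#' @export
ira_config <- function(gamma_F_by_nucleus = c(N = 0.2, HN = 0.02, C = 0.3, H = 0.05),
                       pf_threshold = 0.07, n_exponent = 6, gamma_D = 1.0,
                       k_D = 1.0, r_min = 4.25,
                       sigma_D_schedule = c(0.15, 0.15, 0.15, 0.1, 0.05),
                       f_schedule = c(50, 50, 20, 10, 5),
                       no_template_pd = c(intra = 1.0, sequential = 0.5,
                                          rd2 = 0.3, rd3 = 0.2, rd4 = 0.15,
                                          long = 0.1),
                       sigma_f = NULL, normalized_pf = FALSE) {
  if (length(sigma_D_schedule) != length(f_schedule)) {
    stop("sigma_D_schedule and f_schedule must have the same length (one entry per cycle)")
  }
  if (any(f_schedule <= 1)) stop("stripping factors must be > 1")
  stopifnot(all(gamma_F_by_nucleus > 0), all(sigma_D_schedule > 0),
            gamma_D > 0, k_D > 0, r_min > 0)
  structure(list(gamma_F_by_nucleus = gamma_F_by_nucleus,
                 pf_threshold = pf_threshold, n_exponent = n_exponent,
                 gamma_D = gamma_D, k_D = k_D, r_min = r_min,
                 sigma_D_schedule = sigma_D_schedule, f_schedule = f_schedule,
                 no_template_pd = no_template_pd, sigma_f = sigma_f,
                 normalized_pf = isTRUE(normalized_pf)),
            class = "ira_config")
}

gamma_for_dim <- function(dim_label, config) {
  g <- config$gamma_F_by_nucleus
  key <- if (dim_label %in% names(g)) dim_label else
    if (dim_label == "Cprime") "C" else "H"
  unname(g[key])
}

sigma_f_for <- function(form, res, atom, dim_label, config) {
  floor_sd <- gamma_for_dim(dim_label, config) / 2
  if (is.null(config$sigma_f)) return(floor_sd)
  v <- unname(config$sigma_f[paste(form, res, toupper(atom), sep = ":")])
  ifelse(is.na(v), floor_sd, pmax(v, floor_sd))
}

#' Frequency-agreement probability P_F
#'
#' Product over dimensions of a Gaussian kernel in the standardized
#' deviation between assigned shift and peak position. The default
#' unit-max convention gives P_F in (0, 1] with P_F = 1 at exact match;
#' the density-normalized variant multiplies each dimension by
#' 1/sqrt(2 pi (sigma^2 + gamma^2)).
#'
#' @param mu assigned shift(s), one per dimension (ppm).
#' @param a peak position(s), same length.
#' @param sigma_f per-dimension resonance sd (ppm).
#' @param gamma_f per-dimension uncertainty floor (ppm).
#' @param normalized density-normalized variant.
#' @export
score_pf <- function(mu, a, sigma_f, gamma_f, normalized = FALSE) {
  s2 <- sigma_f^2 + gamma_f^2
  delta2 <- (mu - a)^2 / s2
  pf <- exp(-0.5 * sum(delta2))
  if (normalized) pf <- pf * prod(1 / sqrt(2 * pi * s2))
  pf
}

#' Distance-plausibility probability P_D
#'
#' With a template distance r_0: k_D * Phi(n (r_min - r_0) /
#' sqrt(n^2 sigma_D^2 + gamma_D^2)). For a template ensemble the average
#' over models is used. Without a template, a sequence-separation class
#' prior.
#'
#' @param r0 template distance(s) (Angstrom); vector averages as an
#'   ensemble. `NULL` or `NA` selects the class prior.
#' @param sep_class separation class (for the prior fallback).
#' @param sigma_D current cycle's distance uncertainty.
#' @param config an [ira_config()].
#' @export
score_pd <- function(r0, sep_class, sigma_D, config = ira_config()) {
  if (is.null(r0) || all(is.na(r0))) {
    return(unname(config$no_template_pd[sep_class]))
  }
  r0 <- r0[!is.na(r0)]
  n <- config$n_exponent
  z <- n * (config$r_min - r0) / sqrt(n^2 * sigma_D^2 + config$gamma_D^2)
  mean(config$k_D * stats::pnorm(z))
}

#' Estimate per-resonance frequency uncertainties from the peak lists
#'
#' For every assigned resonance, collects the peak positions (in the
#' matching dimensions) that lie within 3 gamma_F of it and for which it
#' is the nearest resonance, and takes their sample sd. Resonances with a
#' single observation keep the floor gamma_F / 2.
#'
#' @param peaks a [peak_list] or named list of them.
#' @param shifts a [shift_table].
#' @param config an [ira_config()].
#' @return named numeric vector (`"form:res:atom"`).
#' @export
estimate_sigma_f <- function(peaks, shifts, config = ira_config()) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks)
  sh <- as.data.frame(shifts)
  obs <- stats::setNames(vector("list", nrow(sh)),
                         paste(sh$form, sh$residue_index, toupper(sh$atom), sep = ":"))
  for (pk in peaks) {
    dims <- peak_dims(pk)
    pos <- peak_positions(pk)
    for (d in seq_along(dims)) {
      cand <- if (dims[d] == "HN") which(sh$nucleus == "HN")
        else if (dims[d] == "H") which(sh$nucleus %in% c("H", "HN"))
        else if (dims[d] == "N") which(sh$nucleus == "N")
        else which(sh$nucleus %in% c("C", "Cprime"))
      if (!length(cand)) next
      gam <- gamma_for_dim(dims[d], config)
      for (p in seq_len(nrow(pos))) {
        dd <- abs(sh$shift[cand] - pos[p, d])
        k <- which.min(dd)
        if (dd[k] <= 3 * gam) {
          key <- cand[k]
          obs[[key]] <- c(obs[[key]], pos[p, d])
        }
      }
    }
  }
  out <- vapply(seq_along(obs), function(i) {
    v <- obs[[i]]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }, numeric(1))
  names(out) <- names(obs)
  out[!is.na(out)]
}

#' Generate assignment candidates for a set of peaks
#'
#' For each peak, every atom tuple whose shifts match all dimensions with
#' P_F above the threshold becomes a candidate. Both conformational forms
#' are searched, but a candidate pairs atoms within one form (a cross peak
#' arises within one molecule). Candidates whose protons both map to
#' U-form resonances at sequence separation of four residues or fewer are
#' marked `excluded_medium_range_U` (the unstructured form produces only
#' short-range contacts, so these are bookkeeping for U-form peaks, not
#' structural restraints). Peaks left with no active candidate are dropped
#' from restraint generation but retained in the audit.
#'
#' For 3D lists with dims (HN, N, H) the first two dimensions must match
#' one residue's amide pair; 2D (H, H) lists match free proton pairs.
#'
#' @param peaks a [peak_list] or named list of them.
#' @param shifts a [shift_table] containing S-form (and, where duplicated,
#'   U-form) entries.
#' @param config an [ira_config()].
#' @return data.frame of candidates (one row per peak x atom tuple) with
#'   columns `list_name`, `peak_id`, `form`, `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `sep_class`, `p_f`, `p_d`, `p`, `status`; attribute
#'   `dropped_peaks` lists peaks without candidates.
#' @export
generate_candidates <- function(peaks, shifts, config = ira_config()) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks = peaks)
  sh <- as.data.frame(shifts)
  sh$atom <- toupper(sh$atom)
  out <- list()
  dropped <- list()
  for (ln in names(peaks)) {
    pk <- peaks[[ln]]
    dims <- peak_dims(pk)
    pos <- peak_positions(pk)
    if (!nrow(pk)) next
    is_3d_edited <- length(dims) == 3 && dims[2] %in% c("N", "C")
    is_2d_hh <- length(dims) == 2 && all(dims %in% c("H", "HN"))
    if (!is_3d_edited && !is_2d_hh) {
      stop("unsupported peak list geometry: dims ", paste(dims, collapse = ","))
    }
    for (form in unique(sh$form)) {
      sf <- sh[sh$form == form, ]
      protons <- sf[sf$nucleus %in% c("H", "HN"), ]
      if (is_3d_edited) {
        # origin protons whose attached heavy atom matches dimension 2
        h_atoms <- if (dims[2] == "N") "HN" else
          names(ATTACHED_HEAVY)[ATTACHED_HEAVY != "N"]
        orig <- do.call(rbind, lapply(h_atoms, function(ha) {
          hh <- sf[sf$atom == ha, c("residue_index", "shift")]
          hv <- sf[sf$atom == ATTACHED_HEAVY[ha], c("residue_index", "shift")]
          m <- merge(hh, hv, by = "residue_index", suffixes = c("_h", "_x"))
          if (nrow(m)) m$atom <- ha
          m
        }))
        if (is.null(orig) || !nrow(orig) || !nrow(protons)) next
        g1 <- gamma_for_dim(dims[1], config); g2 <- gamma_for_dim(dims[2], config)
        g3 <- gamma_for_dim(dims[3], config)
        s1 <- sigma_f_for(form, orig$residue_index, orig$atom, dims[1], config)
        s2 <- sigma_f_for(form, orig$residue_index,
                          ATTACHED_HEAVY[orig$atom], dims[2], config)
        s3 <- sigma_f_for(form, protons$residue_index, protons$atom, dims[3], config)
        for (p in seq_len(nrow(pk))) {
          d1 <- (orig$shift_h - pos[p, 1])^2 / (s1^2 + g1^2)
          d2 <- (orig$shift_x - pos[p, 2])^2 / (s2^2 + g2^2)
          p12 <- exp(-0.5 * (d1 + d2))
          ok_i <- which(p12 > config$pf_threshold)
          if (!length(ok_i)) next
          d3 <- (protons$shift - pos[p, 3])^2 / (s3^2 + g3^2)
          p3 <- exp(-0.5 * d3)
          ok_j <- which(p3 * max(p12[ok_i]) > config$pf_threshold)
          for (i in ok_i) for (j in ok_j) {
            pf <- p12[i] * p3[j]
            if (pf <= config$pf_threshold) next
            ra <- orig$residue_index[i]; rb <- protons$residue_index[j]
            if (ra == rb && protons$atom[j] == orig$atom[i]) next  # diagonal
            out[[length(out) + 1]] <- data.frame(
              list_name = ln, peak_id = pk$peak_id[p], form = form,
              res_a = ra, atom_a = orig$atom[i], res_b = rb,
              atom_b = protons$atom[j], sep_class = separation_class(ra, rb),
              p_f = pf, stringsAsFactors = FALSE)
          }
        }
      } else {
        if (!nrow(protons)) next
        g1 <- gamma_for_dim(dims[1], config); g2 <- gamma_for_dim(dims[2], config)
        sA <- sigma_f_for(form, protons$residue_index, protons$atom, dims[1], config)
        sB <- sigma_f_for(form, protons$residue_index, protons$atom, dims[2], config)
        for (p in seq_len(nrow(pk))) {
          pa <- exp(-0.5 * (protons$shift - pos[p, 1])^2 / (sA^2 + g1^2))
          pb <- exp(-0.5 * (protons$shift - pos[p, 2])^2 / (sB^2 + g2^2))
          ok_a <- which(pa > config$pf_threshold)
          ok_b <- which(pb * max(c(pa[ok_a], 0)) > config$pf_threshold)
          for (i in ok_a) for (j in ok_b) {
            if (i == j) next
            pf <- pa[i] * pb[j]
            if (pf <= config$pf_threshold) next
            ra <- protons$residue_index[i]; rb <- protons$residue_index[j]
            out[[length(out) + 1]] <- data.frame(
              list_name = ln, peak_id = pk$peak_id[p], form = form,
              res_a = ra, atom_a = protons$atom[i], res_b = rb,
              atom_b = protons$atom[j], sep_class = separation_class(ra, rb),
              p_f = pf, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  cand <- if (length(out)) do.call(rbind, out) else
    data.frame(list_name = character(0), peak_id = character(0),
               form = character(0), res_a = integer(0), atom_a = character(0),
               res_b = integer(0), atom_b = character(0),
               sep_class = character(0), p_f = numeric(0))
  cand$p_d <- NA_real_
  cand$p <- NA_real_
  cand$status <- ifelse(cand$form == "U" & cand$sep_class != "long",
                        "excluded_medium_range_U", "active")
  # peaks with zero active candidates are dropped from restraint generation
  for (ln in names(peaks)) {
    ids <- peaks[[ln]]$peak_id
    has_active <- ids %in% cand$peak_id[cand$list_name == ln &
                                          cand$status == "active"]
    if (any(!has_active)) {
      dropped[[ln]] <- ids[!has_active]
    }
  }
  attr(cand, "dropped_peaks") <- dropped
  cand
}

# template distances for candidate proton pairs; NA where atoms missing
candidate_template_distances <- function(candidates, ensemble) {
  models <- if (inherits(ensemble, "ensemble")) ensemble$models else ensemble
  topo <- models[[1]]$topology
  key_a <- paste0(candidates$res_a, ":", candidates$atom_a)
  key_b <- paste0(candidates$res_b, ":", candidates$atom_b)
  ia <- unname(topo$index[key_a])
  ib <- unname(topo$index[key_b])
  sapply(models, function(m) {
    d <- rep(NA_real_, nrow(candidates))
    ok <- !is.na(ia) & !is.na(ib)
    d[ok] <- sqrt(rowSums((m$xyz[ia[ok], , drop = FALSE] -
                             m$xyz[ib[ok], , drop = FALSE])^2))
    d
  })
}

# score p_d for all candidates (template = NULL -> class priors).
# Candidates of both forms are scored against the template: U-form
# possibilities whose protons are far apart in the structured-form
# template lose distance plausibility and are stripped, which is how
# unstructured-form peaks end up excluded from restraint generation.
score_pd_all <- function(candidates, template, cycle_index, config) {
  prior <- unname(config$no_template_pd[candidates$sep_class])
  if (is.null(template)) {
    candidates$p_d <- prior
  } else {
    sigma_D <- config$sigma_D_schedule[min(cycle_index,
                                           length(config$sigma_D_schedule))]
    r0 <- candidate_template_distances(candidates, template)
    r0 <- matrix(r0, nrow = nrow(candidates))
    n <- config$n_exponent
    z <- n * (config$r_min - r0) / sqrt(n^2 * sigma_D^2 + config$gamma_D^2)
    pd <- rowMeans(config$k_D * stats::pnorm(z))
    miss <- is.na(pd) & candidates$status != "excluded_medium_range_U"
    if (any(miss)) {
      warning(sum(miss), " candidates reference atoms absent from the template; using class priors")
    }
    pd[is.na(pd)] <- prior[is.na(pd)]
    # medium-range U-form possibilities describe the unstructured
    # molecule's own contacts; they keep the coil class priors rather
    # than being measured against the structured-form template
    excl <- candidates$status == "excluded_medium_range_U"
    pd[excl] <- prior[excl]
    candidates$p_d <- pd
  }
  candidates$p <- candidates$p_f * candidates$p_d
  candidates
}

#' Strip low-probability candidates
#'
#' Per peak, candidates with P strictly below P_max / f are flagged
#' `stripped` (retaining their scores for audit); the top candidate always
#' survives, and ties at P_max all survive. P_max is taken over all of the
#' peak's surviving assignment possibilities including the medium-range
#' U-form ones: a peak whose dominant interpretation is an
#' unstructured-form contact thereby sheds its weaker structured-form
#' candidates and drops out of restraint generation.
#'
#' @param candidates candidate data.frame with `p` filled in.
#' @param f stripping factor (> 1).
#' @export
strip_candidates <- function(candidates, f) {
  stopifnot(f > 1)
  act <- candidates$status == "active"
  live <- act | candidates$status == "excluded_medium_range_U"
  if (!any(act)) return(candidates)
  key <- paste(candidates$list_name, candidates$peak_id)
  pmaxs <- tapply(candidates$p[live], key[live], max)
  thr <- pmaxs[key] / f
  strip <- act & !is.na(thr) & candidates$p < thr
  candidates$status[strip] <- "stripped"
  candidates
}

#' Run the iterative assignment / structure-calculation cycles
#'
#' Cycle 1 scores distance plausibility with the template-free class
#' priors; each later cycle rescores against the previous cycle's template
#' ensemble with that cycle's sigma_D, then strips with that cycle's f.
#' After every stripping except the last, `engine` converts the surviving
#' assignments into a new template ensemble.
#'
#' @param peaks a [peak_list] or named list of them.
#' @param shifts a [shift_table].
#' @param engine `function(restraint_set, cycle) -> ensemble` (a template
#'   provider, e.g. a wrapper around [anneal_pool()] + [select_ensemble()]).
#' @param config an [ira_config()].
#' @param d_max,i_min calibration parameters passed to
#'   [assignments_to_restraints()].
#' @return list: `candidates` (final scores and statuses), `audit`
#'   (per-cycle counts), `restraints` (final restraint set), `template`
#'   (last engine ensemble).
#' @export
run_cycles <- function(peaks, shifts, engine, config = ira_config(),
                       d_max = 4.25, i_min = NULL) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks = peaks)
  n_cycles <- length(config$f_schedule)
  cand <- generate_candidates(peaks, shifts, config)
  template <- NULL
  audit <- list()
  for (cy in seq_len(n_cycles)) {
    cand <- score_pd_all(cand, template, cy, config)
    cand <- strip_candidates(cand, config$f_schedule[cy])
    key <- paste(cand$list_name, cand$peak_id)
    act <- cand$status == "active"
    n_unamb <- sum(table(key[act]) == 1)
    audit[[cy]] <- data.frame(
      cycle = cy, f = config$f_schedule[cy],
      sigma_D = config$sigma_D_schedule[cy],
      n_active = sum(act), n_stripped = sum(cand$status == "stripped"),
      n_excluded = sum(cand$status == "excluded_medium_range_U"),
      n_peaks_assigned = length(unique(key[act])),
      n_unambiguous = n_unamb)
    if (cy < n_cycles) {
      rs <- assignments_to_restraints(cand, peaks, d_max = d_max, i_min = i_min)
      template <- tryCatch(engine(rs, cy), error = function(e) {
        stop(structure(class = c("ira_engine_error", "error", "condition"),
                       list(message = paste0("engine failed in cycle ", cy,
                                             ": ", conditionMessage(e)),
                            call = sys.call(-1),
                            state = list(candidates = cand,
                                         audit = do.call(rbind, audit)))))
      })
    }
  }
  list(candidates = cand, audit = do.call(rbind, audit),
       restraints = assignments_to_restraints(cand, peaks, d_max = d_max,
                                              i_min = i_min),
       template = template)
}

#' Convert surviving assignments into ambiguous distance restraints
#'
#' One restraint per peak that retains at least one active S-form
#' candidate; its member pairs are the active S-form candidates' proton
#' pairs; the target distance comes from [calibrate_noe_distance()]
#' against the smallest intensity among restrained peaks (per list).
#' Peaks whose active candidates are all U-form are attributed to the
#' unstructured molecule and produce no restraint. Upper bounds of
#' restraints involving pseudo-atoms (`Q*`) get +1.0 Angstrom.
#'
#' @param candidates candidate table after stripping.
#' @param peaks the peak lists the candidates refer to.
#' @param d_max,flat_frac calibration parameters.
#' @param i_min reference intensity; default: per-list minimum over
#'   restrained peaks.
#' @return a [restraint_set()].
#' @export
assignments_to_restraints <- function(candidates, peaks, d_max = 4.25,
                                      flat_frac = 0.33, i_min = NULL) {
  if (inherits(peaks, "peak_list")) peaks <- list(peaks = peaks)
  act <- candidates[candidates$status == "active" & candidates$form == "S", ]
  dist_list <- list()
  for (ln in unique(act$list_name)) {
    pk <- peaks[[ln]]
    sub <- act[act$list_name == ln, ]
    ids <- unique(sub$peak_id)
    inten <- stats::setNames(pk$intensity, pk$peak_id)[ids]
    imin_ln <- i_min %||% min(inten)
    cal <- calibrate_noe_distance(unname(inten), imin_ln, d_max, flat_frac)
    for (k in seq_along(ids)) {
      mem <- sub[sub$peak_id == ids[k],
                 c("res_a", "atom_a", "res_b", "atom_b")]
      mem <- unique(mem)
      upper <- cal$upper[k]
      if (any(startsWith(mem$atom_a, "Q") | startsWith(mem$atom_b, "Q"))) {
        upper <- upper + 1.0  # methyl pseudo-atom correction
      }
      dist_list[[length(dist_list) + 1]] <- distance_restraint(
        mem, target = cal$target[k], lower = cal$lower[k], upper = upper,
        kind = "noe", peak_id = ids[k])
    }
  }
  restraint_set(distance = dist_list)
}

#' Export final assignments as a TSV crosswalk
#' @param candidates candidate table.
#' @param path output path.
#' @export
export_assignments <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the candidate audit trail as JSON-lines
#' @param candidates candidate table (all statuses retained).
#' @param path output path.
#' @param cycle optional cycle tag added to every record.
#' @export
write_ira_audit <- function(candidates, path, cycle = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(candidates))) {
    rec <- as.list(candidates[i, ])
    rec$cycle <- cycle
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
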