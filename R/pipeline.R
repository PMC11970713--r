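# End-to-end orchestration: iterative assignment + structure calculation,
# and the titration analysis. Configs are plain named lists (or a YAML
# file with the same structure via read_run_config); all printed protocol
# constants are the defaults of the component configs.

#' Read a pipeline run configuration from YAML
#'
#' Sections mirror the argument structure of [run_structure_pipeline()] /
#' [run_titration_pipeline()]: `inputs` (file paths), `ira`, `engine`,
#' `metal`, `ncs`, `outputs`, `seed`.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c(cfg$inputs$shifts, cfg$inputs$dihedral_predictions)) {
    if (!is.null(f) && !file.exists(f)) stop("configured input missing: ", f)
  }
  cfg
}

#' Default engine configuration
#'
#' Pool sizes are desk-scale defaults: small, fast template ensembles
#' inside the assignment cycles, a larger pool for the final calculation.
#'
#' @param n_pool final-pool size.
#' @param n_select ensemble size kept from the pool (10, matching the
#'   published selection).
#' @param cycle_pool,cycle_select pool/ensemble size for per-cycle
#'   template structures.
#' @param schedule,cycle_schedule [anneal_schedule()]s for the final pool
#'   and the per-cycle templates.
#' @export
engine_config <- function(n_pool = 30, n_select = 10, cycle_pool = 4,
                          cycle_select = 3,
                          schedule = anneal_schedule(),
                          cycle_schedule = anneal_schedule(n_stages = 6,
                                                           maxit = 80,
                                                           final_maxit = 150)) {
  list(n_pool = n_pool, n_select = n_select, cycle_pool = cycle_pool,
       cycle_select = cycle_select, schedule = schedule,
       cycle_schedule = cycle_schedule)
}

restraint_sep_class <- function(r) {
  seps <- abs(r$pairs$res_a - r$pairs$res_b)
  separation_class(0, min(seps))
}

restraint_counts <- function(rs) {
  if (!length(rs$distance)) {
    return(data.frame(kind = character(0), sep_class = character(0),
                      n = integer(0)))
  }
  kinds <- vapply(rs$distance, `[[`, "", "kind")
  seps <- vapply(rs$distance, restraint_sep_class, "")
  as.data.frame(table(kind = kinds, sep_class = seps),
                responseName = "n", stringsAsFactors = FALSE)
}

ensemble_stats <- function(ens, topology) {
  models <- ens$models
  bb <- which(topology$atoms$atom %in% c("N", "CA", "C"))
  n <- length(models)
  prs <- if (n >= 2) utils::combn(n, 2) else matrix(numeric(0), 2, 0)
  rmsds <- apply(prs, 2, function(ij) {
    superpose_rmsd(models[[ij[1]]], models[[ij[2]]], bb)$rmsd
  })
  data.frame(model_a = prs[1, ], model_b = prs[2, ], backbone_rmsd = rmsds)
}

violation_stats <- function(rs, ens) {
  models <- ens$models
  if (!length(rs$distance) || !length(models)) return(numeric(0))
  topo <- models[[1]]$topology
  vapply(models, function(m) {
    sum(vapply(rs$distance, function(r) {
      ia <- unname(topo$index[paste0(r$pairs$res_a, ":", r$pairs$atom_a)])
      ib <- unname(topo$index[paste0(r$pairs$res_b, ":", r$pairs$atom_b)])
      ok <- !is.na(ia) & !is.na(ib)
      if (!any(ok)) return(0L)
      d <- sqrt(rowSums((m$xyz[ia[ok], , drop = FALSE] -
                           m$xyz[ib[ok], , drop = FALSE])^2))
      reff <- effective_distance(d)
      as.integer(reff < r$lower - 0.1 || reff > r$upper + 0.1)
    }, integer(1)))
  }, numeric(1))
}

#' Run the full assignment + structure-calculation pipeline
#'
#' Candidate generation, the iterative stripping cycles (with per-cycle
#' template structures from the annealing engine), final restraint
#' generation, pool annealing and ensemble selection by combined energy
#' and chemical-shift pseudo-energy. In coupled mode the apo and
#' metal-bound forms are refined simultaneously under the NCS penalty.
#'
#' @param config named list: `sequence` (one-letter, modeled range),
#'   `first_residue`; `shifts` ([shift_table] or TSV path); `peaks` (named
#'   list of [peak_list]s, or of `list(path, dialect, dims)`);
#'   `dihedral_predictions` (data.frame/path, optional);
#'   `beta_probabilities` (named vector, optional); `metal` (optional
#'   `list(mode, coordinating_atoms)`); `shifts_bound`, `peaks_bound`,
#'   `ncs_segments`, `free_segments` for coupled mode (`coupled = TRUE`);
#'   `ira` ([ira_config()]), `engine` ([engine_config()]), `seed`,
#'   `output_dir` (optional).
#' @return list: `ensemble` (or `ensemble_apo`/`ensemble_bound`),
#'   `assignments`, `report`.
#' @export
run_structure_pipeline <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$sequence), !is.null(cfg$shifts), !is.null(cfg$peaks))
  seed <- cfg$seed %||% 1L
  first <- cfg$first_residue %||% 1L
  iracfg <- cfg$ira %||% ira_config()
  eng <- cfg$engine %||% engine_config()

  shifts <- if (is.character(cfg$shifts)) parse_shift_table(cfg$shifts) else cfg$shifts
  peaks <- lapply(cfg$peaks, function(p) {
    if (inherits(p, "peak_list")) p
    else parse_peak_list(p$path, p$dialect %||% "tsv", p$dims)
  })

  if (is.null(iracfg$sigma_f)) {
    iracfg$sigma_f <- estimate_sigma_f(peaks, shifts, iracfg)
  }

  metal_atoms <- if (!is.null(cfg$metal)) cfg$metal$coordinating_atoms else NULL
  restraint_refs <- if (!is.null(metal_atoms)) {
    c(atom_ref(metal_atoms$res, metal_atoms$atom),
      if (!is.null(metal_atoms$attached))
        atom_ref(metal_atoms$res, metal_atoms$attached))
  } else character(0)
  topo <- build_topology(cfg$sequence, restraint_refs, first_residue = first)

  aux <- restraint_set()
  if (!is.null(cfg$dihedral_predictions)) {
    preds <- if (is.character(cfg$dihedral_predictions))
      parse_dihedral_predictions(cfg$dihedral_predictions) else cfg$dihedral_predictions
    aux <- merge_restraints(aux, restraint_set(dihedral = make_dihedral_restraints(preds)))
  }
  if (!is.null(cfg$beta_probabilities)) {
    hb <- make_hbond_restraints(cfg$beta_probabilities, cfg$sequence,
                                c(first, first + nchar(cfg$sequence) - 1L))
    aux <- merge_restraints(aux, restraint_set(distance = hb))
  }

  engine <- function(rs, cycle) {
    pool <- anneal_pool(topo, merge_restraints(rs, aux),
                        n_pool = eng$cycle_pool,
                        seed = (seed + 1009L * cycle) %% 2147483647L,
                        schedule = eng$cycle_schedule)
    select_ensemble(pool, n_select = eng$cycle_select)
  }

  ira_res <- run_cycles(peaks, shifts, engine, iracfg)
  final_rs <- merge_restraints(ira_res$restraints, aux)

  predictor <- default_shift_predictor()
  out <- list(assignments = ira_res$candidates, audit = ira_res$audit)

  if (isTRUE(cfg$coupled)) {
    stopifnot(!is.null(cfg$metal), !is.null(cfg$ncs_segments))
    topo_b <- build_topology(cfg$sequence, restraint_refs,
                             first_residue = first, metal = TRUE)
    metal_rs <- make_metal_restraints(metal_atoms, cfg$metal$mode %||% "explicit")
    rs_bound <- merge_restraints(final_rs, metal_rs)
    ncs <- make_ncs_coupling(cfg$ncs_segments, cfg$free_segments %||% list())
    runs <- lapply(seq_len(eng$n_pool), function(i) {
      anneal_coupled(topo_b, final_rs, rs_bound, ncs,
                     seed = (seed + 7919L * i) %% 2147483647L,
                     schedule = eng$schedule)
    })
    tot <- vapply(runs, function(r) sum(r$apo$energy) + sum(r$bound$energy),
                  numeric(1))
    keep <- order(tot)[seq_len(min(eng$n_select, length(runs)))]
    ens_apo <- select_ensemble(lapply(runs[keep], `[[`, "apo"),
                               shifts, predictor, n_select = length(keep))
    ens_bound <- select_ensemble(lapply(runs[keep], `[[`, "bound"),
                                 cfg$shifts_bound %||% shifts, predictor,
                                 n_select = length(keep))
    out$ensemble_apo <- ens_apo
    out$ensemble_bound <- ens_bound
    stats <- ensemble_stats(ens_apo, topo_b)
  } else {
    pool <- anneal_pool(topo, final_rs, n_pool = eng$n_pool, seed = seed,
                        schedule = eng$schedule)
    ens <- select_ensemble(pool, shifts, predictor, n_select = eng$n_select)
    out$ensemble <- ens
    stats <- ensemble_stats(ens, topo)
  }

  main_ens <- out$ensemble %||% out$ensemble_apo
  out$report <- list(
    cycles = ira_res$audit,
    restraint_counts = restraint_counts(final_rs),
    ensemble_stats = stats,
    violations = violation_stats(final_rs, main_ens),
    energies = t(vapply(main_ens$models, `[[`, numeric(7), "energy")),
    seed = seed)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$ensemble)) {
      write_ensemble(out$ensemble, file.path(cfg$output_dir, "ensemble.pdb"))
    } else {
      write_ensemble(out$ensemble_apo, file.path(cfg$output_dir, "ensemble_apo.pdb"))
      write_ensemble(out$ensemble_bound, file.path(cfg$output_dir, "ensemble_bound.pdb"))
    }
    export_assignments(out$assignments,
                       file.path(cfg$output_dir, "assignments.tsv"))
    write_report(out$report, cfg$output_dir)
  }
  out
}

#' Run the titration analysis pipeline
#'
#' Tracks HSQC peaks across the series (the intermediate-exchange dropout
#' signature of binding-site residues), then computes the per-residue
#' shift-perturbation profile between the apo and saturated states and
#' ranks candidate binding-site residues. If an assigned bound-form shift
#' table is supplied (`shifts_bound`, the usual situation: the endpoint is
#' reassigned from dedicated experiments), the profile compares the two
#' assigned tables over all shared atoms; otherwise an endpoint table is
#' reconstructed from the tracked peak positions (amide shifts only).
#' Truncation thresholds come from [estimate_tau()] on reference residues,
#' falling back to the configured defaults with a warning.
#'
#' @param config named list: `series` (a [titration_series]);
#'   `shifts_apo` ([shift_table], S- and optionally U-form apo entries);
#'   `shifts_bound` (optional [shift_table] of the saturated state);
#'   `reference_residues` (optional, for [estimate_tau()]);
#'   `matching_radius` (per-nucleus, default `c(HN = 0.06, N = 0.6)`);
#'   `k` (ranking depth, default 3); `csp` ([csp_config()]).
#' @return list: `trajectories`, `profile`, `ranking`,
#'   `broadened_residues`, `tau`, `report`.
#' @export
run_titration_pipeline <- function(config) {
  cfg <- config
  series <- cfg$series
  stopifnot(inherits(series, "titration_series"))
  if (length(series$points) < 2) stop("titration series needs at least two points")
  shifts_apo <- cfg$shifts_apo
  radii <- cfg$matching_radius %||% c(HN = 0.06, N = 0.6)
  k <- cfg$k %||% 3
  csp <- cfg$csp %||% csp_config()

  traj <- track_titration(series, radii)

  # map apo peaks to residues through the apo shift table (HN, N)
  sh <- as.data.frame(shifts_apo)
  amides <- merge(sh[sh$atom == "HN", c("residue_index", "form", "shift")],
                  sh[sh$atom == "N", c("residue_index", "form", "shift")],
                  by = c("residue_index", "form"), suffixes = c("_hn", "_n"))
  apo_pk <- series$points[[1]]$peaks
  apo_pos <- peak_positions(apo_pk)
  assign_res <- function(w) {
    d2 <- ((amides$shift_hn - w[1]) / 0.03)^2 + ((amides$shift_n - w[2]) / 0.3)^2
    i <- which.min(d2)
    if (d2[i] > 25) return(c(NA, NA))
    c(amides$residue_index[i], amides$form[i])
  }
  res_map <- t(apply(apo_pos, 1, assign_res))
  res_of <- as.integer(res_map[, 1]); form_of <- res_map[, 2]

  n_pts <- length(series$points)
  end_rows <- list()
  broadened <- integer(0)
  for (i in seq_along(traj)) {
    if (is.na(res_of[i]) || form_of[i] != "S") next
    st <- traj[[i]]$status
    mid <- st[-c(1, n_pts)]
    if (any(mid == "broadened_out")) broadened <- c(broadened, res_of[i])
    if (st[n_pts] == "broadened_out") next
    final <- apo_pos[i, ] + traj[[i]]$drift
    rt <- sh$residue_type[sh$residue_index == res_of[i]][1]
    end_rows[[length(end_rows) + 1]] <- data.frame(
      residue_index = res_of[i], residue_type = rt,
      atom = c("HN", "N"), shift = as.numeric(final), form = "S",
      stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$shifts_bound)) {
    bt <- as.data.frame(cfg$shifts_bound)
    end_tab <- shift_table(bt[bt$form == "S", ])
    apo_tab <- shift_table(sh[sh$form == "S", ])
  } else {
    end_tab <- shift_table(do.call(rbind, end_rows))
    apo_tab <- shift_table(sh[sh$form == "S" & sh$atom %in% c("HN", "N") &
                                sh$residue_index %in% end_tab$residue_index, ])
  }

  tau <- if (!is.null(cfg$reference_residues)) {
    estimate_tau(apo_tab, end_tab, cfg$reference_residues, csp)
  } else {
    warning("no reference residues configured; using default truncation thresholds")
    csp$tau_by_atomclass
  }
  csp$tau_by_atomclass <- tau
  profile <- compute_delta_rms(apo_tab, end_tab, csp)
  ranking <- rank_binding_site(profile, k)

  report <- list(n_points = n_pts,
                 ratios = vapply(series$points, `[[`, numeric(1), "ratio"),
                 n_trajectories = length(traj),
                 broadened_residues = sort(unique(broadened)),
                 tau = tau, ranking = ranking)
  list(trajectories = traj, profile = profile, ranking = ranking,
       broadened_residues = sort(unique(broadened)), tau = tau,
       report = report)
}

#' Write a run report (JSON plus a human-readable summary)
#' @param report report list from a pipeline run.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines("run report", con)
  for (nm in names(report)) {
    writeLines(paste0("== ", nm), con)
    writeLines(utils::capture.output(print(report[[nm]])), con)
  }
  invisible(dir)
}
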