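#!/usr/bin/env Rscript
# Generate the synthetic study system: a miniature three-strand beta-sheet
# domain with a trigonal tri-sulfur metal site, coexisting in a structured
# (S) and unstructured (U) form. Writes every input the later analysis
# stages read: assigned shift tables for both forms and both metal states,
# NOESY peak lists (with held-out ground truth), TALOS-style dihedral
# predictions, and an HSQC titration series.

library(irafold)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("building toy ground-truth fold (seed ", seed, ") ...")
truth <- make_toy_fold(6, seed = seed)
saveRDS(truth, file.path(out, "truth.rds"))
message("  sequence: ", truth$sequence)
message("  site residues: ", paste(truth$site_residues, collapse = ", "))

shifts <- simulate_shifts(truth)
write_shift_table(shifts, file.path(out, "shifts_apo.tsv"))
shifts_bound <- simulate_shifts(truth, state = "bound")
write_shift_table(shifts_bound, file.path(out, "shifts_bound.tsv"))

sim <- simulate_noesy(truth)
write_peak_list(sim$peaks$n15, file.path(out, "noesy_n15.tsv"))
write_peak_list(sim$peaks$c13, file.path(out, "noesy_c13.tsv"))
utils::write.table(sim$truth_map, file.path(out, "noesy_truth_map.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("NOESY: ", nrow(sim$peaks$n15), " 15N-edited + ", nrow(sim$peaks$c13),
        " 13C-edited peaks (", sum(sim$truth_map$is_decoy), " U-form decoys)")

dihp <- simulate_dihedral_predictions(truth)
write_dihedral_predictions(dihp, file.path(out, "dihedral_pred.tab"))

ser <- simulate_titration(truth)
gt <- attr(ser, "ground_truth")
for (i in seq_along(ser$points)) {
  write_peak_list(ser$points[[i]]$peaks,
                  file.path(out, sprintf("hsqc_ratio_%04.2f.tsv",
                                         ser$points[[i]]$ratio)))
}
saveRDS(ser, file.path(out, "titration.rds"))
jsonlite::write_json(
  list(seed = seed, sequence = truth$sequence,
       site_residues = truth$site_residues,
       bound_fraction = gt$bound_fraction),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
message("titration: ", length(ser$points), " points, bound fraction ",
        paste(round(gt$bound_fraction, 2), collapse = " "))
message("done; inputs in ", out)
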