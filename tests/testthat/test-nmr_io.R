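test_that("sparky peak lists parse, with header skipping and errors at bad rows", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("Assignment  w1  w2  Height", "",
               "?-? 8.21 120.3 1.5e6",
               "?-? 7.95 118.2 2.2e5"), f)
  pk <- parse_peak_list(f, "sparky")
  expect_s3_class(pk, "peak_list")
  expect_equal(nrow(pk), 2)
  expect_equal(peak_dims(pk), c("HN", "N"))
  expect_equal(peak_positions(pk)[1, ], c(w1 = 8.21, w2 = 120.3),
               ignore_attr = TRUE)
  expect_equal(pk$intensity[1], 1.5e6)

  writeLines(c("Assignment  w1  w2  Height"), f)
  expect_warning(pk0 <- parse_peak_list(f, "sparky"), "no data rows")
  expect_equal(nrow(pk0), 0)

  writeLines(c("?-? 8.21 bad 1.5e6"), f)
  expect_error(parse_peak_list(f, "sparky"), "line 1")
})

test_that("peak lists fold negative intensities to magnitude with a flag", {
  expect_message(
    pk <- peak_list(cbind(c(8.1, 8.2), c(120, 121)), c("HN", "N"),
                    c(-100, 50)),
    "folded")
  expect_true(all(pk$intensity > 0))
  expect_true(attr(pk, "folded_negative"))
})

test_that("peak list tsv dialect round-trips positions and ids", {
  pk <- peak_list(cbind(c(8.123, 7.456), c(120.111, 118.222), c(4.3, 2.1)),
                  c("HN", "N", "H"), c(10, 20))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peak_list(pk, f)
  pk2 <- parse_peak_list(f, "tsv")
  expect_equal(peak_dims(pk2), peak_dims(pk))
  expect_equal(pk2$peak_id, pk$peak_id)
  expect_equal(peak_positions(pk2), peak_positions(pk), tolerance = 1e-3)
})

test_that("shift tables validate duplicates, forms and nucleus consistency", {
  df <- data.frame(residue_index = c(44, 44), residue_type = "M",
                   atom = c("CE", "CE"), shift = c(17.2, 17.3),
                   form = "S")
  expect_error(shift_table(df), "duplicate")
  df$form <- c("S", "U")
  st <- shift_table(df)
  expect_equal(nrow(st), 2)
  expect_equal(st$nucleus, c("C", "C"))

  # missing form defaults to S with a message
  expect_message(st2 <- shift_table(df[1, setdiff(names(df), "form")]),
                 "defaulting")
  expect_equal(st2$form, "S")

  bad <- data.frame(residue_index = 1, residue_type = "A", atom = "HN",
                    nucleus = "C", shift = 8.2, form = "S")
  expect_error(shift_table(bad), "inconsistent")
})

test_that("shift table TSV round-trips", {
  st <- shift_table(data.frame(residue_index = c(1, 2), residue_type = c("A", "C"),
                               atom = c("HN", "CA"), shift = c(8.2412, 58.3311),
                               form = c("S", "U")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_shift_table(st, f)
  st2 <- parse_shift_table(f)
  expect_equal(st2$shift, st$shift, tolerance = 1e-3)
  expect_equal(st2$form, st$form)
})

test_that("dihedral prediction tables parse and validate", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("residue_index residue_type angle value spread class",
               "5 V phi -120 10 Strong",
               "5 V psi 130 12 Dyn"), f)
  dp <- parse_dihedral_predictions(f)
  expect_equal(nrow(dp), 2)
  expect_equal(dp$class, c("Strong", "Dyn"))

  writeLines(c("residue_index residue_type angle value spread class",
               "5 V phi -120 -1 Strong"), f)
  expect_error(parse_dihedral_predictions(f), "negative")

  writeLines(c("residue_index residue_type angle value class",
               "5 V phi -120 Strong"), f)
  expect_error(parse_dihedral_predictions(f), "spread")
})

test_that("multi-model PDB writes and round-trips; metal becomes HETATM", {
  topo <- build_topology("ACM", c("2:SG", "3:SD"), metal = TRUE)
  n <- nrow(topo$atoms)
  m1 <- list(xyz = matrix(rnorm(3 * n, sd = 5), n, 3), topology = topo)
  m2 <- list(xyz = m1$xyz + 0.5, topology = topo)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(list(m1, m2), f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 2)
  expect_equal(sum(grepl("^HETATM", txt)), 2)
  expect_true(any(grepl("AG$", txt[grepl("^HETATM", txt)])))

  models <- read_ensemble(f)
  expect_equal(length(models), 2)
  expect_equal(as.matrix(models[[1]][, c("x", "y", "z")]), m1$xyz,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(models[[1]]$atom, topo$atoms$atom)

  expect_error(write_ensemble(list(), f), "empty")
  m3 <- list(xyz = m1$xyz[-1, ], topology = build_topology("AC", "2:SG"))
  expect_error(write_ensemble(list(m1, m3), f), "atom counts")
})

test_that("bio3d reads our multi-model PDB identically (independent parser)", {
  skip_if_not_installed("bio3d")
  topo <- build_topology("ACM", c("2:SG", "3:SD"))
  n <- nrow(topo$atoms)
  m1 <- list(xyz = matrix(rnorm(3 * n, sd = 5), n, 3), topology = topo)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(list(m1), f)
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), n)
  expect_equal(round(pdb$atom$x, 3), round(m1$xyz[, 1], 3))
  expect_equal(pdb$atom$elety[1:4], topo$atoms$atom[1:4])
})

test_that("titration series validates ordering and apo reference", {
  pk <- peak_list(cbind(8.2, 120), c("HN", "N"), 1)
  expect_error(titration_series(list(list(ratio = 0.5, peaks = pk))),
               "ratio 0")
  expect_error(titration_series(list(list(ratio = 0, peaks = pk),
                                     list(ratio = 1, peaks = pk),
                                     list(ratio = 0.5, peaks = pk))),
               "nondecreasing")
  ser <- titration_series(list(list(ratio = 0, peaks = pk),
                               list(ratio = 1, peaks = pk)))
  expect_s3_class(ser, "titration_series")
})

test_that("reduced NMR-STAR shift loops parse with alias normalization", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "loop_",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  5 MET H  8.28",
    "  5 MET N  119.6",
    "  5 MET HB2 2.01",
    "  5 MET HB3 2.09",
    "stop_"), f)
  st <- parse_nmrstar_shifts(f)
  expect_s3_class(st, "shift_table")
  # H aliases to HN; the stereo pair collapses onto one HB pseudo entry
  expect_setequal(st$atom, c("HN", "N", "HB"))
  expect_equal(st$shift[st$atom == "HN"], 8.28)
  expect_equal(st$residue_type, rep("M", 3))
  expect_error(parse_nmrstar_shifts(withr::local_tempfile(fileext = ".str")),
               "no such file")
})

test_that("aborted cycles preserve the last completed state", {
  sh <- shift_table(data.frame(
    residue_index = rep(c(1, 5), each = 3), residue_type = "A",
    atom = rep(c("HN", "N", "HA"), 2),
    shift = c(8.10, 119.0, 4.20, 8.60, 124.0, 4.70), form = "S"))
  pk <- peak_list(rbind(c(8.10, 119.0, 4.70)), c("HN", "N", "H"), 1)
  boom <- function(rs, cycle) stop("engine exploded")
  err <- tryCatch(run_cycles(pk, sh, boom), error = function(e) e)
  expect_s3_class(err, "ira_engine_error")
  expect_match(conditionMessage(err), "cycle 1")
  expect_true(is.data.frame(err$state$candidates))
})
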