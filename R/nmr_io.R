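# Domain containers and file I/O: shift tables, peak lists, dihedral
# prediction tables, multi-model PDB ensembles.
#
# Construct numbering is the single coordinate system: residue indices are
# 1-based and ranges are inclusive everywhere.

#' Construct a chemical-shift table
#'
#' A shift table holds assigned chemical shifts, one row per
#' (residue, atom, form). The `form` column distinguishes the structured
#' (`"S"`) and unstructured (`"U"`) conformation of the same polypeptide,
#' which coexist in solution and each carry a full resonance set.
#'
#' @param df data.frame with columns `residue_index`, `residue_type`
#'   (one-letter code), `atom`, `shift` (ppm) and optionally `nucleus` and
#'   `form`. A missing `form` column defaults to `"S"` (with a message); a
#'   missing `nucleus` column is derived from the atom name.
#' @return a `shift_table` (a validated data.frame).
#' @export
shift_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("residue_index", "residue_type", "atom", "shift")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("shift table missing columns: ", paste(miss, collapse = ", "))
  if (!"form" %in% names(df)) {
    message("shift table has no 'form' column; defaulting all entries to form S")
    df$form <- "S"
  }
  if (!"nucleus" %in% names(df)) df$nucleus <- nucleus_of(df$atom)
  df$residue_index <- as.integer(df$residue_index)
  df$shift <- as.numeric(df$shift)
  if (any(!is.finite(df$shift))) stop("non-finite chemical shift in table")
  if (!all(df$form %in% c("S", "U"))) stop("form must be 'S' or 'U'")
  bad <- df$nucleus != nucleus_of(df$atom)
  if (any(bad)) {
    stop("nucleus inconsistent with atom name for: ",
         paste(unique(df$atom[bad]), collapse = ", "))
  }
  key <- paste(df$residue_index, toupper(df$atom), df$form)
  if (anyDuplicated(key)) {
    stop("duplicate shift entries for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df <- df[, c("residue_index", "residue_type", "atom", "nucleus", "shift", "form")]
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Read a chemical-shift table from TSV
#'
#' The canonical dialect is a plain tab-separated file with named columns
#' `residue_index`, `residue_type`, `atom`, `nucleus`, `shift_ppm`, `form`
#' (`nucleus` and `form` optional). Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a [shift_table].
#' @export
parse_shift_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if ("shift_ppm" %in% names(df)) names(df)[names(df) == "shift_ppm"] <- "shift"
  shift_table(df)
}

#' Read assigned shifts from a reduced NMR-STAR file
#'
#' Convenience reader for the `_Atom_chem_shift` loop of an NMR-STAR
#' (BMRB-style) file: rows are mapped onto the package's shift table using
#' `Seq_ID`, `Comp_ID` (three-letter), `Atom_ID` and `Val`. Only this loop
#' is read; the full NMR-STAR schema is out of scope. Legacy atom-name
#' aliases are normalized via `alias_map` (e.g. `H` for the amide proton).
#'
#' @param path file path.
#' @param form conformational form to assign to all entries.
#' @param alias_map named character vector mapping file atom names to
#'   canonical ones.
#' @return a [shift_table].
#' @export
parse_nmrstar_shifts <- function(path, form = "S",
                                 alias_map = c(H = "HN", HA2 = "HA",
                                               HA3 = "HA", HB2 = "HB",
                                               HB3 = "HB")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # locate the atom-chem-shift loop: tag block then data rows
  tag_idx <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (!length(tag_idx)) stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("^\\s*_Atom_chem_shift\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  rows <- list()
  for (ln in lines[body_start:length(lines)]) {
    t <- trimws(ln)
    if (t == "" || startsWith(t, "#")) next
    if (t == "stop_" || startsWith(t, "loop_") || startsWith(t, "_")) break
    tok <- strsplit(t, "\\s+")[[1]]
    if (length(tok) < length(tags)) next
    rows[[length(rows) + 1]] <- tok[seq_along(tags)]
  }
  if (!length(rows)) stop("empty _Atom_chem_shift loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  miss <- setdiff(need, tags)
  if (length(miss)) stop("NMR-STAR loop missing tags: ", paste(miss, collapse = ", "))
  three <- toupper(m[, "Comp_ID"])
  one <- names(AA3)[match(three, AA3)]
  if (anyNA(one)) stop("unknown residue type(s): ",
                       paste(unique(three[is.na(one)]), collapse = ", "))
  atom <- toupper(m[, "Atom_ID"])
  hit <- atom %in% names(alias_map)
  atom[hit] <- alias_map[atom[hit]]
  df <- data.frame(residue_index = as.integer(m[, "Seq_ID"]),
                   residue_type = one, atom = atom,
                   shift = as.numeric(m[, "Val"]), form = form,
                   stringsAsFactors = FALSE)
  # collapse stereo pairs that alias to the same pseudo atom
  df <- df[!duplicated(df[, c("residue_index", "atom", "form")]), ]
  shift_table(df)
}

#' Write a chemical-shift table as TSV
#' @param x a [shift_table].
#' @param path output path.
#' @export
write_shift_table <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "shift"] <- "shift_ppm"
  out$shift_ppm <- sprintf("%.5f", out$shift_ppm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a peak list
#'
#' NOESY/HSQC cross peaks with one position (ppm) per spectral dimension.
#' Intensities are stored as absolute magnitude; negative inputs are folded
#' to magnitude and the list is flagged via `attr(x, "folded_negative")`.
#'
#' @param position numeric matrix (peaks x dims), ppm.
#' @param dims character vector of per-dimension nucleus labels (length 2
#'   or 3), e.g. `c("HN", "N", "H")`.
#' @param intensity numeric vector of peak intensities.
#' @param peak_id optional character ids; defaults to `pk0001`, ...
#' @return a `peak_list` data.frame with columns `peak_id`, `w1..wk`,
#'   `intensity` and a `dims` attribute.
#' @export
peak_list <- function(position, dims, intensity, peak_id = NULL) {
  position <- as.matrix(position)
  if (length(dims) != ncol(position)) stop("len(dims) != number of position columns")
  if (!length(dims) %in% c(2L, 3L)) stop("peak lists must have 2 or 3 dimensions")
  if (nrow(position) != length(intensity)) stop("intensity length mismatch")
  folded <- any(intensity < 0)
  if (folded) message("negative intensities folded to magnitude (", sum(intensity < 0), " peaks)")
  intensity <- abs(as.numeric(intensity))
  if (any(intensity == 0)) stop("zero peak intensity not allowed")
  if (is.null(peak_id)) peak_id <- sprintf("pk%04d", seq_len(nrow(position)))
  if (anyDuplicated(peak_id)) stop("duplicate peak_id")
  df <- data.frame(peak_id = as.character(peak_id), stringsAsFactors = FALSE)
  for (k in seq_along(dims)) df[[paste0("w", k)]] <- as.numeric(position[, k])
  df$intensity <- intensity
  attr(df, "dims") <- as.character(dims)
  attr(df, "folded_negative") <- folded
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Dimension labels of a peak list
#' @param x a `peak_list`.
#' @export
peak_dims <- function(x) attr(x, "dims")

#' Position matrix of a peak list
#' @param x a `peak_list`.
#' @export
peak_positions <- function(x) {
  as.matrix(as.data.frame(x)[, paste0("w", seq_along(peak_dims(x))), drop = FALSE])
}

# ppm-range heuristic used when a Sparky file does not announce its nuclei.
infer_dims <- function(pos) {
  apply(pos, 2, function(v) {
    m <- mean(v)
    if (m >= 90) "N" else if (m >= 12) "C" else if (all(v >= 5.2 & v <= 11.5)) "HN" else "H"
  })
}

#' Read a peak list
#'
#' Two dialects. `sparky`: whitespace table whose rows are
#' `assignment w1 ... wk intensity` (header lines starting with
#' `Assignment` or `#`, and blank lines, are skipped); per-dimension nuclei
#' are taken from `dims` or inferred from ppm ranges. `tsv`: the package's
#' own tab-separated format written by [write_peak_list()], which stores
#' `dims` in a `# dims:` comment line.
#'
#' @param path file path.
#' @param dialect `"sparky"` or `"tsv"`.
#' @param dims optional character vector of per-dimension nucleus labels.
#' @return a [peak_list].
#' @export
parse_peak_list <- function(path, dialect = c("sparky", "tsv"), dims = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "tsv") {
    dimline <- grep("^#\\s*dims:", lines, value = TRUE)
    if (is.null(dims) && length(dimline)) {
      dims <- strsplit(trimws(sub("^#\\s*dims:", "", dimline[1])), "\\s+")[[1]]
    }
    df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
    if (is.null(dims)) stop("tsv peak list lacks a '# dims:' line and no dims given")
    return(peak_list(as.matrix(df[, wcols, drop = FALSE]), dims, df$intensity, df$peak_id))
  }
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*(Assignment|#)", lines)
  rows <- lines[keep]
  lineno <- which(keep)
  if (!length(rows)) {
    warning("peak list file contains no data rows: ", path)
    dims <- dims %||% c("HN", "N")
    pos <- matrix(numeric(0), 0, length(dims))
    return(peak_list(pos, dims, numeric(0), character(0)))
  }
  toks <- strsplit(trimws(rows), "\\s+")
  nnum <- length(toks[[1]]) - 1L
  pos <- matrix(NA_real_, length(rows), nnum - 1L)
  height <- numeric(length(rows))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    vals <- suppressWarnings(as.numeric(tk[-1]))
    if (length(tk) != nnum + 1L || any(is.na(vals))) {
      stop("malformed peak row at line ", lineno[i], " of ", path)
    }
    pos[i, ] <- vals[seq_len(nnum - 1L)]
    height[i] <- vals[nnum]
  }
  if (is.null(dims)) dims <- infer_dims(pos)
  peak_list(pos, dims, height, sprintf("pk%04d", seq_along(rows)))
}

#' Write a peak list (tsv dialect, or a Sparky-style list)
#' @param x a [peak_list].
#' @param path output path.
#' @param dialect output dialect; `tsv` round-trips exactly through
#'   [parse_peak_list()], `sparky` writes an `Assignment w1 .. Height` table.
#' @export
write_peak_list <- function(x, path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  dims <- peak_dims(x)
  pos <- peak_positions(x)
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# dims: ", paste(dims, collapse = " ")), con)
    df <- data.frame(peak_id = x$peak_id, stringsAsFactors = FALSE)
    for (k in seq_along(dims)) df[[paste0("w", k)]] <- sprintf("%.5f", pos[, k])
    df$intensity <- sprintf("%.8g", x$intensity)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- paste(c("Assignment", paste0("w", seq_along(dims)), "Height"), collapse = "\t")
    rows <- apply(cbind("?-?", format(round(pos, 3), trim = TRUE),
                        format(x$intensity, trim = TRUE)), 1, paste, collapse = "\t")
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

#' Construct a titration series
#'
#' @param points list of `list(ratio = <metal:protein molar ratio>,
#'   peaks = <peak_list>)`, ordered by nondecreasing ratio; the first point
#'   must be the apo reference (ratio 0).
#' @export
titration_series <- function(points) {
  ratios <- vapply(points, function(p) p$ratio, numeric(1))
  if (length(points) == 0) stop("empty titration series")
  if (ratios[1] != 0) stop("titration series must start at molar ratio 0 (apo reference)")
  if (is.unsorted(ratios)) stop("molar ratios must be nondecreasing")
  structure(list(points = points), class = "titration_series")
}

#' Read TALOS-style dihedral predictions
#'
#' Whitespace-separated table with header columns `residue_index`,
#' `residue_type`, `angle` (phi/psi), `value`, `spread`, `class`.
#' The classification tag (e.g. `Strong`, `Dyn`) is preserved verbatim;
#' filtering happens at restraint generation.
#'
#' @param path file path.
#' @return data.frame of per-(residue, angle) predictions.
#' @export
parse_dihedral_predictions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue_index", "angle", "value", "spread", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dihedral prediction table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$angle %in% c("phi", "psi"))) stop("angle must be phi or psi")
  if (any(df$value < -180 | df$value > 180)) stop("predicted angle outside [-180, 180]")
  if (any(df$spread < 0)) stop("negative prediction spread")
  df$residue_index <- as.integer(df$residue_index)
  df
}

#' Write dihedral predictions in the format read by
#' [parse_dihedral_predictions()]
#' @param df prediction data.frame.
#' @param path output path.
#' @export
write_dihedral_predictions <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- multi-model PDB ---------------------------------------------------

element_of <- function(atom) {
  a <- toupper(atom)
  ifelse(a == "AG", "AG", substr(sub("^[0-9]+", "", a), 1, 1))
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL records, occupancy 1.00, element column filled.
#' A metal atom (residue index 0, atom `AG`) is written as a HETATM.
#'
#' @param models list of conformers (each with `$xyz` and `$topology`), or
#'   an [select_ensemble()] result.
#' @param path output path.
#' @export
write_ensemble <- function(models, path) {
  if (inherits(models, "ensemble")) models <- models$models
  if (!length(models)) stop("empty model list")
  at <- models[[1]]$topology$atoms
  n_atoms <- nrow(at)
  for (m in models) {
    if (nrow(m$topology$atoms) != n_atoms)
      stop("inconsistent atom counts across models")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    xyz <- models[[mi]]$xyz
    for (i in seq_len(n_atoms)) {
      is_het <- at$res[i] == 0L
      rec <- if (is_het) "HETATM" else "ATOM"
      resn <- if (is_het) " AG" else aa_three(at$res_type[i])
      name <- at$atom[i]
      namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      writeLines(sprintf("%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         rec, i, namef, resn, "A", at$res[i],
                         xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.00, 0.00,
                         element_of(name)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB written by [write_ensemble()]
#'
#' @param path file path.
#' @return list of models, each a data.frame with columns `res`,
#'   `res_type` (three-letter), `atom`, `x`, `y`, `z`, `element`.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      cur <- list()
    } else if (startsWith(tag, "ENDMDL")) {
      models[[length(models) + 1L]] <- do.call(rbind, cur)
      cur <- NULL
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      row <- data.frame(
        res = as.integer(substr(ln, 23, 26)),
        res_type = trimws(substr(ln, 18, 20)),
        atom = trimws(substr(ln, 13, 16)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        element = trimws(substr(ln, 77, 78)),
        stringsAsFactors = FALSE)
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1L]] <- row
    }
  }
  if (!length(models) && !is.null(cur)) models[[1]] <- do.call(rbind, cur)
  if (!length(models)) stop("no models found in ", path)
  models
}
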