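#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Classify an atom name into its NMR nucleus class
#'
#' Atom labels follow IUPAC-like conventions: `HN` (amide proton), `N` and
#' side-chain nitrogens, `C` (carbonyl, reported as `Cprime`), aliphatic
#' carbons (`CA`, `CB`, ...), protons (`HA`, `HB`, pseudo-atoms `QB`, ...)
#' and sulfurs (`SG`, `SD`).
#'
#' @param atom_name character vector of atom labels.
#' @return character vector with values in
#'   `c("HN", "H", "N", "Cprime", "C", "S", "metal")`.
#' @export
nucleus_of <- function(atom_name) {
  out <- character(length(atom_name))
  for (i in seq_along(atom_name)) {
    a <- toupper(atom_name[i])
    out[i] <-
      if (a %in% c("AG", "CU", "ZN")) "metal"
      else if (a == "HN" || a == "H") "HN"
      else if (startsWith(a, "H") || startsWith(a, "Q")) "H"
      else if (startsWith(a, "N")) "N"
      else if (a == "C") "Cprime"
      else if (startsWith(a, "C")) "C"
      else if (startsWith(a, "S")) "S"
      else if (startsWith(a, "O")) "O"
      else stop("cannot classify atom name: ", atom_name[i])
  }
  out
}

# Sequence-separation class used by the assignment priors.
separation_class <- function(res_a, res_b) {
  d <- abs(res_a - res_b)
  ifelse(d == 0, "intra",
    ifelse(d == 1, "sequential",
      ifelse(d == 2, "rd2",
        ifelse(d == 3, "rd3",
          ifelse(d == 4, "rd4", "long")))))
}

# One- to three-letter amino-acid code.
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

aa_three <- function(one) {
  out <- AA3[toupper(one)]
  if (any(is.na(out))) stop("unknown residue type: ",
                            paste(one[is.na(out)], collapse = ", "))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
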