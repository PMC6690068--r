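# Featurization: canonical nonstereo SMILES, a 2048-bit radius-2 circular
# (Morgan/ECFP4) fingerprint, and six physicochemical descriptors (MolWt,
# NumHDonors, NumHAcceptors, NumRotatableBonds, MolLogP, TPSA) min-max
# scaled on the training portion only.  Chemistry is computed with Open
# Babel through ChemmineOB; a "precomputed" path lets the modelling stack
# run on synthetic fingerprints with no chemistry dependency.

.n_fp_bits <- 2048L
.physchem_names <- c("MolWt", "NumHDonors", "NumHAcceptors",
                     "NumRotatableBonds", "MolLogP", "TPSA")
# Open Babel SMARTS for a rotatable bond: non-terminal, non-ring single
# bond not adjacent to a triple bond.
.rotor_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

parse_error <- function(smiles) {
  stop(structure(
    class = c("cpqsar_parse_error", "error", "condition"),
    list(message = paste0("unparsable structure: ", smiles),
         call = NULL, smiles = smiles)))
}

require_chemmineob <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("the Open Babel backend requires the ChemmineOB package",
         call. = FALSE)
  }
}

ob_mol <- function(smiles) {
  require_chemmineob()
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  if (is.null(mols) || !length(mols)) parse_error(smiles)
  mols
}

#' Canonical nonstereo SMILES
#'
#' Canonicalizes a SMILES string and strips stereochemistry, so that
#' stereoisomers map to the same output string; 2D fingerprints cannot
#' distinguish them anyway.  Deterministic and idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical nonstereo SMILES.
#' @export
canonicalize_structure <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) parse_error(s)
    props <- tryCatch(suppressWarnings(ChemmineOB::prop_OB(ob_mol(s))),
                      error = function(e) {
                        if (inherits(e, "cpqsar_parse_error")) stop(e)
                        NULL
                      })
    out <- props$cansmiNS
    if (is.null(out) || !length(out) || is.na(out) || !nzchar(out)) {
      parse_error(s)
    }
    trimws(out[[1L]])
  }, character(1L), USE.NAMES = FALSE)
}

# Fold Open Babel's 4096-bit ECFP4 vector to 2048 bits by OR-ing halves.
fold_fingerprint <- function(bits, n_bits = .n_fp_bits) {
  bits <- as.integer(bits != 0)
  while (length(bits) > n_bits) {
    half <- length(bits) / 2L
    bits <- as.integer(bits[seq_len(half)] | bits[half + seq_len(half)])
  }
  bits
}

#' Raw molecular descriptors
#'
#' Computes, per structure, the radius-2 circular fingerprint folded to
#' 2048 bits and six physicochemical descriptors in native units (MolWt in
#' g/mol; H-bond donor/acceptor and rotatable-bond counts; MolLogP; TPSA
#' in A^2), using Open Babel.  Descriptor definitions follow Open Babel's
#' conventions.
#'
#' @param smiles character vector of canonical SMILES.
#' @return list with `fingerprint` (matrix `length(smiles)` x 2048 of
#'   0/1) and `physchem` (matrix `length(smiles)` x 6, columns `MolWt`,
#'   `NumHDonors`, `NumHAcceptors`, `NumRotatableBonds`, `MolLogP`,
#'   `TPSA`).
#' @export
compute_raw_descriptors <- function(smiles) {
  require_chemmineob()
  n <- length(smiles)
  fp <- matrix(0L, n, .n_fp_bits)
  pc <- matrix(NA_real_, n, length(.physchem_names),
               dimnames = list(NULL, .physchem_names))
  for (i in seq_len(n)) {
    mol <- ob_mol(smiles[[i]])
    props <- suppressWarnings(ChemmineOB::prop_OB(mol))
    if (!nrow(props)) parse_error(smiles[[i]])
    raw_fp <- suppressWarnings(ChemmineOB::fingerprint_OB(mol, "ECFP4"))
    fp[i, ] <- fold_fingerprint(raw_fp)
    rotors <- suppressWarnings(
      ChemmineOB::smartsSearch_OB(mol, .rotor_smarts, uniqueMatches = TRUE))
    pc[i, ] <- c(props$MW, props$HBD, props$HBA1, as.numeric(rotors),
                 props$logP, props$TPSA)
    if (any(!is.finite(pc[i, ]))) parse_error(smiles[[i]])
  }
  list(fingerprint = fp, physchem = pc)
}

#' Fit a min-max scaler
#'
#' Records per-column minima and maxima of the fitting set.  Fit only on
#' the designated training portion; calibration/test/temporal compounds
#' are transformed with the training parameters and may fall outside
#' `[0, 1]` (no clipping).
#'
#' @param x numeric matrix (fitting set, columns = descriptors).
#' @return object of class `minmax_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
            class = "minmax_scaler")
}

#' Apply (or invert) a fitted min-max scaler
#'
#' `apply_scaler` maps `x' = (x - min) / (max - min)`; a degenerate
#' constant column (max == min) maps to 0.  `invert_scaler` recovers
#' native units.
#'
#' @param x numeric matrix or vector with as many columns as the scaler.
#' @param scaler a `minmax_scaler` from [fit_scaler()].
#' @return transformed matrix.
#' @export
apply_scaler <- function(x, scaler) {
  if (!inherits(scaler, "minmax_scaler")) {
    stop("scaler has not been fitted: pass the result of fit_scaler()",
         call. = FALSE)
  }
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  range <- scaler$max - scaler$min
  range[range == 0] <- Inf  # constant column -> 0 everywhere
  sweep(sweep(x, 2L, scaler$min, "-"), 2L, range, "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(x, scaler) {
  if (!inherits(scaler, "minmax_scaler")) {
    stop("scaler has not been fitted: pass the result of fit_scaler()",
         call. = FALSE)
  }
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  range <- scaler$max - scaler$min
  sweep(sweep(x, 2L, range, "*"), 2L, scaler$min, "+")
}

#' Assemble the 2054-column feature matrix
#'
#' Fixed layout: 2048 fingerprint bits (`fp0001`..`fp2048`) followed by
#' the six physicochemical descriptors in the documented order.  The
#' physchem columns are stored raw; protocols scale them per split (see
#' [run_qsar_protocol()]).
#'
#' @param fingerprint 0/1 matrix with 2048 columns (or `n_bits`).
#' @param physchem numeric matrix with 6 columns.
#' @param ids optional row names (compound or structure keys).
#' @return numeric matrix with attribute `physchem_cols` marking the
#'   descriptor columns.
#' @export
assemble_features <- function(fingerprint, physchem, ids = NULL) {
  fingerprint <- as.matrix(fingerprint)
  physchem <- as.matrix(physchem)
  stopifnot(nrow(fingerprint) == nrow(physchem),
            ncol(physchem) == length(.physchem_names))
  colnames(fingerprint) <- sprintf("fp%04d", seq_len(ncol(fingerprint)))
  colnames(physchem) <- .physchem_names
  x <- cbind(fingerprint, physchem)
  if (!is.null(ids)) rownames(x) <- ids
  attr(x, "physchem_cols") <- ncol(fingerprint) + seq_len(ncol(physchem))
  x
}

physchem_cols <- function(x) {
  attr(x, "physchem_cols") %||% (ncol(x) - length(.physchem_names) + seq_along(.physchem_names))
}

#' Featurize structures with the chemistry toolkit
#'
#' Convenience wrapper: canonicalize, compute raw descriptors, assemble.
#'
#' @param smiles character vector of SMILES.
#' @param canonicalize canonicalize first (default TRUE).
#' @return feature matrix from [assemble_features()], rownames = canonical
#'   SMILES.
#' @export
featurize_structures <- function(smiles, canonicalize = TRUE) {
  keys <- if (canonicalize) canonicalize_structure(smiles) else smiles
  raw <- compute_raw_descriptors(keys)
  assemble_features(raw$fingerprint, raw$physchem, ids = keys)
}

#' Write / read a feature matrix with sidecar scaler parameters
#'
#' Dense CSV (row key + 2054 columns) plus `<path>.scaler.json` holding
#' fitted min/max values, preserving the assembly order bit-exactly.
#'
#' @param x feature matrix from [assemble_features()].
#' @param path CSV path.
#' @param scaler optional `minmax_scaler` to store alongside.
#' @return `write_features`: invisibly, `path`; `read_features`: list
#'   with `x` and `scaler` (NULL when no sidecar exists).
#' @export
write_features <- function(x, path, scaler = NULL) {
  df <- data.frame(key = rownames(x) %||% as.character(seq_len(nrow(x))),
                   as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(scaler)) {
    jsonlite::write_json(list(min = scaler$min, max = scaler$max),
                         paste0(path, ".scaler.json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  attr(x, "physchem_cols") <- ncol(x) - length(.physchem_names) +
    seq_along(.physchem_names)
  scaler_path <- paste0(path, ".scaler.json")
  scaler <- NULL
  if (file.exists(scaler_path)) {
    raw <- jsonlite::read_json(scaler_path, simplifyVector = TRUE)
    scaler <- structure(list(min = raw$min, max = raw$max),
                        class = "minmax_scaler")
  }
  list(x = x, scaler = scaler)
}
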