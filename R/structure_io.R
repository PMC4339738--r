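# Residue tables ------------------------------------------------------------

#' @keywords internal
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

# Average residue masses (Da), i.e. amino acid minus one water.
#' @keywords internal
aa_residue_masses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' Look up per-residue masses from one-letter codes
#'
#' Standard average residue masses; unknown residues (`X`) receive the mean
#' of the twenty standard values.
#'
#' @param one_letter character vector of one-letter residue codes.
#' @return numeric vector of masses in Da.
#' @export
residue_masses <- function(one_letter) {
  m <- unname(aa_residue_masses[one_letter])
  m[is.na(m)] <- mean(aa_residue_masses)
  m
}

# Conditions -----------------------------------------------------------------

flexcmp_error <- function(msg, class) {
  stop(structure(class = c(class, "flexcmp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# CalphaStructure ------------------------------------------------------------

#' Construct a C-alpha bead structure
#'
#' One bead per residue, holding the reference configuration of the elastic
#' network. Coordinates are stored in nanometres.
#'
#' @param coordinates N x 3 numeric matrix of bead positions (nm).
#' @param structure_id short label for the structure.
#' @param residue_labels data frame with columns `chain`, `resno`, `insert`,
#'   `resname` (3-letter codes); defaults to a poly-alanine chain "A".
#' @param masses per-residue masses in Da; derived from the sequence when
#'   omitted.
#' @param warnings character vector of parse warnings to carry along.
#' @return an object of class `calpha_structure` with fields `structure_id`,
#'   `residue_labels`, `one_letter_sequence`, `coordinates`, `masses`,
#'   `warnings`.
#' @export
calpha_structure <- function(coordinates, structure_id = "structure",
                             residue_labels = NULL, masses = NULL,
                             warnings = character()) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  n <- nrow(coordinates)
  if (n < 2L || ncol(coordinates) != 3L)
    flexcmp_error("coordinates must be an N x 3 matrix with N >= 2",
                  "flexcmp_parse_error")
  if (!all(is.finite(coordinates)))
    flexcmp_error("coordinates contain non-finite values", "flexcmp_parse_error")
  if (is.null(residue_labels)) {
    residue_labels <- data.frame(chain = rep("A", n), resno = seq_len(n),
                                 insert = rep("", n), resname = rep("ALA", n),
                                 stringsAsFactors = FALSE)
  }
  if (nrow(residue_labels) != n)
    flexcmp_error("residue_labels and coordinates differ in length",
                  "flexcmp_parse_error")
  one <- unname(aa_three_to_one[residue_labels$resname])
  one[is.na(one)] <- "X"
  seq1 <- paste(one, collapse = "")
  if (is.null(masses)) masses <- residue_masses(one)
  if (length(masses) != n)
    flexcmp_error("masses and coordinates differ in length", "flexcmp_parse_error")
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(class = "calpha_structure",
            list(structure_id = structure_id,
                 residue_labels = residue_labels,
                 one_letter_sequence = seq1,
                 coordinates = coordinates,
                 masses = as.numeric(masses),
                 warnings = warnings))
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("<calpha_structure> %s: %d residues, %d chain(s)\n",
              x$structure_id, nrow(x$coordinates),
              length(unique(x$residue_labels$chain))))
  if (length(x$warnings))
    cat(sprintf("  %d parse warning(s)\n", length(x$warnings)))
  invisible(x)
}

#' Number of beads in a structure
#' @param s a `calpha_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(s) nrow(s$coordinates)

# PDB reading ----------------------------------------------------------------

#' Read the C-alpha trace of a PDB file
#'
#' Extracts one bead per residue from the first MODEL of a PDB file,
#' converting coordinates from Angstrom to nm. Alternate locations are
#' resolved by keeping the highest-occupancy CA (ties: first in file). MSE
#' (selenomethionine) HETATM records are treated as MET; all other HETATM
#' residues are skipped and recorded as warnings on the returned structure.
#'
#' @param path PDB file path.
#' @param chains optional character vector of chain identifiers to keep.
#' @param structure_id label for the structure; defaults to the file name.
#' @return a [calpha_structure()].
#' @export
read_pdb_calpha <- function(path, chains = NULL, structure_id = NULL) {
  if (!file.exists(path))
    flexcmp_error(sprintf("cannot read PDB file '%s'", path), "flexcmp_parse_error")
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) flexcmp_error(
      sprintf("unreadable PDB file '%s': %s", path, conditionMessage(e)),
      "flexcmp_parse_error"))
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  warns <- character()

  het <- at$type == "HETATM" & at$resid != "MSE"
  if (any(het)) {
    skipped <- unique(at$resid[het])
    warns <- c(warns, sprintf("heteroatom residue '%s' ignored", skipped))
  }
  ca <- at[at$elety == "CA" & (at$type == "ATOM" |
                               (at$type == "HETATM" & at$resid == "MSE")), ,
           drop = FALSE]
  if (!is.null(chains)) ca <- ca[ca$chain %in% chains, , drop = FALSE]
  if (nrow(ca) < 2L)
    flexcmp_error(sprintf("fewer than 2 C-alpha atoms found in '%s'", path),
                  "flexcmp_parse_error")

  # resolve altlocs per residue identity, keeping file order of residues
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  keep <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      alts <- ca$alt[idx]
      if (any(duplicated(alts)))
        flexcmp_error(sprintf(
          "duplicate C-alpha for residue %s %s%s in '%s'",
          ca$chain[idx[1]], ca$resno[idx[1]], ca$insert[idx[1]], path),
          "flexcmp_parse_error")
      occ <- ca$o[idx]
      occ[is.na(occ)] <- 0
      idx <- idx[which.max(occ)]  # ties: first
    }
    keep <- c(keep, idx)
  }
  ca <- ca[keep, , drop = FALSE]

  nonstd <- setdiff(unique(ca$resid), names(aa_three_to_one))
  if (length(nonstd))
    warns <- c(warns,
               sprintf("non-standard residue '%s' assigned mean mass", nonstd))

  labels <- data.frame(chain = ca$chain, resno = ca$resno, insert = ca$insert,
                       resname = ca$resid, stringsAsFactors = FALSE)
  coords <- cbind(ca$x, ca$y, ca$z) / 10  # Angstrom -> nm
  s <- calpha_structure(coords, structure_id = structure_id,
                        residue_labels = labels, warnings = warns)
  if (length(warns)) warning(sprintf("%s: %s", structure_id,
                                     paste(warns, collapse = "; ")),
                             call. = FALSE)
  s
}

#' Write a C-alpha structure as a PDB file
#'
#' Emits fixed-column ATOM records (coordinates converted nm to Angstrom),
#' one CA per residue, with occupancy 1.00.
#'
#' @param s a `calpha_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb_calpha <- function(s, path) {
  lab <- s$residue_labels
  xyz <- s$coordinates * 10
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, lab$resname[i], substr(lab$chain[i], 1, 1), lab$resno[i],
            ifelse(nzchar(lab$insert[i]), substr(lab$insert[i], 1, 1), " "),
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Distance validation --------------------------------------------------------

#' Validate minimum C-alpha pair distances
#'
#' The pair potential is only guaranteed to be at a minimum of the energy at
#' the input configuration when no two beads are anomalously close; pairs
#' closer than 2.78 Angstrom (0.278 nm) are rejected. The comparison is
#' strict: a pair at exactly 0.278 nm passes.
#'
#' @param s a `calpha_structure`.
#' @return invisibly `TRUE` on success; otherwise an error of class
#'   `flexcmp_validation_error` naming the first offending pair.
#' @export
validate_min_distance <- function(s) {
  dm <- as.matrix(stats::dist(s$coordinates))
  dm[upper.tri(dm, diag = TRUE)] <- Inf
  if (any(dm < 0.278)) {
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    flexcmp_error(sprintf(
      "C-alpha pair (%d, %d) at %.4g nm is closer than the 0.278 nm (2.78 A) minimum",
      ij[["col"]], ij[["row"]], min(dm)), "flexcmp_validation_error")
  }
  invisible(TRUE)
}

# Alignment reading ----------------------------------------------------------

#' Read a gapped multiple alignment in FASTA format
#'
#' Both `-` and `.` are accepted as gap characters (structural aligners
#' differ); sequence letters are upper-cased. All records must have the same
#' gapped length.
#'
#' @param path FASTA file path.
#' @return an object of class `gapped_alignment` with fields `names`, `seqs`
#'   (gapped strings over `A..Z` and `-`) and `column_count`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    flexcmp_error(sprintf("cannot read alignment file '%s'", path),
                  "flexcmp_parse_error")
  recs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  gapped_alignment(vapply(recs, paste, character(1), collapse = ""),
                   names(recs))
}

#' Construct a gapped alignment from sequences
#'
#' @param seqs character vector of gapped sequences.
#' @param names record names; defaults to `names(seqs)`.
#' @return a `gapped_alignment`.
#' @export
gapped_alignment <- function(seqs, names = base::names(seqs)) {
  if (length(seqs) < 2L)
    flexcmp_error("alignment needs at least 2 records", "flexcmp_parse_error")
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  if (any(!nzchar(seqs)))
    flexcmp_error("alignment contains an empty record", "flexcmp_parse_error")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    flexcmp_error(sprintf(
      "ragged alignment: record lengths %s differ",
      paste(unique(len), collapse = ", ")), "flexcmp_parse_error")
  structure(class = "gapped_alignment",
            list(names = as.character(names), seqs = unname(seqs),
                 column_count = len[[1]]))
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat(sprintf("<gapped_alignment> %d records x %d columns\n",
              length(x$seqs), x$column_count))
  invisible(x)
}

# Tabular writers ------------------------------------------------------------

output_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("flexcmp"))
  c(sprintf("# flexcmp %s", ver),
    sprintf("# config: %s", config_hash(config)))
}

#' Write a profile table aligned on alignment columns
#'
#' Rows are alignment columns; one column per structure; fields are empty at
#' alignment gaps.
#'
#' @param t a `profile_table` (see [aligned_profiles()]) or a data frame whose
#'   first column indexes alignment columns.
#' @param path output path.
#' @param config optional configuration list, hashed into the file header.
#' @return invisibly, `path`.
#' @export
write_profile_table <- function(t, path, config = NULL) {
  df <- if (inherits(t, "profile_table")) t$table else as.data.frame(t)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a labelled symmetric matrix as tab-separated text
#'
#' @param m a `similarity_matrix`, `correlation_matrix`, or plain matrix with
#'   dimnames.
#' @param path output path.
#' @param config optional configuration list, hashed into the file header.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path, config = NULL) {
  mat <- if (inherits(m, "similarity_matrix")) {
    v <- m$values; dimnames(v) <- list(m$labels, m$labels); v
  } else if (inherits(m, "correlation_matrix")) {
    v <- m$C
    dimnames(v) <- list(paste0("r", seq_len(nrow(v))),
                        paste0("r", seq_len(ncol(v))))
    v
  } else as.matrix(m)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- rownames(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  df <- data.frame(label = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write normal modes as plain text
#'
#' One row per mode: the eigenvalue followed by the 3N components of the
#' mass-weighted eigenvector.
#'
#' @param modes a `mode_set` (see [compute_modes()]).
#' @param path output path.
#' @param config optional configuration list, hashed into the file header.
#' @return invisibly, `path`.
#' @export
write_modes <- function(modes, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  writeLines(sprintf("# %d non-trivial modes, %d atoms, %d trivial modes removed",
                     length(modes$eigenvalues), modes$n_atoms, modes$n_trivial),
             con)
  for (m in seq_along(modes$eigenvalues)) {
    writeLines(paste(format(c(modes$eigenvalues[m], modes$vectors[, m]),
                            digits = 17, scientific = TRUE, trim = TRUE),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# FNV-1a 32-bit over the deparsed configuration; cheap content fingerprint
# for output provenance headers. Arithmetic kept in doubles (R integers
# cannot hold unsigned 32-bit values); the xor only ever touches the low
# byte, and the modular product is split to stay within exact double range.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (((h %/% 65536) * p) %% 65536) * 65536 + ((h %% 65536) * p)
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
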