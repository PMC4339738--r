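# Alignment mapping -----------------------------------------------------------

#' Map alignment columns to residues of each structure
#'
#' Checks that each record's ungapped sequence matches its structure's
#' one-letter sequence (`X` matches anything) and builds, per structure, the
#' column-to-residue index map. The conserved column set comprises the
#' columns with no gap in any record; the comparative similarity measures
#' are computed on these residues only.
#'
#' @param aln a `gapped_alignment`.
#' @param structures list of `calpha_structure`, one per alignment record, in
#'   record order.
#' @return object of class `alignment_map`: `column_to_residue` (list of
#'   integer vectors, `NA` at gaps), `conserved_columns`, `nonconserved`,
#'   `labels`.
#' @export
map_alignment <- function(aln, structures) {
  if (length(structures) != length(aln$seqs))
    flexcmp_error(sprintf(
      "alignment has %d records but %d structures were supplied",
      length(aln$seqs), length(structures)), "flexcmp_mapping_error")
  maps <- vector("list", length(structures))
  for (k in seq_along(structures)) {
    chars <- strsplit(aln$seqs[[k]], "")[[1]]
    is_gap <- chars == "-"
    ungapped <- chars[!is_gap]
    sseq <- strsplit(structures[[k]]$one_letter_sequence, "")[[1]]
    if (length(ungapped) != length(sseq))
      flexcmp_error(sprintf(
        "alignment record '%s' has %d residues but structure '%s' has %d",
        aln$names[k], length(ungapped), structures[[k]]$structure_id,
        length(sseq)), "flexcmp_mapping_error")
    mism <- which(ungapped != sseq & ungapped != "X" & sseq != "X")
    if (length(mism))
      flexcmp_error(sprintf(
        "structure '%s' disagrees with alignment record '%s' at residue %d ('%s' vs '%s')",
        structures[[k]]$structure_id, aln$names[k], mism[1],
        sseq[mism[1]], ungapped[mism[1]]), "flexcmp_mapping_error")
    m <- rep(NA_integer_, aln$column_count)
    m[!is_gap] <- seq_along(sseq)
    maps[[k]] <- m
  }
  gapless <- Reduce(`&`, lapply(maps, function(m) !is.na(m)))
  conserved <- which(gapless)
  if (!length(conserved))
    flexcmp_error("alignment has no gap-free (conserved) columns",
                  "flexcmp_mapping_error")
  structure(class = "alignment_map",
            list(column_to_residue = maps,
                 conserved_columns = conserved,
                 nonconserved = which(!gapless),
                 labels = vapply(structures, function(s) s$structure_id,
                                 character(1))))
}

# Effective Hessian ------------------------------------------------------------

#' Effective Hessian over the alignment-conserved residues
#'
#' Reduces the full Hessian to the conserved coordinates by the Schur
#' complement `H_aa - H_ab H_bb^{-1} H_ab^T`, the exact quadratic energy of
#' the conserved subsystem after minimising over the non-conserved
#' coordinates. When every residue is conserved the reduction is the
#' identity. A singular `H_bb` falls back to the Moore-Penrose pseudo-inverse
#' with a warning. Modes of the reduced system are computed with the
#' conserved atoms' masses.
#'
#' @param h full `enm_hessian` for one structure.
#' @param map an `alignment_map` covering that structure.
#' @param structure_index position of the structure in the map.
#' @param masses optional per-conserved-atom masses (defaults to residue
#'   masses of the conserved atoms).
#' @return object of class `reduced_mode_set`: `effective_hessian`
#'   (3|a| x 3|a|), `modes` (a `mode_set`), `conserved_residues`,
#'   `structure_id`.
#' @export
effective_hessian <- function(h, map, structure_index, masses = NULL) {
  a_res <- map$column_to_residue[[structure_index]][map$conserved_columns]
  n <- nrow(h$structure$coordinates)
  b_res <- setdiff(seq_len(n), a_res)
  coord_idx <- function(res) as.vector(t(outer(res, 0:2, function(r, c) 3 * (r - 1) + 1 + c)))
  ai <- coord_idx(a_res)
  H <- h$matrix
  if (!length(b_res)) {
    Hred <- H[ai, ai, drop = FALSE]
  } else {
    bi <- coord_idx(b_res)
    Haa <- H[ai, ai, drop = FALSE]
    Hab <- H[ai, bi, drop = FALSE]
    Hbb <- H[bi, bi, drop = FALSE]
    X <- tryCatch(solve(Hbb, t(Hab)), error = function(e) {
      warning("H_bb is singular; using its pseudo-inverse", call. = FALSE)
      MASS::ginv(Hbb) %*% t(Hab)
    })
    Hred <- Haa - Hab %*% X
  }
  Hred <- (Hred + t(Hred)) / 2
  if (is.null(masses)) masses <- h$structure$masses[a_res]
  # package the reduced operator as a hessian-like object for compute_modes;
  # keep the full pair list restricted to conserved atoms for connectivity
  keep_pair <- h$pairs$i %in% a_res & h$pairs$j %in% a_res
  remap <- match(seq_len(n), a_res)
  hred_obj <- structure(class = "enm_hessian", list(
    matrix = Hred,
    structure = list(structure_id = h$structure$structure_id,
                     masses = masses,
                     coordinates = h$structure$coordinates[a_res, , drop = FALSE]),
    pairs = list(i = remap[h$pairs$i[keep_pair]],
                 j = remap[h$pairs$j[keep_pair]]),
    params = h$params))
  modes <- compute_modes(hred_obj, masses = masses)
  structure(class = "reduced_mode_set",
            list(effective_hessian = Hred, modes = modes,
                 conserved_residues = a_res,
                 coordinates = h$structure$coordinates[a_res, , drop = FALSE],
                 structure_id = h$structure$structure_id))
}

# Aligned profiles --------------------------------------------------------------

#' Fluctuation and deformation profiles tabulated on alignment columns
#'
#' Computes per-structure profiles from each structure's full (unreduced)
#' mode set over all non-trivial modes and places the values at their
#' alignment columns; fields at gaps stay empty so profiles of different
#' structures line up for comparison.
#'
#' @param structures list of `calpha_structure`.
#' @param map matching `alignment_map`.
#' @param mode_sets list of full `mode_set`, one per structure.
#' @param params [enm_params()] used for the Hessians.
#' @return list with elements `fluctuations` and `deformation`, each a
#'   `profile_table` (field `table`: data frame with `column` plus one column
#'   per structure, `NA` at gaps).
#' @export
aligned_profiles <- function(structures, map, mode_sets, params = enm_params()) {
  stopifnot(length(structures) == length(mode_sets))
  ncol_aln <- length(map$column_to_residue[[1]])
  place <- function(values, k) {
    out <- rep(NA_real_, ncol_aln)
    m <- map$column_to_residue[[k]]
    out[!is.na(m)] <- values[m[!is.na(m)]]
    out
  }
  fl <- de <- data.frame(column = seq_len(ncol_aln))
  for (k in seq_along(structures)) {
    fl[[map$labels[k]]] <- place(fluctuations(mode_sets[[k]])$values, k)
    de[[map$labels[k]]] <- place(
      deformation_energies(mode_sets[[k]], structures[[k]], params)$values, k)
  }
  list(fluctuations = structure(class = "profile_table",
                                list(table = fl, kind = "fluctuations")),
       deformation = structure(class = "profile_table",
                               list(table = de, kind = "deformation_energy")))
}

# RMSIP -------------------------------------------------------------------------

unit_columns <- function(D) sweep(D, 2, sqrt(colSums(D^2)), "/")

# Displacement directions are only comparable in a common frame: rotate B's
# mode vectors into A's frame with the Kabsch rotation of the conserved
# coordinates. Skipped when either side carries no coordinates (synthetic
# mode sets) or when superposition is disabled.
superposed_displacements <- function(red_A, red_B, D) {
  if (is.null(red_A$coordinates) || is.null(red_B$coordinates)) return(D)
  rotate_mode_displacements(D, kabsch_rotation(red_A$coordinates,
                                               red_B$coordinates))
}

#' Root Mean Squared Inner Product of two mode subspaces
#'
#' `RMSIP = sqrt( (1/10) sum_{i,j<=10} (X_i . Y_j)^2 )` over the ten
#' lowest-frequency non-trivial modes of two systems reduced to the same
#' conserved residues; a purely directional subspace overlap that ignores the
#' eigenvalue spectra. Unit-normalised cartesian displacement vectors are
#' compared by default.
#'
#' @param red_A,red_B `reduced_mode_set` objects over the same conserved
#'   columns.
#' @param n_modes subspace dimension (default 10); when fewer modes are
#'   available all are used with a warning.
#' @param mass_weighted compare mass-weighted eigenvectors instead of
#'   cartesian displacements.
#' @param superpose rotate B's mode vectors into A's frame (Kabsch on the
#'   conserved coordinates) before comparing; displacement directions are
#'   only meaningful in a common frame.
#' @return RMSIP in `[0, 1]`.
#' @export
rmsip <- function(red_A, red_B, n_modes = 10, mass_weighted = FALSE,
                  superpose = TRUE) {
  DA <- if (mass_weighted) red_A$modes$vectors else red_A$modes$displacements
  DB <- if (mass_weighted) red_B$modes$vectors else red_B$modes$displacements
  if (nrow(DA) != nrow(DB))
    flexcmp_error("reduced systems have different dimensions",
                  "flexcmp_mapping_error")
  if (superpose) DB <- superposed_displacements(red_A, red_B, DB)
  avail <- min(ncol(DA), ncol(DB))
  if (avail < n_modes) {
    warning(sprintf("only %d non-trivial modes available; using all of them",
                    avail), call. = FALSE)
    n_modes <- avail
  }
  S <- crossprod(unit_columns(DA[, seq_len(n_modes), drop = FALSE]),
                 unit_columns(DB[, seq_len(n_modes), drop = FALSE]))
  sqrt(sum(S^2) / n_modes)
}

# Bhattacharyya coefficient ------------------------------------------------------

# covariance from the n lowest-frequency modes reaching var_frac of the total
# 1/lambda variance; trace-normalised
reduced_covariance <- function(red, var_frac, mass_weighted = FALSE,
                               D = NULL) {
  if (is.null(D))
    D <- if (mass_weighted) red$modes$vectors else red$modes$displacements
  D <- unit_columns(D)
  w <- 1 / red$modes$eigenvalues
  n <- which(cumsum(w) >= var_frac * sum(w))[1]
  A <- D[, seq_len(n), drop = FALSE] %*% (w[seq_len(n)] * t(D[, seq_len(n), drop = FALSE]))
  list(A = A / sum(diag(A)), n = n)
}

#' Bhattacharyya coefficient of two mode covariance matrices
#'
#' Overlap of the Gaussian ensembles implied by the covariances of two
#' reduced systems; unlike RMSIP it is sensitive to the energetic weighting
#' of the modes, not only their directions. Covariances are built as
#' `sum_m (1/lambda_m) d_m d_m^T` and rank-reduced in two steps: each
#' protein keeps its `n` lowest-frequency modes retaining `var_protein` of
#' its variance (trace-normalised to `A_n`, `B_m`), then both are projected
#' on the `s` leading eigenvectors of `(A_n + B_m)/2` retaining `var_joint`
#' of its variance. The coefficient is
#' `BC = exp( -(1/2s) ln[ |(A~+B~)/2| (|A~||B~|)^(-1/2) ] )`,
#' evaluated through log-determinants.
#'
#' @param red_A,red_B `reduced_mode_set` objects over the same conserved
#'   columns.
#' @param var_protein per-protein variance fraction retained (default 0.95).
#' @param var_joint joint variance fraction retained for the projection
#'   (default 0.75).
#' @param mass_weighted use mass-weighted eigenvectors instead of cartesian
#'   displacements.
#' @param superpose rotate B's mode vectors into A's frame before building
#'   its covariance (see [rmsip()]).
#' @param details return the intermediate quantities as well.
#' @return BC in `(0, 1]`, or a list when `details = TRUE`.
#' @export
bhattacharyya <- function(red_A, red_B, var_protein = 0.95, var_joint = 0.75,
                          mass_weighted = FALSE, superpose = TRUE,
                          details = FALSE) {
  if (nrow(red_A$modes$displacements) != nrow(red_B$modes$displacements))
    flexcmp_error("reduced systems have different dimensions",
                  "flexcmp_mapping_error")
  DB <- if (mass_weighted) red_B$modes$vectors else red_B$modes$displacements
  if (superpose) DB <- superposed_displacements(red_A, red_B, DB)
  ra <- reduced_covariance(red_A, var_protein, mass_weighted)
  rb <- reduced_covariance(red_B, var_protein, mass_weighted, D = DB)
  Mavg <- (ra$A + rb$A) / 2
  e <- eigen((Mavg + t(Mavg)) / 2, symmetric = TRUE)
  s <- which(cumsum(e$values) >= var_joint * sum(e$values))[1]
  V <- e$vectors[, seq_len(s), drop = FALSE]
  At <- crossprod(V, ra$A %*% V)
  Bt <- crossprod(V, rb$A %*% V)
  logdet <- function(M) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      flexcmp_error("projected covariance is not positive definite",
                    "flexcmp_validation_error")
    sum(log(ev))
  }
  bc <- exp(-(1 / (2 * s)) *
              (logdet((At + Bt) / 2) - 0.5 * (logdet(At) + logdet(Bt))))
  if (!details) return(bc)
  list(bc = bc, n = ra$n, m = rb$n, s = s, A_tilde = At, B_tilde = Bt)
}

# Similarity matrix ----------------------------------------------------------------

#' Pairwise similarity matrix with complete-linkage clustering
#'
#' Computes RMSIP or BC for every pair of reduced systems, with unit
#' diagonal, and attaches a complete-linkage dendrogram built on the
#' distance `1 - similarity`.
#'
#' @param reduced list of `reduced_mode_set` (>= 2), all over the same
#'   conserved columns.
#' @param measure `"BC"` or `"RMSIP"`.
#' @param ... passed to [bhattacharyya()] or [rmsip()].
#' @return object of class `similarity_matrix`: `labels`, `values`,
#'   `measure`, `dendrogram` (an `hclust`).
#' @export
similarity_matrix <- function(reduced, measure = c("BC", "RMSIP"), ...) {
  measure <- match.arg(measure)
  k <- length(reduced)
  if (k < 2L)
    flexcmp_error("need at least 2 structures", "flexcmp_mapping_error")
  V <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    V[i, j] <- V[j, i] <- switch(measure,
      BC = bhattacharyya(reduced[[i]], reduced[[j]], ...),
      RMSIP = rmsip(reduced[[i]], reduced[[j]], ...))
  }
  labels <- vapply(reduced, function(r) r$structure_id, character(1))
  dimnames(V) <- list(labels, labels)
  dend <- stats::hclust(stats::as.dist(1 - V), method = "complete")
  structure(class = "similarity_matrix",
            list(labels = labels, values = V, measure = measure,
                 dendrogram = dend))
}

#' @export
print.similarity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<similarity_matrix> %s, %d structures\n", x$measure,
              length(x$labels)))
  print(round(x$values, digits))
  invisible(x)
}

#' Heat map of a similarity matrix with its dendrogram
#'
#' Uses `pheatmap` when installed, falling back to `stats::heatmap`.
#'
#' @param x a `similarity_matrix`.
#' @param ... passed to the underlying heat-map function.
#' @return invisibly, `x`.
#' @export
plot.similarity_matrix <- function(x, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(x$values,
                       cluster_rows = x$dendrogram, cluster_cols = x$dendrogram,
                       main = x$measure, ...)
  } else {
    stats::heatmap(x$values, Rowv = stats::as.dendrogram(x$dendrogram),
                   Colv = stats::as.dendrogram(x$dendrogram),
                   scale = "none", main = x$measure, ...)
  }
  invisible(x)
}
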