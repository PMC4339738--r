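# Fluctuations ---------------------------------------------------------------

#' Normalised atomic fluctuation profile
#'
#' Per-atom mean-square displacement amplitude summed over the retained
#' non-trivial modes, each weighted by the reciprocal of its eigenvalue:
#' `f_i = sum_m (1/lambda_m) |d_m,i|^2` with `d_m` the cartesian
#' displacements. Values are normalised to sum to one by default.
#'
#' @param modes a `mode_set` with at least one non-trivial mode.
#' @param normalization `"sum"` (values sum to 1) or `"max"` (maximum is 1,
#'   for visual comparison).
#' @return object of class `fluctuation_profile`: `values` (length N),
#'   `normalization`.
#' @export
fluctuations <- function(modes, normalization = c("sum", "max")) {
  normalization <- match.arg(normalization)
  if (length(modes$eigenvalues) < 1L)
    flexcmp_error("no non-trivial modes available", "flexcmp_validation_error")
  W <- sweep(modes$displacements^2, 2, modes$eigenvalues, "/")
  per_coord <- rowSums(W)
  f <- per_coord[c(TRUE, FALSE, FALSE)] + per_coord[c(FALSE, TRUE, FALSE)] +
    per_coord[c(FALSE, FALSE, TRUE)]
  f <- switch(normalization, sum = f / sum(f), max = f / max(f))
  structure(class = "fluctuation_profile",
            list(values = unname(f), normalization = paste0(normalization, "_to_one")))
}

# Deformation energies --------------------------------------------------------

#' Normalised atomic deformation-energy profile
#'
#' Attributes the elastic energy stored by each mode's displacement field to
#' individual atoms: for mode m, pair (i, j) stores
#' `e_ij = k(r0_ij) (u_ij . (a_m,i - a_m,j))^2`, split half to each partner,
#' with `a_m = d_m / sqrt(lambda_m)` the displacement at thermal amplitude.
#' Per-atom totals are averaged over modes with `1/lambda` weights and
#' normalised to sum to one. Because the energy total of a unit mode is
#' exactly its eigenvalue, weighting unit-mode energies by `1/lambda` alone
#' would give every mode an equal share and wash out localisation; the
#' thermal amplitudes keep the soft modes - the ones that dominate the
#' actual motion - in charge of where energy accumulates. Rigid domains
#' score low; flexible hinges between domains score high.
#'
#' @param modes a `mode_set`.
#' @param structure the `calpha_structure` the modes were computed from.
#' @param params the [enm_params()] used for the Hessian.
#' @param normalization as in [fluctuations()].
#' @return object of class `deformation_profile`: `values`, `normalization`.
#' @export
deformation_energies <- function(modes, structure, params = enm_params(),
                                 normalization = c("sum", "max")) {
  normalization <- match.arg(normalization)
  if (length(modes$eigenvalues) < 1L)
    flexcmp_error("no non-trivial modes available", "flexcmp_validation_error")
  pg <- pair_geometry(structure, params)
  D <- modes$displacements
  ii <- 3 * (pg$i - 1)
  jj <- 3 * (pg$j - 1)
  # projection of the relative displacement on the pair axis, pairs x modes
  proj <- pg$u[, 1] * (D[ii + 1, , drop = FALSE] - D[jj + 1, , drop = FALSE]) +
          pg$u[, 2] * (D[ii + 2, , drop = FALSE] - D[jj + 2, , drop = FALSE]) +
          pg$u[, 3] * (D[ii + 3, , drop = FALSE] - D[jj + 3, , drop = FALSE])
  # proj is computed from unit modes; the thermal amplitude contributes one
  # 1/lambda and the cross-mode weighting the other
  pair_tot <- (pg$k * proj^2) %*% (1 / modes$eigenvalues^2)  # pairs x 1
  # reference scale: the same sum without the axis projection; a rigid-body
  # field gives projections that are pure rounding noise relative to this
  diff2 <- (D[ii + 1, , drop = FALSE] - D[jj + 1, , drop = FALSE])^2 +
           (D[ii + 2, , drop = FALSE] - D[jj + 2, , drop = FALSE])^2 +
           (D[ii + 3, , drop = FALSE] - D[jj + 3, , drop = FALSE])^2
  scale_tot <- sum((pg$k * diff2) %*% (1 / modes$eigenvalues^2))
  n <- modes$n_atoms
  f <- numeric(n)
  acc_i <- rowsum(as.numeric(pair_tot), pg$i)
  acc_j <- rowsum(as.numeric(pair_tot), pg$j)
  f[as.integer(rownames(acc_i))] <- f[as.integer(rownames(acc_i))] + acc_i[, 1]
  f[as.integer(rownames(acc_j))] <- f[as.integer(rownames(acc_j))] + acc_j[, 1]
  f <- 0.5 * f
  if (sum(f) > 1e-14 * scale_tot) {
    f <- switch(normalization, sum = f / sum(f), max = f / max(f))
  } else {
    # a rigid-body field stores no energy anywhere; report exact zeros
    f <- numeric(n)
  }
  structure(class = "deformation_profile",
            list(values = unname(f), normalization = paste0(normalization, "_to_one")))
}

# Correlation matrix ----------------------------------------------------------

#' Inter-residue correlation matrix
#'
#' Normalised covariance of atomic displacements over the retained modes:
#' `C_ij = sum_m (1/lambda_m) d_m,i . d_m,j`, normalised by the square roots
#' of the diagonal terms so that `C_ii = 1` and `C_ij` lies in `[-1, 1]`
#' (expected inner product of the displacements of atoms i and j; -1 and 1
#' are maximal anti-correlation and correlation).
#'
#' @param modes a `mode_set`; at most `n_modes` lowest-frequency modes used.
#' @param n_modes mode cap (default 200, the single-analysis convention).
#' @return object of class `correlation_matrix`: `C` (N x N),
#'   `n_modes_used`.
#' @export
correlation_matrix <- function(modes, n_modes = 200) {
  if (length(modes$eigenvalues) < 1L)
    flexcmp_error("no non-trivial modes available", "flexcmp_validation_error")
  keep <- seq_len(min(n_modes, length(modes$eigenvalues)))
  G <- sweep(modes$displacements[, keep, drop = FALSE], 2,
             sqrt(modes$eigenvalues[keep]), "/")
  K <- tcrossprod(G)  # 3N x 3N covariance
  xs <- seq(1, nrow(K), by = 3)
  Num <- K[xs, xs] + K[xs + 1, xs + 1] + K[xs + 2, xs + 2]
  dn <- sqrt(diag(Num))
  C <- Num / tcrossprod(dn)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(class = "correlation_matrix",
            list(C = C, n_modes_used = length(keep)))
}

# Viewer script ---------------------------------------------------------------

#' Percentile rule for the correlation-network threshold
#'
#' 95 for structures with fewer than 200 C-alpha atoms, 99.9 for more than
#' 2000, linearly interpolated in N between.
#'
#' @param n number of C-alpha atoms.
#' @return percentile in `[95, 99.9]`.
#' @export
correlation_percentile <- function(n) {
  if (n < 200) 95
  else if (n > 2000) 99.9
  else 95 + (n - 200) * (99.9 - 95) / (2000 - 200)
}

#' PyMOL script of the significant correlation network
#'
#' Renders significant inter-residue correlations as distance objects on a
#' cartoon representation: positive correlations above the threshold in red,
#' negative ones below its negative in blue. Only pairs at least 0.8 nm apart
#' in the reference structure are eligible, focusing on couplings not
#' dominated by the stiff backbone springs; the threshold is the chosen
#' percentile of |C_ij| over eligible pairs. The percentile and threshold are
#' written as header comments. A script is emitted even when no pair (or
#' only one pair) passes.
#'
#' @param C a `correlation_matrix`.
#' @param s the matching `calpha_structure` (same N).
#' @param percentile override for the automatic [correlation_percentile()]
#'   rule.
#' @param min_distance eligibility distance in nm (default 0.8).
#' @return object of class `viewer_script`: `text` (the script),
#'   `percentile`, `threshold`, `positive_pairs`, `negative_pairs`
#'   (two-column index matrices).
#' @export
correlation_viewer_script <- function(C, s, percentile = NULL,
                                      min_distance = 0.8) {
  n <- nrow(C$C)
  if (n != nrow(s$coordinates))
    flexcmp_error("correlation matrix and structure differ in size",
                  "flexcmp_parse_error")
  if (is.null(percentile)) percentile <- correlation_percentile(n)
  dm <- as.matrix(stats::dist(s$coordinates))
  elig <- upper.tri(dm) & dm >= min_distance
  thr <- if (any(elig))
    unname(stats::quantile(abs(C$C[elig]), percentile / 100)) else Inf
  pos <- which(elig & C$C > thr, arr.ind = TRUE)
  neg <- which(elig & C$C < -thr, arr.ind = TRUE)
  lab <- s$residue_labels
  sel <- function(i) {
    ch <- lab$chain[i]
    chain_part <- ifelse(nzchar(ch) & !is.na(ch),
                         paste0("chain ", ch, " and "), "")
    sprintf("(%sresi %s%s and name CA)", chain_part, lab$resno[i], lab$insert[i])
  }
  dist_cmds <- function(pairs, obj) {
    if (!nrow(pairs)) return(character())
    sprintf("distance %s, %s, %s", obj, sel(pairs[, 1]), sel(pairs[, 2]))
  }
  text <- c(
    "# flexcmp correlation network",
    sprintf("# percentile: %g", percentile),
    sprintf("# threshold: %.6g", thr),
    sprintf("# eligible pairs (>= %g nm apart): %d", min_distance, sum(elig)),
    "bg_color white",
    "hide everything",
    "show cartoon",
    "color grey80",
    dist_cmds(pos, "pos_corr"),
    dist_cmds(neg, "neg_corr"),
    if (nrow(pos)) c("color red, pos_corr", "hide labels, pos_corr"),
    if (nrow(neg)) c("color blue, neg_corr", "hide labels, neg_corr"))
  structure(class = "viewer_script",
            list(text = paste(text, collapse = "\n"),
                 percentile = percentile, threshold = thr,
                 positive_pairs = unname(pos), negative_pairs = unname(neg)))
}

#' @export
print.viewer_script <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

# Overlap analysis ------------------------------------------------------------

# Kabsch optimal rotation: centered(Y) %*% R least-squares matches centered(X)
kabsch_rotation <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Kabsch least-squares superposition of Y onto X (both N x 3)
kabsch_superpose <- function(X, Y) {
  R <- kabsch_rotation(X, Y)
  sweep(sweep(Y, 2, colMeans(Y)) %*% R, 2, colMeans(X), "+")
}

# rotate every per-atom 3-vector of a 3N x M displacement matrix by R
# (row-vector convention: d' = d %*% R)
rotate_mode_displacements <- function(D, R) {
  matrix(crossprod(R, matrix(D, nrow = 3)), nrow = nrow(D),
         dimnames = dimnames(D))
}

#' Overlap of normal modes with an observed conformational change
#'
#' Identifies which modes of conformation A contribute most to the observed
#' structural difference between two conformations of the same protein.
#' B is least-squares superposed onto A (Kabsch, all C-alpha) before
#' differencing; the squared overlap of each retained mode with the
#' difference vector is
#' `O_m = (d_m . dR)^2 / (|d_m|^2 |dR|^2)` and the cumulative overlap is
#' `CO_k = sqrt(sum_{m<=k} O_m)`.
#'
#' @param modes_A `mode_set` of conformation A.
#' @param s_A,s_B the two conformations (same residue count and sequence).
#' @return object of class `overlap_result`: `squared_overlaps`,
#'   `cumulative`, `delta` (flattened superposed difference, nm), `rmsd` (nm).
#' @export
overlap_analysis <- function(modes_A, s_A, s_B) {
  if (nrow(s_A$coordinates) != nrow(s_B$coordinates) ||
      s_A$one_letter_sequence != s_B$one_letter_sequence)
    flexcmp_error("the two conformations differ in residue count or sequence",
                  "flexcmp_parse_error")
  Bfit <- kabsch_superpose(s_A$coordinates, s_B$coordinates)
  delta <- as.numeric(t(Bfit - s_A$coordinates))
  nd2 <- sum(delta^2)
  rmsd <- sqrt(nd2 / nrow(s_A$coordinates))
  if (rmsd < 1e-6)
    flexcmp_error("conformations are identical after superposition (RMSD ~ 0)",
                  "flexcmp_validation_error")
  D <- modes_A$displacements
  proj <- as.numeric(crossprod(D, delta))
  O <- proj^2 / (colSums(D^2) * nd2)
  structure(class = "overlap_result",
            list(squared_overlaps = O,
                 cumulative = sqrt(cumsum(O)),
                 delta = delta,
                 rmsd = rmsd))
}

#' Write overlap results as tab-separated text
#'
#' @param o an `overlap_result`.
#' @param path output path.
#' @param config optional configuration list, hashed into the file header.
#' @return invisibly, `path`.
#' @export
write_overlap <- function(o, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  writeLines(sprintf("# rmsd_nm: %.6g", o$rmsd), con)
  df <- data.frame(mode = seq_along(o$squared_overlaps),
                   squared_overlap = o$squared_overlaps,
                   cumulative_overlap = o$cumulative)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
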