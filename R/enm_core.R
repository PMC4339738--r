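# C-alpha force field --------------------------------------------------------

#' C-alpha elastic network force-field parameters
#'
#' Parameters of the distance-dependent pair force constant
#' \deqn{k(r) = a r - b \textrm{ for } r < d; \quad c r^{-6} \textrm{ for } r \ge d}
#' fitted against an all-atom model. The defaults are the published values
#' `a = 8.6e5` kJ mol^-1 nm^-3, `b = 2.39e5` kJ mol^-1 nm^-2, `c = 128`
#' kJ mol^-1 nm^4, `d = 0.4` nm, and give near-uniform stiff springs for
#' sequence neighbours (which cluster just under 0.4 nm apart) and an
#' inverse-sixth-power decay for all other pairs.
#'
#' @param a,b linear-branch coefficients (kJ mol^-1 nm^-3, kJ mol^-1 nm^-2).
#' @param c long-range coefficient (kJ mol^-1 nm^4).
#' @param d branch-boundary distance (nm).
#' @return an object of class `enm_params`.
#' @export
enm_params <- function(a = 8.6e5, b = 2.39e5, c = 128, d = 0.4) {
  if (a * d - b <= 0 || c * d^-6 <= 0)
    flexcmp_error("force constant must be positive on both branches at r = d",
                  "flexcmp_parse_error")
  structure(class = "enm_params", list(a = a, b = b, c = c, d = d))
}

#' Distance-dependent pair force constant
#'
#' Evaluates `k(r) = a*r - b` for `r < d` and `k(r) = c*r^-6` for `r >= d`;
#' the boundary `r = d` belongs to the long-range branch.
#'
#' @param r pair distance(s) in nm; must be positive.
#' @param params an [enm_params()] object.
#' @return force constant(s) in kJ mol^-1 nm^-2.
#' @export
pair_force_constant <- function(r, params = enm_params()) {
  if (any(!is.finite(r)) || any(r <= 0))
    flexcmp_error("pair distance must be positive and finite",
                  "flexcmp_parse_error")
  ifelse(r < params$d, params$a * r - params$b, params$c * r^-6)
}

# Hessian --------------------------------------------------------------------

# pair list with reference geometry: indices, distance, unit vector, k
pair_geometry <- function(s, params = enm_params(), cutoff = NULL) {
  xyz <- s$coordinates
  n <- nrow(xyz)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  dv <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  if (!is.null(cutoff)) {
    keep <- r <= cutoff
    i <- i[keep]; j <- j[keep]; dv <- dv[keep, , drop = FALSE]; r <- r[keep]
  }
  list(i = i, j = j, r = r, u = dv / r, k = pair_force_constant(r, params))
}

#' Assemble the elastic-network Hessian
#'
#' Analytic second derivative of the total pair potential
#' `U = sum_ij k(r0_ij) (|R_ij| - |r0_ij|)^2` at the input configuration:
#' each pair contributes `-2 k u u^T` to its off-diagonal 3x3 block (u the
#' unit vector along the reference pair separation) and `+2 k u u^T` to both
#' diagonal blocks. All pairs interact by default; the r^-6 decay of `k`
#' provides the effective locality. An optional hard cutoff is available for
#' very large systems.
#'
#' @param s a `calpha_structure` that passes [validate_min_distance()].
#' @param params an [enm_params()] object.
#' @param cutoff optional interaction cutoff in nm (default: none).
#' @return object of class `enm_hessian`: fields `matrix` (3N x 3N, units
#'   kJ mol^-1 nm^-2), `structure` and `pairs`.
#' @export
build_hessian <- function(s, params = enm_params(), cutoff = NULL) {
  validate_min_distance(s)
  n <- nrow(s$coordinates)
  pg <- pair_geometry(s, params, cutoff)
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_along(pg$i)) {
    i <- pg$i[p]; j <- pg$j[p]
    blk <- 2 * pg$k[p] * tcrossprod(pg$u[p, ])
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  structure(class = "enm_hessian",
            list(matrix = H, structure = s, pairs = pg, params = params,
                 cutoff = cutoff))
}

#' Elastic potential energy of a configuration
#'
#' Evaluates the full anharmonic network energy
#' `U(R) = sum_ij k(r0_ij) (|R_ij| - r0_ij)^2` for a displaced configuration;
#' used for curvature checks against the analytic Hessian.
#'
#' @param h an `enm_hessian` (carries the reference geometry and springs).
#' @param coordinates N x 3 matrix of displaced positions (nm).
#' @return energy in kJ mol^-1.
#' @export
potential_energy <- function(h, coordinates) {
  pg <- h$pairs
  dv <- coordinates[pg$j, , drop = FALSE] - coordinates[pg$i, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  sum(pg$k * (r - pg$r)^2)
}

# connectivity of the spring graph (for trivial-mode diagnostics)
network_connected <- function(n, i, j) {
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  adj <- split(c(j, i), c(i, j))
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Normal modes ---------------------------------------------------------------

#' Compute mass-weighted normal modes
#'
#' Full symmetric eigendecomposition of `M^(-1/2) H M^(-1/2)`. Eigenvalues
#' are the squared vibrational frequencies in model units
#' (kJ mol^-1 nm^-2 Da^-1). Trivial (rigid-body) modes are identified as the
#' eigenvalues below `trivial_tol * lambda_max` — six for a connected
#' three-dimensional network, five for collinear toys — and removed from the
#' returned set. More than six near-zero modes raise a warning, escalated to
#' an error when the spring graph is disconnected.
#'
#' @param h an `enm_hessian`.
#' @param masses per-atom masses in Da; defaults to the structure's residue
#'   masses. Pass `rep(1, N)` for uniform mass weighting.
#' @param trivial_tol relative eigenvalue threshold for the rigid-body null
#'   space.
#' @return object of class `mode_set`: `eigenvalues` (ascending, non-trivial),
#'   `vectors` (3N x M orthonormal mass-weighted eigenvectors),
#'   `displacements` (3N x M cartesian displacements `M^(-1/2) X`),
#'   `n_trivial`, `n_atoms`, `masses`, `all_eigenvalues`.
#' @export
compute_modes <- function(h, masses = NULL, trivial_tol = 1e-9) {
  if (is.null(masses)) masses <- h$structure$masses
  n <- length(masses)
  stopifnot(nrow(h$matrix) == 3 * n)
  w <- rep(1 / sqrt(masses), each = 3)
  Hw <- h$matrix * tcrossprod(w)
  Hw <- (Hw + t(Hw)) / 2
  e <- eigen(Hw, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  n_zero <- sum(vals < trivial_tol * max(vals))
  if (n_zero > 6L) {
    connected <- network_connected(n, h$pairs$i, h$pairs$j)
    if (!connected)
      flexcmp_error(sprintf(
        "spring network is disconnected: %d near-zero modes found", n_zero),
        "flexcmp_validation_error")
    warning(sprintf("%d near-zero modes found (expected at most 6)", n_zero),
            call. = FALSE)
  }
  keep <- seq.int(n_zero + 1L, length(vals))
  structure(class = "mode_set",
            list(eigenvalues = vals[keep],
                 vectors = vecs[, keep, drop = FALSE],
                 displacements = vecs[, keep, drop = FALSE] * w,
                 n_trivial = n_zero,
                 n_atoms = n,
                 masses = masses,
                 all_eigenvalues = vals))
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d atoms, %d non-trivial modes (%d trivial removed)\n",
              x$n_atoms, length(x$eigenvalues), x$n_trivial))
  invisible(x)
}

#' Keep the lowest-frequency non-trivial modes
#'
#' The single-structure analyses conventionally use at most the first 200
#' non-trivial modes; fewer are kept when fewer are available.
#'
#' @param modes a `mode_set`.
#' @param k number of modes to keep (default 200).
#' @return a `mode_set` with `min(k, available)` modes.
#' @export
truncate_modes <- function(modes, k = 200) {
  if (k < 1) flexcmp_error("mode count must be >= 1", "flexcmp_parse_error")
  keep <- seq_len(min(k, length(modes$eigenvalues)))
  modes$eigenvalues <- modes$eigenvalues[keep]
  modes$vectors <- modes$vectors[, keep, drop = FALSE]
  modes$displacements <- modes$displacements[, keep, drop = FALSE]
  modes
}
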