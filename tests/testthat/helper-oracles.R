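# Independent oracles and small utilities shared across test files.
# These deliberately re-derive quantities from first principles (loops,
# finite differences, direct determinants) rather than calling the package
# code paths they check.

# network energy coded independently of potential_energy(): explicit loops
# over pairs, piecewise force constant inlined
oracle_energy <- function(xyz, xyz0, a = 8.6e5, b = 2.39e5, cc = 128, d = 0.4) {
  n <- nrow(xyz0)
  U <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    r0 <- sqrt(sum((xyz0[i, ] - xyz0[j, ])^2))
    k <- if (r0 < d) a * r0 - b else cc * r0^-6
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    U <- U + k * (r - r0)^2
  }
  U
}

# central-difference Hessian of a scalar function of flattened coordinates
numeric_hessian <- function(f, x0, h = 1e-5) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pp <- pm <- mp <- mm <- x0
    pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * h^2)
  }
  H
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(s, R = random_rotation(), shift = rnorm(3)) {
  calpha_structure(sweep(s$coordinates %*% t(R), 2, shift, "+"),
                   structure_id = s$structure_id,
                   residue_labels = s$residue_labels)
}

# flattened rigid-body displacement fields (3 translations + 3 rotations)
rigid_basis <- function(coords) {
  n <- nrow(coords)
  cen <- sweep(coords, 2, colMeans(coords))
  trans <- lapply(1:3, function(k) rep(diag(3)[k, ], n))
  rots <- lapply(1:3, function(k) {
    ax <- diag(3)[k, ]
    as.numeric(t(t(apply(cen, 1, function(p) pracma_cross(ax, p)))))
  })
  do.call(cbind, c(trans, rots))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent superposition route: bio3d's fitting plus a linear solve for
# the rotation, applied to each mode vector of B
oracle_superposed_DB <- function(red_A, red_B) {
  D <- red_B$modes$displacements
  XA <- red_A$coordinates; XB <- red_B$coordinates
  if (is.null(XA) || is.null(XB)) return(D)
  fit <- matrix(suppressWarnings(
    bio3d::fit.xyz(bio3d::as.xyz(as.numeric(t(XA))),
                   bio3d::as.xyz(as.numeric(t(XB))))), ncol = 3, byrow = TRUE)
  R <- qr.solve(sweep(XB, 2, colMeans(XB)), sweep(fit, 2, colMeans(fit)))
  apply(D, 2, function(col)
    as.numeric(t(matrix(col, ncol = 3, byrow = TRUE) %*% R)))
}

# brute-force RMSIP: explicit double sum over normalised columns
oracle_rmsip <- function(red_A, red_B, k = 10) {
  DA <- red_A$modes$displacements
  DB <- oracle_superposed_DB(red_A, red_B)
  acc <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xi <- DA[, i] / sqrt(sum(DA[, i]^2))
    yj <- DB[, j] / sqrt(sum(DB[, j]^2))
    acc <- acc + sum(xi * yj)^2
  }
  sqrt(acc / k)
}

# brute-force BC: full covariances, the two rank reductions, direct det()
oracle_bc <- function(red_A, red_B, vp = 0.95, vj = 0.75) {
  DB_rot <- oracle_superposed_DB(red_A, red_B)
  cov_of <- function(red, D) {
    w <- 1 / red$modes$eigenvalues
    A <- matrix(0, nrow(D), nrow(D))
    n <- min(which(cumsum(w) / sum(w) >= vp))
    for (m in seq_len(n)) {
      dm <- D[, m] / sqrt(sum(D[, m]^2))
      A <- A + w[m] * dm %*% t(dm)
    }
    A / sum(diag(A))
  }
  A <- cov_of(red_A, red_A$modes$displacements)
  B <- cov_of(red_B, DB_rot)
  e <- eigen((A + B) / 2, symmetric = TRUE)
  s <- min(which(cumsum(e$values) / sum(e$values) >= vj))
  V <- e$vectors[, seq_len(s), drop = FALSE]
  At <- t(V) %*% A %*% V
  Bt <- t(V) %*% B %*% V
  exp(-(1 / (2 * s)) * log(det((At + Bt) / 2) / sqrt(det(At) * det(Bt))))
}

# a reduced_mode_set-shaped object with a prescribed spectrum and basis,
# for constructed similarity cases
synthetic_reduced <- function(eigenvalues, basis, id = "synthetic") {
  structure(class = "reduced_mode_set", list(
    effective_hessian = NULL,
    modes = list(eigenvalues = eigenvalues,
                 vectors = basis,
                 displacements = basis,
                 n_trivial = 0L,
                 n_atoms = nrow(basis) / 3,
                 masses = rep(1, nrow(basis) / 3)),
    conserved_residues = seq_len(nrow(basis) / 3),
    structure_id = id))
}

# tiny PDB writer for hand-crafted parser fixtures (Angstrom coordinates)
write_pdb_lines <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

atom_line <- function(serial, resname, chain, resno, x, y, z,
                      name4 = " CA ", alt = " ", occ = 1, type = "ATOM",
                      insert = " ") {
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00           C",
          type, serial, name4, alt, resname, chain, resno, insert, x, y, z, occ)
}
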